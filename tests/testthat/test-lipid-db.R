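test_that("species names build and parse as exact inverses", {
  expect_equal(build_species_name("PE", 33, 0, 1), "PE 33:0c1")
  expect_equal(build_species_name("PE", 34, 1), "PE 34:1")
  expect_equal(build_species_name("aPG", 50, 2), "aPG 50:2")

  p <- parse_species_name(c("PG 35:0c1", "PE 32:1"))
  expect_equal(p$class, c("PG", "PE"))
  expect_equal(p$total_carbons, c(35L, 32L))
  expect_equal(p$double_bonds, c(0L, 1L))
  expect_equal(p$cyclopropane, c(1L, 0L))

  expect_error(parse_species_name("XX 10:0"), "XX")
  expect_error(parse_species_name("PE 10-0"), "Malformed")
  expect_error(build_species_name("XX", 10, 0), "XX")

  # round trip over the full enumeration
  db <- lipid_database(db_config())
  rt <- parse_species_name(db$name)
  expect_equal(rt$class, db$class)
  expect_equal(rt$total_carbons, db$total_carbons)
  expect_equal(rt$double_bonds, db$double_bonds)
  expect_equal(rt$cyclopropane, db$cyclopropane)
})

test_that("molecular formulas match a structure-assembly oracle", {
  expect_equal(formula_string(molecular_formula("PE", 34, 1)), "C39H76NO8P")

  # two spot checks per class against independent structural assembly
  for (cl in lipid_classes()$class) {
    rng <- list(PA = c(32, 34), PE = c(32, 36), PG = c(30, 34),
                PS = c(32, 34), PGP = c(32, 34), `CDP-DAG` = c(32, 34),
                CL = c(66, 70), DLCL = c(30, 34), aPE = c(48, 50),
                aPG = c(48, 50), PBut = c(32, 34))[[cl]]
    for (tc in rng) {
      got <- molecular_formula(cl, tc, 1, 0)
      want <- oracle_species_formula(cl, tc, 1)
      expect_equal(unclass(got), want, ignore_attr = TRUE,
                   label = paste(cl, tc))
    }
  }

  # a cyclopropane ring is isobaric with one double bond
  expect_identical(molecular_formula("PE", 33, 0, 1),
                   molecular_formula("PE", 33, 1, 0))
  # a butyl ester is exactly C4H8 heavier than the free acid
  d <- unclass(molecular_formula("PBut", 32, 0)) -
    unclass(molecular_formula("PA", 32, 0))
  expect_equal(unname(d), c(4L, 8L, 0L, 0L, 0L))

  expect_error(molecular_formula("PE", 3, 0), "minimum")
})

test_that("deprotonated masses agree with an independent mass oracle", {
  f <- molecular_formula("PE", 34, 1)
  expect_equal(monoisotopic_mz(f), oracle_mz(unclass(f)), tolerance = 1e-9)
  expect_equal(monoisotopic_mz(f), 716.5236, tolerance = 1e-3)
  expect_error(monoisotopic_mz(elemental_formula(C = 2)), "hydrogen")

  # CH2 and H2 increments are exact across the whole database
  db <- lipid_database(db_config())
  for (cl in unique(db$class)) {
    d <- db[db$class == cl & db$cyclopropane == 0, ]
    ch2 <- dplyr::inner_join(d, d, by = c("double_bonds"),
                             relationship = "many-to-many")
    ch2 <- ch2[ch2$total_carbons.y == ch2$total_carbons.x + 1, ]
    if (nrow(ch2)) expect_equal(ch2$mz.y - ch2$mz.x,
                                rep(14.01565, nrow(ch2)), tolerance = 2e-5)
    h2 <- dplyr::inner_join(d, d, by = c("total_carbons"),
                            relationship = "many-to-many")
    h2 <- h2[h2$double_bonds.y == h2$double_bonds.x + 1, ]
    if (nrow(h2)) expect_equal(h2$mz.x - h2$mz.y,
                               rep(2.01565, nrow(h2)), tolerance = 2e-5)
  }
})

test_that("isotope ratios match brute-force polynomial expansion", {
  expect_equal(isotope_ratio("C39H76NO8P", 0), 1.0)
  n <- 39
  expect_equal(isotope_ratio("C39H76NO8P", 1), n * 0.011 / 0.989)
  expect_equal(isotope_ratio("C39H76NO8P", 2), 0.0917, tolerance = 1e-3)

  db <- lipid_database(db_config())
  for (f in unique(db$formula)) {
    nC <- unname(oracle_count_atoms(f)["C"])
    for (k in 0:2) {
      expect_equal(isotope_ratio(f, k), oracle_isotope_ratio(nC, k),
                   tolerance = 1e-6, label = paste(f, k))
    }
  }
  expect_error(isotope_ratio(elemental_formula(C = 1, H = 1), 2), "carbon")
  expect_error(isotope_ratio("C10H20", 3), "k must be")
})

test_that("database enumeration follows the configured combination rule", {
  cfg <- db_config(classes = list(
    PE = list(carbons = c(30, 36), max_mod = 2, cyclopropane = 1)))
  db <- lipid_database(cfg)
  # 7 carbon values x {(0,0),(1,0),(2,0),(0,1),(1,1)} = 35 entries
  expect_equal(nrow(db), 35L)

  full <- lipid_database(db_config())
  expect_equal(sum(full$canonical), 231L)
  expect_equal(length(unique(full$class)), 11L)
  expect_true(all(full$mz >= 350 & full$mz <= 1750))
  expect_false(any(duplicated(full[, c("class", "total_carbons",
                                       "double_bonds", "cyclopropane")])))
  # deterministic
  expect_identical(full, lipid_database(db_config()))
  expect_warning(db0 <- lipid_database(db_config(classes = list())),
                 "Empty")
  expect_equal(nrow(db0), 0L)
})

test_that("isobaric annotations share mass and resolve by carbon parity", {
  db <- lipid_database(db_config())
  for (cl in c("PE", "PG")) {
    a <- db[db$class == cl & db$double_bonds == 0 & db$cyclopropane == 1, ]
    b <- db[db$class == cl & db$double_bonds == 1 & db$cyclopropane == 0, ]
    j <- dplyr::inner_join(a, b, by = "total_carbons")
    expect_true(nrow(j) > 0)
    expect_equal(j$mz.x, j$mz.y, tolerance = 1e-12)
    expect_identical(j$formula.x, j$formula.y)
    # odd carbons -> the cyclopropane name is canonical
    expect_true(all(j$canonical.x == (j$total_carbons %% 2 == 1)))
    expect_true(all(j$canonical.y == (j$total_carbons %% 2 == 0)))
  }
})

test_that("database round-trips through CSV and JSON export", {
  db <- lipid_database(db_config(classes = list(
    PE = list(carbons = c(32, 34), max_mod = 1, cyclopropane = 1))))
  csv <- tempfile(fileext = ".csv")
  json <- tempfile(fileext = ".json")
  write_lipid_database(db, csv)
  write_lipid_database(db, json)
  back_csv <- read_lipid_database(csv)
  back_json <- read_lipid_database(json)
  expect_equal(back_csv$name, db$name)
  expect_equal(back_csv$mz, db$mz, tolerance = 1e-9)
  expect_equal(back_json$formula, db$formula)
})
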