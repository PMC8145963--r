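# A tiny hand-built feature table around three PE species and one PG
# species is enough to exercise matching, de-isotoping, filtering,
# forced integration and normalization deterministically.
tiny_db <- function() {
  lipid_database(db_config(classes = list(
    PE = list(carbons = c(32, 36), max_mod = 2, cyclopropane = 1),
    PG = list(carbons = c(32, 36), max_mod = 1, cyclopropane = 1))))
}

test_that("features match to species by m/z and class retention window", {
  db <- tiny_db()
  pe_rt <- db$rt_center[db$name == "PE 34:1"][1]
  ft <- tibble::tibble(
    mz = c(716.50, 716.60, 999.0, 716.52),
    rt = c(pe_rt, pe_rt, pe_rt, 0.45),
    s1 = c(100, 50, 20, 30), s2 = c(10, 5, 2, 3))
  lip <- match_features(ft, db)
  tab <- tidy(lip)
  # two features within tolerance in the PE window are summed onto
  # PE 34:1; the feature in a foreign window and the one with no mass
  # match stay unmatched
  expect_equal(tab$intensity[tab$species == "PE 34:1" &
                               tab$sample_id == "s1"], 150)
  expect_equal(nrow(unmatched_features(lip)), 2L)
  # matching is independent of feature order
  lip2 <- match_features(ft[c(3, 1, 4, 2), ], db)
  expect_equal(lipidome_matrix(lip2), lipidome_matrix(lip))
})

test_that("ambiguous retention times resolve to the nearest window center", {
  db <- tiny_db()
  # rt in the PG/aPG overlap region: PG window is 0.9-1.3 in the class
  # table, the neighbour starts at 1.2
  ft <- tibble::tibble(mz = db$mz[db$name == "PG 34:1"][1], rt = 1.25,
                       s1 = 10)
  lip <- match_features(ft, db)
  expect_true(any(grepl("overlapping windows",
                        processing_log(lip))) ||
                nrow(tidy(lip)) == 1) # only PG enumerated here
  expect_equal(lipidome_species(lip)$class, "PG")
})

test_that("deisotoping removes exactly the predicted A+2 overlap", {
  db <- tiny_db()
  pe_rt <- db$rt_center[db$name == "PE 34:2"][1]
  f342 <- db$formula[db$name == "PE 34:2"][1]
  r2 <- isotope_ratio(f342, 2)
  ft <- tibble::tibble(
    mz = c(db$mz[db$name == "PE 34:2"][1],
           db$mz[db$name == "PE 34:1"][1]),
    rt = pe_rt,
    s1 = c(1000, 1000 * r2),  # PE 34:1 signal is pure isotope overlap
    s2 = c(500, 300))
  lip <- deisotope(match_features(ft, db), db)
  m <- lipidome_matrix(lip)
  expect_equal(m["PE 34:1", "s1"], 0)
  expect_equal(m["PE 34:2", "s1"], 1000)
  # genuine signal is corrected, not zeroed
  expect_equal(m["PE 34:1", "s2"], 300 - 500 * r2)
  # never negative, idempotent on envelope-free input
  expect_true(all(m >= 0))
  iso_free <- match_features(ft[1, ], db)
  expect_equal(lipidome_matrix(deisotope(iso_free, db)),
               lipidome_matrix(iso_free))
})

test_that("noise filtering keeps species above threshold in enough samples", {
  db <- tiny_db()
  pe_rt <- db$rt_center[db$name == "PE 34:1"][1]
  ft <- tibble::tibble(
    mz = db$mz[match(c("PE 34:1", "PE 32:1", "PE 36:2"), db$name)],
    rt = pe_rt,
    s1 = c(1000, 90, 0), s2 = c(800, 80, 0))
  lip <- match_features(ft, db)
  kept <- noise_filter(lip, min_intensity = 100, min_samples = 1)
  expect_setequal(lipidome_species(kept)$name, c("PE 34:1"))
  # boundary: above threshold in exactly one sample is retained
  kept2 <- noise_filter(lip, min_intensity = 85, min_samples = 1)
  expect_true("PE 32:1" %in% lipidome_species(kept2)$name)
  # all-zero species are always removed
  expect_false("PE 36:2" %in% lipidome_species(kept2)$name)
})

test_that("forced integration completes the matrix and flags provenance", {
  db <- tiny_db()
  pe_rt <- db$rt_center[db$name == "PE 34:1"][1]
  ft <- tibble::tibble(
    mz = db$mz[match(c("PE 34:1", "PE 32:1"), db$name)],
    rt = pe_rt,
    s1 = c(1000, 40), s2 = c(900, 0))
  lip <- noise_filter(match_features(ft, db), min_intensity = 100,
                      min_samples = 1)
  # only PE 34:1 survives; re-attach PE 32:1 by relaxing the filter
  lip2 <- noise_filter(match_features(ft, db), min_intensity = 30,
                       min_samples = 1)
  done <- force_integrate(lip2, ft)
  tab <- tidy(done)
  expect_false(any(is.na(tab$intensity)))
  # the sub-threshold intensity in s1 is present as detected signal;
  # the truly absent cell is flagged force_integrated with value 0
  expect_equal(tab$intensity[tab$species == "PE 32:1" &
                               tab$sample_id == "s1"], 40)
  expect_equal(tab$provenance[tab$species == "PE 32:1" &
                                tab$sample_id == "s2"],
               "force_integrated")
  expect_equal(tab$intensity[tab$species == "PE 32:1" &
                               tab$sample_id == "s2"], 0)
})

test_that("normalization yields exact percent compositions", {
  db <- tiny_db()
  pe_rt <- db$rt_center[db$name == "PE 34:1"][1]
  ft <- tibble::tibble(
    mz = db$mz[match(c("PE 34:1", "PE 32:1"), db$name)],
    rt = pe_rt, s1 = c(3, 1), s2 = c(0, 0), s3 = c(5, 5))
  lip <- normalize_lipidome(match_features(ft, db))
  m <- lipidome_matrix(lip)
  expect_equal(unname(m[, "s1"]),
               if (rownames(m)[1] == "PE 32:1") c(25, 75) else c(75, 25))
  expect_equal(unname(colSums(m)), rep(100, ncol(m)), tolerance = 1e-12)
  # all-zero sample is dropped and reported
  expect_false("s2" %in% colnames(m))
  expect_equal(attr(lip, "dropped_samples"), "s2")
})

test_that("the full annotation pipeline recovers simulated ground truth", {
  st <- scaled_study()
  lip <- annotate_lipidome(st$features, st$database)
  m <- lipidome_matrix(lip)
  truth <- st$truth$compositions[, colnames(m), drop = FALSE]
  common <- intersect(rownames(m), rownames(truth))
  err <- abs(m[common, ] - truth[common, ])
  # per species: mean absolute deviation across samples below 1% point
  expect_lt(max(rowMeans(err)), 1)
  # species lost to the noise filter are all trace-level
  missing <- setdiff(rownames(truth), rownames(m))
  if (length(missing)) expect_lt(max(truth[missing, ]), 0.1)
  # exact closure
  expect_equal(unname(colSums(m)), rep(100, ncol(m)), tolerance = 1e-9)
})

test_that("a noise-free, envelope-free table round-trips exactly", {
  cfg <- study_config(seed = 19, n_constructs = 4, replicates = 2,
                      control_replicates = 2, feature_cv = 0,
                      decoy_rate = 0, detection_limit = 0,
                      emit_isotopes = FALSE, bio_cv = 0)
  st <- simulate_study(cfg)
  lip <- annotate_lipidome(st$features, st$database,
                           correct_isotopes = FALSE)
  m <- lipidome_matrix(lip)
  truth <- st$truth$compositions[rownames(m), colnames(m)]
  expect_equal(m, truth, tolerance = 1e-9)
})
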