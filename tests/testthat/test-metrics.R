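long_lip <- function(mat) {
  tidyr::pivot_longer(
    dplyr::bind_cols(tibble::tibble(species = rownames(mat)),
                     tibble::as_tibble(mat)),
    cols = -"species", names_to = "sample_id", values_to = "intensity")
}

test_that("acyl properties are chain-weighted means of the composition", {
  one <- tibble::tibble(species = "PE 34:1", sample_id = "s1",
                        intensity = 100)
  p <- acyl_properties(one)
  expect_equal(p$mean_chain_length, 17)
  expect_equal(p$unsaturation_index, 0.5)
  expect_equal(p$cyclopropane_fraction, 0)

  # CL contributes 4 chains per mole: 50/50 PE 32:0 + CL 64:0 has
  # 16-carbon chains throughout
  two <- tibble::tibble(species = c("PE 32:0", "CL 64:0"),
                        sample_id = "s1", intensity = c(50, 50))
  expect_equal(acyl_properties(two)$mean_chain_length, 16)
  # chain weighting differs from mole weighting when chain counts differ
  three <- tibble::tibble(species = c("PE 32:0", "CL 72:0"),
                          sample_id = "s1", intensity = c(50, 50))
  expect_equal(acyl_properties(three)$mean_chain_length,
               (2 * 16 + 4 * 18) / 6)
  expect_equal(acyl_properties(three, weighting = "mole")$mean_chain_length,
               (16 + 18) / 2)

  # scale invariance in the percent scale
  sc <- dplyr::mutate(two, intensity = intensity * 7)
  expect_equal(acyl_properties(sc), acyl_properties(two))

  # removing a species at the current mean leaves the mean unchanged
  four <- tibble::tibble(species = c("PE 32:0", "PE 36:0", "PG 34:0"),
                         sample_id = "s1", intensity = c(30, 30, 40))
  expect_equal(acyl_properties(four)$mean_chain_length, 17)
  expect_equal(acyl_properties(four[1:2, ])$mean_chain_length, 17)

  expect_error(acyl_properties(one[0, ]), "Empty")
})

test_that("butanol Z-scores read the butanol group against controls", {
  mat <- rbind("PE 34:1" = c(10, 10, 10, 12, 12, 12),
               "PE 32:1" = c(5, 6, 7, 6, 6, 6),
               "PG 34:1" = c(3, 3, 3, 3, 3, 3))
  colnames(mat) <- paste0("s", 1:6)
  meta <- tibble::tibble(sample_id = paste0("s", 1:6),
                         butanol = c(0, 0, 0, 1, 1, 1))
  z <- butanol_zscore(long_lip(mat), meta)
  # zero control variance -> undefined, flagged
  expect_true(is.na(z$z[z$species == "PE 34:1"]))
  expect_match(z$note[z$species == "PE 34:1"], "zero control variance")
  # identical groups -> Z = 0 (constant species also undefined)
  expect_equal(z$z[z$species == "PE 32:1"], 0)
  expect_true(is.na(z$z[z$species == "PG 34:1"]))
  # sign convention: higher under butanol is positive
  mat2 <- rbind("PE 34:1" = c(10, 11, 9, 14, 15, 13))
  colnames(mat2) <- paste0("s", 1:6)
  z2 <- butanol_zscore(long_lip(mat2), meta)
  expect_gt(z2$z, 0)
  expect_error(butanol_zscore(long_lip(mat), meta[meta$butanol == 0, ]),
               "control")
})

test_that("PBut scores among the top butanol responders in ClsB cultures", {
  st <- scaled_study()
  lip <- annotate_lipidome(st$features, st$database)
  meta <- st$metadata
  clsb <- meta$sample_id[meta$gene == "clsB" & meta$construct_type == "OV"]
  z <- butanol_zscore(lip, meta, samples = clsb)
  pbut <- z[grepl("^PBut", z$species), ]
  expect_true(nrow(pbut) > 0)
  # induced from exactly zero: present with butanol, absent without, so
  # the Z-score is degenerate (infinite) and flagged as undefined
  expect_gt(max(pbut$mean_butanol), 0)
  expect_equal(max(pbut$mean_control), 0)
  expect_true(all(is.na(pbut$z)))
  expect_match(pbut$note[which.max(pbut$mean_butanol)], "zero control")
})

test_that("correlation structure recovers planted co-regulation blocks", {
  set.seed(77)
  n <- 60
  blocks <- list(paste0("PE 3", 0:4, ":1"), paste0("PG 3", 0:4, ":1"),
                 paste0("PA 3", 1:5, ":0"))
  factors <- matrix(rnorm(3 * n), nrow = 3)
  mat <- do.call(rbind, purrr::imap(blocks, function(sp, b) {
    m <- matrix(rep(factors[b, ], each = length(sp)), nrow = length(sp))
    m + matrix(rnorm(length(sp) * n, sd = 0.1), nrow = length(sp)) + 10
  }))
  rownames(mat) <- unlist(blocks)
  colnames(mat) <- paste0("s", seq_len(n))
  cs <- correlation_structure(long_lip(mat), k = 3)
  expect_equal(dim(cs$correlation), c(15, 15))
  expect_true(all(abs(cs$correlation) <= 1 + 1e-12))
  expect_equal(unname(diag(cs$correlation)), rep(1, 15))
  truth_lab <- rep(seq_along(blocks), lengths(blocks))
  names(truth_lab) <- unlist(blocks)
  ari <- mclust::adjustedRandIndex(
    cs$clusters$cluster, truth_lab[cs$clusters$species])
  expect_gte(ari, 0.9)

  # permutation of samples leaves the structure unchanged
  cs2 <- correlation_structure(long_lip(mat[, sample(n)]), k = 3)
  expect_equal(cs2$correlation, cs$correlation, tolerance = 1e-12)

  # exact co-variation and anti-variation
  two <- rbind("PE 34:1" = c(1, 2, 3, 4), "PE 34:2" = c(2, 4, 6, 8),
               "PG 34:1" = c(4, 3, 2, 1))
  colnames(two) <- paste0("s", 1:4)
  cs3 <- correlation_structure(long_lip(two), k = 2)
  expect_equal(cs3$correlation["PE 34:1", "PE 34:2"], 1)
  expect_equal(cs3$correlation["PE 34:1", "PG 34:1"], -1)
  expect_equal(cs3$hclust$merge[1, ], c(-1, -2)) # r = 1 pair merges first

  # constant species are excluded with a record
  withc <- rbind(two, "PA 34:0" = c(5, 5, 5, 5))
  cs4 <- correlation_structure(long_lip(withc), k = 2)
  expect_equal(cs4$excluded, "PA 34:0")
  expect_error(correlation_structure(long_lip(two[, 1:2])), "3 samples")
})

test_that("dendrogram exports as readable newick", {
  two <- rbind("A" = c(1, 2, 3, 4), "B" = c(2, 4, 6, 9),
               "C" = c(4, 3, 2, 1))
  rownames(two) <- c("PE 34:1", "PE 34:2", "PG 34:1")
  colnames(two) <- paste0("s", 1:4)
  cs <- correlation_structure(long_lip(two), k = 2)
  f <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(cs, f)
  tr <- ape::read.tree(f)
  # spaces and colons are not legal in bare newick labels; ape
  # substitutes them on write
  expect_setequal(tr$tip.label,
                  gsub(":", "-", gsub(" ", "_", rownames(two))))
})

test_that("class annotation bars align with clustering leaves", {
  bars <- class_annotation_bars(c("aPG 49:1c1", "PE 36:2"))
  expect_equal(bars$class, c("aPG", "PE"))
  expect_equal(bars$double_bonds, c(1L, 2L))
  expect_equal(bars$cyclopropane, c(TRUE, FALSE))
  expect_error(class_annotation_bars("nonsense"), "Malformed")

  two <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 9), c(4, 3, 2, 1))
  rownames(two) <- c("PE 34:1", "PE 34:2", "PG 34:1")
  colnames(two) <- paste0("s", 1:4)
  cs <- correlation_structure(long_lip(two), k = 2)
  bars2 <- class_annotation_bars(cs)
  expect_equal(nrow(bars2), 3L)
  expect_setequal(bars2$species, rownames(two))
})

test_that("butanol reduces the cyclopropane fraction as planted", {
  st <- scaled_study()
  lip <- annotate_lipidome(st$features, st$database)
  meta <- st$metadata
  ap <- dplyr::left_join(acyl_properties(lip), meta, by = "sample_id")
  wt <- ap[ap$construct_type %in% c("WT", "EV"), ]
  expect_lt(mean(wt$cyclopropane_fraction[wt$butanol == 1]),
            mean(wt$cyclopropane_fraction[wt$butanol == 0]))
})
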