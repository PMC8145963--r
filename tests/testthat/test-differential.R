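test_that("marker selection is reproducible and flags uninformative data", {
  set.seed(5)
  x <- matrix(rnorm(40 * 12, 10), nrow = 40,
              dimnames = list(NULL, paste0("sp", 1:12)))
  y <- rep(c("a", "b"), each = 20)
  # pure noise: classifier sits at chance, which is flagged
  p0 <- rf_select_markers(x, y, n_trees = 60, seed = 3, cv_folds = 0)
  expect_true(p0$noninformative)

  # two informative species out of twelve
  x2 <- x
  x2[y == "b", 1] <- x2[y == "b", 1] + 4
  x2[y == "b", 2] <- x2[y == "b", 2] - 4
  p1 <- rf_select_markers(x2, y, n_trees = 60, seed = 3, cv_folds = 3)
  expect_false(p1$noninformative)
  expect_true(all(c("sp1", "sp2") %in% p1$panel))
  expect_lt(p1$cv_error, 0.2)
  # bit-for-bit reproducible under the same seed
  p2 <- rf_select_markers(x2, y, n_trees = 60, seed = 3, cv_folds = 3)
  expect_identical(p1$panel, p2$panel)
  expect_identical(p1$trace, p2$trace)
  # the trace covers every elimination step down to the floor
  expect_equal(p1$trace$n_features[1], 12)
  expect_equal(min(p1$trace$n_features), 2)

  expect_error(rf_select_markers(x, rep("a", 40), n_trees = 10), "two classes")
  expect_error(rf_select_markers(x, y, cv_folds = 100), "folds")
})

test_that("marker summary reports averages and construct extremes", {
  st <- scaled_study()
  lip <- annotate_lipidome(st$features, st$database)
  meta <- st$metadata
  panel <- intersect(st$truth$marker_species,
                     lipidome_species(lip)$name)
  ms <- marker_summary(panel, lip, meta)
  expect_setequal(ms$species, panel)
  expect_true(all(ms$min_pct <= ms$average_pct + 1e-9))
  expect_true(all(ms$average_pct <= ms$max_pct + 1e-9))
  expect_true(is.finite(attr(ms, "panel_total_ref_pct")))
  absent <- setdiff(st$database$name, lipidome_species(lip)$name)[1]
  expect_error(marker_summary(absent, lip, meta), "absent")

  # a construct planted to maximize a marker is found as its argmax
  drv <- st$truth$marker_drivers
  strong <- drv[drv$marker == "PE 34:1" & drv$log_effect > 0, ]
  if (nrow(strong) > 0) {
    row <- ms[ms$species == "PE 34:1", ]
    expect_true(grepl("\\(OV\\)|\\(KO\\)", row$max_construct))
  }
})

test_that("gene tags count top and bottom constructs per marker", {
  st <- scaled_study()
  lip <- annotate_lipidome(st$features, st$database)
  meta <- st$metadata
  panel <- intersect(st$truth$marker_species,
                     lipidome_species(lip)$name)
  tags <- gene_tag_counts(panel, lip, meta, k = 5)
  expect_equal(sum(tags$n), length(panel) * 10)
  expect_true(all(tags$n <= 2 * length(panel)))
  expect_true(all(tags$gene %in% meta$gene))
  expect_error(gene_tag_counts(panel, lip, meta, k = 50), "constructs")
})

test_that("regularized ANOVA reduces to the classical test at conf = 0", {
  set.seed(31)
  x <- matrix(rnorm(60 * 15, 10), nrow = 60,
              dimnames = list(paste0("sp", 1:60), NULL))
  g <- rep(c("a", "b", "c"), each = 5)
  res <- cybert_anova(x, g, window = 21, conf = 0)
  f_classic <- apply(x, 1, function(v)
    summary(stats::aov(v ~ factor(g)))[[1]][["F value"]][1])
  p_classic <- apply(x, 1, function(v)
    summary(stats::aov(v ~ factor(g)))[[1]][["Pr(>F)"]][1])
  expect_equal(unname(res$f), unname(f_classic), tolerance = 1e-8)
  expect_equal(unname(res$p), unname(p_classic), tolerance = 1e-8)
})

test_that("regularization shrinks variance dispersion and keeps order-invariance", {
  set.seed(32)
  x <- matrix(rnorm(120 * 12, 10, sd = rep(runif(120, 0.5, 2), 12)),
              nrow = 120, dimnames = list(paste0("sp", 1:120), NULL))
  g <- rep(c("a", "b"), each = 6)
  res <- cybert_anova(x, g, window = 31, conf = 5)
  expect_lt(stats::var(res$s2_reg), stats::var(res$s2))
  expect_true(all(res$p_adj >= res$p - 1e-12))
  expect_true(all(res$p >= 0 & res$p <= 1))

  perm <- sample(nrow(x))
  res_perm <- cybert_anova(x[perm, ], g, window = 31, conf = 5)
  expect_equal(res_perm$p[match(res$species, res_perm$species)], res$p,
               tolerance = 1e-12)

  expect_warning(cybert_anova(x[1:5, ], g, window = 31), "clipped")
  expect_error(cybert_anova(x, rep("a", 12)), "two groups")
  expect_error(cybert_anova(x[, 1:3], c("a", "a", "b")), ">= 2 samples")
})

test_that("a planted two-fold shift is detected at n = 3 per group", {
  set.seed(33)
  n_sp <- 120
  x <- matrix(exp(rnorm(n_sp * 6, 0, 0.15)) *
                rep(exp(runif(n_sp, -2, 2)), 6), nrow = n_sp,
              dimnames = list(paste0("sp", 1:n_sp), NULL))
  g <- rep(c("ctl", "trt"), each = 3)
  shifted <- sample(n_sp, 10)
  x[shifted, g == "trt"] <- x[shifted, g == "trt"] * 2
  res <- cybert_anova(x, g, window = 31, conf = 5)
  hit <- res$species[res$significant]
  expect_gte(sum(paste0("sp", shifted) %in% hit), 8)
  # and few false positives
  expect_lte(sum(!hit %in% paste0("sp", shifted)), 10)
})

test_that("the recovered marker core is stable across forest seeds", {
  st <- scaled_study()
  lip <- annotate_lipidome(st$features, st$database)
  meta <- st$metadata[match(colnames(lipidome_matrix(lip)),
                            st$metadata$sample_id), ]
  labels <- paste0(
    ifelse(meta$construct_type %in% c("WT", "EV"), meta$construct_type,
           paste0(meta$gene, ":", meta$construct_type)),
    ":", meta$butanol)
  panels <- lapply(1:3, function(s)
    rf_select_markers(lip, labels, n_trees = 100, seed = s,
                      cv_folds = 0, panel_size = 10)$panel)
  mk <- st$truth$marker_species
  cores <- lapply(panels, intersect, x = mk)
  shared <- Reduce(intersect, cores)
  expect_gte(length(shared), 8)
  jac <- combn(3, 2, function(ij)
    length(intersect(panels[[ij[1]]], panels[[ij[2]]])) /
      length(union(panels[[ij[1]]], panels[[ij[2]]])))
  expect_gte(min(jac), 0.6)
})
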