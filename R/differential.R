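#' Marker-lipid selection by random-forest backward elimination
#'
#' Trains a random-forest classifier on the species x sample matrix and
#' repeatedly eliminates the least important feature(s), tracking the
#' out-of-bag (OOB) error at every step. The returned panel is the
#' smallest feature set whose OOB error is within `tolerance_se` standard
#' errors of the minimum over the whole elimination trace (a 1-SE rule).
#' The run is reproducible bit-for-bit under `seed`.
#'
#' @param x A lipidome, or a numeric matrix/data frame with samples in
#'   rows and species in columns.
#' @param labels Factor (or coercible) of class labels, one per sample --
#'   typically the joint genetic-construct x butanol label.
#' @param n_trees Trees per forest (default 500).
#' @param drop_fraction Fraction of remaining features eliminated per
#'   iteration (default 0.1, at least one); set small for strict
#'   one-at-a-time elimination.
#' @param min_features Stop when this many features remain (default 2).
#' @param tolerance_se Panel-size rule: smallest panel within this many
#'   standard errors of the minimum OOB error (default 1).
#' @param panel_size Optional fixed panel size: return the `panel_size`
#'   features that survive elimination longest (the "top-k panel" of a
#'   screening study) instead of applying the OOB tolerance rule.
#'   Redundant species can substitute for one another, so the
#'   OOB-optimal panel size fluctuates between datasets; a fixed-size
#'   panel is the stable way to compare against a reference panel.
#' @param cv_folds If > 0, additionally estimate the selected panel's
#'   accuracy by k-fold cross-validation (default 10; 0 to skip).
#' @param seed Integer seed controlling all forest randomness.
#' @param importance Importance measure, `"gini"` (default) or
#'   `"permutation"`.
#' @return Object of class `marker_panel`: list with `panel` (species,
#'   ranked by final importance), `trace` (tibble `step`, `n_features`,
#'   `oob_error`), `oob_error`, `cv_error`, `importance` (tibble for the
#'   selected panel), `noninformative` (TRUE when even the full forest is
#'   at chance level).
#' @export
rf_select_markers <- function(x, labels, n_trees = 500, drop_fraction = 0.1,
                              min_features = 2, tolerance_se = 1,
                              panel_size = NULL, cv_folds = 10, seed = 1,
                              importance = c("gini", "permutation")) {
  importance <- match.arg(importance)
  if (inherits(x, "lipidome")) x <- t(lipidome_matrix(x))
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nrow(x) != length(labels)) abort("One label per sample is required.")
  if (nlevels(labels) < 2) abort("At least two classes are required.")
  if (cv_folds > nrow(x)) abort("Fewer samples than cross-validation folds.")
  stopifnot(n_trees >= 1)
  colnames(x) <- colnames(x) %||% paste0("V", seq_len(ncol(x)))

  set.seed(seed)
  features <- colnames(x)
  trace <- list()
  sets <- list()
  step <- 0L
  imp_col <- if (importance == "gini") "MeanDecreaseGini" else
    "MeanDecreaseAccuracy"
  repeat {
    step <- step + 1L
    rf <- randomForest::randomForest(
      x[, features, drop = FALSE], labels, ntree = n_trees,
      importance = (importance == "permutation"))
    err <- mean(rf$err.rate[n_trees, "OOB"])
    trace[[step]] <- tibble(step = step, n_features = length(features),
                            oob_error = err)
    sets[[step]] <- features
    if (length(features) <= min_features) break
    imp <- randomForest::importance(rf)[, imp_col]
    n_drop <- max(1L, floor(drop_fraction * length(features)))
    n_drop <- min(n_drop, length(features) - min_features)
    features <- features[!features %in%
                           names(sort(imp))[seq_len(n_drop)]]
  }
  trace <- dplyr::bind_rows(trace)
  e_min <- min(trace$oob_error)
  se <- sqrt(e_min * (1 - e_min) / nrow(x))
  if (is.null(panel_size)) {
    ok <- which(trace$oob_error <= e_min + tolerance_se * se)
    chosen <- ok[which.min(trace$n_features[ok])]
  } else {
    chosen <- which(trace$n_features >= panel_size)
    chosen <- chosen[which.min(trace$n_features[chosen])]
  }
  panel <- sets[[chosen]]
  if (!is.null(panel_size) && length(panel) > panel_size) {
    # keep the features that survive elimination longest
    survival <- vapply(panel, function(p) {
      max(which(vapply(sets, function(st) p %in% st, logical(1))))
    }, numeric(1))
    panel <- panel[order(-survival)][seq_len(panel_size)]
  }

  # refit on the panel to rank members by importance
  rf_panel <- randomForest::randomForest(
    x[, panel, drop = FALSE], labels, ntree = n_trees, importance = TRUE)
  imp_panel <- randomForest::importance(rf_panel)[, "MeanDecreaseGini"]
  panel <- names(sort(imp_panel, decreasing = TRUE))

  chance <- 1 - max(table(labels)) / length(labels)
  full_err <- trace$oob_error[1]
  cv_error <- NA_real_
  if (cv_folds > 0) {
    folds <- sample(rep(seq_len(cv_folds), length.out = nrow(x)))
    pred <- factor(rep(NA_character_, nrow(x)), levels = levels(labels))
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      if (nlevels(droplevels(labels[tr])) < 2) next
      fit <- randomForest::randomForest(x[tr, panel, drop = FALSE],
                                        droplevels(labels[tr]),
                                        ntree = n_trees)
      pred[!tr] <- as.character(stats::predict(fit,
                                               x[!tr, panel, drop = FALSE]))
    }
    cv_error <- mean(pred != labels, na.rm = TRUE)
  }

  structure(list(
    panel = panel,
    trace = trace,
    oob_error = trace$oob_error[chosen],
    cv_error = cv_error,
    importance = tibble(species = names(sort(imp_panel, decreasing = TRUE)),
                        importance = unname(sort(imp_panel,
                                                 decreasing = TRUE))),
    noninformative = full_err >= chance - 2 * se,
    n_trees = n_trees, seed = seed
  ), class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("<marker_panel> ", length(x$panel), " species, OOB error ",
      sprintf("%.3f", x$oob_error),
      if (!is.na(x$cv_error)) sprintf(", CV error %.3f", x$cv_error), "\n",
      sep = "")
  if (isTRUE(x$noninformative))
    cat("  note: classifier at chance level; panel is non-informative\n")
  cat("  ", paste(x$panel, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.marker_panel <- function(x, ...) x$importance

#' @export
glance.marker_panel <- function(x, ...) {
  tibble(n_panel = length(x$panel), oob_error = x$oob_error,
         cv_error = x$cv_error, noninformative = x$noninformative)
}

construct_label <- function(metadata) {
  ifelse(metadata$construct_type %in% c("WT", "EV"),
         metadata$construct_type,
         paste0(metadata$gene, " (", metadata$construct_type, ")"))
}

#' Marker panel summary table
#'
#' Per marker: its average percent contribution over all samples (and
#' over the wild-type reference group), and the maximum and minimum
#' per-construct mean abundances together with the constructs attaining
#' them -- the "which gene pushed this lipid to its extremes" ledger.
#'
#' @param panel A `marker_panel` or character vector of species.
#' @param lipidome A normalized lipidome.
#' @param metadata Sample metadata (`sample_id`, `gene`,
#'   `construct_type`, `butanol`).
#' @param reference_group Construct type used for the reference total
#'   (default `"WT"`).
#' @return Tibble with `species`, `average_pct`, `average_ref_pct`,
#'   `max_pct`, `max_construct`, `min_pct`, `min_construct`; the summed
#'   panel contribution in the reference group is attached as attribute
#'   `panel_total_ref_pct`.
#' @export
marker_summary <- function(panel, lipidome, metadata,
                           reference_group = "WT") {
  if (inherits(panel, "marker_panel")) panel <- panel$panel
  tab <- as_tibble(lipidome)
  missing_sp <- setdiff(panel, unique(tab$species))
  if (length(missing_sp) > 0) {
    abort(paste0("Marker(s) absent from lipidome: ",
                 paste(missing_sp, collapse = ", ")))
  }
  meta <- as_tibble(metadata)
  meta$construct <- construct_label(meta)
  tab <- dplyr::inner_join(tab[tab$species %in% panel, ],
                           meta[, c("sample_id", "construct",
                                    "construct_type")],
                           by = "sample_id")
  by_construct <- dplyr::summarise(
    dplyr::group_by(tab, .data$species, .data$construct),
    mean_pct = mean(.data$intensity), .groups = "drop")
  out <- dplyr::summarise(
    dplyr::group_by(tab, .data$species),
    average_pct = mean(.data$intensity),
    average_ref_pct = mean(.data$intensity[.data$construct_type ==
                                             reference_group]),
    .groups = "drop")
  extremes <- dplyr::summarise(
    dplyr::group_by(by_construct, .data$species),
    max_pct = max(.data$mean_pct),
    max_construct = .data$construct[which.max(.data$mean_pct)],
    min_pct = min(.data$mean_pct),
    min_construct = .data$construct[which.min(.data$mean_pct)],
    .groups = "drop")
  out <- dplyr::left_join(out, extremes, by = "species")
  out <- out[order(-out$average_pct), ]
  ref_tab <- tab[tab$construct_type == reference_group, , drop = FALSE]
  total_ref <- if (nrow(ref_tab) > 0) {
    per_sample <- dplyr::summarise(
      dplyr::group_by(ref_tab, .data$sample_id),
      s = sum(.data$intensity), .groups = "drop")
    mean(per_sample$s)
  } else NA_real_
  attr(out, "panel_total_ref_pct") <- total_ref
  out
}

#' Gene tag counts over marker extremes
#'
#' For every marker lipid, the `k` genetic constructs with the highest
#' and the `k` with the lowest mean abundance contribute one tag each
#' (gene symbol); tags are counted over all markers. With a 10-species
#' panel and k = 5 this yields 100 tags -- the tabular form of a gene
#' tag cloud.
#'
#' @inheritParams marker_summary
#' @param k Number of top and bottom constructs per marker (default 5).
#' @return Tibble with `gene`, `n`, sorted by decreasing count.
#' @export
gene_tag_counts <- function(panel, lipidome, metadata, k = 5) {
  if (inherits(panel, "marker_panel")) panel <- panel$panel
  meta <- as_tibble(metadata)
  meta <- meta[meta$construct_type %in% c("KO", "OV"), , drop = FALSE]
  meta$construct <- construct_label(meta)
  n_constructs <- length(unique(meta$construct))
  if (n_constructs < 2 * k) {
    abort(sprintf("Need at least %d constructs for k = %d.", 2 * k, k))
  }
  tab <- dplyr::inner_join(
    as_tibble(lipidome)[as_tibble(lipidome)$species %in% panel, ],
    meta[, c("sample_id", "construct", "gene")], by = "sample_id")
  by_construct <- dplyr::summarise(
    dplyr::group_by(tab, .data$species, .data$construct, .data$gene),
    mean_pct = mean(.data$intensity), .groups = "drop")
  tags <- dplyr::reframe(
    dplyr::group_by(by_construct, .data$species),
    gene = {
      # top and bottom k constructs, kept disjoint when ties (e.g. many
      # zero-abundance constructs) would otherwise overlap
      top <- order(-.data$mean_pct)[seq_len(k)]
      bottom <- setdiff(order(.data$mean_pct), top)[seq_len(k)]
      c(.data$gene[top], .data$gene[bottom])
    })
  out <- dplyr::count(tags, .data$gene, sort = TRUE)
  out
}

#' Bayes-regularized one-way ANOVA across lipidomes
#'
#' Per-species one-way ANOVA in which the pooled within-group variance is
#' shrunk toward a background variance estimated from species of similar
#' abundance, stabilizing tests for low-replicate designs (the Cyber-T
#' approach). Species are ranked by overall mean abundance; the
#' background variance of a species is the mean pooled within-group
#' variance over a sliding window of `window` species centered on its
#' rank. With `df_w = N - k` within-group degrees of freedom the
#' regularized variance is
#' \deqn{s^2_{reg} = (conf \cdot s^2_{bg} + df_w \cdot s^2) /
#'   (conf + df_w),}
#' i.e. `conf` pseudo-observations of the background; the F statistic
#' uses this denominator with `conf + df_w` denominator degrees of
#' freedom. At `conf = 0` the test is exactly the classical one-way
#' ANOVA. P-values are Benjamini-Hochberg adjusted; species with
#' adjusted p below `alpha` are flagged significant.
#'
#' @param x A lipidome, or a numeric matrix with species in rows and
#'   samples in columns.
#' @param groups Factor (or coercible) of group labels, one per sample;
#'   at least two groups with two samples each.
#' @param window Sliding-window size in species for the background
#'   variance (default 101; clipped with a warning when larger than the
#'   species count).
#' @param conf Bayes confidence value: weight of the background variance
#'   in pseudo-observations (default 5).
#' @param alpha Significance threshold on the adjusted p-value
#'   (default 0.05).
#' @return Tibble with `species`, `mean_abundance`, `f`, `p`, `p_adj`,
#'   `significant`, `s2`, `s2_bg`, `s2_reg`; the window actually used is
#'   attached as attribute `window`.
#' @export
cybert_anova <- function(x, groups, window = 101, conf = 5, alpha = 0.05) {
  if (inherits(x, "lipidome")) x <- lipidome_matrix(x)
  x <- as.matrix(x)
  groups <- factor(groups)
  if (ncol(x) != length(groups)) abort("One group label per sample.")
  if (nlevels(groups) < 2) abort("At least two groups are required.")
  if (any(table(groups) < 2)) abort("Each group needs >= 2 samples.")
  stopifnot(conf >= 0)
  n_species <- nrow(x)
  if (window > n_species) {
    warn(sprintf("Window (%d) larger than species count (%d); clipped.",
                 window, n_species))
    window <- n_species
  }
  if (window %% 2 == 0) window <- window - 1

  N <- ncol(x)
  k <- nlevels(groups)
  df_b <- k - 1
  df_w <- N - k
  grand <- rowMeans(x)
  g_idx <- split(seq_len(N), groups)
  g_n <- lengths(g_idx)
  g_means <- vapply(g_idx, function(j) rowMeans(x[, j, drop = FALSE]),
                    numeric(n_species))
  ssb <- rowSums(sweep(sweep(g_means, 1, grand)^2, 2, g_n, `*`))
  ssw <- rowSums(vapply(seq_along(g_idx), function(gi) {
    rowSums((x[, g_idx[[gi]], drop = FALSE] - g_means[, gi])^2)
  }, numeric(n_species)))
  s2 <- ssw / df_w

  # background variance: rolling mean of s2 over abundance rank
  ord <- order(grand)
  half <- (window - 1) / 2
  s2_bg_ord <- vapply(seq_len(n_species), function(i) {
    lo <- max(1, min(i - half, n_species - window + 1))
    hi <- min(n_species, lo + window - 1)
    mean(s2[ord][lo:hi])
  }, numeric(1))
  s2_bg <- numeric(n_species)
  s2_bg[ord] <- s2_bg_ord

  s2_reg <- (conf * s2_bg + df_w * s2) / (conf + df_w)
  f <- (ssb / df_b) / s2_reg
  p <- stats::pf(f, df_b, conf + df_w, lower.tail = FALSE)
  p[s2_reg == 0 & ssb == 0] <- 1
  p[s2_reg == 0 & ssb > 0] <- 0
  p_adj <- stats::p.adjust(p, method = "BH")
  out <- tibble(species = rownames(x) %||% paste0("S", seq_len(n_species)),
                mean_abundance = grand,
                f = f, p = p, p_adj = p_adj,
                significant = p_adj < alpha,
                s2 = s2, s2_bg = s2_bg, s2_reg = s2_reg)
  attr(out, "window") <- window
  attr(out, "conf") <- conf
  out
}
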