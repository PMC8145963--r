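#' Membrane acyl properties per sample
#'
#' Chain-weighted mean acyl chain length (carbons per chain), unsaturation
#' index (double bonds per chain) and cyclopropane fraction (rings per
#' chain) of each sample's composition. With species weight
#' \eqn{w_i = \mathrm{percent}_i \times n_{chains,i}} (a cardiolipin
#' contributes four chains per mole, a headgroup acylate three), the mean
#' chain length is \eqn{\sum_i w_i (C_i/n_{chains,i}) / \sum_i w_i}, and
#' analogously for double bonds and rings. Mole weighting (each species
#' weighted by its percent alone) is available via `weighting`.
#'
#' @param lipidome A normalized lipidome (or any long tibble with
#'   `species`, `sample_id`, `intensity`).
#' @param weighting `"chain"` (default, physically meaningful) or
#'   `"mole"`.
#' @return Tibble with `sample_id`, `mean_chain_length`,
#'   `unsaturation_index`, `cyclopropane_fraction`.
#' @examples
#' # a membrane of pure PE 34:1 has 17-carbon chains, half of them
#' # unsaturated:
#' lip <- tibble::tibble(species = "PE 34:1", sample_id = "s1",
#'                       intensity = 100)
#' acyl_properties(lip)
#' @export
acyl_properties <- function(lipidome, weighting = c("chain", "mole")) {
  weighting <- match.arg(weighting)
  tab <- as_tibble(lipidome)
  if (nrow(tab) == 0) abort("Empty composition: no acyl properties.")
  info <- parse_species_name(unique(tab$species))
  info$n_chains <- lipid_classes()$n_chains[match(info$class,
                                                  lipid_classes()$class)]
  tab <- dplyr::left_join(tab, info, by = c("species" = "name"))
  tab$w <- tab$intensity * if (weighting == "chain") tab$n_chains else 1
  out <- dplyr::summarise(
    dplyr::group_by(tab, .data$sample_id),
    mean_chain_length = sum(.data$w * .data$total_carbons /
                              .data$n_chains) / sum(.data$w),
    unsaturation_index = sum(.data$w * .data$double_bonds /
                               .data$n_chains) / sum(.data$w),
    cyclopropane_fraction = sum(.data$w * .data$cyclopropane /
                                  .data$n_chains) / sum(.data$w),
    .groups = "drop")
  out
}

#' Per-species butanol response Z-scores
#'
#' For each species, \eqn{Z = (\bar x_{butanol} - \bar x_{control}) /
#' s_{control}}: the butanol group read against the control
#' distribution, positive meaning higher abundance under n-butanol
#' exposure. Species with zero control variance get `NA` with a note.
#'
#' @param lipidome A normalized lipidome.
#' @param metadata Sample metadata with `sample_id` and `butanol`
#'   (0/1 or logical) columns.
#' @param samples Optional character vector restricting the contrast to a
#'   subset of samples (e.g. wild-type only).
#' @return Tibble with `species`, `mean_control`, `mean_butanol`,
#'   `sd_control`, `z`, `note`.
#' @export
butanol_zscore <- function(lipidome, metadata, samples = NULL) {
  tab <- as_tibble(lipidome)
  meta <- as_tibble(metadata)[, c("sample_id", "butanol")]
  if (!is.null(samples)) meta <- meta[meta$sample_id %in% samples, ]
  tab <- dplyr::inner_join(tab, meta, by = "sample_id")
  if (!any(as.logical(tab$butanol)) || !any(!as.logical(tab$butanol))) {
    abort("Both butanol and control samples are required.")
  }
  out <- dplyr::summarise(
    dplyr::group_by(tab, .data$species),
    mean_control = mean(.data$intensity[!as.logical(.data$butanol)]),
    mean_butanol = mean(.data$intensity[as.logical(.data$butanol)]),
    sd_control = stats::sd(.data$intensity[!as.logical(.data$butanol)]),
    .groups = "drop")
  out$z <- ifelse(out$sd_control > 0,
                  (out$mean_butanol - out$mean_control) / out$sd_control,
                  NA_real_)
  out$note <- ifelse(is.na(out$z), "undefined: zero control variance", "")
  out
}

#' Lipid-lipid correlation structure with hierarchical clustering
#'
#' Pairwise correlations of species abundances across samples, clustered
#' by hierarchical agglomeration on the distance 1 - r. Species with zero
#' variance have undefined correlations and are excluded (logged in the
#' result). The merge order is made deterministic by ordering species
#' alphabetically before clustering.
#'
#' @param lipidome A normalized lipidome (>= 3 samples, >= 2 species).
#' @param method Correlation method passed to [stats::cor()]
#'   (default `"pearson"` on percent values; `"spearman"` available for
#'   users worried about compositional bias).
#' @param linkage Agglomeration rule for [stats::hclust()]
#'   (default `"average"`).
#' @param k Number of clusters for the reported cut (default 6).
#' @return Object of class `lipid_corr`: list with `correlation`
#'   (species x species matrix), `hclust`, `clusters` (tibble `species`,
#'   `cluster`), `excluded`, `k`.
#' @export
correlation_structure <- function(lipidome, method = "pearson",
                                  linkage = "average", k = 6) {
  mat <- t(lipidome_matrix(lipidome)) # samples x species
  if (nrow(mat) < 3) abort("At least 3 samples are required.")
  mat <- mat[, order(colnames(mat)), drop = FALSE]
  sds <- apply(mat, 2, stats::sd)
  excluded <- colnames(mat)[sds == 0 | is.na(sds)]
  mat <- mat[, !(colnames(mat) %in% excluded), drop = FALSE]
  if (ncol(mat) < 2) abort("At least 2 non-constant species are required.")
  r <- stats::cor(mat, method = method)
  hc <- stats::hclust(stats::as.dist(1 - r), method = linkage)
  k <- min(k, ncol(mat))
  ct <- stats::cutree(hc, k = k)
  structure(list(correlation = r, hclust = hc,
                 clusters = tibble(species = names(ct),
                                   cluster = unname(ct)),
                 excluded = excluded, k = k,
                 method = method, linkage = linkage),
            class = "lipid_corr")
}

#' @export
print.lipid_corr <- function(x, ...) {
  cat("<lipid_corr> ", nrow(x$correlation), " species, ",
      x$method, " correlation, ", x$linkage, " linkage, k = ", x$k, "\n",
      sep = "")
  if (length(x$excluded))
    cat("  excluded (constant):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.lipid_corr <- function(x, ...) {
  r <- x$correlation
  out <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble(species1 = rownames(r)), as_tibble(r)),
    cols = -"species1", names_to = "species2", values_to = "r")
  dplyr::left_join(out, x$clusters, by = c("species1" = "species"))
}

#' @export
glance.lipid_corr <- function(x, ...) {
  tibble(n_species = nrow(x$correlation), k = x$k,
         n_excluded = length(x$excluded),
         mean_abs_r = mean(abs(x$correlation[upper.tri(x$correlation)])))
}

#' Export the clustering dendrogram in newick format
#'
#' @param x A `lipid_corr` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(x, path) {
  ape::write.tree(ape::as.phylo(x$hclust), file = path)
  invisible(path)
}

#' Per-species class/unsaturation/cyclopropane annotation bars
#'
#' Tabular analogue of the colored annotation bars above a clustered
#' correlation heatmap: per species its class, total number of double
#' bonds and whether the chains contain a cyclopropane moiety, aligned to
#' the clustering leaf order when a `lipid_corr` object is supplied.
#'
#' @param species Character vector of species names, or a `lipid_corr`
#'   object (leaf order is used).
#' @return Tibble with `species`, `class`, `double_bonds`,
#'   `cyclopropane` (logical).
#' @export
class_annotation_bars <- function(species) {
  if (inherits(species, "lipid_corr")) {
    species <- species$hclust$labels[species$hclust$order]
  }
  info <- parse_species_name(species)
  tibble(species = info$name, class = info$class,
         double_bonds = info$double_bonds,
         cyclopropane = info$cyclopropane >= 1)
}
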