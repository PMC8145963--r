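#' Run the full lipidome analysis pipeline
#'
#' Orchestrates database construction, growth phenotyping with QC,
#' feature annotation (matching, de-isotoping, noise filtering, forced
#' integration, normalization), acyl-property metrics, butanol Z-scores,
#' correlation clustering, marker selection, marker summaries, gene tag
#' counts and regularized differential testing, from a single set of
#' inputs. QC-excluded samples are removed from every downstream table.
#'
#' @param features Feature table (`mz`, `rt`, sample columns) or a
#'   `synthetic_study` (its tables are used directly).
#' @param od OD600 table (`time_min` + sample columns); ignored when
#'   `features` is a study.
#' @param metadata Sample metadata; ignored when `features` is a study.
#' @param database Database tibble (default: [lipid_database()] of
#'   `db`).
#' @param db [db_config()] used when `database` is NULL.
#' @param mz_tolerance Matching tolerance (Th).
#' @param min_od QC threshold on maximum OD600 (default 0.2).
#' @param run_markers Run random-forest marker selection (the most
#'   expensive stage; default TRUE).
#' @param n_trees,drop_fraction,cv_folds,panel_size Forwarded to
#'   [rf_select_markers()].
#' @param window,conf Forwarded to [cybert_anova()]; the differential
#'   test contrasts butanol exposure.
#' @param seed Seed for the stochastic stages.
#' @return List of class `lipidome_pipeline` with elements `lipidome`,
#'   `growth`, `qc`, `acyl`, `zscores`, `correlation`, `markers`,
#'   `marker_table`, `tag_counts`, `differential`, `manifest`.
#' @export
run_pipeline <- function(features, od = NULL, metadata = NULL,
                         database = NULL, db = db_config(),
                         mz_tolerance = 0.3, min_od = 0.2,
                         run_markers = TRUE, n_trees = 500,
                         drop_fraction = 0.1, cv_folds = 0,
                         panel_size = NULL,
                         window = 101, conf = 5, seed = 1) {
  if (inherits(features, "synthetic_study")) {
    study <- features
    features <- study$features
    od <- study$od
    metadata <- study$metadata
    database <- database %||% study$database
  }
  database <- database %||% lipid_database(db)
  metadata <- as_tibble(metadata)

  growth <- fit_growth(od, metadata)
  qc <- qc_filter(growth, min_od = min_od)
  kept_ids <- qc$kept$sample_id

  feat_kept <- features[, c("mz", "rt",
                            intersect(names(features), kept_ids))]
  lip <- annotate_lipidome(feat_kept, database,
                           mz_tolerance = mz_tolerance)
  meta_kept <- metadata[metadata$sample_id %in%
                          unique(as_tibble(lip)$sample_id), ]

  acyl <- dplyr::left_join(acyl_properties(lip), meta_kept,
                           by = "sample_id")
  z <- butanol_zscore(
    lip, meta_kept,
    samples = meta_kept$sample_id[meta_kept$construct_type %in%
                                    c("WT", "EV")])
  corr <- correlation_structure(lip)

  markers <- NULL
  marker_table <- NULL
  tags <- NULL
  if (run_markers) {
    lab_meta <- meta_kept[match(colnames(lipidome_matrix(lip)),
                                meta_kept$sample_id), ]
    labels <- paste0(construct_label(lab_meta), ":", lab_meta$butanol)
    markers <- rf_select_markers(lip, labels, n_trees = n_trees,
                                 drop_fraction = drop_fraction,
                                 cv_folds = cv_folds,
                                 panel_size = panel_size, seed = seed)
    marker_table <- marker_summary(markers, lip, meta_kept)
    n_constructs <- length(unique(construct_label(
      lab_meta[lab_meta$construct_type %in% c("KO", "OV"), ])))
    if (n_constructs >= 10) {
      tags <- gene_tag_counts(markers, lip, meta_kept)
    }
  }

  diff <- cybert_anova(
    lip,
    groups = meta_kept$butanol[match(colnames(lipidome_matrix(lip)),
                                     meta_kept$sample_id)],
    window = window, conf = conf)

  growth_calls <- compare_to_controls(qc$kept)

  manifest <- list(
    package = "colipidr",
    version = as.character(utils::packageVersion("colipidr")),
    seed = seed,
    n_samples = length(kept_ids),
    n_excluded = nrow(qc$excluded),
    n_species = nrow(lipidome_species(lip)),
    parameters = list(mz_tolerance = mz_tolerance, min_od = min_od,
                      n_trees = n_trees, window = window, conf = conf),
    parameter_hash = rlang::hash(list(mz_tolerance, min_od, n_trees,
                                      drop_fraction, window, conf, seed)),
    timestamp = format(Sys.time(), tz = "UTC")
  )

  structure(list(lipidome = lip, growth = growth, qc = qc, acyl = acyl,
                 zscores = z, correlation = corr, markers = markers,
                 marker_table = marker_table, tag_counts = tags,
                 differential = diff, growth_calls = growth_calls,
                 manifest = manifest),
            class = "lipidome_pipeline")
}

#' @export
print.lipidome_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("<lipidome_pipeline> ", m$n_species, " species x ", m$n_samples,
      " samples (", m$n_excluded, " QC-excluded), seed ", m$seed, "\n",
      sep = "")
  invisible(x)
}

#' Write the pipeline report bundle
#'
#' Emits every report table as CSV, the dendrogram in newick format and
#' the manifest as JSON into `dir`.
#'
#' @param result A `lipidome_pipeline` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) if (!is.null(x)) readr::write_csv(x, file.path(dir, f))
  w(as_tibble(result$lipidome), "lipidome_percent.csv")
  w(unmatched_features(result$lipidome), "unmatched_features.csv")
  w(result$growth, "growth_summaries.csv")
  w(result$qc$excluded, "qc_excluded.csv")
  w(result$acyl, "acyl_properties.csv")
  w(result$zscores, "butanol_zscores.csv")
  w(tidy(result$correlation), "lipid_correlations.csv")
  w(result$correlation$clusters, "lipid_clusters.csv")
  write_dendrogram_newick(result$correlation,
                          file.path(dir, "lipid_dendrogram.nwk"))
  if (!is.null(result$markers)) {
    w(result$markers$trace, "oob_trace.csv")
    w(result$marker_table, "marker_panel.csv")
  }
  w(result$tag_counts, "gene_tag_counts.csv")
  w(result$differential, "differential_tests.csv")
  w(result$growth_calls, "growth_classification.csv")
  writeLines(processing_log(result$lipidome),
             file.path(dir, "processing_log.txt"))
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
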