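# A lipidome is a long tibble (species, sample_id, intensity, provenance)
# carrying the matched species table, unmatched features, a processing log
# and a normalized flag as attributes. All annotate-stage verbs take a
# lipidome first and return a lipidome, so they chain with the pipe.

new_lipidome <- function(df, species, unmatched = NULL, log = character(),
                         normalized = FALSE, dropped_samples = character()) {
  structure(as_tibble(df),
            species = species,
            unmatched = unmatched,
            log = log,
            normalized = normalized,
            dropped_samples = dropped_samples,
            class = c("lipidome", class(as_tibble(df))))
}

lipidome_update <- function(x, df = NULL, species = NULL, log_add = NULL,
                            normalized = NULL, dropped_samples = NULL) {
  new_lipidome(
    df %||% as_tibble(x),
    species = species %||% attr(x, "species"),
    unmatched = attr(x, "unmatched"),
    log = c(attr(x, "log"), log_add),
    normalized = normalized %||% attr(x, "normalized"),
    dropped_samples = dropped_samples %||% attr(x, "dropped_samples")
  )
}

#' @export
print.lipidome <- function(x, ...) {
  sp <- attr(x, "species")
  cat("<lipidome> ", nrow(sp), " species x ",
      length(unique(x$sample_id)), " samples",
      if (isTRUE(attr(x, "normalized"))) " (percent of total signal)" else
        " (raw intensity)", "\n", sep = "")
  NextMethod()
}

#' Species table, unmatched features and processing log of a lipidome
#'
#' @param x A lipidome as produced by [match_features()].
#' @return `lipidome_species()`: tibble of annotated species;
#'   `unmatched_features()`: tibble of features with no database match;
#'   `processing_log()`: character vector of log lines.
#' @export
lipidome_species <- function(x) attr(x, "species")

#' @rdname lipidome_species
#' @export
unmatched_features <- function(x) attr(x, "unmatched")

#' @rdname lipidome_species
#' @export
processing_log <- function(x) attr(x, "log")

#' Match mz/rt features against the in-silico lipid database
#'
#' A feature is assigned to a species when its retention time falls in the
#' species' class window and its m/z lies within `mz_tolerance` of the
#' species' deprotonated mass. A feature whose retention time falls in
#' overlapping windows of two classes is resolved to the class with the
#' nearest window center (logged). Isobaric annotations within a class
#' (cyclopropane ring vs double bond) are resolved to the database's
#' canonical name. Intensities of several features matching one species
#' are summed; features matching nothing are kept in a side table.
#'
#' @param features Data frame with columns `mz`, `rt`, then one numeric
#'   intensity column per sample.
#' @param database Database tibble from [lipid_database()].
#' @param mz_tolerance Matching half-width in Th (default 0.3, matching a
#'   unit-resolution ion trap).
#' @return A lipidome: long tibble (`species`, `sample_id`, `intensity`,
#'   `provenance`) with the species table, unmatched features and log as
#'   attributes (see [lipidome_species()]).
#' @export
match_features <- function(features, database, mz_tolerance = 0.3) {
  stopifnot(mz_tolerance > 0)
  features <- as_tibble(features)
  stopifnot(all(c("mz", "rt") %in% names(features)))
  sample_ids <- setdiff(names(features), c("mz", "rt"))
  if (anyDuplicated(sample_ids)) abort("Sample ids must be unique.")
  db <- database[database$canonical %||% TRUE, , drop = FALSE]
  db <- db[order(db$mz), , drop = FALSE]
  cls <- lipid_classes()
  cls <- cls[cls$class %in% unique(db$class), , drop = FALSE]

  log_lines <- character()
  n <- nrow(features)
  assigned <- character(n)
  for (i in seq_len(n)) {
    rt <- features$rt[i]
    hit_cls <- cls[cls$rt_min <= rt & rt <= cls$rt_max, , drop = FALSE]
    if (nrow(hit_cls) == 0) next
    if (nrow(hit_cls) > 1) {
      j <- which.min(abs(hit_cls$rt_center - rt))
      log_lines <- c(log_lines, sprintf(
        "feature mz=%.4f rt=%.2f in overlapping windows (%s); resolved to %s",
        features$mz[i], rt, paste(hit_cls$class, collapse = ","),
        hit_cls$class[j]))
      hit_cls <- hit_cls[j, , drop = FALSE]
    }
    cand <- db[db$class == hit_cls$class &
                 abs(db$mz - features$mz[i]) <= mz_tolerance, , drop = FALSE]
    if (nrow(cand) == 0) next
    assigned[i] <- cand$name[which.min(abs(cand$mz - features$mz[i]))]
  }

  matched <- features[assigned != "", , drop = FALSE]
  matched$species <- assigned[assigned != ""]
  unmatched <- features[assigned == "", , drop = FALSE]

  long <- tidyr::pivot_longer(matched, cols = dplyr::all_of(sample_ids),
                              names_to = "sample_id", values_to = "intensity")
  long$intensity[is.na(long$intensity)] <- 0
  long <- dplyr::summarise(dplyr::group_by(long, .data$species,
                                           .data$sample_id),
                           intensity = sum(.data$intensity), .groups = "drop")
  species <- db[db$name %in% unique(long$species), , drop = FALSE]
  # complete grid so the matrix has no structural gaps
  sp_names <- species$name
  long <- tidyr::complete(long, species = !!sp_names,
                          sample_id = !!sample_ids,
                          fill = list(intensity = 0))
  long$provenance <- ifelse(long$intensity > 0, "detected", "missing")
  long <- long[order(match(long$species, species$name),
                     match(long$sample_id, sample_ids)), ]
  new_lipidome(long, species = species, unmatched = unmatched,
               log = c(log_lines,
                       sprintf("matched %d/%d features to %d species",
                               nrow(matched), n, nrow(species))))
}

#' Correct 13C A+2 isotope overlap between species
#'
#' Within each class, processed in order of increasing m/z, a species
#' lying ~2.0067 Th (two 13C) above another species of the same class
#' receives that species' A+2 isotope signal on top of its own
#' monoisotopic peak. The contribution, `isotope_ratio(formula, 2)` times
#' the already-corrected intensity of the lighter species, is subtracted
#' and clipped at zero (clipping is logged). A+1 peaks fall at odd
#' nominal-mass offsets and never coincide with another species, so only
#' the A+2 overlap needs correction.
#'
#' @param lipidome A lipidome from [match_features()].
#' @param database Database tibble (for formulas).
#' @param gap_tolerance Allowed deviation of the observed mass gap from
#'   2.0067 Th (default 0.1; the true gap to the H2-lighter homolog is
#'   2.0157, merged at unit resolution).
#' @param p13c 13C natural abundance (default 0.011).
#' @return The corrected lipidome.
#' @export
deisotope <- function(lipidome, database, gap_tolerance = 0.1, p13c = 0.011) {
  species <- attr(lipidome, "species")
  if (nrow(species) == 0 || nrow(lipidome) == 0) return(lipidome)
  wide <- tidyr::pivot_wider(
    as_tibble(lipidome)[, c("species", "sample_id", "intensity")],
    names_from = "sample_id", values_from = "intensity")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$species
  iso_gap <- 2 * 1.0033548
  n_clip <- 0L
  for (cl in unique(species$class)) {
    sp <- species[species$class == cl, , drop = FALSE]
    sp <- sp[order(sp$mz), , drop = FALSE]
    for (i in seq_len(nrow(sp))) {
      lighter <- which(abs(sp$mz[i] - sp$mz - iso_gap) <= gap_tolerance)
      for (j in lighter) {
        contrib <- mat[sp$name[j], ] * isotope_ratio(sp$formula[j], 2,
                                                     p = p13c)
        corrected <- mat[sp$name[i], ] - contrib
        n_clip <- n_clip + sum(corrected < 0 & contrib > 0)
        mat[sp$name[i], ] <- pmax(corrected, 0)
      }
    }
  }
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble(species = rownames(mat)),
                     as_tibble(mat)),
    cols = -"species", names_to = "sample_id", values_to = "intensity")
  out <- dplyr::left_join(
    as_tibble(lipidome)[, c("species", "sample_id", "provenance")],
    long, by = c("species", "sample_id"))
  out <- out[, c("species", "sample_id", "intensity", "provenance")]
  lipidome_update(lipidome, df = out,
                  log_add = sprintf("deisotoped (%d cells clipped at zero)",
                                    n_clip))
}

#' Remove species that never rise above the noise floor
#'
#' A species is retained when its (corrected) intensity exceeds
#' `min_intensity` in at least `min_samples` samples. The default
#' threshold is three times the estimated noise floor, taken as the
#' median positive intensity of the unmatched features (the best
#' available proxy for chemical noise); removed species are logged.
#'
#' @param lipidome A lipidome.
#' @param min_intensity Intensity threshold; `NULL` for the default.
#' @param min_samples Minimum number of samples above threshold
#'   (default 1).
#' @return The filtered lipidome.
#' @export
noise_filter <- function(lipidome, min_intensity = NULL, min_samples = 1) {
  stopifnot(min_samples >= 0)
  if (is.null(min_intensity)) {
    min_intensity <- 3 * estimate_noise_floor(lipidome)
  }
  stopifnot(min_intensity >= 0)
  tab <- as_tibble(lipidome)
  keep_tab <- dplyr::summarise(
    dplyr::group_by(tab, .data$species),
    n_above = sum(.data$intensity > min_intensity), .groups = "drop")
  keep <- keep_tab$species[keep_tab$n_above >= min_samples]
  removed <- setdiff(keep_tab$species, keep)
  species <- attr(lipidome, "species")
  lipidome_update(
    lipidome,
    df = tab[tab$species %in% keep, , drop = FALSE],
    species = species[species$name %in% keep, , drop = FALSE],
    log_add = sprintf(
      "noise filter (threshold %.1f, >= %d sample(s)): removed %d species%s",
      min_intensity, min_samples, length(removed),
      if (length(removed)) paste0(" [", paste(removed, collapse = ", "), "]")
      else ""))
}

estimate_noise_floor <- function(lipidome, mz_tolerance = 0.3) {
  un <- attr(lipidome, "unmatched")
  if (is.null(un) || nrow(un) == 0) return(0)
  # unmatched 13C satellites (A+1/A+2 of annotated species) carry real
  # signal and must not enter the noise estimate
  sp_mz <- attr(lipidome, "species")$mz
  sat_mz <- c(sp_mz + 1.0033548, sp_mz + 2 * 1.0033548)
  is_sat <- vapply(un$mz, function(m) any(abs(sat_mz - m) <= mz_tolerance),
                   logical(1))
  un <- un[!is_sat, , drop = FALSE]
  if (nrow(un) == 0) return(0)
  vals <- unlist(un[, setdiff(names(un), c("mz", "rt"))], use.names = FALSE)
  vals <- vals[!is.na(vals) & vals > 0]
  if (length(vals) == 0) return(0)
  stats::median(vals)
}

#' Force integration of missing species/sample cells
#'
#' For every retained species and every sample in which no signal was
#' assigned, the feature table is re-read at the species' expected m/z
#' and retention-time window; whatever intensity is found there (0 when
#' the compound was genuinely not recorded) fills the cell, and the
#' cell's provenance is set to `"force_integrated"`. The completed matrix
#' has no missing cells, so minor compounds carry reliable values in all
#' samples.
#'
#' @param lipidome A lipidome whose species list has been finalized by
#'   [noise_filter()].
#' @param features The original feature table (columns `mz`, `rt`,
#'   samples).
#' @param mz_tolerance Matching half-width in Th (default 0.3).
#' @return The completed lipidome.
#' @export
force_integrate <- function(lipidome, features, mz_tolerance = 0.3) {
  species <- attr(lipidome, "species")
  tab <- as_tibble(lipidome)
  features <- as_tibble(features)
  miss <- which(tab$intensity <= 0 | is.na(tab$intensity))
  n_forced <- 0L
  for (i in miss) {
    sp <- species[species$name == tab$species[i], , drop = FALSE]
    rows <- abs(features$mz - sp$mz) <= mz_tolerance &
      features$rt >= sp$rt_min & features$rt <= sp$rt_max
    val <- sum(features[[tab$sample_id[i]]][rows], na.rm = TRUE)
    tab$intensity[i] <- val
    tab$provenance[i] <- "force_integrated"
    n_forced <- n_forced + 1L
  }
  lipidome_update(lipidome, df = tab,
                  log_add = sprintf("force-integrated %d cells", n_forced))
}

#' Normalize a lipidome to percent of total signal
#'
#' Each sample column is scaled so that the sum over all species is
#' exactly 100. Samples with no lipid signal at all (e.g. cell-free
#' incubations) cannot be normalized and are dropped with a log entry.
#'
#' @param lipidome A lipidome with raw intensities.
#' @return The lipidome on the percent scale (`normalized` attribute set).
#' @export
normalize_lipidome <- function(lipidome) {
  tab <- as_tibble(lipidome)
  totals <- dplyr::summarise(dplyr::group_by(tab, .data$sample_id),
                             total = sum(.data$intensity), .groups = "drop")
  dead <- totals$sample_id[totals$total <= 0]
  tab <- tab[!tab$sample_id %in% dead, , drop = FALSE]
  tab <- dplyr::mutate(dplyr::group_by(tab, .data$sample_id),
                       intensity = 100 * .data$intensity /
                         sum(.data$intensity))
  tab <- dplyr::ungroup(tab)
  lipidome_update(
    lipidome, df = tab, normalized = TRUE,
    dropped_samples = c(attr(lipidome, "dropped_samples"), dead),
    log_add = if (length(dead))
      sprintf("normalization: dropped %d all-zero sample(s) [%s]",
              length(dead), paste(dead, collapse = ", "))
    else "normalized to percent of total signal")
}

#' Annotate a feature table end to end
#'
#' Convenience wrapper chaining [match_features()], [deisotope()],
#' [noise_filter()], [force_integrate()] and [normalize_lipidome()].
#'
#' @inheritParams match_features
#' @inheritParams noise_filter
#' @param normalize Normalize to percent of total signal (default TRUE).
#' @param correct_isotopes Apply [deisotope()] (default TRUE; disable
#'   only for data known to carry no isotope envelopes).
#' @return A lipidome.
#' @export
annotate_lipidome <- function(features, database, mz_tolerance = 0.3,
                              min_intensity = NULL, min_samples = 1,
                              normalize = TRUE, correct_isotopes = TRUE) {
  out <- match_features(features, database, mz_tolerance = mz_tolerance)
  if (correct_isotopes) out <- deisotope(out, database)
  out <- out |>
    noise_filter(min_intensity = min_intensity, min_samples = min_samples) |>
    force_integrate(features, mz_tolerance = mz_tolerance)
  if (normalize) out <- normalize_lipidome(out)
  out
}

#' Lipidome as a species-by-sample matrix
#'
#' @param lipidome A lipidome.
#' @return Numeric matrix, species in rows, samples in columns.
#' @export
lipidome_matrix <- function(lipidome) {
  wide <- tidyr::pivot_wider(
    as_tibble(lipidome)[, c("species", "sample_id", "intensity")],
    names_from = "sample_id", values_from = "intensity")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$species
  mat
}

#' @export
tidy.lipidome <- function(x, ...) as_tibble(x)
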