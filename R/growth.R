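#' Maximum specific growth rate from an OD600 curve
#'
#' Slides a fixed-width window over log-transformed, blank-corrected OD
#' readings and returns the largest least-squares slope, converted to
#' 1/h. Only readings above `od_floor` enter the fit; windows must be
#' fully contained in a run of consecutive valid readings.
#'
#' @param time_min Time points in minutes (strictly increasing; a 5-min
#'   grid in the standard microplate protocol).
#' @param od OD600 readings.
#' @param window_points Window width in readings (default 11, i.e. 55 min
#'   on a 5-min grid).
#' @param od_floor Minimum blank-corrected OD for a reading to enter the
#'   fit (default 0.02).
#' @param blank Blank OD subtracted before log transformation
#'   (default 0).
#' @return List with `mu_max` (1/h; `NA` when no window of valid
#'   readings exists), `t_start`, `t_end` (minutes).
#' @examples
#' t <- seq(0, 960, by = 5)
#' od <- 0.02 * exp(0.6 * t / 60)
#' mu_max(t, od)$mu_max # 0.6
#' @export
mu_max <- function(time_min, od, window_points = 11, od_floor = 0.02,
                   blank = 0) {
  stopifnot(length(time_min) == length(od), all(diff(time_min) > 0),
            window_points >= 3)
  odc <- od - blank
  valid <- !is.na(odc) & odc > od_floor
  best <- list(mu_max = NA_real_, t_start = NA_real_, t_end = NA_real_)
  runs <- rle(valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (r in which(runs$values & runs$lengths >= window_points)) {
    idx <- starts[r]:ends[r]
    t_h <- time_min[idx] / 60
    y <- log(odc[idx])
    for (s in seq_len(length(idx) - window_points + 1)) {
      w <- s:(s + window_points - 1)
      slope <- stats::cov(t_h[w], y[w]) / stats::var(t_h[w])
      if (is.na(best$mu_max) || slope > best$mu_max) {
        best <- list(mu_max = slope, t_start = time_min[idx[w[1]]],
                     t_end = time_min[idx[w[length(w)]]])
      }
    }
  }
  best
}

#' Steady-state OD600 of a growth curve
#'
#' Identifies the longest trailing segment over which the windowed slope
#' of log OD stays below `slope_threshold` (in 1/h) and returns the
#' median OD over that plateau. Curves still rising at the end of the
#' run fall back to the final reading, flagged with `plateau = FALSE`.
#'
#' @inheritParams mu_max
#' @param slope_threshold Windowed log-slope below which the culture is
#'   considered stationary (default 0.02 1/h).
#' @return List with `steady_state_od`, `plateau` (logical),
#'   `t_plateau_start` (minutes, `NA` without plateau).
#' @export
steady_state_od <- function(time_min, od, window_points = 11,
                            slope_threshold = 0.02, blank = 0) {
  stopifnot(length(time_min) == length(od), all(diff(time_min) > 0))
  odc <- pmax(od - blank, 1e-6)
  n <- length(odc)
  if (n < window_points) {
    return(list(steady_state_od = odc[n], plateau = FALSE,
                t_plateau_start = NA_real_))
  }
  t_h <- time_min / 60
  y <- log(odc)
  n_win <- n - window_points + 1
  slopes <- vapply(seq_len(n_win), function(s) {
    w <- s:(s + window_points - 1)
    stats::cov(t_h[w], y[w]) / stats::var(t_h[w])
  }, numeric(1))
  flat <- abs(slopes) < slope_threshold
  if (!flat[n_win]) {
    return(list(steady_state_od = odc[n], plateau = FALSE,
                t_plateau_start = NA_real_))
  }
  first <- n_win
  while (first > 1 && flat[first - 1]) first <- first - 1
  idx <- first:n
  list(steady_state_od = stats::median(odc[idx]), plateau = TRUE,
       t_plateau_start = time_min[first])
}

#' Growth summaries for a plate of OD600 curves
#'
#' Applies [mu_max()] and [steady_state_od()] to every well of a wide
#' OD table and joins sample metadata.
#'
#' @param od_table Data frame with a `time_min` column and one numeric
#'   column per well/sample.
#' @param metadata Optional metadata joined by `sample_id`.
#' @inheritParams mu_max
#' @inheritParams steady_state_od
#' @return Tibble with one row per sample: `sample_id`, `mu_max`,
#'   `t_start`, `t_end`, `steady_state_od`, `plateau`, `max_od`, plus
#'   metadata columns.
#' @export
fit_growth <- function(od_table, metadata = NULL, window_points = 11,
                       od_floor = 0.02, blank = 0,
                       slope_threshold = 0.02) {
  od_table <- as_tibble(od_table)
  stopifnot("time_min" %in% names(od_table))
  wells <- setdiff(names(od_table), "time_min")
  out <- purrr::map_dfr(wells, function(w) {
    m <- mu_max(od_table$time_min, od_table[[w]],
                window_points = window_points, od_floor = od_floor,
                blank = blank)
    s <- steady_state_od(od_table$time_min, od_table[[w]],
                         window_points = window_points,
                         slope_threshold = slope_threshold, blank = blank)
    tibble(sample_id = w, mu_max = m$mu_max, t_start = m$t_start,
           t_end = m$t_end, steady_state_od = s$steady_state_od,
           plateau = s$plateau,
           max_od = max(od_table[[w]] - blank, na.rm = TRUE))
  })
  if (!is.null(metadata)) {
    out <- dplyr::left_join(out, as_tibble(metadata), by = "sample_id")
  }
  out
}

#' Quality-control filter on growth summaries
#'
#' Cultures whose maximum blank-corrected OD600 never reaches `min_od`
#' did not grow enough to yield a reliable lipidome and are excluded
#' from downstream analysis (inclusive boundary: `max_od == min_od` is
#' kept).
#'
#' @param summaries Tibble from [fit_growth()].
#' @param min_od Minimum maximum-OD (default 0.2).
#' @return List with `kept` and `excluded` tibbles (each carrying a
#'   `qc_pass` column); `kept` and `excluded` partition the input.
#' @export
qc_filter <- function(summaries, min_od = 0.2) {
  summaries <- as_tibble(summaries)
  summaries$qc_pass <- summaries$max_od >= min_od
  list(kept = summaries[summaries$qc_pass, , drop = FALSE],
       excluded = summaries[!summaries$qc_pass, , drop = FALSE])
}

#' Classify constructs against their controls
#'
#' Welch two-sample t-tests of each genetic construct's replicate growth
#' parameters against its matched control -- wild type (WT) for
#' knock-outs, empty vector (EV) for overexpressors -- separately per
#' butanol condition and per metric (`mu_max`, `steady_state_od`).
#' Two-sided, uncorrected p-values against `alpha`; the sign of the
#' difference gives the `higher` / `lower` call, non-significant
#' comparisons are `ns`. Constructs with fewer than two replicates are
#' reported `ns` with a flag.
#'
#' @param summaries Growth summaries with metadata columns `gene`,
#'   `construct_type` (KO/OV/WT/EV) and `butanol`.
#' @param alpha Significance level (default 0.05).
#' @return Tibble with `gene`, `construct_type`, `butanol`, `metric`,
#'   `estimate`, `control_mean`, `p`, `call`, `flag`.
#' @export
compare_to_controls <- function(summaries, alpha = 0.05) {
  s <- as_tibble(summaries)
  stopifnot(all(c("gene", "construct_type", "butanol") %in% names(s)))
  metrics <- c("mu_max", "steady_state_od")
  combos <- dplyr::distinct(
    s[s$construct_type %in% c("KO", "OV"), ,
      drop = FALSE][, c("gene", "construct_type", "butanol")])
  out <- purrr::pmap_dfr(combos, function(gene, construct_type, butanol) {
    ctrl_type <- if (construct_type == "KO") "WT" else "EV"
    grp <- s[s$gene == gene & s$construct_type == construct_type &
               s$butanol == butanol, , drop = FALSE]
    ctrl <- s[s$construct_type == ctrl_type & s$butanol == butanol, ,
              drop = FALSE]
    purrr::map_dfr(metrics, function(m) {
      gv <- grp[[m]][!is.na(grp[[m]])]
      cv <- ctrl[[m]][!is.na(ctrl[[m]])]
      if (length(gv) < 2 || length(cv) < 2) {
        return(tibble(gene = gene, construct_type = construct_type,
                      butanol = butanol, metric = m,
                      estimate = mean(gv), control_mean = mean(cv),
                      p = NA_real_, call = "ns",
                      flag = "insufficient replicates"))
      }
      tt <- stats::t.test(gv, cv)
      call <- if (tt$p.value < alpha) {
        if (mean(gv) > mean(cv)) "higher" else "lower"
      } else "ns"
      tibble(gene = gene, construct_type = construct_type,
             butanol = butanol, metric = m, estimate = mean(gv),
             control_mean = mean(cv), p = tt$p.value, call = call,
             flag = "")
    })
  })
  out
}
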