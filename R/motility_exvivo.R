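#' Segment directed runs from a particle trajectory
#'
#' Positions are projected onto the track's microtubule polarity axis (unit
#' vector toward the plus end, derived upstream from EB1 comets). A run in
#' one direction is an inclusion-maximal frame window that (i) starts and
#' ends with a step in that direction, (ii) never contains more than
#' `max_reversal_tolerance` consecutive counter-direction (or zero) steps,
#' (iii) has net displacement of at least `min_run_length`, and (iv) spans
#' at least `min_run_frames` frame intervals. Plus- and minus-direction runs
#' are segmented independently. Speed is net displacement over duration.
#'
#' @param track data.frame for one track with columns `t` (s, strictly
#'   increasing), `x`, `y` (µm).
#' @param polarity unit vector `c(ux, uy)` toward the microtubule plus end,
#'   or `NULL` when no polarity reference exists (runs are then segmented
#'   along the track's own net-displacement axis and reported with `NA`
#'   direction and `direction_defined = FALSE`).
#' @param min_run_length minimum net displacement (µm), default 0.5.
#' @param min_run_frames minimum number of frame intervals, default 3.
#' @param max_reversal_tolerance maximum consecutive counter-steps, default 1.
#' @return data.frame with one row per run: `direction` (`"plus"`,
#'   `"minus"` or `NA`), `start_frame`, `end_frame` (1-based frame indices),
#'   `length` (µm), `duration` (s), `mean_speed` (µm/s),
#'   `direction_defined`.
#' @export
segment_runs <- function(track, polarity,
                         min_run_length = 0.5, min_run_frames = 3L,
                         max_reversal_tolerance = 1L) {
  stopifnot(all(c("t", "x", "y") %in% names(track)))
  if (nrow(track) < 2 || any(diff(track$t) <= 0)) {
    stop_rnp("track must have >= 2 frames with strictly increasing t",
             class = "rnp_validation_error")
  }
  defined <- !is.null(polarity)
  if (!defined) {
    disp <- c(track$x[nrow(track)] - track$x[1],
              track$y[nrow(track)] - track$y[1])
    if (all(disp == 0)) disp <- c(1, 0)
    polarity <- disp / sqrt(sum(disp^2))
  }
  u <- polarity / sqrt(sum(polarity^2))
  s <- track$x * u[1] + track$y * u[2]
  out <- rbind(
    run_windows(s, track$t, +1, min_run_length, min_run_frames,
                max_reversal_tolerance),
    run_windows(s, track$t, -1, min_run_length, min_run_frames,
                max_reversal_tolerance))
  if (nrow(out) == 0) {
    out$direction <- character(0)
  } else {
    out$direction <- if (defined) {
      ifelse(out$sign > 0, "plus", "minus")
    } else {
      NA_character_
    }
  }
  out$direction_defined <- rep(defined, nrow(out))
  out$sign <- NULL
  out[, c("direction", "start_frame", "end_frame", "length", "duration",
          "mean_speed", "direction_defined")]
}

# Inclusion-maximal run windows along projected coordinate s for one
# direction sign. Steps with sgn * ds <= 0 count as counter-steps.
run_windows <- function(s, t, sgn, min_len, min_frames, tol) {
  empty <- data.frame(sign = numeric(0), start_frame = integer(0),
                      end_frame = integer(0), length = numeric(0),
                      duration = numeric(0), mean_speed = numeric(0))
  n <- length(s)
  ds <- sgn * diff(s)
  forward <- ds > 0
  if (!any(forward)) return(empty)
  # cr[k]: length of the consecutive counter-step run ending at step k
  cr <- integer(n - 1L)
  run <- 0L
  for (k in seq_len(n - 1L)) {
    run <- if (forward[k]) 0L else run + 1L
    cr[k] <- run
  }
  bad <- cr > tol
  cand <- list()
  for (a in which(forward)) {
    # largest frame b such that steps a..b-1 contain no bad step
    nb <- which(bad & seq_along(bad) >= a)
    b_max <- if (length(nb)) nb[1] else n
    if (b_max <= a) next
    ends <- a + which(forward[a:(b_max - 1L)])  # ends with a forward step
    ends <- ends[ends - a >= min_frames & sgn * (s[ends] - s[a]) >= min_len]
    if (!length(ends)) next
    cand[[length(cand) + 1L]] <- c(a, max(ends))
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  keep <- logical(nrow(cand))
  best_b <- -Inf  # starts are ascending; drop windows contained in earlier ones
  for (i in seq_len(nrow(cand))) {
    if (cand[i, 2] > best_b) { keep[i] <- TRUE; best_b <- cand[i, 2] }
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(sign = sgn, start_frame = cand[, 1], end_frame = cand[, 2],
             length = sgn * (s[cand[, 2]] - s[cand[, 1]]),
             duration = t[cand[, 2]] - t[cand[, 1]],
             mean_speed = sgn * (s[cand[, 2]] - s[cand[, 1]]) /
               (t[cand[, 2]] - t[cand[, 1]]))
}

#' Segment runs for a table of tracks
#'
#' @param tracks data.frame with `track_id`, `t`, `x`, `y` (and optionally
#'   `intensity`).
#' @param polarity data.frame with `track_id`, `ux`, `uy`; tracks without a
#'   polarity row get `NA` directions.
#' @param ... passed to [segment_runs()].
#' @return data.frame of runs with a `track_id` column.
#' @export
segment_runs_all <- function(tracks, polarity = NULL, ...) {
  chunks <- split(tracks, factor(tracks$track_id,
                                 levels = unique(tracks$track_id)))
  res <- lapply(chunks, function(trk) {
    id <- trk$track_id[1]
    pol <- NULL
    if (!is.null(polarity)) {
      row <- polarity[polarity$track_id == id, , drop = FALSE]
      if (nrow(row) == 1) pol <- c(row$ux, row$uy)
    }
    runs <- segment_runs(trk, pol, ...)
    if (nrow(runs)) cbind(track_id = id, runs) else NULL
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(data.frame(track_id = character(), direction = character(),
                      start_frame = integer(), end_frame = integer(),
                      length = numeric(), duration = numeric(),
                      mean_speed = numeric(), direction_defined = logical()))
  }
  do.call(rbind, res)
}

#' Plus/minus polarity distribution of runs
#'
#' @param runs data.frame of runs with a `direction` column; rows with
#'   undefined direction are dropped.
#' @param strata optional vector (same length as rows of `runs`) to
#'   stratify by, e.g. relative RNA units; `NULL` pools everything.
#' @return data.frame per stratum: `stratum`, `n_plus`, `n_minus`,
#'   `pct_plus`, `pct_minus`. Empty strata are omitted.
#' @export
polarity_fractions <- function(runs, strata = NULL) {
  keep <- !is.na(runs$direction)
  runs <- runs[keep, , drop = FALSE]
  strata <- if (is.null(strata)) rep("all", nrow(runs)) else strata[keep]
  tab <- table(stratum = strata, direction = factor(runs$direction,
                                                    c("plus", "minus")))
  out <- data.frame(stratum = rownames(tab),
                    n_plus = as.integer(tab[, "plus"]),
                    n_minus = as.integer(tab[, "minus"]))
  out <- out[out$n_plus + out$n_minus > 0, , drop = FALSE]
  out$pct_plus <- 100 * out$n_plus / (out$n_plus + out$n_minus)
  out$pct_minus <- 100 - out$pct_plus
  out
}

#' Fisher exact test of polarity between two conditions
#'
#' @param counts_a,counts_b length-2 integer vectors `(plus, minus)`.
#' @return two-sided Fisher exact p-value on the 2x2 table.
#' @export
polarity_test <- function(counts_a, counts_b) {
  fisher.test(rbind(counts_a, counts_b))$p.value
}

#' Run speed and length statistics across conditions
#'
#' Per stratum x direction cell: quartiles of speed and run length per
#' condition, pairwise Mann-Whitney U tests against the control, and the
#' percent difference in mean travel distance (and mean speed) relative to
#' the control. Cells with fewer than 3 runs in either condition are
#' flagged and not tested.
#'
#' @param runs data.frame of runs with `direction`, `length`, `mean_speed`,
#'   plus `stratum` and `condition` columns.
#' @param control name of the control condition.
#' @return data.frame with one row per stratum x direction x condition
#'   (non-control), carrying `n`, `n_ctrl`, medians and quartiles,
#'   `p_speed`, `p_length`, `dmean_length_pct`, `dmean_speed_pct`,
#'   `flagged`.
#' @export
run_metrics <- function(runs, control) {
  stopifnot(all(c("direction", "length", "mean_speed", "stratum",
                  "condition") %in% names(runs)))
  runs <- runs[!is.na(runs$direction), , drop = FALSE]
  cells <- unique(runs[, c("stratum", "direction")])
  conds <- setdiff(unique(runs$condition), control)
  out <- list()
  for (r in seq_len(nrow(cells))) {
    st <- cells$stratum[r]; dir <- cells$direction[r]
    ctrl <- runs[runs$stratum == st & runs$direction == dir &
                   runs$condition == control, , drop = FALSE]
    for (cond in conds) {
      cc <- runs[runs$stratum == st & runs$direction == dir &
                   runs$condition == cond, , drop = FALSE]
      flagged <- nrow(cc) < 3 || nrow(ctrl) < 3
      q <- function(v) unname(stats::quantile(v, c(0.25, 0.5, 0.75)))
      row <- data.frame(
        stratum = st, direction = dir, condition = cond,
        n = nrow(cc), n_ctrl = nrow(ctrl),
        speed_q1 = NA_real_, speed_med = NA_real_, speed_q3 = NA_real_,
        length_q1 = NA_real_, length_med = NA_real_, length_q3 = NA_real_,
        p_speed = NA_real_, p_length = NA_real_,
        dmean_length_pct = NA_real_, dmean_speed_pct = NA_real_,
        flagged = flagged)
      if (nrow(cc) > 0) {
        row[, c("speed_q1", "speed_med", "speed_q3")] <- q(cc$mean_speed)
        row[, c("length_q1", "length_med", "length_q3")] <- q(cc$length)
      }
      if (!flagged) {
        row$p_speed <- wilcox.test(cc$mean_speed, ctrl$mean_speed)$p.value
        row$p_length <- wilcox.test(cc$length, ctrl$length)$p.value
        row$dmean_length_pct <-
          100 * (mean(cc$length) - mean(ctrl$length)) / mean(ctrl$length)
        row$dmean_speed_pct <-
          100 * (mean(cc$mean_speed) - mean(ctrl$mean_speed)) /
          mean(ctrl$mean_speed)
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' Stratify tracks by relative RNA units
#'
#' Per-series mixture calibration converts track intensities to relative
#' RNA units (intensity / unit); these are rounded half-up and mapped to
#' the strata `"1"`, `"2"`, `">2"`. Values rounding to zero (dim, sub-unit
#' particles) return `NA` and are excluded from stratified statistics.
#'
#' @param intensities per-track intensities (a.u.).
#' @param model ex vivo `calibration_model` for the same time-lapse series
#'   (policy `smallest_mean`).
#' @return character vector of strata (`"1"`, `"2"`, `">2"` or `NA`).
#' @export
stratify_by_rna <- function(intensities, model) {
  units <- normalize_intensity(intensities, model)
  rounded <- floor(units + 0.5)
  out <- rep(NA_character_, length(units))
  out[rounded == 1] <- "1"
  out[rounded == 2] <- "2"
  out[rounded >= 3] <- ">2"
  out
}
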