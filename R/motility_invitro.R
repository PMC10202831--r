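#' Classify microtubule binding and processive events in a trace
#'
#' A trace is the per-frame position of one particle. Contiguous frame
#' stretches are candidate events. An event lasting at least
#' `min_binding_frames` continuous frames is a binding event; a binding
#' event that exhibits unidirectional movement of at least
#' `min_processive_px` pixels during its lifetime is also processive.
#' Unidirectional movement is evaluated over sub-windows whose per-frame
#' steps never change sign (zero steps allowed, no backsteps); the
#' alternative `"net"` mode instead thresholds the absolute start-to-end
#' displacement of the whole event.
#'
#' @param trace data.frame with `frame` (strictly increasing integers) and
#'   `position` (µm along the microtubule).
#' @param min_binding_frames minimum continuous frames, default 3.
#' @param min_processive_px minimum unidirectional displacement in pixels,
#'   default 5.
#' @param pixel_size µm per pixel, default 0.107.
#' @param mode `"subwindow"` (default) or `"net"`, see above.
#' @return data.frame with one row per candidate event: `start_frame`,
#'   `end_frame`, `n_frames`, `binding`, `processive`, `max_unidir_disp`
#'   (µm).
#' @export
classify_events <- function(trace, min_binding_frames = 3L,
                            min_processive_px = 5L, pixel_size = 0.107,
                            mode = c("subwindow", "net")) {
  mode <- match.arg(mode)
  stopifnot(all(c("frame", "position") %in% names(trace)))
  f <- trace$frame
  if (length(f) == 0) {
    return(data.frame(start_frame = integer(), end_frame = integer(),
                      n_frames = integer(), binding = logical(),
                      processive = logical(), max_unidir_disp = numeric()))
  }
  if (any(diff(f) <= 0)) {
    stop_rnp("trace frame index must be strictly increasing",
             class = "rnp_validation_error")
  }
  thr <- min_processive_px * pixel_size
  seg_id <- cumsum(c(1L, as.integer(diff(f) > 1)))
  res <- lapply(split(seq_along(f), seg_id), function(ix) {
    pos <- trace$position[ix]
    n <- length(ix)
    disp <- max_unidirectional_disp(pos)
    binding <- n >= min_binding_frames
    eps <- 1e-9  # float guard for displacements summing to exactly thr
    moved <- if (mode == "subwindow") disp >= thr - eps else
      abs(pos[n] - pos[1]) >= thr - eps
    data.frame(start_frame = f[ix[1]], end_frame = f[ix[n]], n_frames = n,
               binding = binding, processive = binding && moved,
               max_unidir_disp = disp)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Largest |displacement| over any sub-window whose steps are sign-constant
# (all >= 0 or all <= 0). Within such a window the displacement is maximal
# over the full window, so it suffices to scan maximal same-sign stretches.
max_unidirectional_disp <- function(pos) {
  if (length(pos) < 2) return(0)
  ds <- diff(pos)
  best <- 0
  for (sgn in c(1, -1)) {
    ok <- sgn * ds >= 0
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      best <- max(best, abs(pos[ends[k] + 1L] - pos[starts[k]]))
    }
  }
  best
}

#' Classify events for a whole trace table
#'
#' @param traces data.frame with `trace_id`, `mt_id`, `region`
#'   (`"mt"`/`"background"`), `frame`, `position`.
#' @param ... passed to [classify_events()].
#' @return data.frame of events with `trace_id`, `mt_id`, `region` columns.
#' @export
classify_events_all <- function(traces, ...) {
  chunks <- split(traces, factor(traces$trace_id,
                                 levels = unique(traces$trace_id)))
  res <- lapply(chunks, function(tr) {
    ev <- classify_events(tr[order(tr$frame), ], ...)
    if (nrow(ev)) {
      cbind(trace_id = tr$trace_id[1], mt_id = tr$mt_id[1],
            region = tr$region[1], ev)
    }
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(data.frame(trace_id = character(), mt_id = character(),
                      region = character(), start_frame = integer(),
                      end_frame = integer(), n_frames = integer(),
                      binding = logical(), processive = logical(),
                      max_unidir_disp = numeric()))
  }
  do.call(rbind, res)
}

#' Background-correct binding frequencies
#'
#' Subtracts the mean binding frequency observed in microtubule-free
#' surface regions (sized to the median microtubule length) from each
#' microtubule's observed binding frequency. Corrected values are floored
#' at zero with a flag.
#'
#' @param observed numeric vector of per-microtubule binding frequencies.
#' @param background numeric vector of per-region background frequencies;
#'   empty skips the correction with a warning.
#' @return data.frame with `observed`, `corrected`, `floored` and an
#'   attribute `background_mean`.
#' @export
background_correct <- function(observed, background) {
  if (length(background) == 0) {
    warning("no background regions; correction skipped")
    out <- data.frame(observed = observed, corrected = observed,
                      floored = FALSE)
    attr(out, "background_mean") <- NA_real_
    return(out)
  }
  bg <- mean(background)
  corrected <- observed - bg
  out <- data.frame(observed = observed,
                    corrected = pmax(corrected, 0),
                    floored = corrected < 0)
  attr(out, "background_mean") <- bg
  out
}

#' Per-microtubule event summary
#'
#' Tallies binding and processive events per microtubule and converts them
#' to duration- and length-normalized frequencies (events per µm per min);
#' raw per-microtubule counts are kept alongside. Condition-level
#' aggregates report the mean and SD over microtubules, each microtubule
#' contributing one observation.
#'
#' @param events classified events (from [classify_events_all()]); only
#'   `region == "mt"` rows are tallied against microtubules.
#' @param mt data.frame with `mt_id`, `length` (µm); zero-length
#'   microtubules are excluded.
#' @param duration movie length in frames.
#' @param frame_rate frames per second.
#' @return list with `per_mt` (data.frame `mt_id`, `mt_length`,
#'   `n_binding`, `n_processive`, `frac_processive` (NA-flagged when no
#'   binding events), `freq_binding`, `freq_processive`) and `aggregate`
#'   (mean and SD of each metric over microtubules).
#' @export
per_mt_summary <- function(events, mt, duration, frame_rate = 4) {
  mt <- mt[mt$length > 0, , drop = FALSE]
  if (nrow(mt) == 0) {
    stop_rnp("need >= 1 microtubule with positive length",
             class = "rnp_validation_error")
  }
  duration_min <- duration / frame_rate / 60
  ev <- events[events$region == "mt" & events$binding, , drop = FALSE]
  per <- data.frame(mt_id = mt$mt_id, mt_length = mt$length)
  per$n_binding <- vapply(per$mt_id, function(id) {
    sum(ev$mt_id == id)
  }, integer(1))
  per$n_processive <- vapply(per$mt_id, function(id) {
    sum(ev$mt_id == id & ev$processive)
  }, integer(1))
  per$frac_processive <- ifelse(per$n_binding > 0,
                                per$n_processive / per$n_binding, NA_real_)
  per$freq_binding <- per$n_binding / (per$mt_length * duration_min)
  per$freq_processive <- per$n_processive / (per$mt_length * duration_min)
  metrics <- c("n_binding", "n_processive", "frac_processive",
               "freq_binding", "freq_processive")
  agg <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per[[m]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(metrics, function(m) sd(per[[m]], na.rm = TRUE), numeric(1)),
    n_mt = nrow(per))
  list(per_mt = per, aggregate = agg)
}

#' Relative motility metrics between conditions
#'
#' Normalizes per-microtubule values of a condition to the mean of the
#' matching reference condition (e.g. with vs. without Staufen) and tests
#' the two conditions with a Mann-Whitney test.
#'
#' @param condition numeric per-microtubule values for the test condition.
#' @param reference numeric per-microtubule values for the reference
#'   condition (mean must be > 0).
#' @return list with `relative` (condition values / reference mean),
#'   `relative_mean`, `mw_p`.
#' @export
relative_metrics <- function(condition, reference) {
  ref_mean <- mean(reference)
  if (!is.finite(ref_mean) || ref_mean <= 0) {
    stop_rnp("reference mean must be > 0", class = "rnp_validation_error")
  }
  list(relative = condition / ref_mean,
       relative_mean = mean(condition) / ref_mean,
       mw_p = wilcox.test(condition, reference)$p.value)
}

#' Welch ANOVA with Brown-Forsythe variance check across conditions
#'
#' Multi-condition comparison of relative metrics: Welch's
#' heteroscedastic ANOVA on the group means plus the Brown-Forsythe
#' (median-centered Levene) test of variance homogeneity.
#'
#' @param groups named list of numeric vectors.
#' @return list with `welch_p` and `brown_forsythe_p`.
#' @export
welch_anova_bf <- function(groups) {
  if (length(groups) < 2) {
    stop_rnp("need >= 2 groups", class = "rnp_validation_error")
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  welch <- oneway.test(values ~ g, var.equal = FALSE)
  bf <- car::leveneTest(values ~ g, center = stats::median)
  list(welch_p = welch$p.value, brown_forsythe_p = bf[["Pr(>F)"]][1])
}
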