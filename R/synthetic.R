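#' Simulate a two-channel RNP / reporter field
#'
#' Generates the input of the colocalization pipeline with recorded ground
#' truth. RNP positions are uniform inside the geometry (outside nuclear
#' masks). Each RNP carries a true copy number drawn from `copy_dist`; its
#' intensity is `copies * unit * (1 + N(0, cv))` (multiplicative noise,
#' floored at 0). With probability `coloc_prob[bin(copies)]` the RNP is
#' truly colocalized and receives a reporter placed uniformly within
#' `coloc_radius / 2` of it (strictly inside the detection cutoff), with
#' intensity `reporter_slope * copies * (1 + N(0, cv))`. `background_reporters`
#' additional single-molecule reporters (intensity
#' `reporter_slope * (1 + N(0, cv))`) are placed uniformly in the geometry.
#'
#' @param n_rna number of RNPs.
#' @param geometry an [oocyte_geometry()].
#' @param copy_dist named numeric vector: names are integer copy numbers,
#'   values probabilities summing to 1. Default `c("1" = .5, "2" = .35,
#'   "4" = .15)`, reflecting that most RNPs carry 1-2 copies.
#' @param unit single-copy intensity (a.u.), default 100.
#' @param cv coefficient of variation of the multiplicative intensity noise,
#'   default 0.15.
#' @param coloc_prob named numeric vector mapping copy-number bin labels
#'   (see [copy_bins()]) to true colocalization probabilities; unnamed bins
#'   default to 0.
#' @param reporter_slope reporter intensity per RNA copy (a.u.), default 50.
#' @param background_reporters count of non-colocalized reporters,
#'   default 100.
#' @param coloc_radius detection radius (µm) whose half defines the true
#'   placement radius, default 0.25.
#' @param compartment,specimen_id,stage labels stamped on all detections.
#' @param seed RNG seed.
#' @return list with `detections` (`rnp_detections`, channels `rna` and
#'   `reporter`) and `truth` (per-RNP `copies`, `colocalized`,
#'   `reporter_intensity`, plus the generator parameters).
#' @export
gen_rnp_field <- function(n_rna, geometry,
                          copy_dist = c("1" = 0.5, "2" = 0.35, "4" = 0.15),
                          unit = 100, cv = 0.15,
                          coloc_prob = c(), reporter_slope = 50,
                          background_reporters = 100, coloc_radius = 0.25,
                          compartment = "oocyte", specimen_id = "sim1",
                          stage = "9", seed = NULL) {
  if (abs(sum(copy_dist) - 1) > 1e-8) {
    stop_rnp("copy_dist must sum to 1", class = "rnp_validation_error")
  }
  if (length(coloc_prob) && (any(coloc_prob < 0) || any(coloc_prob > 1))) {
    stop_rnp("coloc_prob values must lie in [0, 1]",
             class = "rnp_validation_error")
  }
  if (!inherits(geometry, "oocyte_geometry") || free_area(geometry) <= 0) {
    stop_rnp("geometry must be an oocyte_geometry with positive free area",
             class = "rnp_geometry_error")
  }
  with_seed(seed, {
    pos <- sample_in_geometry(n_rna, geometry)
    copies <- as.integer(sample(names(copy_dist), n_rna, replace = TRUE,
                                prob = copy_dist))
    inten <- pmax(copies * unit * (1 + rnorm(n_rna, 0, cv)), 0)
    bin <- assign_bin(copies)$label
    p <- unname(ifelse(bin %in% names(coloc_prob), coloc_prob[bin], 0))
    colocalized <- runif(n_rna) < p

    n_col <- sum(colocalized)
    # reporters placed uniformly within a disc of radius coloc_radius / 2
    ang <- runif(n_col, 0, 2 * pi)
    rad <- (coloc_radius / 2) * sqrt(runif(n_col))
    rep_pos <- pos[colocalized, , drop = FALSE] +
      cbind(rad * cos(ang), rad * sin(ang))
    rep_int <- pmax(reporter_slope * copies[colocalized] *
                      (1 + rnorm(n_col, 0, cv)), 0)
    bg_pos <- sample_in_geometry(background_reporters, geometry)
    bg_int <- pmax(reporter_slope * (1 + rnorm(background_reporters, 0, cv)), 0)

    rnp <- data.frame(
      id = paste0("rnp", seq_len(n_rna)), specimen_id = specimen_id,
      channel = "rna", x = pos[, 1], y = pos[, 2], intensity = inten,
      compartment = compartment, stage = stage)
    n_reporters <- n_col + background_reporters
    reporters <- data.frame(
      id = paste0("rep", seq_len(n_reporters), recycle0 = TRUE),
      specimen_id = rep(specimen_id, n_reporters),
      channel = rep("reporter", n_reporters),
      x = c(rep_pos[, 1], bg_pos[, 1]), y = c(rep_pos[, 2], bg_pos[, 2]),
      intensity = c(rep_int, bg_int),
      compartment = rep(compartment, n_reporters),
      stage = rep(stage, n_reporters))
    truth <- list(
      rnp = data.frame(id = rnp$id, copies = copies, bin = bin,
                       colocalized = colocalized,
                       reporter_intensity = {
                         ri <- rep(NA_real_, n_rna)
                         ri[colocalized] <- rep_int
                         ri
                       }),
      params = list(copy_dist = copy_dist, unit = unit, cv = cv,
                    coloc_prob = coloc_prob, reporter_slope = reporter_slope,
                    background_reporters = background_reporters,
                    coloc_radius = coloc_radius, seed = seed))
    list(detections = as_detections(rbind(rnp, reporters)), truth = truth)
  })
}

#' Simulate an AP-profiled signal point cloud in an oocyte
#'
#' Samples `n_points` signal carriers inside the outline with density along
#' the AP axis proportional to `ap_profile` (uniform orthogonally within the
#' outline), each with weight `1 / n_points` so the total signal is 1.
#'
#' @param geometry an [oocyte_geometry()].
#' @param ap_profile vectorized nonnegative function of AP fraction in
#'   `[0, 1]`.
#' @param n_points number of points.
#' @param seed RNG seed.
#' @return data.frame with columns `x`, `y`, `weight`.
#' @export
gen_oocyte_signal <- function(geometry, ap_profile, n_points, seed = NULL) {
  grid <- seq(0, 1, length.out = 512)
  vals <- ap_profile(grid)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop_rnp("ap_profile must be finite and nonnegative",
             class = "rnp_validation_error")
  }
  mx <- max(vals)
  if (mx <= 0) {
    stop_rnp("ap_profile is identically zero", class = "rnp_validation_error")
  }
  with_seed(seed, {
    out <- matrix(NA_real_, 0, 2)
    while (nrow(out) < n_points) {
      m <- max(2L * (n_points - nrow(out)), 256L)
      cand <- sample_in_geometry(m, geometry)
      tfrac <- pmin(pmax(ap_fraction(cand, geometry), 0), 1)
      keep <- runif(m) < ap_profile(tfrac) / mx
      out <- rbind(out, cand[keep, , drop = FALSE])
    }
    out <- out[seq_len(n_points), , drop = FALSE]
    data.frame(x = out[, 1], y = out[, 2], weight = 1 / n_points)
  })
}

#' Simulate directed RNP trajectories with microtubule polarity labels
#'
#' Each track carries one constant-velocity run along its microtubule
#' polarity axis (plus-end-directed with probability `plus_fraction`),
#' flanked by stationary pause frames, with additive Gaussian localization
#' noise. The per-track polarity reference (unit vector toward the
#' microtubule plus end) emulates EB1-comet-derived polarity. Track
#' intensity reflects a true RNA copy number drawn from `rna_units_dist`.
#'
#' @param n_tracks number of tracks.
#' @param plus_fraction probability that a run is plus-end directed.
#' @param speed_plus,speed_minus functions `n -> speeds` (µm/s); defaults
#'   uniform on `[0.5, 1.5]`.
#' @param runlen_plus,runlen_minus functions `n -> run lengths` (µm);
#'   defaults `0.5 + rexp(n, 1)`.
#' @param rna_units_dist named probability vector over true copy numbers.
#' @param unit,cv single-copy intensity and noise CV for track intensities.
#' @param loc_noise localization noise SD in µm (default 0.02).
#' @param pause_frames stationary frames before and after the run.
#' @param frame_rate frames per second (default 20).
#' @param seed RNG seed.
#' @return list with `tracks` (data.frame `track_id`, `t`, `x`, `y`,
#'   `intensity`), `polarity` (data.frame `track_id`, `ux`, `uy`), and
#'   `truth` (one row per run: direction, speed, length, duration, copies).
#' @export
gen_tracks <- function(n_tracks, plus_fraction = 0.65,
                       speed_plus = function(n) runif(n, 0.5, 1.5),
                       speed_minus = function(n) runif(n, 0.5, 1.5),
                       runlen_plus = function(n) 0.5 + rexp(n, 1),
                       runlen_minus = function(n) 0.5 + rexp(n, 1),
                       rna_units_dist = c("1" = 0.5, "2" = 0.35, "4" = 0.15),
                       unit = 100, cv = 0.15, loc_noise = 0.02,
                       pause_frames = 3L, frame_rate = 20, seed = NULL) {
  if (plus_fraction < 0 || plus_fraction > 1) {
    stop_rnp("plus_fraction must lie in [0, 1]", class = "rnp_validation_error")
  }
  with_seed(seed, {
    dt <- 1 / frame_rate
    plus <- runif(n_tracks) < plus_fraction
    speed <- ifelse(plus, speed_plus(n_tracks), speed_minus(n_tracks))
    rlen <- ifelse(plus, runlen_plus(n_tracks), runlen_minus(n_tracks))
    copies <- as.integer(sample(names(rna_units_dist), n_tracks,
                                replace = TRUE, prob = rna_units_dist))
    inten <- pmax(copies * unit * (1 + rnorm(n_tracks, 0, cv)), 0)
    # random polarity axis orientation per track
    theta <- runif(n_tracks, 0, 2 * pi)
    rows <- vector("list", n_tracks)
    truth <- vector("list", n_tracks)
    for (i in seq_len(n_tracks)) {
      run_frames <- max(ceiling(rlen[i] / (speed[i] * dt)), 3L)
      length_i <- run_frames * speed[i] * dt
      n_frames <- run_frames + 2L * pause_frames + 1L
      s <- c(rep(0, pause_frames),
             seq(0, length_i, length.out = run_frames + 1L),
             rep(length_i, pause_frames))
      sgn <- if (plus[i]) 1 else -1
      u <- c(cos(theta[i]), sin(theta[i]))
      x0 <- runif(1, 0, 50); y0 <- runif(1, 0, 50)
      rows[[i]] <- data.frame(
        track_id = paste0("trk", i),
        t = (seq_len(n_frames) - 1L) * dt,
        x = x0 + sgn * s * u[1] + rnorm(n_frames, 0, loc_noise),
        y = y0 + sgn * s * u[2] + rnorm(n_frames, 0, loc_noise),
        intensity = inten[i])
      truth[[i]] <- data.frame(
        track_id = paste0("trk", i),
        direction = if (plus[i]) "plus" else "minus",
        speed = speed[i], length = length_i,
        duration = run_frames * dt, copies = copies[i],
        intensity = inten[i])
    }
    list(tracks = do.call(rbind, rows),
         polarity = data.frame(track_id = paste0("trk", seq_len(n_tracks)),
                               ux = cos(theta), uy = sin(theta)),
         truth = do.call(rbind, truth))
  })
}

#' Simulate in vitro single-molecule traces on microtubules
#'
#' Per microtubule, specific landing events arrive as a Poisson process with
#' rate `binding_rate` (events per µm per min). Each event dwells a
#' geometric number of frames (mean `mean_dwell`, minimum 1). A fraction
#' `processive_fraction` of specific events with dwell of at least 3 frames
#' move unidirectionally at a velocity drawn from `velocity_dist`; the rest
#' jitter in place. Non-specific surface landings occur uniformly over the
#' imaging surface at `background_rate` events per minute per region sized
#' to the median microtubule length: they appear both in microtubule-free
#' background regions and, scaled by microtubule length, within each
#' microtubule's kymograph region (never processive). This is what the
#' background correction removes.
#'
#' @param n_microtubules number of microtubules.
#' @param mt_length_dist function `n -> lengths` (µm); default
#'   `runif(n, 5, 15)`.
#' @param binding_rate on-microtubule landing rate (events/µm/min).
#' @param processive_fraction fraction of >= 3-frame events that are
#'   processive.
#' @param velocity_dist function `n -> velocities` (µm/s); default
#'   `runif(n, 0.5, 1.5)`.
#' @param background_rate non-specific landing rate (events per
#'   median-length region per min).
#' @param n_background_regions number of microtubule-free regions.
#' @param duration movie length in frames.
#' @param frame_rate frames per second (default 4).
#' @param mean_dwell mean event dwell in frames (default 8).
#' @param jitter_sd positional jitter SD in µm for non-processive events.
#' @param seed RNG seed.
#' @return list with `traces` (data.frame `trace_id`, `mt_id`, `region`
#'   (`"mt"`/`"background"`), `frame`, `position` in µm along the
#'   microtubule), `mt` (data.frame `mt_id`, `length`), and `truth`
#'   (per-event table with a `nonspecific` flag, plus the generator
#'   parameters).
#' @export
gen_invitro <- function(n_microtubules,
                        mt_length_dist = function(n) runif(n, 5, 15),
                        binding_rate = 2, processive_fraction = 0.5,
                        velocity_dist = function(n) runif(n, 0.5, 1.5),
                        background_rate = 0.5, n_background_regions = 5L,
                        duration = 720L, frame_rate = 4, mean_dwell = 8,
                        jitter_sd = 0.02, seed = NULL) {
  if (binding_rate < 0 || background_rate < 0) {
    stop_rnp("rates must be >= 0", class = "rnp_validation_error")
  }
  with_seed(seed, {
    mt_len <- mt_length_dist(n_microtubules)
    med_len <- stats::median(mt_len)
    duration_min <- duration / frame_rate / 60
    # one row per event: where it lands and whether it is specific
    n_spec <- rpois(n_microtubules, binding_rate * mt_len * duration_min)
    n_ns_mt <- rpois(n_microtubules,
                     background_rate * (mt_len / med_len) * duration_min)
    n_bg <- rpois(n_background_regions, background_rate * duration_min)
    ev <- data.frame(
      mt_id = c(rep(paste0("mt", seq_len(n_microtubules)), n_spec),
                rep(paste0("mt", seq_len(n_microtubules)), n_ns_mt),
                rep(paste0("bg", seq_len(n_background_regions)), n_bg)),
      region = c(rep("mt", sum(n_spec) + sum(n_ns_mt)),
                 rep("background", sum(n_bg))),
      region_len = c(rep(mt_len, n_spec), rep(mt_len, n_ns_mt),
                     rep(med_len, sum(n_bg))),
      nonspecific = c(rep(FALSE, sum(n_spec)),
                      rep(TRUE, sum(n_ns_mt) + sum(n_bg))))
    n_ev <- nrow(ev)
    if (n_ev > 0) {
      ev$trace_id <- paste0("tr", seq_len(n_ev))
      ev$dwell <- pmin(1L + stats::rgeom(n_ev, 1 / mean_dwell), duration)
      ev$start <- vapply(ev$dwell, function(d) {
        sample.int(max(duration - d + 1L, 1L), 1L)
      }, integer(1))
      ev$processive <- !ev$nonspecific & ev$dwell >= 3L &
        runif(n_ev) < processive_fraction
      x0 <- runif(n_ev) * ev$region_len
      vel <- velocity_dist(n_ev) * sample(c(-1, 1), n_ev, replace = TRUE)
      idx <- rep(seq_len(n_ev), ev$dwell)
      off <- sequence(ev$dwell) - 1L
      pos <- ifelse(ev$processive[idx],
                    x0[idx] + vel[idx] * off / frame_rate,
                    x0[idx] + rnorm(length(idx), 0, jitter_sd))
      traces_df <- data.frame(
        trace_id = ev$trace_id[idx], mt_id = ev$mt_id[idx],
        region = ev$region[idx], frame = ev$start[idx] + off,
        position = pos)
    } else {
      traces_df <- data.frame(trace_id = character(), mt_id = character(),
                              region = character(), frame = integer(),
                              position = numeric())
    }
    events_df <- if (n_ev > 0) {
      ev[, c("trace_id", "mt_id", "region", "dwell", "processive",
             "nonspecific")]
    } else {
      data.frame(trace_id = character(), mt_id = character(),
                 region = character(), dwell = integer(),
                 processive = logical(), nonspecific = logical())
    }
    list(traces = traces_df,
         mt = data.frame(mt_id = paste0("mt", seq_len(n_microtubules)),
                         length = mt_len),
         truth = list(events = events_df,
                      params = list(binding_rate = binding_rate,
                                    processive_fraction = processive_fraction,
                                    background_rate = background_rate,
                                    duration = duration,
                                    frame_rate = frame_rate,
                                    median_mt_length = med_len,
                                    seed = seed)))
  })
}
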