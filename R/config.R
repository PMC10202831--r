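#' Analysis configuration
#'
#' Bundles the tunable parameters shared across the pipeline stages. All
#' lengths are in micrometers; the acquisition interval follows from
#' `frame_rate`. A single `rng_seed` governs every stochastic step
#' (randomization nulls, grouping, simulations) so runs are reproducible.
#'
#' @param pixel_size Pixel edge length in µm used to convert pixel-based
#'   thresholds (default 0.107 µm, so the 5-pixel processivity threshold
#'   corresponds to ~0.54 µm).
#' @param coloc_radius Nearest-neighbor distance (µm) below which an RNP and
#'   a reporter are called colocalized. Default 0.25 µm, on the order of the
#'   lateral resolution of the imaging.
#' @param n_randomizations Number of reporter-channel randomizations used to
#'   estimate the expected (chance) colocalization frequency.
#' @param group_size RNPs per group when estimating confidence intervals of
#'   corrected colocalization frequencies (default 50).
#' @param bin_max_exponent Largest exponent i of the power-of-two copy-number
#'   bins \eqn{[2^i, 2^{i+1})} (default 8, i.e. bins up to 256:511).
#' @param min_binding_frames Minimum number of continuous frames for a
#'   microtubule binding event (default 3).
#' @param min_processive_px Minimum unidirectional displacement in pixels for
#'   a processive event (default 5).
#' @param frame_rate Acquisition rate in frames per second (default 20).
#' @param rng_seed Integer seed for all stochastic steps.
#'
#' @return An object of class `rnp_config` (a validated list).
#' @examples
#' cfg <- rnp_config(rng_seed = 1)
#' cfg$coloc_radius
#' @export
rnp_config <- function(pixel_size = 0.107,
                       coloc_radius = 0.25,
                       n_randomizations = 100L,
                       group_size = 50L,
                       bin_max_exponent = 8L,
                       min_binding_frames = 3L,
                       min_processive_px = 5L,
                       frame_rate = 20,
                       rng_seed = 1L) {
  cfg <- list(
    pixel_size = as.numeric(pixel_size),
    coloc_radius = as.numeric(coloc_radius),
    n_randomizations = as.integer(n_randomizations),
    group_size = as.integer(group_size),
    bin_max_exponent = as.integer(bin_max_exponent),
    min_binding_frames = as.integer(min_binding_frames),
    min_processive_px = as.integer(min_processive_px),
    frame_rate = as.numeric(frame_rate),
    rng_seed = as.integer(rng_seed)
  )
  counts <- c("n_randomizations", "group_size", "min_binding_frames",
              "min_processive_px")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L) {
      stop_rnp("'%s' must be a count >= 1", nm, class = "rnp_validation_error")
    }
  }
  if (cfg$bin_max_exponent < 0L) {
    stop_rnp("'bin_max_exponent' must be >= 0", class = "rnp_validation_error")
  }
  for (nm in c("pixel_size", "coloc_radius", "frame_rate")) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop_rnp("'%s' must be > 0", nm, class = "rnp_validation_error")
    }
  }
  structure(cfg, class = "rnp_config")
}

#' @export
print.rnp_config <- function(x, ...) {
  cat("<rnp_config>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
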