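#' Calibrate spot intensities into relative RNA units
#'
#' Single-molecule FISH (or MS2/MCP-GFP) spots have intensities proportional
#' to the number of RNA copies they contain. A Gaussian mixture is fitted to
#' the raw intensity distribution; one mixture component corresponds to the
#' unimolecular (single-copy) population and its mean defines the intensity
#' of one RNA unit. Two unit-selection policies are supported:
#' \describe{
#'   \item{`smallest_mean`}{the smallest fitted component mean is the unit
#'     (used for ex vivo time-lapse series, fitted per series);}
#'   \item{`dominant_component`}{the mean of the component carrying the
#'     largest mixture weight is the unit (used for fixed-tissue data, where
#'     the single-copy population dominates the nurse cells and its mean is
#'     in practice almost the lowest fitted mean).}
#' }
#'
#' @param intensities numeric vector of raw intensities (>= 50 finite,
#'   positive values required).
#' @param K_range candidate numbers of mixture components; the best K is
#'   chosen by BIC. Default 1:8.
#' @param policy unit-selection policy, see above. Default
#'   `"dominant_component"`.
#' @param seed RNG seed governing the initialization restarts.
#' @param n_restarts number of independently initialized EM fits (model-based
#'   hierarchical initialization on a random data subset); the restart with
#'   the best BIC wins. For samples small enough that initialization uses
#'   all points, a single deterministic fit is performed.
#' @param merge_ratio adjacent fitted components whose mean ratio falls
#'   below this value are consolidated (weight-averaged) before unit
#'   selection. Genuine copy-number populations have means at integer
#'   multiples of the unit, so no two resolvable populations below five
#'   copies can have a mean ratio under 5/4; closer pairs are split
#'   artifacts of a single population. Default 1.25; set to 1 to disable.
#' @return A `calibration_model`: list with `K`, `means`, `sds`, `weights`
#'   (sorted by ascending mean), `unit`, `policy` and `fit_diagnostics`
#'   (`loglik`, `bic` per K, `n_points`, `seed`).
#' @examples
#' set.seed(1)
#' x <- c(rnorm(600, 100, 15), rnorm(300, 200, 25), rnorm(100, 400, 40))
#' m <- fit_mixture(x, policy = "smallest_mean")
#' m$unit
#' @export
fit_mixture <- function(intensities, K_range = 1:8,
                        policy = c("dominant_component", "smallest_mean"),
                        seed = NULL, n_restarts = 10L, merge_ratio = 1.25) {
  policy <- match.arg(policy)
  x <- intensities[is.finite(intensities) & intensities > 0]
  if (length(x) < 50) {
    stop_rnp("need >= 50 finite positive intensities (got %d)", length(x),
             class = "rnp_sample_size_error")
  }
  if (diff(range(x)) < .Machine$double.eps * max(abs(x))) {
    # degenerate: a single point mass; sigma -> 0 guard
    model <- list(K = 1L, means = x[1], sds = 0, weights = 1,
                  unit = x[1], policy = policy,
                  fit_diagnostics = list(loglik = Inf, bic = NULL,
                                         n_points = length(x), seed = seed))
    class(model) <- "calibration_model"
    return(model)
  }
  mclustBIC <- mclust::mclustBIC  # Mclust() resolves this in the caller
  one_fit <- function() {
    tryCatch(mclust::Mclust(x, G = K_range, modelNames = "V",
                            verbose = FALSE),
             error = function(e) NULL)
  }
  # initialization subsamples the data for large n; restart and keep the
  # best-BIC fit (for small n the initialization is deterministic)
  subset_size <- mclust::mclust.options("subset")
  if (length(x) <= subset_size) n_restarts <- 1L
  seeds <- derive_seeds(seed %||% sample.int(.Machine$integer.max, 1),
                        n_restarts)
  fit <- NULL
  best_bic <- -Inf
  for (s in seeds) {
    f <- with_seed(s, one_fit())
    if (!is.null(f)) {
      b <- max(f$BIC, na.rm = TRUE)
      if (b > best_bic) { best_bic <- b; fit <- f }
    }
  }
  if (is.null(fit)) {
    stop_rnp("mixture fit failed to converge for all K in [%d, %d]",
             min(K_range), max(K_range), class = "rnp_calibration_error")
  }
  means <- as.numeric(fit$parameters$mean)
  sds <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sds) == 1L) sds <- rep(sds, length(means))
  weights <- as.numeric(fit$parameters$pro)
  ord <- order(means)
  means <- means[ord]; sds <- sds[ord]; weights <- weights[ord]
  merged <- merge_components(means, sds, weights, merge_ratio)
  means <- merged$means; sds <- merged$sds; weights <- merged$weights
  unit <- switch(policy,
                 smallest_mean = means[1],
                 dominant_component = means[which.max(weights)])
  model <- list(
    K = length(means), means = means, sds = sds, weights = weights,
    unit = unit, policy = policy,
    fit_diagnostics = list(loglik = fit$loglik,
                           bic = fit$BIC[, "V", drop = TRUE],
                           K_fitted = fit$G, n_merged = merged$n_merged,
                           n_points = length(x), seed = seed))
  class(model) <- "calibration_model"
  model
}

# Consolidate adjacent mixture components (sorted by mean) whose mean ratio
# is below `ratio`: moments are combined by mixture weight.
merge_components <- function(means, sds, weights, ratio) {
  n_merged <- 0L
  repeat {
    if (length(means) < 2) break
    r <- means[-1] / means[-length(means)]
    i <- which(r < ratio)
    if (!length(i)) break
    i <- i[1]
    w <- weights[i] + weights[i + 1]
    mu <- (weights[i] * means[i] + weights[i + 1] * means[i + 1]) / w
    # pooled second moment: within- plus between-component variance
    v <- (weights[i] * (sds[i]^2 + means[i]^2) +
            weights[i + 1] * (sds[i + 1]^2 + means[i + 1]^2)) / w - mu^2
    means <- c(means[seq_len(i - 1)], mu, means[-seq_len(i + 1)])
    sds <- c(sds[seq_len(i - 1)], sqrt(max(v, 0)), sds[-seq_len(i + 1)])
    weights <- c(weights[seq_len(i - 1)], w, weights[-seq_len(i + 1)])
    n_merged <- n_merged + 1L
  }
  list(means = means, sds = sds, weights = weights, n_merged = n_merged)
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> K = %d, unit = %.4g (policy: %s)\n",
              x$K, x$unit, x$policy))
  comp <- data.frame(mean = x$means, sd = x$sds, weight = x$weights)
  print(comp, digits = 4)
  invisible(x)
}

#' Convert a raw intensity to relative RNA units
#'
#' @param intensity raw intensity (a.u.), scalar or vector.
#' @param model a `calibration_model` with `unit > 0`.
#' @return `intensity / model$unit` (dimensionless relative RNA units).
#' @export
normalize_intensity <- function(intensity, model) {
  stopifnot(inherits(model, "calibration_model"), model$unit > 0)
  intensity / model$unit
}

#' Power-of-two copy-number bins
#'
#' RNPs are stratified by normalized RNA content into bins
#' \eqn{[2^i, 2^{i+1})} for \eqn{i = 0, \dots,} `bin_max_exponent`, labelled
#' `"1"`, `"2:3"`, `"4:7"`, `"8:15"`, and so on.
#'
#' @param bin_max_exponent largest exponent (default 8).
#' @return data.frame with columns `index`, `label`, `lower`, `upper`
#'   (half-open intervals).
#' @export
copy_bins <- function(bin_max_exponent = 8L) {
  i <- 0:bin_max_exponent
  lower <- 2^i
  upper <- 2^(i + 1)
  label <- ifelse(i == 0, "1", paste0(lower, ":", upper - 1))
  data.frame(index = i, label = label, lower = lower, upper = upper)
}

#' Assign normalized RNA content to a copy-number bin
#'
#' Values in \eqn{[2^i, 2^{i+1})} map to bin i. Values in `[0.5, 1)` are
#' rounded up into bin `"1"`; values below 0.5 are flagged `sub_unit` and
#' excluded downstream by default. Values at or above \eqn{2^{max+1}} clamp
#' to the top bin with `clamped = TRUE`.
#'
#' @param relative_units nonnegative numeric vector of normalized RNA
#'   content.
#' @param bin_max_exponent largest exponent (default 8).
#' @return data.frame with columns `index` (NA for sub-unit), `label`
#'   (`"sub_unit"` or a bin label) and `clamped`.
#' @examples
#' assign_bin(c(0.2, 0.7, 1, 3.999, 4, 5.2, 600))$label
#' @export
assign_bin <- function(relative_units, bin_max_exponent = 8L) {
  if (any(!is.finite(relative_units)) || any(relative_units < 0)) {
    stop_rnp("relative_units must be finite and >= 0",
             class = "rnp_validation_error")
  }
  bins <- copy_bins(bin_max_exponent)
  idx <- floor(log2(pmax(relative_units, .Machine$double.xmin)))
  idx[relative_units < 1] <- 0  # [0.5, 1) rounds up into bin "1"
  clamped <- idx > bin_max_exponent
  idx[clamped] <- bin_max_exponent
  sub <- relative_units < 0.5
  out <- data.frame(index = ifelse(sub, NA_integer_, idx),
                    label = ifelse(sub, "sub_unit", bins$label[idx + 1]),
                    clamped = clamped & !sub)
  out
}

#' Calibrate a detection table
#'
#' Fits the intensity mixture (on nurse-cell detections of the requested
#' channel when any are present, otherwise on all non-excluded detections of
#' that channel), then adds `relative_units` and `bin_label` columns for
#' every detection of that channel.
#'
#' @param detections an `rnp_detections` table.
#' @param channel `"rna"` or `"reporter"`.
#' @param config an [rnp_config()].
#' @param policy unit policy passed to [fit_mixture()].
#' @return list with `detections` (augmented table) and `model`.
#' @export
calibrate_detections <- function(detections, channel = "rna",
                                 config = rnp_config(),
                                 policy = "dominant_component") {
  detections <- as_detections(detections)
  usable <- drop_excluded(detections)
  chan <- usable[usable$channel == channel, , drop = FALSE]
  ref <- chan[chan$compartment == "nurse_cell", , drop = FALSE]
  if (nrow(ref) < 50) ref <- chan
  model <- fit_mixture(ref$intensity, policy = policy,
                       seed = config$rng_seed)
  sel <- detections$channel == channel
  ru <- rep(NA_real_, nrow(detections))
  ru[sel] <- normalize_intensity(detections$intensity[sel], model)
  bl <- rep(NA_character_, nrow(detections))
  bl[sel] <- assign_bin(ru[sel], config$bin_max_exponent)$label
  detections$relative_units <- ru
  detections$bin_label <- bl
  list(detections = detections, model = model)
}
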