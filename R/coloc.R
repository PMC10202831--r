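#' Nearest-neighbor pairs between RNPs and reporters
#'
#' For each RNP, finds the geometrically nearest reporter (Euclidean
#' distance, 2D by default or 3D when both tables carry finite `z`). Ties
#' are broken toward the lowest reporter id. With no reporters, distances
#' are `Inf` and no pair is assigned (not an error).
#'
#' @param rnps,reporters `rnp_detections` tables from the same specimen and
#'   compartment; `excluded`-compartment rows are dropped.
#' @param use_z use 3D distances (requires finite `z` in both tables).
#' @return data.frame with one row per RNP: `rnp_id`, `nn_id`,
#'   `nn_distance` (µm).
#' @export
nearest_neighbor_pairs <- function(rnps, reporters, use_z = FALSE) {
  rnps <- drop_excluded(as_detections(rnps))
  reporters <- drop_excluded(as_detections(reporters))
  reporters <- reporters[order(reporters$id), , drop = FALSE]
  if (nrow(reporters) == 0) {
    return(data.frame(rnp_id = rnps$id, nn_id = NA_character_,
                      nn_distance = Inf))
  }
  if (use_z) {
    if (any(!is.finite(rnps$z)) || any(!is.finite(reporters$z))) {
      stop_rnp("use_z = TRUE requires finite z coordinates",
               class = "rnp_validation_error")
    }
    nn <- nn_pairs3_cpp(rnps$x, rnps$y, rnps$z,
                        reporters$x, reporters$y, reporters$z)
  } else {
    nn <- nn_pairs_cpp(rnps$x, rnps$y, reporters$x, reporters$y)
  }
  data.frame(rnp_id = rnps$id, nn_id = reporters$id[nn$index],
             nn_distance = nn$distance)
}

#' Observed colocalization frequency per copy-number bin
#'
#' @param pairs output of [nearest_neighbor_pairs()] augmented with a `bin`
#'   column (copy-number bin label per RNP; `"sub_unit"` rows are excluded).
#' @param coloc_radius colocalization cutoff in µm.
#' @return data.frame per non-empty bin: `bin`, `n_rnp`, `f_obs` (percent).
#' @export
observed_frequency <- function(pairs, coloc_radius) {
  stopifnot("bin" %in% names(pairs))
  pairs <- pairs[pairs$bin != "sub_unit", , drop = FALSE]
  if (nrow(pairs) == 0) {
    return(data.frame(bin = character(), n_rnp = integer(),
                      f_obs = numeric()))
  }
  hit <- pairs$nn_distance <= coloc_radius
  agg <- aggregate(hit, by = list(bin = pairs$bin),
                   FUN = function(v) c(n = length(v), f = 100 * mean(v)))
  data.frame(bin = agg$bin, n_rnp = as.integer(agg$x[, "n"]),
             f_obs = agg$x[, "f"])
}

#' Expected (chance) colocalization frequency via randomization
#'
#' Estimates the colocalization frequency expected from object densities
#' alone: reporter positions are repeatedly resampled uniformly inside the
#' compartment geometry (minus nuclear masks, reporter count preserved;
#' RNP positions stay fixed) and the observed frequency is recomputed.
#'
#' @param rnps calibrated RNP detections with a `bin_label` column.
#' @param reporters reporter detections (only their count is used).
#' @param geometry compartment [oocyte_geometry()].
#' @param coloc_radius cutoff (µm).
#' @param n_randomizations number of randomizations (default 100).
#' @param seed RNG seed.
#' @return data.frame per bin: `bin`, `n_rnp`, `f_exp` (percent, mean over
#'   randomizations), `mc_se` (Monte Carlo standard error of `f_exp`).
#' @export
expected_frequency <- function(rnps, reporters, geometry, coloc_radius,
                               n_randomizations = 100L, seed = NULL) {
  rnps <- drop_excluded(as_detections(rnps))
  stopifnot("bin_label" %in% names(rnps))
  rnps <- rnps[rnps$bin_label != "sub_unit", , drop = FALSE]
  if (free_area(geometry) <= 0) {
    stop_rnp("geometry has no positive free area", class = "rnp_geometry_error")
  }
  n_rep <- nrow(drop_excluded(as_detections(reporters)))
  bins <- sort(unique(rnps$bin_label))
  n_rnp <- as.integer(table(factor(rnps$bin_label, levels = bins)))
  if (n_rep == 0 || coloc_radius <= 0 || nrow(rnps) == 0) {
    return(data.frame(bin = bins, n_rnp = n_rnp, f_exp = 0, mc_se = 0))
  }
  freq <- with_seed(seed, {
    vapply(seq_len(n_randomizations), function(b) {
      pos <- sample_in_geometry(n_rep, geometry)
      hit <- any_within_cpp(rnps$x, rnps$y, pos[, 1], pos[, 2], coloc_radius)
      100 * vapply(bins, function(bn) mean(hit[rnps$bin_label == bn]),
                   numeric(1))
    }, numeric(length(bins)))
  })
  freq <- matrix(freq, nrow = length(bins))
  data.frame(bin = bins, n_rnp = n_rnp,
             f_exp = rowMeans(freq),
             mc_se = apply(freq, 1, sd) / sqrt(n_randomizations))
}

#' Density-corrected colocalization frequency
#'
#' @param f_obs,f_exp observed and expected frequencies (percent), scalars,
#'   vectors, or the data.frames returned by [observed_frequency()] and
#'   [expected_frequency()] (merged on `bin`).
#' @return `f_obs - f_exp`; negative values indicate depletion of the
#'   reporter from the RNPs relative to chance.
#' @export
corrected_frequency <- function(f_obs, f_exp) {
  if (is.data.frame(f_obs) && is.data.frame(f_exp)) {
    m <- merge(f_obs, f_exp[, c("bin", "f_exp", "mc_se")], by = "bin")
    m$f_corr <- m$f_obs - m$f_exp
    return(m)
  }
  f_obs - f_exp
}

#' Grouped confidence interval for corrected colocalization
#'
#' RNPs of one bin are randomly partitioned into groups of `group_size`
#' (the remainder is dropped). Each group yields a corrected frequency
#' (group observed percentage minus the bin's expected percentage); the
#' group values give the mean, a t-based 95% confidence interval, and a
#' one-sample t test against zero. Bins whose test yields p > 0.01 are
#' flagged as not different from zero.
#'
#' @param colocalized logical vector: per-RNP colocalization indicator.
#' @param f_exp expected frequency (percent) for this bin.
#' @param group_size RNPs per group (default 50).
#' @param seed RNG seed for the random partition.
#' @return list with `mean`, `ci95` (length 2), `p_zero`, `n_groups`,
#'   `zero_flag` (TRUE when p > 0.01 or the test is degenerate with mean 0)
#'   and `degenerate` (zero variance across groups).
#' @export
grouped_ci <- function(colocalized, f_exp, group_size = 50L, seed = NULL) {
  n_groups <- length(colocalized) %/% group_size
  if (n_groups < 2) {
    stop_rnp("need at least 2 complete groups (have %d RNPs, group size %d)",
             length(colocalized), group_size,
             class = "rnp_insufficient_data_error")
  }
  g <- with_seed(seed, sample(length(colocalized)))[seq_len(n_groups * group_size)]
  idx <- matrix(g, nrow = group_size)
  vals <- 100 * colMeans(matrix(colocalized[idx], nrow = group_size)) - f_exp
  m <- mean(vals)
  if (sd(vals) == 0) {
    return(list(mean = m, ci95 = c(m, m), p_zero = NA_real_,
                n_groups = n_groups, zero_flag = m == 0, degenerate = TRUE))
  }
  tt <- t.test(vals, mu = 0)
  list(mean = m, ci95 = unname(tt$conf.int), p_zero = tt$p.value,
       n_groups = n_groups, zero_flag = tt$p.value > 0.01,
       degenerate = FALSE)
}

#' Mean normalized reporter intensity of colocalized pairs per bin
#'
#' For pairs within the colocalization radius, reporter intensities are
#' normalized by the reporter calibration unit and averaged per copy-number
#' bin; optionally divided by a nurse-cell reference value to compare
#' compartments.
#'
#' @param pairs nearest-neighbor pairs with `bin` and `reporter_intensity`
#'   columns.
#' @param reporter_model reporter `calibration_model`.
#' @param coloc_radius cutoff (µm).
#' @param reference optional reference value (e.g. nurse-cell mean) to
#'   divide by.
#' @return data.frame per bin with `bin`, `n_pairs`, `mean_reporter_units`
#'   (bins without colocalized pairs are omitted).
#' @export
reporter_intensity_per_bin <- function(pairs, reporter_model, coloc_radius,
                                       reference = NULL) {
  stopifnot(all(c("bin", "reporter_intensity") %in% names(pairs)))
  sel <- pairs$nn_distance <= coloc_radius & pairs$bin != "sub_unit"
  pairs <- pairs[sel, , drop = FALSE]
  if (nrow(pairs) == 0) {
    return(data.frame(bin = character(), n_pairs = integer(),
                      mean_reporter_units = numeric()))
  }
  units <- normalize_intensity(pairs$reporter_intensity, reporter_model)
  if (!is.null(reference)) units <- units / reference
  agg <- aggregate(units, by = list(bin = pairs$bin),
                   FUN = function(v) c(n = length(v), m = mean(v)))
  data.frame(bin = agg$bin, n_pairs = as.integer(agg$x[, "n"]),
             mean_reporter_units = agg$x[, "m"])
}

#' Linear scaling of reporter intensity with RNA copy number
#'
#' Ordinary least squares of normalized reporter intensity on copy number.
#' With a second group, a shared model with a group-by-copies interaction is
#' fitted and the interaction p-value reports whether the two slopes differ.
#'
#' @param copies numeric vector of RNA copy numbers (>= 3 distinct values).
#' @param reporter_units normalized reporter intensities.
#' @param group optional factor of two levels for slope comparison.
#' @return list with `slope`, `intercept`, `slope_ci`, `r_squared`,
#'   `slope_p` and (two-group case) `slope2`, `interaction_p`.
#' @export
fit_scaling <- function(copies, reporter_units, group = NULL) {
  if (length(unique(copies)) < 3) {
    stop_rnp("need >= 3 distinct copy-number values",
             class = "rnp_validation_error")
  }
  if (is.null(group)) {
    fit <- lm(reporter_units ~ copies)
    sm <- summary(fit)
    return(list(slope = unname(coef(fit)["copies"]),
                intercept = unname(coef(fit)["(Intercept)"]),
                slope_ci = unname(confint(fit)["copies", ]),
                r_squared = sm$r.squared,
                slope_p = sm$coefficients["copies", "Pr(>|t|)"]))
  }
  group <- factor(group)
  if (nlevels(group) != 2) {
    stop_rnp("group must have exactly 2 levels", class = "rnp_validation_error")
  }
  fit <- lm(reporter_units ~ copies * group)
  sm <- summary(fit)
  cf <- coef(fit)
  inter_term <- grep(":", names(cf), value = TRUE)
  list(slope = unname(cf["copies"]),
       slope2 = unname(cf["copies"] + cf[inter_term]),
       intercept = unname(cf["(Intercept)"]),
       slope_ci = unname(confint(fit)["copies", ]),
       r_squared = sm$r.squared,
       slope_p = sm$coefficients["copies", "Pr(>|t|)"],
       interaction_p = sm$coefficients[inter_term, "Pr(>|t|)"])
}

#' Full per-bin colocalization analysis
#'
#' Chains nearest-neighbor pairing, observed / expected / corrected
#' frequencies, grouped confidence intervals, and the mean normalized
#' reporter intensity for one specimen-compartment.
#'
#' @param rnps calibrated RNP detections (with `bin_label`).
#' @param reporters reporter detections.
#' @param geometry compartment [oocyte_geometry()].
#' @param config an [rnp_config()].
#' @param reporter_model optional reporter `calibration_model`; when absent,
#'   `mean_reporter_units` is omitted.
#' @return data.frame, one row per copy-number bin, with the fields of the
#'   colocalization result: `bin`, `n_rnp`, `f_obs`, `f_exp`, `f_corr`,
#'   `ci_lo`, `ci_hi`, `p_zero`, `zero_flag`, `rel_abundance` and
#'   (if calibrated) `mean_reporter_units`. Bins with fewer than two
#'   complete groups get `NA` intervals.
#' @export
coloc_analysis <- function(rnps, reporters, geometry, config = rnp_config(),
                           reporter_model = NULL) {
  rnps <- as_detections(rnps)
  stopifnot("bin_label" %in% names(rnps))
  rnps <- drop_excluded(rnps)
  rnps <- rnps[rnps$bin_label != "sub_unit", , drop = FALSE]
  reporters <- drop_excluded(as_detections(reporters))
  pairs <- nearest_neighbor_pairs(rnps, reporters)
  pairs$bin <- rnps$bin_label[match(pairs$rnp_id, rnps$id)]
  pairs$reporter_intensity <-
    reporters$intensity[match(pairs$nn_id, reporters$id)]
  obs <- observed_frequency(pairs, config$coloc_radius)
  expd <- expected_frequency(rnps, reporters, geometry, config$coloc_radius,
                             config$n_randomizations,
                             seed = config$rng_seed)
  res <- corrected_frequency(obs, expd)
  res$rel_abundance <- res$n_rnp / sum(res$n_rnp)
  seeds <- derive_seeds(config$rng_seed + 1L, nrow(res))
  ci <- lapply(seq_len(nrow(res)), function(k) {
    bn <- res$bin[k]
    ind <- pairs$nn_distance[pairs$bin == bn] <= config$coloc_radius
    if (length(ind) %/% config$group_size < 2) {
      return(list(ci95 = c(NA_real_, NA_real_), p_zero = NA_real_,
                  zero_flag = NA))
    }
    grouped_ci(ind, res$f_exp[k], config$group_size, seed = seeds[k])
  })
  res$ci_lo <- vapply(ci, function(z) z$ci95[1], numeric(1))
  res$ci_hi <- vapply(ci, function(z) z$ci95[2], numeric(1))
  res$p_zero <- vapply(ci, function(z) z$p_zero %||% NA_real_, numeric(1))
  res$zero_flag <- vapply(ci, function(z) isTRUE(z$zero_flag), logical(1))
  if (!is.null(reporter_model)) {
    ri <- reporter_intensity_per_bin(pairs, reporter_model,
                                     config$coloc_radius)
    res <- merge(res, ri[, c("bin", "mean_reporter_units")],
                 by = "bin", all.x = TRUE)
  }
  res[order(match(res$bin, copy_bins(config$bin_max_exponent)$label)), ]
}
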