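#' AP-axis-normalized RNA distribution matrix
#'
#' Redistributes a weighted signal point cloud into a `dim` x `dim`
#' (default 100 x 100) matrix normalized to the oocyte geometry. Each column
#' holds the relative amount of signal found under 1% of the
#' anteroposterior axis length (anterior = column 1, posterior = column
#' `dim`); the row coordinate is the point's fractional position along the
#' chord of the outline perpendicular to the AP axis at that AP position, so
#' both axes are shape-normalized. Entries sum to 1.
#'
#' @param signal data.frame with columns `x`, `y` and optionally `weight`
#'   (default 1 per point). Points outside the outline are dropped with a
#'   warning.
#' @param geometry an [oocyte_geometry()].
#' @param specimen_id identifier stored on the result.
#' @param dim matrix dimension (default 100).
#' @return A `distribution_matrix`: list with `M` (`dim` x `dim`, sums to
#'   1), `specimen_id`, `ap_length` (µm) and `centroid_ap` (geometric center
#'   of the outline as % of AP length).
#' @export
build_matrix <- function(signal, geometry, specimen_id = NA_character_,
                         dim = 100L) {
  stopifnot(all(c("x", "y") %in% names(signal)))
  w <- signal$weight %||% rep(1, nrow(signal))
  if ("weight" %in% names(signal)) w <- signal$weight
  pts <- cbind(signal$x, signal$y)
  inside <- points_in_poly(pts, geometry$outline)
  if (any(!inside)) {
    warning(sprintf("%d point(s) outside the outline dropped", sum(!inside)))
    pts <- pts[inside, , drop = FALSE]
    w <- w[inside]
  }
  if (nrow(pts) == 0 || sum(w) <= 0) {
    stop_rnp("zero total signal inside the outline",
             class = "rnp_validation_error")
  }
  tfrac <- pmin(pmax(ap_fraction(pts, geometry), 0), 1)
  ext <- chord_extent(tfrac, geometry)
  v <- perp_offset(pts, geometry)
  span <- ext[, 2] - ext[, 1]
  rfrac <- ifelse(is.finite(span) & span > 0,
                  (v - ext[, 1]) / span, 0.5)
  rfrac <- pmin(pmax(rfrac, 0), 1)
  col <- pmin(floor(tfrac * dim) + 1L, dim)
  row <- pmin(floor(rfrac * dim) + 1L, dim)
  M <- matrix(0, dim, dim)
  acc <- rowsum(w, group = (col - 1L) * dim + row)
  M[as.integer(rownames(acc))] <- acc
  M <- M / sum(M)
  structure(list(M = M, specimen_id = specimen_id,
                 ap_length = ap_length(geometry),
                 centroid_ap = 100 * centroid_ap_fraction(geometry)),
            class = "distribution_matrix")
}

#' @export
print.distribution_matrix <- function(x, ...) {
  cat(sprintf(
    "<distribution_matrix> %s: %dx%d, AP length %.3g um, centroid at %.1f%% AP\n",
    x$specimen_id, nrow(x$M), ncol(x$M), x$ap_length, x$centroid_ap))
  invisible(x)
}

#' Average distribution matrices across a cohort
#'
#' Entrywise mean and population standard deviation (n divisor) over the
#' matrices of oocytes of the same genotype and stage.
#'
#' @param matrices list of `distribution_matrix` objects (or plain matrices
#'   of identical dimension).
#' @return list with `mean`, `sd` (matrices) and `n`.
#' @export
average_cohort <- function(matrices) {
  if (length(matrices) < 1) {
    stop_rnp("need at least one matrix", class = "rnp_validation_error")
  }
  ms <- lapply(matrices, function(m) {
    if (inherits(m, "distribution_matrix")) m$M else as.matrix(m)
  })
  d <- base::dim(ms[[1]])
  if (!all(vapply(ms, function(m) identical(base::dim(m), d), logical(1)))) {
    stop_rnp("matrices differ in shape", class = "rnp_validation_error")
  }
  arr <- simplify2array(ms)
  mu <- apply(arr, c(1, 2), mean)
  sdm <- sqrt(apply(arr, c(1, 2), function(v) mean((v - mean(v))^2)))
  list(mean = mu, sd = sdm, n = length(ms))
}

#' Center of mass of the signal along the AP axis
#'
#' Signal-weighted mean anteroposterior position, in percent of the AP axis
#' length, relative to the geometric center of the oocyte outline: 0 is the
#' geometric center, positive values lie toward the posterior.
#'
#' @param x a `distribution_matrix`, or a data.frame point cloud with `x`,
#'   `y` and optional `weight` columns (then `geometry` is required).
#' @param geometry an [oocyte_geometry()] (ignored when `x` is a
#'   `distribution_matrix`).
#' @return signed center-of-mass in % of AP length.
#' @export
center_of_mass <- function(x, geometry = NULL) {
  if (inherits(x, "distribution_matrix")) {
    colmass <- colSums(x$M)
    centers <- (seq_along(colmass) - 0.5) / length(colmass) * 100
    return(sum(colmass * centers) - x$centroid_ap)
  }
  stopifnot(!is.null(geometry))
  w <- x$weight %||% rep(1, nrow(x))
  if ("weight" %in% names(x)) w <- x$weight
  if (sum(w) <= 0) {
    stop_rnp("zero total signal", class = "rnp_validation_error")
  }
  tfrac <- ap_fraction(cbind(x$x, x$y), geometry)
  100 * (sum(w * tfrac) / sum(w) - centroid_ap_fraction(geometry))
}

#' Compare center-of-mass values across conditions
#'
#' Omnibus Kruskal-Wallis test over all groups followed by pairwise
#' Mann-Whitney U tests of each condition against the control.
#'
#' @param groups named list of numeric vectors of center-of-mass values
#'   (>= 2 groups, each >= 3 values).
#' @param control name of the control group.
#' @return list with `kruskal_p` and `pairwise` (data.frame `condition`,
#'   `p`).
#' @export
compare_com <- function(groups, control) {
  if (length(groups) < 2) {
    stop_rnp("need at least two groups", class = "rnp_validation_error")
  }
  if (!control %in% names(groups)) {
    stop_rnp("control group '%s' not found", control,
             class = "rnp_validation_error")
  }
  if (any(vapply(groups, length, integer(1)) < 3)) {
    stop_rnp("each group needs >= 3 values", class = "rnp_validation_error")
  }
  kw <- kruskal.test(groups)
  others <- setdiff(names(groups), control)
  pw <- data.frame(
    condition = others,
    p = vapply(others, function(g) {
      wilcox.test(groups[[g]], groups[[control]], exact = NULL)$p.value
    }, numeric(1)))
  list(kruskal_p = kw$p.value, pairwise = pw)
}

#' Linear fit of center of mass against oocyte size
#'
#' Ordinary least squares of center-of-mass values on oocyte size (outline
#' area, µm², used as a proxy for developmental stage), reporting whether
#' the slope differs from zero.
#'
#' @param sizes oocyte sizes (µm²), >= 3 points, not all equal.
#' @param com center-of-mass values (% AP length).
#' @return list with `slope`, `intercept`, `r_squared`, `slope_p`,
#'   `slope_ci`.
#' @export
fit_com_vs_size <- function(sizes, com) {
  if (length(sizes) < 3) {
    stop_rnp("need >= 3 points", class = "rnp_validation_error")
  }
  if (diff(range(sizes)) == 0) {
    stop_rnp("sizes are constant; slope undefined",
             class = "rnp_validation_error")
  }
  fit <- lm(com ~ sizes)
  sm <- summary(fit)
  list(slope = unname(coef(fit)["sizes"]),
       intercept = unname(coef(fit)["(Intercept)"]),
       r_squared = sm$r.squared,
       slope_p = sm$coefficients["sizes", "Pr(>|t|)"],
       slope_ci = unname(confint(fit)["sizes", ]))
}
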