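#' Mean signal per unit area per compartment
#'
#' Sums detection intensities (or point weights) falling inside each
#' compartment polygon and divides by the polygon area, yielding a mean
#' signal density comparable across compartments of different size.
#'
#' @param signal data.frame with columns `x`, `y` and either `intensity` or
#'   `weight` (defaults to 1 per point).
#' @param compartments named list of polygons (matrices with x, y columns).
#'   Polygons must not overlap.
#' @return data.frame with `compartment`, `n`, `mean_intensity` (signal per
#'   µm²) and `flagged` (TRUE for compartments without any signal carrier,
#'   to be excluded from ratios).
#' @export
compartment_means <- function(signal, compartments) {
  stopifnot(all(c("x", "y") %in% names(signal)))
  v <- signal$intensity %||% signal$weight %||% rep(1, nrow(signal))
  if ("intensity" %in% names(signal)) v <- signal$intensity
  else if ("weight" %in% names(signal)) v <- signal$weight
  polys <- lapply(compartments, function(p) {
    p <- as.matrix(as.data.frame(p)[, 1:2]); storage.mode(p) <- "double"; p
  })
  for (p in polys) {
    if (poly_area(p) <= 0) {
      stop_rnp("compartment polygon with non-positive area",
               class = "rnp_geometry_error")
    }
  }
  pts <- cbind(signal$x, signal$y)
  member <- vapply(polys, function(p) points_in_poly(pts, p),
                   logical(nrow(pts)))
  member <- matrix(member, nrow = nrow(pts))
  if (any(rowSums(member) > 1)) {
    stop_rnp("compartment polygons overlap (a point falls in several)",
             class = "rnp_geometry_error")
  }
  out <- data.frame(
    compartment = names(polys),
    n = colSums(member),
    mean_intensity = vapply(seq_along(polys), function(k) {
      sum(v[member[, k]]) / poly_area(polys[[k]])
    }, numeric(1)))
  out$flagged <- out$n == 0
  out
}

#' Enrichment ratios relative to the nurse cells
#'
#' Normalizes compartment mean signal densities to the nurse-cell value.
#' The follicle-cell ratio serves as an internal control: follicle cells do
#' not receive germline transport, so their ratio should be insensitive to
#' perturbations of the transport machinery.
#'
#' @param means data.frame from [compartment_means()]; must contain a
#'   `nurse_cell` row with positive mean.
#' @return data.frame with `compartment`, `ratio` (compartment mean /
#'   nurse-cell mean) and `is_control` (TRUE for `follicle_cell`); flagged
#'   compartments are excluded.
#' @export
enrichment_ratio <- function(means) {
  means <- means[!means$flagged, , drop = FALSE]
  nc <- means$mean_intensity[means$compartment == "nurse_cell"]
  if (length(nc) != 1 || nc <= 0) {
    stop_rnp("nurse_cell mean must be present and > 0",
             class = "rnp_validation_error")
  }
  data.frame(compartment = means$compartment,
             ratio = means$mean_intensity / nc,
             is_control = means$compartment == "follicle_cell")
}

#' Compare enrichment between groups of specimens
#'
#' Two-sample unpaired t tests (Welch by default, classic pooled-variance by
#' flag) between each condition and the control, plus a one-sample t test of
#' each group against a stated null value.
#'
#' @param groups named list of numeric vectors (per-specimen ratios), with
#'   at least 3 specimens per group for the two-sample tests.
#' @param control name of the control group.
#' @param mu null value for the one-sample tests (default 1, i.e. no
#'   enrichment).
#' @param var_equal use the pooled-variance Student t instead of Welch.
#' @return list with `pairwise` (data.frame `condition`, `p`) and
#'   `one_sample` (data.frame `condition`, `p`, `flag_null` TRUE when
#'   p > 0.01) and `variance_assumption`.
#' @export
compare_enrichment <- function(groups, control, mu = 1, var_equal = FALSE) {
  if (!control %in% names(groups)) {
    stop_rnp("control group '%s' not found", control,
             class = "rnp_validation_error")
  }
  if (any(vapply(groups, length, integer(1)) < 3)) {
    stop_rnp("each group needs >= 3 specimens", class = "rnp_validation_error")
  }
  others <- setdiff(names(groups), control)
  pw <- data.frame(
    condition = others,
    p = vapply(others, function(g) {
      t.test(groups[[g]], groups[[control]], var.equal = var_equal)$p.value
    }, numeric(1)))
  os <- data.frame(
    condition = names(groups),
    p = vapply(groups, function(v) t.test(v, mu = mu)$p.value, numeric(1)))
  os$flag_null <- os$p > 0.01
  list(pairwise = pw, one_sample = os,
       variance_assumption = if (var_equal) "pooled" else "welch")
}
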