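#' Oocyte geometry: outline, AP axis, nuclear exclusion masks
#'
#' Represents the manually drawn region of interest of one oocyte: a simple
#' closed polygon outline (µm), the anterior and posterior endpoints of the
#' anteroposterior (AP) axis, and optional nuclear mask polygons excluded
#' from all analyses. The AP axis is the straight anterior-to-posterior
#' segment; AP fraction 0 is the anterior, 1 the posterior.
#'
#' @param outline numeric matrix or data.frame with columns x, y (>= 3
#'   vertices, in µm). A duplicated final vertex is removed; the polygon is
#'   treated as closed.
#' @param anterior,posterior numeric length-2 points (µm); snapped to the
#'   nearest outline vertex/edge when within `snap_tol`; must lie on or
#'   inside the outline.
#' @param nuclear_masks list of polygons (matrices with x, y columns); may be
#'   empty.
#' @param snap_tol snapping tolerance in µm (default 1).
#' @return An object of class `oocyte_geometry`.
#' @examples
#' g <- oocyte_geometry(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
#'                      anterior = c(0, 0.5), posterior = c(1, 0.5))
#' @export
oocyte_geometry <- function(outline, anterior, posterior,
                            nuclear_masks = list(), snap_tol = 1) {
  outline <- as.matrix(as.data.frame(outline)[, 1:2])
  colnames(outline) <- c("x", "y")
  storage.mode(outline) <- "double"
  if (any(!is.finite(outline))) {
    stop_rnp("outline has non-finite coordinates", class = "rnp_geometry_error")
  }
  # closure convention: drop duplicated final vertex
  n <- nrow(outline)
  if (n >= 2 && all(outline[1, ] == outline[n, ])) {
    outline <- outline[-n, , drop = FALSE]
  }
  if (nrow(outline) < 3) {
    stop_rnp("outline polygon needs at least 3 distinct vertices",
             class = "rnp_geometry_error")
  }
  if (!poly_is_simple(outline)) {
    stop_rnp("outline polygon is self-intersecting",
             class = "rnp_geometry_error")
  }
  if (poly_area(outline) <= 0) {
    stop_rnp("outline polygon has zero area", class = "rnp_geometry_error")
  }
  anterior <- as.numeric(anterior)[1:2]
  posterior <- as.numeric(posterior)[1:2]
  anterior <- snap_to_outline(anterior, outline, snap_tol)
  posterior <- snap_to_outline(posterior, outline, snap_tol)
  if (all(anterior == posterior)) {
    stop_rnp("anterior and posterior must differ", class = "rnp_geometry_error")
  }
  for (p in list(anterior, posterior)) {
    if (!points_in_poly(matrix(p, 1), outline)) {
      stop_rnp("AP endpoint (%g, %g) lies outside the outline", p[1], p[2],
               class = "rnp_geometry_error")
    }
  }
  nuclear_masks <- lapply(nuclear_masks, function(m) {
    m <- as.matrix(as.data.frame(m)[, 1:2])
    colnames(m) <- c("x", "y")
    storage.mode(m) <- "double"
    nm <- nrow(m)
    if (nm >= 2 && all(m[1, ] == m[nm, ])) m <- m[-nm, , drop = FALSE]
    if (nrow(m) < 3) {
      stop_rnp("nuclear mask polygon needs >= 3 vertices",
               class = "rnp_geometry_error")
    }
    m
  })
  structure(list(outline = outline, anterior = anterior,
                 posterior = posterior, nuclear_masks = nuclear_masks),
            class = "oocyte_geometry")
}

#' @export
print.oocyte_geometry <- function(x, ...) {
  cat(sprintf(
    "<oocyte_geometry> %d outline vertices, area %.3g um^2, AP length %.3g um, %d nuclear mask(s)\n",
    nrow(x$outline), poly_area(x$outline),
    sqrt(sum((x$posterior - x$anterior)^2)), length(x$nuclear_masks)))
  invisible(x)
}

#' Read an oocyte geometry from CSV or JSON
#'
#' Two neutral on-disk formats are accepted:
#' \itemize{
#' \item vertex CSV with columns `x`, `y` and an optional `role` column
#'   (`outline` (default), `anterior`, `posterior`, `nuclear_mask`) plus an
#'   optional `ring` column separating multiple nuclear masks;
#' \item a GeoJSON-like JSON object with members `outline` (array of
#'   `[x, y]` pairs), `anterior`, `posterior` and optional `nuclear_masks`.
#' }
#'
#' @param path file path; format chosen by extension (`.json` vs anything
#'   else, read as CSV).
#' @return An `oocyte_geometry`.
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) {
    stop_rnp("file not found: %s", path, class = "rnp_io_error")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    masks <- obj$nuclear_masks %||% list()
    if (is.matrix(masks)) masks <- list(masks)
    return(oocyte_geometry(obj$outline, unlist(obj$anterior),
                           unlist(obj$posterior), masks))
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(df))) {
    stop_rnp("geometry CSV needs columns x, y", class = "rnp_schema_error")
  }
  if (!"role" %in% names(df)) df$role <- "outline"
  ant <- df[df$role == "anterior", c("x", "y")]
  post <- df[df$role == "posterior", c("x", "y")]
  if (nrow(ant) != 1 || nrow(post) != 1) {
    stop_rnp("geometry CSV must contain exactly one anterior and one posterior row",
             class = "rnp_schema_error")
  }
  mk <- df[df$role == "nuclear_mask", , drop = FALSE]
  masks <- list()
  if (nrow(mk)) {
    ring <- if ("ring" %in% names(mk)) mk$ring else rep(1, nrow(mk))
    masks <- lapply(split(mk[, c("x", "y")], ring), as.matrix)
  }
  oocyte_geometry(df[df$role == "outline", c("x", "y")],
                  as.numeric(ant), as.numeric(post), masks)
}

#' Write an oocyte geometry to JSON
#' @param geometry an `oocyte_geometry`.
#' @param path output path.
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "oocyte_geometry"))
  jsonlite::write_json(list(
    outline = unname(geometry$outline),
    anterior = geometry$anterior,
    posterior = geometry$posterior,
    nuclear_masks = lapply(geometry$nuclear_masks, unname)
  ), path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

## ---- polygon primitives -------------------------------------------------

# Shoelace area (absolute value), vertices as rows, open polygon.
poly_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Polygon centroid (shoelace formula).
poly_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Simplicity check: no two non-adjacent edges intersect.
poly_is_simple <- function(poly) {
  n <- nrow(poly)
  seg <- cbind(poly, poly[c(2:n, 1), , drop = FALSE])
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      adjacent <- (j == i + 1) || (i == 1 && j == n)
      if (adjacent) next
      if (segments_intersect(seg[i, 1:2], seg[i, 3:4],
                             seg[j, 1:2], seg[j, 3:4])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
    return(TRUE)
  }
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

# Vectorized point-in-polygon (boundary counts as inside).
points_in_poly <- function(pts, poly) {
  pracma::inpolygon(pts[, 1], pts[, 2], poly[, 1], poly[, 2],
                    boundary = TRUE)
}

snap_to_outline <- function(p, outline, tol) {
  n <- nrow(outline)
  best <- p; best_d <- Inf
  for (i in seq_len(n)) {
    a <- outline[i, ]; b <- outline[if (i == n) 1 else i + 1, ]
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab * ab)
    t <- min(max(t, 0), 1)
    q <- a + t * ab
    d <- sqrt(sum((p - q)^2))
    if (d < best_d) { best_d <- d; best <- q }
  }
  if (best_d <= tol && best_d > 0) best else p
}

# Area of outline minus nuclear masks (masks assumed disjoint and inside).
free_area <- function(geometry) {
  poly_area(geometry$outline) -
    sum(vapply(geometry$nuclear_masks, poly_area, numeric(1)))
}

# Rejection-sample n points uniformly inside the outline and outside all
# nuclear masks. Caller manages the RNG state.
sample_in_geometry <- function(n, geometry) {
  out <- matrix(NA_real_, 0, 2)
  if (n == 0) return(out)
  bb <- apply(geometry$outline, 2, range)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 64L)
    cand <- cbind(runif(m, bb[1, 1], bb[2, 1]), runif(m, bb[1, 2], bb[2, 2]))
    keep <- points_in_poly(cand, geometry$outline)
    for (mask in geometry$nuclear_masks) {
      keep <- keep & !points_in_poly(cand, mask)
    }
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

## ---- AP-axis coordinates ------------------------------------------------

# Fraction along the straight anterior->posterior axis (0 = anterior,
# 1 = posterior), unclamped.
ap_fraction <- function(pts, geometry) {
  axis <- geometry$posterior - geometry$anterior
  len2 <- sum(axis^2)
  ((pts[, 1] - geometry$anterior[1]) * axis[1] +
     (pts[, 2] - geometry$anterior[2]) * axis[2]) / len2
}

ap_length <- function(geometry) {
  sqrt(sum((geometry$posterior - geometry$anterior)^2))
}

# Geometric center of the outline expressed as AP fraction.
centroid_ap_fraction <- function(geometry) {
  ap_fraction(matrix(poly_centroid(geometry$outline), 1), geometry)
}

# Signed perpendicular offset of points from the AP axis (µm).
perp_offset <- function(pts, geometry) {
  axis <- geometry$posterior - geometry$anterior
  u <- axis / sqrt(sum(axis^2))
  nvec <- c(-u[2], u[1])
  (pts[, 1] - geometry$anterior[1]) * nvec[1] +
    (pts[, 2] - geometry$anterior[2]) * nvec[2]
}

# For each point, the [min, max] signed perpendicular offsets where the
# perpendicular line through the point's AP position crosses the outline.
# Used to express the orthogonal coordinate as a fraction of the local chord.
chord_extent <- function(ap_frac, geometry) {
  axis <- geometry$posterior - geometry$anterior
  u <- axis / sqrt(sum(axis^2))
  nvec <- c(-u[2], u[1])
  L <- sqrt(sum(axis^2))
  outline <- geometry$outline
  n <- nrow(outline)
  # vertex coordinates in (s = along-axis µm, v = perpendicular µm)
  sv <- cbind((outline[, 1] - geometry$anterior[1]) * u[1] +
                (outline[, 2] - geometry$anterior[2]) * u[2],
              (outline[, 1] - geometry$anterior[1]) * nvec[1] +
                (outline[, 2] - geometry$anterior[2]) * nvec[2])
  s0 <- ap_frac * L
  lo <- rep(Inf, length(s0)); hi <- rep(-Inf, length(s0))
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s1 <- sv[i, 1]; s2 <- sv[j, 1]
    v1 <- sv[i, 2]; v2 <- sv[j, 2]
    cross <- (s1 - s0) * (s2 - s0) <= 0
    if (!any(cross)) next
    if (s1 == s2) {
      lo[cross] <- pmin(lo[cross], min(v1, v2))
      hi[cross] <- pmax(hi[cross], max(v1, v2))
    } else {
      t <- (s0[cross] - s1) / (s2 - s1)
      v <- v1 + t * (v2 - v1)
      lo[cross] <- pmin(lo[cross], v)
      hi[cross] <- pmax(hi[cross], v)
    }
  }
  none <- !is.finite(lo)
  lo[none] <- NA_real_; hi[none] <- NA_real_
  cbind(lo, hi)
}
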