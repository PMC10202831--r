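# Shared fixtures and independent oracles used across the test files.

square_geometry <- function(side = 100) {
  oocyte_geometry(rbind(c(0, 0), c(side, 0), c(side, side), c(0, side)),
                  anterior = c(0, side / 2), posterior = c(side, side / 2))
}

make_detections <- function(x, y, intensity = 100, channel = "rna",
                            compartment = "oocyte", id = NULL,
                            specimen_id = "s1") {
  n <- length(x)
  as_detections(data.frame(
    id = id %||% sprintf("%s%03d", substr(channel, 1, 3), seq_len(n)),
    specimen_id = specimen_id, channel = channel, x = x, y = y,
    intensity = rep_len(intensity, n), compartment = compartment))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive all-pairs nearest-neighbor search (the oracle for the Rcpp
# implementation); ties broken toward the lowest reporter id.
nn_oracle <- function(rnps, reporters) {
  reporters <- reporters[order(reporters$id), , drop = FALSE]
  t(vapply(seq_len(nrow(rnps)), function(i) {
    d <- sqrt((reporters$x - rnps$x[i])^2 + (reporters$y - rnps$y[i])^2)
    j <- which(d == min(d))[1]
    c(index = j, distance = d[j])
  }, c(index = 0, distance = 0)))
}

# Brute-force run segmentation: enumerate every frame window, keep windows
# valid under the run definition, return the inclusion-maximal ones.
run_oracle <- function(s, t, sgn, min_len = 0.5, min_frames = 3L, tol = 1L) {
  n <- length(s)
  valid <- list()
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      ds <- sgn * diff(s[a:b])
      if (ds[1] <= 0 || ds[length(ds)] <= 0) next
      r <- rle(ds <= 0)
      if (any(r$lengths[r$values] > tol)) next
      if ((b - a) < min_frames) next
      if (sgn * (s[b] - s[a]) < min_len) next
      valid[[length(valid) + 1L]] <- c(a, b)
    }
  }
  if (!length(valid)) return(matrix(integer(0), 0, 2))
  w <- do.call(rbind, valid)
  keep <- vapply(seq_len(nrow(w)), function(i) {
    !any(w[, 1] <= w[i, 1] & w[, 2] >= w[i, 2] &
           (w[, 1] != w[i, 1] | w[, 2] != w[i, 2]))
  }, logical(1))
  w[keep, , drop = FALSE]
}

# Exhaustive oracle for the processivity criterion: the largest displacement
# over any frame window whose steps never change sign.
unidir_oracle <- function(pos) {
  n <- length(pos)
  best <- 0
  if (n < 2) return(0)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      ds <- diff(pos[a:b])
      if (all(ds >= 0) || all(ds <= 0)) {
        best <- max(best, abs(pos[b] - pos[a]))
      }
    }
  }
  best
}

# Two-sided Fisher exact p by hypergeometric enumeration on a 2x2 table
# (rows fixed margins): sum of probabilities of tables at most as likely.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
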