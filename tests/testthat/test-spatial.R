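geom <- square_geometry(100)

test_that("distribution matrices are normalized and correctly binned", {
  # all signal at the posterior pole -> only column 100 occupied
  sig <- data.frame(x = rep(99.9, 50), y = runif(50, 1, 99))
  m <- build_matrix(sig, geom)
  expect_equal(sum(m$M), 1, tolerance = 1e-9)
  expect_equal(sum(m$M[, 100]), 1, tolerance = 1e-12)
  expect_equal(sum(m$M[, 1:99]), 0)

  # hand-computed 3-point oracle in a unit square
  g1 <- square_geometry(1)
  pts <- data.frame(x = c(0.005, 0.505, 0.995),
                    y = c(0.005, 0.505, 0.995),
                    weight = c(0.5, 0.3, 0.2))
  m3 <- build_matrix(pts, g1)
  expect_equal(m3$M[1, 1], 0.5)
  expect_equal(m3$M[51, 51], 0.3)
  expect_equal(m3$M[100, 100], 0.2)
  expect_equal(sum(m3$M), 1)

  # uniform signal: column occupancy uniform within Monte Carlo error
  set.seed(9)
  u <- gen_oocyte_signal(geom, function(t) rep(1, length(t)), 2e4, seed = 9)
  # boundary points can fall on the outline within float tolerance
  mu <- suppressWarnings(build_matrix(u, geom))
  expect_lt(max(abs(colSums(mu$M) - 0.01)), 0.004)

  suppressWarnings(
    expect_error(build_matrix(data.frame(x = 200, y = 200), geom),
                 class = "rnp_validation_error"))
})

test_that("matrices and center of mass are invariant to coordinate scale", {
  set.seed(10)
  sig <- gen_oocyte_signal(geom, function(t) t + 0.2, 2000, seed = 10)
  m1 <- build_matrix(sig, geom)
  g2 <- square_geometry(200)
  sig2 <- data.frame(x = 2 * sig$x, y = 2 * sig$y, weight = sig$weight)
  m2 <- build_matrix(sig2, g2)
  expect_equal(m2$M, m1$M)
  expect_equal(center_of_mass(sig2, g2), center_of_mass(sig, geom))
})

test_that("cohort averaging uses entrywise mean and population SD", {
  a <- matrix(0.25, 2, 2)
  one <- average_cohort(list(a))
  expect_equal(one$mean, a)
  expect_equal(one$sd, matrix(0, 2, 2))
  expect_equal(average_cohort(list(a, a))$sd, matrix(0, 2, 2))

  b <- a; b[1, 1] <- a[1, 1] + 0.2
  two <- average_cohort(list(a, b))
  expect_equal(two$sd[1, 1], 0.1)  # population SD, n divisor
  expect_equal(two$sd[2, 2], 0)
  expect_error(average_cohort(list(a, matrix(0, 3, 3))),
               class = "rnp_validation_error")
})

test_that("center of mass follows the signed AP convention", {
  # symmetric signal in a symmetric outline -> exactly 0
  sym <- data.frame(x = c(20, 80), y = c(50, 50), weight = c(0.5, 0.5))
  expect_equal(center_of_mass(sym, geom), 0)

  # all signal at the posterior pole of a rectangle -> +50
  post <- data.frame(x = 100, y = 50, weight = 1)
  expect_equal(center_of_mass(post, geom), 50)

  # direct formula on toy weighted points
  toy <- data.frame(x = c(10, 70), y = c(30, 60), weight = c(1, 3))
  expect_equal(center_of_mass(toy, geom),
               100 * ((1 * 0.1 + 3 * 0.7) / 4 - 0.5))

  # mirror flip A<->P negates the CoM in a symmetric outline
  set.seed(11)
  sig <- gen_oocyte_signal(geom, function(t) t^2 + 0.05, 3000, seed = 11)
  mir <- data.frame(x = 100 - sig$x, y = sig$y, weight = sig$weight)
  expect_equal(center_of_mass(mir, geom), -center_of_mass(sig, geom),
               tolerance = 1e-10)

  # matrix-based and point-based CoM agree up to binning resolution
  m <- build_matrix(sig, geom)
  expect_equal(center_of_mass(m), center_of_mass(sig, geom), tolerance = 0.5)
})

test_that("center-of-mass group comparisons use rank tests", {
  x <- c(1.2, 0.8, 1.5, 0.9, 1.1)
  same <- suppressWarnings(compare_com(list(control = x, test = x), "control"))
  expect_equal(same$pairwise$p, 1)

  set.seed(12)
  g <- list(control = rnorm(20), shifted = rnorm(20, 5), near = rnorm(20, 0.1))
  out <- compare_com(g, "control")
  expect_lt(out$kruskal_p, 0.001)
  expect_lt(out$pairwise$p[out$pairwise$condition == "shifted"], 0.001)
  expect_gt(out$pairwise$p[out$pairwise$condition == "near"], 0.01)

  expect_error(compare_com(list(a = x), "a"), class = "rnp_validation_error")
})

test_that("size-vs-CoM regression reports slope and fit quality", {
  sizes <- c(100, 200, 300, 400)
  perfect <- suppressWarnings(fit_com_vs_size(sizes, 0.05 * sizes - 2))
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$slope, 0.05)

  set.seed(8)
  sizes2 <- runif(100, 50, 500)
  fit <- fit_com_vs_size(sizes2, 0.02 * sizes2 + rnorm(100, 0, 0.5))
  expect_true(fit$slope_ci[1] <= 0.02 && 0.02 <= fit$slope_ci[2])
  expect_lt(fit$slope_p, 0.01)

  indep <- fit_com_vs_size(sizes2, rnorm(100, 1, 0.5))
  expect_true(indep$slope_ci[1] < 0 && indep$slope_ci[2] > 0)

  expect_error(fit_com_vs_size(rep(100, 5), rnorm(5)),
               class = "rnp_validation_error")
})
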