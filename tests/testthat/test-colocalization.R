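geom <- square_geometry(100)

test_that("nearest-neighbor pairing matches the exhaustive oracle", {
  rnps <- make_detections(c(0, 5), c(0, 0))
  reps <- make_detections(c(1, 3), c(0, 0), channel = "reporter")
  p <- nearest_neighbor_pairs(rnps, reps)
  expect_equal(p$nn_distance, c(1, 2))
  expect_equal(p$nn_id, c("rep001", "rep002"))

  empty <- nearest_neighbor_pairs(rnps, reps[0, ])
  expect_true(all(is.infinite(empty$nn_distance)))

  # tie-break toward the lowest reporter id
  tie_reps <- make_detections(c(1, -1), c(0, 0), channel = "reporter",
                              id = c("z9", "a1"))
  tie <- nearest_neighbor_pairs(make_detections(0, 0), tie_reps)
  expect_equal(tie$nn_id, "a1")

  # random instances up to 1000 objects against brute force
  set.seed(101)
  for (case in 1:5) {
    n <- sample(c(10, 100, 1000), 1)
    m <- sample(c(5, 50, 500), 1)
    rn <- make_detections(runif(n, 0, 50), runif(n, 0, 50))
    rp <- make_detections(runif(m, 0, 50), runif(m, 0, 50),
                          channel = "reporter")
    got <- nearest_neighbor_pairs(rn, rp)
    want <- nn_oracle(rn, rp)
    expect_equal(got$nn_distance, unname(want[, "distance"]))
    expect_equal(got$nn_id, sort(rp$id)[want[, "index"]])
  }
})

test_that("observed frequency is the within-radius percentage per bin", {
  pairs <- data.frame(rnp_id = sprintf("r%02d", 1:10),
                      nn_id = "x", nn_distance = c(rep(0.1, 4), rep(1, 6)),
                      bin = "1")
  out <- observed_frequency(pairs, 0.25)
  expect_equal(out$f_obs, 40)
  expect_equal(out$n_rnp, 10L)
  expect_equal(observed_frequency(transform(pairs, nn_distance = 0), 0.25)$f_obs, 100)
  expect_equal(observed_frequency(transform(pairs, nn_distance = 2), 0.25)$f_obs, 0)
  # monotone in the radius
  radii <- c(0.05, 0.1, 0.25, 0.5, 1, 2)
  fs <- vapply(radii, function(r) observed_frequency(pairs, r)$f_obs,
               numeric(1))
  expect_false(is.unsorted(fs))
})

test_that("randomized expected frequency matches the Poisson closed form", {
  # lambda reporters per um^2 in a large box: f_exp ~ 100 (1 - exp(-lambda pi r^2))
  r <- 0.25
  lam <- 1
  n_rep <- round(lam * 100 * 100)
  set.seed(7)
  rnps <- make_detections(runif(400, 2, 98), runif(400, 2, 98))
  rnps$bin_label <- "1"
  reps <- make_detections(runif(n_rep, 0, 100), runif(n_rep, 0, 100),
                          channel = "reporter")
  fe <- expected_frequency(rnps, reps, geom, r, n_randomizations = 100,
                           seed = 8)
  theory <- 100 * (1 - exp(-lam * pi * r^2))
  expect_lt(abs(fe$f_exp - theory), 3 * fe$mc_se + 0.2)

  expect_equal(expected_frequency(rnps, reps[0, ], geom, r, 10, 1)$f_exp, 0)
  expect_equal(expected_frequency(rnps, reps, geom, 0, 10, 1)$f_exp, 0)
})

test_that("corrected frequency subtracts the expected value", {
  expect_equal(corrected_frequency(100, 10), 90)
  expect_equal(corrected_frequency(15, 15), 0)
  obs <- data.frame(bin = "1", n_rnp = 10L, f_obs = 50)
  expd <- data.frame(bin = "1", f_exp = 5, mc_se = 0.1)
  expect_equal(corrected_frequency(obs, expd)$f_corr, 45)
})

test_that("grouped confidence intervals behave like binomial group means", {
  # remainder rule: 101 values at group size 50 -> 2 groups, 1 dropped
  g <- grouped_ci(rep(c(TRUE, FALSE), length.out = 101), f_exp = 0,
                  group_size = 50, seed = 1)
  expect_equal(g$n_groups, 2L)

  # degenerate zero-variance case flagged
  gd <- grouped_ci(rep(TRUE, 100), f_exp = 0, group_size = 50, seed = 1)
  expect_true(gd$degenerate)
  expect_equal(gd$ci95, c(100, 100))

  expect_error(grouped_ci(rep(TRUE, 60), 0, 50),
               class = "rnp_insufficient_data_error")

  # coverage: group means of Bernoulli(0.2) indicators, CI covers 20%
  set.seed(5)
  covered <- vapply(1:200, function(i) {
    ind <- runif(2000) < 0.2
    ci <- grouped_ci(ind, f_exp = 0, group_size = 50)$ci95
    ci[1] <= 20 && 20 <= ci[2]
  }, logical(1))
  expect_gt(mean(covered), 0.9)
})

test_that("reporter intensity per bin reflects the generator slope", {
  m <- fit_mixture(rep(50, 60))  # reporter unit = 50
  pairs <- data.frame(
    rnp_id = sprintf("r%03d", 1:300), nn_id = "x",
    nn_distance = 0.1,
    bin = rep(c("1", "2:3", "4:7"), each = 100),
    reporter_intensity = 50 * 0.5 * rep(c(1, 2.5, 5.5), each = 100))
  out <- reporter_intensity_per_bin(pairs, m, 0.25)
  expect_equal(out$mean_reporter_units[out$bin == "1"], 0.5)
  expect_equal(out$mean_reporter_units[out$bin == "2:3"], 1.25)
  # reference normalization
  out2 <- reporter_intensity_per_bin(pairs, m, 0.25, reference = 0.5)
  expect_equal(out2$mean_reporter_units[out2$bin == "1"], 1)
  # non-colocalized pairs excluded
  far <- transform(pairs, nn_distance = 1)
  expect_equal(nrow(reporter_intensity_per_bin(far, m, 0.25)), 0)
})

test_that("scaling fits recover slopes and detect slope differences", {
  set.seed(6)
  copies <- rep(c(1, 2, 4, 8), each = 250)
  y1 <- 0.1 * copies + rnorm(1000, 0, 0.2)
  y2 <- 0.5 * copies + rnorm(1000, 0, 0.2)
  two <- fit_scaling(c(copies, copies), c(y1, y2),
                     group = rep(c("a", "b"), each = 1000))
  expect_lt(abs(two$slope - 0.1), 0.05)
  expect_lt(abs(two$slope2 - 0.5), 0.05)
  expect_lt(two$interaction_p, 0.01)

  # duplicated groups: identical slopes, interaction estimate 0
  dup <- fit_scaling(c(copies, copies), c(y1, y1),
                     group = rep(c("a", "b"), each = 1000))
  expect_equal(dup$slope, dup$slope2)

  # zero-slope data: CI contains 0
  flat <- fit_scaling(copies, rnorm(1000, 1, 0.3))
  expect_true(flat$slope_ci[1] < 0 && flat$slope_ci[2] > 0)

  expect_error(fit_scaling(rep(c(1, 2), 50), rnorm(100)),
               class = "rnp_validation_error")
})

test_that("independent channels yield corrected frequencies near zero", {
  # null calibration at modest scale; the full-size check lives in the
  # acceptance suite
  res <- vapply(1:10, function(s) {
    sim <- gen_rnp_field(1000, geom, coloc_prob = c(),
                         background_reporters = 500, seed = 300 + s)
    det <- sim$detections
    rnps <- det[det$channel == "rna", ]
    rnps$bin_label <- sim$truth$rnp$bin
    reps <- det[det$channel == "reporter", ]
    cfg <- rnp_config(rng_seed = 400 + s, n_randomizations = 50)
    out <- coloc_analysis(rnps, reps, geom, cfg)
    sum(out$f_corr * out$n_rnp) / sum(out$n_rnp)
  }, numeric(1))
  expect_lt(abs(mean(res)), 1)
})
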