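test_that("steady directed motion yields a single run with correct speed", {
  # +0.05 um/frame for 40 frames at 20 fps along the plus axis
  trk <- data.frame(t = (0:40) / 20, x = 0.05 * (0:40), y = 0)
  runs <- segment_runs(trk, polarity = c(1, 0))
  expect_equal(nrow(runs), 1)
  expect_equal(runs$direction, "plus")
  expect_equal(runs$mean_speed, 1.0)
  expect_equal(runs$length, 2.0)

  # pure Brownian jitter: no runs at a 0.5 um threshold
  set.seed(15)
  jit <- data.frame(t = (0:60) / 20, x = rnorm(61, 0, 0.02),
                    y = rnorm(61, 0, 0.02))
  expect_equal(nrow(segment_runs(jit, c(1, 0))), 0)
})

test_that("a bidirectional track yields one run per direction", {
  up <- 0.06 * (0:25)
  down <- up[26] - 0.08 * (1:25)
  trk <- data.frame(t = (0:50) / 20, x = c(up, down), y = 0)
  runs <- segment_runs(trk, c(1, 0))
  expect_equal(sort(runs$direction), c("minus", "plus"))
  expect_equal(runs$length[runs$direction == "plus"], 1.5, tolerance = 1e-9)
  expect_equal(runs$length[runs$direction == "minus"], 2.0, tolerance = 1e-9)
})

test_that("run segmentation equals the brute-force window oracle", {
  set.seed(16)
  for (case in 1:40) {
    n <- sample(10:100, 1)
    # mix of drift and noise segments to produce rich step-sign patterns
    drift <- cumsum(sample(c(-0.08, 0, 0.02, 0.08), n, replace = TRUE))
    x <- drift + rnorm(n, 0, 0.02)
    trk <- data.frame(t = (seq_len(n) - 1) / 20, x = x, y = 0)
    got <- segment_runs(trk, c(1, 0))
    for (sgn in c(1, -1)) {
      want <- run_oracle(x, trk$t, sgn)
      dirname <- if (sgn > 0) "plus" else "minus"
      sub <- got[got$direction == dirname, , drop = FALSE]
      expect_equal(nrow(sub), nrow(want))
      if (nrow(want)) {
        ord <- order(sub$start_frame)
        expect_equal(sub$start_frame[ord], unname(want[, 1]))
        expect_equal(sub$end_frame[ord], unname(want[, 2]))
      }
    }
  }
})

test_that("reversing the polarity axis swaps plus and minus labels", {
  sim <- gen_tracks(30, plus_fraction = 0.5, seed = 17)
  runs_fwd <- segment_runs_all(sim$tracks, sim$polarity)
  rev_pol <- transform(sim$polarity, ux = -ux, uy = -uy)
  runs_rev <- segment_runs_all(sim$tracks, rev_pol)
  key <- function(r) r[order(r$track_id, r$start_frame),
                       c("track_id", "start_frame", "end_frame", "length")]
  expect_equal(key(runs_fwd), key(runs_rev), ignore_attr = TRUE)
  m <- merge(runs_fwd, runs_rev,
             by = c("track_id", "start_frame", "end_frame"))
  expect_true(all(m$direction.x != m$direction.y))
})

test_that("generator runs are recovered with correct polarity shares", {
  sim <- gen_tracks(200, plus_fraction = 0.7, loc_noise = 0.01, seed = 18)
  runs <- segment_runs_all(sim$tracks, sim$polarity)
  pf <- polarity_fractions(runs)
  truth_share <- 100 * mean(sim$truth$direction == "plus")
  expect_lt(abs(pf$pct_plus - truth_share), 5)
  # recovered run lengths match ground truth within localization noise
  m <- merge(runs, sim$truth, by = "track_id")
  expect_lt(median(abs(m$length.x - m$length.y)), 0.15)
})

test_that("polarity tables and Fisher tests follow exact counts", {
  runs <- data.frame(direction = c(rep("plus", 7), rep("minus", 3)))
  pf <- polarity_fractions(runs)
  expect_equal(pf$pct_plus, 70)
  all_plus <- polarity_fractions(data.frame(direction = rep("plus", 5)))
  expect_equal(c(all_plus$pct_plus, all_plus$pct_minus), c(100, 0))

  expect_equal(polarity_test(c(50, 50), c(50, 50)), 1)
  expect_equal(polarity_test(c(80, 20), c(50, 50)),
               fisher_oracle(80, 20, 50, 50), tolerance = 1e-9)
})

test_that("run metrics compare conditions against the control", {
  set.seed(19)
  base <- data.frame(direction = "plus", stratum = "1",
                     length = rexp(200, 1), mean_speed = runif(200, 0.8, 1.2))
  ctrl <- cbind(base, condition = "control")
  test_same <- cbind(base, condition = "same")
  longer <- data.frame(direction = "plus", stratum = "1",
                       length = rexp(200, 1 / 1.5),
                       mean_speed = runif(200, 0.8, 1.2),
                       condition = "longer")
  out <- run_metrics(rbind(ctrl, test_same, longer), control = "control")
  same_row <- out[out$condition == "same", ]
  expect_equal(same_row$dmean_length_pct, 0)
  expect_gt(same_row$p_length, 0.99)
  long_row <- out[out$condition == "longer", ]
  expect_lt(long_row$p_length, 0.01)
  expect_lt(abs(long_row$dmean_length_pct - 50), 20)

  # single-run cells are flagged, not tested
  tiny <- rbind(ctrl, data.frame(direction = "plus", stratum = "1",
                                 length = 1, mean_speed = 1,
                                 condition = "tiny"))
  trow <- run_metrics(tiny, "control")
  expect_true(trow$flagged[trow$condition == "tiny"])
  expect_true(is.na(trow$p_length[trow$condition == "tiny"]))
})

test_that("RNA stratification rounds half-up into 1 / 2 / >2", {
  m <- fit_mixture(rep(100, 60))
  expect_equal(stratify_by_rna(c(130, 200, 90, 260, 380, 30), m),
               c("1", "2", "1", ">2", ">2", NA))

  # generator copies {1, 2, 4} at cv 0.15 recovered for >= 90% of tracks
  sim <- gen_tracks(400, rna_units_dist = c("1" = 0.4, "2" = 0.4, "4" = 0.2),
                    unit = 100, cv = 0.15, seed = 20)
  strata <- stratify_by_rna(sim$truth$intensity, m)
  want <- c("1" = "1", "2" = "2", "4" = ">2")[as.character(sim$truth$copies)]
  expect_gt(mean(strata == want, na.rm = TRUE), 0.9)
})
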