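test_that("event classification applies the dwell and displacement rules", {
  # 2-frame landing: no binding event
  short <- data.frame(frame = 1:2, position = c(0, 1))
  expect_false(any(classify_events(short)$binding))

  # 10-frame dwell with monotone 6-px displacement: binding + processive
  mono <- data.frame(frame = 1:10, position = 0.107 * (0:9) * (6 / 9))
  ev <- classify_events(mono)
  expect_true(ev$binding && ev$processive)

  # 10-frame dwell, +-1 px jitter, net 0: binding but not processive
  jig <- data.frame(frame = 1:10,
                    position = 0.107 * c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1))
  ev2 <- classify_events(jig)
  expect_true(ev2$binding)
  expect_false(ev2$processive)

  # net mode thresholds the whole-event displacement instead
  zigzag <- data.frame(frame = 1:6,
                       position = 0.107 * c(0, 3, 1, 4, 2, 6))
  expect_false(classify_events(zigzag)$processive)  # no unidir sub-window >= 5 px
  expect_true(classify_events(zigzag, mode = "net")$processive)

  expect_error(classify_events(data.frame(frame = c(1, 1, 2), position = 0)),
               class = "rnp_validation_error")

  # frame gaps split a trace into separate candidate events
  gap <- data.frame(frame = c(1:4, 10:11), position = 0)
  evg <- classify_events(gap)
  expect_equal(nrow(evg), 2)
  expect_equal(evg$binding, c(TRUE, FALSE))
})

test_that("classification equals the exhaustive window oracle", {
  set.seed(21)
  for (case in 1:300) {
    n <- sample(2:50, 1)
    pos <- cumsum(sample(c(-2, -1, 0, 1, 2) * 0.107, n, replace = TRUE))
    ev <- classify_events(data.frame(frame = seq_len(n), position = pos))
    expect_equal(ev$max_unidir_disp, unidir_oracle(pos), tolerance = 1e-12)
    expect_equal(ev$processive,
                 ev$binding && unidir_oracle(pos) >= 5 * 0.107 - 1e-12)
    # processive implies binding on every input
    expect_true(!ev$processive || ev$binding)
  }
})

test_that("background correction subtracts the mean region frequency", {
  expect_equal(background_correct(c(2, 3), numeric(0))$corrected, c(2, 3)) |>
    expect_warning("skipped")
  same <- background_correct(c(1, 1), c(1, 1))
  expect_equal(same$corrected, c(0, 0))
  off <- background_correct(c(2, 0.1), c(0.5, 0.7))
  expect_equal(off$corrected, c(1.4, 0))
  expect_equal(off$floored, c(FALSE, TRUE))
  expect_equal(attr(off, "background_mean"), 0.6)
})

test_that("per-microtubule summaries tally events and frequencies", {
  events <- data.frame(
    trace_id = sprintf("t%d", 1:5),
    mt_id = c("mt1", "mt1", "mt1", "mt1", "bg1"),
    region = c(rep("mt", 4), "background"),
    binding = TRUE, processive = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  mt <- data.frame(mt_id = "mt1", length = 10)
  s <- per_mt_summary(events, mt, duration = 240, frame_rate = 4)
  expect_equal(s$per_mt$n_binding, 4L)
  expect_equal(s$per_mt$frac_processive, 0.5)
  expect_equal(s$per_mt$freq_binding, 4 / (10 * 1))  # 240 frames at 4 fps = 1 min

  # no binding events: fraction undefined and flagged as NA
  s0 <- per_mt_summary(events[0, ], mt, 240, 4)
  expect_true(is.na(s0$per_mt$frac_processive))

  # simulated processive fraction recovered within binomial tolerance
  sim <- gen_invitro(15, processive_fraction = 0.6, binding_rate = 2,
                     background_rate = 0, seed = 22)
  ev <- classify_events_all(sim$traces)
  sm <- per_mt_summary(ev, sim$mt, 720, 4)
  agg <- sm$aggregate
  frac <- agg$mean[agg$metric == "frac_processive"]
  n_bind <- sum(sm$per_mt$n_binding)
  # short (<3-frame) landings are never processive, diluting the fraction
  tru <- sim$truth$events
  p_true <- sum(tru$processive) / sum(tru$dwell >= 3)
  expect_lt(abs(frac - p_true), 3 * sqrt(p_true * (1 - p_true) / n_bind) + 0.05)
})

test_that("relative metrics normalize to the reference mean", {
  ref <- c(2, 2.2, 1.8, 2.1, 1.9)
  same <- suppressWarnings(relative_metrics(ref, ref))  # rank ties
  expect_equal(same$relative_mean, 1.0)
  halved <- relative_metrics(ref / 2, ref)
  expect_equal(halved$relative_mean, 0.5)
  expect_error(relative_metrics(ref, rep(0, 5)),
               class = "rnp_validation_error")
})

test_that("multi-condition comparisons use Welch ANOVA with BF check", {
  set.seed(23)
  g <- list(a = rnorm(15, 1, 0.1), b = rnorm(15, 0.4, 0.2),
            c = rnorm(15, 1.0, 0.1))
  out <- welch_anova_bf(g)
  expect_lt(out$welch_p, 1e-4)
  expect_true(is.finite(out$brown_forsythe_p))
  same <- welch_anova_bf(list(a = g$a, b = g$a + 0))
  expect_gt(same$welch_p, 0.99)
})
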