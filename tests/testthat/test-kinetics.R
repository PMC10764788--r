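test_that("rescaled FPT reduces to the plain FPT when no bias is deposited", {
  s <- two_wells_setup()
  # MetaD active but pace beyond the trajectory length: zero bias throughout
  cfg <- metad_config(width = 1.3, pace = 1e7, grid_bounds = c(-60, 60))
  tr <- run_trajectory(s$pot, s$thermo, stop_criterion("le", 2.8), s$init,
                       metad = cfg, seed = 23, record_segments = TRUE)
  expect_false(tr$censored)
  expect_equal(rescale_trajectory(tr), tr$fpt_ns, tolerance = 1e-9)
})

test_that("rescaled FPT sums segment exposures up to the first passage", {
  segs <- data.frame(duration_steps = c(100, 100, 40),
                     rescaled_ns = c(0.2, 0.3, 0.1),
                     transition = c(0, 0, 1))
  expect_equal(rescale_trajectory(segs), 0.6)
  no_hit <- data.frame(duration_steps = 1, rescaled_ns = 1, transition = 0)
  expect_error(rescale_trajectory(no_hit), "no first passage")
  rec <- structure(list(segments = NULL), class = "trajectory_record")
  expect_error(rescale_trajectory(rec), "missing")
})

test_that("bias always dilates time: rescaled duration >= real duration", {
  s <- two_wells_setup()
  cfg <- metad_config(width = 1.3, pace = 100, grid_bounds = c(-100, 100))
  tr <- run_trajectory(s$pot, s$thermo, s$stop, s$init, metad = cfg,
                       schedule = reset_schedule("sharp", period = 0.05),
                       seed = 24, record_segments = TRUE)
  segs <- as.data.frame(tr$segments)
  expect_true(all(segs$rescaled_ns >=
                    segs$duration_steps * s$thermo$dt * 1e-6 - 1e-12))
  expect_gt(max(segs$rescaled_ns /
                  (segs$duration_steps * s$thermo$dt * 1e-6)), 1)
})

test_that("product-limit estimate equals the empirical survival without censoring", {
  set.seed(31)
  t <- rexp(200, 2)
  km <- survival_from_segments(t, event = rep(1, 200))
  emp <- vapply(km$time, function(u) mean(t > u), numeric(1))
  expect_equal(km$surv, emp, tolerance = 1e-12)
})

test_that("product-limit handles censoring as in the hand-worked table", {
  km <- survival_from_segments(c(1, 2, 3, 4, 5), event = c(1, 0, 1, 1, 0))
  ev <- km[km$n_event > 0, ]
  expect_equal(ev$time, c(1, 3, 4))
  expect_equal(ev$surv, c(4 / 5, 4 / 5 * 2 / 3, 4 / 5 * 2 / 3 * 1 / 2),
               tolerance = 1e-12)
  # all censored: survival stays at 1
  all_c <- survival_from_segments(c(1, 2, 3), event = c(0, 0, 0))
  expect_true(all(all_c$surv == 1))
  # discarding censored segments is available as a sensitivity switch
  km2 <- survival_from_segments(c(1, 2, 3, 4, 5), event = c(1, 0, 1, 1, 0),
                                discard_censored = TRUE)
  expect_equal(attr(km2, "n_segments"), 3)
})

test_that("exponential fits recover a known rate within 5 percent", {
  set.seed(37)
  t <- rexp(1e4, 2)
  fit <- fit_exponential_survival(
    survival_from_segments(t, event = rep(1, length(t))))
  expect_equal(fit$k, 2, tolerance = 0.05)
  expect_equal(fit$tau_est, 0.5, tolerance = 0.05)
  expect_gt(fit$r_squared, 0.99)
  expect_lt(fit$ks_statistic, 0.05)
  # the exponential is scale-free: a short-time window gives the same rate
  short <- fit_exponential_survival(
    survival_from_segments(t, event = rep(1, length(t))),
    window = c(0, stats::quantile(t, 0.1)))
  expect_equal(short$k, 2, tolerance = 0.1)
})

test_that("a survival plateau is flagged by poor fit quality", {
  set.seed(41)
  # a sub-population that effectively never transitions
  t <- c(rexp(300, 10), rexp(40, 0.05))
  fit <- fit_exponential_survival(
    survival_from_segments(t, event = rep(1, length(t))),
    risk_floor = 0.05)
  pure <- fit_exponential_survival(
    survival_from_segments(rexp(340, 10), event = rep(1, 340)),
    risk_floor = 0.05)
  expect_lt(fit$r_squared, pure$r_squared)
  expect_gt(fit$ks_statistic, pure$ks_statistic)
  expect_lt(fit$r_squared, 0.95)
})

test_that("prediction error is the plain relative deviation", {
  expect_equal(prediction_error(5, 5), 0)
  expect_equal(prediction_error(5, 10), 1)
  expect_equal(prediction_error(4, 2), 0.5)
  expect_error(prediction_error(0, 1), "positive")
})

test_that("the segment pipeline recovers exponential kinetics", {
  # sharp-resetting segments carved from true exponential first-passage
  # processes: survival + fit must recover the underlying rate
  set.seed(43)
  k <- 2; period <- 0.15
  segs <- do.call(rbind, lapply(1:2000, function(i) {
    tau <- rexp(1, k)
    n_full <- floor(tau / period)
    rbind(
      if (n_full > 0)
        data.frame(rescaled_ns = rep(period, n_full), transition = 0),
      data.frame(rescaled_ns = tau - n_full * period, transition = 1))
  }))
  fit <- infer_mfpt(segs)
  expect_equal(fit$k, k, tolerance = 0.05)
  expect_equal(prediction_error(1 / k, fit$tau_est), 0, tolerance = 0.05)
})

test_that("tradeoff scans are deterministic and structurally sound", {
  s <- two_wells_setup()
  cfg <- metad_config(width = 1.3, pace = 50)
  run <- function() tradeoff_scan(
    s$pot, s$thermo, stop_criterion("le", 2.0), s$init,
    metad_base = cfg, bias_rates = c(2e4), reset_periods = c(0.005),
    tau_true = 0.003, n = 8, seed = 3, max_steps = 2e5)
  a <- run(); b <- run()
  expect_identical(a, b)
  expect_equal(a$protocol, c("iMetaD", "iMetaD+SR"))
  expect_true(all(a$speedup > 0))
})
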