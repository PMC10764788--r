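test_that("linear CV projects positions correctly", {
  expect_equal(cv_value(cv_spec(0), c(2, 17)), 2)
  expect_equal(cv_value(cv_spec(pi / 2), c(2, 17)), 17)
  th <- asin(0.407) # worst rotation studied for the FE model (~24 degrees)
  expect_equal(cv_value(cv_spec(th), c(1, 1)), cos(th) + sin(th))
  m <- rbind(c(1, 0), c(0, 1))
  expect_equal(cv_value(cv_spec(th), m), c(cos(th), sin(th)))
})

test_that("well-tempered hill heights decay with the accumulated bias", {
  cfg <- metad_config(height = 0.5, width = 1.3, bias_factor = 10,
                      grid_bounds = c(-30, 30))
  b <- bias_state(cfg)
  h1 <- deposit_hill(b, 0)
  expect_equal(h1, 0.5) # first hill: no bias yet, scaling factor exp(0)
  h2 <- deposit_hill(b, 0)
  expect_equal(h2, 0.5 * exp(-0.5 / 9), tolerance = 1e-9)

  # gamma_B -> infinity recovers non-tempered deposition
  bnt <- bias_state(metad_config(height = 0.5, width = 1.3,
                                 bias_factor = 1e12,
                                 grid_bounds = c(-30, 30)))
  deposit_hill(bnt, 0)
  expect_equal(deposit_hill(bnt, 0), 0.5, tolerance = 1e-9)
})

test_that("bias energy queries follow the Gaussian closed form", {
  cfg <- metad_config(height = 0.5, width = 1.3, grid_bounds = c(-30, 30))
  b <- bias_state(cfg)
  expect_equal(bias_energy(b, c(-5, 0, 12)), c(0, 0, 0)) # empty bias
  deposit_hill(b, 0)
  expect_equal(bias_energy(b, 0), 0.5, tolerance = 1e-6)
  interp_tol <- 0.5 * (cfg$grid_spacing / cfg$width)^2
  expect_equal(bias_energy(b, 1.3), 0.5 * exp(-0.5), tolerance = interp_tol)
  expect_error(bias_energy(b, 40), "outside")
})

test_that("bias force is the chain rule through the CV", {
  cfg <- metad_config(height = 0.5, width = 1.3, grid_bounds = c(-30, 30))
  b <- bias_state(cfg)
  deposit_hill(b, 0)
  expect_equal(unname(bias_force(b, cv_spec(0), c(0, 0))), c(0, 0),
               tolerance = 1e-9)
  # repulsive: at +sigma the push is outward, magnitude (h/sigma) exp(-1/2)
  f <- bias_force(b, cv_spec(0), c(1.3, 0))
  expect_equal(unname(f[1]), (0.5 / 1.3) * exp(-0.5), tolerance = 1e-3)
  expect_equal(unname(f[2]), 0)
  # a CV along y exerts no x-force
  by <- bias_state(cfg)
  deposit_hill(by, 2)
  fy <- bias_force(by, cv_spec(pi / 2), c(100, 2.5))
  expect_equal(unname(fy[1]), 0)
  expect_true(abs(fy[2]) > 0)
})

test_that("grid equals the direct sum over the hill log", {
  cfg <- metad_config(height = 0.5, width = 1.3, grid_bounds = c(-40, 40))
  b <- bias_state(cfg)
  set.seed(42)
  centers <- runif(30, -20, 20)
  for (cc in centers) deposit_hill(b, cc)
  q <- runif(100, -25, 25)
  direct <- vapply(q, function(s) {
    sum(b$hills$height * exp(-(s - b$hills$center)^2 / (2 * 1.3^2)))
  }, numeric(1))
  bound <- sum(b$hills$height) * (cfg$grid_spacing / cfg$width)^2
  expect_lt(max(abs(bias_energy(b, q) - direct)), bound + 1e-9)
  expect_true(all(b$grid_v >= 0))
})

test_that("exposure integral accumulates dt * exp(bias)", {
  cfg <- metad_config(height = 2, width = 1.3, grid_bounds = c(-30, 30))
  b <- bias_state(cfg)
  for (i in 1:50) record_exposure(b, 0.3, dt_fs = 1)
  expect_equal(b$exposure_ns, 50 * 1e-6) # zero bias: exp(0) = 1
  # nearly constant bias V0 over the visited range (one very wide hill)
  bc <- bias_state(metad_config(height = 2, width = 1e4,
                                grid_bounds = c(-30, 30)))
  deposit_hill(bc, 0)
  for (i in 1:50) record_exposure(bc, 0.3, dt_fs = 1)
  expect_equal(bc$exposure_ns, 50 * 1e-6 * exp(2), tolerance = 1e-6)
  # piecewise path against a brute-force per-step sum
  bp <- bias_state(cfg)
  deposit_hill(bp, 1)
  deposit_hill(bp, -2)
  path <- seq(-3, 3, length.out = 40)
  bp$exposure_ns <- 0
  for (s in path) record_exposure(bp, s, dt_fs = 1)
  brute <- sum(1e-6 * exp(bias_energy(bp, path)))
  expect_equal(bp$exposure_ns, brute, tolerance = 1e-12)
})

test_that("reset clears grid, hill log and exposure", {
  cfg <- metad_config(height = 0.5, width = 1.3, grid_bounds = c(-30, 30))
  b <- bias_state(cfg)
  deposit_hill(b, 0); deposit_hill(b, 3)
  record_exposure(b, 0, 1)
  reset_bias(b)
  expect_true(all(b$grid_v == 0))
  expect_true(all(b$grid_dv == 0))
  expect_equal(nrow(b$hills), 0)
  expect_equal(b$exposure_ns, 0)
})

test_that("the engine's grid matches an independent rebuild of its hill log", {
  s <- two_wells_setup()
  cfg <- metad_config(width = 1.3, pace = 20, grid_bounds = c(-60, 60))
  tr <- run_trajectory(s$pot, s$thermo, stop_criterion("le", -1e9), s$init,
                       metad = cfg, max_steps = 3000, seed = 5,
                       return_hills = TRUE, return_bias_grid = TRUE)
  expect_true(tr$censored)
  expect_equal(nrow(tr$hills), 3000 / 20)
  rebuilt <- bias_from_hills(as.data.frame(tr$hills), cfg)
  grid <- as.data.frame(tr$bias_grid)
  expect_equal(grid$bias, rebuilt$grid_v, tolerance = 1e-10)
  expect_equal(grid$dbias, rebuilt$grid_dv, tolerance = 1e-10)
  expect_true(all(grid$bias >= 0))
})

test_that("a reset zeroes the engine bias; later hills restart from scratch", {
  s <- two_wells_setup()
  cfg <- metad_config(width = 1.3, pace = 100, grid_bounds = c(-60, 60))
  # sharp resets every 1000 steps; stop after 3.5 segments
  tr <- run_trajectory(s$pot, s$thermo, stop_criterion("le", -1e9), s$init,
                       metad = cfg,
                       schedule = reset_schedule("sharp", period = 1e-3),
                       max_steps = 3500, seed = 6,
                       return_hills = TRUE, return_bias_grid = TRUE)
  expect_equal(tr$n_resets, 3)
  hills <- as.data.frame(tr$hills)
  # only hills from the final (partial) segment survive in the grid
  last_seg <- hills[hills$time_fs > 3000, ]
  expect_equal(nrow(last_seg), 5)
  # the first hill after each reset is deposited at full height again
  first_after_reset <- hills$height[hills$time_fs %in% c(100, 1100, 2100, 3100)]
  expect_equal(first_after_reset, rep(0.5, 4), tolerance = 1e-12)
  rebuilt <- bias_from_hills(last_seg, cfg)
  expect_equal(as.data.frame(tr$bias_grid)$bias, rebuilt$grid_v,
               tolerance = 1e-10)
})
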