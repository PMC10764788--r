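test_that("Maxwell-Boltzmann initial velocities have the right moments", {
  th <- thermo_config()
  expect_equal(th$kBT_mech, 2.494e-4, tolerance = 1e-3)
  v <- sample_velocities(th, 1e6, seed = 1)
  sd_th <- sqrt(th$kBT_mech / th$mass) # ~2.5e-3 A/fs
  expect_lt(abs(mean(v)), 4 * sd_th / sqrt(length(v)))
  expect_equal(mean(v^2), th$kBT_mech / th$mass, tolerance = 0.01)
  # determinism of the stream
  expect_identical(sample_velocities(th, 10, seed = 3, stream_id = 2),
                   sample_velocities(th, 10, seed = 3, stream_id = 2))
  expect_false(any(sample_velocities(th, 10, seed = 3) ==
                   sample_velocities(th, 10, seed = 4)))
})

test_that("configurational and kinetic equipartition hold in a harmonic well", {
  k <- 0.1 # kBT / A^2
  pot <- make_potential("harmonic1d_test", list(k = k))
  th <- thermo_config()
  xs <- c(); vs <- c()
  for (j in 1:40) {
    tr <- run_trajectory(pot, th, stop_criterion("le", -1e9), c(0, 0),
                         max_steps = 2e6, sample_every = 100,
                         seed = 11, traj_id = j)
    s <- as.data.frame(tr$samples)
    s <- s[s$time_fs > 2e5, ] # discard equilibration
    xs <- c(xs, s$x); vs <- c(vs, s$vx, s$vy)
  }
  expect_equal(mean(xs^2), 1 / k, tolerance = 0.05)         # var(x) = kBT/k
  expect_equal(mean(vs^2), th$kBT_mech / th$mass, tolerance = 0.02)
})

test_that("free diffusion satisfies the Einstein relation", {
  pot <- make_potential("harmonic1d_test", list(k = 0)) # free particle
  th <- thermo_config()
  D <- th$kBT_mech / (th$mass * th$friction) # 6.24e-4 A^2/fs
  tmax <- 5e4
  disp2 <- numeric(0)
  for (j in 1:800) {
    tr <- run_trajectory(pot, th, stop_criterion("le", -1e9), c(0, 0),
                         max_steps = tmax, sample_every = tmax,
                         seed = 12, traj_id = j)
    s <- as.data.frame(tr$samples)
    xy <- s[nrow(s), c("x", "y")]
    disp2 <- c(disp2, xy$x^2, xy$y^2)
  }
  expect_equal(mean(disp2), 2 * D * tmax, tolerance = 0.10)
})

test_that("Poisson resetting produces exponential inter-reset intervals", {
  s <- two_wells_setup()
  rate <- 1000 # ns^-1 -> mean interval 1000 fs
  tr <- run_trajectory(s$pot, s$thermo, stop_criterion("le", -1e9), s$init,
                       schedule = reset_schedule("poisson", rate = rate),
                       max_steps = 3e6, seed = 13, record_segments = TRUE)
  segs <- as.data.frame(tr$segments)
  dur <- segs$duration_steps[segs$transition == 0]
  dur <- dur[-length(dur)] # last segment is cut by the step cap
  expect_gt(length(dur), 2000)
  ks <- suppressWarnings(stats::ks.test(dur, "pexp", rate = rate * 1e-6))
  expect_gt(ks$p.value, 0.01)
  expect_equal(tr$n_resets, length(dur))
})

test_that("trajectories are deterministic in (seed, traj_id)", {
  s <- two_wells_setup()
  a <- run_trajectory(s$pot, s$thermo, stop_criterion("le", 2.9), s$init,
                      seed = 7, traj_id = 3)
  b <- run_trajectory(s$pot, s$thermo, stop_criterion("le", 2.9), s$init,
                      seed = 7, traj_id = 3)
  c <- run_trajectory(s$pot, s$thermo, stop_criterion("le", 2.9), s$init,
                      seed = 7, traj_id = 4)
  expect_identical(a$fpt_steps, b$fpt_steps)
  expect_false(identical(a$fpt_steps, c$fpt_steps))
})

test_that("resetting does not perturb the dynamics noise stream", {
  # a trajectory that transits before the first reset must be identical to
  # the unreset one with the same seed
  s <- two_wells_setup()
  free <- run_trajectory(s$pot, s$thermo, stop_criterion("le", 2.0), s$init,
                         seed = 21, traj_id = 1)
  # sharp period far beyond the observed FPT
  reset <- run_trajectory(s$pot, s$thermo, stop_criterion("le", 2.0), s$init,
                          schedule = reset_schedule("sharp", period = 1),
                          seed = 21, traj_id = 1)
  expect_identical(free$fpt_steps, reset$fpt_steps)
})

test_that("degenerate and censored bookkeeping is exact", {
  s <- two_wells_setup()
  # criterion already true at initialisation
  tr0 <- run_trajectory(s$pot, s$thermo, stop_criterion("le", 5), s$init,
                        seed = 1)
  expect_equal(tr0$fpt_steps, 0)
  expect_false(tr0$censored)

  # sharp resetting faster than any possible transit
  trc <- run_trajectory(s$pot, s$thermo, stop_criterion("le", -1e9), s$init,
                        schedule = reset_schedule("sharp", period = 1e-4),
                        max_steps = 1e4, seed = 2, record_segments = TRUE)
  expect_true(trc$censored)
  expect_true(is.na(trc$fpt_steps))
  expect_equal(trc$n_resets, floor(1e4 / 100))
  expect_true(all(as.data.frame(trc$segments)$transition == 0))

  # total elapsed time equals the sum of segment durations
  trt <- run_trajectory(s$pot, s$thermo, stop_criterion("le", -3), s$init,
                        schedule = reset_schedule("poisson", rate = 100),
                        seed = 3, record_segments = TRUE)
  expect_false(trt$censored)
  segs <- as.data.frame(trt$segments)
  expect_equal(sum(segs$duration_steps), trt$fpt_steps)
  expect_equal(sum(segs$transition), 1)
  expect_equal(trt$n_resets, nrow(segs) - 1)
})

test_that("the unbiased in-well density is Boltzmann along x", {
  # long run that stays right of the barrier; compare conditional moments
  # of x (given x > 0.5) with the Boltzmann integrals over that support
  s <- two_wells_setup()
  tr <- run_trajectory(s$pot, s$thermo, stop_criterion("le", -1e9),
                       s$init, max_steps = 2e7, sample_every = 2000,
                       seed = 31)
  x <- as.data.frame(tr$samples)$x
  x <- x[x > 0.5]
  w <- function(u) exp(-potential_energy(s$pot, u, 0))
  z <- stats::integrate(w, 0.5, 100)$value
  m1 <- stats::integrate(function(u) u * w(u), 0.5, 100)$value / z
  m2 <- stats::integrate(function(u) u^2 * w(u), 0.5, 100)$value / z
  expect_equal(mean(x), m1, tolerance = 0.15)
  expect_equal(mean(x^2), m2, tolerance = 0.30)
})
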