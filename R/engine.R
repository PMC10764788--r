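#' Thermostat and integrator settings
#'
#' Settings for the NVT Langevin integrator: a single particle of mass
#' \code{mass} coupled to a heat bath at \code{temperature} with friction
#' \code{friction}, advanced with the BAOAB splitting at timestep \code{dt}.
#' The derived field \code{kBT_mech} is the thermal energy in the internal
#' mechanical unit system (g A^2 fs^-2 mol^-1); at 300 K it equals
#' about 2.494e-4.
#'
#' @param temperature bath temperature in K.
#' @param mass particle mass in g/mol.
#' @param friction Langevin friction coefficient in fs^-1.
#' @param dt integration timestep in fs.
#' @return an object of class \code{"thermo_config"}.
#' @export
thermo_config <- function(temperature = 300, mass = 40, friction = 0.01,
                          dt = 1) {
  stopifnot(temperature > 0, mass > 0, friction >= 0, dt > 0)
  kB <- 8.31446261815324e-3                 # kJ/mol/K
  structure(list(temperature = temperature, mass = mass,
                 friction = friction, dt = dt,
                 kBT_mech = kB * temperature * 1e-4),
            class = "thermo_config")
}

#' Linear collective variable
#'
#' A linear CV in the plane, \eqn{s(x, y) = x \cos\theta + y \sin\theta}.
#' \code{angle = 0} is the x-coordinate, which is the optimal CV for both
#' model potentials; rotating the CV away from the x-axis makes it
#' progressively suboptimal.
#'
#' @param angle rotation angle \eqn{\theta} in radians.
#' @return an object of class \code{"cv_spec"}.
#' @export
cv_spec <- function(angle = 0) {
  stopifnot(is.finite(angle))
  structure(list(angle = angle), class = "cv_spec")
}

#' CV value of a position
#'
#' @param cv a \code{cv_spec}.
#' @param position numeric length-2 \code{c(x, y)} or a two-column matrix.
#' @return CV value(s) in Angstrom.
#' @export
cv_value <- function(cv, position) {
  stopifnot(inherits(cv, "cv_spec"))
  if (is.matrix(position))
    position[, 1] * cos(cv$angle) + position[, 2] * sin(cv$angle)
  else
    position[1] * cos(cv$angle) + position[2] * sin(cv$angle)
}

#' Well-tempered metadynamics settings
#'
#' @param height initial Gaussian hill height in \eqn{k_BT}.
#' @param width Gaussian hill width sigma in Angstrom (1.3 for the two-wells
#'   model, 0.15 for the Faradjian--Elber model).
#' @param bias_factor well-tempered bias factor (> 1); deposited heights are
#'   scaled by \eqn{\exp(-V_{bias}/((\gamma_B - 1) k_BT))}.
#' @param pace steps between hill depositions. The equivalent deposition
#'   rate in ns^-1 is \code{1e6 / (pace * dt)} at \code{dt} in fs.
#' @param grid_spacing bias grid spacing in Angstrom.
#' @param grid_bounds numeric length-2; CV range covered by the grid. A CV
#'   excursion beyond the bounds is an error (it signals a misconfigured
#'   grid), not a clamp. The default span is generous because the model
#'   traps are soft: once partially filled with bias, walkers make
#'   excursions of hundreds of Angstrom in long unreset runs.
#' @return an object of class \code{"metad_config"}.
#' @export
metad_config <- function(height = 0.5, width = 1.3, bias_factor = 10,
                         pace = 100, grid_spacing = 0.01,
                         grid_bounds = c(-500, 500)) {
  stopifnot(height > 0, width > 0, bias_factor > 1, pace >= 1,
            grid_spacing > 0, length(grid_bounds) == 2,
            grid_bounds[1] < grid_bounds[2])
  structure(list(height = height, width = width, bias_factor = bias_factor,
                 pace = as.integer(pace), grid_spacing = grid_spacing,
                 grid_bounds = grid_bounds),
            class = "metad_config")
}

#' Convert a bias deposition rate to a pace
#'
#' Hills per nanosecond to integration steps between hills:
#' \code{pace = round(1 / (rate * dt))} with \code{dt} in fs. A rate of
#' 1e4 ns^-1 at dt = 1 fs is one hill every 100 steps.
#'
#' @param rate_ns bias deposition rate in ns^-1.
#' @param dt timestep in fs.
#' @return integer pace.
#' @export
pace_from_rate <- function(rate_ns, dt = 1) {
  stopifnot(rate_ns > 0, dt > 0)
  max(1L, as.integer(round(1e6 / (rate_ns * dt))))
}

#' Resetting schedule
#'
#' Stochastic resetting stops the trajectory and restarts it from the fixed
#' initial position with fresh Maxwell--Boltzmann velocities; any
#' metadynamics bias is zeroed at the same moment. Poisson resetting draws
#' inter-reset intervals from an exponential distribution with rate
#' \code{rate}; sharp resetting uses a fixed \code{period}.
#'
#' @param mode \code{"none"}, \code{"poisson"} or \code{"sharp"}.
#' @param rate Poisson resetting rate in ns^-1.
#' @param period sharp resetting period in ns.
#' @return an object of class \code{"reset_schedule"}.
#' @export
reset_schedule <- function(mode = c("none", "poisson", "sharp"),
                           rate = NULL, period = NULL) {
  mode <- match.arg(mode)
  if (mode == "poisson") {
    stopifnot(!is.null(rate), rate >= 0)
    if (rate == 0) mode <- "none"
  }
  if (mode == "sharp") stopifnot(!is.null(period), period > 0)
  structure(list(mode = mode, rate = rate, period = period),
            class = "reset_schedule")
}

#' First-passage stop criterion
#'
#' Committor-style criterion on the x-coordinate, tested after every
#' integration step; the first-passage time is the earliest instant at
#' which it holds, tallied across resetting events.
#'
#' @param op \code{"le"} (\eqn{x \le c}), \code{"lt"} (\eqn{x < c}) or
#'   \code{"between"} (\eqn{c < x < c_2}).
#' @param threshold threshold c in Angstrom.
#' @param upper upper bound for \code{op = "between"}.
#' @return an object of class \code{"stop_criterion"}.
#' @export
stop_criterion <- function(op = c("le", "lt", "between"), threshold,
                           upper = NULL) {
  op <- match.arg(op)
  if (op == "between") stopifnot(!is.null(upper), upper > threshold)
  structure(list(op = op, threshold = threshold, upper = upper),
            class = "stop_criterion")
}

.stop_code <- function(stop) {
  switch(stop$op, le = 0L, lt = 1L, between = 2L)
}

#' Maxwell-Boltzmann velocity draws
#'
#' Samples initial velocities from the engine's own velocity stream; each
#' component is an independent zero-mean Gaussian with variance
#' \eqn{k_BT/m} (in (A/fs)^2).
#'
#' @param thermo a \code{thermo_config}.
#' @param n number of 2D draws.
#' @param seed,stream_id seed of the velocity stream; identical pairs give
#'   identical draws.
#' @return an \code{n} x 2 matrix of velocities (A/fs).
#' @export
sample_velocities <- function(thermo, n, seed = 1, stream_id = 0) {
  stopifnot(inherits(thermo, "thermo_config"), n >= 1)
  sample_velocities_cpp(as.integer(n), thermo$temperature, thermo$mass,
                        as.double(seed), as.double(stream_id))
}

#' Run one Langevin trajectory to first passage
#'
#' Integrates a single particle on a model potential until the stop
#' criterion holds (or \code{max_steps} is exceeded, in which case the
#' record is flagged censored). Optionally deposits a well-tempered
#' metadynamics bias along a linear CV and/or applies a resetting
#' schedule; the bias grid and the hill-deposition clock are zeroed at
#' every reset, while the first-passage clock keeps running.
#'
#' @param potential a \code{potential2d}.
#' @param thermo a \code{thermo_config}.
#' @param stop a \code{stop_criterion}.
#' @param init_position numeric length-2, fixed initial position (Angstrom).
#' @param cv a \code{cv_spec} (used only when \code{metad} is given).
#' @param metad a \code{metad_config}, or \code{NULL} for unbiased dynamics.
#' @param schedule a \code{reset_schedule}.
#' @param seed base seed; combined with \code{traj_id} it determines three
#'   independent streams (dynamics noise, velocity initialisation, reset
#'   times), so adding resetting does not perturb the dynamics stream.
#' @param traj_id trajectory index used for seed splitting.
#' @param max_steps cap on total integration steps.
#' @param sample_every if > 0, record the state every that many steps.
#' @param return_hills,return_bias_grid,record_segments request the hill
#'   log, the final bias grid, and the per-segment record (duration,
#'   rescaled duration, transition flag) used by the kinetics-inference
#'   layer.
#' @return a list of class \code{"trajectory_record"} with elements
#'   \code{fpt_steps} (NA when censored), \code{fpt_ns}, \code{n_resets},
#'   \code{censored}, and the optional extras.
#' @export
run_trajectory <- function(potential, thermo = thermo_config(),
                           stop, init_position,
                           cv = cv_spec(0), metad = NULL,
                           schedule = reset_schedule("none"),
                           seed = 1, traj_id = 0, max_steps = 1e9,
                           sample_every = 0,
                           return_hills = FALSE, return_bias_grid = FALSE,
                           record_segments = FALSE) {
  stopifnot(inherits(potential, "potential2d"),
            inherits(thermo, "thermo_config"),
            inherits(stop, "stop_criterion"),
            inherits(schedule, "reset_schedule"),
            length(init_position) == 2)
  metad_on <- !is.null(metad)
  if (metad_on) stopifnot(inherits(metad, "metad_config"))
  reset_code <- switch(schedule$mode, none = 0L, poisson = 1L, sharp = 2L)
  res <- run_trajectory_cpp(
    .pot_code(potential), .pot_par(potential),
    init_position[1], init_position[2],
    thermo$temperature, thermo$mass, thermo$friction, thermo$dt,
    .stop_code(stop), stop$threshold,
    if (is.null(stop$upper)) 0 else stop$upper,
    metad_on, cv$angle,
    if (metad_on) metad$height else 0,
    if (metad_on) metad$width else 1,
    if (metad_on) metad$bias_factor else 10,
    if (metad_on) metad$pace else 0L,
    if (metad_on) metad$grid_bounds[1] else -1,
    if (metad_on) metad$grid_bounds[2] else 1,
    if (metad_on) metad$grid_spacing else 1,
    reset_code,
    if (identical(schedule$mode, "poisson")) schedule$rate else 0,
    if (identical(schedule$mode, "sharp")) schedule$period else 0,
    max_steps, as.double(seed), as.double(traj_id),
    as.integer(sample_every), return_hills, return_bias_grid,
    record_segments)
  res$fpt_ns <- if (is.na(res$fpt_steps)) NA_real_ else
    res$fpt_steps * thermo$dt * 1e-6
  res$integrator <- "BAOAB"
  class(res) <- "trajectory_record"
  res
}

#' Run an ensemble of independent first-passage trajectories
#'
#' Runs \code{n} independent trajectories with per-trajectory seeds derived
#' from \code{seed} by counter-based splitting (trajectory \code{j} is
#' reproducible in isolation), and collects the first-passage times into an
#' \code{\link{fpt_ensemble}}.
#'
#' @inheritParams run_trajectory
#' @param n number of trajectories.
#' @param keep_segments collect per-segment records for kinetics inference.
#' @param metadata named list stored on the ensemble.
#' @return an \code{\link{fpt_ensemble}}; when \code{keep_segments} is
#'   \code{TRUE} it carries a \code{segments} data frame (traj_id, segment,
#'   duration_steps, rescaled_ns, transition).
#' @export
run_fpt_ensemble <- function(n, potential, thermo = thermo_config(),
                             stop, init_position,
                             cv = cv_spec(0), metad = NULL,
                             schedule = reset_schedule("none"),
                             seed = 1, max_steps = 1e9,
                             keep_segments = FALSE, metadata = list()) {
  stopifnot(n >= 1)
  fpt_steps <- numeric(n); n_resets <- numeric(n); censored <- logical(n)
  seg_list <- if (keep_segments) vector("list", n) else NULL
  for (j in seq_len(n)) {
    tr <- run_trajectory(potential, thermo, stop, init_position, cv, metad,
                         schedule, seed = seed, traj_id = j,
                         max_steps = max_steps,
                         record_segments = keep_segments)
    fpt_steps[j] <- tr$fpt_steps
    n_resets[j] <- tr$n_resets
    censored[j] <- tr$censored
    if (keep_segments && !is.null(tr$segments)) {
      s <- as.data.frame(tr$segments)
      s$traj_id <- j
      s$segment <- seq_len(nrow(s))
      seg_list[[j]] <- s
    }
  }
  ens <- fpt_ensemble(tau = fpt_steps * thermo$dt * 1e-6,
                      censored = censored,
                      metadata = c(metadata,
                                   list(dt = thermo$dt, seed = seed,
                                        potential = potential$family,
                                        integrator = "BAOAB")))
  ens$fpt_steps <- fpt_steps
  ens$n_resets <- n_resets
  if (keep_segments) ens$segments <- do.call(rbind, seg_list)
  ens
}

#' @export
print.trajectory_record <- function(x, ...) {
  cat("<trajectory_record>",
      if (x$censored) "censored" else sprintf("FPT = %.6g ns", x$fpt_ns),
      sprintf("(%d resets)\n", as.integer(x$n_resets)))
  invisible(x)
}
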