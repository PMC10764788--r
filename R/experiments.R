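#' Experiment configuration
#'
#' A fully serializable description of one set of first-passage
#' simulations: potential, thermostat, CV, optional metadynamics bias,
#' resetting schedule, stop criterion, trajectory count and base seed.
#' Re-running an identical configuration reproduces every output.
#'
#' @param potential family name or a \code{potential2d}.
#' @param potential_params parameter overrides when \code{potential} is a
#'   family name (keys mirror the closed-form symbols: A1, A2, B, C,
#'   sigma1, sigma2, y_scale).
#' @param thermo a \code{\link{thermo_config}}.
#' @param cv_angle CV rotation angle theta (radians).
#' @param metad a \code{\link{metad_config}} or \code{NULL}.
#' @param schedule a \code{\link{reset_schedule}}.
#' @param stop a \code{\link{stop_criterion}}.
#' @param init_position fixed initial position (Angstrom).
#' @param n_trajectories number of independent trajectories.
#' @param seed base seed.
#' @param max_steps per-trajectory cap.
#' @param keep_segments record per-segment rescaling data.
#' @return an object of class \code{"experiment_config"}.
#' @export
experiment_config <- function(potential = "two_wells",
                              potential_params = list(),
                              thermo = thermo_config(),
                              cv_angle = 0,
                              metad = NULL,
                              schedule = reset_schedule("none"),
                              stop = stop_criterion("le", -3),
                              init_position = c(3, 0),
                              n_trajectories = 100,
                              seed = 1,
                              max_steps = 1e9,
                              keep_segments = FALSE) {
  pot <- if (inherits(potential, "potential2d")) potential
         else make_potential(potential, potential_params)
  stopifnot(inherits(thermo, "thermo_config"),
            inherits(schedule, "reset_schedule"),
            inherits(stop, "stop_criterion"),
            n_trajectories >= 1)
  structure(list(potential = pot, thermo = thermo, cv_angle = cv_angle,
                 metad = metad, schedule = schedule, stop = stop,
                 init_position = init_position,
                 n_trajectories = as.integer(n_trajectories),
                 seed = seed, max_steps = max_steps,
                 keep_segments = keep_segments),
            class = "experiment_config")
}

#' Run a configured experiment
#'
#' Executes \code{n_trajectories} independent trajectories with
#' counter-split per-trajectory seeds and, when \code{out_dir} is given,
#' writes the FPT table (TSV), the per-segment sidecar (TSV, if recorded)
#' and a JSON summary (MFPT, SEM, COV, censored count, configuration
#' echo).
#'
#' @param config an \code{\link{experiment_config}}.
#' @param out_dir optional output directory.
#' @return the \code{\link{fpt_ensemble}}, invisibly when writing.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  ens <- run_fpt_ensemble(
    config$n_trajectories, config$potential, config$thermo, config$stop,
    config$init_position, cv_spec(config$cv_angle), config$metad,
    config$schedule, seed = config$seed, max_steps = config$max_steps,
    keep_segments = config$keep_segments,
    metadata = list(cv_angle = config$cv_angle,
                    reset_mode = config$schedule$mode,
                    reset_rate = config$schedule$rate,
                    bias_pace = config$metad$pace))
  if (is.null(out_dir)) return(ens)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fpt_table(ens, file.path(out_dir, "fpt_table.tsv"))
  if (!is.null(ens$segments))
    utils::write.table(ens$segments, file.path(out_dir, "segments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  s <- fpt_summary(ens)
  jsonlite::write_json(
    list(mfpt_ns = s$mfpt, sd_ns = s$sd, sem_ns = s$sem, cov = s$cov,
         n = s$n, n_censored = s$n_censored,
         potential = config$potential$family,
         cv_angle = config$cv_angle,
         reset_mode = config$schedule$mode,
         seed = config$seed, integrator = "BAOAB"),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(ens)
}

#' Replicate a model-system sweep at reduced scale
#'
#' Re-runs, at a fraction \code{scale} of 1e4 trajectories per point, one
#' of the model-potential sweeps: the SR-only resetting-rate sweep
#' (\code{"sr_rates"}), the metadynamics pace sweep with and without
#' optimal resetting (\code{"metad_paces"}), the combined MetaD+SR
#' resetting-rate sweep at a bias rate of 1e4 ns^-1
#' (\code{"metad_sr_rates"}), the COV-versus-pace curve with predicted
#' additional speedups (\code{"cov_paces"}), and the rotated-CV sweep on
#' the Faradjian--Elber potential (\code{"fe_angles"}).
#'
#' @param name sweep name (see above).
#' @param scale fraction of 1e4 trajectories per point, in (0, 1].
#' @param seed base seed.
#' @param out_dir optional directory for TSV outputs.
#' @return a data frame with one row per sweep point (rates, speedups,
#'   SEMs, ...), with the scale recorded as an attribute.
#' @export
replicate_figure <- function(name = c("sr_rates", "metad_paces",
                                      "metad_sr_rates", "cov_paces",
                                      "fe_angles"),
                             scale = 0.02, seed = 1, out_dir = NULL) {
  name <- match.arg(name)
  stopifnot(scale > 0, scale <= 1)
  n <- max(4L, as.integer(round(1e4 * scale)))
  th <- thermo_config()
  tw <- make_potential("two_wells")
  fe <- make_potential("faradjian_elber")
  stop_tw <- stop_criterion("le", -3)
  stop_fe <- stop_criterion("lt", -1)
  base <- function(pot, stp, n_base, sd) {
    run_fpt_ensemble(n_base, pot, th, stp, c(3, 0), seed = sd)
  }
  res <- switch(name,
    sr_rates = {
      ref <- base(tw, stop_tw, n, seed)
      rates <- c(5, 10, 25, 50, 100, 200, 500)
      rows <- lapply(seq_along(rates), function(i) {
        ens <- run_fpt_ensemble(n, tw, th, stop_tw, c(3, 0),
                                schedule = reset_schedule("poisson",
                                                          rate = rates[i]),
                                seed = seed + i)
        sp <- speedup(ref, ens)
        data.frame(rate = rates[i], speedup = sp$speedup, sem = sp$sem)
      })
      out <- do.call(rbind, rows)
      attr(out, "argmax_rate") <- out$rate[which.max(out$speedup)]
      out
    },
    metad_paces = {
      ref <- base(tw, stop_tw, n, seed)
      bias_rates <- c(20, 100, 1000, 1e4)
      rows <- lapply(seq_along(bias_rates), function(i) {
        cfg <- metad_config(width = 1.3, pace = pace_from_rate(bias_rates[i]))
        ens <- run_fpt_ensemble(n, tw, th, stop_tw, c(3, 0), metad = cfg,
                                seed = seed + 100 + i)
        sp <- speedup(ref, ens)
        opt <- optimal_reset_rate(ens, lower = 1, upper = 2000)
        ens_sr <- run_fpt_ensemble(
          n, tw, th, stop_tw, c(3, 0), metad = cfg,
          schedule = reset_schedule("poisson", rate = opt$r_star),
          seed = seed + 200 + i)
        sp_sr <- speedup(ref, ens_sr)
        data.frame(bias_rate = bias_rates[i], speedup = sp$speedup,
                   sem = sp$sem, opt_reset_rate = opt$r_star,
                   speedup_sr = sp_sr$speedup, sem_sr = sp_sr$sem)
      })
      do.call(rbind, rows)
    },
    metad_sr_rates = {
      ref <- base(tw, stop_tw, n, seed)
      cfg <- metad_config(width = 1.3, pace = 100)
      rates <- c(0, 25, 50, 125, 250, 500, 1000)
      rows <- lapply(seq_along(rates), function(i) {
        sched <- if (rates[i] == 0) reset_schedule("none")
                 else reset_schedule("poisson", rate = rates[i])
        ens <- run_fpt_ensemble(n, tw, th, stop_tw, c(3, 0), metad = cfg,
                                schedule = sched, seed = seed + 300 + i)
        sp <- speedup(ref, ens)
        data.frame(rate = rates[i], speedup = sp$speedup, sem = sp$sem)
      })
      out <- do.call(rbind, rows)
      attr(out, "argmax_rate") <- out$rate[which.max(out$speedup)]
      out
    },
    cov_paces = {
      bias_rates <- c(20, 100, 1000, 1e4)
      rows <- lapply(seq_along(bias_rates), function(i) {
        cfg <- metad_config(width = 1.3, pace = pace_from_rate(bias_rates[i]))
        ens <- run_fpt_ensemble(n, tw, th, stop_tw, c(3, 0), metad = cfg,
                                seed = seed + 400 + i)
        s <- fpt_summary(ens)
        opt <- optimal_reset_rate(ens, lower = 1, upper = 2000)
        data.frame(bias_rate = bias_rates[i], cov = s$cov,
                   mfpt_ns = s$mfpt, opt_reset_rate = opt$r_star,
                   predicted_extra_speedup = opt$max_speedup)
      })
      do.call(rbind, rows)
    },
    fe_angles = {
      ref <- base(fe, stop_fe, n, seed)
      angles <- asin(c(0, 0.1, 0.2, 0.3, sin(24 * pi / 180)))
      cfg <- metad_config(width = 0.15, pace = 100)
      rows <- lapply(seq_along(angles), function(i) {
        ens <- run_fpt_ensemble(n, fe, th, stop_fe, c(3, 0),
                                cv = cv_spec(angles[i]), metad = cfg,
                                seed = seed + 500 + i)
        sp <- speedup(ref, ens)
        opt <- optimal_reset_rate(ens, lower = 1, upper = 5000)
        ens_sr <- run_fpt_ensemble(
          n, fe, th, stop_fe, c(3, 0), cv = cv_spec(angles[i]), metad = cfg,
          schedule = reset_schedule("poisson", rate = opt$r_star),
          seed = seed + 600 + i)
        sp_sr <- speedup(ref, ens_sr)
        data.frame(sin_theta = sin(angles[i]), speedup = sp$speedup,
                   sem = sp$sem, opt_reset_rate = opt$r_star,
                   speedup_sr = sp_sr$speedup, sem_sr = sp_sr$sem)
      })
      do.call(rbind, rows)
    })
  attr(res, "scale") <- scale
  attr(res, "n_per_point") <- n
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(res, file.path(out_dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

#' Synthetic first-passage ensembles
#'
#' Draws a seeded FPT sample from a family with closed-form moments, for
#' testing the analytics without simulation: exponential (COV 1),
#' deterministic (COV 0), lognormal, or a two-exponential mixture (heavy
#' tailed, COV > 1 for well-separated rates).
#'
#' @param family \code{"exponential"}, \code{"deterministic"},
#'   \code{"lognormal"}, \code{"mixture"}.
#' @param n sample size.
#' @param rate exponential rate (ns^-1).
#' @param tau0 deterministic FPT (ns).
#' @param meanlog,sdlog lognormal parameters.
#' @param rates,weights mixture component rates and weights.
#' @param seed RNG seed.
#' @return an \code{\link{fpt_ensemble}} with
#'   \code{metadata$synthetic = TRUE}.
#' @export
synthesize_fpt_ensemble <- function(family = c("exponential",
                                               "deterministic",
                                               "lognormal", "mixture"),
                                    n, rate = 1, tau0 = 1,
                                    meanlog = 0, sdlog = 1,
                                    rates = c(10, 0.1),
                                    weights = c(0.9, 0.1),
                                    seed = 1) {
  family <- match.arg(family)
  stopifnot(n >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tau <- switch(family,
    exponential = stats::rexp(n, rate),
    deterministic = rep(tau0, n),
    lognormal = stats::rlnorm(n, meanlog, sdlog),
    mixture = {
      stopifnot(length(rates) == length(weights),
                abs(sum(weights) - 1) < 1e-9)
      comp <- sample.int(length(rates), n, replace = TRUE, prob = weights)
      stats::rexp(n, rates[comp])
    })
  fpt_ensemble(tau, metadata = list(synthetic = TRUE, family = family,
                                    seed = seed))
}
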