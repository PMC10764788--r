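#' Rescaled first-passage time of a biased trajectory
#'
#' Converts a metadynamics trajectory (without resetting) into an
#' unbiased-equivalent first-passage time by the acceleration-factor
#' rescaling of infrequent metadynamics,
#' \eqn{\tau^* = \sum_t \mathrm{d}t\, e^{V_{bias}(s(t),t)/k_BT}},
#' accumulated by the engine up to the first passage.
#'
#' @param record a \code{trajectory_record} obtained with
#'   \code{record_segments = TRUE}, or its \code{segments} matrix.
#' @return rescaled FPT in ns.
#' @export
rescale_trajectory <- function(record) {
  segs <- if (inherits(record, "trajectory_record")) record$segments
          else record
  if (is.null(segs)) stop("missing per-segment bias-exposure record; ",
                          "run with record_segments = TRUE")
  segs <- as.data.frame(segs)
  if (!any(segs$transition > 0))
    stop("trajectory has no first passage; rescaled FPT undefined")
  last <- which(segs$transition > 0)[1]
  sum(segs$rescaled_ns[seq_len(last)])
}

#' Product-limit survival over rescaled segment durations
#'
#' Treats the inter-reset segments of sharp-resetting iMetaD runs as
#' independent short trajectories: each segment contributes its rescaled
#' duration, as an event when the first passage occurred within the
#' segment and as a right-censored observation when the segment ended by
#' reset (or by the step cap). The survival function of the unbiased FPT
#' at short times is then estimated by the Kaplan--Meier product-limit
#' estimator (events precede censorings at tied times, the standard
#' convention).
#'
#' @param segments data frame with columns \code{rescaled_ns} and
#'   \code{transition} (as produced by \code{\link{run_fpt_ensemble}} with
#'   \code{keep_segments = TRUE}), or a numeric vector of rescaled times
#'   together with \code{event}.
#' @param event logical/0-1 vector when \code{segments} is a numeric vector.
#' @param discard_censored if \code{TRUE}, censored segments are dropped
#'   instead of entering the product limit (sensitivity switch).
#' @return object of class \code{"survival_curve"}: data frame columns
#'   \code{time} (rescaled ns), \code{surv}, \code{n_risk},
#'   \code{n_event}, plus attributes \code{n_segments}, \code{n_events}.
#' @export
survival_from_segments <- function(segments, event = NULL,
                                   discard_censored = FALSE) {
  if (is.numeric(segments)) {
    stopifnot(!is.null(event), length(event) == length(segments))
    df <- data.frame(rescaled_ns = segments, transition = as.integer(event))
  } else {
    df <- as.data.frame(segments)
  }
  stopifnot(all(c("rescaled_ns", "transition") %in% names(df)))
  if (discard_censored) df <- df[df$transition > 0, , drop = FALSE]
  if (nrow(df) == 0) stop("no segments left")
  fit <- survival::survfit(
    survival::Surv(df$rescaled_ns, df$transition > 0) ~ 1)
  out <- data.frame(time = fit$time, surv = fit$surv,
                    n_risk = fit$n.risk, n_event = fit$n.event)
  structure(out, class = c("survival_curve", "data.frame"),
            n_segments = nrow(df),
            n_events = sum(df$transition > 0))
}

#' Fit an exponential decay to a survival curve
#'
#' Assumes the (rescaled) survival probability decays exponentially and
#' extracts the unbiased rate from the slope of \eqn{\ln S} versus
#' rescaled time by weighted least squares, the weights being the
#' per-point event counts. The default window keeps times at which the
#' number at risk is still at least \code{risk_floor} of all segments
#' (over-deposition corrupts the estimate at long rescaled times, so the
#' fit deliberately uses short times only).
#'
#' @param curve a \code{survival_curve}.
#' @param window optional numeric length-2 window on rescaled time (ns).
#' @param risk_floor fraction of segments that must still be at risk for a
#'   point to enter the default window.
#' @param min_events minimum number of distinct event times required.
#' @return list of class \code{"inference_result"}: \code{k} (ns^-1),
#'   \code{tau_est} (ns), \code{r_squared}, \code{ks_statistic},
#'   \code{window}, \code{n_points}.
#' @export
fit_exponential_survival <- function(curve, window = NULL,
                                     risk_floor = 0.2, min_events = 5) {
  stopifnot(inherits(curve, "survival_curve"))
  df <- curve[curve$n_event > 0 & curve$surv > 0 & curve$time > 0, ,
              drop = FALSE]
  if (is.null(window)) {
    n_seg <- attr(curve, "n_segments")
    df <- df[df$n_risk >= risk_floor * n_seg, , drop = FALSE]
    window <- if (nrow(df)) c(0, max(df$time)) else c(0, 0)
  } else {
    df <- df[df$time >= window[1] & df$time <= window[2], , drop = FALSE]
  }
  if (nrow(df) < min_events)
    stop("fewer than ", min_events, " event times in the fit window; ",
         "survival curve unfit for rate estimation")
  fit <- stats::lm(log(surv) ~ time, data = df, weights = df$n_event)
  slope <- stats::coef(fit)[["time"]]
  if (slope >= 0)
    stop("non-positive decay rate estimate; survival does not decay ",
         "exponentially on the window")
  k <- -slope
  r2 <- summary(fit)$r.squared
  ks <- max(abs(df$surv - exp(-k * df$time)))
  structure(list(k = k, tau_est = 1 / k, r_squared = r2,
                 ks_statistic = ks, window = window,
                 n_points = nrow(df)),
            class = "inference_result")
}

#' @export
print.inference_result <- function(x, ...) {
  cat(sprintf(
    "<inference_result> k = %.4g ns^-1, tau_est = %.4g ns (R^2 %.3f, KS %.3f)\n",
    x$k, x$tau_est, x$r_squared, x$ks_statistic))
  invisible(x)
}

#' Relative error of an MFPT estimate
#'
#' \eqn{|\langle\tau\rangle_{true} - \langle\tau\rangle_{est}| /
#' \langle\tau\rangle_{true}}.
#'
#' @param tau_true true unbiased MFPT (> 0).
#' @param tau_est estimated MFPT.
#' @return dimensionless error.
#' @export
prediction_error <- function(tau_true, tau_est) {
  if (any(tau_true <= 0)) stop("tau_true must be positive")
  abs(tau_true - tau_est) / tau_true
}

#' Full inference pipeline for one biased ensemble
#'
#' Segments -> product-limit survival -> exponential fit -> MFPT estimate.
#'
#' @param segments per-segment records (see
#'   \code{\link{survival_from_segments}}).
#' @param ... passed to \code{\link{fit_exponential_survival}}.
#' @return an \code{inference_result}.
#' @export
infer_mfpt <- function(segments, ...) {
  fit_exponential_survival(survival_from_segments(segments), ...)
}

#' Speedup / prediction-error tradeoff scan
#'
#' Runs the full pipeline (simulate -> rescale -> survival -> exponential
#' fit -> error) for a set of bias deposition rates without resetting and,
#' at a fixed bias rate, for a set of sharp-resetting periods. Speedup is
#' measured in wall simulation steps against the supplied unbiased MFPT.
#'
#' @param potential,thermo,stop,init_position,cv simulation setup as in
#'   \code{\link{run_fpt_ensemble}}.
#' @param metad_base a \code{\link{metad_config}} whose pace is replaced
#'   per protocol.
#' @param bias_rates bias deposition rates (ns^-1) for the no-resetting
#'   branch.
#' @param reset_periods sharp-resetting periods (ns) for the resetting
#'   branch, all at \code{sr_bias_rate}.
#' @param sr_bias_rate bias rate of the resetting branch (defaults to the
#'   largest of \code{bias_rates}).
#' @param tau_true reference unbiased MFPT (ns).
#' @param n trajectories per protocol.
#' @param seed base seed.
#' @param max_steps per-trajectory step cap.
#' @return data frame: protocol, bias_rate, reset_period, speedup,
#'   tau_est, error, r_squared, n_events.
#' @export
tradeoff_scan <- function(potential, thermo = thermo_config(), stop,
                          init_position, cv = cv_spec(0), metad_base,
                          bias_rates, reset_periods,
                          sr_bias_rate = max(bias_rates),
                          tau_true, n = 100, seed = 1, max_steps = 1e9) {
  run_one <- function(bias_rate, period, idx) {
    cfg <- metad_base
    cfg$pace <- pace_from_rate(bias_rate, thermo$dt)
    sched <- if (is.na(period)) reset_schedule("none")
             else reset_schedule("sharp", period = period)
    ens <- run_fpt_ensemble(n, potential, thermo, stop, init_position,
                            cv, cfg, sched, seed = seed + idx,
                            max_steps = max_steps, keep_segments = TRUE)
    s <- fpt_summary(ens)
    mean_steps <- mean(ens$fpt_steps[!ens$censored], na.rm = TRUE)
    inf <- try(infer_mfpt(ens$segments), silent = TRUE)
    ok <- !inherits(inf, "try-error")
    data.frame(
      protocol = if (is.na(period)) "iMetaD" else "iMetaD+SR",
      bias_rate = bias_rate,
      reset_period = period,
      speedup = tau_true * 1e6 / thermo$dt / mean_steps,
      tau_est = if (ok) inf$tau_est else NA_real_,
      error = if (ok) prediction_error(tau_true, inf$tau_est) else NA_real_,
      r_squared = if (ok) inf$r_squared else NA_real_,
      n_events = sum(ens$segments$transition > 0),
      n_censored = s$n_censored)
  }
  rows <- list()
  for (i in seq_along(bias_rates))
    rows[[length(rows) + 1]] <- run_one(bias_rates[i], NA_real_, i)
  for (j in seq_along(reset_periods))
    rows[[length(rows) + 1]] <-
      run_one(sr_bias_rate, reset_periods[j], length(bias_rates) + j)
  do.call(rbind, rows)
}
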