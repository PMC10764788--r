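#' First-passage-time ensemble
#'
#' Container for a sample of first-passage times (FPTs) with censoring
#' flags and free-form metadata. Censored entries (trajectories stopped by
#' a step cap rather than by a first passage) are excluded from all moment
#' statistics; their count is reported.
#'
#' @param tau FPT samples in ns (NA allowed for censored entries).
#' @param censored logical vector, same length as \code{tau}.
#' @param metadata named list (potential, CV angle, bias rate, seeds, ...).
#' @return an object of class \code{"fpt_ensemble"}.
#' @export
fpt_ensemble <- function(tau, censored = rep(FALSE, length(tau)),
                         metadata = list()) {
  stopifnot(length(tau) >= 1, length(censored) == length(tau))
  if (any(tau[!censored] < 0, na.rm = TRUE))
    stop("first-passage times must be non-negative")
  structure(list(tau = as.double(tau), censored = as.logical(censored),
                 metadata = metadata),
            class = "fpt_ensemble")
}

.uncensored <- function(ens) {
  stopifnot(inherits(ens, "fpt_ensemble"))
  tau <- ens$tau[!ens$censored]
  tau[!is.na(tau)]
}

#' Ensemble summary: MFPT, SEM, COV
#'
#' The mean first-passage time (MFPT), standard deviation, standard error
#' of the mean (std/sqrt(N)) and coefficient of variation (std/MFPT) of
#' the uncensored samples. The standard deviation is the population one
#' (denominator N) by default, so that an exponential ensemble has COV
#' exactly 1 in the large-N limit; set \code{ddof = 1} for the sample
#' standard deviation.
#'
#' @param ens an \code{fpt_ensemble}.
#' @param ddof delta degrees of freedom for the standard deviation (0 =
#'   population, 1 = sample).
#' @return list with \code{mfpt}, \code{sd}, \code{sem}, \code{cov},
#'   \code{n}, \code{n_censored} (times in ns).
#' @export
fpt_summary <- function(ens, ddof = 0) {
  tau <- .uncensored(ens)
  n <- length(tau)
  if (n == 0) stop("all samples are censored; no moment statistics")
  m <- mean(tau)
  s <- if (n >= 2) {
    sqrt(sum((tau - m)^2) / (n - ddof))
  } else NA_real_
  list(mfpt = m, sd = s, sem = s / sqrt(n), cov = s / m, n = n,
       n_censored = sum(ens$censored))
}

#' @export
print.fpt_ensemble <- function(x, ...) {
  s <- try(fpt_summary(x), silent = TRUE)
  cat("<fpt_ensemble> n =", length(x$tau), "\n")
  if (!inherits(s, "try-error"))
    cat(sprintf("  MFPT %.6g ns  (SEM %.3g), COV %.3f, censored %d\n",
                s$mfpt, s$sem, s$cov, s$n_censored))
  invisible(x)
}

#' Empirical Laplace transform of the FPT distribution
#'
#' \eqn{\tilde f(r) = \langle e^{-r\tau} \rangle \approx N^{-1} \sum_j
#' e^{-r \tau_j}}, evaluated over the uncensored samples.
#'
#' @param ens an \code{fpt_ensemble}.
#' @param r resetting rate(s), ns^-1 (non-negative).
#' @return values in (0, 1].
#' @export
laplace_transform <- function(ens, r) {
  if (any(r < 0)) stop("r must be non-negative")
  tau <- .uncensored(ens)
  vapply(r, function(ri) mean(exp(-ri * tau)), numeric(1))
}

#' MFPT under Poisson resetting, predicted from FPT samples
#'
#' Predicts the mean first-passage time under Poisson resetting at rate
#' \eqn{r} from the FPT distribution \emph{without} resetting:
#' \deqn{\langle\tau\rangle_r = \frac{1 - \tilde f(r)}{r\, \tilde f(r)},}
#' with \eqn{\tilde f} the empirical Laplace transform of the samples.
#' At \eqn{r = 0} the analytic limit (the sample mean) is returned.
#'
#' @param ens an \code{fpt_ensemble} of complete (uncensored) FPTs obtained
#'   without resetting.
#' @param r resetting rate(s) in ns^-1.
#' @return predicted MFPT(s) in ns.
#' @export
mfpt_under_resetting <- function(ens, r) {
  if (any(r < 0)) stop("r must be non-negative")
  if (any(ens$censored))
    stop("the resetting predictor requires complete FPTs; ",
         "use the kinetics-inference layer for censored data")
  m0 <- mean(.uncensored(ens))
  vapply(r, function(ri) {
    if (ri == 0) return(m0)
    f <- laplace_transform(ens, ri)
    if (f < .Machine$double.xmin)
      stop("Laplace transform underflows at r = ", ri,
           " ns^-1; use a smaller rate")
    (1 - f) / (ri * f)
  }, numeric(1))
}

#' Speedup of one ensemble over another
#'
#' The ratio of mean first-passage timesteps, reference over test (e.g.
#' unbiased over biased), with a delta-method standard error.
#'
#' @param reference,test \code{fpt_ensemble}s sharing the same timestep.
#' @return list with \code{speedup} and \code{sem}.
#' @export
speedup <- function(reference, test) {
  a <- fpt_summary(reference); b <- fpt_summary(test)
  if (b$mfpt == 0) stop("test ensemble has zero mean; speedup undefined")
  s <- a$mfpt / b$mfpt
  sem <- s * sqrt((a$sem / a$mfpt)^2 + (b$sem / b$mfpt)^2)
  list(speedup = s, sem = sem)
}

#' Predicted speedup curve over a resetting-rate grid
#'
#' Evaluates the resetting predictor on a rate grid and reports the
#' speedup \eqn{\langle\tau\rangle_0 / \langle\tau\rangle_r} relative to
#' the same ensemble without resetting, the optimal rate (grid argmax,
#' ties broken toward the smallest rate, optionally refined by
#' golden-section search), and the sign of the initial slope, which equals
#' the sign of COV - 1.
#'
#' @param ens an \code{fpt_ensemble} without resetting.
#' @param rates sorted non-negative rate grid (ns^-1).
#' @param refine if \code{TRUE}, refine the argmax by golden-section search
#'   between its grid neighbours (1\% relative tolerance in rate).
#' @return list of class \code{"speedup_curve"}: \code{rates},
#'   \code{mfpt_r}, \code{speedup}, \code{r_star}, \code{max_speedup},
#'   \code{initial_slope_sign}, \code{cov}.
#' @export
speedup_curve <- function(ens, rates, refine = TRUE) {
  if (length(rates) == 0) stop("empty rate grid")
  if (is.unsorted(rates) || any(rates < 0))
    stop("rates must be sorted and non-negative")
  m0 <- mean(.uncensored(ens))
  mr <- mfpt_under_resetting(ens, rates)
  sp <- m0 / mr
  i_star <- which(sp >= max(sp))[1]
  r_star <- rates[i_star]
  s_star <- sp[i_star]
  if (refine && r_star > 0 && length(rates) >= 3) {
    lo <- if (i_star > 1) rates[i_star - 1] else rates[i_star] / 2
    hi <- if (i_star < length(rates)) rates[i_star + 1] else 2 * rates[i_star]
    opt <- stats::optimize(function(r) m0 / mfpt_under_resetting(ens, r),
                           c(lo, hi), maximum = TRUE, tol = 0.01 * r_star)
    if (opt$objective > s_star) {
      r_star <- opt$maximum; s_star <- opt$objective
    }
  }
  cov <- fpt_summary(ens)$cov
  structure(list(rates = rates, mfpt_r = mr, speedup = sp,
                 r_star = r_star, max_speedup = s_star,
                 initial_slope_sign = sign(cov - 1), cov = cov),
            class = "speedup_curve")
}

#' @export
print.speedup_curve <- function(x, ...) {
  cat(sprintf(
    "<speedup_curve> %d rates; r* = %.4g ns^-1, max speedup %.4g (COV %.3f)\n",
    length(x$rates), x$r_star, x$max_speedup, x$cov))
  invisible(x)
}

#' Optimal resetting rate from FPT samples
#'
#' Logarithmic grid scan of the resetting predictor followed by
#' golden-section refinement.
#'
#' @param ens an \code{fpt_ensemble} without resetting.
#' @param lower,upper rate bounds in ns^-1.
#' @param points_per_decade grid density.
#' @return list with \code{r_star}, \code{max_speedup}, and the underlying
#'   \code{curve}.
#' @export
optimal_reset_rate <- function(ens, lower = 1e-2, upper = 1e4,
                               points_per_decade = 32) {
  stopifnot(lower > 0, upper > lower)
  n <- ceiling(log10(upper / lower) * points_per_decade) + 1
  grid <- 10^seq(log10(lower), log10(upper), length.out = n)
  cur <- speedup_curve(ens, grid, refine = TRUE)
  list(r_star = cur$r_star, max_speedup = cur$max_speedup, curve = cur)
}

#' Bootstrap standard error of a statistic of an FPT ensemble
#'
#' @param ens an \code{fpt_ensemble}.
#' @param stat function of a numeric vector of uncensored FPTs.
#' @param n_boot number of resamples.
#' @param seed RNG seed for the resampling.
#' @return standard error of \code{stat} across resamples.
#' @export
bootstrap_sem <- function(ens, stat, n_boot = 1000, seed = 1) {
  tau <- .uncensored(ens)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  reps <- vapply(seq_len(n_boot),
                 function(i) stat(sample(tau, replace = TRUE)),
                 numeric(1))
  stats::sd(reps)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Write / read an FPT table
#'
#' Plain tab-separated serialization of an ensemble: columns
#' \code{traj_id}, \code{seed}, \code{fpt_ns}, \code{fpt_steps},
#' \code{n_resets}, \code{censored}.
#'
#' @param ens an \code{fpt_ensemble}.
#' @param path file path.
#' @return \code{write_fpt_table} returns \code{path} invisibly;
#'   \code{read_fpt_table} returns an \code{fpt_ensemble}.
#' @export
write_fpt_table <- function(ens, path) {
  n <- length(ens$tau)
  dt <- ens$metadata$dt %||% 1
  df <- data.frame(
    traj_id = seq_len(n),
    seed = ens$metadata$seed %||% NA,
    fpt_ns = ens$tau,
    fpt_steps = ens$fpt_steps %||% (ens$tau * 1e6 / dt),
    n_resets = ens$n_resets %||% 0,
    censored = as.integer(ens$censored))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fpt_table
#' @export
read_fpt_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  ens <- fpt_ensemble(df$fpt_ns, censored = df$censored > 0,
                      metadata = list(source = path))
  ens$fpt_steps <- df$fpt_steps
  ens$n_resets <- df$n_resets
  ens
}

`%||%` <- function(a, b) if (is.null(a)) b else a
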