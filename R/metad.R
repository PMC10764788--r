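#' Well-tempered metadynamics bias state (reference implementation)
#'
#' An explicit R-level bias object mirroring the compiled engine's grid:
#' accumulated bias energy and its analytic derivative along the CV, a
#' hill log, and the running exposure integral used for bias rescaling.
#' The compiled engine maintains the same state internally; this object
#' exists for direct inspection and for cross-checking the engine's hill
#' log against an independent accumulation.
#'
#' @param config a \code{\link{metad_config}}.
#' @return an environment of class \code{"bias_state"} with fields
#'   \code{grid_cv}, \code{grid_v} (kBT), \code{grid_dv} (kBT/A),
#'   \code{hills} (data frame), \code{exposure_ns}.
#' @export
bias_state <- function(config) {
  stopifnot(inherits(config, "metad_config"))
  e <- new.env(parent = emptyenv())
  e$config <- config
  e$grid_cv <- seq(config$grid_bounds[1], config$grid_bounds[2],
                   by = config$grid_spacing)
  e$grid_v <- numeric(length(e$grid_cv))
  e$grid_dv <- numeric(length(e$grid_cv))
  e$hills <- data.frame(time_fs = numeric(0), center = numeric(0),
                        sigma = numeric(0), height = numeric(0))
  e$exposure_ns <- 0
  class(e) <- "bias_state"
  e
}

.bias_interp <- function(bias, cv, what = "grid_v") {
  gb <- bias$config$grid_bounds
  if (any(cv < gb[1] | cv > gb[2]))
    stop("CV value outside the bias grid [", gb[1], ", ", gb[2], "]")
  stats::approx(bias$grid_cv, get(what, envir = bias), xout = cv)$y
}

#' Deposit one well-tempered hill
#'
#' Adds a Gaussian of width sigma and height
#' \eqn{h \exp(-V_{bias}(s_0) / ((\gamma_B - 1) k_BT))} at the current CV
#' value, updating the grid (energy and analytic derivative) and the hill
#' log. Hills are truncated at 6 sigma, as in the compiled engine.
#'
#' @param bias a \code{bias_state} (modified in place).
#' @param cv_now current CV value (Angstrom).
#' @param time_fs deposition time, for the hill log.
#' @return the deposited height (kBT), invisibly.
#' @export
deposit_hill <- function(bias, cv_now, time_fs = NA_real_) {
  cfg <- bias$config
  h <- cfg$height * exp(-.bias_interp(bias, cv_now) / (cfg$bias_factor - 1))
  d <- bias$grid_cv - cv_now
  sel <- abs(d) <= 6 * cfg$width
  g <- h * exp(-d[sel]^2 / (2 * cfg$width^2))
  bias$grid_v[sel] <- bias$grid_v[sel] + g
  bias$grid_dv[sel] <- bias$grid_dv[sel] - g * d[sel] / cfg$width^2
  bias$hills <- rbind(bias$hills,
                      data.frame(time_fs = time_fs, center = cv_now,
                                 sigma = cfg$width, height = h))
  invisible(h)
}

#' Bias energy at a CV value
#'
#' Linear interpolation of the accumulated bias grid.
#'
#' @param bias a \code{bias_state}.
#' @param cv CV value(s) within the grid bounds.
#' @return bias energy in kBT (non-negative).
#' @export
bias_energy <- function(bias, cv) .bias_interp(bias, cv, "grid_v")

#' Bias force on the particle
#'
#' Chain rule through the linear CV:
#' \eqn{F = -\mathrm{d}V_{bias}/\mathrm{d}s \cdot (\cos\theta, \sin\theta)},
#' with the derivative taken from the analytic sum of logged hill
#' gradients (accumulated on the grid), not from finite differences of
#' the energy grid.
#'
#' @param bias a \code{bias_state}.
#' @param cv a \code{\link{cv_spec}}.
#' @param position numeric length-2 \code{c(x, y)}.
#' @return force components (fx, fy) in kBT/A.
#' @export
bias_force <- function(bias, cv, position) {
  s <- cv_value(cv, position)
  dv <- .bias_interp(bias, s, "grid_dv")
  c(fx = -dv * cos(cv$angle), fy = -dv * sin(cv$angle))
}

#' Accumulate bias exposure for iMetaD rescaling
#'
#' Advances the running integral
#' \eqn{I \mathrel{+}= \mathrm{d}t\, e^{V_{bias}(s)/k_BT}} that converts
#' biased time into rescaled (unbiased-equivalent) time.
#'
#' @param bias a \code{bias_state} (modified in place).
#' @param cv_now current CV value.
#' @param dt_fs timestep in fs.
#' @return updated exposure integral in ns, invisibly.
#' @export
record_exposure <- function(bias, cv_now, dt_fs) {
  bias$exposure_ns <- bias$exposure_ns +
    dt_fs * 1e-6 * exp(.bias_interp(bias, cv_now))
  invisible(bias$exposure_ns)
}

#' Reset a bias state
#'
#' Zeroes the grid, hill log and exposure integral, as done at every
#' resetting event.
#'
#' @param bias a \code{bias_state} (modified in place).
#' @return the bias, invisibly.
#' @export
reset_bias <- function(bias) {
  bias$grid_v[] <- 0
  bias$grid_dv[] <- 0
  bias$hills <- bias$hills[0, ]
  bias$exposure_ns <- 0
  invisible(bias)
}

#' Rebuild a bias state from a hill log
#'
#' Reconstructs the grid by summing the logged (already well-tempered)
#' hill Gaussians; used to cross-check the engine's grid against its own
#' hill log.
#'
#' @param hills data frame or matrix with columns \code{center} and
#'   \code{height} (and optionally \code{time_fs}).
#' @param config a \code{\link{metad_config}} providing sigma and the grid.
#' @return a \code{bias_state}.
#' @export
bias_from_hills <- function(hills, config) {
  b <- bias_state(config)
  hills <- as.data.frame(hills)
  for (i in seq_len(nrow(hills))) {
    d <- b$grid_cv - hills$center[i]
    sel <- abs(d) <= 6 * config$width
    g <- hills$height[i] * exp(-d[sel]^2 / (2 * config$width^2))
    b$grid_v[sel] <- b$grid_v[sel] + g
    b$grid_dv[sel] <- b$grid_dv[sel] - g * d[sel] / config$width^2
  }
  b$hills <- data.frame(time_fs = hills$time_fs %||% NA_real_,
                        center = hills$center, sigma = config$width,
                        height = hills$height)
  b
}

#' Write a hill log in a HILLS-style tab-separated dialect
#'
#' Columns: time (ps), cv center, sigma, height (kBT), bias factor.
#'
#' @param hills hill log (data frame or matrix with \code{time_fs},
#'   \code{center}, \code{height}).
#' @param config a \code{\link{metad_config}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_hills <- function(hills, config, path) {
  hills <- as.data.frame(hills)
  df <- data.frame(time = hills$time_fs * 1e-3,
                   cv = hills$center,
                   sigma = config$width,
                   height = hills$height,
                   biasf = config$bias_factor)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
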