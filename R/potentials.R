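#' Analytic 2D model potentials
#'
#' Constructs one of the analytic model potentials used throughout the
#' package. Energies are expressed in units of \eqn{k_BT} at 300 K and
#' lengths in Angstrom.
#'
#' Two families of barrier-crossing landscapes are available, plus a 1D
#' harmonic test potential used for integrator validation:
#' \describe{
#'   \item{\code{two_wells}}{A soft two-dimensional harmonic trap split into
#'     two metastable states by a Gaussian ridge along \eqn{x = 0}:
#'     \eqn{V(x,y) = A_1 x^2 + A_2 y^2 + B \exp(-C x^2)}. With the default
#'     parameters the barrier is about 5 \eqn{k_BT} at every \eqn{y}.}
#'   \item{\code{faradjian_elber}}{A modified Faradjian--Elber potential,
#'     \eqn{V(x,y) = A_1 (x^6 + y'^6) + A_2 \exp(-x^2/\sigma_1^2)
#'     [1 - B \exp(-y'^2/\sigma_2^2)]} with \eqn{y' = y_{scale}\, y}.
#'     The Gaussian ridge is about 12 \eqn{k_BT} high at large \eqn{|y|}
#'     but has a narrow saddle of only about 3 \eqn{k_BT} near
#'     \eqn{y = 0}.}
#'   \item{\code{harmonic1d_test}}{\eqn{V = k x^2 / 2}, flat in \eqn{y};
#'     used by equipartition and diffusion oracles (\code{k = 0} gives free
#'     diffusion).}
#' }
#'
#' @param family one of \code{"two_wells"}, \code{"faradjian_elber"},
#'   \code{"harmonic1d_test"}.
#' @param overrides named list overriding the default parameters
#'   (\code{A1}, \code{A2}, \code{B}, \code{C} for \code{two_wells};
#'   \code{A1}, \code{A2}, \code{B}, \code{sigma1}, \code{sigma2},
#'   \code{y_scale} for \code{faradjian_elber}; \code{k} for the harmonic
#'   test family).
#' @return an object of class \code{"potential2d"}.
#' @examples
#' pot <- make_potential("two_wells")
#' potential_energy(pot, 0, 0)   # barrier top: 5 kBT
#' @export
make_potential <- function(family = c("two_wells", "faradjian_elber",
                                      "harmonic1d_test"),
                           overrides = list()) {
  family <- match.arg(family)
  defaults <- switch(family,
    two_wells = list(A1 = 1e-3, A2 = 1e-2, B = 5, C = 1.3),
    faradjian_elber = list(A1 = 1.2e-5, A2 = 12, B = 0.75,
                           sigma1 = 1, sigma2 = 0.5, y_scale = 0.1),
    harmonic1d_test = list(k = 1))
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s) for family '", family, "': ",
         paste(unknown, collapse = ", "))
  params <- utils::modifyList(defaults, overrides)
  if (family == "two_wells" && params$C <= 0)
    stop("two_wells requires C > 0")
  if (family == "faradjian_elber" &&
      (params$sigma1 <= 0 || params$sigma2 <= 0))
    stop("faradjian_elber requires sigma1 > 0 and sigma2 > 0")
  if (family == "harmonic1d_test" && params$k < 0)
    stop("harmonic1d_test requires k >= 0")
  structure(list(family = family, params = params),
            class = "potential2d")
}

# integer family code + packed parameter vector for the compiled engine
.pot_code <- function(pot) {
  switch(pot$family, two_wells = 0L, faradjian_elber = 1L,
         harmonic1d_test = 2L)
}

.pot_par <- function(pot) {
  p <- pot$params
  switch(pot$family,
    two_wells = c(p$A1, p$A2, p$B, p$C),
    faradjian_elber = c(p$A1, p$A2, p$B, p$sigma1, p$sigma2, p$y_scale),
    harmonic1d_test = c(p$k))
}

#' Potential energy
#'
#' Closed-form evaluation of a model potential; vectorized over coordinates.
#'
#' @param pot a \code{potential2d}.
#' @param x,y coordinates in Angstrom (recycled to common length).
#' @return energies in \eqn{k_BT}.
#' @export
potential_energy <- function(pot, x, y) {
  stopifnot(inherits(pot, "potential2d"))
  n <- max(length(x), length(y))
  x <- rep_len(as.double(x), n); y <- rep_len(as.double(y), n)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("coordinates must be finite")
  potential_energy_cpp(.pot_code(pot), .pot_par(pot), x, y)
}

#' Force (negative gradient) of a model potential
#'
#' @inheritParams potential_energy
#' @return a two-column matrix (\code{fx}, \code{fy}) in \eqn{k_BT}/Angstrom.
#' @export
potential_force <- function(pot, x, y) {
  stopifnot(inherits(pot, "potential2d"))
  n <- max(length(x), length(y))
  x <- rep_len(as.double(x), n); y <- rep_len(as.double(y), n)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("coordinates must be finite")
  g <- potential_grad_cpp(.pot_code(pot), .pot_par(pot), x, y)
  out <- -g
  colnames(out) <- c("fx", "fy")
  out
}

#' @export
print.potential2d <- function(x, ...) {
  cat("<potential2d> family:", x$family, "\n  parameters:",
      paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Barrier summary of a 1D section
#'
#' Locates the minima and the intervening barrier of the section
#' \eqn{V(x, y = y_0)} by a dense scan followed by golden-section
#' refinement, and reports the barrier height
#' \eqn{V(\mathrm{max}) - V(\mathrm{min})}. If several interior maxima
#' exist, the highest one between the two outermost minima is reported.
#'
#' @param pot a \code{potential2d}.
#' @param y fixed \eqn{y} value of the section (Angstrom).
#' @param xlim scan range in \eqn{x}.
#' @param step scan step (Angstrom).
#' @return list with \code{minima} (x positions), \code{barrier_x},
#'   \code{barrier_height} (\eqn{k_BT}), \code{v_min}, \code{v_max}.
#' @examples
#' barrier_summary(make_potential("two_wells"))$barrier_height  # ~5 kBT
#' @export
barrier_summary <- function(pot, y = 0, xlim = c(-10, 10), step = 1e-3) {
  stopifnot(inherits(pot, "potential2d"), length(xlim) == 2, step > 0)
  xs <- seq(xlim[1], xlim[2], by = step)
  vs <- potential_energy(pot, xs, y)
  n <- length(vs)
  interior <- 2:(n - 1)
  is_min <- vs[interior] < vs[interior - 1] & vs[interior] <= vs[interior + 1]
  minima_idx <- interior[is_min]
  if (length(minima_idx) < 2)
    stop("section has fewer than two minima; no barrier to report")
  lo <- min(minima_idx); hi <- max(minima_idx)
  refine <- function(idx, f, minimize) {
    a <- xs[max(idx - 1, 1)]; b <- xs[min(idx + 1, n)]
    opt <- stats::optimize(f, c(a, b), maximum = !minimize,
                           tol = .Machine$double.eps^0.5)
    if (minimize) c(opt$minimum, opt$objective)
    else c(opt$maximum, opt$objective)
  }
  f <- function(x) potential_energy(pot, x, y)
  min_ref <- vapply(c(lo, hi), refine, numeric(2), f = f, minimize = TRUE)
  between <- lo:hi
  bmax_idx <- between[which.max(vs[between])]
  max_ref <- refine(bmax_idx, f, minimize = FALSE)
  v_min <- min(min_ref[2, ])
  list(minima = min_ref[1, ],
       barrier_x = max_ref[1],
       v_min = v_min,
       v_max = max_ref[2],
       barrier_height = max_ref[2] - v_min)
}
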