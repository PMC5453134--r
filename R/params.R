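#' Parameter blocks of the rule-of-mixtures material model
#'
#' Constructors for the four parameter blocks and the composite parameter set
#' used throughout the package. Stress-valued parameters (\code{mu},
#' \code{A1}, \code{A2}, \code{C}, \code{nu2}) are all expressed in one common
#' pressure unit (MPa or kPa); the energy constant \code{c} is in the same
#' unit (1 J/m^3 = 1 Pa, converted on fixture load).
#'
#' @param mu shear modulus of the matrix (> 0, stress units).
#' @param N number of rigid links per network chain (> 0); the locking
#'   stretch is \eqn{\sqrt N}.
#' @param c additive energy constant (energy-density units, any sign).
#' @return an object of class \code{"isotropic_params"},
#'   \code{"fiber_params"}, \code{"softening_params"},
#'   \code{"pseudoelastic_params"} or \code{"material_params"}.
#' @name parameter-blocks
NULL

#' @rdname parameter-blocks
#' @export
isotropic_params <- function(mu, N, c = 0) {
  check_positive_scalar(mu, "mu")
  check_positive_scalar(N, "N")
  stopifnot(is.numeric(c), length(c) == 1L, is.finite(c))
  structure(list(mu = mu, N = N, c = c), class = "isotropic_params")
}

#' @rdname parameter-blocks
#' @param f equivalent anisotropic volumetric fraction, in \[0, 1\].
#' @param A1,A2 fiber energy constants (stress units, any sign).
#' @export
fiber_params <- function(f = 0, A1 = 0, A2 = 0) {
  stopifnot(is.numeric(f), length(f) == 1L, is.finite(f))
  if (f < 0 || f > 1)
    stop_domain("`f` must lie in [0, 1] (a volumetric fraction)")
  stopifnot(is.finite(A1), is.finite(A2))
  structure(list(f = f, A1 = A1, A2 = A2), class = "fiber_params")
}

#' @rdname parameter-blocks
#' @param b dimensionless softening parameter (>= 0).
#' @param C residual-strain constant (>= 0); enters the stress as
#'   \eqn{\mu C/2} times the residual-strain energy gradient.
#' @param n residual exponent, >= 1 (default 1, the value used in practice).
#' @export
softening_params <- function(b = 0, C = 0, n = 1) {
  stopifnot(is.numeric(b), b >= 0, is.numeric(C), C >= 0)
  if (!is.numeric(n) || n < 1)
    stop_domain("`n` must be >= 1")
  structure(list(b = b, C = C, n = n), class = "softening_params")
}

#' @rdname parameter-blocks
#' @param m1 dimensionless scale of the eta1 softening variable (> 0).
#' @param r1 dimensionless, >= 1; controls the depth of unloading softening.
#' @param r2 dimensionless (> 0); controls the stretch dependence of nu1.
#' @param gamma dimensionless; the residual-stress modulus is
#'   \eqn{\nu_2 = \gamma\mu}.
#' @export
pseudoelastic_params <- function(m1, r1, r2, gamma) {
  check_positive_scalar(m1, "m1")
  check_positive_scalar(r1, "r1")
  check_positive_scalar(r2, "r2")
  stopifnot(is.numeric(gamma), length(gamma) == 1L, is.finite(gamma))
  structure(list(m1 = m1, r1 = r1, r2 = r2, gamma = gamma),
            class = "pseudoelastic_params")
}

#' @rdname parameter-blocks
#' @param iso an \code{isotropic_params} block.
#' @param fib a \code{fiber_params} block.
#' @param soft a \code{softening_params} block, or NULL.
#' @param pe a \code{pseudoelastic_params} block, or NULL.
#' @param unit stress unit string ("MPa" or "kPa"), metadata only.
#' @export
material_params <- function(iso, fib = fiber_params(), soft = NULL, pe = NULL,
                            unit = "MPa") {
  stopifnot(inherits(iso, "isotropic_params"), inherits(fib, "fiber_params"))
  if (!is.null(soft)) stopifnot(inherits(soft, "softening_params"))
  if (!is.null(pe)) stopifnot(inherits(pe, "pseudoelastic_params"))
  structure(list(iso = iso, fib = fib, soft = soft, pe = pe, unit = unit),
            class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat(sprintf("Material parameters [%s]\n", x$unit))
  cat(sprintf("  matrix: mu = %g, N = %g, c = %g\n",
              x$iso$mu, x$iso$N, x$iso$c))
  cat(sprintf("  fiber:  f = %g, A1 = %g, A2 = %g\n",
              x$fib$f, x$fib$A1, x$fib$A2))
  if (!is.null(x$soft))
    cat(sprintf("  softening: b = %g, C = %g, n = %g\n",
                x$soft$b, x$soft$C, x$soft$n))
  if (!is.null(x$pe))
    cat(sprintf("  pseudo-elastic: m1 = %g, r1 = %g, r2 = %g, gamma = %g\n",
                x$pe$m1, x$pe$r1, x$pe$r2, x$pe$gamma))
  invisible(x)
}
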