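#' Non-monotonous stress-softening factor
#'
#' The exponential Mullins kernel applied to the stress once the material is
#' strained below its historical maximum strain intensity \code{M}. Two
#' readings of the kernel are provided:
#' \describe{
#'   \item{\code{"literal"} (default)}{\eqn{\exp[-b (M - m)(m/M)]}}
#'   \item{\code{"sqrt"}}{\eqn{\exp[-b(\sqrt M - \sqrt m)\sqrt{m/M}]}}
#' }
#' Both equal 1 on the primary path (\eqn{m = M}), are positive, and decrease
#' as the state retreats from the historical maximum; every downstream result
#' depends only on this contract, and the kernel is selectable everywhere.
#'
#' @param m current strain intensity(ies), \eqn{\sqrt 3 \le m \le M}.
#' @param M historical maximum strain intensity.
#' @param b dimensionless softening parameter (>= 0).
#' @param kernel \code{"literal"} or \code{"sqrt"}.
#' @return softening factor(s) in (0, 1\].
#' @export
softening_factor <- function(m, M, b, kernel = c("literal", "sqrt")) {
  kernel <- match.arg(kernel)
  if (b < 0) stop_domain("`b` must be nonnegative")
  if (any(m < sqrt(3) - 1e-9))
    stop_domain("strain intensity m cannot fall below sqrt(3)")
  if (any(m > M * (1 + 1e-12)))
    stop_history("m exceeds the historical maximum M: extend the primary path instead")
  m <- pmin(m, M)
  switch(kernel,
         literal = exp(-b * (M - m) * (m / M)),
         sqrt    = exp(-b * (sqrt(M) - sqrt(m)) * sqrt(m / M)))
}

#' Residual-strain energy gradient
#'
#' Gradient of the permanent-set potential
#' \eqn{\sum_a (\lambda_{max,a}^n - \lambda_a^n)^2} with respect to the
#' current stretches:
#' \deqn{f_k = -2 n \lambda_k^{n-1} (\lambda_{max,k}^n - \lambda_k^n)}
#'
#' @param lams current principal stretches (length 3).
#' @param lam_maxes principal stretches at the reversal point (length 3).
#' @param n residual exponent (default 1).
#' @return numeric length-3 gradient.
#' @export
residual_gradient <- function(lams, lam_maxes, n = 1) {
  stopifnot(length(lams) == 3L, length(lam_maxes) == 3L)
  if (any(lams <= 0) || any(lam_maxes <= 0))
    stop_domain("stretches must be positive")
  -2 * n * lams^(n - 1) * (lam_maxes^n - lams^n)
}

#' Deformation history of a uniaxial loading path
#'
#' Captures the reversal point of a uniaxial primary path: the maximum strain
#' intensity \code{M}, the per-axis stretch maxima
#' \eqn{(\lambda_{max}, \lambda_{max}^{-1/2}, \lambda_{max}^{-1/2})}, and the
#' total energy \eqn{W_{max} = W_T(\lambda_{max})} at reversal (needed by the
#' pseudo-elastic law). \code{lambda_max} may be below 1 for compression
#' histories; \code{M} measures intensity regardless of strain sign.
#'
#' @param lambda_max axial stretch at which unloading begins (> 0).
#' @param iso,fib parameter blocks; when supplied, \code{W_max} is evaluated.
#' @return an object of class \code{"deformation_history"}.
#' @export
deformation_history <- function(lambda_max, iso = NULL, fib = NULL) {
  check_positive_scalar(lambda_max, "lambda_max")
  W_max <- if (!is.null(iso))
    w_total_uniaxial(lambda_max, iso, if (is.null(fib)) fiber_params() else fib)
  else NA_real_
  structure(
    list(M = strain_intensity(lambda_max),
         lambda_max = lambda_max,
         lambda_max_axes = c(lambda_max, rep(1 / sqrt(lambda_max), 2)),
         W_max = W_max),
    class = "deformation_history")
}

#' Stress-softened principal stress difference
#'
#' The non-monotonous stress-softened constitutive law: the virgin stress
#' difference plus the residual-strain term, modulated by the softening
#' kernel,
#' \deqn{\tau_j - \tau_k = \left[(T_j - T_k) + \frac{\mu C}{2}
#'   (\lambda_j f_j - \lambda_k f_k)\right]
#'   e^{-b(M - m)(m/M)}}
#' It reduces exactly to the virgin law at the reversal point.
#'
#' @param state a \code{"deformation_state"} with \eqn{m \le M}.
#' @param history a [deformation_history()].
#' @param iso,fib,soft parameter blocks.
#' @param j,k distinct principal directions.
#' @param kernel softening-kernel variant, see [softening_factor()].
#' @param fiber_term see [virgin_stress_diff()].
#' @return softened Cauchy stress difference \eqn{\tau_j - \tau_k}.
#' @export
softened_stress_diff <- function(state, history, iso, fib, soft,
                                 j = 1, k = 2,
                                 kernel = c("literal", "sqrt"),
                                 fiber_term = c("isotropized", "literal")) {
  stopifnot(inherits(history, "deformation_history"),
            inherits(soft, "softening_params"))
  if (state$m > history$M * (1 + 1e-9))
    stop_history("state lies beyond the recorded history: use the virgin law")
  lams <- c(state$lambda1, state$lambda2, state$lambda3)
  fk <- residual_gradient(lams, history$lambda_max_axes, soft$n)
  virgin <- virgin_stress_diff(state, iso, fib, j, k, fiber_term)
  resid <- (iso$mu * soft$C / 2) * (lams[j] * fk[j] - lams[k] * fk[k])
  (virgin + resid) * softening_factor(state$m, history$M, soft$b, kernel)
}

# vectorised uniaxial engineering stress on the softened (unloading/reloading)
# branch; lam may be a vector, history is frozen.
uniaxial_softened_stress <- function(lam, history, iso, fib, soft,
                                     kernel = c("literal", "sqrt"),
                                     fiber_term = c("isotropized", "literal")) {
  kernel <- match.arg(kernel)
  fiber_term <- match.arg(fiber_term)
  if (any(lam <= 0)) stop_domain("stretches must be positive")
  m <- strain_intensity(lam)
  if (any(m > history$M * (1 + 1e-9)))
    stop_history("stretch beyond the recorded history: use the virgin law")
  l1 <- lam; l2 <- 1 / sqrt(lam)
  I1 <- lam^2 + 2 / lam
  coef <- virgin_coefficient(I1, iso, fib, fiber_term)
  n <- soft$n
  f1 <- -2 * n * l1^(n - 1) * (history$lambda_max_axes[1]^n - l1^n)
  f2 <- -2 * n * l2^(n - 1) * (history$lambda_max_axes[2]^n - l2^n)
  tau <- (coef * (l1^2 - l2^2) +
            (iso$mu * soft$C / 2) * (l1 * f1 - l2 * f2)) *
    softening_factor(pmin(m, history$M), history$M, soft$b, kernel)
  tau / lam
}

#' Residual stretch (permanent set) after unloading
#'
#' The stretch at which the softened unloading branch crosses zero stress.
#' Solved by bracketed root finding on \eqn{(\lambda_{lock}^{-}, \lambda_{max}]}
#' to a residual of ~1e-12; returns exactly 1 when \code{C = 0} (ideal Mullins
#' behaviour without permanent set).
#'
#' @param history a [deformation_history()].
#' @param iso,fib,soft parameter blocks.
#' @param kernel,fiber_term model variants.
#' @return residual stretch \eqn{\lambda_{res}} with
#'   \eqn{\sigma(\lambda_{res}) = 0}.
#' @export
residual_stretch <- function(history, iso, fib, soft,
                             kernel = c("literal", "sqrt"),
                             fiber_term = c("isotropized", "literal")) {
  kernel <- match.arg(kernel)
  fiber_term <- match.arg(fiber_term)
  if (soft$C == 0) return(1)
  f <- function(l) uniaxial_softened_stress(l, history, iso, fib, soft,
                                            kernel, fiber_term)
  # lower end of the search: stay clear of compressive chain locking
  lock_lo <- tryCatch(
    stats::uniroot(function(l) l^2 + 2 / l - 3 * iso$N * 0.995,
                   c(1e-3, 1), tol = 1e-12)$root,
    error = function(e) 1e-3)
  lo_bound <- max(1e-3, lock_lo * 1.05)
  # the unloading branch only exists where m <= M; in compression m rises
  # again, so stop the search at the compressive stretch with m = M
  if (history$lambda_max > 1) {
    m_lo <- tryCatch(
      stats::uniroot(function(l) strain_intensity(l) - history$M,
                     c(max(lo_bound, 1e-3), 1), tol = 1e-12)$root,
      error = function(e) lo_bound)
    lo_bound <- max(lo_bound, m_lo * (1 + 1e-9))
  }
  grid <- seq(history$lambda_max, lo_bound, length.out = 400L)
  vals <- f(grid)
  sgn <- which(vals[-1] * vals[-length(vals)] <= 0)
  if (!length(sgn))
    stop_domain("no sign change on the unloading branch: no residual stretch in bracket")
  i <- sgn[1]
  stats::uniroot(f, c(grid[i + 1], grid[i]), tol = 1e-12)$root
}
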