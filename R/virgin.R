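#' Material response function of the amended non-Gaussian network
#'
#' The scalar \eqn{\aleph = 2\,\partial W_{iso}/\partial I_1} multiplying
#' \eqn{B} in the Cauchy stress of the incompressible isotropic network:
#' \deqn{\aleph = \frac{\mu}{3\lambda_r}\left[\beta +
#'   \frac{1}{8\sqrt N}\left(\frac{1}{\lambda_r} -
#'   \frac{1}{\beta(1 - \lambda_r^2 - 2\lambda_r/\beta)}\right)\right]}
#' In the Gaussian limit \eqn{N \to \infty}, \eqn{\beta \to 3\lambda_r} and
#' \eqn{\aleph \to \mu} (neo-Hookean response).
#'
#' @param lambda_r relative chain stretch(es) in (0, 1).
#' @param mu shear modulus.
#' @param N links per chain.
#' @return response function value(s), stress units.
#' @export
response_function <- function(lambda_r, mu, N) {
  check_positive_scalar(mu, "mu")
  check_positive_scalar(N, "N")
  if (any(lambda_r <= 0)) stop_domain("lambda_r must be positive")
  if (any(lambda_r >= 1))
    stop_locking("chain locking: relative chain stretch >= 1 in response function")
  beta <- inverse_langevin(lambda_r)
  denom <- beta - beta * lambda_r^2 - 2 * lambda_r  # beta*(1 - lr^2 - 2 lr/beta)
  mu / (3 * lambda_r) *
    (beta + (1 / (8 * sqrt(N))) * (1 / lambda_r - 1 / denom))
}

# coefficient multiplying (lambda_j^2 - lambda_k^2) in the virgin stress
# difference; fiber_term = "literal" keeps the printed {x_ji^2 - x_ki^2}
# factor, which is identically zero for the eight-chain direction cosines.
virgin_coefficient <- function(I1, iso, fib,
                               fiber_term = c("isotropized", "literal")) {
  fiber_term <- match.arg(fiber_term)
  lr <- relative_chain_stretch(I1, iso$N)
  aleph <- response_function(lr, iso$mu, iso$N)
  base <- (1 - fib$f) * aleph
  if (fiber_term == "isotropized")
    base <- base + (2 * fib$f / 3) * (fib$A1 + (2 * fib$A2 / 3) * (I1 - 3))
  base
}

#' Virgin-material principal Cauchy stress difference
#'
#' Pressure-eliminated stress difference of the never-unloaded material:
#' \deqn{T_j - T_k = \left[(1-f)\,\aleph + \frac{2f}{3}\left(A_1 +
#'   \frac{2A_2}{3}(I_1 - 3)\right)\right](\lambda_j^2 - \lambda_k^2)}
#' The default \code{fiber_term = "isotropized"} uses the derivative of the
#' isotropized fiber energy; \code{"literal"} retains the direction-cosine
#' difference factor, which vanishes identically for the eight-chain
#' orientation set and is provided for audit only.
#'
#' @param state a \code{"deformation_state"}.
#' @param iso,fib parameter blocks.
#' @param j,k distinct principal directions in 1:3.
#' @param fiber_term \code{"isotropized"} (default) or \code{"literal"}.
#' @return Cauchy stress difference \eqn{T_j - T_k}.
#' @export
virgin_stress_diff <- function(state, iso, fib, j = 1, k = 2,
                               fiber_term = c("isotropized", "literal")) {
  stopifnot(inherits(state, "deformation_state"))
  if (!j %in% 1:3 || !k %in% 1:3 || j == k)
    stop_domain("`j` and `k` must be distinct indices in 1:3")
  lams <- c(state$lambda1, state$lambda2, state$lambda3)
  coef <- virgin_coefficient(state$I1, iso, fib, fiber_term)
  coef * (lams[j]^2 - lams[k]^2)
}

#' Uniaxial engineering stress of the virgin material
#'
#' For uniaxial extension/compression with traction-free lateral faces,
#' \eqn{T_2 = T_3 = 0} and the engineering (nominal) stress is
#' \eqn{\sigma = (T_1 - T_2)/\lambda}, which coincides with
#' \eqn{dW_T/d\lambda} along the uniaxial path.
#'
#' @param lam axial stretch(es), > 0; values below 1 are compression and give
#'   negative stress.
#' @param iso,fib parameter blocks.
#' @param fiber_term see [virgin_stress_diff()].
#' @return engineering stress, vectorised over \code{lam}.
#' @export
uniaxial_engineering_stress <- function(lam, iso, fib = fiber_params(),
                                        fiber_term = c("isotropized", "literal")) {
  if (any(!is.finite(lam)) || any(lam <= 0))
    stop_domain("stretches must be positive and finite")
  I1 <- lam^2 + 2 / lam
  coef <- virgin_coefficient(I1, iso, fib, fiber_term)
  coef * (lam^2 - 1 / lam) / lam
}
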