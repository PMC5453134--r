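#' Pseudo-elastic softening variables
#'
#' The scalar variables of the modified Dorfmann-Ogden pseudo-elastic
#' unloading law, all driven by the total energy \eqn{W_T} relative to its
#' value \eqn{W_{max}} at the reversal point:
#' \deqn{\eta_1 = 1 - \frac{1}{r_1}\tanh\frac{W_{max} - W_T}{\mu m_1}, \quad
#'   \eta_2 = \frac{1}{r_1\tanh 1}\tanh\left[(W_T/W_{max})^\alpha\right]}
#' \deqn{\nu_1 = \nu_2\left(1 - \frac{1}{r_2}\tanh[10(\lambda_{max}-1)]\right),
#'   \quad \alpha = \frac{1}{10}\left(3 + \frac{8 W_{max}}{5\mu}\right)}
#' At the reversal point \eqn{\eta_1 = 1} and \eqn{\eta_2 = 1/r_1}, so the
#' unloading branch meets the virgin curve up to a gap proportional to
#' \eqn{1 - 1/r_1} (vanishing as \eqn{r_1 \to 1}).
#'
#' @param W_T current total energy density (must not exceed \code{W_max}).
#' @param W_max energy at the reversal point.
#' @param mu shear modulus.
#' @param m1,r1,r2 pseudo-elastic material parameters.
#' @param alpha exponent from [pe_alpha()].
#' @param lambda_max axial stretch at reversal.
#' @param nu2 residual-stress modulus \eqn{\gamma\mu}.
#' @return the corresponding scalar(s).
#' @name pseudoelastic-variables
NULL

#' @rdname pseudoelastic-variables
#' @export
pe_alpha <- function(W_max, mu) {
  check_positive_scalar(mu, "mu")
  if (any(W_max < 0)) stop_domain("W_max must be nonnegative")
  (3 + 8 * W_max / (5 * mu)) / 10
}

#' @rdname pseudoelastic-variables
#' @export
eta1 <- function(W_T, W_max, mu, m1, r1) {
  if (any(W_T > W_max * (1 + 1e-9) + 1e-12))
    stop_history("W_T exceeds W_max: state beyond recorded history")
  1 - (1 / r1) * tanh(pmax(W_max - W_T, 0) / (mu * m1))
}

#' @rdname pseudoelastic-variables
#' @export
eta2 <- function(W_T, W_max, r1, alpha) {
  if (any(W_max <= 0))
    stop_domain("W_max must be positive for the eta2 softening variable")
  if (any(W_T < 0)) stop_domain("W_T must be nonnegative in eta2")
  if (any(W_T > W_max * (1 + 1e-9) + 1e-12))
    stop_history("W_T exceeds W_max: state beyond recorded history")
  tanh(pmin(W_T / W_max, 1)^alpha) / (r1 * tanh(1))
}

#' @rdname pseudoelastic-variables
#' @export
nu1 <- function(lambda_max, nu2, r2) {
  nu2 * (1 - (1 / r2) * tanh(10 * (lambda_max - 1)))
}

#' Pseudo-elastic principal stress difference on unloading
#'
#' The modified Dorfmann-Ogden unloading law built on the rule-of-mixtures
#' virgin stress:
#' \deqn{\tau_j - \tau_k = \left[(T_j - T_k) + (1 - \eta_2)
#'   (\nu_1\lambda_j^2 - \nu_2\lambda_k^2)\right]\eta_1}
#' with the softening variables of [eta1()], [eta2()], [nu1()] evaluated from
#' the state's energy \eqn{W_T} and the recorded history. The additive energy
#' constant \code{c} enters \eqn{W_T} and \eqn{W_{max}} consistently.
#'
#' @param state a \code{"deformation_state"} on the unloading branch.
#' @param history a [deformation_history()] carrying \code{W_max}.
#' @param iso,fib parameter blocks shared with the virgin law.
#' @param pe a [pseudoelastic_params()] block.
#' @param j,k distinct principal directions.
#' @param fiber_term see [virgin_stress_diff()].
#' @return pseudo-elastic stress difference \eqn{\tau_j - \tau_k}.
#' @export
pseudoelastic_stress_diff <- function(state, history, iso, fib, pe,
                                      j = 1, k = 2,
                                      fiber_term = c("isotropized", "literal")) {
  stopifnot(inherits(history, "deformation_history"),
            inherits(pe, "pseudoelastic_params"))
  if (!is.finite(history$W_max))
    stop_domain("history carries no W_max: build it with parameter blocks")
  W_T <- w_total(state, iso, fib)
  W_T <- min(W_T, history$W_max)   # guard roundoff at the reversal point
  lams <- c(state$lambda1, state$lambda2, state$lambda3)
  nu2 <- pe$gamma * iso$mu
  n1 <- nu1(history$lambda_max, nu2, pe$r2)
  a <- pe_alpha(max(history$W_max, 0), iso$mu)
  e1 <- eta1(W_T, history$W_max, iso$mu, pe$m1, pe$r1)
  e2 <- eta2(max(W_T, 0), history$W_max, pe$r1, a)
  virgin <- virgin_stress_diff(state, iso, fib, j, k, fiber_term)
  (virgin + (1 - e2) * (n1 * lams[j]^2 - nu2 * lams[k]^2)) * e1
}

# vectorised uniaxial engineering stress on the pseudo-elastic unloading branch
uniaxial_pseudoelastic_stress <- function(lam, history, iso, fib, pe,
                                          fiber_term = c("isotropized", "literal")) {
  fiber_term <- match.arg(fiber_term)
  if (any(lam <= 0)) stop_domain("stretches must be positive")
  I1 <- lam^2 + 2 / lam
  coef <- virgin_coefficient(I1, iso, fib, fiber_term)
  l1 <- lam; l2 <- 1 / sqrt(lam)
  W_T <- pmin(w_total_uniaxial(lam, iso, fib), history$W_max)
  nu2 <- pe$gamma * iso$mu
  n1 <- nu1(history$lambda_max, nu2, pe$r2)
  a <- pe_alpha(max(history$W_max, 0), iso$mu)
  e1 <- eta1(W_T, history$W_max, iso$mu, pe$m1, pe$r1)
  e2 <- eta2(pmax(W_T, 0), history$W_max, pe$r1, a)
  tau <- (coef * (l1^2 - l2^2) + (1 - e2) * (n1 * l1^2 - nu2 * l2^2)) * e1
  tau / lam
}
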