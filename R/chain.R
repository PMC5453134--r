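#' Langevin function
#'
#' \eqn{\mathcal{L}(\beta) = \coth\beta - 1/\beta}, the force-extension law of
#' the freely jointed chain. A series expansion is used below a small-argument
#' threshold to avoid catastrophic cancellation.
#'
#' @param beta nonnegative numeric vector.
#' @return values in \[0, 1).
#' @export
langevin <- function(beta) {
  if (any(!is.finite(beta)) || any(beta < 0))
    stop_domain("`beta` must be nonnegative and finite")
  out <- numeric(length(beta))
  small <- beta < 1e-2
  b <- beta[small]
  out[small] <- b / 3 - b^3 / 45 + 2 * b^5 / 945 - b^7 / 4725
  b <- beta[!small]
  out[!small] <- 1 / tanh(b) - 1 / b
  out
}

# derivative dL/dbeta, needed by the Newton iteration
langevin_prime <- function(beta) {
  out <- numeric(length(beta))
  small <- beta < 1e-2
  b <- beta[small]
  out[small] <- 1 / 3 - b^2 / 15 + 2 * b^4 / 189 - b^6 / 675
  b <- beta[!small]
  # 1/sinh^2 underflows harmlessly; avoid overflow of sinh for large beta
  s2 <- ifelse(b > 350, 0, 1 / sinh(b)^2)
  out[!small] <- 1 / b^2 - s2
  out
}

#' Inverse Langevin function
#'
#' Numerical inverse of [langevin()], by a safeguarded Newton iteration seeded
#' with the Pade approximant \eqn{\beta_0 = y(3 - y^2)/(1 - y^2)} and bracketed
#' in \eqn{[0,\; 3/(1-y) + 10]}. The converged numeric root (residual below
#' 1e-13) is the contract, not the approximant.
#'
#' @param y numeric vector in \[0, 1). Values at or above 1 correspond to a
#'   fully extended chain and raise a locking error.
#' @return \eqn{\beta \ge 0} with \code{langevin(beta) == y} to ~1e-13.
#' @export
inverse_langevin <- function(y) {
  if (any(!is.finite(y)) || any(y < 0))
    stop_domain("`y` must be in [0, 1)")
  if (any(y >= 1))
    stop_locking("inverse Langevin undefined at y >= 1: chain fully extended")
  beta <- y * (3 - y^2) / (1 - y^2)   # Pade seed, exact at y = 0
  lo <- rep(0, length(y))
  hi <- 3 / (1 - y) + 10
  for (iter in seq_len(60L)) {
    r <- langevin(beta) - y
    if (all(abs(r) <= 1e-13)) break
    lo[r < 0] <- beta[r < 0]
    hi[r > 0] <- beta[r > 0]
    step <- r / pmax(langevin_prime(beta), 1e-300)
    beta_new <- beta - step
    bad <- beta_new <= lo | beta_new >= hi | !is.finite(beta_new)
    beta_new[bad] <- (lo[bad] + hi[bad]) / 2     # bisection fallback
    beta <- beta_new
  }
  beta[y == 0] <- 0
  beta
}

#' Relative chain stretch of the eight-chain network
#'
#' For a deformation state with first invariant \eqn{I_1}, the chain stretch
#' is \eqn{\lambda_{chain} = \sqrt{I_1/3}} and the relative chain stretch is
#' \eqn{\lambda_r = \lambda_{chain}/\sqrt N = \sqrt{I_1/(3N)}}, which must stay
#' below 1 (the locking stretch \eqn{\lambda_L = \sqrt N}).
#'
#' @param state a \code{"deformation_state"}, or a numeric vector of \eqn{I_1}
#'   values.
#' @param N number of rigid links per chain (> 0).
#' @return relative chain stretch(es) in (0, 1).
#' @export
relative_chain_stretch <- function(state, N) {
  check_positive_scalar(N, "N")
  I1 <- if (inherits(state, "deformation_state")) state$I1 else state
  if (any(I1 < 3 - 1e-9))
    stop_domain("I1 must be >= 3 for an isochoric deformation")
  lr <- sqrt(I1 / (3 * N))
  if (any(lr >= 1)) {
    i <- which.max(lr)
    stop_locking(sprintf(
      "chain locking: relative chain stretch %.6g >= 1 at I1 = %.6g with N = %.6g (locking stretch sqrt(N) = %.6g)",
      lr[i], I1[i], N, sqrt(N)))
  }
  lr
}
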