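#' Deformation state from principal stretches
#'
#' Builds an incompressible (or general) principal-stretch deformation state
#' carrying the invariants of the right Cauchy-Green tensor and the strain
#' intensity \eqn{m = \sqrt{\mathrm{tr}\,B^2} = \sqrt{I_1^2 - 2 I_2}}.
#' All downstream constitutive machinery works in the principal frame, where
#' \eqn{B} is diagonal with entries \eqn{\lambda_i^2}; the tensors themselves
#' are never materialised.
#'
#' @param lambda1,lambda2,lambda3 principal stretches (dimensionless, > 0).
#' @return An object of class \code{"deformation_state"}: a list with fields
#'   \code{lambda1}, \code{lambda2}, \code{lambda3}, \code{I1}, \code{I2},
#'   \code{I3} and \code{m}.
#' @details In the undeformed state \eqn{m = \sqrt 3}; \eqn{m > \sqrt 3} for
#'   every other isochoric deformation. \eqn{I_3 = (\lambda_1\lambda_2\lambda_3)^2}
#'   equals 1 for incompressible states.
#' @seealso [uniaxial_state()]
#' @export
#' @examples
#' state_from_stretches(2, 2^-0.5, 2^-0.5)$m  # sqrt(16.5)
state_from_stretches <- function(lambda1, lambda2, lambda3) {
  check_positive_scalar(lambda1, "lambda1")
  check_positive_scalar(lambda2, "lambda2")
  check_positive_scalar(lambda3, "lambda3")
  l2 <- c(lambda1, lambda2, lambda3)^2
  I1 <- sum(l2)
  I2 <- l2[1] * l2[2] + l2[1] * l2[3] + l2[2] * l2[3]
  I3 <- prod(l2)
  structure(
    list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
         I1 = I1, I2 = I2, I3 = I3,
         m = sqrt(I1^2 - 2 * I2)),
    class = "deformation_state")
}

#' Uniaxial incompressible deformation state
#'
#' The homogeneous uniaxial state \eqn{\lambda_1 = \lambda},
#' \eqn{\lambda_2 = \lambda_3 = \lambda^{-1/2}}, for which the strain
#' intensity reduces to \eqn{m = \sqrt{\lambda^4 + 2\lambda^{-2}}}.
#' Compression (\eqn{\lambda < 1}) is supported.
#'
#' @param lam axial stretch (> 0).
#' @return A \code{"deformation_state"}.
#' @export
uniaxial_state <- function(lam) {
  check_positive_scalar(lam, "lam")
  state_from_stretches(lam, 1 / sqrt(lam), 1 / sqrt(lam))
}

#' Strain intensity of a uniaxial state
#'
#' Vectorised \eqn{m(\lambda) = \sqrt{\lambda^4 + 2\lambda^{-2}}}; equals
#' \eqn{\sqrt 3} at \eqn{\lambda = 1} and grows in both extension and
#' compression.
#'
#' @param lam axial stretch(es), all > 0.
#' @return numeric vector of strain intensities.
#' @export
strain_intensity <- function(lam) {
  if (any(!is.finite(lam)) || any(lam <= 0))
    stop_domain("stretches must be positive and finite")
  sqrt(lam^4 + 2 / lam^2)
}

#' @export
print.deformation_state <- function(x, ...) {
  cat(sprintf("Deformation state: lambda = (%.6g, %.6g, %.6g)\n",
              x$lambda1, x$lambda2, x$lambda3))
  cat(sprintf("  I1 = %.8g, I2 = %.8g, I3 = %.8g, m = %.8g\n",
              x$I1, x$I2, x$I3, x$m))
  invisible(x)
}
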