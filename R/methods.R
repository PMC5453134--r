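#' @export
print.mullins_fit <- function(x, ...) {
  cat(sprintf("Constitutive fit: %s model (%s stress)\n",
              x$model, x$stress_kind))
  cat("Estimates:\n")
  print(signif(x$estimate, 6))
  cat(sprintf("RSS %.6g; RMS loading %.4g, unloading %.4g; %s after %d LM iterations\n",
              x$rss, x$branch_rms[["loading"]], x$branch_rms[["unloading"]],
              if (x$converged) "converged" else "NOT converged", x$niter))
  invisible(x)
}

#' @export
summary.mullins_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mullins_fit")
}

#' @export
print.summary.mullins_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("\nSoftening kernel: %s; fiber term: %s\n", f$kernel, f$fiber_term))
  cat(sprintf("Data: %d samples (%d loading, %d non-loading), unit %s\n",
              nrow(f$data), sum(f$data$phase == "loading"),
              sum(f$data$phase != "loading"),
              attr(f$data, "unit")))
  cat(sprintf("Multi-start: %d starts, seed %d; LM info code %d (%s)\n",
              f$config$n_starts, f$config$seed, f$info, f$message))
  invisible(x)
}

#' @export
coef.mullins_fit <- function(object, ...) object$estimate

#' @export
fitted.mullins_fit <- function(object, ...) object$fitted.values

#' @export
residuals.mullins_fit <- function(object, ...) object$residuals

#' Predict stress along a stretch path
#'
#' Evaluates the fitted constitutive law along a new stretch path (the
#' deformation history is reconstructed from the path itself, as in the
#' simulator) or, by default, along the path of the fitted data.
#'
#' @param object a \code{"mullins_fit"}.
#' @param newdata numeric vector of stretches, or a data frame with a
#'   \code{stretch} column; NULL for the training path.
#' @param ... unused.
#' @return numeric vector of model stresses (same stress kind as the data).
#' @export
predict.mullins_fit <- function(object, newdata = NULL, ...) {
  stretch <- if (is.null(newdata)) object$data$stretch
             else if (is.numeric(newdata)) newdata
             else newdata$stretch
  model_stress_for_curve(stretch, object$params, object$model,
                         kernel = object$kernel,
                         fiber_term = object$fiber_term,
                         stress_kind = object$stress_kind)
}

#' @export
plot.mullins_fit <- function(x, ...) {
  df <- as.data.frame(x$data)
  graphics::plot(df$stretch, df$stress,
                 col = ifelse(df$phase == "loading", "grey30", "steelblue"),
                 pch = 16, cex = 0.6,
                 xlab = "stretch", ylab = sprintf("%s stress [%s]",
                                                 x$stress_kind,
                                                 attr(x$data, "unit")), ...)
  graphics::lines(df$stretch, x$fitted.values, col = "firebrick", lwd = 1.5)
  graphics::legend("topleft", bty = "n",
                   legend = c("data (loading)", "data (unloading)", "fit"),
                   col = c("grey30", "steelblue", "firebrick"),
                   pch = c(16, 16, NA), lty = c(NA, NA, 1))
  invisible(x)
}

#' Simulate replicate noisy curves from a fitted model
#'
#' Draws replicate stress-stretch curves: the fitted model curve along the
#' training path plus Gaussian noise with the residual standard deviation.
#'
#' @param object a \code{"mullins_fit"}.
#' @param nsim number of replicates.
#' @param seed integer seed.
#' @param ... unused.
#' @return a list of \code{"stress_stretch_curve"} objects.
#' @export
simulate.mullins_fit <- function(object, nsim = 1, seed = NULL, ...) {
  sd_hat <- stats::sd(object$residuals)
  base <- as.data.frame(object$data)
  base$stress <- object$fitted.values
  seed <- if (is.null(seed)) 1L else seed
  with_local_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      rep <- base
      rep$stress <- rep$stress + stats::rnorm(nrow(rep), 0, sd_hat)
      new_curve(rep, attr(object$data, "stress_kind"),
                attr(object$data, "unit"))
    })
  })
}
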