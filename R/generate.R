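# run an expression with a locally seeded RNG, restoring global state after
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate synthetic loading-unloading curves with noise
#'
#' Samples the model curve produced by [simulate_cycles()] and adds
#' zero-mean Gaussian noise of a stated standard deviation to the stress.
#' Bitwise reproducible for a fixed seed; the generator leaves the global
#' RNG state untouched.
#'
#' @inheritParams simulate_cycles
#' @param n_points_per_branch samples per program leg.
#' @param noise_sd standard deviation of the additive stress noise, in the
#'   curve's stress unit (0 for an exact model curve). A convenient choice
#'   for recovery studies is a percentage of the peak absolute stress.
#' @param seed integer seed for the noise (ignored when \code{noise_sd = 0}).
#' @return a \code{"stress_stretch_curve"}.
#' @export
generate_cycle_data <- function(params, program, n_points_per_branch = 100L,
                                noise_sd = 0, seed = 1L,
                                model = c("softened", "pseudoelastic", "virgin"),
                                kernel = c("literal", "sqrt"),
                                fiber_term = c("isotropized", "literal"),
                                stress_kind = c("engineering", "cauchy")) {
  if (noise_sd < 0) stop_domain("`noise_sd` must be nonnegative")
  curve <- simulate_cycles(program, params, model = model,
                           n_per_branch = n_points_per_branch,
                           kernel = kernel, fiber_term = fiber_term,
                           stress_kind = stress_kind)
  if (noise_sd > 0) {
    noise <- with_local_seed(seed, stats::rnorm(nrow(curve), 0, noise_sd))
    curve$stress <- curve$stress + noise
  }
  curve
}
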