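# stress-stretch curve container: a plain data.frame with metadata attributes
new_curve <- function(df, stress_kind = "engineering", unit = "MPa") {
  stopifnot(all(c("stretch", "stress") %in% names(df)))
  structure(df, class = c("stress_stretch_curve", "data.frame"),
            stress_kind = stress_kind, unit = unit)
}

#' @export
print.stress_stretch_curve <- function(x, ...) {
  cat(sprintf("Stress-stretch curve: %d samples, %s stress [%s]\n",
              nrow(x), attr(x, "stress_kind"), attr(x, "unit")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Simulate uniaxial loading-unloading cycles
#'
#' Traverses a stretch program (a sequence of target stretches starting at 1)
#' while tracking the deformation history. On the primary path (strain
#' intensity at or beyond its historical maximum) the virgin constitutive law
#' applies and the history is updated continuously; below the maximum the
#' selected inelastic law (stress-softened or pseudo-elastic) applies with
#' frozen history. Reloading retraces the softened branch and rejoins the
#' virgin curve at the previous maximum with no stress discontinuity
#' (idealised Mullins behaviour).
#'
#' @param program numeric vector of target stretches; must start at 1.
#'   Compression targets (< 1) are allowed and also extend the history, since
#'   the strain intensity grows on both sides of \eqn{\lambda = 1}.
#' @param params a [material_params()] set (with a \code{soft} block for
#'   \code{model = "softened"}, a \code{pe} block for
#'   \code{model = "pseudoelastic"}).
#' @param model \code{"softened"}, \code{"pseudoelastic"} or \code{"virgin"}.
#' @param n_per_branch samples per program leg.
#' @param kernel softening-kernel variant, see [softening_factor()].
#' @param fiber_term see [virgin_stress_diff()].
#' @param stress_kind \code{"engineering"} (default) or \code{"cauchy"}
#'   (\eqn{T = \sigma\lambda}).
#' @return a \code{"stress_stretch_curve"} data frame with columns
#'   \code{stretch}, \code{stress}, \code{phase}
#'   (loading/unloading/reloading) and \code{cycle}.
#' @export
#' @examples
#' p <- material_params(isotropic_params(0.95, 1.082),
#'                      fiber_params(0.09, 0, 30),
#'                      softening_params(2.8, 0.98))
#' curve <- simulate_cycles(c(1, 1.2, 1, 1.25), p)
simulate_cycles <- function(program, params,
                            model = c("softened", "pseudoelastic", "virgin"),
                            n_per_branch = 50L,
                            kernel = c("literal", "sqrt"),
                            fiber_term = c("isotropized", "literal"),
                            stress_kind = c("engineering", "cauchy")) {
  model <- match.arg(model)
  kernel <- match.arg(kernel)
  fiber_term <- match.arg(fiber_term)
  stress_kind <- match.arg(stress_kind)
  stopifnot(inherits(params, "material_params"))
  if (length(program) < 2L)
    stop_domain("`program` must contain at least a start (1) and one target stretch")
  if (abs(program[1] - 1) > 1e-12)
    stop_domain("`program` must start at the undeformed stretch 1")
  if (any(program <= 0)) stop_domain("program stretches must be positive")
  if (model == "softened" && is.null(params$soft))
    stop_domain("softened model requires a softening_params block")
  if (model == "pseudoelastic" && is.null(params$pe))
    stop_domain("pseudoelastic model requires a pseudoelastic_params block")

  iso <- params$iso; fib <- params$fib
  # pre-flight locking check over the whole program envelope
  mx <- max(program^2 + 2 / program)
  if (mx >= 3 * iso$N)
    stop_locking(sprintf(
      "program reaches I1 = %.4g >= 3N = %.4g: chain locking for N = %.4g",
      mx, 3 * iso$N, iso$N))

  lams <- numeric(0)
  leg_id <- integer(0)
  for (i in seq_len(length(program) - 1L)) {
    leg <- seq(program[i], program[i + 1], length.out = n_per_branch + 1L)
    if (i > 1L) leg <- leg[-1L]
    lams <- c(lams, leg)
    leg_id <- c(leg_id, rep.int(i, length(leg)))
  }

  m <- strain_intensity(lams)
  M <- sqrt(3); lam_rev <- 1
  stress <- numeric(length(lams))
  phase <- character(length(lams))
  virgin_flag <- logical(length(lams))
  tol <- 1e-12
  for (i in seq_along(lams)) {
    if (m[i] >= M * (1 - tol)) {
      virgin_flag[i] <- TRUE
      if (m[i] > M) { M <- m[i]; lam_rev <- lams[i] }
      stress[i] <- uniaxial_engineering_stress(lams[i], iso, fib, fiber_term)
      phase[i] <- "loading"
    } else {
      hist <- deformation_history(lam_rev, iso, fib)
      stress[i] <- switch(model,
        softened = uniaxial_softened_stress(lams[i], hist, iso, fib,
                                            params$soft, kernel, fiber_term),
        pseudoelastic = uniaxial_pseudoelastic_stress(lams[i], hist, iso, fib,
                                                      params$pe, fiber_term),
        virgin = uniaxial_engineering_stress(lams[i], iso, fib, fiber_term))
      phase[i] <- if (i > 1L && m[i] < m[i - 1L]) "unloading" else "reloading"
    }
  }
  # cycle index: advances when leaving an unloading branch
  cycle <- integer(length(lams))
  cyc <- 1L
  for (i in seq_along(lams)) {
    if (i > 1L && phase[i - 1L] == "unloading" && phase[i] != "unloading")
      cyc <- cyc + 1L
    cycle[i] <- cyc
  }
  if (stress_kind == "cauchy") stress <- stress * lams
  new_curve(data.frame(stretch = lams, stress = stress,
                       phase = phase, cycle = cycle),
            stress_kind = stress_kind, unit = params$unit)
}
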