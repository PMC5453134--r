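#' Fitting configuration
#'
#' Options for the bounded Levenberg-Marquardt calibration in
#' [mullins_fit()].
#'
#' @param lower,upper named numeric vectors overriding the default parameter
#'   bounds (defaults keep \code{mu > 0}, \code{N} above the locking bound
#'   implied by the data, \code{0 <= f <= 1}, \code{b, C >= 0},
#'   \code{1 <= r1 <= 5}).
#' @param fixed character vector of parameter names to hold at their starting
#'   values.
#' @param branch_weights named numeric vector, weights for loading vs
#'   non-loading (unloading/reloading) residuals.
#' @param n_starts number of multi-starts (the first start is the supplied
#'   initial value, the rest are seeded jitters of it); the objective is
#'   multimodal in (N, b), so a handful of starts buys robustness cheaply.
#' @param seed integer seed controlling the start jitter (full determinism:
#'   identical inputs give identical results).
#' @param start_spread relative spread of the multi-start jitter.
#' @param maxiter maximum Levenberg-Marquardt iterations per start.
#' @param ftol,ptol LM convergence tolerances.
#' @return an object of class \code{"fit_config"}.
#' @export
fit_config <- function(lower = NULL, upper = NULL, fixed = character(),
                       branch_weights = c(loading = 1, unloading = 1),
                       n_starts = 8L, seed = 1L, start_spread = 0.2,
                       maxiter = 200L, ftol = 1e-12, ptol = 1e-10) {
  stopifnot(all(c("loading", "unloading") %in% names(branch_weights)),
            all(branch_weights >= 0), n_starts >= 1L)
  structure(list(lower = lower, upper = upper, fixed = fixed,
                 branch_weights = branch_weights, n_starts = as.integer(n_starts),
                 seed = as.integer(seed), start_spread = start_spread,
                 maxiter = as.integer(maxiter), ftol = ftol, ptol = ptol),
            class = "fit_config")
}

#' Free parameters of each constitutive model
#'
#' The softened (Mullins + permanent set) law exposes seven free material
#' parameters; the pseudo-elastic law adds four unloading parameters on top
#' of a given virgin parameter set.
#'
#' @param model \code{"softened"} or \code{"pseudoelastic"}.
#' @return character vector of parameter names in fitting order.
#' @export
free_parameters <- function(model = c("softened", "pseudoelastic")) {
  model <- match.arg(model)
  switch(model,
         softened = c("mu", "N", "A1", "A2", "b", "C", "f"),
         pseudoelastic = c("m1", "r1", "r2", "gamma"))
}

# classify curve rows once: which rows follow the virgin law, and for the
# others, the row index of the reversal point governing their history.
# Depends only on the stretch path, never on parameters.
classify_curve <- function(stretch) {
  m <- strain_intensity(stretch)
  runmax <- cummax(m)
  virgin <- m >= runmax * (1 - 1e-12)
  rev_row <- integer(length(stretch))
  last_v <- NA_integer_
  for (i in seq_along(stretch)) {
    if (virgin[i]) last_v <- i else rev_row[i] <- last_v
  }
  list(virgin = virgin, rev_row = rev_row)
}

# model engineering/cauchy stress evaluated at the rows of an observed curve,
# honouring the history implied by the stretch path
model_stress_for_curve <- function(stretch, params, model, cls = NULL,
                                   kernel = "literal",
                                   fiber_term = "isotropized",
                                   stress_kind = "engineering") {
  if (is.null(cls)) cls <- classify_curve(stretch)
  iso <- params$iso; fib <- params$fib
  out <- numeric(length(stretch))
  if (any(cls$virgin))
    out[cls$virgin] <- uniaxial_engineering_stress(stretch[cls$virgin],
                                                   iso, fib, fiber_term)
  idx <- which(!cls$virgin)
  if (length(idx)) {
    for (rv in unique(cls$rev_row[idx])) {
      rows <- idx[cls$rev_row[idx] == rv]
      hist <- deformation_history(stretch[rv], iso, fib)
      out[rows] <- switch(model,
        softened = uniaxial_softened_stress(stretch[rows], hist, iso, fib,
                                            params$soft, kernel, fiber_term),
        pseudoelastic = uniaxial_pseudoelastic_stress(stretch[rows], hist,
                                                      iso, fib, params$pe,
                                                      fiber_term),
        virgin = uniaxial_engineering_stress(stretch[rows], iso, fib,
                                             fiber_term))
    }
  }
  if (stress_kind == "cauchy") out <- out * stretch
  out
}

# rebuild a material_params set with named free parameters replaced
apply_theta <- function(start, theta) {
  iso <- start$iso; fib <- start$fib; soft <- start$soft; pe <- start$pe
  for (nm in names(theta)) {
    v <- theta[[nm]]
    switch(nm,
           mu = { iso$mu <- v }, N = { iso$N <- v }, c = { iso$c <- v },
           f = { fib$f <- v }, A1 = { fib$A1 <- v }, A2 = { fib$A2 <- v },
           b = { soft$b <- v }, C = { soft$C <- v }, n = { soft$n <- v },
           m1 = { pe$m1 <- v }, r1 = { pe$r1 <- v }, r2 = { pe$r2 <- v },
           gamma = { pe$gamma <- v },
           stop_domain(sprintf("unknown parameter '%s'", nm)))
  }
  material_params(iso, fib, soft = soft, pe = pe, unit = start$unit)
}

extract_theta <- function(start, names) {
  all <- c(mu = start$iso$mu, N = start$iso$N, c = start$iso$c,
           f = start$fib$f, A1 = start$fib$A1, A2 = start$fib$A2,
           b = if (!is.null(start$soft)) start$soft$b else NA,
           C = if (!is.null(start$soft)) start$soft$C else NA,
           m1 = if (!is.null(start$pe)) start$pe$m1 else NA,
           r1 = if (!is.null(start$pe)) start$pe$r1 else NA,
           r2 = if (!is.null(start$pe)) start$pe$r2 else NA,
           gamma = if (!is.null(start$pe)) start$pe$gamma else NA)
  all[names]
}

default_bounds <- function(model, free, stretch) {
  I1max <- max(stretch^2 + 2 / stretch)
  lower <- c(mu = 1e-10, N = I1max / (3 * 0.995^2), A1 = -Inf, A2 = -Inf,
             b = 0, C = 0, f = 0, m1 = 1e-6, r1 = 1 + 1e-8, r2 = 1e-3,
             gamma = 0)
  upper <- c(mu = Inf, N = Inf, A1 = Inf, A2 = Inf, b = Inf, C = Inf, f = 1,
             m1 = Inf, r1 = 5, r2 = Inf, gamma = Inf)
  list(lower = lower[free], upper = upper[free])
}

#' Calibrate a constitutive model to a stress-stretch curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) of the stress-softened or pseudo-elastic model to a
#' loading-unloading uniaxial curve. The loss is the branch-weighted residual
#' sum of squares over all samples; a seeded multi-start around the initial
#' values guards against the multimodality of the objective in \code{(N, b)}.
#' Chain locking is excluded by construction: the lower bound on \code{N} is
#' derived from the maximum stretch in the data so the inverse Langevin never
#' sees a fully extended chain.
#'
#' @param curve a \code{"stress_stretch_curve"} (see [read_curve()],
#'   [generate_cycle_data()]) with at least one loading and one
#'   unloading/reloading sample.
#' @param model \code{"softened"} (free parameters mu, N, A1, A2, b, C, f) or
#'   \code{"pseudoelastic"} (free parameters m1, r1, r2, gamma; the virgin
#'   parameters are taken from \code{start} and held fixed unless listed in
#'   \code{free}).
#' @param start a [material_params()] set providing starting values (and the
#'   fixed parameters).
#' @param config a [fit_config()].
#' @param free optional character vector overriding the default free set.
#' @param kernel,fiber_term model variants, see [softening_factor()] and
#'   [virgin_stress_diff()].
#' @return an object of class \code{"mullins_fit"} with methods
#'   \code{print}, \code{summary}, \code{coef}, \code{predict}, \code{plot},
#'   \code{fitted}, \code{residuals} and \code{simulate}.
#' @export
#' @examples
#' truth <- material_fixture("male_mouse_skin")$params
#' curve <- generate_cycle_data(truth, c(1, 1.2, 1), 25)
#' fit <- mullins_fit(curve, "softened", truth,
#'                    config = fit_config(n_starts = 1))
#' coef(fit)
mullins_fit <- function(curve, model = c("softened", "pseudoelastic"),
                        start, config = fit_config(), free = NULL,
                        kernel = c("literal", "sqrt"),
                        fiber_term = c("isotropized", "literal")) {
  model <- match.arg(model)
  kernel <- match.arg(kernel)
  fiber_term <- match.arg(fiber_term)
  stopifnot(inherits(start, "material_params"), inherits(config, "fit_config"))
  df <- as.data.frame(curve)
  if (!all(c("stretch", "stress") %in% names(df)))
    stop_domain("curve must have `stretch` and `stress` columns")
  if (is.null(df$phase)) df$phase <- infer_phases(df$stretch)
  stress_kind <- attr(curve, "stress_kind")
  if (is.null(stress_kind)) stress_kind <- "engineering"

  cls <- classify_curve(df$stretch)
  if (!any(cls$virgin) || all(cls$virgin))
    stop_domain(sprintf(
      "fitting the %s model requires both a loading and an unloading branch",
      model))
  if (model == "softened" && is.null(start$soft))
    stop_domain("start must carry a softening_params block")
  if (model == "pseudoelastic" && is.null(start$pe))
    stop_domain("start must carry a pseudoelastic_params block")

  free <- if (is.null(free)) free_parameters(model) else free
  free <- setdiff(free, config$fixed)
  if (!length(free)) stop_domain("no free parameters left to fit")
  theta0 <- extract_theta(start, free)
  if (anyNA(theta0)) stop_domain("start values missing for some free parameters")

  bounds <- default_bounds(model, free, df$stretch)
  if (!is.null(config$lower)) bounds$lower[names(config$lower)] <- config$lower
  if (!is.null(config$upper)) bounds$upper[names(config$upper)] <- config$upper
  theta0 <- pmin(pmax(theta0, bounds$lower), bounds$upper)

  w <- ifelse(df$phase == "loading",
              config$branch_weights[["loading"]],
              config$branch_weights[["unloading"]])
  sw <- sqrt(w)
  scale <- max(abs(df$stress), 1e-12)

  resid_fn <- function(theta) {
    names(theta) <- free
    pars <- apply_theta(start, theta)
    pred <- tryCatch(
      model_stress_for_curve(df$stretch, pars, model, cls, kernel,
                             fiber_term, stress_kind),
      mullins_error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred)))
      return(rep(1e6 * scale, nrow(df)))   # reject the trial, do not crash
    sw * (pred - df$stress)
  }

  # seeded multi-start: start 1 is the supplied init, the rest jitter it
  starts <- with_local_seed(config$seed, {
    lapply(seq_len(config$n_starts), function(i) {
      if (i == 1L) return(theta0)
      jit <- exp(stats::rnorm(length(theta0), 0, config$start_spread))
      add <- stats::rnorm(length(theta0), 0, config$start_spread)
      # multiplicative jitter preserves sign and scale; zero values get a
      # small additive kick proportional to the stress scale
      th <- ifelse(theta0 != 0, theta0 * jit, add * scale * 0.01)
      pmin(pmax(th, bounds$lower + 1e-12), bounds$upper)
    })
  })

  best <- NULL; nfev <- 0L
  for (th in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = th, lower = bounds$lower, upper = bounds$upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = config$maxiter, ftol = config$ftol,
                           ptol = config$ptol)),
      error = function(e) NULL)
    if (is.null(res)) next
    nfev <- nfev + res$niter
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) stop_domain("all optimisation starts failed")

  estimate <- stats::setNames(as.numeric(best$par), free)
  params_hat <- apply_theta(start, estimate)
  pred <- model_stress_for_curve(df$stretch, params_hat, model, cls, kernel,
                                 fiber_term, stress_kind)
  resid <- df$stress - pred
  loading <- df$phase == "loading"
  branch_rms <- c(loading = sqrt(mean(resid[loading]^2)),
                  unloading = if (any(!loading)) sqrt(mean(resid[!loading]^2))
                              else NA_real_)
  structure(list(
    model = model, estimate = estimate, params = params_hat, start = start,
    free = free, rss = sum(w * resid^2), branch_rms = branch_rms,
    converged = best$info %in% 1:4, info = best$info,
    message = best$message, niter = nfev,
    data = curve, fitted.values = pred, residuals = resid,
    config = config, kernel = kernel, fiber_term = fiber_term,
    stress_kind = stress_kind, call = match.call()),
    class = "mullins_fit")
}

#' @rdname mullins_fit
#' @param ... passed on to [mullins_fit()].
#' @export
fit_softened <- function(curve, start, config = fit_config(), ...) {
  mullins_fit(curve, "softened", start, config, ...)
}

#' @rdname mullins_fit
#' @export
fit_pseudoelastic <- function(curve, start, config = fit_config(), ...) {
  mullins_fit(curve, "pseudoelastic", start, config, ...)
}
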