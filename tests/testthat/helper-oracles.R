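# Independent oracles used across the suite.

# plain bisection inverse of coth(b) - 1/b, independent of the package's
# Newton iteration
bisect_inverse_langevin <- function(y, tol = 1e-13) {
  vapply(y, function(yy) {
    if (yy == 0) return(0)
    lo <- 1e-14
    hi <- 3 / (1 - yy) + 10
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      val <- 1 / tanh(mid) - 1 / mid - yy
      if (abs(val) < tol) break
      if (val < 0) lo <- mid else hi <- mid
    }
    mid
  }, numeric(1))
}

# central-difference derivative
num_deriv <- function(f, x, h = 1e-6 * pmax(abs(x), 1)) {
  (f(x + h) - f(x - h)) / (2 * h)
}

# total energy along the uniaxial path, composed from the exported pieces
w_total_uni <- function(lam, iso, fib) {
  I1 <- lam^2 + 2 / lam
  (1 - fib$f) * w_iso(I1, iso) + fib$f * w_aniso(I1, 1, fib)
}

# small convenience parameter sets used in several files
mouse_params <- function() {
  material_params(isotropic_params(0.95, 1.082),
                  fiber_params(0.09, 0, 30),
                  softening_params(2.8, 0.98 / 0.95),
                  unit = "MPa")
}

# perturb all scale parameters of a set by a common factor
perturb_params <- function(p, fac) {
  material_params(
    isotropic_params(p$iso$mu * fac, 1 + (p$iso$N - 1) * fac, p$iso$c),
    fiber_params(p$fib$f, p$fib$A1, p$fib$A2 * fac),
    if (!is.null(p$soft))
      softening_params(p$soft$b * fac, p$soft$C * fac, p$soft$n),
    p$pe, p$unit)
}
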