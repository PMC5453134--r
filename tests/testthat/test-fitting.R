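test_that("noiseless self-consistency: truth start gives zero residual", {
  truth <- mouse_params()
  curve <- generate_cycle_data(truth, c(1, 1.2, 1), 25)
  fit <- mullins_fit(curve, "softened", truth,
                     config = fit_config(n_starts = 1))
  expect_lt(fit$rss, 1e-18)
  expect_true(fit$converged)
  expect_equal(coef(fit)[["mu"]], 0.95)
  expect_equal(unname(fitted(fit)), curve$stress, tolerance = 1e-12)
  expect_equal(unname(residuals(fit)), rep(0, nrow(curve)), tolerance = 1e-12)
})

test_that("noiseless recovery from a perturbed start (f held at its known value)", {
  # f is structurally confounded with mu, A1, A2 in the isotropized mixture
  # (only (1-f)mu, f*A1, f*A2 are identifiable), so recovery experiments fix
  # the fiber fraction, as an energy-split measurement would in practice.
  truth <- mouse_params()
  curve <- generate_cycle_data(truth, c(1, 1.25, 1), 50)
  init <- perturb_params(truth, 1.2)
  fit <- mullins_fit(curve, "softened", init,
                     config = fit_config(n_starts = 4, seed = 3, fixed = "f"))
  expect_lt(abs(coef(fit)[["mu"]] / 0.95 - 1), 0.01)
  expect_lt(abs(coef(fit)[["b"]] / 2.8 - 1), 0.05)
  expect_lt(fit$rss, 1e-10)
})

test_that("fits are deterministic given the seed", {
  truth <- mouse_params()
  curve <- generate_cycle_data(truth, c(1, 1.2, 1), 20, 0.05, seed = 5)
  init <- perturb_params(truth, 0.85)
  cfg <- fit_config(n_starts = 3, seed = 17, fixed = c("f", "A1"))
  f1 <- mullins_fit(curve, "softened", init, config = cfg)
  f2 <- mullins_fit(curve, "softened", init, config = cfg)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$rss, f2$rss)
})

test_that("fit is invariant to a uniform stress rescaling", {
  truth <- mouse_params()
  curve <- generate_cycle_data(truth, c(1, 1.2, 1), 30, 0.03, seed = 9)
  init <- perturb_params(truth, 1.1)
  cfg <- fit_config(n_starts = 2, seed = 1, fixed = c("f", "A1"))
  fit1 <- mullins_fit(curve, "softened", init, config = cfg)
  # rescale MPa -> kPa: stress, mu, A1, A2 scale; N, b, C, f do not
  k <- 1000
  curve_k <- curve; curve_k$stress <- curve$stress * k
  init_k <- material_params(
    isotropic_params(init$iso$mu * k, init$iso$N, init$iso$c * k),
    fiber_params(init$fib$f, init$fib$A1 * k, init$fib$A2 * k),
    init$soft, unit = "kPa")
  fit2 <- mullins_fit(curve_k, "softened", init_k, config = cfg)
  expect_equal(coef(fit2)[["mu"]], coef(fit1)[["mu"]] * k, tolerance = 1e-6)
  expect_equal(coef(fit2)[["A2"]], coef(fit1)[["A2"]] * k, tolerance = 1e-4)
  for (nm in c("N", "b", "C"))
    expect_equal(coef(fit2)[[nm]], coef(fit1)[[nm]], tolerance = 1e-6)
})

test_that("pseudo-elastic fitting recovers the unloading parameters", {
  truth <- material_fixture("occipital_tension")$params
  curve <- generate_cycle_data(truth, c(1, 1.3, 1), 50,
                               model = "pseudoelastic")
  fit <- mullins_fit(curve, "pseudoelastic", truth,
                     config = fit_config(n_starts = 1))
  expect_lt(fit$rss, 1e-12)

  # seeded noisy recovery of the residual-stress modulus gamma on a
  # two-cycle suture protocol; the noise level (0.5% of peak stress) is set
  # by a power analysis: the linearized sd of gamma-hat is ~4% there
  pg <- material_fixture("pgc25_suture")$params
  prog <- c(1, 1.25, 1, 1.5, 1)
  exact <- simulate_cycles(prog, pg, n_per_branch = 100,
                           model = "pseudoelastic")
  noisy <- generate_cycle_data(pg, prog, 100,
                               0.005 * max(abs(exact$stress)),
                               seed = 2003, model = "pseudoelastic")
  init <- pg
  init$pe <- pseudoelastic_params(pg$pe$m1 * 1.2, pg$pe$r1,
                                  pg$pe$r2 * 1.2, pg$pe$gamma * 0.8)
  fpe <- mullins_fit(noisy, "pseudoelastic", init,
                     config = fit_config(n_starts = 8, seed = 3))
  expect_lt(abs(coef(fpe)[["gamma"]] / pg$pe$gamma - 1), 0.10)
  # loading-only data cannot constrain an unloading law
  loading <- simulate_cycles(c(1, 1.3), truth, n_per_branch = 30)
  expect_error(mullins_fit(loading, "pseudoelastic", truth),
               class = "mullins_domain_error")
})

test_that("fit object methods behave", {
  truth <- mouse_params()
  curve <- generate_cycle_data(truth, c(1, 1.2, 1), 20, 0.02, seed = 2)
  fit <- mullins_fit(curve, "softened", truth,
                     config = fit_config(n_starts = 1))
  expect_s3_class(fit, "mullins_fit")
  expect_named(coef(fit), free_parameters("softened"))
  expect_output(print(fit), "softened model")
  expect_output(print(summary(fit)), "Multi-start")
  pred <- predict(fit)
  expect_equal(pred, unname(fitted(fit)))
  pred_new <- predict(fit, newdata = c(1, 1.05, 1.1))
  expect_length(pred_new, 3)
  expect_equal(pred_new[1], 0, tolerance = 1e-12)
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]]$stress, sims[[2]]$stress))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
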