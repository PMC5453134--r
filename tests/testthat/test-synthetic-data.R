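test_that("fixture registry transcribes every published constant verbatim", {
  # (mu, N, A1, A2, b, C, f%) per row, with the printed units
  expected <- list(
    vaginal_longitudinal  = c(0.085, 3.25, -6.5, 70, 1.3, 0.7, 0.2),
    vaginal_transverse    = c(0.085, 3.25, -6.5, 3.93, 1.3, 0.7, 0.2),
    male_mouse_skin       = c(0.95, 1.082, 0, 30, 2.8, 0.98, 9.0),
    female_mouse_skin     = c(0.77, 1.18, 0, 20, 2.55, 1.2, 9.0),
    pgc25_suture          = c(100, 2.35, 0, 1300, 0.95, 0.008, 10),
    polypropylene_suture  = c(300, 50.5, -7500, -2100, 0.6, 0.0024, 1.35),
    csm_trachea           = c(5, 1.029, 0, 2500, 1.3, 2.1, 0.8),
    asm_trachea           = c(5, 1.029, 0, 15, 1.3, 2.1, 0.8),
    cam_trachea           = c(10, 1.045, 0, 35000, 1, 3.4, 0.6),
    aam_trachea           = c(10, 1.045, 0, 1.5, 1, 3.4, 0.6),
    frontal_tension       = c(2.6, 1.065, -150, -3000, 2.7, 4.6, 1),
    frontal_compression   = c(2.6, 1.065, -150, -3000, 2.5, 0.6, 1),
    occipital_tension     = c(2.65, 2.5, -350, 650, 2.7, 3.8, 0.93),
    occipital_compression = c(2.65, 2.5, -350, 650, 2.7, 3.8, 0.93))
  expect_length(setdiff(names(expected), fixture_names()), 0)
  for (nm in names(expected)) {
    p <- material_fixture(nm)$printed
    expect_identical(unname(c(p$mu, p$N, p$A1, p$A2, p$b, p$C, p$f_percent)),
                     expected[[nm]], label = nm)
  }
  # stress units as printed: kPa mu for trachea/brain, MPa elsewhere;
  # the trachea table prints its fiber constants in MPa
  expect_identical(material_fixture("csm_trachea")$printed$mu_unit, "kPa")
  expect_identical(material_fixture("csm_trachea")$printed$A_unit, "MPa")
  expect_identical(material_fixture("frontal_tension")$printed$A_unit, "kPa")
  # rubber energy-split set
  r <- material_fixture("rubber")$printed
  expect_identical(c(r$mu, r$N, r$A1, r$A2, r$f_percent, r$c_Jm3),
                   c(0.475, 28.13, 0, 0.0001, 25, -0.1880))
  # caption pseudo-elastic sets
  pe <- material_fixture("vaginal_longitudinal")$pe
  expect_identical(c(pe$m1, pe$r1, pe$r2, pe$gamma), c(1.8, 1.0001, 0.1, 0.3))
  pe <- material_fixture("frontal_tension")$pe
  expect_identical(c(pe$m1, pe$r1, pe$r2, pe$gamma), c(0.095, 1.001, 0.8, 0.1))
  expect_identical(material_fixture("occipital_tension")$pe$r1, 2.5)
})

test_that("unit conversions to the working stress unit are applied on load", {
  fx <- material_fixture("csm_trachea")
  expect_equal(fx$params$fib$A2, 2500 * 1000)       # MPa -> kPa
  expect_equal(fx$params$fib$f, 0.008)              # percent -> fraction
  expect_equal(fx$params$soft$C, 2.1 / 5)           # printed mu*C -> C
  fxm <- material_fixture("male_mouse_skin")
  expect_equal(fxm$params$iso$c, 0.0994e-6)         # J/m^3 -> MPa
  # the ambiguous vaginal fraction is exposed under both readings
  expect_equal(material_fixture("vaginal_longitudinal")$params$fib$f, 0.002)
  expect_equal(material_fixture("vaginal_longitudinal",
                                f_as_fraction = TRUE)$params$fib$f, 0.2)
  expect_message(material_fixture("csm_trachea", verbose = TRUE), "converted")
  err <- tryCatch(material_fixture("nope"), error = identity)
  expect_s3_class(err, "mullins_domain_error")
  expect_match(conditionMessage(err), "male_mouse_skin")
})

test_that("every fixture yields a finite single-valued increasing primary curve", {
  for (nm in fixture_names()) {
    fx <- material_fixture(nm)
    lp <- fx$lambda_protocol
    grid <- if (lp >= 1) seq(1, lp, length.out = 120)
            else seq(lp, 1, length.out = 120)
    sig <- uniaxial_engineering_stress(grid, fx$params$iso, fx$params$fib)
    expect_true(all(is.finite(sig)), label = nm)
    expect_true(all(diff(sig) > 0), label = nm)
  }
  # tracheal protocols stay within the experimentally observed window
  for (nm in c("csm_trachea", "asm_trachea", "cam_trachea", "aam_trachea")) {
    lp <- material_fixture(nm)$lambda_protocol
    expect_true(lp >= 1.048 && lp <= 1.215, label = nm)
  }
})

test_that("synthetic curves are exact at zero noise and seed-reproducible", {
  p <- mouse_params()
  exact <- generate_cycle_data(p, c(1, 1.2, 1), 40, noise_sd = 0)
  model <- simulate_cycles(c(1, 1.2, 1), p, n_per_branch = 40)
  expect_identical(exact$stress, model$stress)

  a <- generate_cycle_data(p, c(1, 1.2, 1), 40, 0.05, seed = 42)
  b <- generate_cycle_data(p, c(1, 1.2, 1), 40, 0.05, seed = 42)
  expect_identical(a$stress, b$stress)
  c2 <- generate_cycle_data(p, c(1, 1.2, 1), 40, 0.05, seed = 43)
  expect_false(identical(a$stress, c2$stress))

  # empirical residual SD close to nominal (2% of peak stress, n = 100/leg)
  exact2 <- simulate_cycles(c(1, 1.25, 1), p, n_per_branch = 100)
  sd_nom <- 0.02 * max(abs(exact2$stress))
  noisy <- generate_cycle_data(p, c(1, 1.25, 1), 100, sd_nom, seed = 8)
  sd_emp <- sd(noisy$stress - exact2$stress)
  expect_lt(abs(sd_emp / sd_nom - 1), 0.3)

  # locking detected before any sampling
  expect_error(generate_cycle_data(p, c(1, 1.4), 10),
               class = "mullins_locking_error")
})
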