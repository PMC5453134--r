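test_that("softening factor honours its kernel contract", {
  M <- strain_intensity(1.6)
  for (kern in c("literal", "sqrt")) {
    expect_equal(softening_factor(M, M, 2.8, kern), 1)
    expect_equal(softening_factor(strain_intensity(1.2), M, 0, kern), 1)
    ms <- strain_intensity(seq(1.55, 1.05, length.out = 30))
    fs <- softening_factor(ms, M, 2.8, kern)
    expect_true(all(fs > 0 & fs <= 1))
    expect_true(all(diff(fs) < 0))    # decreasing as m retreats from M
  }
  # literal kernel against a direct independent evaluation
  m <- strain_intensity(1.2)
  expect_equal(softening_factor(m, M, 2.8, "literal"),
               exp(-2.8 * (M - m) * (m / M)), tolerance = 1e-14)
  expect_error(softening_factor(M * 1.01, M, 1),
               class = "mullins_history_error")
})

test_that("residual-strain gradient matches hand differentiation", {
  expect_equal(residual_gradient(c(2, 2^-0.5, 2^-0.5),
                                 c(2, 2^-0.5, 2^-0.5)), c(0, 0, 0))
  expect_equal(residual_gradient(c(1.5, 1, 1), c(2, 1, 1), n = 1)[1], -1)
  expect_equal(residual_gradient(c(1, 1, 1), c(2, 1, 1), n = 2)[1], -12)
})

test_that("softened law reduces to the virgin law at the reversal point", {
  set.seed(31)
  for (i in 1:8) {
    iso <- isotropic_params(runif(1, 0.1, 2), runif(1, 2, 20))
    fib <- fiber_params(runif(1, 0, 0.3), runif(1, -1, 1), runif(1, 0, 5))
    soft <- softening_params(runif(1, 0, 3), runif(1, 0, 2))
    lmax <- runif(1, 1.2, 0.9 * sqrt(iso$N))
    if (lmax^2 + 2 / lmax >= 3 * iso$N * 0.98) next
    h <- deformation_history(lmax, iso, fib)
    s <- uniaxial_state(lmax)
    expect_equal(softened_stress_diff(s, h, iso, fib, soft),
                 virgin_stress_diff(s, iso, fib), tolerance = 1e-10)
  }
})

test_that("softening orders the unloading branch below the virgin curve", {
  iso <- isotropic_params(0.95, 4); fib <- fiber_params(0.1, 0, 3)
  h <- deformation_history(1.6, iso, fib)
  lam <- seq(1.05, 1.55, length.out = 40)
  virgin <- uniaxial_engineering_stress(lam, iso, fib)
  # b > 0, C = 0: pure Mullins softening
  soft_b <- softening_params(b = 2, C = 0)
  unl <- mullins:::uniaxial_softened_stress(lam, h, iso, fib, soft_b)
  expect_true(all(unl < virgin))
  expect_true(all(unl > 0))
  # C = 0, b = 0 reduces to ideal elasticity
  ideal <- mullins:::uniaxial_softened_stress(lam, h, iso, fib,
                                              softening_params(0, 0))
  expect_equal(ideal, virgin, tolerance = 1e-12)
})

test_that("permanent set: residual stretch exists, is a root, grows with C", {
  iso <- isotropic_params(0.95, 4); fib <- fiber_params(0.1, 0, 3)
  h <- deformation_history(1.6, iso, fib)
  expect_identical(residual_stretch(h, iso, fib, softening_params(2, 0)), 1)
  prev <- 1
  for (C in c(0.1, 0.5, 1.0)) {
    soft <- softening_params(2, C)
    lr <- residual_stretch(h, iso, fib, soft)
    expect_gt(lr, 1)
    expect_lt(lr, 1.6)
    sig <- mullins:::uniaxial_softened_stress(lr, h, iso, fib, soft)
    expect_lt(abs(sig), 1e-9)
    expect_gte(lr, prev)       # non-decreasing in C
    prev <- lr
  }
  # unloading all the way to lambda = 1 leaves a compressive stress when C > 0
  s1 <- mullins:::uniaxial_softened_stress(1, h, iso, fib,
                                           softening_params(2, 0.5))
  expect_lt(s1, 0)
  # fixture-grade parameters: male mouse unloaded from near its protocol max
  fx <- material_fixture("male_mouse_skin")$params
  hm <- deformation_history(1.25, fx$iso, fx$fib)
  lrm <- residual_stretch(hm, fx$iso, fx$fib, fx$soft)
  expect_true(lrm > 1 && lrm < 1.25)
})

test_that("cycle simulator reproduces idealised Mullins behaviour", {
  p <- mouse_params()
  # single loading equals the virgin curve
  single <- simulate_cycles(c(1, 1.2), p, n_per_branch = 40)
  expect_equal(single$stress,
               uniaxial_engineering_stress(single$stretch, p$iso, p$fib),
               tolerance = 1e-12)
  expect_true(all(single$phase == "loading"))

  # reloading retraces the unloading branch when history is unchanged
  cyc <- simulate_cycles(c(1, 1.2, 1, 1.2), p, n_per_branch = 40)
  unl <- cyc[cyc$phase == "unloading", ]
  rel <- cyc[cyc$phase == "reloading", ]
  rel <- rel[order(rel$stretch), ]
  unl <- unl[order(unl$stretch), ]
  shared <- intersect(round(unl$stretch, 12), round(rel$stretch, 12))
  expect_gt(length(shared), 30)
  expect_equal(unl$stress[match(shared, round(unl$stretch, 12))],
               rel$stress[match(shared, round(rel$stretch, 12))],
               tolerance = 1e-10)

  # deeper second cycle: softened below virgin, rejoins beyond old maximum
  cyc2 <- simulate_cycles(c(1, 1.15, 1, 1.25), p, n_per_branch = 60)
  virgin_at <- function(l) uniaxial_engineering_stress(l, p$iso, p$fib)
  rel2 <- cyc2[cyc2$phase == "reloading" & cyc2$stretch > 1.05 &
                 cyc2$stretch < 1.149, ]
  expect_true(all(rel2$stress < virgin_at(rel2$stretch)))
  beyond <- cyc2[cyc2$stretch > 1.151 & cyc2$cycle == 2, ]
  expect_equal(beyond$stress, virgin_at(beyond$stretch), tolerance = 1e-9)
  # no stress discontinuity anywhere along the sampled path
  expect_true(all(abs(diff(cyc2$stress)) <
                    0.2 * diff(range(cyc2$stress))))

  # history monotonicity: running maximum of m never decreases
  m <- strain_intensity(cyc2$stretch)
  expect_true(all(diff(cummax(m)) >= 0))

  expect_error(simulate_cycles(c(1), p), class = "mullins_domain_error")
  expect_error(simulate_cycles(c(1.2, 1), p), class = "mullins_domain_error")
})

test_that("compression excursions extend the history too", {
  fx <- material_fixture("occipital_tension")$params
  cyc <- simulate_cycles(c(1, 0.85, 1, 1.2, 1), fx, n_per_branch = 40)
  expect_true(all(is.finite(cyc$stress)))
  # the compressive leg is primary loading (m grows below lambda = 1)
  first_leg <- cyc[seq_len(41), ]
  expect_true(all(first_leg$phase == "loading"))
  expect_true(all(first_leg$stress <= 0))
})
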