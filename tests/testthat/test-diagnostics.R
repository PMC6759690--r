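test_that("residualized covariates are centred and orthogonal to the other modifiers", {
  sim <- simulate_cohort(2000, scenario_preset("base"), seed = 1)
  spec <- xyz_spec()
  z <- residualize_covariate(sim, spec, "x1")
  expect_lt(abs(mean(z)), 1e-10)
  expect_lt(abs(sum(z * sim$X[, "x2"])), 1e-8)
  expect_lt(abs(sum(z * sim$X[, "x3"])), 1e-8)
  expect_lt(abs(cor(z, sim$X[, "x2"])), 1e-10)
  # a lone modifier is simply centred
  spec1 <- model_spec("y", "a", paste0("x", 1:3), step4 = "x1")
  expect_equal(residualize_covariate(sim, spec1, "x1"),
               sim$X[, "x1"] - mean(sim$X[, "x1"]))
  # an uncorrelated covariate residualizes to (approximately) itself centred
  set.seed(2)
  X <- cbind(x1 = rnorm(5000), x2 = rnorm(5000))
  d <- cohort_data(rnorm(5000), rbinom(5000, 1, 0.5), X)
  z2 <- residualize_covariate(d, xyz_spec(2), "x1")
  expect_equal(z2, X[, "x1"] - mean(X[, "x1"]), tolerance = 0.05)
  expect_error(residualize_covariate(sim, spec, "x9"), "not a step-4")
})

test_that("partial curves recover exact polynomial structure and apply shifts", {
  set.seed(3)
  z <- rnorm(500)
  ite <- 2 - 0.5 * z + 0.25 * z^2
  curve <- partial_effect_curve(ite, z, degree = 2)
  expect_equal(unname(curve$quad_coefs), c(2, -0.5, 0.25), tolerance = 1e-10)
  # grid values reproducible from coefficients + shift
  shifted <- partial_effect_curve(ite, z, degree = 2, vertical_shift = 0.1)
  g <- shifted$grid
  expect_equal(g$fitted,
               2 - 0.5 * g$z + 0.25 * g$z^2 + 0.1, tolerance = 1e-10)
  # value at zero on the relative scale is exp(intercept + shift)
  rel <- partial_effect_curve(ite, z, degree = 2, vertical_shift = -0.015,
                              report_relative = TRUE)
  at0 <- rel$quad_coefs[["intercept"]] + rel$vertical_shift
  expect_equal(exp(at0), exp(2 - 0.015), tolerance = 1e-10)
  expect_gte(nrow(rel$grid), 100)
  expect_error(partial_effect_curve(ite, z, degree = 3), "degree")
  expect_error(partial_effect_curve(ite, z[-1]), "lengths differ")
})

test_that("shift_for_reference pins the curve at zero to a reference effect", {
  set.seed(4)
  z <- rnorm(300)
  ite <- -0.14 + 0.05 * z
  curve <- partial_effect_curve(ite, z, degree = 1, report_relative = TRUE)
  s <- shift_for_reference(curve, 0.855)
  pinned <- partial_effect_curve(ite, z, degree = 1, vertical_shift = s,
                                 report_relative = TRUE)
  expect_equal(exp(pinned$quad_coefs[["intercept"]] + pinned$vertical_shift),
               0.855, tolerance = 1e-10)
})

test_that("degree-1 partial-curve slope equals the multivariate step-4 coefficient", {
  sim <- simulate_cohort(1000, scenario_preset("base"), seed = 5)
  spec <- xyz_spec()
  ite <- estimate_ite(sim, spec)
  multi <- regress_ite(ite, sim, spec)
  for (nm in paste0("x", 1:3)) {
    z <- residualize_covariate(sim, spec, nm)
    curve <- partial_effect_curve(ite, z, degree = 1)
    expect_equal(curve$quad_coefs[["linear"]], multi$estimate[[nm]],
                 tolerance = 1e-8)
  }
})

test_that("the third-covariate curve is flat while x1 has unit slope", {
  sim <- simulate_cohort(5e4, scenario_preset("base"), seed = 6)
  spec <- xyz_spec()
  ite <- estimate_ite(sim, spec)
  c1 <- partial_effect_curve(ite, residualize_covariate(sim, spec, "x1"), degree = 2)
  c3 <- partial_effect_curve(ite, residualize_covariate(sim, spec, "x3"), degree = 2)
  expect_equal(c1$quad_coefs[["linear"]], 1, tolerance = 0.05)
  expect_equal(c3$quad_coefs[["linear"]], 0, tolerance = 0.05)
})

test_that("histogram summaries bin every observation and track the mean", {
  set.seed(7)
  v <- rnorm(1234)
  for (nb in c(5, 13, 40)) {
    h <- ite_histogram(v, n_bins = nb)
    expect_equal(sum(h$counts), 1234)
    expect_equal(length(h$counts), nb)
    expect_equal(h$mean, mean(v))
  }
  hfd <- ite_histogram(v)  # Freedman-Diaconis default
  expect_equal(sum(hfd$counts), 1234)
  # a zero ITE vector has all relative mass at 1
  h1 <- ite_histogram(rep(0, 50), n_bins = 3, scale = "relative")
  expect_equal(h1$mean, 1)
  expect_equal(sum(h1$counts), 50)
  expect_true(all(h1$breaks[1] <= 1 & 1 <= h1$breaks[4]))
})

test_that("increased-heterogeneity scenarios widen the effect distribution", {
  base <- simulate_cohort(1e5, scenario_preset("base"), seed = 8)
  het <- simulate_cohort(1e5, scenario_preset("high_het"), seed = 9)
  expect_gt(var(het$ite_true), var(base$ite_true))
  hb <- ite_histogram(base$ite_true)
  hh <- ite_histogram(het$ite_true)
  expect_gt(diff(range(hh$breaks)), diff(range(hb$breaks)))
})

test_that("share_below reports the fraction of reducing relative effects", {
  ite <- c(-0.2, -0.1, 0.1)
  expect_equal(share_below(ite), 2 / 3)
  expect_equal(share_below(ite, threshold = 0, scale = "absolute"), 2 / 3)
})
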