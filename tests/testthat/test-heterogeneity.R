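test_that("an exactly linear ITE vector is decomposed without error", {
  set.seed(1)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, paste0("x", 1:3)))
  d <- cohort_data(rnorm(100), rbinom(100, 1, 0.5), X)
  ite <- 3 + X[, "x1"] + 0.5 * X[, "x2"]
  fit <- regress_ite(ite, d, xyz_spec())
  expect_equal(unname(fit$estimate), c(3, 1, 0.5, 0), tolerance = 1e-10)
  # constant ITE: intercept only
  fitc <- regress_ite(rep(1.7, 100), d, xyz_spec())
  expect_equal(unname(fitc$estimate), c(1.7, 0, 0, 0), tolerance = 1e-10)
})

test_that("univariate mode fits one single-modifier model per covariate", {
  sim <- simulate_cohort(5e4, scenario_preset("base"), seed = 2)
  spec <- xyz_spec()
  ite <- estimate_ite(sim, spec)
  fit <- regress_ite(ite, sim, spec, mode = "univariate")
  expect_equal(fit$mode, "univariate")
  expect_named(fit$estimate, paste0("x", 1:3))
  # population single-covariate slopes under correlations 0.5:
  # cov(cate, xj)/var(xj) = (1.25, 1.0, 0.75)
  expect_equal(unname(fit$estimate), c(1.25, 1.0, 0.75), tolerance = 0.05)
  expect_false(is.null(fit$univariate_intercepts))
})

test_that("interaction-model point estimates equal the four-step estimates", {
  for (seed in 1:100) {
    d <- random_cohort(n = 60, J = 2, seed = seed)
    spec <- xyz_spec(2)
    f_imp <- regress_ite(estimate_ite(d, spec), d, spec)
    f_int <- fit_interaction_model(d, spec)
    expect_equal(f_imp$estimate, f_int$estimate, tolerance = 1e-8)
  }
})

test_that("the comparator refuses expanded step-1 designs and empty arms", {
  d <- random_cohort(50, 2, seed = 3)
  expect_error(fit_interaction_model(d, xyz_spec(2, expand_quadratics = TRUE)),
               "different specifications")
  d$a <- rep(0L, 50)
  expect_error(fit_interaction_model(d, xyz_spec(2)), "degenerate")
})

test_that("relative effects exponentiate estimates and preserve CI ordering", {
  d <- random_cohort(80, 2, seed = 4)
  spec <- xyz_spec(2, report_relative = TRUE)
  fit <- bootstrap_procedure(d, spec, run_config(n_bootstrap = 50, seed = 5))
  rel <- relative_effects(fit)
  expect_equal(rel$relative$estimate, exp(fit$estimate))
  expect_true(all(rel$relative$ci_low < rel$relative$ci_high))
  # zero coefficient maps to multiplier 1
  expect_equal(unname(exp(0)), 1)
  fit0 <- regress_ite(rep(0, d$n), d, xyz_spec(2, report_relative = TRUE))
  expect_equal(unname(relative_effects(fit0)$relative$estimate), c(1, 1, 1),
               tolerance = 1e-12)
  # refuses when relative reporting was never requested
  plain <- regress_ite(estimate_ite(d, xyz_spec(2)), d, xyz_spec(2))
  expect_error(relative_effects(plain), "not requested")
})

test_that("multiplicative modifiers compose by product", {
  expect_equal(round(compose_relative(0.855, 0.890, 0.949), 3), 0.722)
  expect_equal(compose_relative(c(0.9, 1.1), 2), 0.9 * 1.1 * 2)
})

test_that("omitted-variable bias identity is exact in sample", {
  for (seed in 1:100) {
    d <- random_cohort(n = 50, J = 3, seed = 100 + seed)
    ovb <- omitted_variable_bias(d, xyz_spec(3), "x2")
    expect_equal(ovb$predicted_bias, ovb$realized_bias, tolerance = 1e-10)
    expect_equal(ovb$short, ovb$long + ovb$predicted_bias, tolerance = 1e-10)
  }
  expect_error(omitted_variable_bias(random_cohort(40, 2, seed = 6),
                                     xyz_spec(2), "x9"),
               "not in the step-4")
})

test_that("a null coefficient on the omitted modifier predicts zero bias", {
  set.seed(7)
  X <- matrix(rnorm(450), 150, 3, dimnames = list(NULL, paste0("x", 1:3)))
  d <- cohort_data(rnorm(150), rbinom(150, 1, 0.5), X)
  ite <- 2 + X[, "x1"]  # x2 plays no role
  long <- regress_ite(ite, d, xyz_spec())
  Zr <- cbind(1, X[, c("x1", "x3")])
  gamma <- bf_ols(Zr, X[, "x2"])
  pred <- long$estimate[["x2"]] * gamma
  expect_lt(max(abs(pred)), 1e-10)
})

test_that("step-4 fitted values vary less than the true ITEs", {
  sim <- simulate_cohort(5000, scenario_preset("base"), seed = 8)
  spec <- xyz_spec()
  fit <- regress_ite(estimate_ite(sim, spec), sim, spec)
  expect_lt(var(fit$fitted), var(sim$ite_true))
})
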