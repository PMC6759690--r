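test_that("feature expansion produces the documented column sets", {
  X3 <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, paste0("x", 1:3)))
  ex <- expand_features(X3)
  expect_equal(ncol(ex$X), 9)  # 3 originals + 3 squares + 3 products
  expect_equal(colnames(ex$X),
               c("x1", "x2", "x3", "x1_sq", "x2_sq", "x3_sq",
                 "x1_x_x2", "x1_x_x3", "x2_x_x3"))

  X2 <- X3[, 1:2]
  expect_equal(ncol(expand_features(X2)$X), 5)  # 2 + 2 + 1

  Xb <- X3; Xb[, 2] <- rbinom(10, 1, 0.5)
  exb <- expand_features(Xb)
  expect_equal(ncol(exb$X), 8)  # binary square dropped
  expect_equal(exb$expansion_record$dropped_squares, "x2")

  Xc <- X3; Xc[, 3] <- 1
  expect_error(expand_features(Xc), "constant column.*x3")
})

test_that("noiseless generating equations are recovered to machine precision", {
  scn0 <- scenario(1, c(2, 3, 4), 4, c(3, 3.5, 4), noise_sd0 = 0, noise_sd1 = 0)
  d <- simulate_cohort(200, scn0, seed = 1)
  m <- fit_arm_models(d, xyz_spec())
  expect_equal(unname(m$coef0), c(1, 2, 3, 4), tolerance = 1e-10)
  expect_equal(unname(m$coef1), c(4, 3, 3.5, 4), tolerance = 1e-10)
  expect_lt(m$sigma0, 1e-10)
  ite <- estimate_ite(d, xyz_spec())
  expect_equal(ite$ite_hat, 3 + d$X[, "x1"] + 0.5 * d$X[, "x2"], tolerance = 1e-10)
})

test_that("arm fits equal the brute-force normal-equations solution", {
  for (seed in 1:20) {
    d <- random_cohort(n = sample(15:50, 1), J = 2, seed = seed)
    m <- fit_arm_models(d, xyz_spec(2))
    Z <- cbind(1, d$X)
    expect_equal(unname(m$coef0), bf_ols(Z[d$a == 0L, ], d$y[d$a == 0L]),
                 tolerance = 1e-9)
    expect_equal(unname(m$coef1), bf_ols(Z[d$a == 1L, ], d$y[d$a == 1L]),
                 tolerance = 1e-9)
  }
})

test_that("degenerate splits and collinear designs are refused with clear errors", {
  d <- random_cohort(30, 2, seed = 5)
  d$a <- rep(1L, 30)
  expect_error(fit_arm_models(d, xyz_spec(2)), "degenerate treatment split")
  d2 <- random_cohort(30, 2, seed = 6)
  d2$X <- cbind(d2$X, x3 = d2$X[, "x1"] + d2$X[, "x2"])
  expect_error(fit_arm_models(d2, xyz_spec(3)), "rank deficient.*x3")
})

test_that("predictions match explicit dot products and in-sample fitted values", {
  d <- random_cohort(50, 2, seed = 7)
  m <- fit_arm_models(d, xyz_spec(2))
  pred <- predict_potential_outcomes(m, d$X)
  for (i in c(1, 17, 50)) {
    z <- c(1, d$X[i, ])
    expect_equal(pred$yhat0[i], sum(m$coef0 * z))
    expect_equal(pred$yhat1[i], sum(m$coef1 * z))
  }
  # zero row under the noiseless generating equations
  scn0 <- scenario(1, c(2, 3, 4), 4, c(3, 3.5, 4), noise_sd0 = 0, noise_sd1 = 0)
  d0 <- simulate_cohort(100, scn0, seed = 8)
  m0 <- fit_arm_models(d0, xyz_spec())
  p0 <- predict_potential_outcomes(m0, matrix(0, 1, 3,
                                              dimnames = list(NULL, paste0("x", 1:3))))
  expect_equal(p0$yhat0, 1, tolerance = 1e-10)
  expect_equal(p0$yhat1, 4, tolerance = 1e-10)
  expect_error(predict_potential_outcomes(m, d$X[, 1, drop = FALSE]),
               "missing")
})

test_that("identical arm equations with zero noise imply identically zero ITEs", {
  scn <- scenario(2, c(1, -1), 2, c(1, -1), noise_sd0 = 0, noise_sd1 = 0)
  d <- simulate_cohort(100, scn, seed = 9)
  ite <- estimate_ite(d, xyz_spec(2))
  expect_equal(ite$ite_hat, rep(0, 100), tolerance = 1e-10)
})

test_that("estimated mean ITE tracks the true mean CATE on noisy data", {
  sim <- simulate_cohort(500, scenario_preset("base"), seed = 10)
  ite <- estimate_ite(sim, xyz_spec())
  expect_equal(mean(ite$ite_hat), mean(sim$cate_true), tolerance = 0.2)
})

test_that("shared-residual imputation reproduces prediction-difference ITEs exactly", {
  for (seed in c(3, 14, 27)) {
    d <- random_cohort(60, 2, seed = seed)
    ite <- estimate_ite(d, xyz_spec(2))
    comp <- impute_counterfactuals(d, ite$models, shared_residual = TRUE)
    expect_equal(comp$ite, ite$ite_hat, tolerance = 1e-12)
    # completed table keeps the factual outcome untouched
    expect_equal(ifelse(d$a == 1L, comp$y1, comp$y0), d$y)
  }
})

test_that("dropping the shared residual inflates ITE dispersion on noisy data", {
  d <- simulate_cohort(1000, scenario_preset("base"), seed = 15)
  ite <- estimate_ite(d, xyz_spec())
  bare <- impute_counterfactuals(d, ite$models, shared_residual = FALSE)
  expect_gt(var(bare$ite), var(ite$ite_hat))
  # with zero noise the two coincide
  scn0 <- scenario(1, c(2, 3, 4), 4, c(3, 3.5, 4), noise_sd0 = 0, noise_sd1 = 0)
  d0 <- simulate_cohort(100, scn0, seed = 16)
  ite0 <- estimate_ite(d0, xyz_spec())
  bare0 <- impute_counterfactuals(d0, ite0$models, shared_residual = FALSE)
  expect_equal(bare0$ite, ite0$ite_hat, tolerance = 1e-8)
})

test_that("large-sample step-4 estimates are consistent for the true deltas", {
  sim <- simulate_cohort(1e5, scenario_preset("base"), seed = 17)
  fit <- regress_ite(estimate_ite(sim, xyz_spec()), sim, xyz_spec())
  expect_equal(unname(fit$estimate), c(3, 1, 0.5, 0), tolerance = 0.05)
})
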