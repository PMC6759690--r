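# Brute-force OLS oracle: solve the normal equations directly, independent of
# the QR-based fitting path used by the package.
bf_ols <- function(Z, y) {
  unname(drop(solve(t(Z) %*% Z, t(Z) %*% y)))
}

# Small random cohort with independent-normal covariates, a random (but never
# degenerate) treatment split and a noisy linear outcome.
random_cohort <- function(n = 40, J = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rnorm(n * J), n, J,
              dimnames = list(NULL, paste0("x", seq_len(J))))
  repeat {
    a <- rbinom(n, 1L, 0.4)
    if (sum(a) >= J + 3 && sum(1 - a) >= J + 3) break
  }
  y <- 1 + drop(X %*% seq_len(J)) + a * (2 - drop(X %*% rep(0.5, J))) + rnorm(n)
  cohort_data(y, a, X)
}

xyz_spec <- function(J = 3, ...) {
  model_spec("y", "a", step1 = paste0("x", seq_len(J)), ...)
}

# CSV fixture written on the fly
write_cohort_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}
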