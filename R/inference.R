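# One whole-procedure pass on prebuilt designs, used for bootstrap replicates
# and the Monte-Carlo driver. Z1 and Z4 carry the intercept column. Returns
# the step-4 coefficient vector, or NULL when the replicate is degenerate
# (undersized arm or rank-deficient design) and must be redrawn.
fit_deltas_fast <- function(y, a, Z1, Z4, min_arm) {
  i0 <- a == 0L
  n0 <- sum(i0); n1 <- length(a) - n0
  if (n0 < min_arm || n1 < min_arm) return(NULL)
  f0 <- .lm.fit(Z1[i0, , drop = FALSE], y[i0])
  f1 <- .lm.fit(Z1[!i0, , drop = FALSE], y[!i0])
  if (f0$rank < ncol(Z1) || f1$rank < ncol(Z1)) return(NULL)
  ite <- drop(Z1 %*% (f1$coefficients - f0$coefficients))
  f4 <- .lm.fit(Z4, ite)
  if (f4$rank < ncol(Z4)) return(NULL)
  f4$coefficients
}

# step-4 slope of a single-covariate regression per modifier (univariate mode)
fit_univariate_fast <- function(ite, Z4) {
  k <- ncol(Z4) - 1L
  out <- numeric(k)
  for (j in seq_len(k)) {
    f <- .lm.fit(Z4[, c(1L, j + 1L), drop = FALSE], ite)
    if (f$rank < 2L) return(NULL)
    out[j] <- f$coefficients[2L]
  }
  out
}

#' Bootstrap the entire four-step procedure
#'
#' Resamples individuals (rows) with replacement and reruns all four steps —
#' arm-specific outcome fits, prediction of both potential outcomes, ITE
#' computation and the step-4 modifier regression — on every resample, so the
#' resulting standard errors reflect that the ITEs being regressed are
#' themselves estimated. Replicates that produce a degenerate split
#' (undersized arm) or a rank-deficient design are redrawn and counted;
#' 100 consecutive failures abort with a diagnostic.
#'
#' Confidence intervals are formed either by normal approximation around the
#' full-sample point estimate (default) or from percentile quantiles of the
#' replicate estimates.
#'
#' @param data A [cohort_data()].
#' @param spec A [model_spec()].
#' @param config A [run_config()]; `config$seed`, when non-NULL, makes the
#'   run fully reproducible.
#' @param mode Step-4 mode passed to [regress_ite()].
#' @return The point-estimate `het_fit` with `se`, `ci_low`, `ci_high`
#'   filled in, and a `boot` component of class `bootstrap_result` holding
#'   the B x K replicate matrix, per-coefficient SEs, both CI variants and
#'   the redraw count `n_failed`.
#' @export
bootstrap_procedure <- function(data, spec, config = run_config(),
                                mode = c("multivariate", "univariate")) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "cohort_data"), inherits(config, "run_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  ite <- estimate_ite(data, spec, config$min_arm_size_factor)
  fit <- regress_ite(ite, data, spec, mode)

  ex <- step1_design(data, spec)
  Z1 <- cbind(1, ex$X)
  Z4 <- cbind(1, data$X[, spec$step4, drop = FALSE])
  min_arm <- ncol(Z1) + config$min_arm_size_factor
  B <- config$n_bootstrap
  K <- length(fit$estimate)
  est <- matrix(NA_real_, B, K, dimnames = list(NULL, names(fit$estimate)))
  n <- data$n
  n_failed <- 0L
  for (b in seq_len(B)) {
    consec <- 0L
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      cf <- if (mode == "multivariate") {
        fit_deltas_fast(data$y[idx], data$a[idx],
                        Z1[idx, , drop = FALSE], Z4[idx, , drop = FALSE],
                        min_arm)
      } else {
        i0 <- data$a[idx] == 0L
        if (sum(i0) < min_arm || sum(!i0) < min_arm) NULL else {
          Z1b <- Z1[idx, , drop = FALSE]
          f0 <- .lm.fit(Z1b[i0, , drop = FALSE], data$y[idx][i0])
          f1 <- .lm.fit(Z1b[!i0, , drop = FALSE], data$y[idx][!i0])
          if (f0$rank < ncol(Z1) || f1$rank < ncol(Z1)) NULL else
            fit_univariate_fast(drop(Z1b %*% (f1$coefficients - f0$coefficients)),
                                Z4[idx, , drop = FALSE])
        }
      }
      if (!is.null(cf)) break
      n_failed <- n_failed + 1L
      consec <- consec + 1L
      if (consec >= 100L)
        stop("bootstrap aborted: 100 consecutive degenerate replicates ",
             "(arm sizes or design rank); the sample is too small or too ",
             "unbalanced for B = ", B, " resamples of n = ", n)
    }
    est[b, ] <- cf
  }

  se <- apply(est, 2L, stats::sd)
  z <- stats::qnorm(1 - (1 - config$ci_level) / 2)
  alpha <- (1 - config$ci_level) / 2
  pct <- apply(est, 2L, stats::quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  boot <- structure(list(replicates = est, se = se,
                         ci_normal_low = fit$estimate - z * se,
                         ci_normal_high = fit$estimate + z * se,
                         ci_percentile_low = stats::setNames(pct[1L, ], names(se)),
                         ci_percentile_high = stats::setNames(pct[2L, ], names(se)),
                         n_failed = n_failed, config = config),
                    class = "bootstrap_result")
  fit$se <- se
  if (config$ci_method == "normal") {
    fit$ci_low <- boot$ci_normal_low
    fit$ci_high <- boot$ci_normal_high
  } else {
    fit$ci_low <- boot$ci_percentile_low
    fit$ci_high <- boot$ci_percentile_high
  }
  fit$boot <- boot
  fit
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> B = %d replicates (%d degenerate redraws)\n",
              nrow(x$replicates), x$n_failed))
  print(data.frame(coefficient = names(x$se), se = unname(x$se)), digits = 4)
  invisible(x)
}

#' Does a confidence interval cover the truth?
#'
#' Closed-interval check used by the Monte-Carlo coverage evaluation:
#' covered iff `ci_low <= truth <= ci_high` (endpoints count).
#'
#' @param ci_low,ci_high Interval endpoints (vectors recycle as usual).
#' @param truth True parameter value(s).
#' @return Logical vector.
#' @export
evaluate_coverage <- function(ci_low, ci_high, truth) {
  if (any(ci_low > ci_high)) stop("`ci_low` must not exceed `ci_high`")
  ci_low <= truth & truth <= ci_high
}
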