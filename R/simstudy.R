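#' Monte-Carlo validation study
#'
#' Repeats the full pipeline over many simulated datasets from a
#' [scenario()]: generate a cohort, estimate the step-4 coefficients with the
#' chosen estimator, attach bootstrap (imputation estimator) or analytic OLS
#' (interaction estimator) standard errors, and score each dataset's
#' confidence interval against the scenario's true CATE coefficients. The
#' summary reports, per coefficient, the Monte-Carlo average estimate,
#' average standard error and CI coverage proportion.
#'
#' When a modifier is omitted from step 4 (`omit`), coverage is still scored
#' against the full-model truth, so the omitted-variable bias shows up as
#' shifted averages and degraded coverage rather than being hidden by a
#' redefined target.
#'
#' @param scn A [scenario()].
#' @param n_sims Number of simulated datasets.
#' @param n Rows per dataset.
#' @param config A [run_config()]; `config$seed` drives per-dataset child
#'   seeds so the study is reproducible and datasets are independent.
#' @param estimator `"imputation"` (the four-step procedure, bootstrap
#'   inference) or `"interaction"` (single interacted OLS, analytic
#'   inference).
#' @param omit Optional modifier name excluded from step 4 (and from the
#'   interaction terms of the comparator).
#' @param bootstrap Set `FALSE` to skip inference and record point estimates
#'   only (SE and coverage reported as `NA`).
#' @param quantile_method Treatment-threshold convention, see
#'   [assign_treatment()].
#' @param progress_every Emit a progress message every this many datasets
#'   (0 silences progress).
#' @return An object of class `study_summary`: a per-coefficient table of
#'   truth, average estimate, average SE and coverage, carrying the per-sim
#'   estimate matrix and study metadata as attributes.
#' @export
run_study <- function(scn, n_sims, n, config = run_config(),
                      estimator = c("imputation", "interaction"),
                      omit = NULL, bootstrap = TRUE,
                      quantile_method = c("empirical", "theoretical"),
                      progress_every = 50L) {
  estimator <- match.arg(estimator)
  quantile_method <- match.arg(quantile_method)
  stopifnot(inherits(scn, "scenario"), n_sims >= 1L)
  xnames <- paste0("x", seq_len(scn$n_covariates))
  if (!is.null(omit) && !omit %in% xnames)
    stop("`omit` must be one of: ", paste(xnames, collapse = ", "))
  step4 <- setdiff(xnames, omit)
  spec <- model_spec("y", "a", step1 = xnames, step4 = step4)
  truth_full <- scenario_truth(scn)
  truth <- truth_full[c("(Intercept)", step4)]
  K <- length(truth)

  if (!is.null(config$seed)) set.seed(config$seed)
  sim_seeds <- sample.int(.Machine$integer.max, n_sims)
  boot_config <- config
  boot_config$seed <- NULL  # child RNG streams flow from the per-sim seed

  est <- se <- matrix(NA_real_, n_sims, K, dimnames = list(NULL, names(truth)))
  cov <- matrix(NA, n_sims, K, dimnames = list(NULL, names(truth)))
  z <- stats::qnorm(1 - (1 - config$ci_level) / 2)
  for (i in seq_len(n_sims)) {
    set.seed(sim_seeds[i])
    sim <- tryCatch({
      cohort <- simulate_cohort(n, scn, quantile_method = quantile_method)
      if (estimator == "imputation") {
        if (bootstrap) {
          fit <- bootstrap_procedure(cohort, spec, boot_config)
          list(est = fit$estimate, se = fit$se,
               cov = evaluate_coverage(fit$ci_low, fit$ci_high, truth))
        } else {
          fit <- regress_ite(estimate_ite(cohort, spec), cohort, spec)
          list(est = fit$estimate, se = rep(NA_real_, K), cov = rep(NA, K))
        }
      } else {
        fit <- fit_interaction_model(cohort, spec)
        if (bootstrap) {
          lo <- fit$estimate - z * fit$naive_se
          hi <- fit$estimate + z * fit$naive_se
          list(est = fit$estimate, se = fit$naive_se,
               cov = evaluate_coverage(lo, hi, truth))
        } else {
          list(est = fit$estimate, se = rep(NA_real_, K), cov = rep(NA, K))
        }
      }
    }, error = function(e) stop("dataset ", i, ": ", conditionMessage(e)))
    est[i, ] <- sim$est
    se[i, ] <- sim$se
    cov[i, ] <- sim$cov
    if (progress_every > 0L && i %% progress_every == 0L)
      message("run_study: ", i, "/", n_sims, " datasets done")
  }

  tab <- data.frame(coefficient = names(truth),
                    truth = unname(truth),
                    avg_estimate = unname(colMeans(est)),
                    avg_se = unname(colMeans(se)),
                    coverage = unname(colMeans(cov)),
                    row.names = NULL)
  structure(tab,
            estimates = est, ses = se, covered = cov,
            scenario = scn$name, n_sims = n_sims, n = n,
            n_bootstrap = if (bootstrap) config$n_bootstrap else 0L,
            seed = config$seed, estimator = estimator, omit = omit,
            class = c("study_summary", "data.frame"))
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf("<study_summary> scenario '%s', %s estimator, %d datasets of n = %d, B = %d\n",
              attr(x, "scenario"), attr(x, "estimator"),
              attr(x, "n_sims"), attr(x, "n"), attr(x, "n_bootstrap")))
  if (!is.null(attr(x, "omit"))) cat("  step-4 omitted:", attr(x, "omit"), "\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Compare two study summaries cell by cell
#'
#' @param summary_a,summary_b [run_study()] results over the same scenario
#'   and coefficient set.
#' @param tolerance Maximum absolute difference tolerated per cell.
#' @return A data frame of per-coefficient differences in average estimate,
#'   average SE and coverage with a `pass` flag per row; the largest per-sim
#'   point-estimate difference (when both carry estimate matrices of the
#'   same shape) is attached as attribute `max_estimate_diff`.
#' @export
compare_estimators <- function(summary_a, summary_b, tolerance = 0.05) {
  stopifnot(inherits(summary_a, "study_summary"), inherits(summary_b, "study_summary"))
  if (!identical(summary_a$coefficient, summary_b$coefficient) ||
      nrow(summary_a) != nrow(summary_b))
    stop("summaries have mismatched coefficient sets")
  diff_est <- abs(summary_a$avg_estimate - summary_b$avg_estimate)
  diff_se <- abs(summary_a$avg_se - summary_b$avg_se)
  diff_cov <- abs(summary_a$coverage - summary_b$coverage)
  out <- data.frame(coefficient = summary_a$coefficient,
                    diff_avg_estimate = diff_est,
                    diff_avg_se = diff_se,
                    diff_coverage = diff_cov,
                    pass = pmax(diff_est, diff_se, diff_cov, na.rm = TRUE) <= tolerance)
  ea <- attr(summary_a, "estimates"); eb <- attr(summary_b, "estimates")
  if (!is.null(ea) && !is.null(eb) && identical(dim(ea), dim(eb)))
    attr(out, "max_estimate_diff") <- max(abs(ea - eb))
  out
}
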