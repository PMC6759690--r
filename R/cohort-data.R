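#' Cohort data container
#'
#' Bundles an outcome vector, a binary treatment indicator and a covariate
#' matrix into a validated container used throughout the package. All three
#' components must have the same number of rows; the treatment must be coded
#' exactly 0/1; missing values are not allowed (ingestion via [read_cohort()]
#' drops incomplete rows before construction).
#'
#' @param y Numeric outcome vector (possibly already log-transformed).
#' @param a Treatment indicator; values must be exactly 0 or 1.
#' @param X Numeric covariate matrix (or data frame of numeric columns) with
#'   unique column names.
#' @return An object of class `cohort_data`: a list with elements `y`, `a`,
#'   `X` and `n`.
#' @examples
#' d <- cohort_data(y = rnorm(5), a = c(0, 1, 0, 1, 0),
#'                  X = matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("x1", "x2"))))
#' d$n
#' @export
cohort_data <- function(y, a, X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) stop("`X` must be a numeric matrix")
  if (is.null(colnames(X)) || anyDuplicated(colnames(X)))
    stop("`X` must have unique column names")
  y <- as.numeric(y)
  n <- length(y)
  if (n < 1L) stop("cohort must contain at least one row")
  if (length(a) != n || nrow(X) != n)
    stop("`y`, `a` and `X` must have identical row counts")
  a_num <- suppressWarnings(as.numeric(a))
  if (anyNA(a_num) || !all(a_num %in% c(0, 1)))
    stop("treatment not binary: `a` must contain only 0 and 1")
  if (anyNA(y) || anyNA(X)) stop("missing values are not allowed in cohort data")
  structure(list(y = y, a = as.integer(a_num), X = X, n = n),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("<cohort_data> n = %d, treated = %d, covariates: %s\n",
              x$n, sum(x$a), paste(colnames(x$X), collapse = ", ")))
  invisible(x)
}

#' Analysis specification
#'
#' Names the outcome, the treatment, the covariates used to model the two
#' potential outcomes (step 1) and the effect modifiers the estimated
#' individual treatment effects are regressed on (step 4). The step-4 set may
#' be smaller than the step-1 set. Factor variables must arrive pre-encoded as
#' 0/1 indicators so that the step-4 intercept retains its "reference
#' individual" interpretation.
#'
#' @param outcome,treatment Column names of the outcome and the 0/1 treatment.
#' @param step1 Character vector of covariate names for the arm-specific
#'   outcome models.
#' @param step4 Covariate names for the ITE regression; defaults to `step1`.
#' @param expand_quadratics,expand_pairwise Add squared terms / pairwise
#'   products of the step-1 covariates to the outcome models (squares of 0/1
#'   indicator columns are dropped as duplicates). Off by default; the
#'   diagnostics workflow that screens for non-linear effect modification
#'   turns them on.
#' @param center_continuous Centre continuous (non 0/1) covariates after
#'   ingestion so the step-4 intercept describes an individual with average
#'   continuous covariates and zeros on all indicators.
#' @param report_relative Report step-4 estimates also on the exponentiated
#'   (multiplicative) scale; meaningful when the outcome is log-transformed.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(outcome, treatment, step1, step4 = step1,
                       expand_quadratics = FALSE, expand_pairwise = FALSE,
                       center_continuous = FALSE, report_relative = FALSE) {
  stopifnot(is.character(outcome), length(outcome) == 1L,
            is.character(treatment), length(treatment) == 1L,
            is.character(step1), length(step1) >= 1L,
            is.character(step4), length(step4) >= 1L)
  covs <- union(step1, step4)
  if (outcome %in% covs || treatment %in% covs || outcome == treatment)
    stop("outcome and treatment names must be disjoint from covariate names")
  structure(list(outcome = outcome, treatment = treatment,
                 step1 = step1, step4 = step4,
                 expand_quadratics = isTRUE(expand_quadratics),
                 expand_pairwise = isTRUE(expand_pairwise),
                 center_continuous = isTRUE(center_continuous),
                 report_relative = isTRUE(report_relative)),
            class = "model_spec")
}

# check that the covariates a spec refers to exist in a cohort
check_spec <- function(spec, data) {
  missing <- setdiff(union(spec$step1, spec$step4), colnames(data$X))
  if (length(missing))
    stop("covariates not present in data: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Run configuration for bootstrap inference
#'
#' @param n_bootstrap Number of bootstrap replications of the whole procedure.
#' @param ci_method `"normal"` (point estimate +/- z * bootstrap SE) or
#'   `"percentile"` (empirical quantiles of replicate estimates).
#' @param ci_level Confidence level in (0, 1).
#' @param seed Optional integer seed governing all randomness of a run.
#' @param min_arm_size_factor A fitted arm must contain at least
#'   `ncol(design) + min_arm_size_factor` rows; replicates violating this are
#'   redrawn.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_bootstrap = 1000L, ci_method = c("normal", "percentile"),
                       ci_level = 0.95, seed = NULL, min_arm_size_factor = 2L) {
  ci_method <- match.arg(ci_method)
  n_bootstrap <- as.integer(n_bootstrap)
  if (is.na(n_bootstrap) || n_bootstrap < 1L) stop("`n_bootstrap` must be a positive integer")
  if (!is.numeric(ci_level) || ci_level <= 0 || ci_level >= 1)
    stop("`ci_level` must lie in (0, 1)")
  min_arm_size_factor <- as.integer(min_arm_size_factor)
  if (is.na(min_arm_size_factor) || min_arm_size_factor < 1L)
    stop("`min_arm_size_factor` must be a positive integer")
  structure(list(n_bootstrap = n_bootstrap, ci_method = ci_method,
                 ci_level = ci_level, seed = seed,
                 min_arm_size_factor = min_arm_size_factor),
            class = "run_config")
}

#' Read a cohort from CSV
#'
#' Reads a rectangular CSV (header row, one row per individual), keeps the
#' columns the specification uses, drops rows with missing values in any used
#' column (complete-case policy; the number of dropped rows is reported via a
#' message), optionally centres continuous covariates, and returns a validated
#' [cohort_data()] object.
#'
#' @param path Path to a CSV file.
#' @param spec A [model_spec()].
#' @return A `cohort_data` object. Attributes: `dropped` (number of
#'   incomplete rows removed) and, when centring was requested,
#'   `centering_means`.
#' @export
read_cohort <- function(path, spec) {
  df <- utils::read.csv(path, check.names = FALSE)
  used <- c(spec$outcome, spec$treatment, union(spec$step1, spec$step4))
  missing <- setdiff(used, names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  df <- df[used]
  complete <- stats::complete.cases(df)
  dropped <- sum(!complete)
  if (dropped > 0L) {
    message(dropped, " row(s) with missing values in used columns dropped")
    df <- df[complete, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no complete rows left after filtering")
  a <- df[[spec$treatment]]
  if (!all(suppressWarnings(as.numeric(a)) %in% c(0, 1)))
    stop("treatment not binary: column '", spec$treatment, "' must contain only 0/1")
  covs <- union(spec$step1, spec$step4)
  X <- as.matrix(df[covs])
  if (!is.numeric(X)) stop("covariate columns must be numeric")
  data <- cohort_data(df[[spec$outcome]], a, X)
  attr(data, "dropped") <- dropped
  if (spec$center_continuous) {
    cont <- covs[!vapply(covs, function(nm) all(X[, nm] %in% c(0, 1)), logical(1))]
    if (length(cont)) data <- center_covariates(data, cont)
  }
  data
}

#' Centre selected covariate columns
#'
#' Subtracts the sample mean from each named column so the intercept of the
#' ITE regression can be read as the effect for an individual with average
#' values on these covariates. An affine shift only: variances are untouched.
#' The removed means are stored in the `centering_means` attribute so results
#' can be mapped back to the original scale.
#'
#' @param data A [cohort_data()] object.
#' @param names Covariate column names to centre.
#' @return The cohort with the named columns mean-centred.
#' @export
center_covariates <- function(data, names) {
  stopifnot(inherits(data, "cohort_data"))
  unknown <- setdiff(names, colnames(data$X))
  if (length(unknown))
    stop("unknown covariate(s): ", paste(unknown, collapse = ", "))
  means <- colMeans(data$X[, names, drop = FALSE])
  data$X[, names] <- sweep(data$X[, names, drop = FALSE], 2L, means)
  prev <- attr(data, "centering_means")
  attr(data, "centering_means") <- c(prev, means)
  data
}

#' Write a results table to CSV
#'
#' Serialises a [regress_ite()] fit (or a Monte-Carlo [run_study()] summary)
#' as a CSV with one row per coefficient. Numbers are written with full
#' precision and round-trip losslessly well beyond 12 significant digits.
#'
#' @param fit A `het_fit` or `study_summary` object, or a plain data frame.
#' @param path Output file path.
#' @return The written data frame, invisibly.
#' @export
write_results <- function(fit, path) {
  tab <- if (is.data.frame(fit)) fit else as.data.frame(fit)
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e)
    stop("cannot write results to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(tab)
}
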