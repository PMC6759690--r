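# OLS via QR with an explicit rank check. The method's interpretation relies
# on a known design, so rank deficiency is an error (naming the aliased
# columns), never a silent column drop.
ols_coef <- function(Z, y) {
  qr_ <- qr(Z)
  if (qr_$rank < ncol(Z)) {
    aliased <- colnames(Z)[qr_$pivot[(qr_$rank + 1L):ncol(Z)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(aliased, collapse = ", "))
  }
  stats::setNames(qr.coef(qr_, y), colnames(Z))
}

#' Expand a covariate matrix with quadratic and interaction terms
#'
#' Augments the design used for the arm-specific outcome models so that
#' non-linearities can surface in the estimated treatment effects. Column
#' order is deterministic: the original covariates, then their squares (a
#' square of a 0/1 indicator duplicates the original and is dropped), then
#' all pairwise products in lexicographic index order.
#'
#' @param X Numeric covariate matrix with column names.
#' @param quadratics,pairwise Which expansions to add.
#' @return A list with the expanded matrix `X` and an `expansion_record`
#'   describing exactly which columns were added or dropped, so that
#'   prediction-time designs can be rebuilt identically.
#' @export
expand_features <- function(X, quadratics = TRUE, pairwise = TRUE) {
  if (ncol(X) < 1L) stop("`X` needs at least one column")
  const <- colnames(X)[apply(X, 2L, function(v) max(v) - min(v) == 0)]
  if (length(const))
    stop("constant column(s) cannot be expanded: ", paste(const, collapse = ", "))
  nm <- colnames(X)
  binary <- vapply(seq_len(ncol(X)), function(j) all(X[, j] %in% c(0, 1)), logical(1))
  cols <- list(X)
  rec <- list(base = nm, squares = character(), dropped_squares = character(),
              products = character(),
              quadratics = isTRUE(quadratics), pairwise = isTRUE(pairwise))
  if (quadratics) {
    keep <- which(!binary)
    rec$squares <- paste0(nm[keep], "_sq")
    rec$dropped_squares <- nm[binary]
    if (length(keep)) {
      sq <- X[, keep, drop = FALSE]^2
      colnames(sq) <- rec$squares
      cols <- c(cols, list(sq))
    }
  }
  if (pairwise && ncol(X) >= 2L) {
    idx <- utils::combn(ncol(X), 2L)
    pr <- X[, idx[1L, ], drop = FALSE] * X[, idx[2L, ], drop = FALSE]
    rec$products <- paste0(nm[idx[1L, ]], "_x_", nm[idx[2L, ]])
    colnames(pr) <- rec$products
    cols <- c(cols, list(pr))
  }
  list(X = do.call(cbind, cols), expansion_record = rec)
}

# rebuild an expanded design exactly as recorded at fitting time
apply_expansion <- function(X, rec) {
  missing <- setdiff(rec$base, colnames(X))
  if (length(missing))
    stop("prediction covariates do not match fitted design; missing: ",
         paste(missing, collapse = ", "))
  X <- X[, rec$base, drop = FALSE]
  if (!rec$quadratics && !rec$pairwise) return(X)
  expand_features(X, quadratics = rec$quadratics, pairwise = rec$pairwise)$X
}

step1_design <- function(data, spec) {
  check_spec(spec, data)
  X <- data$X[, spec$step1, drop = FALSE]
  if (spec$expand_quadratics || spec$expand_pairwise) {
    ex <- expand_features(X, quadratics = spec$expand_quadratics,
                          pairwise = spec$expand_pairwise)
  } else {
    ex <- list(X = X, expansion_record = list(base = spec$step1,
                                              squares = character(),
                                              dropped_squares = character(),
                                              products = character(),
                                              quadratics = FALSE, pairwise = FALSE))
  }
  ex
}

#' Fit arm-specific potential-outcome models (step 1)
#'
#' Fits one ordinary-least-squares regression of the outcome on the
#' (optionally expanded) step-1 covariates within each treatment stratum:
#' the untreated rows identify the Y0 equation, the treated rows the Y1
#' equation. Each arm must contain at least `ncol(design) + 2` rows and a
#' full-rank design.
#'
#' @param data A [cohort_data()].
#' @param spec A [model_spec()].
#' @param min_arm_size_factor Minimum rows an arm must exceed the number of
#'   design columns by.
#' @return An object of class `arm_models` with coefficient vectors `coef0`
#'   and `coef1` (intercept first), the expanded `feature_names`, the
#'   `expansion_record`, and per-arm sizes and residual SDs.
#' @export
fit_arm_models <- function(data, spec, min_arm_size_factor = 2L) {
  stopifnot(inherits(data, "cohort_data"), inherits(spec, "model_spec"))
  ex <- step1_design(data, spec)
  Z <- cbind("(Intercept)" = 1, ex$X)
  p <- ncol(Z)
  n0 <- sum(data$a == 0L); n1 <- sum(data$a == 1L)
  if (n0 == 0L || n1 == 0L)
    stop("degenerate treatment split: one arm is empty")
  if (min(n0, n1) < p + min_arm_size_factor)
    stop("degenerate treatment split: an arm has fewer than ",
         p + min_arm_size_factor, " rows for ", p, " design columns")
  i0 <- data$a == 0L
  c0 <- ols_coef(Z[i0, , drop = FALSE], data$y[i0])
  c1 <- ols_coef(Z[!i0, , drop = FALSE], data$y[!i0])
  r0 <- data$y[i0] - drop(Z[i0, , drop = FALSE] %*% c0)
  r1 <- data$y[!i0] - drop(Z[!i0, , drop = FALSE] %*% c1)
  structure(list(coef0 = c0, coef1 = c1,
                 feature_names = colnames(ex$X),
                 expansion_record = ex$expansion_record,
                 n0 = n0, n1 = n1,
                 sigma0 = sqrt(sum(r0^2) / max(n0 - p, 1L)),
                 sigma1 = sqrt(sum(r1^2) / max(n1 - p, 1L))),
            class = "arm_models")
}

#' @export
print.arm_models <- function(x, ...) {
  p <- length(x$coef0)
  cat(sprintf("<arm_models> %d design columns; n0 = %d (%.1f obs/param), n1 = %d (%.1f obs/param)\n",
              p, x$n0, x$n0 / p, x$n1, x$n1 / p))
  cat("  untreated:", paste(signif(x$coef0, 4), collapse = " "), "\n")
  cat("  treated:  ", paste(signif(x$coef1, 4), collapse = " "), "\n")
  invisible(x)
}

#' Predict both potential outcomes for every individual (step 2)
#'
#' Applies each arm's fitted equation to all rows, regardless of the
#' treatment actually received, rebuilding the expanded design exactly as at
#' fitting time.
#'
#' @param models An [fit_arm_models()] result.
#' @param X Covariate matrix containing at least the fitted base columns.
#' @return A list with numeric vectors `yhat0` and `yhat1`.
#' @export
predict_potential_outcomes <- function(models, X) {
  stopifnot(inherits(models, "arm_models"))
  Xe <- apply_expansion(X, models$expansion_record)
  if (!identical(colnames(Xe), models$feature_names))
    stop("prediction design columns do not match fitted feature names")
  Z <- cbind(1, Xe)
  list(yhat0 = drop(Z %*% models$coef0), yhat1 = drop(Z %*% models$coef1))
}

#' Estimate individual treatment effects (steps 1-3)
#'
#' Composes the arm-model fit, the prediction of both potential outcomes and
#' their difference: `ite_hat = yhat1 - yhat0`.
#'
#' @inheritParams fit_arm_models
#' @return An object of class `ite_vector`: `ite_hat`, `yhat0`, `yhat1` and
#'   the underlying `models`.
#' @export
estimate_ite <- function(data, spec, min_arm_size_factor = 2L) {
  models <- fit_arm_models(data, spec, min_arm_size_factor)
  pred <- predict_potential_outcomes(models, data$X)
  structure(list(ite_hat = pred$yhat1 - pred$yhat0,
                 yhat0 = pred$yhat0, yhat1 = pred$yhat1,
                 models = models),
            class = "ite_vector")
}

#' @export
print.ite_vector <- function(x, ...) {
  cat(sprintf("<ite_vector> n = %d, mean = %.4f, sd = %.4f\n",
              length(x$ite_hat), mean(x$ite_hat), stats::sd(x$ite_hat)))
  invisible(x)
}

#' Complete the data by single imputation of counterfactual outcomes
#'
#' Keeps the observed outcome for the arm each individual was actually in and
#' imputes the missing potential outcome from the other arm's fitted
#' equation. With `shared_residual = TRUE` the individual's observed residual
#' is carried over to the counterfactual (residuals assumed not to vary with
#' treatment), in which case the implied ITE equals the prediction-difference
#' ITE of [estimate_ite()] exactly. With `shared_residual = FALSE` the bare
#' prediction is used and the implied ITEs retain the factual noise.
#'
#' @param data A [cohort_data()].
#' @param models An [fit_arm_models()] result.
#' @param shared_residual Carry the observed residual into the counterfactual?
#' @return A data frame with columns `a`, `y0`, `y1` (observed or imputed)
#'   and `ite = y1 - y0`.
#' @export
impute_counterfactuals <- function(data, models, shared_residual = TRUE) {
  stopifnot(inherits(data, "cohort_data"), inherits(models, "arm_models"))
  pred <- predict_potential_outcomes(models, data$X)
  treated <- data$a == 1L
  resid <- data$y - ifelse(treated, pred$yhat1, pred$yhat0)
  corr <- if (shared_residual) resid else 0
  y0 <- ifelse(treated, pred$yhat0 + corr, data$y)
  y1 <- ifelse(treated, data$y, pred$yhat1 + corr)
  data.frame(a = data$a, y0 = y0, y1 = y1, ite = y1 - y0)
}
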