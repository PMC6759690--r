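new_het_fit <- function(estimate, naive_se = NULL, mode = "multivariate",
                        estimator = "imputation", report_relative = FALSE,
                        fitted = NULL, extra = list()) {
  structure(c(list(estimate = estimate, naive_se = naive_se,
                   se = NULL, ci_low = NULL, ci_high = NULL,
                   mode = mode, estimator = estimator,
                   report_relative = report_relative, fitted = fitted),
              extra),
            class = "het_fit")
}

#' Regress estimated treatment effects on modifiers (step 4)
#'
#' The final step of the procedure: an OLS regression of the estimated ITEs
#' on an intercept plus the step-4 modifier covariates. The intercept
#' estimates \eqn{\Delta\alpha}, the expected treatment effect of an
#' individual with zeros on all (centred / indicator) modifiers; the slopes
#' estimate \eqn{\Delta\beta_j}, how the expected effect shifts per unit of
#' each modifier.
#'
#' In `"univariate"` mode each modifier gets its own single-covariate
#' regression of the same ITE vector; the per-model intercepts are kept
#' internally but no common intercept is reported.
#'
#' Standard errors attached here are the naive OLS ones, which ignore that
#' the ITEs are themselves estimates; they are labelled as such and
#' inference should come from [bootstrap_procedure()].
#'
#' @param ite An [estimate_ite()] result (or a bare numeric vector).
#' @param data The [cohort_data()] the ITEs were estimated on.
#' @param spec A [model_spec()]; `spec$step4` names the modifiers.
#' @param mode `"multivariate"` (one joint fit) or `"univariate"`.
#' @return An object of class `het_fit` with fields `estimate` (named vector,
#'   intercept first in multivariate mode), `naive_se`, `mode`, and slots
#'   `se`/`ci_low`/`ci_high` to be filled by the bootstrap.
#' @export
regress_ite <- function(ite, data, spec, mode = c("multivariate", "univariate")) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "cohort_data"), inherits(spec, "model_spec"))
  check_spec(spec, data)
  v <- if (inherits(ite, "ite_vector")) ite$ite_hat else as.numeric(ite)
  if (length(v) != data$n) stop("ITE vector length does not match cohort size")
  X4 <- data$X[, spec$step4, drop = FALSE]
  if (mode == "multivariate") {
    Z <- cbind("(Intercept)" = 1, X4)
    cf <- ols_coef(Z, v)
    fitted <- drop(Z %*% cf)
    res <- v - fitted
    sigma2 <- sum(res^2) / (data$n - ncol(Z))
    se <- sqrt(sigma2 * diag(chol2inv(chol(crossprod(Z)))))
    out <- new_het_fit(cf, stats::setNames(se, names(cf)),
                       mode = mode, report_relative = spec$report_relative,
                       fitted = fitted)
  } else {
    est <- se <- icpt <- stats::setNames(numeric(length(spec$step4)), spec$step4)
    for (nm in spec$step4) {
      Z <- cbind("(Intercept)" = 1, X4[, nm, drop = FALSE])
      cf <- ols_coef(Z, v)
      res <- v - drop(Z %*% cf)
      s2 <- sum(res^2) / (data$n - 2L)
      vce <- s2 * diag(chol2inv(chol(crossprod(Z))))
      est[nm] <- cf[2L]; se[nm] <- sqrt(vce[2L]); icpt[nm] <- cf[1L]
    }
    out <- new_het_fit(est, se, mode = mode,
                       report_relative = spec$report_relative,
                       extra = list(univariate_intercepts = icpt))
  }
  out
}

#' @export
print.het_fit <- function(x, ...) {
  cat(sprintf("<het_fit> %s %s fit\n", x$estimator, x$mode))
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' @export
as.data.frame.het_fit <- function(x, ...) {
  nm <- names(x$estimate)
  tab <- data.frame(coefficient = nm, estimate = unname(x$estimate))
  add <- function(tab, field, col) {
    if (!is.null(x[[field]])) tab[[col]] <- unname(x[[field]])
    tab
  }
  tab <- add(tab, "naive_se", "naive_se")
  tab <- add(tab, "se", "se")
  tab <- add(tab, "ci_low", "ci_low")
  tab <- add(tab, "ci_high", "ci_high")
  if (!is.null(x$relative)) {
    tab$rel_estimate <- unname(x$relative$estimate)
    if (!is.null(x$relative$ci_low)) {
      tab$rel_ci_low <- unname(x$relative$ci_low)
      tab$rel_ci_high <- unname(x$relative$ci_high)
    }
  }
  tab
}

#' Exponentiate step-4 estimates to the multiplicative scale
#'
#' When the outcome is modelled in logarithms, exponentiated step-4
#' coefficients are relative (multiplicative) effects: a modifier coefficient
#' b multiplies the treatment effect ratio by exp(b) per unit. Point
#' estimates and CI endpoints are exponentiated elementwise; monotonicity of
#' exp preserves interval ordering.
#'
#' @param fit A `het_fit` produced under `report_relative = TRUE`.
#' @return The fit with a `relative` component holding exponentiated
#'   estimates (and CI endpoints when present).
#' @export
relative_effects <- function(fit) {
  stopifnot(inherits(fit, "het_fit"))
  if (!isTRUE(fit$report_relative))
    stop("relative reporting was not requested; set `report_relative = TRUE` ",
         "in the model spec (outcome must be on the log scale)")
  rel <- list(estimate = exp(fit$estimate))
  if (!is.null(fit$ci_low)) {
    rel$ci_low <- exp(fit$ci_low)
    rel$ci_high <- exp(fit$ci_high)
  }
  fit$relative <- rel
  fit
}

#' Compose multiplicative effects
#'
#' Relative effects on the exponentiated scale combine by product: the
#' expected treatment effect of an individual deviating from the reference
#' group on several modifiers is the reference effect times each modifier's
#' multiplier.
#'
#' @param ... Numeric multipliers (vectors are multiplied elementwise into
#'   the composition).
#' @return The product of all supplied multipliers.
#' @examples
#' compose_relative(0.855, 0.890, 0.949)  # 0.722
#' @export
compose_relative <- function(...) {
  prod(unlist(list(...)))
}

#' Interaction-model comparator
#'
#' A single OLS regression of the outcome on an intercept, the step-1
#' covariates as main effects, the treatment indicator, and the treatment
#' interacted with each step-4 modifier. The treatment main effect and the
#' interaction coefficients estimate the same \eqn{(\Delta\alpha,
#' \Delta\beta)} as the four-step procedure, and when the step-1 and step-4
#' covariate sets coincide (and no feature expansion is used) the two sets of
#' point estimates are algebraically identical, because stratifying by
#' treatment is equivalent to fully interacting with it.
#'
#' The comparator refuses to run with step-1 feature expansion enabled: the
#' expanded stratified fit and this simple interaction model estimate
#' different specifications and their estimates are not comparable.
#'
#' @inheritParams fit_arm_models
#' @return A `het_fit` (estimator `"interaction"`) with analytic OLS
#'   standard errors and the same coefficient naming as [regress_ite()].
#' @export
fit_interaction_model <- function(data, spec) {
  stopifnot(inherits(data, "cohort_data"), inherits(spec, "model_spec"))
  check_spec(spec, data)
  if (spec$expand_quadratics || spec$expand_pairwise)
    stop("interaction comparator is only defined for unexpanded step-1 designs; ",
         "with feature expansion the two models estimate different specifications")
  if (sum(data$a == 0L) == 0L || sum(data$a == 1L) == 0L)
    stop("degenerate treatment split: one arm is empty")
  X1 <- data$X[, spec$step1, drop = FALSE]
  X4 <- data$X[, spec$step4, drop = FALSE]
  inter <- X4 * data$a
  colnames(inter) <- paste0("a:", spec$step4)
  Z <- cbind("(Intercept)" = 1, X1, a = data$a, inter)
  cf <- ols_coef(Z, data$y)
  res <- data$y - drop(Z %*% cf)
  sigma2 <- sum(res^2) / (data$n - ncol(Z))
  se <- stats::setNames(sqrt(sigma2 * diag(chol2inv(chol(crossprod(Z))))),
                        colnames(Z))
  keep <- c("a", paste0("a:", spec$step4))
  est <- stats::setNames(cf[keep], c("(Intercept)", spec$step4))
  new_het_fit(est, stats::setNames(se[keep], names(est)),
              mode = "multivariate", estimator = "interaction",
              report_relative = spec$report_relative,
              extra = list(full_coefficients = cf))
}

#' Omitted-variable bias decomposition for the ITE regression
#'
#' When a modifier is dropped from step 4, each retained coefficient absorbs
#' a bias equal to (coefficient of the omitted modifier in the full ITE
#' regression) times (coefficient of the retained modifier in an auxiliary
#' OLS of the omitted modifier on the retained ones). In-sample this
#' short-equals-long-plus-product identity is exact, so the predicted and
#' realised (short-minus-long) biases coincide to machine precision on any
#' fixed dataset.
#'
#' @param data A [cohort_data()].
#' @param spec_full A [model_spec()] whose step-4 set includes `omitted_name`.
#' @param omitted_name The modifier to drop.
#' @param ite Optional precomputed [estimate_ite()] result (step 1 is
#'   unaffected by the omission).
#' @return A data frame with one row per retained coefficient (intercept
#'   included): `long` and `short` estimates, `predicted_bias`
#'   (lambda x gamma) and `realized_bias` (short minus long).
#' @export
omitted_variable_bias <- function(data, spec_full, omitted_name, ite = NULL) {
  stopifnot(inherits(data, "cohort_data"), inherits(spec_full, "model_spec"))
  if (!omitted_name %in% spec_full$step4)
    stop("'", omitted_name, "' is not in the step-4 covariate set")
  retained <- setdiff(spec_full$step4, omitted_name)
  if (is.null(ite)) ite <- estimate_ite(data, spec_full)
  long <- regress_ite(ite, data, spec_full)
  spec_short <- spec_full
  spec_short$step4 <- retained
  short <- regress_ite(ite, data, spec_short)
  # auxiliary regression: omitted modifier on intercept + retained modifiers
  Zr <- cbind("(Intercept)" = 1, data$X[, retained, drop = FALSE])
  gamma <- ols_coef(Zr, data$X[, omitted_name])
  lambda <- long$estimate[[omitted_name]]
  nm <- c("(Intercept)", retained)
  data.frame(coefficient = nm,
             long = unname(long$estimate[nm]),
             short = unname(short$estimate[nm]),
             predicted_bias = unname(lambda * gamma[nm]),
             realized_bias = unname(short$estimate[nm] - long$estimate[nm]),
             row.names = NULL)
}
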