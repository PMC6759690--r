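#' Residualize a modifier against the other modifiers
#'
#' For a one-covariate plot to show the covariate's *partial* association
#' with the treatment effect, the covariate must first be corrected for
#' multicollinearity: it is regressed (OLS, with intercept) on all other
#' step-4 modifiers and replaced by the residual. The residual has mean
#' exactly zero and is orthogonal to every other modifier, so the slope of a
#' straight-line fit of the ITEs on it equals the covariate's coefficient in
#' the multivariate step-4 regression.
#'
#' @param data A [cohort_data()].
#' @param spec A [model_spec()]; residualization runs within `spec$step4`.
#' @param name The modifier to residualize.
#' @return Numeric vector of residuals (the centred covariate itself when it
#'   is the only modifier).
#' @export
residualize_covariate <- function(data, spec, name) {
  stopifnot(inherits(data, "cohort_data"), inherits(spec, "model_spec"))
  check_spec(spec, data)
  if (!name %in% spec$step4) stop("'", name, "' is not a step-4 covariate")
  others <- setdiff(spec$step4, name)
  x <- data$X[, name]
  if (length(others) == 0L) return(x - mean(x))
  Z <- cbind("(Intercept)" = 1, data$X[, others, drop = FALSE])
  x - drop(Z %*% ols_coef(Z, x))
}

#' Partial covariate-effect curve
#'
#' Least-squares polynomial fit (straight line or quadratic) of estimated
#' ITEs on a residualized modifier, evaluated on a grid for plotting. The
#' curve can be shifted vertically — useful to make its value at zero equal
#' a reference-group effect estimated elsewhere — and optionally
#' exponentiated for reporting on the multiplicative scale (shift is applied
#' before exponentiation).
#'
#' @param ite An [estimate_ite()] result or numeric vector.
#' @param zres Residualized modifier from [residualize_covariate()].
#' @param degree 1 (line) or 2 (quadratic).
#' @param vertical_shift Constant added to the fitted curve (log scale when
#'   `report_relative`).
#' @param report_relative Exponentiate the shifted curve?
#' @param covariate_name Label stored with the curve.
#' @param n_grid Number of grid points (>= 100) spanning the observed range.
#' @return An object of class `partial_curve`: `quad_coefs` (intercept,
#'   linear, quadratic — quadratic 0 for degree 1), `vertical_shift`, and a
#'   `grid` data frame with `z` and `fitted` on the reporting scale.
#' @export
partial_effect_curve <- function(ite, zres, degree = 2L, vertical_shift = 0,
                                 report_relative = FALSE,
                                 covariate_name = deparse(substitute(zres)),
                                 n_grid = 101L) {
  v <- if (inherits(ite, "ite_vector")) ite$ite_hat else as.numeric(ite)
  if (length(v) != length(zres)) stop("`ite` and `zres` lengths differ")
  if (!degree %in% c(1L, 2L)) stop("`degree` must be 1 or 2")
  n_grid <- max(as.integer(n_grid), 100L)
  Z <- if (degree == 2L) cbind(1, zres, zres^2) else cbind(1, zres)
  colnames(Z) <- c("intercept", "linear", "quadratic")[seq_len(ncol(Z))]
  cf <- ols_coef(Z, v)
  quad_coefs <- c(intercept = unname(cf[1L]), linear = unname(cf[2L]),
                  quadratic = if (degree == 2L) unname(cf[3L]) else 0)
  z <- seq(min(zres), max(zres), length.out = n_grid)
  fitted <- quad_coefs[["intercept"]] + quad_coefs[["linear"]] * z +
    quad_coefs[["quadratic"]] * z^2 + vertical_shift
  if (report_relative) fitted <- exp(fitted)
  structure(list(covariate_name = covariate_name, zres = zres,
                 quad_coefs = quad_coefs, vertical_shift = vertical_shift,
                 report_relative = report_relative,
                 grid = data.frame(z = z, fitted = fitted)),
            class = "partial_curve")
}

#' @export
print.partial_curve <- function(x, ...) {
  cat(sprintf("<partial_curve> %s: intercept %.4f, slope %.4f, quadratic %.4f, shift %+.4f%s\n",
              x$covariate_name, x$quad_coefs[["intercept"]],
              x$quad_coefs[["linear"]], x$quad_coefs[["quadratic"]],
              x$vertical_shift,
              if (x$report_relative) " (relative scale)" else ""))
  invisible(x)
}

#' Vertical shift aligning a curve with a reference-group effect
#'
#' The level of a partial curve is of secondary interest, but it is natural
#' to pin the curve's value at zero to the reference-group effect from the
#' step-4 regression. This helper returns the additive shift achieving that;
#' for a curve reported on the relative scale, supply the reference effect as
#' a multiplier (the shift is computed on the log scale).
#'
#' @param curve A [partial_effect_curve()] result.
#' @param reference Target value of the curve at `z = 0`, on the curve's
#'   reporting scale.
#' @return The vertical shift to pass to [partial_effect_curve()].
#' @export
shift_for_reference <- function(curve, reference) {
  stopifnot(inherits(curve, "partial_curve"))
  target <- if (curve$report_relative) log(reference) else reference
  target - curve$quad_coefs[["intercept"]]
}

#' Histogram summary of estimated treatment effects
#'
#' Bins the estimated ITEs (or their exponentials, for log-modelled
#' outcomes) into equal-width bins and records the mean as the
#' dashed-line marker of the usual display. The number of bins defaults to
#' the Freedman-Diaconis rule.
#'
#' @param ite An [estimate_ite()] result or numeric vector.
#' @param n_bins Number of equal-width bins; `NULL` for Freedman-Diaconis.
#' @param scale `"absolute"` or `"relative"` (exponentiate before binning).
#' @return An object of class `hist_summary`: `breaks`, `counts` (summing to
#'   n), `mean` of the plotted values, and the `scale` used.
#' @export
ite_histogram <- function(ite, n_bins = NULL, scale = c("absolute", "relative")) {
  scale <- match.arg(scale)
  v <- if (inherits(ite, "ite_vector")) ite$ite_hat else as.numeric(ite)
  if (length(v) < 1L) stop("need at least one effect estimate")
  if (scale == "relative") v <- exp(v)
  if (is.null(n_bins)) n_bins <- max(grDevices::nclass.FD(v), 1L)
  rng <- range(v)
  if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE, include.lowest = TRUE)
  structure(list(breaks = h$breaks, counts = h$counts, mean = mean(v),
                 scale = scale, n = length(v)),
            class = "hist_summary")
}

#' @export
print.hist_summary <- function(x, ...) {
  cat(sprintf("<hist_summary> %d values in %d bins (%s scale), mean = %.4f\n",
              x$n, length(x$counts), x$scale, x$mean))
  invisible(x)
}

#' Share of effects below a threshold
#'
#' For effects reported on the relative scale the natural threshold is 1
#' (no effect): the returned share answers "for what fraction of individuals
#' is the estimated effect a reduction?".
#'
#' @inheritParams ite_histogram
#' @param threshold Cut-point on the chosen scale (default 1, for relative).
#' @return Proportion of values strictly below `threshold`.
#' @export
share_below <- function(ite, threshold = 1, scale = c("relative", "absolute")) {
  scale <- match.arg(scale)
  v <- if (inherits(ite, "ite_vector")) ite$ite_hat else as.numeric(ite)
  if (scale == "relative") v <- exp(v)
  mean(v < threshold)
}
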