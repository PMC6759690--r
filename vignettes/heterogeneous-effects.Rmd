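---
title: "Assessing effect heterogeneity by imputing potential outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing effect heterogeneity by imputing potential outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hteimpute)
```

## The model and its assumptions

`hteimpute` targets settings where a binary treatment or exposure $A$ may
affect a continuous outcome $Y$ differently across individuals. Each
individual has two potential outcomes, modelled linearly:

$$Y_{0i} = \alpha_0 + \sum_j \beta_{j0} X_{ji} + \varepsilon_{0i}, \qquad
  Y_{1i} = \alpha_1 + \sum_j \beta_{j1} X_{ji} + \varepsilon_{1i}.$$

The individual treatment effect $Y_{1i}-Y_{0i}$ is never observed, but its
conditional expectation given covariates is
$\Delta\alpha + \sum_j \Delta\beta_j X_{ji}$ with
$\Delta\alpha = \alpha_1-\alpha_0$ and $\Delta\beta_j = \beta_{j1}-\beta_{j0}$.
This CATE function is the estimand throughout: it captures the component of
heterogeneity that observed covariates can explain, and its variance is
smaller than that of the raw ITE by exactly the variance of the error
difference. We deliberately do not attempt to simulate or estimate the raw
ITE including $\Delta\varepsilon$: that would require untestable assumptions
about the correlation between the two error terms, which are never jointly
observed. The package's working assumption — residuals that do not vary with
treatment — makes the four-step estimator identical to a single-imputation
completion of the missing potential outcomes (`impute_counterfactuals()`
demonstrates the identity, and `shared_residual = FALSE` shows the noisier
alternative).

Causal interpretation rests on the usual conditions: causal consistency,
no unmeasured confounding (errors mean-zero given $X$), homoscedastic and
non-autocorrelated errors, and correct functional form. Without
exchangeability the output is still a valid description of heterogeneous
*associations*.

## The four steps and their contracts

1. `fit_arm_models()` — OLS of the outcome on the step-1 covariates within
   each treatment stratum. The solver is QR-based and rank-revealing;
   a rank-deficient design is an *error naming the aliased columns*, never a
   silent drop, because the interpretation of every downstream coefficient
   depends on knowing the design. Each arm must exceed the design size by
   `min_arm_size_factor` (default 2) rows; per-arm observation/parameter
   ratios are shown by `print()` so overfitting is visible rather than
   policed.
2. `predict_potential_outcomes()` — both linear predictions for every row,
   rebuilt from a stored expansion record so prediction-time and fit-time
   designs cannot drift apart.
3. `estimate_ite()` — the difference of the two predictions.
4. `regress_ite()` — OLS of the estimated ITEs on an intercept plus the
   step-4 modifiers, which may be a deliberately smaller, interpretable
   subset of the step-1 set. Univariate mode refits one single-modifier
   model per covariate (sharing the one ITE vector, reporting no common
   intercept); multivariate mode is one joint fit.

When the step-1 and step-4 sets coincide and no expansion is used, the
four-step estimates equal those of one fully interacted OLS of $Y$ on main
effects, $A$, and $A \times$ modifiers — stratification and full interaction
are the same projection. The test suite asserts this to $10^{-8}$ on 100
random datasets. With expansion enabled the two models differ by
construction, so `fit_interaction_model()` refuses the comparison instead of
quietly comparing different estimands.

## Inference: bootstrap the whole procedure

The step-4 OLS standard errors ignore that the ITEs are estimated; in the
common all-covariates case the step-4 residuals are exactly zero and the
naive SEs are degenerate. They are therefore reported only under the label
`naive_se`. Real inference resamples individuals with replacement and reruns
all four steps per replicate (`bootstrap_procedure()`, default
$B = 1000$). Choices made here:

* **Unstratified resampling.** The procedure's sampling variability includes
  variability in arm sizes, so rows are resampled without fixing the
  treated count.
* **Failed replicates are redrawn, not skipped**, keeping $B$ fixed;
  skipping would bias quantiles in small samples. The redraw count is
  reported (`n_failed`). After 100 consecutive degenerate redraws the run
  aborts with a diagnostic — at that point the data cannot support the
  resampling scheme.
* **Normal-approximation CIs by default** (point estimate
  $\pm z_{0.975} \cdot \mathrm{SE}$ with the exact normal quantile, not a
  rounded 1.96); percentile intervals are available via
  `ci_method = "percentile"` and agree closely at realistic $B$.
* **Determinism.** A configured seed fixes the whole run; replicates are
  reduced in index order.

## What the simulator emulates

`scenario_preset("base")` generates three standard-normal covariates with
pairwise correlations 0.5, treatment assigned to the 30% of individuals with
the lowest latent index (covariate sum plus standard-normal noise — so
treatment is confounded by construction), and outcomes
$Y_0 = 1 + 2X_1 + 3X_2 + 4X_3 + \varepsilon_0$,
$Y_1 = 4 + 3X_1 + 3.5X_2 + 4X_3 + \varepsilon_1$ with unit error SDs,
implying the CATE $3 + X_1 + 0.5X_2$. `high_het` widens the treated-arm
slopes (CATE $3 + 2X_1 + 2X_2$); `high_corr` raises the $X_1$–$X_2$
correlation to 0.9.

Two conventions were genuinely open and are settled as follows:

* **Treatment threshold.** The latent-index quantile is computed *within
  each realised dataset* (type-7 linear interpolation, strict `<`), making
  the treated fraction deterministic — exactly 150 of 500 under the base
  preset — and hence testable. The distribution-theoretic threshold
  ($\sqrt{7}\,\Phi^{-1}(0.3)$ under the base correlation structure) is
  available as `quantile_method = "theoretical"`.
* **Error coupling.** The two potential-outcome errors are drawn
  independently. Only `cate_true` is used as estimation truth, and it is
  invariant to that coupling; `ite_true` is retained for variance
  decomposition checks ($\mathrm{Var}[ITE] = \sum_j \Delta\beta_j^2
  \mathrm{Var}[X_j] + \mathrm{Var}[\Delta\varepsilon]$).

The generator retains `y0_true`, `y1_true`, `ite_true` and `cate_true`, so
tests can score estimates against truth without re-deriving it. What the
simulator does *not* emulate: non-normal or discrete covariates, non-linear
response surfaces, heteroscedastic errors, measurement error, or informative
missingness. Passing tests therefore certify the estimator's behaviour under
a correctly specified linear world, not robustness to violations of it.

## The Monte-Carlo study

`run_study()` repeats generate → estimate → bootstrap → score over many
datasets and reports per-coefficient average estimate, average bootstrap SE
and CI coverage. The package's validation study uses 1000 datasets of
$n = 500$ with $B = 500$ bootstrap replicates (about a minute on one CPU);
$B = 1000$ reproduces the reference SE digits and is the default for
analyses. Per-dataset child seeds derive deterministically from the study
seed, so halving `n_sims` changes averages only by Monte-Carlo error.

In the omitted-modifier variant (`omit = "x2"`), coverage is still scored
against the full-model truth: bias is supposed to be visible, not absorbed
into a redefined target. The direction and size of that bias follow the
omitted-variable formula — bias in a retained coefficient equals the omitted
modifier's effect on the ITE times the auxiliary regression coefficient of
the retained covariate in a regression of the omitted one on all retained
ones. `omitted_variable_bias()` computes predicted and realised biases;
in-sample they agree to machine precision, which the tests assert on 100
random datasets. The same decomposition explains why the interaction model's
bias differs: its auxiliary regression runs on the $A \times X$ products
(controlling main effects), not on the covariates themselves.

## Diagnostics

Histograms (`ite_histogram()`) summarise the estimated effect distribution;
on the relative scale values are exponentiated before binning and
`share_below()` reports the fraction of individuals with, e.g., a reducing
effect. Bin count defaults to Freedman–Diaconis — a deliberate choice, since
no binning rule is canonical for this display.

Covariate–effect curves correct for multicollinearity by residualization:
each modifier is regressed on the other step-4 modifiers and replaced by the
residual (`residualize_covariate()`). The residual is exactly centred and
orthogonal to the other modifiers, so a degree-1 fit of the ITEs on it
recovers precisely the multivariate step-4 coefficient (asserted to
$10^{-8}$), while a degree-2 fit (`partial_effect_curve()`) screens for
non-linearity. For this screening workflow the step-1 design should include
quadratic and interaction terms (`expand_quadratics`, `expand_pairwise`) —
otherwise step-1 linearity forces the curves to look linear. Squares of 0/1
indicators are dropped from the expansion as exact duplicates.

Curve levels are of secondary interest; `vertical_shift` (with helper
`shift_for_reference()`) pins the curve's value at zero to a reference-group
estimate. The shift is user-supplied because it reconciles two estimates of
the same quantity computed under different step-1 designs — a dataset-specific
adjustment, not a model parameter. On the relative scale the shift is applied
before exponentiation.

## The synthetic lifestyle cohort

`generate_fixture()` builds a fully synthetic cohort shaped like a
population-based study of a rare exposure (11% prevalence) and a
log-transformed outcome: binary lifestyle indicators, two continuous
covariates in analysis units, confounded exposure assignment, and
multiplicative modifier effects around a reference-group effect of 0.855.
It exists so the relative-scale workflow (`center_continuous`,
`report_relative`, `relative_effects()`, multiplicative composition) can be
demonstrated and recovery-tested end to end; it is not calibrated to any
real dataset and no real-data estimate should be read off it. Continuous
modifiers act on centred values, so the intercept describes an individual
with average activity and energy intake and zeros on all indicators.
Centring happens after complete-case filtering, so "average" always refers
to the analysed sample.

## Numerical choices and degenerate inputs

* Binary checks are exact: a treatment column must contain only 0/1; a
  covariate is treated as an indicator (square dropped, never centred by
  `read_cohort()`) only if all values are exactly 0 or 1.
* Complete-case deletion applies to used columns only and is logged;
  covariate imputation is intentionally out of scope.
* Constant columns are refused at expansion time by name.
* Results tables round-trip through CSV at full double precision.
* All OLS fits share one QR path with explicit rank checks; the
  bootstrap's inner loop uses the same decomposition via `.lm.fit` for
  speed, with rank failures routed to the redraw policy.

## Limitations

Linear models, continuous outcomes, binary treatments. No multiple
imputation of counterfactuals, no machine-learning ITE learners, no
multilevel structure, no multiplicity adjustment of step-4 inference, and no
sandwich/heteroscedasticity-robust variants. Unmeasured confounding — of the
average effect or of the heterogeneity itself — is not detectable from
within the method.
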