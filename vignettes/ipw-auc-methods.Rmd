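---
title: "IPW estimation of the AUC in two-phase case-control designs: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IPW estimation of the AUC in two-phase case-control designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twophaseAUC)
```

## The estimation problem

A two-phase biomarker study measures disease status $D \in \{0, 1\}$ and
cheap covariates on a phase-one cohort of size $N$ ($N_D$ cases,
$N_{\bar D}$ controls), then measures the expensive markers $X$ (and
possibly $Y$) on a phase-two subsample, drawn separately among cases and
controls with probabilities that may depend on covariate strata. The
estimand is the population classification accuracy
$\mathrm{AUC}_x = P(X_D > X_{\bar D})$ for a randomly drawn case-control
pair, and, for paired markers, $\Delta\mathrm{AUC} =
\mathrm{AUC}_y - \mathrm{AUC}_x$. Markers are oriented so that larger
values are more disease-like; the package never auto-flips.

When controls are frequency-matched to cases on a covariate correlated
with the marker, the phase-two control sample is not representative of
the control population and the empirical AUC over sampled pairs is
inconsistent. The package estimates the AUC by inverse probability
weighting: each sampled subject contributes with weight $1/\hat p$,
where $\hat p$ is its (estimated) phase-two sampling probability, and
the weighted concordance count is divided by the weighted pair count.
Being a ratio estimator, the result is invariant to rescaling the
weights within an arm, and with per-stratum empirical weights it is algebraically
identical to the stratified double-sum representation used for
finite-population stratified sampling (an exact identity, tested
bit-level on fixtures).

## Sampling-weight models

Weights are always fitted separately for cases and controls — the two
arms are sampled by separate mechanisms and share no parameters.

* **Stratum fractions** (`fit_stratum_weights`): $\hat\pi_k = n_k /
  N_k$, the proportion of the arm's phase-one subjects sampled from
  stratum $k$. This is the estimator of choice for designs with
  discrete matching strata, and it is the weight model used throughout
  the simulation driver.
* **Logistic weights** (`fit_logistic_weights`): maximum-likelihood
  logit of the sampling indicator on phase-one covariates, for
  continuous design covariates. A saturated logistic model on discrete
  strata reproduces the stratum fractions to numerical precision
  (tested to 1e-8). Fitted probabilities at or below 1e-8 are a hard
  error rather than a silent truncation: the asymptotic theory requires
  $p > 0$, and such tiny weights mean the design, not the code, needs
  fixing.
* **Known weights** (`known_weights`): the design's true probabilities,
  available under Bernoulli sampling. These exist mainly to quantify
  the efficiency cost of *not* estimating weights; the variance then
  keeps the second-moment inflation terms but drops the
  weight-estimation corrections.

Strata with no sampled subjects cannot be weighted and are refused
(extrapolating a weight for them has no basis in the data). Strata with
sampling fraction exactly 1 are perfectly observed: nothing about their
weight is estimated, so they are excluded from the estimated-parameter
set and contribute zero weight-estimation correction. This convention
also makes the all-cases design (case fraction 1) come out with no
case-side correction, consistent with the closed-form design variances
below.

## Asymptotic variance plug-ins

Write $F(x)$ for the control CDF of the marker evaluated with strict
inequality (matching the AUC indicator) and $S(v)$ for the case
survival; the *placement values* $F(X_{D i})$ and $S(X_{\bar D j})$
both average to the AUC. The variance of
$\sqrt N(\widehat{\mathrm{AUC}} - \mathrm{AUC})$ is estimated per arm
as

$$
\hat\Sigma_{\text{arm}} =
\hat E\!\left\{\tfrac{1}{p}\,(\text{placement} - \widehat{\mathrm{AUC}})^2\right\}
\;-\; \hat B^\top \hat I^{-1} \hat B ,
\qquad
\hat B = \hat E\!\left\{(\text{placement} - \widehat{\mathrm{AUC}})\,
\tfrac{1}{p}\,\tfrac{\partial p}{\partial\theta}\right\},
$$

combined as $\hat\Sigma = \hat\Sigma_D/\hat\lambda +
\hat\Sigma_{\bar D}/(1-\hat\lambda)$ with $\hat\lambda = N_D/N$, and
$\widehat{\mathrm{var}} = \hat\Sigma / N$. Here $\hat I$ is the weight
model's information matrix (diagonal
$\hat P(k)/\{\hat\pi_k(1-\hat\pi_k)\}$ for stratum weights, the usual
logistic information otherwise), and the quadratic form is the
efficiency gain from estimating the weights — dropped in known-weights
mode. For $\Delta\mathrm{AUC}$ the same expression is used with the
*paired difference of centred placements*
$(F_y - \mathrm{AUC}_y) - (F_x - \mathrm{AUC}_x)$ per subject; the
cross-marker covariance and cross inflation terms are carried
automatically, and the variance is identically zero when the two
markers coincide.

Two derivation-level choices deserve a record:

* **Centred moments.** The single-marker variance is often written in
  an expanded form: placement variance, plus an uncentred second-moment
  inflation $E\{(1-p)/p \cdot F^2\}$, minus AUC-scaled coupling terms.
  The centred form above is that same expression recombined (the
  package reports both decompositions in the `components` field, and
  the test suite checks term-by-term agreement against an independent
  brute-force evaluation). For the two-marker difference, only the
  fully centred form has the required degeneracy property
  ($\hat\Sigma_{xy} = 0$ when $y \equiv x$); the package therefore
  centres all placement moments at the estimate throughout, which is
  also what a direct influence-function derivation of the ratio
  estimator plus MLE weight correction yields.
* **Population moments are IPW moments.** Every expectation in the
  plug-in is an IPW-weighted empirical moment over sampled subjects
  (Hájek-normalised within arm), so it estimates a case/control
  *population* moment under the biased design; unweighted moments over
  the biased sample would target the wrong law. With stratum weights
  the normalising constant is exactly the arm size (the
  Horvitz–Thompson count identity), and the IPW mean of the placements
  equals the IPW AUC exactly, so "centring at the estimate" and
  "centring at the empirical mean" coincide.

The same code path with all probabilities set to 1 reproduces the
classical full-data AUC variance, which is what the package uses for
the naive empirical estimator's CI (computed on the phase-two sample
only). Finite-population stratified sampling is handled by the same
plug-in with empirically estimated stratum fractions: the asymptotic
variance of the IPW estimator is the same under the two designs at
matched fractions, and the Monte-Carlo suite checks that the two Var×N
values agree within simulation error.

Numerical safeguards: a plug-in $\hat\Sigma$ that comes out (slightly)
negative in very small samples is clipped to zero with a warning, and
Wald inference then refuses to run rather than fabricating a zero-width
interval. A singular information restricted to the estimated strata is
an error advising stratum merging. Wald CIs are reported on the plain
(untransformed) scale, unclipped and clipped to the parameter range;
tie handling defaults to the strict indicator (markers are modelled as
continuous) with a midrank option for rounded real-world data. The
DeLong comparator always uses the midrank convention, as its structural
components are defined that way; with two identical markers its
variance degenerates and the test returns $p = 1$ by documented
convention.

A design-respecting bootstrap (`bootstrap_variance`) resamples
phase-one cases and controls with replacement and re-estimates the
stratum fractions per replicate; it exists purely as an independent
check of the analytic plug-ins and is validated to agree with them
within 15% on mid-size simulated cohorts.

## The synthetic-cohort generator

`binormal_model()` encodes the data-generating law used by all
simulation work: disease prevalence $\lambda = 0.1$; a latent covariate
$W^*$ standard normal among controls and $N(0.6, 1)$ among cases,
discretised at the control tertiles $\Phi^{-1}(1/3), \Phi^{-1}(2/3)$
into a three-level stratum; markers jointly normal with $W^*$ given
$D$, standard normal among controls, $X \sim N(\mu_{Dx},
\sigma_{Dx}^2)$ and $Y \sim N(1, 1)$ among cases, with conditional
correlations $\rho_{xy}, \rho_{xw^*}, \rho_{yw^*}$ equal in both arms.
The implied accuracies are closed-form,
$\mathrm{AUC}_x = \Phi(\mu_{Dx}/\sqrt{1 + \sigma_{Dx}^2})$, and the
Monte-Carlo driver scores bias and coverage against these analytic
truths, never against a mega-simulation.

Two phase-two designs are implemented:

* **Bernoulli** (`apply_bernoulli`): cases sampled independently at a
  constant rate $p_c$; a control in stratum $w$ sampled with
  probability $p_c\, P(W = w, D = 1)/P(W = w, D = 0)$, computed exactly
  from the model's normal CDFs, so the expected numbers of sampled
  cases and controls match within every stratum. The true per-subject
  probability is stored for known-weights analyses.
* **FPS** (`apply_fps`): $n_D = \mathrm{round}(N \lambda p_c)$ cases by
  simple random sampling without replacement (cases are drawn
  unstratified, so their sampling stratum collapses to a single label),
  then per stratum exactly as many controls as *realised* sampled cases
  — the frequency-matching rule as practised. A stratum with too few
  controls is an error, never silently exhausted.

The generator emulates what matters for the estimators: biased,
covariate-dependent control selection; marker-covariate and
marker-marker dependence; both randomness regimes for the phase-two
counts. It does not emulate censoring or outcome misclassification
(disease status is taken as given), measurement error in the markers,
continuous matching variables (the logistic weight path covers that
analytically but the generator's stratum is discrete), or auxiliary
covariates beyond the single stratum variable. Passing tests therefore
demonstrate correctness of the estimators under the stated sampling
mechanisms, not robustness to those further data pathologies. A
gamma-marker variant (`generate_gamma_cohort`, Gaussian copula with
gamma marginals) is provided as an extension hook for skewed assays; it
is moment-tested but not calibrated to any reference table.

## Monte-Carlo driver

`run_cell()` loops generate → sample → fit stratum weights → estimate →
variance → test, and reports bias×100, Var×N, coverage of 95% Wald CIs
and rejection rates, each with its Monte-Carlo standard error so that
any comparison can be calibrated. Per-replicate seeds are pre-drawn
from the cell seed, making serial and chunked runs identical.
Replicates that fail estimation (an empty stratum in a small cohort)
are counted, and a cell with more than 1% failures is flagged invalid
rather than averaged over quietly. Problem sizes used in this package's
own verification: phase-one $N = 5000$ with expected phase-two sizes
100–400 per arm; 5000 replicates per cell in `scripts/acceptance.R`
(matching the reference operating characteristics), 100–1000 replicates
in the test suite with 3-standard-error acceptance bands.

## Design-efficiency calculations

For planning, `population_moments()` computes
$\mathrm{var}\{F(X_D)\}$, $\mathrm{var}\{S(X_{\bar D})\}$ and the
within-stratum control variances by adaptive quadrature (relative
tolerance 1e-8; a Monte-Carlo oracle cross-checks the moments in the
tests) under a bivariate-normal marker/covariate model with a binary
median-split stratum. Two closed-form asymptotic variances are then
tabulated: all cases plus frequency-matched stratified controls
(`variance_design_stratified`, analysed with estimated IPW weights) and
all cases plus a same-size simple random control sample
(`variance_design_srs`, the empirical estimator). With one stratum the
two formulas coincide algebraically — the SRS design *is* the
one-stratum special case. Their ratio (`relative_efficiency_curve`)
quantifies when matching pays: at zero marker-covariate correlation the
matched design is strictly less efficient (its stratum-wise sampling
penalty exceeds the pooled one), while with strong correlation the
within-stratum placement variance shrinks enough that matching wins —
the characteristic U-shape in the correlation. The package tabulates;
it deliberately does not optimise sampling fractions, since the choice
involves cost constraints outside the model.

## Other conventions and limitations

* $\Delta$ is oriented as $\mathrm{AUC}_y - \mathrm{AUC}_x$.
* Case strata and control strata are separate namespaces; label
  equality across arms carries no meaning, and the two arms may use
  entirely different stratifications.
* Missing markers are written as empty fields and read from empty or
  `NA`; a marker value on an unsampled row is a validation error, not a
  warning, because it indicates a corrupted extract.
* Inference is asymptotic-normal throughout; no small-sample
  corrections are attempted, so very small phase-two samples (tens of
  subjects per arm) should be interpreted with care.
* Time-to-event outcomes, case-cohort designs, calibration/raking of
  weights with auxiliary variables, ROC points and partial AUC are out
  of scope.
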