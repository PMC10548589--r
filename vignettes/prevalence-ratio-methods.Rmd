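---
title: "Estimating prevalence ratios with the negative log-binomial model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating prevalence ratios with the negative log-binomial model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prevratio)
```

## The problem

Cross-sectional studies measure a binary outcome (disease, consumption,
any event of interest) and ask how its prevalence differs between
exposed and unexposed subjects. The natural effect measure is the
prevalence ratio PR = p₁/p₂. Logistic regression — the habitual choice —
estimates the odds ratio instead, and the identity

OR = PR · (1 − p₂)/(1 − p₁)

shows the OR carries an *inherent* multiplicative bias relative to the
PR. The bias factor is ≈ 1 when both prevalences are below ~10 %, but
grows without bound as prevalence rises: at p₂ ≈ 0.89, p₁ ≈ 0.97 the
factor exceeds 3. Reporting ORs from high-prevalence cross-sectional
data therefore overstates associations badly.

Three standard remedies estimate the PR directly on a log link:
the **log-binomial** model (binomial variance, log link), the
**log-Poisson** working model (equivalently a Cox model at constant
time — at fixed time the Cox estimating equations reduce to the Poisson
score, which is why the package treats `cox_constant_time` as a
documented alias of `log_poisson`), and — the estimator this package is
built around — the **negative log-binomial (NLB)** model: an NB2 GLM,
variance μ + αμ², with log link, applied to the binary outcome so that
`exp(β)` estimates the PR. Because the NB mean is unconstrained below 1
only through its link, the NLB never hits the μ ≤ 1 boundary that makes
the log-binomial fail at high prevalence, and its dispersion parameter
α absorbs extra-Poisson variation.

The Poisson-type likelihoods are *working* likelihoods for a binary
outcome (y! = 1): their variance functions are deliberately
misspecified, which is why all PR models here are paired with the
**sandwich (robust) variance** A⁻¹BA⁻¹ — A the Fisher information at
the estimate, B the outer product of per-subject scores (the Lin–Wei
adjustment of the Poisson working model).

A useful exact result anchors the whole battery: for the saturated
model (intercept + one binary exposure), every log-link family returns
`exp(β₁)` equal to the crude PR, and the robust SE (without
finite-sample scaling) equals the closed-form crude SE
√(1/a − 1/(a+b) + 1/c − 1/(c+d)). The test suite verifies this to
1e-8 on random tables.

## Fitting machinery

All families are fitted by iteratively reweighted least squares
(Fisher scoring) with **step-halving**, so the log-likelihood never
decreases across accepted iterations (the trace is stored in
`loglik_trace`). Convergence requires both `max |Δβ| < ε` and a
relative deviance change `< ε`, with ε = 1e-6 by default and at most
100 iterations. The model-based covariance is the inverse Fisher
information recomputed at the final estimate.

For the log-binomial family the fitted probabilities are constrained to
(0, 1): proposals with μ ≥ 1 − 1e-10 are rejected and the step halved.
Iterates pinned against that constraint are reported as
`converged = "no_boundary"` — non-convergence is first-class data,
displayed as "No converge" in comparison reports, never an exception.
An infeasible starting value is pulled toward the feasible
constant-rate point (intercept = log mean(y)) rather than toward zero,
because on a log link β → 0 drives all μ → 1.

The NLB fit alternates IRLS for β given α with a one-dimensional
likelihood maximization for α given β (on log α, tolerance 1e-9),
declaring convergence only when β, α and the deviance have all
stabilized below ε. The dispersion score at α = 0,
½ Σ[(y − μ)² − y], decides boundary collapse: binary outcomes are
*under*dispersed relative to the Poisson working variance, so on
subject-level binary data α̂ = 0 and the NLB collapses smoothly to the
Poisson fit — which is exactly why its model-based SE reproduces the
Poisson SE while its robust SE reproduces the crude SE. α is treated as
fixed at α̂ in both covariances (profile convention) and counted as a
parameter in BIC = −2ℓ + k·log n; how the original software counted it
is not documented anywhere we know of, so this choice is stated rather
than assumed silently.

Numerical choices worth recording: probabilities are clamped to
[1e-12, 1 − 1e-12] inside likelihoods; weights are floored at 1e-12;
the NB log-likelihood switches to its Poisson limit for α < 1e-10
(it is continuous there); α is capped at 1e6, with the cap reported as
`no_boundary`; 95 % intervals use the exact normal quantile
1.959964…, not 1.96; and rank-deficient designs are rejected up front.

## Mantel–Haenszel reference

Confounder-adjusted comparisons use the MH stratified PR
Σ aᵢn₀ᵢ/nᵢ ∕ Σ cᵢn₁ᵢ/nᵢ as the reference, with the Greenland–Robins
(1985) variance of the log estimate — the standard in mainstream
epidemiological software (the comparison methodology this package
implements never states its MH variance, so the standard one is used
and documented). On a single stratum MH reduces exactly to the crude
estimator. Three metrics compare models against that reference: PR
precision |PR_MH − PR_model|/PR_model·100, the signed confounding
percentage (PR_crude − PR_adj)/PR_adj·100, and SE precision
|SE_MH − SE_model|/SE_model·100. All three are scale-free.

## Reconstructing 2×2 tables from published summaries

Published crude analyses print a handful of rounded numbers — n,
prevalence, PR, log-scale SE, sometimes an OR. `reconstruct_table()`
searches integer tables exhaustively and returns every one whose
statistics, rounded half-to-even to the printed decimals, match. Two
design points:

* **Matching is at printed precision.** The inputs are themselves
  rounded; demanding more would be spurious.
* **Complete-case sizes.** Exposure instruments have item
  non-response, so the analysis n behind a published row is routinely
  below the nominal study n. The search therefore scans effective
  sizes down to `n(1 − allow_missing)` (default 10 %). This matters in
  practice: for the low-prevalence outcome of the survey emulated here
  (n = 5810, prevalence 1.8 %, PR 3.294, SE 0.7126, OR 3.337) *no*
  integer table at exactly n = 5810 is consistent with all printed
  values, while a unique family of tables at effective sizes 5268–5427
  (a ≈ 92–93, c = 2) reproduces every one of them. The published row
  is evidently a complete-case analysis.

An instructive by-product: the printed OR/PR pairs of all five
outcomes imply, through the bias identity, that the exposed group
comprises ~93–97 % of subjects — the exposure margin was never
published, and the synthetic presets use 0.94.

## The synthetic cohort generator

The generator draws from the same model family the estimators assume:
integer ages from a right-skewed mixture (group shares
41.9/24.0/14.0/20.2 % for 18–25/26–29/30–34/35+, uniform within the
first three groups, geometric decay within 35+ solved so the mean age
is exactly 28.2; the achieved SD is 7.63 — the published 7.1 and the
published shares are mutually incompatible with any normal model, and
the group shares, which the estimators actually stratify on, take
priority; note the published shares themselves sum to 100.1 % and are
normalized). Exposure is Bernoulli with a logistic-in-age probability
(slope 0.03 per year in the study presets, inducing positive
confounding), and the outcome is Bernoulli(exp(β₀ + β₁x + f(age))).
β₀ is calibrated in closed form against the exact age distribution so
the marginal prevalence hits its target, and a configuration whose
implied probability exceeds 1 anywhere on the support is refused
*before* any draw — the generating model is exactly the fitted model,
never silently truncated. An optional mean-zero log-scale log-normal
frailty (off by default) induces extra-binomial variation; it raises
the marginal rate above the calibrated target (its multiplier has
expectation > 1) and products above 1 are truncated at draw time, so
it is a perturbation tool, not part of the calibrated presets.

The five study presets target the published marginal prevalences
(1.8/9.6/21.3/85.7/96.1 %) with true conditional PRs set to the
published age-adjusted stratified estimates (2.913/3.407/2.209/
1.241/1.086) and age effects chosen once for plausibility and
feasibility (grouped, e.g. 0.005/0.015/0.045 on the log scale for the
96.1 % outcome — high-prevalence outcomes necessarily take small
effects, which is also why their PRs are near 1). The true age-effect
sizes of the underlying survey are unpublished: the presets are tuned
*only* to reproduce the marginals and the confounding sign, and claims
about real data should be limited accordingly (see
`study_emulation_scope()`).

What passing tests on generator output do show: calibration accuracy
(marginals within 0.5 points averaged over 100 cohorts), correct
confounding direction (crude PR > MH PR), nominal robust-CI coverage
(0.93–0.97 at n = 2000 over 500 replicates with true PR 2 at 10 %
prevalence), and the qualitative high-prevalence phenomenon: with a
numeric age covariate at 96.1 % prevalence the log-binomial fit is
driven to the μ ≤ 1 boundary — the truth has a jump at 35+ that a
log-linear age term must overshoot — while NB and Poisson complete.
What they cannot show: anything about the confidential subject-level
survey data behind the published age-adjusted coefficients, SEs and
BIC values; those are reproduced only structurally/qualitatively
(`study_emulation_scope()` states this limitation, and the boundary
phenomenon itself is stochastic — about one cohort in ten has a
legitimately interior MLE).

## Problem sizes and determinism

The shipped tests use sizes chosen to make Monte-Carlo error small
relative to the assertions: 200,000 bootstrap replicates for the crude
SE check, 1500 replicates for the MH variance check, 100 random tables
for the sandwich identity, 50 datasets (n ≤ 500) for reference-GLM
agreement, 500 replicates of n = 2000 for coverage, 20 replicates of
n = 20,000 for dispersion recovery. All stochastic tests fix their
seeds; `scripts/acceptance.R` derives every seed from its `--seed`
argument.

## Known limitations

* The delta-method crude SE is first-order: at very small case counts
  (e.g. 2 unexposed cases) the bootstrap SD of ln PR exceeds it by
  ~10–15 %. This is a property of the estimator, faithfully shared
  with the software conventions it mirrors.
* Sampling weights, clustered designs and cluster-robust or bootstrap
  variances are out of scope; the analyses emulated here are
  unweighted.
* `cox_constant_time` is an alias, not a partial-likelihood
  implementation.
* Reported inherent-bias percentages recomputed from rounded published
  ratios can differ from originally published ones by a few tenths of
  a point (they were evidently computed from unrounded values); the
  package treats them as derived quantities, not targets.
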