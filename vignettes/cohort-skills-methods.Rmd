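---
title: "Comparing latent socio-emotional skills across cohorts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing latent socio-emotional skills across cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cohortskills` implements a complete chain for comparing latent
socio-emotional skills across birth cohorts when the only measurements are a
handful of ordinal behaviour items rated by parents. This vignette explains
the models, the estimators, the numerical choices, and what the synthetic
data generator does and does not emulate.

## The measurement model

Each child $j$ in group $c$ (a cohort-by-gender cell) carries two latent
skills, externalising and internalising,
$\theta_{jc} = (\theta^{EXT}_{jc}, \theta^{INT}_{jc})'$. Each of the 11
items has a latent response propensity

$$X^*_{ijc} = \nu_{ic} + \lambda_{ic}'\theta_{jc} + u_{ijc}, \qquad
  u_{ijc} \sim N(0, \psi_{ic}),$$

observed only through ordered categories cut at strictly increasing
thresholds $\tau_{s,ic}$ (two finite thresholds for 3-category items, one
for binary items), with $\tau_0 = -\infty$ and $\tau_S = +\infty$. The
structure is congeneric: items 1–6 load only on EXT, items 7–11 only on
INT. Errors are normal (a probit link), which is what makes the polychoric
/ diagonally-weighted least squares machinery applicable; a logistic
variant is deliberately not offered.

Because ordinal items carry no intrinsic location or scale, the model is
identified by normalisations. The package implements the three standard
parameterisations of the *configural* (least restricted) multi-group model
— theta (unit error variances), delta (unit latent-response variances) and
anchored (marker loadings fixed to 1) — and they are statistically
equivalent: the test suite verifies that all three reach the same minimised
discrepancy and the same implied moments to $10^{-6}$.

## The invariance ladder

Whether latent comparisons across groups are meaningful is an empirical
question: the items must relate to the skills identically in every group.
The ladder fits four nested models:

1. **configural** — same loading pattern only;
2. **thresholds** — thresholds equated across groups; with items of at most
   3 categories this is a pure reparameterisation of the configural model
   (the freed intercepts and scales absorb the constraints), and the
   package reproduces that equivalence numerically — including the equal
   free-parameter count (124 for four groups). For binary items the scale
   stays fixed at this level, since with group-specific loadings a freed
   binary scale would only be identified jointly with its intercept;
3. **thresholds + loadings** — licenses cross-group comparison of latent
   *variances* (and distribution shapes);
4. **thresholds + loadings + intercepts** — additionally licenses
   comparison of latent *means*.

Decisions use changes in approximate fit indices relative to the configural
model, because chi-square difference tests over-reject at large $n$. The
default cutoffs — $\Delta\mathrm{CFI} \le -0.010$,
$\Delta\mathrm{RMSEA} \ge 0.010$ (the categorical-data rule),
$\Delta\mathrm{SRMR} \ge 0.010$ — live in `invariance_cutoffs()` and are
configuration, not constants, since the simulation literature offers
several defensible sets. The scaled chi-square difference is reported
alongside. The pipeline enforces the substantive consequence: when
intercept invariance fails, cross-group *mean* comparisons are refused
while variance and shape comparisons remain available.

## Estimation: two-step polychorics and DWLS/WLSMV

Estimation starts from each group's univariate thresholds
($\hat\tau_s = \Phi^{-1}(\hat p_s)$) and pairwise polychoric correlations
(two-step maximum likelihood with thresholds fixed, Olsson-style). The
asymptotic covariance of the stacked statistics is assembled from
per-child influence functions; the correlation influence functions carry
the delta-method correction for the estimated thresholds. Model parameters
minimise the diagonally weighted discrepancy

$$F = \sum_c (s_c - \sigma_c(p))' \,\mathrm{diag}(W_c)^{-1}\, (s_c - \sigma_c(p)),$$

and the *full* weight matrix is used afterwards for sandwich standard
errors and the mean-and-variance-adjusted (WLSMV) test statistic: $F$ is
asymptotically a weighted sum of chi-squares with weights the eigenvalues
of $U\Gamma$, and matching its first two moments gives a scaled statistic
with fractional degrees of freedom. The test suite checks the empirical
size of this test against its nominal 5% level by simulation.

Numerical choices:

* Bivariate normal rectangle probabilities use the arcsine-substitution
  single-integral representation evaluated by 64/96-point Gauss-Legendre
  quadrature; against adaptive 1-D integration the error is at machine
  precision for $|\rho| \le 0.999$, and the degenerate limits are used
  beyond. The correlation search is bounded at $|\rho| \le 0.999$;
  estimates at the bound (e.g. duplicated items) are flagged
  `near_singular`.
* Empty cells contribute nothing to the pairwise likelihood; no continuity
  corrections are applied, because silent cell smoothing changes test
  statistics. An item observed in a single category is a hard error.
* The implied-moment map is plain algebra, so its Jacobian is computed by
  central finite differences (step $10^{-6}\max(1,|p|)$, accurate to about
  $10^{-9}$ relative); an analytic derivative for every level-by-
  parameterisation combination would add much surface for error and no
  measurable precision.
* The optimiser is Levenberg-Marquardt on the weighted residual vector
  (`minpack.lm::nls.lm`, `ftol` $10^{-14}$), with up to two deterministic
  restarts. Convergence is declared on a curvature-scaled relative
  gradient below $10^{-4}$: at verified optima the finite-difference noise
  floor of the raw gradient is around $10^{-5}$ on this scale, so a
  tighter absolute criterion would not be measurable. Start values seed
  thresholds at their observed stage-1 estimates and use slightly varied
  loading starts to avoid symmetric degeneracies; identification is
  checked by the Jacobian's column rank at the start values.

## Factor scores and inequality statistics

Scores are Empirical Bayes Modal: per child, the maximiser of the ordinal
probit likelihood times the group's $N(\kappa_c, \Phi_c)$ prior, computed
with the group's own intercepts and factor covariance (intercepts are not
assumed invariant). The log-posterior is concave, so scoring runs a damped
Newton iteration vectorised over unique response patterns, with a BFGS
fallback; a brute-force grid maximiser over $[-4,4]^2$ serves as the test
oracle. Scores are reported in reference-group standard deviation units
(BCS males by default), dividing by that group's *score* standard
deviation, so the reference group has mean 0 and SD 1 by construction. EBM
scores are shrunken towards the prior mean; consequences (attenuated
regression coefficients, compressed gaps) are handled by simulation-based
oracles in the tests, and no shrinkage correction is applied.

Inequality is summarised by sample-quantile differences (90–10, 75–25,
50–10, 90–50; linear-interpolation quantiles, the common default, fixed
because conventions shift gaps at small $n$) and the variance, with
stratified child-level bootstrap percentile intervals (default $B = 1000$,
smaller in tests), plus two-sample Kolmogorov-Smirnov comparisons of
distribution shape. All of these are location-invariant, which is exactly
why they remain interpretable across cohorts when mean comparisons are
refused. Covariate gradients are reported as within-group mean differences
against a reference category, never as absolute cross-cohort levels.

## Reweighted RIF decomposition

Changes in a distributional statistic between cohorts are decomposed in two
stages. A logit of target-cohort membership on the covariates gives
propensity-odds weights that reweight the source cohort to the target's
covariate distribution; RIF (recentered influence function) regressions in
the source, target and counterfactual samples then split the total change
into composition and coefficient effects with exact per-covariate detail:

$$\Delta = (\bar X_C - \bar X_0)'\beta_0
  + \bar X_C'(\beta_C - \beta_0)
  + \bar X_1'(\beta_1 - \beta_C)
  + (\bar X_1 - \bar X_C)'\beta_C,$$

the four terms being composition, specification error, coefficient effect
and reweighting error. Adding-up is exact by construction (the total is
the difference in mean RIF, and least squares passes through means), and
the tests assert it to $10^{-10}$. Densities at quantiles use a Gaussian
kernel with Silverman's bandwidth (Epanechnikov available, echoing the
score-density plots); propensities are trimmed to $[0.01, 0.99]$ with
counts logged; the full procedure is bootstrapped (default $B = 500$).

One methodological caveat the tests made explicit: for quantile statistics
the specification error is a genuine second-order term — under a large
composition shift it is nonzero in population even when the outcome model
is exactly linear, because the RIF is a first-order expansion of the
functional. For the variance the expansion is exact apart from a
mean-shift term, so a mean-preserving composition-only population puts
100% of the change into the composition effect; that is the configuration
used for the attribution check.

## Outcome regressions

Later outcomes are regressed on the estimated skill scores (plus
covariates, optionally plus a per-cohort cognitive score) by least
squares; binary outcomes run as linear probability models to keep the
means-plus-coefficients reporting layout. Standard errors bootstrap the
*entire* two-step procedure: each replicate resamples children within
group, re-fits the multi-group measurement model, re-scores and re-runs
the regression (a fast mode that skips the measurement refit exists for
inner loops and tests). Cross-cohort coefficient equality is tested from
the bootstrap distribution of the paired coefficient difference. The
cognitive score is a one-factor ULS extraction with Thomson regression
scoring on the continuous cognitive measures, standardised within cohort
and deliberately never compared across cohorts.

## The synthetic generator: what it emulates, what it does not

The study data are restricted-access, so the generator emulates their
statistical structure and the defaults *are* the study conditions: four
groups (two cohorts by gender) of sizes 4800/4745/2800/2772 (cohort totals
9545 and 5572); standardised loadings between 0.5 and 0.8; skewed
category splits (most children well-behaved); an EXT–INT correlation of
0.5; factor SDs 20% larger in the later cohort (wider skill dispersion);
and reporting shifts of $\pm 0.2$ on the intercepts of items 1, 4, 7 and
10 in the later cohort, so that threshold+loading invariance holds while
intercept invariance fails — the partial-invariance configuration the
ladder is designed to detect. Cohort-level covariate distributions follow
the published summary statistics of the two studies (e.g. maternal
post-compulsory education 38% vs 57%, unmarried 5% vs 36%, smoking in
pregnancy 39% vs 20%, maternal age 25.9 vs 29.4), and covariate effects on
skills are signed accordingly (education positive, smoking negative, ...),
with the residual factor covariance chosen so the marginal
$\mathrm{Var}(\theta)$ equals its target exactly. Outcomes depend on both
skills and covariates with the signs found in the study tables
(externalising negative on smoking and BMI, internalising mildly
positive).

Features of real cohort data deliberately *not* emulated: the later
cohort's stratified sampling design and oversampling, attrition and item
non-response (the generator emits complete cases; the loader enforces and
counts the complete-case rule), judgement-based item harmonisation
(already-harmonised items are emitted), and covariate dependence (the
generator draws covariates independently within group, so real-world
covariate correlations — and any composition effects flowing through them
— are absent). Latent skills are normal mixtures over covariate cells
rather than exactly normal; effects are small enough that the probit
formulas hold to a few parts per thousand, and calibration tests that
require exactness zero the covariate effects. Passing tests therefore
demonstrate correctness of the estimators under the assumed model, not
robustness to design features the generator omits.

## Simulation sizes used by the tests

Chosen to give each check adequate power while keeping a full run around
fifteen minutes: oracle equivalence on a 2,000-child sample (all 55 item
pairs) and 100 grid-checked children; parameter recovery at
$n = 10{,}000$ per group; ladder classification over 50 replications per
population at $n = 5{,}000$ per group; robust-test and equality-test size
over 100 replications at two groups of $n = 2{,}000$ with $B = 100$;
decomposition attribution at $n = 10{,}000$ per group. The acceptance
script re-runs the full default-size study end to end.

## Known limitations

* Full-information maximum likelihood for ordinal items, MIMIC models,
  partial-invariance search, alignment methods and Bayesian approximate
  invariance are out of scope.
* EBM scores are modal, not plausible values; no score-uncertainty
  propagation into the inequality statistics beyond the bootstrap of the
  scores-producing pipeline.
* Survey weights are not supported anywhere in the chain.
* The RIF decomposition is linear in the covariates; quantile-regression
  (Machado-Mata) and distribution-regression alternatives are not
  provided.
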