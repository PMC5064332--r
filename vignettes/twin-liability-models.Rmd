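---
title: "Variance decomposition of ordinal twin data under the liability-threshold model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance decomposition of ordinal twin data under the liability-threshold model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinlia)
```

## The model

twinlia analyses ordinal phenotypes — its motivating case is a four-level
depression severity score in adult female twins — with the classical twin
design. The observed category for each individual is assumed to arise from a
latent standard-normal *liability* cut at fixed thresholds
$\tau_1 < \dots < \tau_{K-1}$; with $K$ categories and category prevalences
$p_1, \dots, p_K$ the thresholds are the normal quantiles of the cumulative
prevalences. Thresholds are taken to be identical for both members of a pair
and for both zygosity groups, since severity is assessed with the same
instrument throughout.

Within a pair, the two liabilities are bivariate normal. Decomposing each
liability into additive genetic (A), dominance deviation (D), shared
environment (C) and residual environment (E) factors, with standardized
variance proportions $a^2 + c^2 + d^2 + e^2 = 1$, genetic theory fixes the
cross-twin factor correlations (A: 1 in MZ, 0.5 in DZ; D: 1 and 0.25;
C: 1 and 1; E: 0) and hence the liability correlations

$$r_{MZ} = a^2 + c^2 + d^2, \qquad r_{DZ} = \tfrac12 a^2 + c^2 + \tfrac14 d^2.$$

With only these two statistics, C and D cannot be estimated jointly (the
ACDE model is not identified), which is why the package offers the
ADE, ACE, AE, CE, DE and E models.

## Estimation pipeline

1. **Scoring** (`idsm_score`, `score_cohort`). The four-level severity score
   is built from six yes/no questionnaire answers as an ordinal chain: mild
   requires a self-reported lifetime episode (postnatal-only depression is
   scored 0), moderate additionally a GP or psychiatrist diagnosis, and
   severe/recurrent additionally defined medication and/or more than one
   treated episode. We require each level to include the criteria of the
   levels below it — the instrument describes the levels as increasing
   severity, so e.g. medication without any diagnosis scores mild, not
   severe. Missing answers are never defaulted: records are excluded with a
   reported count.

2. **Double entry** (`double_enter`). Twins within a pair are
   interchangeable and the data carry no meaningful ordering, so each pair
   enters the $K \times K$ table twice, once in each order. The table total
   is twice the pair count; standard errors are computed on the effective
   number of independent pairs, not the doubled total.

3. **Polychoric correlation** (`fit_polychoric`). Two-stage estimation:
   thresholds are fixed at the normal quantiles of the marginal cumulative
   proportions, then the latent correlation maximizes the multinomial
   log-likelihood $\sum_{ij} n_{ij} \log p_{ij}(\tau, \rho)$ by
   one-dimensional optimization. The standard error comes from the curvature
   of the profile log-likelihood, inflated by the double-entry factor. This
   reproduces the correlation-level quantities of a two-group categorical
   analysis without requiring raw-data AGLS machinery; two-stage estimation
   is known to lose very little efficiency relative to joint maximum
   likelihood, and we verified empirically (1,500 replicates at 725 pairs)
   that the reported standard errors match the Monte-Carlo spread of the
   estimator to within a few percent.

4. **Model fitting** (`fit_model`). Each model is fitted by constrained
   weighted least squares on the two correlations,
   $$\chi^2(\theta) = \Big(\frac{r_{MZ} - \rho_{MZ}(\theta)}{se_{MZ}}\Big)^2 +
     \Big(\frac{r_{DZ} - \rho_{DZ}(\theta)}{se_{DZ}}\Big)^2,$$
   subject to non-negative variance proportions summing to at most one.
   Because the implied correlations are linear in the proportions, the
   objective is a convex quadratic and is solved exactly by enumerating the
   active constraint sets — no iterative optimizer, no convergence
   tolerance. An exhaustive grid search over the free simplex serves as the
   independent oracle in the test suite.

5. **Inference** (`compare_nested`, `falconer_heritability`). Nested models
   are compared by the chi-square difference with df equal to the difference
   in nominal free-parameter counts; Falconer's formula
   $H^2 = 2(r_{MZ} - r_{DZ})$ gives the broad-sense heritability, which under
   the model equals $a^2 + 1.5\,d^2$.

`run_full_analysis` chains these stages, optionally after randomly
downsampling the larger zygosity group to the smaller one (a two-group
analysis weighs both groups equally), and optionally repeats the analysis
with the most severe category removed.

## Conventions and edge cases

* **Degrees of freedom.** We fit two statistics, so `df = 2 - (free
  parameters not clipped at a boundary)`. A saturated model (ADE or ACE)
  with an interior solution has `df = 0`, `chi2 = 0`, `p = 1`. When a
  component is clipped at zero — e.g. `c2` whenever `r_DZ < r_MZ/2` — the
  model collapses onto its reduced neighbour (ACE onto AE) and both then
  report identical chi-square *and* identical df. Published tables fitted by
  raw-data AGLS count threshold parameters in their df; that bookkeeping is
  deliberately not reproduced, and boundary collapses are reported
  explicitly via `boundary` flags rather than silently.

* **Boundary null of the dominance test.** The AE-vs-ADE comparison uses the
  plain $\chi^2_1$ difference test. Because $d^2 \ge 0$, the null
  distribution is in truth a 50:50 mixture of a point mass at zero and
  $\chi^2_1$, so the plain test is conservative (empirical size about half
  the nominal level). We keep the plain test because it is the convention of
  the source analyses this package mirrors; the conservatism is visible in
  the size-calibration test.

* **Numerical choices.** Bivariate normal rectangle probabilities use a
  vectorized 24-point Gauss–Legendre quadrature of the arcsine-substituted
  single-integral identity, accurate to well below $10^{-8}$ across
  $|\rho| \le 0.995$ (verified against `mvtnorm::pmvnorm` in the tests);
  cells are floored at $10^{-30}$ inside the log-likelihood; the correlation
  search is confined to $[-0.995, 0.995]$ with boundary estimates flagged;
  categories with empty margins are collapsed with a warning; a cumulative
  marginal proportion of exactly 0 or 1 at an interior cut is an error
  instructing category collapse rather than a silent fix.

* **Severity restriction.** The restricted arm drops every pair in which at
  least one twin scores in the top category and refits with $K-1$ categories
  and freshly estimated thresholds. Dropping (rather than recoding, which is
  available as `restricted_mode = "recode"`) matches a reduced pair count in
  the motivating analysis; re-estimating thresholds is the natural choice
  once the sample changes.

## The synthetic-data generator

`simulate_twin_pairs` draws each pair's liabilities directly from the
implied bivariate normal and discretizes at the thresholds. The default
prevalences are 63/8/14/15% over the four severity levels — the distribution
reported for the motivating cohort, implying an overall "any depression"
prevalence of 37% — and the component-wise construction (separate A/C/D/E
factor draws) is available as `method = "pathwise"` for didactic checks that
the two constructions agree. A master seed deterministically spawns
per-zygosity substreams.

The generator emulates exactly what the analysis model assumes: bivariate
normal liabilities, thresholds common to twins and zygosity groups, no age
or cohort structure, no sex limitation, no assortative mating, no
measurement unreliability beyond what the threshold model absorbs into
$e^2$. Passing recovery tests on these data therefore demonstrates the
correctness of the estimation chain under its own assumptions, not
robustness to the many ways real registry data violate them (age-varying
thresholds, item missingness, zygosity misclassification).

## Power analysis for detecting dominance

`power_reject_ae` estimates, by simulation, the probability that the df = 1
difference test rejects a false AE model when the generating truth contains
dominance; `required_n` finds the total pair count reaching a target power
by bisection on the simulated power curve, smoothing all evaluated points by
isotonic regression (power is monotone in n) so that Monte-Carlo noise
cannot derail the bracket. Replicates with degenerate tables (possible in
small dichotomous samples) are resampled and counted.

Two properties of this design are worth stating plainly. First, the power to
detect dominance depends strongly on how the categories are populated: the
default 63/8/14/15 distribution concentrates most mass in one category and
carries far less information about the latent correlation than equally
populated categories would, so power at a few thousand pairs is modest, and
the simulated requirement for 80% power under the default prevalences is
substantially larger than under balanced categories. Second, a dichotomous
trait at 10% prevalence is dramatically worse again — the simulation
reproduces the classical conclusion that rejecting a false AE model then
needs in excess of twenty thousand pairs. The exact simulated numbers are
computed by `scripts/acceptance.R` and the acceptance tests rather than
quoted here.

Problem sizes were chosen to make the Monte-Carlo error small relative to
the quantities of interest: 1,000 replicates for a single power estimate
(MC se below 1.6 percentage points), 400–500 replicates per evaluated n
inside the bisection, 50,000 pairs per group for parameter-recovery checks,
and 100,000 individuals for generator calibration.

## Known limitations

* Estimation is correlation-level WLS, not raw-data full-information AGLS;
  data-dependent fit statistics of published raw-data analyses are not
  reproducible from correlations alone.
* No age, sex-limitation, or gene–environment interaction modelling.
* Polyserial (ordinal–continuous) correlations are out of scope; all
  variables here are ordinal.
* The parsimony-guided model selection in `run_full_analysis` follows the
  fixed ADE-rooted testing chain (E, DE, AE against ADE); it is a
  transparent convention, not an exhaustive model search.
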