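---
title: "Methods: trait-based extinction-risk analysis for chondrichthyans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait-based extinction-risk analysis for chondrichthyans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chondrorisk)
```

## The problem

Sharks, rays, and chimaeras (class Chondrichthyes) are slow-growing,
late-maturing fishes that are exceptionally sensitive to fishing mortality.
Global Red List assessment of the ~1,041 described species classifies each
as CR, EN, VU (collectively "threatened"), NT, LC, or Data Deficient (DD) —
and nearly half are DD. `chondrorisk` implements the statistical pipeline
around such an assessment: summarizing status by group, modelling the
trait correlates of threat, predicting the status of DD species and
apportioning them across categories, locating spatial hotspots of threat
and irreplaceability, and summarizing fisheries landings trends. Every
stage runs end-to-end on synthetic data with known ground truth, so the
pipeline is testable without any restricted supplementary data.

## The threat model

The binary response scores a species 1 if threatened (CR/EN/VU) and 0 if
LC. NT and DD species are excluded from the response — NT deliberately (it
is neither clearly threatened nor clearly safe), DD because its status is
unknown. For species $i$ with standardized traits $X_{ij}$ the probability
$p_i$ of being threatened follows a binomial GLMM with logit link:

$$\log\frac{p_i}{1-p_i} = \beta_0 + \sum_j \beta_j X_{ij} + u_{\mathrm{order}(i)} + u_{\mathrm{family}(i)} + u_{\mathrm{genus}(i)},$$

with nested taxonomic random intercepts absorbing phylogenetic
non-independence. The traits are maximum body length (cm TL), minimum
depth (m), depth range (max − min depth, m), and geographic range (Extent
of Occurrence, km²). For the *explanatory* models, traits are standardized
to z-scores ([`standardize()`]); collinearity is screened with variance
inflation factors ([`variance_inflation()`], all < 2 in the source data).
`fit_logistic_glmm()` fits the model by approximate maximum likelihood
(Laplace approximation, via `lme4`); fixing all variance components at
zero makes the marginal likelihood equal the GLM likelihood exactly, so
the mixed fit reduces to `fit_logistic_glm()` — a property the tests
exploit as a degenerate-case oracle.

Model comparison uses the small-sample Akaike criterion
$\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$, Akaike weights, and
per-variable importance (the summed weights of models containing the
variable). For GLMMs, $k$ counts fixed effects plus variance components.
Variance explained follows the Nakagawa–Schielzeth decomposition with
$\pi^2/3$ as the logit-link residual variance:
$R^2_m = \sigma^2_f/(\sigma^2_f+\sigma^2_r+\pi^2/3)$ and
$R^2_c = (\sigma^2_f+\sigma^2_r)/(\sigma^2_f+\sigma^2_r+\pi^2/3)$.

The probability-scale effect of a one-SD trait increase is computed
verbatim as $1/(1+e^{\beta_0+\beta_1}) - 1/(1+e^{\beta_0+2\beta_1})$
(`effect_size_pct()`). Note this uses $1/(1+e^{x})$ — the *complement* of
the standard logistic — so the sign convention is idiosyncratic; only the
magnitude, and the antisymmetry in $\beta_1$, should be interpreted.

## Predicting Data Deficient species

The *predictive* models are plain GLMs of increasing complexity on
log10-transformed traits, fitted to the threatened-vs-LC species
(`fit_model_sequence()`). Minimum depth can legitimately be 0 m, so depth
variables are transformed as $\log_{10}(x+1)$; length and EOO, strictly
positive, as $\log_{10}(x)$. Each model reports AICc, weight, in-sample
AUC (the Mann–Whitney pair probability with ties counted ½), and
Nagelkerke pseudo-R². DD species with the predictors present are scored;
those with $\hat p \ge 0.5$ are classified as likely threatened
(`predict_dd()`; the ≥ boundary is deliberate). `choose_threshold()`
provides the confirmatory accuracy scan over the 0–1 threshold grid, with
ties broken toward 0.5.

Scored-but-not-threatened DD species are apportioned between NT and LC
using the observed NT:LC ratio $r$ (`apportion()`). Two readings of
"distributed according to the ratio" exist: treating $r$ as a *share*
(`NT = round(r \cdot \text{remainder})`) reproduces the published
312/389/91 counts exactly and is the default; treating it as *odds*
($r/(1+r)$) is what the phrase literally implies and is available as
`mode = "odds"`. Rounding is half-away-from-zero with the remainder
assigned to LC, so the grand total is conserved exactly.

A structural caveat the synthetic world makes visible: because the
classifier is trained on threatened-vs-LC species only, it estimates
$P(\mathrm{THR} \mid \mathrm{THR}\cup\mathrm{LC})$, which exceeds the
unconditional threat probability whenever some DD species would truly be
NT. On simulated data the threshold count is well calibrated *within the
threatened-or-LC universe* (mean error below half a percentage point
across replicates) but over-predicts the unconditional threatened
fraction by several points. The acceptance test asserts calibration in
the response universe and this limitation is documented rather than
corrected, mirroring the published procedure.

## Tabulation and the family threat test

`summarize_categories()` reproduces the published table conventions:
group size as a percent of the grand total, threatened count as a percent
of the group, and per-category percentages relative to either denominator
(the all-taxa table uses the grand total, the by-habitat table the
group). Printed values round half-away-from-zero to 1 d.p.
(`round_half_away()`).

`family_binomial_test()` compares each family's threatened fraction among
data-sufficient species to a common null rate with exact one-tailed
binomial tail probabilities — families are small, so no normal
approximation is used, and both tails include $P(X=k)$. The null rate is
an input: the published 35.6% is not derivable from the printed totals
(181/554 = 32.7%), so `default_null_rate()` computes
threatened/data-sufficient from the supplied table and nothing is
hard-coded. Regional assessments are combined by mapping LC…CR to 0…4,
averaging over non-DD regions, and rounding half away from zero
(`combine_regional_categories()`); the rounding direction is a package
choice where the source is silent.

## Spatial scores

The cartographic machinery (icosahedral hexagon grids, kriging smoothing)
is deliberately abstracted away: the unit of analysis is a generic
equal-area incidence matrix (`incidence_matrix()`, nominally ~23,322 km²
cells). Per-cell counts of all/threatened/DD/data-sufficient species
(`cell_counts()`) feed a residual-threat regression
(`residual_threat()`): OLS of threatened on data-sufficient counts, whose
positive residuals mark greater-than-expected threat. Irreplaceability
scores each species as the reciprocal of its occupied-cell count; the
cell statistic is either the sum of reciprocals (the figure-caption
definition) or the mean of their log10 (the methods-text definition,
which controls for richness) — the two definitions genuinely disagree in
the source, so both are first-class variants and the choice is recorded
in the output metadata. Cells with no qualifying species are `NA`, not 0,
so map quantiles are not diluted. Endemics are species with EOO strictly
below a threshold (50k/100k/250k/500k km² canonical).

## Fisheries landings

`clean_landings()` implements the published cleaning rules: `"<0.5"` →
0.5 t, `"."` → 0 t and counted as missing; `missing_fraction()` reports
the missing share (1,522 of 13,990 entries → 10.88%, printed as 11%).
`decade_share()` averages each country's annual total over an inclusive
window (default 2000–2009) and normalizes shares to 100%.
`ray_shark_log_ratio()` drops the undifferentiated aggregate and chimaera
categories, then takes the yearly log of ray over shark tonnage; the log
base is configurable (natural log default) because only sign and
zero-crossing are interpreted. `decline_from_bmsy()` converts a
$B/B_{MSY}$ ratio and an assumed $B_{MSY}$ fraction of unexploited
biomass into a percent decline; the printed "declined by between 81% and
89%" corresponds to outward rounding of 81.5 and 88.9
(`decline_interval()`).

## The synthetic world

`simulate_species()` draws a 1,041-species world whose defaults are the
observed structure, fixed once and not tuned: log-normal length around
80 cm; EOO spanning ~354 km² to 278 million km² with latent correlation
0.58 with length; 46% deepwater; true threat from the logistic model
above; threatened species split CR:EN:VU = 25:43:113 and the rest
NT:LC = 132:241; DD masking at 38.4% (shallow) vs 57.6% (deepwater), so
missingness is depth-dependent and the imputation test is honest about
non-random masking. Values the source does not state — taxonomy shape
(13 orders × 4 families × 4 genera), trait dispersions, random-effect SDs
(0.25/0.6/0.25), the EOO–cell placement — were chosen once as field-
realistic and documented here. `simulate_incidence()` places each species
on a contiguous cell block approximating its EOO to within one cell;
`simulate_landings()` injects the missing/`<0.5` tokens at the observed
rates and gives rays a configurable upward trend. All generators are pure
functions of (config, seed).

What a green test does establish: the arithmetic identities, the exact
oracles (closed-form OLS, pair-enumeration AUC, pmf enumeration), and
parameter recovery/calibration under the generative model. What it does
not: agreement with the real species data (the confidential supplementary
tables are not shipped), cross-validated predictive skill (AUC is
in-sample, as published), or robustness to trait error and taxonomic
misclassification, none of which the synthetic world models.

## Numerical choices and limitations

* GLMM convergence and singular fits are flagged, not hidden; a variance
  component estimated at the zero boundary is legitimate output.
* Wald intervals for GLMM fixed effects undercover slightly with few
  clusters (52 families); the recovery tests measure empirical coverage
  across coefficients and replicates rather than demanding per-coefficient
  perfection.
* AICc comparisons require a common n; `fit_model_sequence()` therefore
  fits all models on the common complete-case subset.
* Complete separation in logistic fits raises an explicit warning naming
  the covariate; an invariant response is an error.
* Percentages are reported unrounded, with `round_half_away()` applied
  only at the printing boundary.
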