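---
title: "Multi-site meta-analysis of trait-morphometry associations: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-site meta-analysis of trait-morphometry associations: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roimeta)
```

## The problem

Large consortium studies of brain morphometry cannot pool raw scans: each
cohort measures a trait with its own questionnaire, scans on its own
hardware, and can only share summary statistics. The standard workflow is
therefore two-staged. Each site fits the same covariate-adjusted model and
reports a per-region effect size; a random-effects meta-analysis then
pools those effects region by region, with multiplicity control across
regions and moderator tests for site-level differences. A second,
distinct question is whether the resulting *map* of effect sizes
resembles published case-control effect-size maps of psychiatric
disorders — a question of spatial pattern similarity, where ordinary
correlation p-values are invalid because neighbouring parcels are not
independent.

`roimeta` implements both stages, plus a synthetic multi-site cohort
generator with known ground truth so every stage can be calibrated
without access to any real cohort.

## Site-level model: adjusted partial correlations

For subjects of one site, the association between the trait $t$ and the
morphometry of region $j$, given covariates $C$ (age, sex, a global
measure such as mean cortical thickness or ICV, optional smoking status,
and $m-1$ scanner indicators for an $m$-scanner site), is the partial
correlation

$$ r_j = \mathrm{cor}\{\,t - \hat t(C),\; y_j - \hat y_j(C)\,\}, $$

where $\hat\cdot(C)$ is the least-squares projection onto $[\,1 \mid C\,]$.
The intercept column is always included: correlating non-centred
residuals is ill-defined otherwise. The two-sided p-value uses
$t = r\sqrt{\nu/(1-r^2)}$ with $\nu = n - 2 - k$ degrees of freedom
($k$ = covariate columns after dummy expansion). The test suite checks
this residual-based computation against an algebraically independent
route, the inverse of the correlation matrix of $(t, y_j, C)$, to
$10^{-10}$.

Complete-case filtering is per region: a missing region value removes the
row only for that region, while a missing trait or covariate removes it
everywhere. This maximizes the usable $n$ per region; whether the
original consortium pipelines filtered listwise is not documented
anywhere we could verify, and per-region filtering is the choice that
wastes no data. A site contributes to a region only when
$n - k - 2 \ge 10$; ten residual degrees of freedom is the floor below
which the $t$ approximation (and the Fisher-z variance) stops being
trustworthy.

## Pooling: random-effects meta-analysis

Per-site correlations are transformed before pooling. The default is
Fisher's $z = \operatorname{atanh}(r)$ with covariate-adjusted variance
$1/(n - 3 - k)$; a `raw_r` mode ($v = (1-r^2)^2/(n-1)$) is provided
because consortium reports often state only that "Pearson's r effect
sizes were meta-analyzed" without naming a transform. Both modes are
exercised in the tests; the Fisher default is the variance-stabilized,
better-behaved choice at these effect sizes.

Under the additive heterogeneity model $y_i \sim N(\mu, v_i + \tau^2)$
two estimators of $\tau^2$ are available:

* **DerSimonian–Laird** (closed form): with $w_i = 1/v_i$,
  $Q = \sum w_i (y_i - \bar y_w)^2$ and
  $\tau^2 = \max\{0, (Q - (k-1)) / (\sum w_i - \sum w_i^2 / \sum w_i)\}$.
* **REML** (default, matching the convention of standard meta-analysis
  software): the unique root of the restricted-likelihood score is found
  by bracketed root-finding to tolerance $10^{-12}$ (raw Fisher scoring
  oscillates slowly near small $\tau^2$ at these study sizes, so a
  bracketed solver is both faster and exact). If root-finding fails, the
  function falls back to DL and flags the result.

The pooled mean uses weights $1/(v_i + \tau^2)$; its 95% interval is
computed on the z scale and back-transformed through $\tanh$, so
intervals are deliberately asymmetric on the $r$ scale. The p-value is
the normal approximation $z = \mu/\mathrm{se}$, the convention of the
field's standard tooling. $Q$ and $I^2 = \max\{0,(Q-(k-1))/Q\}\cdot 100$
summarize heterogeneity.

Categorical site-level moderators (questionnaire type, scanner count,
field strength, software version) are tested by mixed-effects
meta-regression: indicator columns for the levels, residual $\tau^2$ by
the same REML machinery, and the omnibus Wald statistic $Q_M$ for all
non-intercept coefficients against $\chi^2_{(\text{levels}-1)}$.

Benjamini–Hochberg FDR is applied **within one modality's region set**
(e.g. across the 68 cortical-thickness parcels), not globally across
modalities: each modality is a separate family of models and the
separate-family choice is the conservative reading of per-modality
analyses. Regions pooled from a single site are reported but flagged and
excluded from the FDR family rather than silently mixed in.

## Spatial pattern similarity

Two cortical maps on the same parcellation are compared by Pearson
correlation; significance comes from a spin permutation null that
preserves spatial autocorrelation. Parcel centroids live on the unit
sphere; each permutation draws a rotation uniformly from SO(3) (QR
decomposition of a Gaussian matrix, sign-corrected, determinant forced to
+1), rotates the left-hemisphere centroids by $M$ and the right by the
mirrored rotation $FMF$ (reflection through the $x=0$ plane, so the two
hemispheres remain mirror-consistent), and reassigns each original parcel
the value of the nearest rotated parcel within its own hemisphere. The
observed correlation is referred to the null distribution of spun-vs-intact
correlations with the add-one estimator $p = (1+b)/(1+m)$, which can
never return zero.

Design choices the literature leaves open, fixed here:

* **Which map is spun**: the first argument (the trait map); the test is
  not exactly symmetric and the choice is logged in the result.
* **Tail**: two-sided by default — published reports often omit
  sidedness, and two-sided is the conservative default; one-sided tails
  are available.
* **Duplicates**: nearest-centroid reassignment permits duplicates (a
  source parcel may be used twice in one rotation while another is
  dropped). A greedy one-to-one variant (`one_to_one = TRUE`) is provided
  because published implementations differ; only that variant preserves
  the per-hemisphere multiset of values exactly.
* **Ties** in the nearest-centroid search break to the lowest index —
  measure-zero events under random rotations, fixed only for determinism.

Subcortical structures have no spherical embedding, so their maps are
compared by Spearman rank correlation with a label-shuffle null (uniform
permutations of one map's labels). The default subcortical set is the 14
bilateral grey-matter structures (thalamus, caudate, putamen, pallidum,
accumbens, hippocampus, amygdala); lateral ventricles can be appended
(`subcortical_region_names(include_ventricles = TRUE)`) since published
region sets are ambiguous on this point.

Two dependent similarity coefficients sharing the trait map $j$ are
compared with Steiger's test: with $\bar r = (r_{jk}+r_{jh})/2$,

$$ Z = \{\operatorname{atanh}(r_{jk}) - \operatorname{atanh}(r_{jh})\}
\sqrt{\frac{n-3}{2 - 2c}},\qquad
c = \frac{r_{kh}(1-2\bar r^2) - \tfrac12 \bar r^2 (1-2\bar r^2 - r_{kh}^2)}
{(1-\bar r^2)^2}, $$

with $n$ the number of regions, passed explicitly because the effective
sample size of a map comparison is itself a modelling choice. The
one-tailed p tests $r_{jk} > r_{jh}$. Applying the test to Spearman
coefficients (as is common for subcortical maps) is an approximation.

## The synthetic cohort generator

`simulation_scenario()` fixes the study conditions; `generate_cohort()`
realizes them. The defaults emulate the structure of a large multi-site
schizotypy-morphometry study: 29 sites totalling ~3,004 subjects (every
site at least 30, sizes lognormal-heterogeneous), ages spanning 12–68
within site-specific ranges, ~46.5% male, three multi-scanner sites with
additive scanner offsets (SD 0.05 units), site-specific affine
"questionnaire" scalings of a standard-normal latent trait, and true
region effects that are small and spatially smooth: a Gaussian-process
map over the parcel centroids with exponential covariance
$\sigma^2 e^{-d/\ell}$ ($\ell = 0.8$ rad, amplitude 0.02 on the
correlation scale — the $|r| \lesssim 0.07$ regime such studies report),
plus a per-site deviation with variance $\tau^2 = 0.001$, matching the
random-effects model under test.

Region values are built generatively:
$y = \text{baseline} + \beta_{\text{age}}\,\text{age} +
\beta_{\text{sex}}\,\text{sex} + \lambda g + \delta_{\text{scanner}} +
\gamma z + \varepsilon$, with baseline ≈ 2.5 (thickness-like units, mm),
$\beta_{\text{age}} \approx -0.01$ mm/yr (age-related thinning),
residual SD 0.12 mm, and a shared global factor $g$ that also defines the
`global` covariate column. Because the covariates are independent of the
latent trait $z$, the loading that yields a target partial correlation
$\rho$ has the closed form $\gamma = \rho\,\sigma/\sqrt{1-\rho^2}$ —
calibration is analytic, not rejection-sampled, and targets with
$|\rho| \ge 0.95$ are rejected as infeasible. A standardized-gamma
latent trait (`trait_distribution = "gamma"`) is available for
sensitivity analyses, since real questionnaire totals are right-skewed;
the calibration involves only second moments and is unaffected.

What the generator does **not** emulate: item-level questionnaire
structure, non-linear covariate effects, spatially structured scanner
artifacts, QC-driven missingness patterns, or cross-region residual
correlation beyond the shared global factor. Passing calibration tests
on these fixtures therefore demonstrates the statistical machinery is
correct under the stated model, not that real cohorts satisfy that
model.

## Numerical and reporting choices

* Atlas centroids within $10^{-6}$ of unit norm are renormalized; further
  off is an error. Geometry on subcortical regions errors rather than
  silently skipping, preventing accidental spin tests on subcortex.
* The Gaussian-process covariance gets a $10^{-8}$ diagonal jitter before
  Cholesky factorization.
* `effect_to_meta_input()` treats $|r| \ge 1 - 10^{-6}$ as a degenerate
  site under the Fisher transform.
* Report files are plain delimited text with a commented header echoing
  the configuration (hash, seed, model, sizes); reruns with the same
  configuration and seed are bit-identical, and subject tables serialize
  doubles at 17 significant digits so file round-trips are exact.
* Sex is coded 0/1; which sex is 1 does not affect the magnitude or the
  trait-association sign of the partial correlation.

## Problem sizes used by the test suite

The packaged tests calibrate each stage at the scale the method is meant
for: 200 replicate 29-site null cohorts for the meta-pipeline, 100
replicates for recovery of a planted $r = .067$ at $n = 3004$, 500
smooth-map pairs × 1,000 rotations for spin-test calibration, 10,000
trivariate-normal replicates for Steiger's test, and 1,000 replicates ×
1,000 permutations for the label-shuffle test. These sizes give binomial
Monte-Carlo intervals tight enough to detect meaningful miscalibration
while keeping the default suite quick to run.

## Known limitations

* The pooled p-value is the conventional normal approximation; with ~29
  sites its extreme tail is mildly anticonservative (a known property of
  the random-effects z-test — the Knapp–Hartung adjustment would fix it
  but is not the field's default), so under a global null the chance
  that *some* region survives BH across 68 parcels runs slightly above
  the nominal 5%. The calibration tests compute and document this.
* Steiger's Z on Spearman coefficients, and on spatially autocorrelated
  maps generally, treats $n$ regions as independent observations; treat
  subcortical comparisons as descriptive.
* The spin null conditions on the parcellation geometry supplied; the
  package deliberately treats centroid coordinates as an input rather
  than shipping any template.
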