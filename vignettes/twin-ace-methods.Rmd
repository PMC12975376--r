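---
title: "Methods: twin ACE variance decomposition of dietary traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin ACE variance decomposition of dietary traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietace)
```

## The scientific question

How much of the person-to-person variation in what young adults eat is
attributable to genetic differences? The classical twin design answers this
by comparing monozygotic (MZ) co-twins, who share essentially all of their
segregating alleles, with dizygotic (DZ) co-twins, who share on average
half. Under the equal-environment assumption — that trait-relevant
environmental sharing is equivalent for MZ and DZ pairs — any excess MZ
similarity is evidence of additive genetic influence, and the phenotypic
variance can be partitioned into additive genetic (A), shared environmental
(C) and nonshared environmental (E) components.

`dietace` implements that analysis end to end for dietary phenotypes
measured by a food-frequency questionnaire (FFQ): parsing and quality
control of the raw answers, conversion to daily intakes and food groups,
energy/nutrient estimation, a priori diet-index scoring (rMED, HNFI, PDI),
covariate adjustment, and maximum-likelihood ACE modeling with nested-model
selection. Because registry data of this kind cannot be redistributed, the
package also contains a first-class synthetic cohort generator with known
generating parameters, so every stage is testable and every reported number
is reproducible from code alone.

## The twin model

For a trait $y$ observed on both members of a twin pair, the model treats
the pair vector as bivariate normal with a common mean $\mu$ and variance
$\sigma^2 = a^2 + c^2 + e^2$ for every twin, and within-pair covariance

$$\operatorname{Cov}_{MZ} = a^2 + c^2, \qquad
  \operatorname{Cov}_{DZ} = \tfrac{1}{2} a^2 + c^2,$$

where $a^2$, $c^2$, $e^2$ are the A, C and E variance components on the raw
scale. The DZ genetic correlation is fixed at $1/2$ (the biometrical
expectation for additive effects) and is deliberately not configurable:
changing it silently changes the model. Reported components are the
standardized fractions $a^2/\sigma^2$ etc.; the A fraction is the
narrow-sense heritability estimate.

The log-likelihood is maximized directly. With equal means and variances
across twins and zygosity groups, the likelihood depends on the data only
through per-zygosity sufficient statistics
($n$, $\sum(y_1 + y_2)$, $\sum(y_1^2 + y_2^2)$, $\sum y_1 y_2$), which makes
each evaluation O(1) and the whole analysis fast enough to run hundreds of
simulation replicates in seconds. Parameters are path coefficients
$(a, c, e)$, squared into components, so the components are nonnegative by
construction; optimization is BFGS from five deterministic starts (one
moment-informed, four scaled perturbations). The submodels AE, CE and E fix
the absent paths at zero; free-parameter counts are 4 (ACE), 3 (AE, CE) and
2 (E), counting the mean.

### Model selection

Per trait, the workflow follows the usual funnel:

1. Pearson within-pair correlations by zygosity; $r_{MZ} > r_{DZ}$ flags a
   possible genetic signal, and Falconer's formula
   $h^2 = 2(r_{MZ} - r_{DZ})$ provides a rough moment estimate, reported
   for diagnostics only.
2. Assumption tests: Welch two-sample *t*-test for equal means and an
   *F*-test for equal variances between MZ and DZ individuals, against a
   Bonferroni-corrected threshold $0.05 / n_{\text{traits}}$. Failing
   traits are excluded from modeling and listed, not silently dropped.
3. The full ACE model and its nested submodels are fitted; each submodel is
   compared with ACE by a likelihood-ratio test (statistic clamped at zero,
   naive $\chi^2$ reference). The chosen model is the one with the lowest
   AIC among ACE and all submodels whose LRT against ACE has $p > 0.05$;
   ties break toward fewer parameters, then AE before CE.
4. The significance of A is judged by the ACE-vs-CE LRT, and those p-values
   are Benjamini–Hochberg adjusted across all analyzed traits.

The naive $\chi^2$ reference is conservative for variance components (the
null value lies on the boundary of the parameter space); the package's own
simulations measure an ACE-vs-CE type-I rate near 0.02 at a nominal 0.05,
consistent with the 50:50 mixture theory, and this conservatism is accepted
as standard practice in the twin literature.

### Confidence intervals

95% CIs for the standardized components are obtained by profile likelihood:
the component of interest is fixed on a grid, the remaining parameters are
re-maximized (the inner maximization over the mean and total variance is
closed-form; only the second free fraction of the ACE model needs a 1-D
numeric search), and the interval bounds solve
$2[\ell_{\max} - \ell_{\text{prof}}(h)] = \chi^2_{1,0.95}$ by root finding.
Intervals are truncated at the parameter boundaries 0 and 1. If root
finding fails, a delta-method interval from the curvature of the profile is
substituted and flagged in the output (`method = "delta"`). In simulation at
the package's reference scale (429 MZ + 987 DZ pairs), profile intervals
cover the generating value for 96–97% of replicates.

## FFQ processing

The questionnaire structure is held in an `ffq_schema`: 108 food items on a
9-level frequency scale, three portion-size photo questions (staple,
protein and vegetable plates, 4 levels), six taste-liking items (two each
for bitter, sweet and sour, 6 levels), an item-to-food-group map onto 30
groups, and an item-by-nutrient composition matrix (~40 nutrients,
per-gram).

Key processing rules:

* **Missingness before imputation.** The fraction of unanswered frequency
  questions is recorded first; records at or above 10% are excluded.
  Afterwards, remaining gaps (including "do not know" style codes, which
  the ingest treats as missing) are filled with the per-question median,
  rounding half-level medians down so the imputed value is a real answer
  category. Imputation therefore never rescues a failing record. Portion
  answers are never imputed: a missing portion indication is itself an
  exclusion.
* **Frequency map.** Levels 1–9 map to
  {0, 0.03, 0.1, 0.14, 0.43, 0.79, 1, 2, 4} intakes/day. The endpoints are
  pinned by the instrument's printed 0–4 intakes/day range; the interior
  values are conventional "times per month/week/day" midpoints and are
  fully overridable in the schema, since the instrument's exact map is not
  public.
* **Portions and nutrients.** Nutrient intake is
  $\sum_j \text{intakes/day}_j \times \text{grams}_j \times \text{content}_{jk}$,
  with grams built from a sex- and age-band-specific reference portion,
  the participant's portion-photo multiplier ({0.7, 1.0, 1.3, 1.6}) for the
  item's plate class, and a per-group scale factor (a pat of butter is not
  a plate of stew).
* **Plausibility screen.** Records are excluded for estimated energy
  below 500 or above 6000 kcal/day, physical activity level (PAL = energy
  intake / Schofield-type basal metabolic rate) below 0.3 or above 4, or
  BMI below 15 or above 140 kg/m²; all bounds strict. The PAL formula is
  explicit in the schema and swappable, since only its bounds are
  standard. After individual exclusions, both members of any incomplete
  pair are removed. The QC waterfall always reconciles:
  input = retained + excluded.

## Diet indices

Three a priori diet-quality indices are scored from the food-group
intakes, following the original definitions:

* **rMED** (0–18): nine components; six beneficial ones scored 0/1/2 by
  sex-specific tertiles of energy density (per 1000 kcal), meat and dairy
  reverse-scored, and alcohol scored 0/2 by a sex-specific moderate range
  (5–25 g/day women, 10–50 g/day men). The olive-oil component is computed
  from total vegetable oil, because the questionnaire does not separate
  olive oil from other cooking oils.
* **HNFI** (0–6): six components, one point each for intake strictly above
  the cohort median.
* **PDI** (18–90): eighteen components quintile-scored on the whole
  cohort, twelve plant groups ascending 1–5 and six animal groups reversed.

Cutpoints are computed within the analyzed cohort but are exportable and
importable, so small test cohorts (or external reference populations) can
be scored against fixed cutpoints. Ties at any cutpoint score into the
lower category; the original publications are silent on ties, and the
lower-category rule is the conservative choice. The exact component-to-food-
group mapping of this instrument is not public; the packaged default
follows the cited original index definitions and is config-overridable.

## Trait preparation

Each trait (30 food groups, total energy, ~39 nutrients, 3 indices, 3
composite + 6 single-item taste preferences, ~82 in all) passes through a
fixed order: **transform → residualize → standardize**.

* Skewness is the moment-based Fisher–Pearson $g_1$; traits with
  $|g_1| > 1$ (strictly) are $\log_{10}(x + 1)$-transformed. The +1 offset
  keeps zero intakes at zero and is a config knob; the choice matters only
  for zero-inflated intakes.
* Covariate sets are fixed per trait class: food groups and nutrients are
  adjusted for sex, body weight, total energy and a sex-by-energy
  interaction; energy for sex and weight; indices for sex, weight and
  energy; taste ratings for sex only. Missing body weight is imputed with
  the sex-specific median before use. Per-trait overrides are possible in
  code, since significance-based pruning of covariates is
  cohort-dependent and no universal final set exists.
* Residuals are standardized with the sample (n−1) SD; the output
  contract is mean 0 and SD 1 to 1e−8, and residuals are orthogonal to
  every design column.

Composite taste traits are the mean of the two item ratings in each taste
class (bitter, sweet, sour); the combination rule is configurable in code.

## The synthetic cohort generator

The generator is the package's substitute for registry data, and its
defaults are the study conditions the package is exercised under: 429 MZ +
987 DZ complete pairs (2832 individuals) at the reference scale, 59.5%
female, age ~24, MZ pairs same-sex and DZ pairs mixed, self-reported
height/weight with plausible BMI, and a latent "healthy diet" trait plus
three taste traits, all with user-specified A/C/E fractions (DZ genetic
correlation fixed at 0.5).

Item answers arise by cutting a latent Gaussian propensity at fixed
thresholds chosen to reproduce realistic marginal frequency distributions
(most items rarely eaten). The propensity is
$\lambda_g \cdot \text{diet}_i + \sqrt{1-\lambda_g^2}\,u_{ij}$, where the
group loading $\lambda_g$ is positive for vegetables, fruit, whole grains,
fish and the like, negative for sweets, snacks and processed meat, and the
item-specific part $u_{ij}$ carries the same ACE structure as the shared
trait. That last point matters: it makes every item — and hence every food
group, nutrient and index — inherit the specified variance fractions at the
latent level, rather than a loading-diluted fraction of them.

What the generator deliberately does **not** emulate: the true Swedish
consumption distribution (only the statistical structure the analysis
assumes), reporting biases correlated with adiposity, seasonal effects, and
assortative mating. Passing tests on synthetic cohorts therefore
demonstrate the correctness and calibration of the machinery, not the
field validity of any particular heritability estimate.

Two engineering choices keep the generator's ground truth exact:

* Records manipulated to be implausible (half "report nothing", half
  "report everything at maximum", plus optional BMI outliers) are labelled
  in a `truth` sidecar, and unmanipulated records are nudged — one ordinal
  level at a time, with energy evaluated on median-imputed answers exactly
  as the QC stage computes it — into a 620–5400 kcal margin (tightened per
  person so PAL stays inside its bounds). The set of QC-excluded
  individuals then equals the truth labels at any seed, which turns QC
  testing into exact set comparison. Records that cross the 10%-missingness
  threshold by chance are likewise labelled.
* All randomness flows from the single integer seed in the simulation
  spec; the generator restores the caller's RNG state, and identical seeds
  yield byte-identical cohort files.

### Attenuation

Cutting a Gaussian at 9 ordinal levels and mapping through the frequency
table attenuates observed-scale twin correlations relative to the latent
ones. At the reference scale with a generating $a^2 = 0.5$, the pipeline's
pooled chosen-model heritability over ~82 derived traits is about 0.34, and
mean twin correlations are about $r_{MZ} = 0.36$, $r_{DZ} = 0.17$. The AE
model is selected for the large majority of traits, as expected when C = 0.
This attenuation is a genuine property of ordinal measurement, not an
estimator bias: the same fitter applied to the latent pair values recovers
the generating fractions without bias (mean error < 0.002 over 200
replicates per setting).

## Numerical choices and verification

* **Oracle equivalence.** When moment estimates are interior, ML ACE
  estimates agree with the closed form
  $\hat a^2 = 2(r_{MZ} - r_{DZ})$, $\hat c^2 = 2 r_{DZ} - r_{MZ}$,
  $\hat e^2 = 1 - r_{MZ}$. The comparison is made on data standardized
  within zygosity: the closed form implicitly allows each zygosity its own
  scale, while the ML equates them, so sampling imbalance in group
  variances alone otherwise produces gaps up to ~0.04 at 2000+2000 pairs.
  Within-zygosity standardization — which is exactly what the
  equal-means/equal-variances assumption gate guarantees in expectation —
  removes that nuisance, and the agreement is then better than 0.002.
* **Degenerate inputs.** Zero-variance twin columns, all-missing
  questions, rank-deficient adjustment designs, non-nested LRT requests
  and empty cohorts all raise informative errors naming the offender.
* **Convergence.** Multi-start BFGS with a relative tolerance of 1e−12;
  the stored log-likelihood is reproducible from the stored parameters to
  1e−8, and the nesting chain
  $\ell_{ACE} \ge \ell_{AE}, \ell_{CE} \ge \ell_E$ holds for every fitted
  trait.
* **Problem sizes.** The test suite runs its simulations at the package's
  reference scale (429 + 987 pairs; 200 replicates for recovery and
  coverage, 100 for selection rates, 1000 for LRT calibration) and one
  full-scale end-to-end cohort of 2832 participants with ~82 traits —
  sizes chosen to give stable Monte-Carlo estimates while keeping a full
  run in a few minutes.

## Known limitations

* No sex-limitation, gene–environment interaction, dominance (ADE),
  multivariate/Cholesky or longitudinal models; the scope is univariate
  ACE and its submodels.
* The naive LRT reference is conservative at the boundary (documented
  above); FDR control is applied to conservative p-values and is therefore
  itself conservative.
* The packaged schema (item–group map, frequency map, portion sizes,
  composition matrix) is a documented synthetic stand-in, dimensionally
  faithful but not a nutrient database; results on real data require
  supplying the instrument's real schema.
* Heritability estimates are population- and context-specific and depend
  on the equal-environment assumption; the package quantifies sampling
  behavior, not those identifying assumptions.

## A compact worked example

```{r example, eval = FALSE}
cfg <- run_config(
  spec = simulation_spec(
    a2 = 0.5, c2 = 0, e2 = 0.5,
    n_mz_pairs = 429, n_dz_pairs = 987,
    covariate_effects = list(sex = 0.3, weight = 0.1),
    missing_rate = 0.02, implausible_fraction = 0.01, seed = 42
  )
)
report <- run_pipeline(cfg)
report$qc_waterfall
tidy(report$result)        # per-trait table: r_mz, r_dz, chosen model, a2 + CI, q
autoplot(report$result)    # heritability bars with profile-likelihood CIs
```
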