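---
title: "Methods: dietary selenium–mercury risk–benefit assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dietary selenium-mercury risk-benefit assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sehgrb)
```

## The problem

Fish and seafood are both the dominant dietary source of mercury for young
children and a key source of selenium and omega-3 fatty acids. Because Hg
binds Se with very high affinity and thereby depletes the Se available for
selenoprotein synthesis, the toxicological meaning of a food's Hg content
depends on how much Se comes with it. `sehgrb` implements the standard
risk–benefit calculus for this trade-off at three levels — per food, per
child, per cohort — for preschool-age children, together with a fully
synthetic data generator so that every stage can be exercised and validated
without access to cohort data.

## Per-food scoring

Concentrations arrive in mg/kg wet weight and are converted to molar units
(µmol/kg) with `to_molar()`, using molar masses of 78.971 g/mol (Se) and
200.59 g/mol (Hg). Two indices are computed from the **unrounded molar
means** of each food category (never from rounded, printed summaries, which
demonstrably shifts the second decimal):

* the **Se:Hg molar ratio**, Se/Hg, with >1 indicating molar Se in excess
  of Hg; and
* the **health benefit value of selenium**,
  \[ \mathrm{HBV_{Se}} = \frac{Se - Hg}{Se}\,(Se + Hg) = Se - \frac{Hg^2}{Se}, \]
  which unlike the raw ratio stays on the µmol/kg scale and does not
  explode for foods with near-zero Hg.

`hbv_se()` satisfies (and the test suite asserts): sign(HBV) =
sign(ratio − 1); HBV ≤ Se with equality iff Hg = 0; strict monotone decrease
in Hg; and scale equivariance (scaling both concentrations by *k* scales
HBV by *k* and leaves the ratio unchanged).

Category summaries (`summarize_category()`) report mean ± SD with the
sample (n − 1) SD — the convention for descriptive tables; the source
material does not state its denominator, so this choice is documented here
deliberately. A category with no detectable Hg reports the ratio as an
`Inf` sentinel and HBV equal to the molar Se mean (the formula's limit).

## Per-child intake assessment

From a food-frequency intake rate `IR` (g/day) and a category concentration
`C` (mg/kg ≡ µg/g):

* `edi()`: EDI = C·IR/BW in µg/kg-BW/day, with the µg/day total alongside;
* `ai_percent()`: percentage of the EFSA adequate Se intake for preschool
  children, AI = 20 µg/day;
* `net_se()`: the Hg-corrected Se intake EDI_Se − EDI_Hg. The subtraction
  is **mass-based** by default, matching the published tables; a
  molar-equivalent mode (subtracting EDI_Hg · M_Se/M_Hg, the Se mass
  stoichiometrically bound by the ingested Hg moles) is available but off
  by default, since the choice is biologically arguable and the mass-based
  form is what the downstream growth models use;
* `hazard_quotient()`: EDI/RfD against the JECFA dietary Hg reference dose
  of 0.23 µg/kg-BW/day, flagging HQ strictly greater than 1.

Safe consumption limits use the separate US EPA reference doses (Hg 0.0001,
Se 0.005 mg/kg/day — these are *never* interchanged with the JECFA dose):
`cr_lim()` gives RfD·BW/C in g/day, and `cr_mm()` converts it to portions
per month as CR_lim · T / MS with T = 30.44 days/month. The division by the
portion size MS is deliberate: it is the only reading under which the
method's published worked results (≈7 and 14.8 fish meals/month at the
65-g EPA child meal; 13, 27 and 67.5 exchange servings/month) are
reproducible, and it matches the US EPA consumption-limit methodology the
formula cites. Two portion conventions coexist: Taiwan MOHW exchange
servings (defaults: fish 35 g, eggs 60 g — back-derived from the published
serving-based limits — plus conventional values for the other categories,
all overridable via `serving_sizes`) and the 65-g EPA fish meal, reported
for fish only.

`servings_to_meet_ai()` returns the exact real number of daily servings
needed to reach the Se AI; for foods eaten in whole practical units (an
egg) a `whole_units` flag applies a ceiling, so 0.64 egg servings is
presented as "one egg". `nutrient_profile_at_ai()` scales a per-serving
nutrient table linearly to that serving count; no recomposition is
attempted.

Population tables can be computed two ways, because cohort sources are
ambiguous about theirs: `"population"` mode (default, used by the
reproduction tests) multiplies category mean concentration by the
population mean intake rate; `"per_child"` mode averages per-child EDIs
(with per-child body weights when available). Both are exposed by
`assess_population_intake()`.

## Growth analysis

`lms_zscore()` implements the Box–Cox LMS transform
z = ((x/M)^L − 1)/(L·S) (log form at L = 0), with `lms_invert()` its exact
inverse; the round-trip is tested to 1e-9. The restricted-tail adjustment
used by growth standards for weight-based indices (linear re-expression
anchored at the ±2 and ±3 SD curves beyond |z| > 3) is applied to
weight-for-age by default and is switchable, since sources do not always
state whether it was used; height-for-age is never tail-adjusted.
`zscore_for_child()` interpolates L, M and S linearly to the child's age in
months within the sex stratum.

Hair Hg is dichotomized at 1 µg/g (`classify_hg_exposure()`), with exactly
1 µg/g classified low to match the "≤1 µg/g" binning convention; "low" is
the factor reference level.

Model building follows the conventional two-step epidemiological procedure:
`screen_covariates()` fits each candidate alone against the outcome and
keeps those with an overall F-test p < 0.2 (categorical candidates are
judged by the joint F-test, preserving input order; constant candidates are
dropped with a warning), and `fit_growth_model()` fits one OLS model per
food category with that category's net AI_Se percentage as the exposure —
per-category models, not a joint model, because that is how such results
are reported; a joint fit can be obtained by passing the other `net_ai_*`
columns as covariates. Intervals are t-based Wald 95% CIs (the default of
standard OLS reporting; no method is named by the source material), rows
with missing values are dropped listwise with a logged count, and a
rank-deficient design is an error naming the collinear terms. Income and
parity enter as categories expanded to indicators with the first level as
reference.

## The synthetic-data generator

The generator's defaults *are* the study conditions, fixed once:

* **Food panel** (`gen_food_panel()`): 108 samples in 11 categories (fish
  split 9 marine / 4 freshwater), independent lognormal Se and Hg draws per
  category moment-matched (`lognormal_params_from_moments()`) to the
  analyzed panel's means and SDs. Se–Hg dependence within a category is
  unknown, so independence is the default and a log-scale correlation hook
  exists for sensitivity analyses only.
* **Cohort** (`gen_cohort()`): n = 349; ages uniform on 0.3–5.5 y (mean
  2.9 y, matching the cohort mean; the uniform is a deliberate
  simplification of the real age distribution); sex Bernoulli(0.54 male);
  hair Hg lognormal matched to mean 1.11, SD 1.15 µg/g — which implies a
  38% exceedance of the 1 µg/g cutoff, slightly below the 42.4% observed
  in the real cohort, suggesting the real distribution is heavier-tailed
  than lognormal; the family is therefore configurable rather than
  asserted. Income and parity follow the observed cohort proportions.
  Weight and height are produced by inverting the LMS reference at each
  child's age from latent standard-normal scores, so the z-score stage
  recovers the latent truth exactly.
* **Intakes**: gamma draws with CV 0.5 around category means back-solved
  from the published population Se intakes divided by the category mean Se
  concentrations (only that product, not the raw FFQ rates, is published);
  e.g. eggs ≈ 33 g/day, milk ≈ 286 g/day.
* **Outcomes** (`gen_outcomes()`): linear in the `net_ai_*` exposures plus
  additive covariate effects and Gaussian noise (default residual SD 0.5
  z-score units); default truth slopes 0.01 (fish, eggs) and −0.41
  (fruits) per net-AI percentage point carry the published effect scale.
  All generating coefficients are written to a truth record.

Every generator is seed-deterministic and restores the caller's RNG state.
`simulate_study()` writes the whole bundle (foods, children, intakes, LMS
table, truth JSON) byte-identically under a fixed seed.

The shipped LMS reference (`synthetic_lms_table()`, also materialized as
`inst/extdata/lms_synthetic.csv`) is **synthetic**: smooth L/M/S curves
over 0–72 months for both sexes whose medians are plausible for this age
range (≈14 kg and ≈92 cm near age 3). It exists so the test suite needs no
reference-table download; a real WHO table in the same six-column layout
drops in unchanged. Consequently, passing tests demonstrate internal
consistency of the z-score machinery, not agreement with the WHO standard
itself.

## What the tests do and do not show

The desk-scale checks reproduce every quantity computable from the
published category-level inputs (HBV and ratio values, molar conversions,
AI percentages, consumption limits, servings-to-AI) at their printed
precision. Two caveats found while pinning them down: the eggs row's
printed mass mean is not exactly consistent with its printed molar mean
under the Se molar mass (a rounding artifact of the source table), so
tests pin the µmol-based quantities; and percentage columns recomputed
from inputs printed to 2 decimals of µg/day can deviate by up to 0.03
percentage points from their printed counterparts through input rounding
alone, so the table-reproduction test uses a 0.05-pp bound with a 0.02-pp
bound on the self-consistent rows.

Statistical guarantees are established by simulation at fixed seeds and
deliberately moderate problem sizes (chosen as the smallest that make the
Monte-Carlo error small against the tolerance): parameter recovery of a
true slope of 0.01 within 10% and 95%-CI coverage within 95 ± 2% over 500
cohorts of n = 349; screening of pure-noise candidates at ≈ the 0.2
threshold rate; moment recovery of the generators at n = 2000 per category
within 3%. Because the synthetic cohort generates outcomes from the same
linear model family the analysis fits, these are *correct-specification*
checks: they validate the estimation machinery, not the biological model.
Real-cohort regression coefficients are not reproducible here (raw data
are unavailable) and are out of scope by design.

## Degenerate inputs and numerical choices

Zero Hg: ratio is an error by default (`Inf` sentinel in summaries); zero
Se: HBV is an error. Nondetect concentration cells (`<MDL` or `<limit`)
are substituted by half the detection limit — a common exposure-assessment
convention; the factor is configurable and the nondetect flag is retained
for audit. Sub-MDL handling in the source tables is unstated, so this
choice is ours. CSV numbers use decimal points only; comma decimals are
rejected rather than silently misread. The LMS inverse is undefined when
1 + L·S·z ≤ 0; the generators draw latent scores well inside the valid
region, and the round-trip tests skip the unrealizable corner.
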