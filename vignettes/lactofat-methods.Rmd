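---
title: "Models and methods behind lactofat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lactofat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactofat)
```

`lactofat` packages four pieces of arithmetic that recur in milk fatty-acid
(FA) monitoring and in diet modeling built on top of it, together with a
synthetic bulk-tank panel generator used to validate the whole chain. This
vignette records the models, their assumptions, the tunable parameters, and
the design decisions taken where more than one convention exists.

## Censoring conventions

The reference laboratory reports an individual FA in g/100 g milk only when
the amount is at least the limit of quantification, 0.001 g/100 g
(`lod`, configurable, defaulted everywhere to 0.001). Everything below is
left-censored. Two complementary summaries exist and the package keeps them
strictly apart:

* **Quantified-only statistics** (`summarize_fa()`): below-LOD samples
  reduce `n` and never enter the mean. For a heavily censored acid this
  mean describes only the upper part of the distribution and is therefore
  elevated. An acid with zero quantified observations yields an explicit
  `n = 0` / `NA` row, never a silent zero.
* **All-sample reconstitution** (`estimate_censored_mean()`): each
  unquantified sample is assigned a fixed imputed value, by convention half
  the LOD (0.0005 g/100 g). For the grass-milk DHA case (249 of 1162
  samples quantified, quantified-only mean 0.00106) this gives ≈ 0.0006
  g/100 g; the servings calculator is wired to this estimate rather than to
  a hard constant.

The two obey a monotonicity invariant (quantified-only mean ≥ reconstituted
mean whenever the imputed value sits below the quantified mean) which is
enforced by test. Group sums (`sum_fa_group()`) make the censoring policy
explicit per call: censored members contribute 0 (`"zero"`) or half the LOD
(`"half_lod"`); members missing from a sample are counted and reported,
never silently skipped. `missing` and `below_lod` are distinct states —
missing observations contribute to neither `n` nor sums.

## Ratio conventions

Panel tables can report a ratio as the *mean of per-sample ratios* or as
the *ratio of mean totals*; for the grass-milk panel these differ (e.g.
0.954 versus about 0.93 for ω-6/ω-3). Both are legitimate, so the package
exposes both and never swaps one for the other: the built-in profiles carry
the panel's mean-of-ratios rows (`la_ala`, `w6_w3`, `w3_w6`) as data, and
`compute_fa_ratios()` recomputes ratio-of-means from any amounts on demand.
Fat standardisation carries ratio rows through unchanged — a linear rescale
cannot alter a ratio — and this scale invariance is a tested property.

## Outlier screening

The monitoring study removed a handful of severe, high outliers partly by
expert consensus; consensus is not reproducible, so `screen_outliers()`
codifies a box-plot fence instead: observations outside
`[Q1 − k·IQR, Q3 + k·IQR]` are flagged and set to missing in a copy of the
panel (the input is never mutated). Defaults `k = 3`, `side = "high"` match
the "severe, high" character of laboratory contamination in this matrix.
Two conventions are fixed deliberately: groups with zero IQR are never
flagged (the fence collapses to equality, and flagging identical values is
meaningless), and codes with fewer than four quantified observations are
skipped with a warning record rather than screened. Screening is idempotent
by construction. Exact reproduction of the original five removals is not
attempted.

## Group means, not least-squares means

Regional, yearly and monthly summaries (`monthly_regional_means()`) are
arithmetic means of quantified values. The original analyses used
mixed-model least-squares means with farm as a random effect; that
machinery is routine statistics outside this package's scope, and under the
balanced sampling designs produced by the synthetic generator the two
estimators coincide in expectation. Recovery tolerances (±10% on seasonal
ratios) absorb the difference. `high_low_months()` reports the descriptive
max/min months and their ratio; `fit_seasonal_peak()` estimates the
seasonal phase by least-squares fit of a single harmonic to the twelve
log monthly means, which locates the peak month far more precisely than the
argmax (see "Recovery testing" below).

## Fat-standardised comparison

Raw grass-fed bulk-tank milk averages ~3.585 g FA/100 g milk against
~3.098 (conventional) and ~3.108 (organic) for retail milks, so amount
comparisons require a common fat basis. `adjust_total_fa()` rescales every
amount by `target / total_fa`; the default target is the mean of the
reference totals (3.103 for the conventional/organic pair), exposed as a
parameter. Percent differences are kept at full precision with a display
convention of one decimal below 10 in magnitude and integers above
(`format_pct_diff()`). Pairwise tests use Welch's t computed from summary
statistics (mean, sd, n) with Welch–Satterthwaite degrees of freedom —
the raw observations behind the reference profiles are unavailable —
displayed to five decimals and never corrected for multiplicity (the
comparisons are reported as-is, mirroring source practice). Comparison rows
for an acid quantified in fewer than 5% of samples on either side are
suppressed rather than reported (DHA in the retail panels: 2/160 and
4/218 quantified samples).

## The dietary LA/ALA model

The model diet is a moderately active woman aged 19–30 consuming 2,100
kcal/day. Constants (all fixed defaults in `energy_constants()`): dairy fat
8.79 kcal/g, nondairy fat 8.90 kcal/g, 0.933 g FA per g dairy fat. The two
intake terms are

* dairy: `kcal / 8.79 × (profile amount / profile total FA) × 0.933` g/day,
* nondairy: `kcal / 8.90 × (per-100 composition) / 100` g/day,

with nondairy compositions `typical_LA` (23.23 g LA, 1.841 g ALA per 100)
and `low_LA` (13.84, 2.731). The source material describes these
compositions both as "per 100 kcal of fat" and through a formula that
treats them as per 100 g of fat; the formula reproduces every published
cell exactly, so the formula is taken as authoritative and the wording
discrepancy is noted here rather than resolved.

Energy allocations (`kcal_allocations()`): dairy fat is 313 kcal/day at 3
servings and 1.5 × 313 = 469.5 at 4.5 servings, constant across fat levels
because servings are fixed. At 33% of energy from fat the nondairy
allocations are the model's reference values (380 and 221.1 kcal); at 20%
and 45% nondairy fat absorbs the remainder `fat_fraction × 2100 − dairy`.
One cell is structurally infeasible: at 20% fat (420 kcal) the 4.5-serving
dairy allocation alone is 469.5 kcal. The nondairy term is floored at zero
and the cell flagged `energy_deficit = TRUE`; its energy-closure invariant
cannot hold and results there describe a dairy-fat-only fat supply. All
other cells close to within 3 kcal.

The baseline ratio (moderate conventional dairy, typical-LA nondairy fat,
33% fat) is always computed from the conventional profile — about 11.33 —
never hard-coded. `build_scenario_grid()` evaluates all 36 scenarios in a
deterministic order; monotonicity (conventional → organic → grass milk
strictly lowers the ratio in every one of the 12 cells), additivity and
homogeneity (uniform kcal rescaling leaves ratios unchanged) are tested
properties.

## The servings calculator

For each food in the daily basket, every FA is converted as
`weight × fat fraction × 0.933 × (amount / total FA) × 1000` mg/day, with
the food-specific fat contents (whole milk 3.25%, cheddar 33.14%, low-fat
yogurt 1.41%, vanilla ice cream 11.1%) applied uniformly to all acids.
Some published daily-intake tabulations apply a whole-milk fat basis to the
long-chain acids of processed dairy foods; `lactofat` does not reproduce
that shortcut, so its EPA/DPA/DHA basket totals are the fat-proportional
values. DHA uses the censoring-aware 0.0006 g/100 g estimate. Ice cream
carries zero dairy-serving equivalents (the recommended-servings invariant
applies to the servings column only) yet contributes weight and fat.
`scale_per_capita()` is a pure linear rescale, so it commutes with summing
and preserves ratios; `dairy_vs_fish()` reports undefined (NA) rather than
infinite ratios where the fish row supplies nothing. The carried
`la_ala_ratio` column reproduces the source panel's printed per-sample
ratio summary (0.954), which is scale-invariant; the ratio of computed LA
to ALA milligrams (≈ 1.01) is always recomputable from the output.

## The synthetic panel generator

No raw monitoring data are public, so the generator emulates the *study
design*: four U.S. regions, three years, a quantification limit, rare
severe high outliers, and seasonal and regional structure.

**Model.** Concentrations are multiplicative:
`value = exp(mu + region offset + a·cos(2π(month − peak)/12) + farm + ε)`,
with `farm ~ N(0, v_farm)` per farm and `ε ~ N(0, v_within)` per sample.
A lognormal is the natural choice for strictly positive concentrations with
CVs of 15–50%. The intercept `mu` is calibrated so that the expected panel
mean equals the target exactly: `mu = log(target) − (v_farm + v_within)/2 −
log(design factor)`, where the design factor is the realized sample mean of
`exp(offset + seasonal)`. This makes `summarize_fa()` unbiased for the
target mean by construction, a property verified over 20 seeds.

**Defaults as study conditions.** Per-acid targets follow the published
panel summary (37 acids, means and CVs); heavily censored minors get latent
means near the LOD chosen so their quantified fractions resemble the
study's (~21% for DHA, enforced against the lognormal-CDF oracle).
Seasonality is a single harmonic with `a = log(high/low ratio)/2`: omega-3
acids peak in December (ratio 1.22), omega-6 in October (1.21), CLA in
September (2.05); saturated, monounsaturated and trans acids carry none.
Regional offsets reproduce the published ordering (California lowest,
Midwest/Northeast highest) with sample-weighted mean ≈ 0. The Mideast
region enters in June 2016. Outliers are injected high-side only
(`rate 5e-4`, ×15).

**Farm panel.** The study accumulated ~1,163 samples from a farm base that
grew to ~140; enrollment history is not published. The generator instead
uses a balanced panel — 34 farms (3 California, 2 Mideast, 17 Midwest, 12
Northeast) sampled monthly over 2014–2016, n = 1,166 — preserving the total
sample count and approximate regional shares. Balance is what makes
month-of-year means estimable with every farm contributing to every month.

**Variance split.** The within/between-farm split is not identified by
published summaries and is a configurable assumption (`farm_share`,
default 0.02 of residual log-variance). Two considerations fix the small
default: scientifically, all farms follow one certified near-100%-forage
ration standard and each bulk-tank sample pools an entire herd, damping
persistent farm differences relative to within-farm month-to-month
variation; statistically, the recovery tolerances below are expressed in
independent-sample standard errors, which are only valid when the
farm-level (cluster) component of the panel mean's sampling error is minor.
Users modeling stronger herd-level clustering should raise `farm_share`
and widen recovery tolerances accordingly.

## Recovery testing: what passing does and does not show

`recovery_report()` screens outliers with the default rule (mirroring the
study's QC step), then checks: annual means within 3 estimated standard
errors of their targets for acids with < 5% expected censoring; the
seasonal peak month, recovered exactly via the harmonic fit; the max/min
monthly ratio within 10%; and the regional structure of the omega-3 family
(California lowest of the three full-period regions, Midwest/Northeast the
top two — the Mideast's 14 late-entry samples make its exact rank
noise-limited by design). Two estimator choices matter:

* The **peak month** uses the harmonic fit, not the argmax of monthly
  means: at n ≈ 1,166 and CLA's CV, adjacent-month means are close enough
  that the argmax misidentifies the peak in a nontrivial fraction of
  correct runs, while the harmonic phase has a standard error well under a
  month.
* **Amplitude recovery is gated on signal-to-noise** (amplitude ≥ 4 × the
  monthly-mean log standard error): the max/min ratio is upward-biased
  under noise, so weak-harmonic, high-CV minor acids (e.g. arachidonic)
  would fail the tolerance under a perfect implementation. They are
  generated but not recovery targets.

Passing these tests shows the pipeline correctly recovers the parameters of
*this* generative model at the study's scale. It does not validate the
lognormal/single-harmonic form against real milk, does not exercise
staggered farm enrollment or drifting yearly means, and says nothing about
mixed-model inference, which the package deliberately omits.

## Numerical and reproducibility choices

All internal computation is at full precision; display rounding (1–2
significant digits for SD/CV/SE, the mixed percent convention, 1-decimal
milligrams) is applied only in formatting helpers and "pretty" outputs.
CSV outputs of `run_pipeline()` serialise at full precision. Generation is
a pure function of (config, seed): the generator seeds R's RNG from
`config$seed` and draws in a fixed acid order, so identical configs produce
byte-identical panel CSVs. The pipeline manifest records the seed, a
configuration hash and per-stage row counts; no timestamps, so reruns are
hash-identical. Problem sizes used throughout the test suite are the
study-scale panel (n ≈ 1,166) and 20-seed recovery loops, which keep the
whole suite under a minute on one CPU.

## Known limitations

* Mixed-model (least-squares-mean, Tukey, Satterthwaite) inference for the
  regional/seasonal tables is out of scope; only descriptive aggregation is
  provided.
* The dietary model operates at the energy/composition level; no
  food-item-level diet construction and no modeling of ALA → EPA/DHA
  conversion physiology.
* Fish composition is a fixed 7-species mean input row, not recomputed from
  species databases.
* The synthetic generator targets statistical structure only — no herd
  genetics, feed chemistry, or dose–response between forage share and FA
  levels.
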