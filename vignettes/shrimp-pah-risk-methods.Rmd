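---
title: "Methods: probabilistic dietary PAH risk assessment for shrimp consumers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic dietary PAH risk assessment for shrimp consumers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shrimppahr)
```

## The problem

Communities with high seafood consumption and below-average body weight can
be poorly served by population-level food-safety screening, which typically
assumes a modest intake (on the order of 13 g/day) and a standard 80 kg
adult. `shrimppahr` implements a community-specific alternative: it takes a
food-frequency survey of shrimp consumers and chemical analyses of the
shrimp they eat, and propagates both through the standard reference-dose
(noncancer) and slope-factor (cancer) risk models, deterministically and by
Monte Carlo simulation.

The package targets polycyclic aromatic hydrocarbons (PAHs), the main
toxicants of concern in petroleum-contaminated seafood. Two endpoints are
computed:

* **Hazard quotients (HQ)** for PAHs with an accepted oral reference dose
  (RfD): naphthalene, fluorene, anthracene/phenanthrene (pooled), pyrene and
  fluoranthene. HQ = average daily intake / RfD; values above 1 flag a
  potential noncancer concern.
* **Lifetime excess cancer risk** for the PAH mixture expressed as
  benzo[a]pyrene (BaP) equivalents via relative potency factors (RPFs),
  using the linear oral-slope-factor paradigm.

## The exposure model

Per-respondent shrimp intake (g/day) is

```
intake = (shrimp per meal) x (g per shrimp) x (meals per week) / 7
```

where grams per shrimp come from the commercial count-per-pound size
classes (midpoint of the count range, 453.592 g/lb; e.g. "medium", 41–50
per lb, is 9.97 g/shrimp). Survey categories reported as ranges ("10–15
shrimp") are resolved to their midpoints; both tables are plain data and can
be overridden from CSV without code changes. Respondents reporting zero
consumption keep a rate of 0 and stay in the population, diluting the mean
exactly as in an empirical survey summary.

Average daily dose for analyte *i* is

```
ADI_i = C_i x IR / (BW x CF)      [mg/kg body weight/day]
```

with `C_i` the tissue concentration in ppm (mg/kg shrimp), `IR` the intake
rate (g/day), `BW` body weight (kg), and `CF = 1000` g/kg. Lifetime excess
cancer risk is

```
risk = C_BaPeq x IR_kg x 365 x ED / (BW x AT) x OSF
```

with `C_BaPeq` in mg BaP equivalents/kg shrimp, `IR_kg` in kg/day
(converted from g/day once, inside the simulation engine), `ED` the
exposure duration in years, `AT = 28,470` days (a 78-year life span), and
`OSF = 7.3` (mg/kg/day)^-1, the oral slope factor for BaP. Exposure is
assumed daily (365 days/year), a conservative choice. ED is drawn from a
continuous uniform distribution on 5–10 years: only the range is specified
by the exposure scenario, and a continuous draw avoids imposing artificial
mass on integer years.

## Chemistry conventions

* **Nondetects.** Analytes below the limit of detection are assumed present
  at LOD/sqrt(2), the standard substitution convention for left-censored
  environmental data. Substitution never touches a detected value and maps
  every nondetect strictly below its LOD.
* **Alkylated homologs.** For noncancer totals, alkylated homologs (e.g.
  2-methylnaphthalene) are assumed as toxic as their parent and summed into
  the parent's concentration. Only parents with an RfD enter the HQ table.
  Anthracene and phenanthrene share a single RfD (0.3 mg/kg-day) and are
  pooled into one row, homologs included.
* **BaP equivalents and tiers.** The carcinogenic potency of the mixture is
  the RPF-weighted sum of analyte concentrations, in µg BaPeq/kg shrimp
  (numerically equal to ng/g). Three nested analyte tiers mirror the usual
  sensitivity analysis of widening the analyte list: the seven priority
  carcinogenic PAHs (cPAHs) with accepted RPFs; plus the remaining
  unsubstituted PAHs; plus the alkylated homologs. Analytes without an
  accepted RPF are conservatively assigned an RPF of 1 (BaP's own potency)
  in the expanded tiers, and are excluded from the strict 7-cPAH tier.

The packaged analyte metadata covers an 81-analyte petroleum-PAH panel.
Per-analyte detection limits are laboratory-specific and rarely published,
so the packaged LODs are an explicit synthetic calibration: cPAH LODs
(0.40878 ng/g) are set so a fully censored 7-cPAH panel yields 0.668 µg
BaPeq/kg — a representative censored-panel value for shrimp tissue with no
cPAH detected at sub-ng/g limits — and the unsubstituted (1.2428 ng/g) and
alkylated (0.5116 ng/g) LODs are set so the censored tier totals are 0.668,
29.67 and 44.50 µg BaPeq/kg. Users with laboratory-reported LODs and RPFs
should drop in their own metadata CSV.

## Distribution fitting

Exposure-factor distributions follow the families conventional in
probabilistic exposure assessment: body weight is screened against normal,
log-normal and Pearson type V; intake rate against Weibull, log-normal and
Pearson type VI. Pearson V is implemented as the inverse-gamma family and
Pearson VI as the scaled beta-prime family, the standard identifications.

Estimation is by maximum likelihood. Normal, log-normal and uniform
estimates are closed form; the Weibull fit is delegated to
`fitdistrplus::fitdist()`; the Pearson families are maximised numerically
(Nelder–Mead on log-parameters) from method-of-moments starting values, so
repeated fits of the same sample are bitwise identical. Families are ranked
by BIC (`k log n − 2 logLik`), ties broken by higher log-likelihood then
family name; a family that fails to fit (e.g. a positive-support family
offered data with zeros) is kept at the bottom of the ranking with its
error recorded rather than aborting the screening. The pipeline records the
full ranking and uses the best-ranked family rather than hard-coding a
winner, since which family wins depends on the data at hand.

Sampling is by inversion (quantile function applied to uniforms), which
makes truncation exact: body weight is truncated to (0, 250) kg — draws are
taken on the restricted quantile range, so no draw ever falls outside and
the sampler targets the renormalised density. The synthetic survey
generator uses a tighter (30, 250) kg interval to avoid physiologically
absurd synthetic adults; the looser (0, 250) kg bound is kept for fitting
real data, where the lower bound is only there to guard the model against
nonphysical draws.

Zero-intake respondents are excluded from intake-rate fitting (all three
candidate families have positive support) but retained in the summary
statistics; a fully censored analyte yields a constant substituted
concentration, which is modelled as a point mass rather than a
zero-variance log-normal.

## Monte Carlo engines

All inputs are drawn independently across iterations and across variables —
no correlation structure is imposed, matching the usual one-dimensional
variability analysis. The default is 10,000 iterations. Percentiles use
linear interpolation on order statistics (R's type-7 estimator), which
matters because upper-percentile HQs and risks are reported. Histograms are
relative-frequency (bar heights sum to 1) over 50 equal-width bins from 0
to the 99.9th percentile, plus one overflow bin to the maximum so no draw
is dropped; the binning is cosmetic and configurable.

Tier comparisons use common random numbers: one draw sequence of (IR, BW,
ED) is shared across tiers, so the risk distributions of different tiers
are exactly proportional to their BaPeq totals, in every percentile. This
makes the tier-expansion factor (about 1.5× when alkylated homologs are
added under the packaged calibration) a deterministic consequence of the
chemistry rather than a Monte Carlo accident.

With all inputs degenerate (point distributions) the Monte Carlo engines
reproduce the deterministic point computations bitwise — the suite uses
this as an oracle. One numerical subtlety: the engine converts g/day to
kg/day by dividing draws by 1000, so bitwise comparisons must feed the
point formula the identically converted value.

## The synthetic-data generator

No survey microdata or chemistry tables are distributable, so the package
ships a generator that emulates their statistical structure:

* **Survey.** Sex drawn 50/50; body weight from sex-specific truncated
  normals (means 67.5/58.9 kg). The SD is not something survey summaries
  report, so the default of 11 kg is a documented calibration knob chosen to
  give an overall mean near 63 kg with an even sex split. Meal frequency,
  portion and size-class PMFs default to a mode of "several times per week"
  (3 meals/week), 10–15 shrimp and medium–large shrimp; the implied mean
  intake is 45.0 g/day. These PMFs are configuration, not claims about any
  particular survey.
* **Chemistry.** Per analyte, a detection coin-flip followed by a
  log-normal concentration (geometric mean/SD); nondetects carry the
  metadata LOD. Default levels keep every detected analyte below 2 ng/g,
  the magnitude seen in lightly contaminated shrimp tissue; analytes not
  configured as detectable are pure nondetects, which makes the default
  table reproduce the censored-tier BaPeq calibration exactly.

Each generated table has its own seed, so adding one generator call never
perturbs the other. What the generator does *not* emulate: temporal changes
in consumption after a disaster event (the risk model is steady-state),
survey nonresponse structure, between-location differences in chemistry,
and correlation between body weight and intake. Tests passing on synthetic
data therefore validate the arithmetic and the statistical machinery, not
the representativeness of any particular survey.

## Problem sizes and reproducibility

The test suite exercises the generator at n = 115 (survey-sized) to 10,000
(convergence checks), Monte Carlo engines at 10,000 iterations, and the
BIC-consistency property at 100 replicates of n = 5,000 — sizes at which
the parametric recovery tolerances (2% relative error) and the
Kolmogorov–Smirnov bound on truncated sampling (statistic < 0.02) are
comfortably met. Every stochastic function takes an explicit seed and
restores the caller's RNG state; a full `run_assessment()` under one seed
is byte-identical across runs, and the emitted manifest records seed,
iteration count and per-stage record counts.

## Known limitations

* Additivity of RPF-weighted potencies is assumed; assigning RPF = 1 to
  un-assessed analytes makes expanded-tier risks grow without bound as the
  analyte list lengthens. That is the point of the tiered analysis — it
  quantifies the cost of the assumption — but expanded-tier numbers should
  be read as sensitivity bounds, not estimates.
* No toxicokinetics, no cooking-loss adjustment (boiling, the dominant
  preparation in the motivating setting, leaves PAH content essentially
  unchanged), no age-dependent adjustment factors.
* Deterministic HQ tables reported at 2 significant figures can disagree
  with hand-rounded published tables in the last digit when the unrounded
  value sits near a rounding boundary (e.g. an HQ of 1.758e-4 prints as
  1.8e-4 here but may appear as 1.7e-4 in a source that rounded an
  intermediate). Machine-readable outputs always keep full precision.
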