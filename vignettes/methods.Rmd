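---
title: "Methods: censored well data, the hazard-quotient model, and Monte Carlo worst cases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: censored well data, the hazard-quotient model, and Monte Carlo worst cases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitrorisk)
```

`nitrorisk` turns a two-season table of well nitrate/nitrite concentrations
into descriptive statistics, standard-limit screening, and a
non-carcinogenic risk estimate with Monte Carlo uncertainty. This vignette
is the package's account of the methods: the data model and its non-detect
handling, the intake equation and its unit conventions, the simulation
engine's numerical choices, what the synthetic generator does and does not
emulate, and the design decisions that were genuinely open.

## The data model and non-detect handling

A `well_table` holds one record per locality with an observation for each
analyte (nitrate, nitrite) and season (spring, autumn). An observation is
either a concentration in mg/L or a non-detect below the analytical limit
of detection — 0.3 mg/L for nitrate (cadmium-reduction colorimetry) and
0.05 mg/L for nitrite (diazotization). A non-detect carries no number; any
statistic over the table must first resolve it under one of four explicit
policies: `exclude` (drop), `zero`, `half_lod` (LOD/2, the classical simple
substitution) or `lod` (an upper bound).

The default policy for descriptive work is `exclude`. The packaged survey's
own per-well "average" column behaves this way: a well with one detected
nitrite season and one ND prints the detected value as its average, which
only the exclusion rule reproduces. `half_lod` is the usual choice when a
concentration must be fed to the risk model and a value is needed for every
well; both are available everywhere a policy is taken, and under `exclude`
no substituted value can ever enter a downstream statistic.

The per-well seasonal average is the arithmetic mean of the two resolved
seasons, falling back to the single resolvable season and to absent when
neither resolves. With the two all-ND nitrite localities excluded, nitrite
statistics run on n = 56 of the 58 wells; the ambiguity between the
printed table (58 rows) and the survey text's well count (59) is recorded
in the fixture's provenance string and deliberately not "repaired".

Numbers are parsed with a locale-independent decimal point and thousands
separators are rejected outright — the coordinate columns of field tables
are a classic source of silent comma corruption. Coordinates are carried as
opaque numerics; no geodesy is attempted.

## Descriptive statistics and tests

`summarize_conc` reports n, range, median (midpoint of the two central
order statistics for even n), mean, and the sample standard deviation with
the n − 1 denominator. All internal values are full precision; only the
report layer rounds, to two decimals with halves away from zero
(`round_half_away`), matching how survey tables are conventionally printed.

Exceedance screening counts wells strictly above a limit ("higher than" is
read as a strict inequality, so a well exactly at 50 mg/L does not exceed).
The default rule compares the per-well seasonal average; an `any_season`
rule is provided because screening practice varies and single-season spikes
can matter. Unresolvable wells leave the denominator. The nitrate limit
defaults to the national standard of 50 mg/L; no nitrite limit is stated in
the source survey, so the configuration default is 3 mg/L (the WHO
short-term guideline) and is overridable.

The hypothesis tests are thin, typed wrappers over `stats`: a one-sample t
test against a standard value, Pearson correlation over complete pairs, and
a Kolmogorov–Smirnov normality check against a normal with the series' own
estimated mean and sd. Estimating the null parameters makes the classical
KS p-value conservative (the Lilliefors caveat); the result object carries
that note, and the test suite cross-checks the D statistic against the
independent Lilliefors implementation in `nortest`. No multiple-testing
correction is applied — the surveys this mirrors apply none.

## The intake model

The target hazard quotient of chronic drinking-water ingestion is

$$\mathrm{THQ} = \frac{C \times EF \times ED \times WIR \times 10^{-3}}
                      {RfD \times AT_n}$$

and the hazard index is the sum over analytes,
$\mathrm{TTHQ} = \mathrm{THQ}_{\mathrm{NO_3^-}} +
\mathrm{THQ}_{\mathrm{NO_2^-}}$, classified against a strict threshold of 1.

Two conventions deserve note. First, with C in mg/L and RfD in mg/kg-day,
the equation only balances dimensionally if WIR (ml/kg-day) is converted to
L/kg-day; the 10⁻³ factor is applied explicitly rather than folded silently
into a parameter, and the pipeline log narrates it. Second, the default
exposure factors (EF 365 day/y; ED 70 y adult, 6 y child; WIR 25 and 20
ml/kg-day; ATn 25,550 and 2,190 day; RfD 1.6 and 0.1 mg/kg-day for nitrate
and nitrite) satisfy EF × ED = ATn for both cohorts, so the chronic scaling
cancels and THQ reduces to C × WIR × 10⁻³ / RfD — the suite asserts the
full and reduced forms agree to machine precision, and the adult/child THQ
ratio at equal C is exactly WIR₂₅/WIR₂₀ = 1.25. Parameters are config-driven
with these values as immutable defaults so other cohorts or reference doses
can be assessed.

Which concentration statistic feeds the deterministic equation is a genuine
modelling choice: the mean gives the central-tendency hazard, the 95th
percentile a conservative screen. `risk_assessment` defaults to the mean
and exposes `conc_stat = "p95"`; the probabilistic answer to the same
question comes from the simulation, which is the better tool for it.

## Monte Carlo engine

Each uncertain input is a declarative `dist_spec`: fixed, normal (truncated
below 0 by rejection resampling — concentrations and intake rates cannot go
negative), lognormal, triangular, or the empirical bootstrap of an observed
series. Concentration defaults to the bootstrap of the per-well seasonal
averages: it needs no distributional claim about data that are visibly
non-normal, at the cost of never extrapolating beyond the observed range.
Exposure factors default to point masses (surveys print point values);
stochastic specs are opt-in, and when exposure duration is stochastic the
averaging time is re-derived as ATn = ED × 365 on every draw so the chronic
scaling stays internally consistent.

Each iteration draws all inputs, evaluates THQ per analyte and sums the
TTHQ; the engine reports percentile tables (default 5/50/95; the 95th is
the conventional "reasonable worst case") plus a convergence diagnostic,
the half-width of a 200-resample bootstrap 95% CI on the 95th-percentile
TTHQ. All percentiles use the type-7 linear-interpolation convention
(index 1 + (n − 1)p/100) — conventions differ in the tail by up to one
order-statistic gap, so fixing and documenting one matters. Because THQ is
increasing and linear in C, percentiles commute with the intake map; the
suite checks this both exactly (single analyte, fixed factors) and within
one order-statistic gap at 10,000 iterations. A seed is mandatory in the
pipeline: identical (configuration, seed) reruns are bit-identical, and the
same seed is shared across cohorts (common random numbers) so cohort
contrasts are free of sampling noise.

Default problem sizes — 10,000 iterations for reported simulations, with
smaller counts in unit tests of structural properties — give a p95-TTHQ
bootstrap CI half-width of about 0.05 on the packaged survey, comfortably
inside the precision at which hazard quotients are interpreted.

## Synthetic well fields

The generator emulates the statistical structure the analysis assumes, so
every stage can be tested without field data: nitrate as a single lognormal
(defaults meanlog 3.28, sdlog 0.56, giving mean ≈ 31 and sd ≈ 19 mg/L — the
scale of the packaged survey, calibrated to its published moments rather
than fitted to its rows, which remain the real-data fixture); nitrite as a
two-component lognormal mixture (65% of wells near the 0.05 mg/L LOD, 35%
in a heavy tail reaching a few mg/L, reflecting the bimodality of the
printed data — a single lognormal cannot show mass at the LOD and a tail to
5.8 simultaneously); a multiplicative autumn/spring effect (default 0.8
with lognormal per-well noise, sdlog 0.2 — most surveyed wells decline
after the recharge season); and censoring of latent draws below the LODs.
The latent values are retained as an audit attribute so tests can verify
that every censored cell was genuinely below its limit.

What the generator does *not* emulate: spatial correlation between wells
(coordinates are cosmetic), correlation between nitrate and nitrite within
a well, season-by-analyte interactions, and measurement error distinct from
field variability. Tests passing on synthetic tables therefore demonstrate
the pipeline's correctness and its statistical contracts, not that real
aquifers satisfy the generator's independence assumptions.

`recover_parameters` closes the loop: on an uncensored table it refits the
spring-nitrate log-moments and checks them against the configuration within
three standard errors (sdlog/√n and sdlog/√(2n)). At n_wells = 2000 the
suite requires recovery in ≥95% of 100 seeded replicates; at toy sizes the
report is produced with a warning that the bounds are uninformative.

## Degenerate inputs and tie-breaks

Empty series error in `summarize_conc` and `percentile`; constant series
error in the t test and KS check (sd = 0) but are legal in the simulation
(a fixed spec is the degenerate distribution, and a degenerate simulation
must — and does, exactly — reproduce the deterministic model). A
classification at exactly the threshold is "safe" (strict inequality,
following "more than 1"). Generator scale parameters may be exactly zero,
collapsing to identical wells; mixture weights must sum to 1.

## Known limitations

Only the ingestion route and non-carcinogenic endpoints are modelled — no
dermal/inhalation routes and no slope-factor carcinogenic risk. The schema
is fixed at two analytes and two seasons in this version. The bootstrap
concentration model cannot exceed the observed maximum, so extreme-tail
percentiles (>99th) are better served by the parametric specs. Exceedance
percentages are as computed from the packaged table; published survey
percentages that cannot be reproduced under any counting rule applicable to
the printed rows are not treated as targets, and the package always reports
its own computed values.
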