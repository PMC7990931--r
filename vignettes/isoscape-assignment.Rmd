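---
title: "Inferring killer whale distributions from tooth and bone oxygen isotopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring killer whale distributions from tooth and bone oxygen isotopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orcascape)
```

## The problem

Sea-surface water in the North Atlantic carries a strong latitudinal
δ¹⁸O gradient: ¹⁸O-depleted Arctic water (a few per mil below zero) is
separated from ¹⁸O-enriched subtropical water by a sharp boundary at the
Gulf Stream. Cetacean body water tracks ambient seawater closely, and the
phosphate of tooth dentine and bone (δ¹⁸O_P) precipitates in equilibrium
with body water, so a whale's tooth records a long-term average of the
seawater δ¹⁸O where it lived. Working backwards — tissue value, to inferred
source-water value with uncertainty, to the set of ocean grid cells
compatible with that value — yields a coarse geographic distribution for
animals, such as stranded killer whales, that were never tracked.

This package implements that chain for a cohort of 22 stranded killer
whales (teeth from the eastern Canadian Arctic, ECA, n = 10, and northwest
Atlantic, NWA, n = 7; mandibular bone from Greenland, n = 2, and Denmark,
n = 3), packaged as `orca_specimens()`, together with the cohort statistics
used to compare and cluster them and synthetic generators to validate the
machinery end to end.

## Inverse calibration and error propagation

Tissue and seawater values are linked by an interspecific linear
calibration

$$\delta^{18}O_P = \beta_0 + \beta_1\,\delta^{18}O_{marine},$$

with published estimates β₀ = 18.73 ± 0.30 ‰ and β₁ = 0.81 ± 0.23.
`invert_calibration()` rearranges it to $(x - \beta_0)/\beta_1$, and
`propagate_se()` carries the three uncertainty sources — the two parameter
SDs plus the analytical measurement error σₓ on the tissue value — through
a first-order Taylor (delta-method) expansion with x, β₀, β₁ independent:

$$SE^2 = \frac{\sigma_x^2 + \sigma_{\beta_0}^2}{\beta_1^2}
       + \frac{(x-\beta_0)^2}{\beta_1^4}\,\sigma_{\beta_1}^2 .$$

`meas_sd` defaults to 0.22 ‰, the average replicate reproducibility of the
phosphate analyses; with that value the delta-method SE reproduces the
published per-specimen "±" column for all 22 whales at two decimals
(`verify_fixture()` checks this), which also settles that the published
column is 1·SE. Confidence intervals use the normal quantile
(z = 1.959964 at 95%), the construction that matches a delta-method SE; a
t quantile has no natural degrees of freedom here because the dominant
uncertainty is the cited calibration, not a sample statistic.

Two modelling choices are worth making explicit. First, β₀ and β₁ are
treated as independent because the source publication gives no covariance;
with a negative sampling covariance (typical for regression coefficients)
the true SE would differ slightly. Second, the propagation is first-order
only. The slope's CV is ≈ 28%, and the exact ratio
$(x^* - \beta_0^*)/\beta_1^*$ with a normal denominator has no finite
variance at all — its sample SD over 10⁶ draws is an order of magnitude
above the delta value and never stabilises, and even its central-68%
quantile half-width runs ~8% wider. The Monte-Carlo oracle
`mc_oracle_se()` therefore simulates the *first-order* model (gradients by
central finite differences, independent of the closed-form algebra) by
default, and keeps `method = "exact"` to document the divergence. The
practical reading: the 95% CIs inherit the first-order approximation and
are somewhat anticonservative given how uncertain the slope is.

## Suess correction of δ¹³C

Oceanic δ¹³C declines secularly as fossil-fuel CO₂ invades the surface
ocean, so carbon values from specimens spanning ~70 years need a common
temporal baseline. Whole teeth and bone integrate over the animal's life,
so each specimen is dated to its deposition midpoint — year of death minus
half the age in growth layer groups (GLGs) — and `suess_adjust()` moves the
raw value to the reference year:

$$\delta^{13}C_{adj} = \delta^{13}C_{raw} + r\,(y_{ref} - y_{mid}),$$

with r = −0.023 ‰ yr⁻¹ and y_ref = 2013 by default. When the age is
unknown (one ECA tooth; all five bone specimens) the midpoint falls back to
the year of death — the only treatment consistent with the published
adjusted value of the age-less ECA tooth — and the record carries an
`age_imputed` flag. `fit_temporal_trend()` provides the OLS screen of
values against midpoint year; on this cohort δ¹⁸O_P shows no trend
(p ≈ 0.8) while δ¹³C_SC declines at ≈ −0.027 ‰ yr⁻¹, close to the adopted
rate. The adjustment is applied unconditionally at the configured rate, and
the screen never gates it.

The packaged `orca_printed_values()` table flags two NWA rows whose
published adjusted cells are interchanged (each matches the formula applied
to the other's raw value) and the five age-less bone rows whose published
adjusted cells cannot be reconstructed from the stated formula; tests
accept the formula-consistent readings and exclude the flagged cells.

## Isoscape assignment

`isoscape_grid()` holds a regular lat × lon grid of sea-surface δ¹⁸O with
`NA` for land/no-data; the interchange format is a CSV grid (first row
longitudes, first column latitudes). `assign_interval()` marks every
non-missing cell whose value lies in the closed interval [ci_lo, ci_hi] —
boundary cells count, the conservative reading of "encompassed" — and
`assign_specimens()` does this per whale from the 95% CI. Only estimate-side
variance enters the interval; prediction variance of the isoscape itself is
deliberately not modelled, so masks are extraction, not interpolation, and
a whale whose CI lies wholly above the grid's values gets an honestly empty
mask (as happens for the most ¹⁸O-enriched whale in the cohort). Latitudes
are normalised ascending and longitudes wrapped to [−180, 180) on read, so
file ordering cannot change a mask.

## Cohort statistics

The rank tests and the clustering are implemented in the package rather
than called, so their algebra is testable against independent oracles
(and cross-checked against `stats::kruskal.test`, `stats::p.adjust`,
`stats::hclust` in the test suite):

* `kruskal_wallis()` — midranks, tie-corrected H, chi-square p on k − 1 df.
  The chi-square approximation is used at all sample sizes; no exact
  small-sample tables.
* `dunn_posthoc()` — pairwise z on mean ranks with the tie term, two-sided
  normal p, Benjamini–Hochberg step-up across all pairs jointly.
* `upgma_cluster()` — average linkage on |Δδ¹⁸O_P| (Euclidean in 1-D) via
  the size-weighted Lance–Williams update. Ties are real here (three
  whales share δ¹⁸O_P = 17.62 exactly), so the tie-break is fixed: among
  minimal-distance pairs, merge the one whose earliest member (input
  order) comes first, then by the other cluster's earliest member. This
  makes the fixture tree reproducible; cutting it at k = 3 (`cut_tree()`)
  isolates one singleton and one 4-whale cluster — the five high-δ¹⁸O_P
  whales — against the main cluster of 17. k = 3 is used for reporting
  because it is the unique cut that yields that five-whale split.
* `group_summary()` — mean and sample SD (n − 1). One caveat: the
  published Denmark δ¹⁸O_P SD (0.39) cannot be reproduced from the printed
  values (they give 0.3974 → 0.40) under either SD convention; it was
  evidently computed from unrounded data. Since ±0.005 rounding of each of
  3 inputs can move the SD by up to ~0.0053, tests compare group SDs at a
  propagated bound of 0.0105 while means are held to half a printed ulp.
* `standardize_profile()` / `within_tooth_index()` — per-GLG series
  anchored to the first GLG, and its sample SD and range as the index of
  interannual variation in distribution.

## What the synthetic generator emulates

`sim_config()` fixes the study conditions for validation. The isoscape is
the minimal structure that carries the assignment logic: value(lat) =
base + slope·lat + step·[lat ≥ front] + noise, defaulting to 1.2 ‰ at the
equator edge, −0.03 ‰ per degree, a −1.5 ‰ step at 42° N, 0.15 ‰ spatial
noise and 10% land on a 60 × 60 grid spanning 0–80° N, 80° W–0° — values
chosen once to bracket the real North Atlantic surface field (≈ +1 ‰ in
the subtropics to ≈ −3 ‰ in the Arctic, with the sharp Gulf Stream front).
Simulated whales draw a true cell in their group's latitude band, a tissue
value from the forward calibration plus measurement noise (per-whale
parameter draws when `draw_calibration` is on, the data-generating process
the propagated CI assumes), and a δ¹³C with the configured Suess drift
evaluated at the deposition midpoint. A single master seed derives fixed
per-component sub-seeds, so regenerating the grid alone never shifts the
cohort draws.

What it does not emulate: ocean circulation or salinity–δ¹⁸O structure,
seasonal or within-life movement (each simulated whale has one home cell),
isoscape prediction error, diet-linked δ¹³C spatial structure, and bone
remodelling. Passing coverage and recovery tests therefore validate the
statistical machinery — not the realism of any particular ocean product or
the biology of tissue averaging.

`coverage_experiment()` closes the loop: with per-whale calibration draws,
the fraction of 1000 simulated whales whose true cell falls inside their
95% mask comes out at ≈ 0.95 (the packaged run prints 0.947), and OLS on
200 simulated pairs recovers β₀ and β₁ within sampling error, as does the
trend fit for the Suess rate. Problem sizes (10⁶ oracle draws, 1000-whale
coverage, 200-pair recovery) are the package's chosen validation scale —
large enough that Monte-Carlo error is far below the tolerances checked.

## Numerical choices and degenerate inputs

* Closed assignment intervals; missing cells never assignable; `lo > hi`
  is an error, not an empty mask.
* The coverage check allows 10⁻⁹ ‰ slack so the zero-width CI of a fully
  noise-free configuration still contains its own value in floating point.
* All-identical data is a hard error in the rank tests (the tie correction
  divides by zero); an all-equal-midpoint design is a hard error in the
  trend fit.
* Ages may be missing but never silently zero: imputation happens only at
  the Suess step and is flagged.
* Presentation rounding (2 d.p.) happens only in `results.csv` written by
  `run_pipeline()`; every other artifact carries full precision.

## Known limitations

The calibration parameters are treated as independent and the propagation
is first-order; with the slope's 28% CV the exact inverse-calibration
distribution is heavy-tailed and the 95% CIs are accordingly optimistic.
Assignment ignores isoscape prediction variance and vertical δ¹⁸O
structure (surface values only). The δ¹³C values are corrected for the
Suess effect but never used for assignment — dietary and metabolic
influences on structural-carbonate δ¹³C cannot be separated from spatial
baseline variation without diet data. And whole-tooth values are lifetime
averages: real seasonal movement across the front is invisible to them,
which is exactly why the per-GLG within-tooth indices exist.
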