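---
title: "Methods: gridded PM2.5 attributable-mortality assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gridded PM2.5 attributable-mortality assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pm25hia)
```

## The attributable-mortality model

`pm25hia` estimates premature mortality attributable to long-term ambient
PM2.5 exposure on regular latitude–longitude grids. In every grid cell,
cause of death and 5-year adult age band it evaluates

$$\Delta M = y_0 \cdot \frac{RR - 1}{RR} \cdot Pop$$

where $y_0$ is the baseline mortality rate (deaths person$^{-1}$
yr$^{-1}$), $Pop$ the exposed population and $RR$ the risk ratio at the
cell's annual-mean concentration. $(RR-1)/RR$ is the attributable
fraction: the share of baseline deaths that would not occur at the
counterfactual exposure. The computation assumes (i) annual-mean
concentration is an adequate long-term exposure metric for everyone in a
cell, (ii) the hazard functions transfer across populations given
age-specific baseline rates, and (iii) causes act independently enough
that cause-specific and envelope estimates can be tabulated side by side.

## Exposure–response functions

The default family is the Global Exposure Mortality Model (GEMM):

$$RR(z) = \exp\{\theta \,\log(1 + z/\alpha)\,\omega(z)\},\qquad
\omega(z) = \frac{1}{1 + e^{-(z-\mu)/\nu}},\qquad
z = \max(0,\, C - z_{cf})$$

$\theta$ is the log-hazard slope (unitless, with standard error),
$\alpha$ (µg m$^{-3}$) sets the curvature of the logarithmic term and
$\mu$, $\nu$ (µg m$^{-3}$) place and scale the logistic weighting. The
counterfactual $z_{cf}$ defaults to 2.4 µg m$^{-3}$, the lowest exposure
observed in the underlying cohorts; it is configurable per parameter row.
At or below $z_{cf}$ all three components of the risk ratio are exactly 1.
The GEMM family was preferred over the Integrated Exposure-Response (IER)
family because its cohorts cover the annual-mean range relevant for
European domains (up to roughly 40 µg m$^{-3}$); the IER form
$RR(z) = 1 + \alpha(1 - e^{-\gamma z^{\delta}})$ is implemented behind the
same interface (`ier_rr()`), with the IER shape parameters stored in the
`alpha`, `mu`, `nu` columns of the shared schema.

Confidence intervals are propagated through $\theta \pm 1.96\,SE(\theta)$
only; no uncertainty is attached to $\alpha,\mu,\nu$. This matches how
95% CIs are conventionally reported for these functions and keeps the
bounds deterministic (no Monte Carlo).

### Parameter table and its provenance

The packaged table `inst/extdata/gemm_params.csv` covers six endpoints:
the NCD+LRI all-cause envelope, IHD, CEV, COPD, LC and LRI. The all-age
slopes and standard errors, the shape constants per endpoint, and the
NCD+LRI age-resolved slope ladder are transcriptions of the commonly
tabulated GEMM constants. The age-resolved IHD and CEV rows are
**synthetic**: cardiovascular risk ratios decline with the logarithm of
age, and the table models this as
$\theta(a) = \theta_{all}\,(1 + 0.9\,\log(60/a_{mid}))$ with the standard
error scaled by the same factor (constant coefficient of variation),
anchored at the transcribed all-age values. This is declared in the file
header; users with access to the original age-resolved constants can drop
in their own CSV via `load_rr_params(path = ...)`. The loader enforces
coverage: every endpoint needs an all-age row or a complete 12-band set,
and IHD/CEV must be age-resolved; COPD, LC and LRI are treated as
age-constant.

## Regions, baseline rates and demography

Europe is partitioned into Western, Central and Eastern regions (packaged
scheme `country_regions.csv`, ISO alpha-2 codes), reflecting systematic
differences in health systems, economy and climate. Baseline rates are
per-person annual probabilities — not per-100,000 — per region × endpoint
× band; `broadcast_coarse_rates()` expands coarser published bands to the
5-year grid with a logged message. The same rate table is used for the
present and the future scenario: holding baseline mortality constant
isolates the effect of concentration and population changes.

Population grids carry the twelve adult bands plus an optional under-25
band that is displayed in pyramids but never enters the mortality
computation. Sexes are merged on ingest. Future population is obtained by
multiplying each cell's band count by a national 2050/2010 ratio: within
a country the spatial pattern is scaled, not redistributed, because the
projection source is national. Cells holding population without a country
code are a hard error rather than a silent omission.

## Grid handling and numerical choices

* Coordinates are cell centers; cells are half-open boxes
  $[c - \Delta/2, c + \Delta/2)$, which makes conservative overlap
  computation unambiguous. Longitudes are normalised to $[-180, 180)$.
* The Earth is a sphere of radius 6371 km; cell areas use
  $A = R^2\,\Delta\lambda\,(\sin\varphi_{top} - \sin\varphi_{bottom})$.
  The sub-0.3% ellipsoidal error is irrelevant at this precision.
* Population regridding is conservative (overlap-area weighted in
  $\sin\varphi \times \lambda$ space), not bilinear: population is an
  extensive quantity and regional totals must be conserved. When the
  target covers the source, per-band totals are preserved to better than
  1e-6 relative (machine precision in practice).
* "Other NCD" is the NCD+LRI envelope minus the five specific causes,
  cellwise and per CI layer, floored at zero with a logged count of floor
  events. Because the subtraction shifts every endpoint's slope in the
  same direction, the resulting bounds can invert; the derived field
  restores the $low \le central \le high$ ordering cellwise. The envelope
  convention (the tabulated "all causes" equals the NCD+LRI function, not
  the sum of causes) matches how such tables add up: five causes plus
  other NCD reproduce the all-cause row exactly when no flooring occurs.
* Aggregation sums cells → regions → continent; CI bounds are summed
  linearly. Printed integer percentages use half-away-from-zero rounding
  (72.57% → +73%). Comparisons against external literature totals are
  expressed relative to this package's estimate,
  $100\,( \hat{x} - x_{ref})/\hat{x}$ (`percent_excess_vs_reference()`),
  which is the convention under which the published comparison
  percentages are mutually consistent.
* Scenario differencing is exact rowwise subtraction.
  `decompose_change()` attributes the change to drivers using the present
  scenario as common reference: climate-only and population-only terms
  are single-input perturbations and the interaction term closes the
  identity exactly. A Shapley-style symmetrised split was considered and
  rejected: the reference-based split has the simplest exact identity and
  the interaction term is reported, not hidden.

## The synthetic-data generator

Real assessments consume external concentration simulations, census grids
and mortality statistics. The generator replaces them with inputs that
have the right statistical structure while remaining fully reproducible
from one seed (each sub-generator runs on a derived stream):

* **Concentration**: spatially smooth lognormal background (median 8
  µg m$^{-3}$, log-spread 0.25, ~5° correlation scale) plus Gaussian
  urban plumes (default six, 15–25 µg m$^{-3}$ amplitude), so hotspot
  cells exceed the 25 µg m$^{-3}$ annual limit value while the domain
  mean stays at rural background levels.
* **Future perturbation**: a south-increase (+2 µg m$^{-3}$) /
  north-decrease (−0.3 µg m$^{-3}$) dipole with a logistic transition at
  47° N, clamped at zero — the qualitative pattern expected from reduced
  southern precipitation scavenging and increased northern wet removal
  under a strong forcing scenario.
* **Population**: clustered settlements (half co-located with
  concentration hotspots), 808 million total, an age pyramid with a 4%
  80+ share, and national projection ratios built to reproduce a future
  pyramid with a 9% 80+ share at 806 million — population aging with a
  nearly flat total. A toy six-country mask (two synthetic countries per
  region) avoids any geographic boundary data; the outermost ring is sea.
* **Baseline rates**: geometric increase with age (×1.35 per band) from
  per-endpoint bases at 25–29, with Western < Central < Eastern
  multipliers (1, 1.25, 1.6) and an all-cause envelope set to twice the
  sum of the specific causes so the envelope consistency check always
  holds.

What the generator does *not* emulate: real coastlines and country
shapes, within-country heterogeneity of aging, correlation between
baseline rates and concentration, seasonal cycles, or calibrated absolute
mortality levels. Passing tests therefore demonstrate correctness of the
arithmetic, conservation and propagation machinery on structurally
realistic inputs — not agreement with any real population's burden.

`known_truth_case()` provides three hand-computable bundles (a
three-region 1×3 domain with one cell at the counterfactual, an
all-counterfactual variant, and a single-cell case tuned to RR = 1.25 so
the expected total is exactly 200 deaths). Their expected summaries are
computed by an independent scalar evaluation of the identity — plain
`exp`/`log` arithmetic, no pipeline code — and the test suite requires
agreement to 1e-12 relative.

## Problem sizes and performance

The default synthetic domain is 50 × 80 cells at 0.5° (4,000 cells × 12
bands × 7 endpoints × 3 CI layers); a full present-plus-future assessment
runs in about a second, and the whole test suite in well under a minute.
Production domains at 0.11° (the resolution at which high-resolution
health impact estimates become reliable) are ~20× larger and remain
comfortably in memory; all kernels are vectorised over cells.

## Known limitations

* No years-of-life-lost, life-table or morbidity outcomes; deaths only.
* No uncertainty beyond the slope CI: shape parameters, baseline rates
  and population are treated as exact.
* Country masks assign one code per cell; coastal cells are not
  fractionally weighted.
* The IER implementation carries no published CI columns; its bounds
  collapse to the central estimate unless a slope SE is supplied.
* The packaged age-resolved IHD/CEV slopes are modeled, not transcribed
  (see above); analyses that hinge on the cardiovascular age gradient
  should substitute verified constants.
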