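---
title: "Methods: context-specific climate analogs for agricultural counties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: context-specific climate analogs for agricultural counties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agroanalogs)
```

## The model

A *climate analog* for a target location is another location whose
present-day climate resembles the target's projected future climate. This
package identifies analog counties for agricultural — specifically
specialty-crop — production, and does so with *context-specific* climate
variables (indices that matter to crop production) rather than only the
generic seasonal temperature and precipitation variables used by most
analog products. The two variable sets can select very different analogs,
which is the motivating observation for supporting both modes and
reporting their overlap.

### Climate variables

For each location and calendar year the package derives either:

* **context mode** (k = 5): annual growing degree days (GDD, base 0 °C,
  upper cutoff 29.44 °C, clipped-average method), frost-free season length
  (longest run of days with Tmin > 0 °C), summer heat degree hours (HDH,
  hourly exceedance above 32 °C over the Jul–Sep block), chill hours
  (hours in the inclusive 0–7.22 °C band between Oct 1 of the prior year
  and Mar 31), and precipitation uniformity (wettest minus driest monthly
  total, mm) — the Köppen-style one-number summary of precipitation
  seasonality; or
* **generic mode** (k = 8): mean temperature and total precipitation for
  each of the four three-month blocks JFM / AMJ / JAS / OND.

Hourly temperatures needed by HDH and chill are estimated from the daily
extremes with a single sine curve
\(T(h) = \frac{T_{max}+T_{min}}{2} + \frac{T_{max}-T_{min}}{2}
\sin\!\big(\tfrac{2\pi (h-9)}{24}\big)\),
which peaks at 15:00, bottoms at 03:00, conserves the daily mean exactly
and stays inside \([T_{min}, T_{max}]\). Several sine/exponential
disaggregation variants exist; this is the simplest member of the family
with those conservation properties, and the package's tests pin its exact
values so any future change is visible.

### Distance, sigma dissimilarity, classification

County climate is summarized by a climate *normal* (multi-year mean
vector \(\mu\)) and the *interannual climatic variability* (ICV): the
covariance \(C\) of the detrended annual values. For target county \(t\)
with future normal \(\mu_t^{fut}\) (one per GCM and scenario) and
candidate county \(c\) with historical normal \(\mu_c\) and historical
ICV \(C_c\), the dissimilarity is the ICV-scaled Mahalanobis distance

\[ D_{tc} = \sqrt{(\mu_t^{fut}-\mu_c)^\top C_c^{-1} (\mu_t^{fut}-\mu_c)}. \]

\(D\) is mapped to *sigma dissimilarity*: the chi-distribution (dof = k)
percentile of \(D\) is re-expressed as the equivalent one-dimensional
sigma level through the chi quantile with 1 dof. On this scale 2σ is the
95th percentile and 4σ the 99.994th. Candidates with σ ≤ 2 are
*acceptable analogs*; targets at σ ≥ 4 from every candidate have *novel*
climates (both thresholds inclusive). A candidate enters the *consensus*
analog set for a target/scenario when it is acceptable in at least
\(m = \lfloor 0.25\, n_{GCM} \rfloor + 1\) ensemble members — 5 of 19 for
the conventional ensemble, 2 of the default 6 pseudo-GCMs here — i.e. in
strictly more than a quarter of the ensemble.

Design choices where the method is genuinely open:

* **Whose ICV scales the distance.** The candidate county's historical
  ICV is used: the candidate is the place actually experiencing the
  climate being offered as an analog, and its own historical variability
  is the natural yardstick for "indistinguishable from normal variation".
* **Degrees of freedom.** dof = k (5 or 8), with no principal-component
  truncation: with at most 8 reasonably conditioned variables, truncation
  (used upstream for dozens of correlated variables) is unnecessary; the
  ridge below handles degeneracy.
* **Detrending before ICV.** Each variable is detrended linearly against
  the year label before the covariance is formed, so a warming trend does
  not inflate the variability yardstick. Regressing on the year *label*
  (not row order) keeps profiles invariant to permuting years.
* **Ridge regularization.** If the ICV covariance has condition number
  above 1e10 (e.g. a county whose frost-free season is 365 days every
  year), `eps * I` is added with `eps = 1e-8 * mean(diag(C))`, falling
  back to an absolute 1e-8 when the covariance is identically zero. On
  well-conditioned inputs this perturbs distances by far less than 0.1 %.
* **Self-pairs.** A target is always in the candidate pool (and, under
  mild warming, often in its own consensus set). Self-pairs are excluded
  from the crop-match statistics and from the "analog in *another*
  specialty county" determination, since a self-match is identically 1.
* **Sigma cap.** Beyond ~8σ the chi-1 quantile of the upper tail is not
  representable in double precision; σ is computed through log survival
  functions and capped at 10 with a saturation flag. Ordering at the 2σ
  and 4σ decision thresholds is unaffected.
* **Empty-set overlap.** The Jaccard overlap of two *empty* analog sets
  is defined as 1 (two "no analog anywhere" verdicts agree) but flagged,
  so reporting can exclude those targets.

### Crop mix

Counties are coded *specialty* when their acreage in the vegetable,
fruit, tree-nut and berry census groups is positive. Targets are the
specialty counties that jointly cover 99 % of specialty acreage (largest
first; ties broken by county id). For each target–analog pair the *match
fraction* is the Jaccard similarity of the two specialty crop sets, and
each target reports the maximum over its consensus analogs. Counties with
disclosure-suppressed (incomplete) crop lists stay in analog sets but are
excluded from match statistics.

## The synthetic world

Real inputs (a gridded daily weather product, a downscaled multi-GCM
ensemble, a cropland raster, a census) are replaced for testing by a
seeded generator whose statistical structure matches what the method
actually consumes:

* a `rows x cols` abstract grid (default 20 x 20) where the row index
  plays latitude's role: annual-mean temperature 12–26 °C from north to
  south, seasonal half-amplitude 13–9 °C, diurnal range 8–12 °C along
  columns; 365-day years with the seasonal peak in mid-July;
* two precipitation regimes split along columns: *winter-wet* columns
  place 85 % of the annual total in Oct–Mar (the ≥ 70 % contract with
  margin), *uniform* columns are proportional to month length (within
  ±25 % of the monthly mean); annual totals 300–1200 mm along columns;
* noise: per-cell daily Gaussian noise (sd 1.5 °C) on the daily mean
  temperature, grid-shared annual temperature effects (sd 0.6 °C),
  grid-shared lognormal annual precipitation factors (sd 0.15), and
  per-day gamma precipitation weights (shape 1). Day noise is AR(0) —
  the simplest structure giving a non-degenerate ICV;
* a pseudo-GCM ensemble (default 6 members, 2 scenarios) built as
  historical climatology + per-GCM warming offset (scenario means 2.0 and
  3.5 °C, per-GCM spread ±0.75 °C) + fresh noise; 10 future years are
  generated per member since only the future *normal* is ever used;
* counties as contiguous row-major runs of near-equal size (40 counties
  of 10 cells by default), each with a quadrant region label; a per-cell
  agricultural fraction U(0.05, 0.95) against the inclusive 1/8 mask
  threshold; and a heavy-tailed (lognormal, sdlog 1.8) specialty crop
  census with climate-correlated crop choices, 80 % specialty counties
  and 10 % disclosure suppression.

These values were fixed once, before any acceptance measurement, as a
caricature of the real system's magnitudes; they are not tuned.

### Planted ground truth

`plant_known_analog(dataset, target, analog)` overwrites the target
county's future series (every GCM/scenario) with the analog county's
historical ag-cell-mean climatology plus the dataset's stored year
effects *and freshly drawn day-level noise with the dataset's own
parameters*. The day-level noise is not optional: the derived indices are
nonlinear in the daily values (clipping, hourly thresholds, monthly
maxima of gamma-weighted days), so a noise-free planted series has
Jensen-shifted normals — in a pilot check the monthly precipitation range
came out 31 mm against the analog's 68 mm, enough to push the planted
pair past 4σ. With matched noise the pair recovers with σ well below 1 in
every ensemble member at the default scale. By default planting also
copies the analog's crop list onto the target and raises both counties'
specialty acreage above the prior maximum, so the planted target cannot
be silently dropped by the 99 %-coverage target selection before reaching
the stage it is meant to exercise.

Recovery tests place the pair in the temperate mid-grid. This is a stated
limitation, not an accident: counties where an index is degenerate (a
never-frost south county has zero season-length variance; a never-hot
north county may log zero HDH in thirty years straight) get a ridge-sized
yardstick for that variable, and any finite future deviation then
saturates the distance. Variance-scaled distances inherently behave this
way at the edge of a variable's climatic range; the real-data analogue is
a Florida county's chill hours.

### What a green test does and does not establish

The generator has no spatial autocorrelation of weather noise, no
bias-correction artifacts, no leap days, no elevation, and counties are
bands rather than polygons. Green tests establish that the *method* —
indices, aggregation, ICV scaling, sigma mapping, consensus, crop
matching — is implemented to contract and recovers known structure; they
say nothing about how well 6 pseudo-GCMs approximate a real 19-member
CMIP ensemble, and the paper-scale headline percentages are out of reach
at desk scale by design.

## Numerical notes

* Mahalanobis distances are solved through a Cholesky factorization;
  tests compare 1000 random SPD systems against an explicit-inverse
  oracle at 1e-10.
* HDH and chill computed through the vectorized array engine equal a
  brute-force hour-by-hour summation on random days at 1e-10.
* σ at dof 1 short-circuits to the identity (an exact mathematical
  identity), so the dof = 1 contract holds to machine precision.
* The first year of any series has an incomplete chill season (no prior
  Oct–Dec): it is dropped from context-mode series (29 of 30 historical
  years survive) rather than zero-filled.
* Ties in the acreage sort are broken by county id; the county that
  crosses the 99 % threshold is included.

## Known limitations

Unweighted (not area-weighted) cell averaging within counties; no
crop-specific GDD bases or alternative chill models (Utah, dynamic); no
distribution-shape or time-series distance extensions; the CLI's
file-based stages hold each weather block in memory, which bounds
practical grid sizes to desk scale.
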