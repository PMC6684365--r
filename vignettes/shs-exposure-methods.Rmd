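---
title: "Methods: assessing occupational second-hand smoke exposure from multi-method monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assessing occupational second-hand smoke exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shsexposure)
```

## The problem

Staff in institutions where smoking is still permitted indoors — prisons
being the prominent example — are occupationally exposed to second-hand
tobacco smoke (SHS). There is no workplace exposure limit for SHS and no
single standard measurement method, so exposure assessment combines several
complementary instruments: multi-day area monitoring of fine particulate
matter (PM2.5) with low-cost optical particle counters, passive-sampler
measurement of airborne nicotine (the SHS-specific tracer), short mobile
measurements during specific duties, and pre/post-shift salivary cotinine
as a biomarker of actual nicotine intake. This package implements the full
data pipeline for such a campaign: device-count conversion, exposure
metrics, nicotine quality control, and the toxicokinetic back-calculation
that converts a biomarker increment into an equivalent air concentration.

## Count-to-mass conversion

The Dylos DC1700 reports particle counts per 0.01 cubic foot in two size
channels, >0.5 µm and >2.5 µm. The difference between the channels counts
fine particles in the 0.5–2.5 µm band, which carries the SHS signal. Mass
concentration is obtained through a monotone piecewise-linear mapping of
that difference, scaled by a per-device factor derived from chamber
comparison against a photometric reference configured for SHS aerosol
(photometer correction factor 0.295):

$$\mathrm{PM}_{2.5}(t) = f_\mathrm{dev}\; g\!\left(N_{>0.5}(t) - N_{>2.5}(t)\right)$$

where $g$ is non-decreasing with $g(0)=0$. Published conversions for this
device class are count-dependent; the piecewise-linear family covers both
fixed-slope and count-dependent forms. The shipped default (breakpoints at
0, 1000 and 10000 counts with slopes 0.010, 0.012 and 0.015 µg/m³ per
count) is a synthetic default documented as such and fully overridable in
the configuration file; every headline statistic the package reproduces
operates on already-converted concentrations, so nothing downstream depends
on these coefficients. Channel inversions (coarse > fine, possible through
counting noise) are clamped to zero with a warning rather than propagated
as negative masses. The mapping must be strictly increasing to be
invertible; the simulator uses the inverse to produce realistic count logs.

## Exposure metrics

Per-series summaries use the arithmetic mean, the sample standard deviation
(n−1), the maximum and the count of observed minutes. Missing minutes are
excluded from every denominator, never imputed: time-fraction statistics
refer to observed 1-minute measurements only.

**Exceedance fractions** report the percentage of observed minutes strictly
above each benchmark (defaults 10 and 25 µg/m³, the WHO indoor-air annual
and 24-h guideline values, and 246 µg/m³, the pre-smoke-free-legislation
average for Scottish bars). Strict inequality is a documented convention —
"exceeds" is read literally; the choice is immaterial for continuous data.

**Day/night medians** split each minute by wall clock into the half-open
day window [07:00, 23:00) and its complement, so the two classes tile the
24-h clock exactly; the half-open end avoids double-counting the boundary
minute. Medians are over observed minutes in each class.

**Cross-prison pooling** takes column-wise medians over the per-site rows,
with the mean of the two central order statistics at even counts — the
convention that reproduces the published overall-median row (e.g. 0.32
µg/m³ from 14 nicotine values).

**Mobile summaries** pool short walk-through measurements across sites into
a per-location/activity table (n, min, max, mean, SD, median, IQR) ordered
by median, plus pooled geometric mean and GSD. GSD is computed as
exp of the (n−1) sample SD of natural-log values, the standard
occupational-hygiene convention.

## Airborne nicotine processing

Passive diffusion monitors give one time-averaged concentration per
deployment, with an analytical LOD of 0.031 µg/m³ over a 6-day period.
Processing follows fixed QC rules, in order:

1. **Tampered monitors** (e.g. membrane damage) are excluded with a logged
   reason.
2. **Field blanks** never contribute a site value; a blank above the LOD
   raises a contamination warning for the whole batch.
3. **Duplicate pairs** merge to their arithmetic mean; agreement is
   reported as the percent deviation of each member from that mean.
4. **Censored filters** are substituted at half the LOD (0.016 µg/m³) for
   summary statistics — note this is the quoted rounded value, accepted by
   the validator as half of 0.031 up to rounding.

The paired PM–nicotine comparison uses only sites where both monitors ran
contemporaneously, and quantifies agreement as the R² of the ordinary
least-squares fit of nicotine on PM — equal to the squared Pearson
correlation for a simple regression, which is how the package's tests
cross-check it. Input concentrations are taken as reported; the package
deliberately surfaces rather than corrects the PM:nicotine ratio, since a
systematic nicotine loss in storage or transport cannot be distinguished
from a true low concentration at analysis time.

## The cotinine back-calculation

The estimator at the package's core, `cotinine_exposure()`, converts
pre/post-shift salivary cotinine pairs into a shift-average SHS-PM2.5
equivalent.

**Eligibility.** Participants are excluded, with per-reason tallies, if a
questionnaire flag shows a non-SHS nicotine source (smoking, nicotine
products, a smoking cohabitant or vehicle), if either sample is invalid or
the post-shift time does not follow the pre-shift time, or if either value
strictly exceeds 5 ng/ml — the optimal discrimination threshold between
smokers and SHS-exposed non-smokers. Boundary equality (exactly 5 ng/ml)
is retained.

**Censoring.** The assay LOD is 0.1 ng/ml; censored values are substituted
at 0.05 ng/ml, matching the national-survey convention so cohort summaries
remain comparable.

**Elimination projection.** Salivary cotinine eliminates first-order with
population half-life $t_{1/2}$ = 16 h (configurable). The hypothetical
post-shift value with zero intake is

$$\hat c_\mathrm{post} = c_\mathrm{pre}\, 2^{-\Delta t / t_{1/2}},$$

with $\Delta t$ each participant's own elapsed time from the recorded
sample timestamps. The projection is a semigroup in elapsed time, which
the tests verify directly.

**Increment and sub-sample.** The shift increment is the measured
post-shift value minus the projection; positive values indicate intake
during the shift. Only participants whose pre-shift sample and projected
post-shift value both exceed the LOD can express a measurable change, so
the PM-equivalent conversion is restricted to that sub-sample. Measured
post-shift values are used as reported (half-LOD substituted when
censored); the sub-sample rules already guarantee a quantified pre-shift
anchor.

**Dosimetry chain.** The increment converts to air concentrations through
the standard passive-smoking dosimetry relations: nicotine inhaled at
breathing rate $\rho$ = 0.72 m³/h is absorbed with fraction $f_a$ = 0.71,
metabolised to cotinine with fraction $f_c$ = 0.78, distributed over
$V_d$ = 63 l (0.9 l/kg × 70 kg) and read in saliva at $r$ = 1.1 times the
plasma concentration. The composed uptake rate

$$k = \rho f_a f_c r / V_d \approx 0.00696\ \mathrm{ng\,ml^{-1}\ per\ \mu g\,m^{-3}\,h}$$

inverts to a shift-average airborne nicotine concentration
$\bar N = \delta/(k\,\Delta t)$, and SHS-PM2.5 is taken as 10 times
airborne nicotine, the ratio that holds where SHS dominates the particle
load. The cohort-level figure converts the sub-sample median increment at
the representative 8-h shift: a median increment of 0.138 ng/ml gives

```{r}
delta_to_pm_equivalent(0.138)
```

The chain's constituent values are each standard in the SHS dosimetry
literature; they were fixed as a set by checking, once, that the composed
coefficient reproduces the published cohort-level worked example, and are
frozen in `rosetta_params()`. Within-shift elimination of newly formed
cotinine is neglected (the accumulation convention of the worked example);
over an 8-h shift this is a ~15% effect absorbed by the composed
coefficient. All constants are configuration, not code.

## The synthetic-data generator

No raw measurement data are deposited, so the generator produces every
pipeline input with the statistical structure the campaign assumes:

- **Area PM**: minute-resolution indoor PM2.5 as an ambient baseline plus
  a Poisson process of smoking events (higher intensity 07:00–23:00 than
  overnight), each contributing a log-normal peak increment that decays
  exponentially with air exchange, plus Gaussian observation noise floored
  at zero. Defaults (baseline 6.6 µg/m³, 3 vs 0.3 events/h, event GM
  12 µg/m³ GSD 2, decay 1.5 h⁻¹, noise SD 2 µg/m³) give 6-day means around
  25–30 µg/m³ — inside the 10–140 µg/m³ range spanned by the monitored
  sites — with day medians well above night medians. These are plausible
  invented parameters, not claims about any prison.
- **Counts**: the generated truth is pushed through the inverse calibration
  and quantised, with the coarse channel a small Poisson fraction, so
  converting the synthetic log back recovers the truth to within
  quantisation.
- **Nicotine**: the time-averaged SHS component divided by the PM:nicotine
  ratio plus sampler noise, censored at 0.031 µg/m³.
- **Cotinine cohort**: log-normal pre-shift values (GM 0.10 ng/ml, GSD 2.5,
  chosen so roughly a third of workers clear both sub-sample rules, as in
  the study cohort), post-shift values from the same elimination-plus-uptake
  model the pipeline inverts, assay noise SD 0.05 ng/ml, floored at zero
  and censored below the LOD. The default uptake coefficient is the exact
  inverse of the configured dosimetry chain, which makes parameter-recovery
  tests well-posed: simulated constant exposures of 10, 25 and 50 µg/m³
  are recovered by the full pipeline within 15% at the cohort median.

What the generator does **not** emulate: occupancy patterns and ventilation
differences between real sites, correlated multi-day weather in the
ambient series, non-SHS particle sources (cooking, dust), between-worker
variation in breathing rate and metabolism, and any systematic
storage/transport loss of nicotine from passive samplers. Passing tests
therefore demonstrate the pipeline's arithmetic and statistical behaviour
under the stated model, not instrument performance in the field.

## Numerical and design choices

- The Dylos log dialect (comma-separated, optional header, minute
  timestamps `YYYY-MM-DD HH:MM`) is a documented assumption; the timestamp
  format is an argument for locale variants. Readers reject rather than
  coerce invalid rows, naming the offending line.
- Timestamps are naive local clock time throughout; the analysis compares
  within-site clock windows only, so no timezone arithmetic is performed.
- Zero-exposure cohorts with assay noise yield increments centred on zero
  (|median of 1,000 cohort medians| under 2 Monte-Carlo SE); the test
  scenario places the pre-shift GM well above the LOD so the check
  isolates the increment arithmetic from censoring, which is exercised
  separately.
- Ambient station matching restricts the station series to the in-prison
  measurement span at the station's native resolution (hourly assumed) —
  no interpolation.
- Problem sizes in the test suite — 6-day single-site simulations, 100-seed
  Monte-Carlo envelopes, 1,000 zero-exposure cohorts of 100 workers,
  recovery at the 407-worker study scale — were chosen as the smallest
  sizes at which each distributional property is sharp.

## Known limitations

- The half-LOD substitution is a simple bound-based imputation; maximum
  likelihood or regression-on-order-statistics estimators for censored
  lognormal data would use the information below the LOD more efficiently,
  but would break comparability with the published convention.
- The elimination model is single-compartment with one population
  half-life; between-individual toxicokinetic variation propagates
  directly into individual PM equivalents, which is why cohort-level
  medians are the primary output.
- The PM:nicotine ratio of 10 is an environment-average; in settings where
  SHS is not the dominant particle source the PM-equivalent scale
  overstates SHS.
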