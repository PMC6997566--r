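---
title: "Parameterizing wheat canopy senescence from spectral index time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parameterizing wheat canopy senescence from spectral index time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senodyn)
library(data.table)
```

## The problem

The ability of a wheat genotype to *stay green* during grain filling
affects grain yield and grain protein concentration. Breeding programs
therefore score canopy greenness visually — typically on a 0–10 scale
(10 = fully green) every few days from early grain fill to maturity —
and summarize each plot's decline by a handful of dynamics parameters.
Visual scoring does not scale to thousands of plots; repeated
hyperspectral reflectance measurements do. `senodyn` implements an
index-based parameterization of canopy senescence dynamics: spectral
index time series are treated exactly like scorings, and both are
reduced to the thermal times at which the canopy passed 80 %, 50 % and
20 % of its maximal greenness.

## Thermal time

All dynamics are expressed in growing degree-days (°C days) after
heading (BBCH 59). From hourly records of maximum and minimum
temperature, the daily mean above a base temperature is

$$\bar T_d = \frac{1}{24}\sum_{h=1}^{24}
  \frac{\max T_{d,h} + \min T_{d,h}}{2} - T_{base},$$

and GDD is the running sum of $\bar T_d$ from the day after the
reference date. The base temperature defaults to 0 °C, the standard
choice for winter wheat in temperate climates; at that base the position
of $T_{base}$ inside or outside the hourly sum is algebraically
indifferent, and the optional clamping of negative daily means at zero
(on by default, the common agronomic convention) never triggers during
grain fill. Days with fewer than 20 of 24 hourly records are treated as
missing data rather than silently averaged.

## From spectra to time courses

Plot-level reflectance spectra (350–2500 nm) are averaged per plot and
date, trimmed to 400–1350, 1475–1781 and 1991–2400 nm (dropping the
noisy detector edge below 400 nm and the atmospheric water-vapour
bands), and reduced to spectral indices through a band-math registry.
Bands resolve to the nearest grid wavelength within ±2 nm; anything
farther is a hard error so indices never drift silently onto the wrong
band. The registry ships the published formulas for NDVI, PSRI, NDRE,
mND705, PSND1, VARIgreen and PRInorm; PSRI uses R750 as its third band,
with `three_band_template()` available for any `(Rx − Ry)/Rz` variant.
First derivatives, continuum removal (division by the upper convex
hull) and column standardization (sample sd, reusable transform) are
provided for full-spectrum work.

Each per-plot index series is min–max scaled to 0–10 over that plot's
assessment period and oriented so that 10 always means the greenest
observed state: senescence-positive indices such as PSRI are inverted.
Per-plot scaling is the only reading consistent with extracting
plot-level dynamics; it also means a scaled course always attains 0 and
10 somewhere in the period. Visual scorings are already on the 0–10
scale and enter unscaled via `time_course()` — rescaling them would
stretch the scale whenever a plot never reaches exactly 0 or 10 and
would distort threshold timing.

## Curve models and dynamics parameters

Two curve models are fitted against thermal time $t$:

* **Linear interpolation** — the exact piecewise-linear interpolant.
* **Gompertz** — $S(t) = 10\,e^{-e^{-b(t-M)}}$ with asymptotes fixed at
  0 and 10, where $M$ (°C days) is the time of maximal senescence rate
  and $b$ (per °C day) the rate parameter. For greenness decaying from
  10 to 0, $b < 0$; rising senescence-degree courses fit with $b > 0$.

Onset, midpoint and end of senescence are the earliest times the curve
falls below 8, 5 and 2 (i.e. 80/50/20 % of the scaled maximum), and the
duration is $T_{sen} = End - On$. For the linear model the first
downward segment crossing is used (later noise-driven re-rises are
ignored, because "falls below" means the earliest such time); for the
Gompertz model the closed form
$t^\* = M - \ln(-\ln(S^\*/10))/b$ applies. A threshold never reached
leaves the parameter missing and flags the plot.

Two courses are compared by the **bias** (mean candidate − reference
difference of a parameter, in °C days) and the **curve error**, the
integral $\int |A(t) - B(t)|\,dt$ over the overlapping thermal window,
computed exactly by trapezoid on the union of both knot sets plus the
intersection points of the two piecewise-linear curves.

```{r closed-form}
t <- seq(400, 900, by = 10)
course <- time_course(t, gompertz_greenness(t, -0.02, 700))
extract_parameters(fit_gompertz(course, n_starts = 50, seed = 1))
closed_form_truth(-0.02, 700)
```

### Numerical choices

The Gompertz fit is a seeded multistart around damped
(Levenberg–Marquardt) least squares: half the starts are a deterministic
grid with $|b|$ log-spaced in $[10^{-3}, 10^{-1}]$ (both signs) and $M$
spanning the observed thermal window, half are uniform random draws;
the best converged start by residual sum of squares wins (50 starts by
default, convergence tolerances $10^{-10}$ on the LM criteria, 200
iterations). Courses need ≥ 4 points for a Gompertz fit, ≥ 2 for the
interpolant, ≥ 3 to be scaled at all; constant series are degenerate
and the plot is excluded with an explicit reason rather than patched.
Orientation is taken from the registry; for unknown sources
`infer_orientation()` uses the pooled correlation of raw values with
thermal time and refuses to guess when $|r| < 0.2$.

## The synthetic trial generator

Real deposited field data are not required: `simulate_trial()` generates
a complete trial with retained ground truth, and every downstream stage
is exercised against it. The generative model, chosen as the minimal
structure that reproduces the field-observed reflectance patterns:

* **Trial** — 150 genotypes × 2 replicates (300 plots). Genotype
  effects enter through $(b, M)$: $M \sim N(700, 60^2)$ °C days
  truncated to [520, 880] and $|b| \sim N(0.02, 0.004^2)$ (floor 0.008),
  matching reported trial-level summaries of onset ≈ 650 °C days and
  duration ≈ 100 °C days; replicates share the genotype values with
  plot-level jitter (sd 15 °C days) on $M$. Heading dates spread with
  sd 3 days around June 1.
* **Scorings** — campaign dates every 3 days (configurable) anchored on
  the median heading date, spanning 300–1150 °C days;
  $score = \mathrm{clamp}(\mathrm{round}(10\,G + \varepsilon), 0, 10)$
  with $\varepsilon \sim N(0, 0.5^2)$.
* **Spectra** — linear two-endmember mixing
  $R(\lambda) = G\,\mathrm{green}(\lambda) + (1-G)\,\mathrm{senescent}(\lambda)$
  on a 1-nm grid at 9 campaign dates. The green endmember has
  chlorophyll absorption wells around 500 and 678 nm, a steep red edge
  to an NIR plateau of 0.48 and leaf-water dips near 1450/1940 nm; the
  senescent endmember has elevated flat VIS reflectance, a muted
  red-edge remnant to a reduced but substantial NIR plateau (dead tissue
  still scatters) and elevated SWIR. By construction reflectance rises
  with senescence in 450–680 and 2000–2400 nm and falls in
  760–1300 nm.
* **Noise** — multiplicative, split into a spectrally correlated
  common-mode factor per spectrum (sd 2 %, calibration/illumination
  drift) and an independent per-band component (sd 0.5 %, detector
  noise). The split matters: plot-averaged field spectra have strongly
  correlated adjacent bands, and ratio indices cancel exactly the
  common mode — an i.i.d.-only model would bury small band differences
  such as the PSRI numerator in noise the instrument does not produce.
* **Confound** — a multiplicative depression of the 750–1350 nm window
  only, depth 15 %, with a rising logistic time profile (onset
  450 °C days after heading, width 80). It emulates spike-orientation
  and canopy-structure changes that set in during early grain fill and
  increasingly dominate the sensor's view. A profile that decays before
  onset would be absorbed entirely by per-plot min–max scaling and
  could never distort derived dynamics, contradicting the field
  observation it models.
* **Traits** — $GY = \beta_0 + \beta_1 On_{true} + e$ with
  $\beta_1 > 0$ and residual sd chosen so the expected correlation with
  true onset equals the configured $\rho = 0.37$; protein is linked to
  the true duration with $\rho = -0.30$.

Because the NIR confound enters NDVI through R800 — one of its two
constituent bands — but PSRI only through its denominator R750 (a small
fraction of PSRI's dynamic range while the canopy is green), the
generator reproduces the characteristic field result: NDVI-derived
onset is biased early by roughly −20 °C days while PSRI-derived onset
is nearly unbiased, and PSRI tracks the scoring course with a smaller
area-between-curves error.

What the generator does **not** emulate: soil and shadow endmembers,
spatial field trends (no row/range structure, hence no spatial
correction stage), genotype-by-year interaction, disease, and the full
physics of canopy structure (the confound is a stylized multiplicative
window effect, not a radiative-transfer result). Passing recovery tests
on this generator therefore demonstrates correctness of the machinery
and qualitative realism of the mechanisms, not field-level accuracy.

## Evaluation machinery

`compare_parameters()` reports per-parameter Pearson r, descriptive
two-sided p (t approximation, no multiplicity correction by default —
a Bonferroni option exists), bias, and the mean curve error over paired
plots. `trait_correlations()` ranks features by $|r|$ against a trait.
`recursive_feature_elimination()` runs repeated random 75/25
train/held-out splits (default 30); per resample it fits the learner on
all current features, drops the least important feature, refits down
through the requested subset sizes, and records held-out RMSE. A
feature's rank is the size of the smallest subset still containing it
(rank 1 = last survivor; survivors of the smallest subset are ordered
by final importance). The default learner is a 200-tree random forest
with permutation importance — robust to non-informative and collinear
predictors — injected through a `fit`/`predict`/`importance` contract
so any regressor can substitute.

## Known limitations

* With 2-day scorings (≈ 30 °C days spacing) and scoring noise sd 0.5,
  the per-plot onset estimate carries a mean absolute error of about
  7 °C days. This is not an optimizer artifact: the Fisher information
  of a Gompertz course sampled at that density bounds the onset sd at
  ≈ 8 °C days, and the multistart LM fit attains that bound. Denser
  scoring or replicate averaging is the only way to better precision.
* Min–max scaling makes every derived parameter conditional on the
  assessment window; truncated windows (senescence not complete) shift
  thresholds. Plots whose course never crosses a threshold are flagged,
  not extrapolated.
* Index-vs-scoring biases contain an intrinsic component from the
  nonlinearity of the index as a function of green fraction (PSRI's
  mid/end lag is visible in the synthetic trial exactly as in field
  reports); bias comparisons between indices are therefore more
  meaningful than absolute biases.
* The default test problem sizes (300-plot trials, 200-plot recovery
  runs, 30-resample RFE) were chosen to make the full suite run in a
  few minutes on a single core while keeping sampling error on reported
  correlations near 0.05.

## Reproducing the analysis

The `analysis/` directory holds the numbered workflow
(`01_simulate_trial.R` … `05_trait_analysis.R`) writing all tables under
`results/`; `scripts/acceptance.R --seed <s> --out <path>` recomputes
the headline quantities from scratch and writes them as JSON. Both run
from the repository root against the installed package.
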