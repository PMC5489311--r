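---
title: "Methods: from band reflectance to per-pixel bloom-driver importance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from band reflectance to per-pixel bloom-driver importance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloomdyn)
```

`bloomdyn` implements an analysis chain for harmful-algal-bloom (HAB)
indicators in a shallow eutrophic basin observed by an ocean-colour sensor:
chlorophyll-a (Chl-a) retrieval from two red/red-edge bands, 14-day
compositing, two-step gap filling, Morlet wavelet periodicity analysis with a
red-noise null, variance-inflation-factor (VIF) screening of environmental
covariates, and per-pixel seasonal variable-importance mapping with a
from-scratch MARS (multivariate adaptive regression splines) implementation.
This vignette records the models, the tunable parameters, and the numerical
decisions, in the order the pipeline runs them.

## Chl-a retrieval and compositing

The semi-analytical band-ratio retrieval inverts an absorption budget at the
red Chl-a absorption peak. With water-leaving reflectances $B(665)$ and
$B(705)$, pure-water absorptions $a_w(665), a_w(709)$ (m$^{-1}$), a scalar
backscattering coefficient $b_b$ (m$^{-1}$), and the Chl-a specific
absorption $\gamma$ (default 0.68 m$^2$ mg$^{-1}$):

$$\mathrm{Chl} \;=\; \frac{\dfrac{B(705)}{B(665)}\,\bigl(a_w(709)+b_b\bigr)\;-\;b_b\;-\;a_w(665)}{\gamma}.$$

Retrieval literature for turbid inland waters varies in the red-edge band
centre (705 vs 708.75 nm) and in the water-absorption values used, so
`optical_constants()` treats all four numbers as configuration (defaults
$a_w(665) = 0.40$, $a_w(709) = 0.70$, $b_b = 1.5$ m$^{-1}$); $b_b$ is a known
scalar because no third band is available to estimate it. Negative
retrievals, which occur at low band ratios, are floored at zero and counted
(`n_floored`), since the quantity is a concentration. `gen_reflectance()`
inverts the same algebra exactly, which gives the round-trip identity the
tests use.

Spatial aggregation (`regrid`) is the area-weighted mean of *observed*
source cells under each target cell — a target is missing only when all its
sources are — chosen over nearest-neighbour (also reasonable) because it is
void-tolerant and preserves means. Temporal compositing (`composite_biweekly`)
averages whatever daily values fall in each 14-day bin. The study calendar is
267 bins starting 5 Jan 2002; a bin belongs to the calendar when its *start*
is on or before the end date (21 Mar 2012). A bin's season is the
meteorological season (MAM/JJA/SON/DJF) of its midpoint date, since 14-day
bins straddle month boundaries. Pixels with *strictly more than* 50% of bins
missing are removed before filling (exactly half missing is retained).

## Two-step gap filling

Step 1 (`knn_impute`) is spatial: each retained pixel's $k$ nearest
neighbours are fixed once, by Euclidean distance between whole time series
over jointly observed bins, scaled by $\sqrt{T/\text{overlap}}$ so thin
overlaps are not spuriously close; $k$ defaults to
$\mathrm{round}(\sqrt{P})$ for $P$ retained pixels (the usual
square-root-of-sample-size imputation heuristic). A missing cell is the
inverse-distance weighted mean of the neighbour values at that bin; a
neighbour at distance zero is used directly. Step 2 (`climatology_fill`)
handles bins where whole neighbourhoods were cloud-masked simultaneously:
the mean of the same pixel's values within ±14 calendar days of the target's
day-of-year in any *other* year (all other years, not just adjacent ones;
configurable via the window).

One numerical decision matters here: **imputed cells never serve as donors**.
Each grid carries a per-cell `imputed` mask; both fills freeze their donor
sets to genuinely observed cells. This stops imputation error from cascading
through chains of fills, and it makes both operations idempotent — re-running
a fill on its own output changes nothing. The cost is that a cell with no
observed donor stays missing and is reported, rather than being reached
through second-hand values.

## Wavelet periodicity

The spatially averaged (unweighted pixel mean) Chl-a series is analysed with
the standard Morlet continuous wavelet transform,
$\psi_0(\eta) = \pi^{-1/4} e^{i\omega_0\eta} e^{-\eta^2/2}$ with
$\omega_0 = 6$, on the dyadic scale set $s_j = s_0\,2^{j\,\delta j}$,
$s_0 = 2\delta t$, $\delta j = 0.25$. $\delta t$ is expressed in years
(14/365.25) so periods read directly in years. The power is $|W_n(s)|^2$, the
global spectrum its time mean per scale, and the cone of influence uses the
Morlet e-folding time $\sqrt{2}s$. The 95% significance level against a red
noise null uses the theoretical AR(1) spectrum at the scale's equivalent
Fourier period, with the lag-1 autocorrelation estimated from the series and
local power treated as $\chi^2_2$ about its mean; the Monte-Carlo
calibration test confirms a 5% (±1.5) exceedance rate inside the cone under
a matched AR(1) null at 1000 replicates.

Numerical choices:

* **Padding.** The frequency-domain convolution pads to four times the next
  power of two rather than the customary next power of two. With minimal
  padding the Morlet tails at the largest scales wrap around the circular
  buffer and the FFT route drifts from the exact time-domain convolution at
  the percent level; 4× padding brings the two independent routes into
  agreement at better than $10^{-6}$, which is the package's own
  cross-implementation contract.
* **Sampling alias.** The closed-form Morlet spectrum is evaluated as the
  folded (Poisson-summation) spectrum of the *sampled* wavelet — the first
  alias image is added — so the FFT route reproduces the discrete
  convolution exactly even at the smallest scales ($s \approx 2\delta t$),
  where the naive truncation at Nyquist loses mass.
* **Scale range.** Scales run up to $N\delta t/2$: longer scales lie outside
  the cone of influence at every time step and only accumulate edge ripple.
* **Peak interpolation.** The dyadic grid quantises peak periods by up to
  $2^{\delta j/2} \approx 9\%$. `dominant_periods()` therefore fits a
  parabola through each local maximum of the global spectrum and its two
  neighbours on the log-period axis (never moving a peak by more than one
  scale step). On a noiseless annual-plus-semiannual series the recovered
  periods land within ~1% of 1.0 and 0.5 years; without interpolation they
  sit on the nearest grid scales (1.065 and 0.533 years).

## Covariates, VIF screening, and lags

Nine biweekly covariates are used: total phosphorus (TP), soluble reactive
phosphorus (SRP), nitrate+nitrite (NO23), total Kjeldahl nitrogen (TKN),
river discharge (Q), precipitation (PCP), wind speed (Wind), water
temperature (WTMP), and solar radiation (Rs). `aggregate_biweekly()` reduces
heterogeneous raw series — hourly to daily to biweekly by means, multiple
monitoring sites (or grid cells) averaged across — and fills WTMP gaps with
the same neighbour-year climatology as the Chl-a series.

Multicollinearity is screened per season with
$\mathrm{VIF}_j = 1/(1-R_j^2)$, where $R_j^2$ is from the OLS regression of
predictor $j$ on all the others (with intercept, on standardised columns;
VIF is scale-invariant, standardising is for conditioning). While any VIF
exceeds 10 — the usual severe-multicollinearity threshold — the worst
offender is removed and the set recomputed; ties remove the variable later
in the canonical table order, for determinism.

`lag_select()` regresses the basin-mean Chl-a on covariates shifted by
0..`max_lag` bins and reports the best lag, flagging the scan inconclusive
when the $R^2$ spread is below 0.05. The per-pixel models deliberately use
same-season (lag 0) predictors; the scan is a diagnostic. On synthetic data
its outcome simply reflects the phase offsets the generator gave the
covariate cycles, which is worth remembering when reading the workflow
output.

## MARS and variable importance

The MARS model is
$Y = \sum_i \beta_i B_i(X) + \varepsilon$ with basis functions that are 1, a
hinge $(x-t)_+$ or $(t-x)_+$, or a product of hinges on distinct variables.
The **forward pass** starts from the intercept and greedily adds reflected
hinge pairs — products of an existing basis function with $(x_v-t)_\pm$ for a
variable $v$ not already in it — choosing the pair with the maximal RSS
reduction (computed jointly for the pair via projection onto the orthogonal
complement of the current basis). It stops at `max_terms` (default
$\min(2p+1, 21)$) basis functions or when the relative RSS reduction falls
below $10^{-4}$. Ties break toward the lower variable index, then the
smaller knot. The **backward pass** deletes the term whose removal least
increases RSS, one at a time, producing one best subset per size, and keeps
the subset minimising
$$\mathrm{GCV} = \frac{\mathrm{RSS}}{N\,(1 - M/N)^2},\qquad
M = m + c \cdot (\text{distinct knot sites}),$$
with $c = 3$ when interactions are allowed (`max_degree` default 2) and
$c = 2$ for additive models. Knot sites are counted exactly on each subset —
a reflected pair shares one site, and a lone surviving hinge still pays for
its knot.

**Knot candidacy.** Candidate knots are order statistics of the variable over
the parent basis function's support, thinned by Friedman's `minspan` and kept
`endspan` observations clear of the support ends (both "auto" by default,
using his $\alpha = 0.05$ formulas; `minspan = 1, endspan = 0` admits every
distinct value). This was a genuinely open design point: with knots at every
observed value the greedy search extracts so much apparent signal from ~60
seasonal bins that GCV keeps sizeable models even when the response is
independent of the predictors. The thinning formulas are part of Friedman's
algorithm and are the defaults of the reference R implementation of MARS,
and with them the null behaves as it should (the test suite verifies mean
seasonal training $R^2 < 0.1$ under a covariate-independent generator, and
pruning to at most two hinge terms in over 90% of pure-noise replicates).
Exact-recovery tests and oracle comparisons set `minspan = 1, endspan = 0`
explicitly.

**Importance** follows the three standard criteria read off the pruning
trace: `nsubsets` (how many pruning subsets contain the variable), the RSS
criterion (RSS decrease of each subset relative to the previous, accrued to
the subset's variables, scaled to max 100), and the GCV analogue. Which
criterion defines "the" most important variable is not determined by the
method itself; the package uses `nsubsets`, with ties broken by the RSS
criterion and then canonical variable order, and reports all three.

## Per-pixel seasonal fitting

For each season and each retained pixel, the pixel's seasonal Chl-a bins
(pooled across the decade, ~66 bins per season) are regressed on the
season's VIF-retained, spatially constant covariates. Pixels with fewer than
`min_bins = 20` seasonal observations are skipped with a logged reason —
MARS needs meaningfully more rows than `max_terms`, and 20 bins is roughly
three years of one season. Outputs are the per-season training-$R^2$ maps
with their spatial means, the per-pixel top variable, and the season ×
variable percentage table of top-variable shares over fitted pixels
(VIF-excluded variables are reported absent).

## The synthetic generator

`synthetic_config()` defines the study conditions the tests run under: a
20 × 30 pixel grid, biweekly over 5 Jan 2002 – 21 Mar 2012 (267 bins);
basin mean 12 µg/L; annual amplitude 8 µg/L peaking at day-of-year 225 (a
late-August bloom maximum, as in temperate eutrophic basins) and semiannual
amplitude 4 µg/L with maxima in late spring and fall; two Gaussian bloom
hotspots (amplitudes 18 and 10 µg/L, decay 4–5 pixels) standing in for
river-outlet plumes; AR(1) noise (coefficient 0.6, stationary SD 2 µg/L)
mixing a basin-wide component with per-pixel components
(`spatial_coherence = 0.3`); cloud gaps as random rectangles in
(time, y, x) totalling ~20% of cells, plus two pixels pushed above 50%
missingness so the sparsity filter is exercised. Rectangles, not i.i.d.
cells, because spatial KNN imputation is only meaningfully tested against
spatially coherent gaps. Covariates get first-order-realistic seasonality
(WTMP and Rs annual cycles, spring discharge peak, discharge-tracking
nutrients, gamma-distributed precipitation, winter-peaking wind); optional
collinearity injection rebuilds one covariate as a linear function of
another at a stated population $R^2$, and optional effect specifications add
a known, spatially constant function of a covariate to Chl-a in one season,
giving ground truth for importance recovery.

What the generator does *not* emulate: advection and patch movement, the
mixed ecological/phenological causal structure of real blooms, retrieval
error that correlates with the signal, non-stationary trends, or
spatially varying covariates. Passing the recovery tests therefore shows the
chain is implemented correctly and is sensitive to planted structure of
realistic magnitude — not that the method would attribute real blooms
correctly.

## Problem sizes and reproducibility

Tests run the per-pixel stage on small grids (12–20 pixels, the full
267-bin calendar), the calibration on 1000 AR(1) replicates, and
recovery simulations at $n = 100$–200; the analysis workflow under
`analysis/` runs the full 20 × 30 default. All stochastic stages consume a
single integer seed through the config objects; equal seeds give identical
outputs end to end, and `run_study()` records seed, parameters and package
version in its manifest.

## Known limitations

* The retrieval treats $b_b$ as known and constant; real backscatter varies
  with suspended sediment, which in a shallow basin is substantial.
* Covariates are spatially constant, so per-pixel differences in importance
  arise only through pixel-level response differences — as in the source
  design, but worth keeping in mind when reading the maps.
* The GCV penalty treats the greedy knot search as if it cost a fixed
  charge per knot; with very small seasonal samples the selection bias is
  only partly absorbed, so training $R^2$ values are optimistic relative to
  out-of-sample skill.
* Global-spectrum significance flags reuse the pointwise red-noise
  threshold, which is conservative for a time-averaged quantity.
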