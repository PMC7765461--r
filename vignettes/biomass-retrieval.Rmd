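---
title: "Retrieving narrowband canopy reflectance from four camera bands and estimating pasture biomass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrieving narrowband canopy reflectance from four camera bands and estimating pasture biomass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pasturespec)
```

## The problem

Commercial UAV multispectral cameras observe a grass canopy in a handful of
broad bands, while many of the spectral features that track pasture state —
chlorophyll absorption depths, red-edge shape, narrowband ratio indices —
are defined on near-continuous reflectance. `pasturespec` implements a
piecewise parametric retrieval that reconstructs top-of-canopy reflectance
over 550–790 nm at 1 nm resolution from four band values (green 550/40,
red 660/40, red edge 735/10, NIR 790/40 nm, boxcar responses by default),
derives continuum-removal band-depth features from the reconstruction, and
feeds either the reconstructed-feature set ("proposed method") or the plain
band/vegetation-index set ("current method") into a tuned random-forest
regression of standing biomass (kg DM/ha), validated both by a random
holdout and by leave-one-location-out spatial cross-validation.

## The piecewise model

Reflectance in this window has two regimes. Below the 685 nm breakpoint the
spectrum is modelled as a straight line anchored on the green and red
bands:

$$f(\lambda) = R_{550} + (\lambda - 550)\,\beta,
\qquad \beta = \frac{B_{red} - B_{green}}{660 - 550},$$

so the segment passes through both band values exactly and is extrapolated
from 660 nm up to the breakpoint. At and beyond 685 nm the red-edge rise is
a three-parameter logistic in the offset wavelength $\lambda' = \lambda -
660$:

$$f(\lambda) = \frac{R_{680}\,K}{R_{680} + (K - R_{680})\,
e^{-C\lambda'}},$$

with the start level $R_{680}$ fixed to the red band, the asymptote $K$
fixed to the NIR band, and only the growth rate $C$ (per nm) free. $C$ is
found by Nelder–Mead on $\log C$ (positivity without a bounded optimizer),
minimizing the squared residuals of the logistic against the observed band
values at the band centers 660, 735 and 790 nm. The residual at 660 nm is
structurally zero; the 790 nm residual is small but nonzero for finite
$C$, because a logistic only reaches its asymptote in the limit. An
optional objective (`objective = "srf"`) convolves the full model spectrum
with the sensor responses instead of evaluating at band centers; band-center
evaluation is the default because it is faster and equally testable.

No continuity constraint ties the two segments together: the jump at
685 nm is a known, documented artifact of the model and its magnitude is
reported per fit (`discontinuity_685`).

### Numerical choices

* **Initialization.** $C_0$ comes from the closed-form inversion of the
  red-edge band, $C_0 = -\log[R_{680}(K - R_{735}) / (R_{735}(K -
  R_{680}))]/75$, with a fallback of 0.02 per nm when that expression is
  undefined (e.g. a red-edge value at or above the NIR band).
* **Convergence.** The Nelder–Mead relative tolerance is kept near machine
  precision (`reltol = 1e-14`, 500 iterations maximum — a few hundred
  scalar evaluations, so cost is negligible). A looser tolerance of 1e-10
  on the objective leaves reflectance residuals near 1e-5, which would
  dominate the round-trip error budget of self-consistent inputs; the
  tight default pushes the optimizer to the same minimizer a 10^5-point
  grid search over $\log C$ finds, to better than 1e-5 relative.
* **Degenerate inputs.** Rows with `red >= nir` have no rising red edge
  (bare soil, senescent patches). They raise a structured non-sigmoid
  error by default; `flat_fallback = TRUE` instead returns a flat spectrum
  at the mean band value, and batch reconstruction
  (`reconstruct_library()`) always isolates per-row failures in its fit
  report rather than aborting.
* **Ties and clipping.** The maximum-band-depth position breaks ties
  toward the shortest wavelength; band responses whose nominal support
  extends past the grid (green at the 550 nm start, NIR at the 790 nm
  end) are clipped to the grid and renormalized, so a flat spectrum always
  maps to its own level.

## A structural limitation worth understanding

Identifying the asymptote with the NIR band value makes the model family
*not closed under resampling*: a finite-steepness logistic is strictly
below its asymptote at 790 nm, so a spectrum generated by the model with
asymptote $K$ has $R(790) < K$, and a reconstruction that re-reads its NIR
band as the new asymptote cannot reproduce the original curve exactly. The
shortfall concentrates in the NIR plateau and shrinks as
$e^{-130C}$; an exact round trip is only possible once the red edge has
effectively saturated by 790 nm ($C \gtrsim 0.12$ per nm), a regime in
which the red-edge band in turn carries almost no information about $C$.
At realistic steepness (inflection near 700–720 nm) the round-trip error is
of order 1% reflectance in the NIR — the same plateau bias the method
exhibits against field spectra. The acceptance suite measures this bound
honestly instead of hiding it; the per-wavelength agreement diagnostics
(`agreement_profile()`) show where it lives.

## Continuum removal and the proposed feature set

`continuum_remove()` computes the upper convex hull of the spectrum over
550–790 nm with a monotone-chain sweep (cross-checked in the tests against
a brute-force all-chords oracle), interpolates it linearly between hull
vertices, and derives continuum-removed reflectance $R/\mathrm{hull}$,
band depth $BD = 1 - R/\mathrm{hull}$, the maximum depth $D_c$ and its
wavelength, and the trapezoid band area. The proposed predictor row is:
band area and its cube, the cubed maximum-depth position (cubic transforms
damp saturation at high biomass), normalized band-depth indices
$(BD - D_c)/(BD + D_c)$ at 556 and 744 nm, the optimized 745/755 nm
normalized ratio index, and the fitted $\beta$ and $C$. The continuum
spans the full reconstruction range so a single hull supports both NBDI
anchors. The current-method row holds NDVI, GNDVI, NDRE, NGRDI, LCI and
SIPI2 (green substituted for the missing blue band) plus the four raw
bands, always computed from the camera bands directly, never from the
reconstruction.

## Biomass modelling workflow

Predictors are filtered by a minimum absolute Pearson correlation of 0.2
with biomass (constants dropped as such), computed on the training portion
only; centering and scaling statistics likewise come from training folds
only. A random forest (via `ranger`) is tuned by grid search over the
number of trees {500, 1000, 1500, 2000} and variables per split
{2, 3, 4, 6, 8} in 10-fold cross-validation, and the selected pair is the
least complex one (fewest trees, then smallest `mtry`) whose RMSE is
within ten percent of the grid minimum — a parsimony rule asserted on
every run. Validation is (i) a 75/25 location-stratified holdout and
(ii) leave-one-location-out spatial cross-validation after each location
is downsampled to the size of the smallest one by biomass-quantile
stratified sampling (4 strata by default), preserving each location's
biomass distribution while removing class imbalance. $R^2$ is the squared
Pearson correlation between observed and predicted, the convention of the
modelling stack this workflow mirrors; RMSE is reported in kg DM/ha.

## What the synthetic generator emulates

No field library ships with the package, so every stage is exercised on
synthetic canopies with known ground truth. Two broadband phenomena drive
grass reflectance in this window: chlorophyll absorption (deepening and
widening with canopy development) and leaf-area-driven NIR scattering
(asymptotic with biomass). The generator encodes them as biomass maps:

| quantity | map | default |
|---|---|---|
| NIR plateau | $K(b) = 0.15 + 0.45(1 - e^{-b/1500})$ | saturates at the 1500 kg DM/ha scale |
| red level | $R_{680}(b) = 0.035 + 0.10\,e^{-b/1200}$ | chlorophyll absorption |
| green level | $R_{550}(b) = 0.05 + 0.12\,e^{-b/1800}$ | visible decline |
| growth rate | $C(b) = 0.042 + 0.010(1 - e^{-b/1500})$ | red-edge steepness |

with biomass uniform on 100–4000 kg DM/ha by default. Each parameter
further receives a per-sample relative scatter of 12% around its biomass
trend: chlorophyll and leaf area are correlated with, not determined by,
standing biomass, and without this scatter all curves would pivot through
a single crossing point near 700 nm, collapsing the across-sample variance
(and any attainable correlation) there in a way real canopies do not show.
The steepness map places the family's low-variance crossing region and
red-edge inflection inside 700–740 nm, where field data show their lowest
retrieval correlation, while keeping the NIR plateau close enough to the
asymptote that the model's plateau shortfall stays near 1%. The emitted
curve is exactly piecewise (the linear segment meets $R_{680}$ at
660 nm), optionally perturbed by structure the model cannot represent — a
fluorescence-like Gaussian bump at 760 nm (amplitude 0.01, FWHM 5 nm) and
a random red-edge inflection wiggle at 720 nm — plus homoscedastic
Gaussian noise (sd 0.005 by default; a heteroscedastic option scales noise
with reflectance), per-location biomass shifts and spectral offsets, and
clipping to [0.001, 1].

What passing tests on these synthetics do **not** show: radiative-transfer
realism (no PROSAIL-class physics), soil and atmosphere effects,
instrument spectral response detail (boxcar and Gaussian shapes stand in
for the digitized datasheet response), or the sampling structure of a real
multi-site field campaign. They do show that every algorithmic claim —
hull correctness, optimizer convergence, leakage-guarded tuning, fold
structure, distribution-preserving downsampling, and the documented
failure modes of the piecewise model — holds under controlled conditions.

In the synthetic world the maximum-band-depth position is pinned by the
family geometry and barely varies, so `max_depth_position_cubed` is
routinely removed by the correlation filter as constant; on field spectra
it varies with the chlorophyll well and survives. This is a known gap
between generator and field behaviour, not a defect of the feature.

## Problem sizes

The shipped tests and the acceptance script run at sizes chosen to make
every property measurable while staying comfortable on a single CPU:
200 spectra for round-trip and per-wavelength fidelity checks, 100 band
rows for optimizer–oracle equivalence, 1000 random 20-point spectra for
the hull oracle, and 500 samples across four locations for the full
modelling pipelines (the spatial stage then works on 4 × smallest-location
capped data). Larger runs only tighten the same estimates.
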