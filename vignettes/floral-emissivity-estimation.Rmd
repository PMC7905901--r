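---
title: "Estimating floral emissivity from thermal-camera point measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating floral emissivity from thermal-camera point measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floremis)
```

## The measurement problem

Thermal cameras do not measure temperature; they measure thermal-infrared
radiance and convert it to temperature using user-supplied parameters, the
most important of which is the target's emissivity $\varepsilon$ — its
capacity to radiate relative to a black body at the same temperature.
Floral tissue is awkward for the standard coating-based emissivity
protocols (flowers are small, fragile, and heat unevenly), so floral
thermography has had to borrow emissivity values measured on leaves. This
package implements the radiometric machinery needed to estimate emissivity
directly from point measurements of flowers held at a known temperature,
by either of the two practical protocols (a contact thermocouple, or
flotation in a temperature-controlled water bath), together with a
synthetic-measurement generator that reproduces the error structure of
those protocols so the whole pipeline can be validated without laboratory
data.

## The radiometric model

The radiance reaching the camera from a non-transmissive grey-body target
decomposes into an emitted, a reflected, and an atmospheric term:

$$W = \varepsilon\,\sigma\rho\,T_{obj}^4
    + (1-\varepsilon)\,\sigma\rho\,T_{ref}^4
    + \sigma(1-\rho)\,T_{env}^4,$$

where $\sigma$ is the Stefan–Boltzmann constant, $\rho$ the air-path
transmissivity, $T_{obj}$ the object temperature, $T_{ref}$ the reflected
temperature of the surroundings (measured with a crumpled-foil
multidirectional mirror) and $T_{env}$ the air temperature. The camera's
*apparent* temperature — its reading with $\varepsilon = 1$ and distance
$0$, i.e. all corrections off — fixes the observed radiance through
$W_{obs} = \sigma T_{app}^4$.

Given a known $T_{obj}$, emissivity can be resolved two ways, and the
package always computes both:

* **closed form** (`emissivity_calc`): rearranging the forward model,
  $\varepsilon = (W_{obs} - \sigma\rho T_{ref}^4 -
  \sigma(1-\rho)T_{env}^4) / (\sigma\rho T_{obj}^4 - \sigma\rho
  T_{ref}^4)$;
* **scalar solve** (`solve_emissivity_point`): the $\varepsilon$ at which
  the expected radiance matches the observed one, found by bracketed
  root-finding on $W_{obs}-W_{exp}(\varepsilon)$ starting from 0.98.
  Because $W_{exp}$ is affine and strictly monotone in $\varepsilon$
  whenever $T_{obj}\neq T_{ref}$, the zero is unique; the solve mirrors
  the spreadsheet-solver workflow common in this literature (including its
  group-of-100 batching, which is mathematically inert here) while
  exceeding its $10^{-6}$ precision.

Estimates are deliberately **not clipped** to $[0,1]$. With a true
emissivity near 1 and ordinary sensor noise, individual estimates slightly
above 1 are the expected signature of an honest estimator, and clipping
would conceal the protocols' error structure; a `clamp` option exists for
users who need camera-admissible values.

## Parameter conventions

| parameter | default | why |
|---|---|---|
| $T_{env}$ | 298.15 K (25 °C) | assumed lab temperature in both protocols |
| $\rho$ | 0.99 | near-perfect air transmission at ~0.5 m working distance; manufacturer transmission functions are proprietary, so $\rho$ is a direct input |
| $\sigma$ | 5.670374419e-8 W m⁻² K⁻⁴ | CODATA; $\sigma$ cancels from emissivity estimates anyway (see below) |
| water $\varepsilon$ | 0.98 | accepted emissivity of water, used to retrieve the bath temperature |
| retrieval $\varepsilon$ | 0.98 | the floral-thermography convention for $T_{0.98}$ comparisons |
| Kelvin offset | 273.15 | exact; sources that round to one decimal (298.2 K) differ from ours by < 0.05 K |

The thermocouple pipeline takes $T_{obj}$ from the thermocouple column
(Celsius converted if needed) and $T_{ref}$ from the record's mirror
reading, falling back to $T_{env}$ when absent. The water-bath pipeline
retrieves the water temperature from the camera's water-point reading at
$\varepsilon = 0.98$ and assigns it as $T_{obj}$ to all three flower
locations of the record; when the table also carries a pre-retrieved water
temperature the two are cross-checked to 0.1 K and mismatches flagged.
Whether the deposited protocol used one reflected-temperature reading per
batch or per record is not recoverable from the record structure, so the
pipeline simply accepts a per-record $T_{ref}$.

## Degenerate inputs

The closed-form denominator $\sigma\rho(T_{obj}^4-T_{ref}^4)$ vanishes as
the surroundings approach the target temperature and turns negative beyond
it; such records produce arbitrarily wild estimates. Any record whose
signed denominator falls at or below $10^{-6}\,\sigma\rho T_{obj}^4$
(which includes every record with $T_{ref}\ge T_{obj}$) is **flagged and
excluded from summaries, but never dropped**: flagged rows travel through
the pipeline with a reason code, and a retention switch
(`include_degenerate = TRUE`, backed by the unscreened
`epsilon_calc_raw` column) reproduces the outlier-bearing summaries of the
retain-everything convention.

## Numerical choices

* **$\sigma$-invariance.** Emissivity estimates are algebraically
  independent of $\sigma$, but computing $W = \sigma T_{app}^4$ and then
  dividing $\sigma$ back out is not exact in floating point
  ($\mathrm{fl}(\sigma x)/\sigma \neq x$ for a few percent of doubles).
  The estimation pipeline therefore works in blackbody-equivalent $T^4$
  space — $\sigma$ never enters — making estimates bit-identical under any
  choice of the constant; the radiance-space interface agrees across
  $\sigma$ values to one unit in the last place.
* **Root solve.** `uniroot` on an affine function, initial bracket
  `init ± 1` extended as needed within $[-5, 5]$, tolerance scaled so the
  radiance residual is below $10^{-10} W_{obs}$; a derivative-free
  minimisation of $|\Delta W|$ is the fallback if bracketing fails.
* **Ties and floors.** The degeneracy floor is relative
  ($10^{-6}$ of $\sigma\rho T_{obj}^4$), so the screen behaves identically
  across the plausible 250–400 K range.

## The synthetic generator

`generate_dataset()` emits tables in exactly the dialect the pipelines
read, with known ground truth attached. Its defaults encode the study
conditions the protocols imply:

* **Thermocouple:** true flower temperatures uniform on 296.9–309.2 K
  (flowers heated above room temperature); reflected temperature coupled
  to the flower as $T_{obj} - U(5, 13)$ K, clipped to the observed
  287.0–300.5 K envelope. The coupling reflects that both quantities track
  the same room while the flower is actively heated; the 5–13 K offset is
  centred on the ~9 K separation of the two observed envelopes.
* **Water bath:** true temperature equal to the set bath temperature
  (308.15 or 318.15 K); reflected temperature uniform on 299.5–301.6 K; a
  verification-thermometer column with 0.2 K noise (within the ±1 K
  verification band).
* **Noise.** Manufacturer specs quote ± bounds, not SDs; a quoted bound is
  interpreted as a 95 % interval, so camera noise defaults to
  $2/1.96 \approx 1.02$ K and thermocouple noise to
  $\max(2.2, 0.75\%\ \text{of the Celsius reading})/1.96$ K. Gaussianity
  is an assumption — the protocols publish no error distribution — so
  tests lean on directions and coverage, not distributional detail.
* **Bias artefacts** default to 0 and are switched on explicitly:
  `contact_bias` (poor thermocouple coupling under-reads pliant petals,
  inflating petal estimates), `elevation_bias` (structures held above the
  waterline never reach bath temperature, deflating estimates) and
  `submersion_bias` (submerged structures run warmer, inflating them —
  the pattern of the one bellflower-like exemplar, which is the default
  `submerged_species`). The protocols establish these artefacts'
  directions, not calibrated magnitudes, which is why a magnitude is a
  user choice.
* **Reproducibility.** One seed drives an independent substream per
  (species, individual, location), so removing a species from a config
  changes no other row and identical configs give byte-identical tables.
  Temperatures are emitted at full precision by default
  (`round_digits = 1` mimics thermal-software exports) so that noiseless
  generation is exactly identifiable end to end.

What the generator does *not* emulate: biophysical heat transfer in real
flowers, spatial temperature gradients across a petal, camera fixed-pattern
noise, or any correlation between the camera's and the thermocouple's
errors. Passing tests therefore demonstrate that the estimation machinery
is correct and that the protocols' artefact directions propagate as
expected — not that real floral data are free of further error sources.

## An inherent bias worth knowing about

Because $T_{obj}$ enters the closed form through its fourth power in the
denominator, zero-mean noise on the recorded object temperature does not
produce zero-mean noise on the emissivity estimate: by Jensen's
inequality the estimate is inflated by roughly
$\varepsilon\,(\sigma_{T}/\Delta T)^2$, where $\Delta T = T_{obj}-T_{ref}$
is the thermal contrast. At the default thermocouple noise (~1.1 K) and
the protocol's typical contrast (~9 K) this is about +0.02 — computed at
run time by the acceptance script (`recovery_true_emissivity_offset`) and
quantified in the test suite. It is the same mechanism that pushes
real-protocol mean estimates past 1.0, and it is why measuring at the
highest safe temperature (maximising $\Delta T$) is good advice. The
package reports the estimator faithfully rather than attempting a
bias correction, which would require knowing the noise SD exactly.

## Problem sizes

The test suite and acceptance script use $10^4$ random scene tuples for
the inversion properties, ~1000 synthetic points for noisy recovery,
~500 points per bias-direction check, and study-shaped rosters (10
species × ~20 flowers, or 6 species × 12 flowers × 2 bath temperatures)
for full-pipeline reprocessing — sizes chosen to estimate means and SEMs
comfortably while keeping a full run in tens of seconds.

## Known limitations

* No humidity/distance → transmissivity model: $\rho$ is an assumed
  input, as the camera vendors' transmission functions are proprietary.
* Emissivity is treated as scalar per point: no spectral or angular
  resolution.
* The repeated-measures ANOVA / post-hoc machinery used to compare
  species in this literature is deliberately out of scope; the summary
  layer produces the grouped means/SD/SEM tables such analyses start
  from, and users can feed them to `lme4`/`emmeans` directly.
* The delimited-text readers target the two deposited-table dialects;
  radiometric image formats are out of scope.
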