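# floremis

Floral infrared emissivity estimation from thermal-camera point
measurements.

Thermal imaging is increasingly used to measure flower temperature, but a
camera only converts radiance to temperature correctly if it is told the
target's emissivity ε — and until recently there were no published
emissivity estimates for floral tissue, forcing researchers to borrow
values measured on leaves. `floremis` implements the full computational
side of estimating floral emissivity from measurements of flowers held at
a known temperature: the radiometric forward model, two ways of resolving
ε from point measurements, the two field protocols in practical use
(contact thermocouple and water-bath flotation), fixed-emissivity
temperature retrieval (the T₀.₉₈ convention), grouped summary statistics,
and a synthetic measurement generator with realistic sensor noise and
protocol bias artefacts for validating the whole pipeline. It is aimed at
plant thermal ecophysiologists and anyone doing quantitative infrared
thermography of small biological targets.

## The model

The radiance entering the camera from a non-transmissive grey body is

    W = ε σ ρ T_obj⁴ + (1 − ε) σ ρ T_ref⁴ + σ (1 − ρ) T_env⁴

with σ the Stefan–Boltzmann constant, ρ the air-path transmissivity,
T_ref the reflected temperature of the surroundings and T_env the air
temperature. The camera's apparent temperature (its reading with ε = 1,
distance 0) gives the observed radiance, W_obs = σ T_app⁴. With T_obj
known — from a thermocouple, or from the water a flower floats in — ε is
resolved per point both in closed form (rearranging the equation above)
and by a bracketed scalar solve on W_obs − W_exp(ε); the two agree to
better than 1e−6 and both are reported. Estimates are not clipped to
[0, 1]: with true emissivity near 1, noise legitimately produces
estimates slightly above 1, and clipping would hide protocol error.

## Worked example

Simulate a small two-species thermocouple study (true petal emissivities
0.98 and 0.99, a 0.5 K contact bias on petals) and re-estimate:

```r
library(floremis)
cfg <- synthetic_config(
  species_profiles = list(
    "Bellis perennis" = c(reproductive_structures = 0.96,
                          petal_base = 0.98, petal_edge = 0.98),
    "Campanula sp." = 0.99),
  n_individuals = 12, contact_bias = 0.5, seed = 42)
raw <- generate_dataset("thermocouple", cfg)
fit <- estimate_emissivity(raw, protocol = "thermocouple")
fit
#> Floral emissivity fit (thermocouple protocol)
#>   72 measurement points (0 flagged degenerate)
#>   solver emissivity: mean 1.0678, sd 0.2253 (n = 72)
#>   solver - calculated: mean 3.9e-16 +/- 9.5e-17 (SEM), n = 72
#>   T_obj - T_0.98 retrieval delta: mean -0.391 K (n = 72)

round(coef(fit), 3)
#>              Bellis perennis:petal_base              Bellis perennis:petal_edge
#>                                   1.085                                   1.084
#> Bellis perennis:reproductive_structures                Campanula sp.:petal_base
#>                                   1.008                                   1.081
#>                Campanula sp.:petal_edge   Campanula sp.:reproductive_structures
#>                                   1.100                                   1.048
```

The output shows what the method genuinely does with noisy data: the two
resolutions (closed form and solver) agree to machine precision; the mean
estimates sit near — and, with sensor noise plus the deliberate contact
bias, above — 1, with petal means inflated relative to reproductive
structures; and the negative retrieval delta says a camera set to
ε = 0.98 slightly overestimates the temperature of these targets.
`summary(fit)` adds grouped mean/SD/SEM tables; `predict(fit, epsilon =
0.95)` retrieves temperatures at any assumed emissivity;
`summarize_deltas(fit)` builds the per-group T_obj − T₀.₉₈ table with a
pooled Average row. A command-line wrapper (`inst/scripts/floremis`)
exposes `simulate`, `estimate`, `t098` and `summarize` subcommands over
delimiter-separated tables.

See the vignette (`vignettes/floral-emissivity-estimation.Rmd`) for the
model, the protocol conventions, the generator's error model, and known
limitations — including the fourth-power (Jensen) inflation of mean
estimates under object-temperature noise.

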