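---
title: "Models and methods behind duplexfit"
author: "duplexfit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind duplexfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexfit)
```

duplexfit quantifies how a bulky non-nucleotide lesion — here, a
fluorescein-carbamoyl group carried on a propanediol backbone unit, with
(nFluL) or without (nFluS) a hexanoyl linker — changes the biophysics of a
short DNA duplex: its melting thermodynamics, its apparent bend, the optical
signature of the fluorophore stacking into the helix, and how efficiently
the nucleotide excision repair (NER) machinery removes it. This vignette
documents the models, the tunable parameters, the numerical choices, and
what the synthetic-data generator does and does not emulate.

## The two-state hybridization model

All melting analysis assumes a bimolecular two-state equilibrium between two
non-self-complementary strands mixed equimolar:

$$A + B \rightleftharpoons AB, \qquad
K(T) = \exp\!\left(-\frac{\Delta H^\circ - T\,\Delta S^\circ}{RT}\right),$$

with $R = 1.9872$ cal mol$^{-1}$ K$^{-1}$. No populated intermediates, no
heat-capacity change. With $C_t$ the **total** single-strand concentration
(both strands summed — conventions differ by a factor of two, so this is
worth stating twice), mass action gives
$K C_t (1-\theta)^2 = 2\theta$ for the duplex fraction $\theta$, whose root
in $[0,1]$ has the closed, numerically stable form
$\theta = a/(a + 1 + \sqrt{2a+1})$ with $a = K C_t$. Setting
$\theta = 1/2$ yields $K(T_m) = 4/C_t$ and the concentration-dependent
melting temperature

$$T_m = \frac{\Delta H^\circ}{\Delta S^\circ + R\,\ln(C_t/4)}.$$

The $\ln(C_t/4)$ coordinate is exactly the molecularity convention of the
non-self-complementary case; a self-complementary mode is deliberately out
of scope (the 16-mers analysed here are not self-complementary). Internally
everything is cal/mol and Kelvin; reporting boundaries use kcal/mol and
Celsius, the units of published melting tables.

## Fitting optical melting curves

An ultraviolet denaturation trace is modelled as

$$A(T) = \theta(T)\,(b_{ds} + m_{ds} T) + (1 - \theta(T))\,(b_{ss} + m_{ss} T),$$

two *linear* sloping baselines bridged by the two-state transition. Linear
baselines are the standard choice for short-duplex UV melting; nothing in
the data here motivates more structure. Preprocessing subtracts a
reference-wavelength channel (e.g. 300 nm) when present, sorts by
temperature and averages duplicates; heating and cooling ramps are fit
separately — hysteresis beyond 1 °C in the model-free midpoints is flagged
(`ramp_hysteresis()`) because it diagnoses non-equilibrium ramping, and
merging ramps is left as an explicit user decision.

`fit_melting_curve()` minimizes the sum of squared residuals over six
parameters with a derivative-free Nelder–Mead simplex
(`stats::optim`). One deliberate reparameterization: the simplex works in
$(T_m, \Delta H^\circ, m_{ds}, b_{ds}, m_{ss}, b_{ss})$, with
$\Delta S^\circ = \Delta H^\circ/T_m - R\ln(C_t/4)$ tied through the
half-dissociation identity. This is algebraically the same least-squares
problem as fitting $(\Delta H^\circ, \Delta S^\circ)$ directly, but far
better conditioned: $\Delta H^\circ$ and $\Delta S^\circ$ are almost
perfectly collinear over a 90 °C window, while $T_m$ and $\Delta H^\circ$
(position and steepness of the transition) are nearly orthogonal. It also
makes the reported $T_m$ *exactly* the $\theta = 1/2$ point of the fitted
model — the definition the van 't Hoff relation presumes — rather than the
derivative maximum, which shifts when baselines slope.

Numerical policy:

* **Initialization.** $T_m$ from `derivative_tm()` — the maximum of a
  Savitzky–Golay smoothed $dA/dT$ (window 11 points, order 2, via
  `signal::sgolayfilt`); a trace whose smoothed derivative has no interior,
  clearly elevated maximum is rejected as non-sigmoidal. Baselines from line
  fits to the outer 20 % of the temperature range. $\Delta H^\circ$ from the
  two-state slope identity
  $d\theta/dT|_{T_m} = \Delta H^\circ / (6 R T_m^2)$ applied to the
  baseline-normalized trace, clamped to $[-250, -40]$ kcal/mol.
* **Restarts.** Five starts jittered by a fixed offset/scale table
  ($T_m \pm$ up to 2 °C, $\Delta H^\circ$ scaled 0.65–1.4), so fits are
  bit-reproducible without any seed plumbing. Each start re-runs the simplex
  from its own endpoint until the SSR improves by less than
  $10^{-14}$ AU$^2$ (at most 8 cycles, $10^4$ evaluations each). Ties are
  broken by SSR, then by proximity to the derivative midpoint. The fit is
  flagged `converged = FALSE` when near-optimal restarts disagree in $T_m$
  by more than 0.5 °C.
* **Identifiability floor.** At least 18 points (three per parameter), at
  least 20 points spanning 30 °C at construction.

The **hypochromicity** of a fit is
$h = 100\,(A_{ss}(T_m) - A_{ds}(T_m))/A_{ss}(T_m)$, both baselines
extrapolated to the fitted $T_m$. The evaluation temperature is a genuine
design decision — published percentages rarely state one — and $T_m$ is the
only point where both baselines are on equal footing; the choice is flagged
here and in the function documentation.

## Van 't Hoff concentration series

`fit_vant_hoff()` regresses $1/T_m$ on $\ln(C_t/4)$ by ordinary least
squares (`stats::lm`), the textbook linearization: slope $= R/\Delta
H^\circ$, intercept $= \Delta S^\circ/\Delta H^\circ$. Unweighted by
default; inverse-variance weighting by supplied $T_m$ errors is available
(instrument error enters as a user-supplied floor, added in quadrature by
the caller if desired — the package does not guess how scatter and
instrument error were combined upstream). Uncertainties propagate to first
order from the slope/intercept covariance, *including the covariance term*:
slope and intercept are strongly anticorrelated, which is why $\Delta
G^\circ_{37}$ carries a far smaller relative error than $\Delta H^\circ$ or
$\Delta S^\circ$ individually — a pattern typical of published melting
tables, where enthalpies carry ±50 % errors next to ±10 % free energies.
Fitting $1000/T_m$ (the usual plot scale) or $1/T_m$ changes nothing after
unit bookkeeping; a test asserts it.

Because published tables print $\Delta S^\circ$, $\Delta H^\circ$,
$\Delta G^\circ_{37}$ *and* $T_m$ side by side even though the last two are
derived, `check_thermo_consistency()` recomputes both from the printed
parameters and flags rows that deviate beyond what rounding of the printed
values can explain: propagating half-unit rounding of $\Delta H^\circ$
(0.1 kcal/mol) and $\Delta S^\circ$ (1 cal/(mol·K)) bounds the derived
$\Delta G^\circ_{37}$ within ~0.2 kcal/mol and $T_m$ within ~0.7 °C, padded
to default tolerances of 0.3 kcal/mol and 1.0 °C. Rows failing either check
are reported, not silently accepted.

## Bend angles from gel mobility

A centrally placed static bend retards a duplex in a nondenaturing gel. The
classical cosine mobility rule,

$$\frac{\mu_{mod}}{\mu_{unmod}} = \cos\!\left(\frac{180^\circ - \alpha}{2}\right),$$

maps the mobility ratio to the *interior* angle $\alpha$ (180° = straight;
values just under 180° denote nearly straight helices, matching the
convention of reported angles like 165.4°). No gel-dependent empirical
calibration factor is applied — none can be justified without a multimer
phasing ladder, which is out of scope. Ratios above 1 (modified duplex
running faster) are outside the model and rejected rather than clamped.
Angle uncertainties from replicate lanes propagate through the first-order
expansion of $\arccos$, which correctly blows up as the ratio approaches 1:
near-straight duplexes have poorly determined angles.

## Titration metrics

Hybridization titrations hold the modified strand fixed (5.4 μM) while the
complement rises (1.25–5.4 μM). Three descriptive metrics — deliberately
descriptive: with four points clustered near saturation, fitting a binding
isotherm for $K_d$ would be numerology, so none is offered:

* `band_value()` — the maximum within ±5 nm of a band center (robust to the
  small peak shifts a 1-nm instrument grid resolves).
* `hypochromic_effect()` — percent band loss at the highest complement
  concentration relative to the zero-complement control. At the fluorescein
  band (495 nm) no dilution correction is needed because the fluorophore
  carrier is at fixed concentration in every sample; a large effect (~40 %)
  is the optical signature of the fluorophore stacking into the duplex,
  while a linker-tethered fluorophore that can evert shows a weaker one
  (≤20 %).
* `quench_fraction()` — $1 - \text{peak}_i/\text{peak}_{control}$ over a
  fluorescence scan, with a monotonicity flag.

`a260_trend()` reports the 260-nm band against *total* strand concentration
with a line-fit residual and a `sublinear` flag (growth lagging the
proportional extrapolation from the control). A duplex hypochromic
contribution at 260 nm makes the trend lag total DNA; note that under
near-stoichiometric binding the *increments* actually accelerate toward the
single-strand extinction as binding saturates, so lag-behind-proportional —
not decelerating increments — is the discriminating signature.

## Excision kinetics

NER excision assays yield band intensities of the labeled 34-nt specific
excision product over incubation time. `normalize_timecourse()` subtracts
the time-zero background (clamping small negative results with a warning);
`efficiency_ratio()` forms the per-time ratio of replicate-*mean* signals —
ratio of means, not mean of ratios, to keep early low-signal points from
exploding — excludes time zero, averages over time points, and attaches a
percentile bootstrap interval over *replicates* (time points within a
course are serially dependent and are not resampled). With a fixed seed the
bootstrap is bit-reproducible and leaves the caller's RNG stream untouched.
`replicate_sd()` is the $n-1$ sample standard deviation used for error
bars over independent experiments.

A structural caveat documented here because it matters for interpretation:
when two substrates follow saturating kinetics
$S(t) = A(1 - e^{-kt})$ with equal plateaus and a rate ratio of 2, the
per-time signal ratio is $1 + e^{-k_L t}$ — it starts near 2 and decays
toward 1. The time-averaged summary ratio is therefore *systematically
below* the underlying rate ratio, and its bootstrap interval is an interval
for that summary, not for the rate ratio. Under this package's default
excision design the summary sits around 1.7–1.8, squarely in the 1.5–2×
band such assays report, while the rate ratio remains 2.

## The synthetic-data generator

`generator_config()` carries three scenario presets mirroring the study
conditions: the unmodified duplex NM
($\Delta H^\circ = -140.0$ kcal/mol, $\Delta S^\circ = -382$ cal/(mol·K),
$h = 14.75\,\%$), nFluL ($-119.4$, $-339$, $13.5\,\%$, 495-nm saturation
effect 20 %, interior bend 165.40°) and nFluS ($-103.5$, $-295$,
$14.3\,\%$, effect 40 %, bend 170.64°, excised twice as fast as nFluL).
Every generator records its ground truth in an attribute (and
`write_simulated_inputs()` writes a key-value manifest), so recovery tests
compare against the recorded truth, never against values re-derived from
the outputs.

Defaults, chosen once as realistic acquisition conditions and then left
alone:

* **Melting**: 5–95 °C in 0.5 °C steps; baseline slopes
  $m_{ss} = 2\times10^{-4}$, $m_{ds} = 5\times10^{-4}$ AU/°C with the
  single-strand baseline anchored at 1 AU at $T_m$ and the duplex baseline
  set by the preset hypochromicity; Gaussian noise 0.002 AU (a well-behaved
  Peltier spectrophotometer at ~1 AU).
* **Titration**: complement grid {1.25, 2.7, 4.05, 5.4} μM (the published
  endpoints with two evenly spaced interior points; the true interior grid
  is not printed), modified strand 5.4 μM; Gaussian bands (260 nm nucleotide
  band, 495 nm fluorophore band, single fluorescence peak); spectra noise
  0.5 % of the control peak. Binding is stoichiometric (tight-limit) by
  default — 16-mer duplexes at μM concentrations and room temperature are
  orders of magnitude past their $K_d$ — with a finite-$K_d$ isotherm mode
  for robustness testing.
* **Excision**: times 0–60 min in 10-min steps,
  $k_{nFluL} = 0.01$, $k_{nFluS} = 0.02$ min$^{-1}$ (visible curvature
  within the hour, per-time ratios spanning ≈1.55–1.9), equal plateaus,
  background 0.02, 5 % multiplicative band noise, 3 replicates — "at least
  three independent experiments" is the convention the error bars assume.

What the generator does *not* emulate — and therefore what passing recovery
tests do not establish about real data: baseline curvature and instrument
drift, wavelength-dependent stray light, intermediate (non-two-state)
melting of damaged duplexes, gel smiling and lane-to-lane mobility
artifacts, densitometry nonlinearity near film saturation, and day-to-day
extract activity variation. Recovery under the generator shows the
estimators are correct and well-conditioned for the assumed models, not
that the models exhaust real instruments.

## Problem sizes and runtime choices

The automated checks use the sizes that make their statistics meaningful at
interactive runtimes: 50 seeded noisy curves for melting-parameter
recovery, a 1000-point grid for the mass-action oracle comparison, 100
seeded runs for excision-interval calibration, and 2000 bootstrap draws by
default (interval width changes by <5 % between 2000 and 10000 draws on the
synthetic fixture).
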