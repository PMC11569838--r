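# duplexfit

Biophysical characterization of short DNA duplexes carrying bulky
non-nucleotide lesions — the kind of fluorescein-carbamoyl adducts used as
model substrates for nucleotide excision repair (NER). Written for bench
scientists who record melting curves, titration spectra and gel band
intensities and want the downstream numbers — thermodynamic parameters,
bend angles, hypochromic effects, excision-efficiency ratios — computed
reproducibly from plain delimited text files.

## What it computes

**Two-state melting thermodynamics.** A bimolecular duplex
A + B ⇌ AB with equimolar non-self-complementary strands obeys
K(T) = exp(−(ΔH° − TΔS°)/RT) and the mass-action relation
K·C~t~·(1−θ)² = 2θ, where C~t~ is the *total* single-strand concentration.
The melting temperature follows in closed form:

    Tm = ΔH° / (ΔS° + R·ln(Ct/4))

`fit_melting_curve()` fits ΔH°, Tm and two sloping linear baselines to a
UV denaturation trace by Nelder–Mead least squares and reports the
hypochromicity h = 100·(A_ss(Tm) − A_ds(Tm))/A_ss(Tm). `fit_vant_hoff()`
regresses 1/Tm on ln(C~t~/4) across a concentration series to estimate
ΔH°, ΔS° with propagated uncertainties and ΔG°₃₇;
`check_thermo_consistency()` flags published-style table rows whose printed
ΔG°₃₇ or Tm disagree with their own ΔH°, ΔS°.

**Bend angles.** `bend_angle()` converts the nondenaturing-gel mobility
ratio of modified to unmodified duplex into an apparent interior bend angle
via the cosine rule μ_mod/μ_unmod = cos((180° − α)/2).

**Titration metrics.** `hypochromic_effect()` (band loss at saturation vs a
zero-complement control, e.g. the 495 nm fluorescein band),
`quench_fraction()` (fluorescence quenching across the series) and
`a260_trend()` (does the 260 nm band track total DNA?).

**Excision kinetics.** `efficiency_ratio()` turns background-corrected
34-nt excision-product band intensities into per-time and time-averaged
between-substrate efficiency ratios with a replicate bootstrap interval.

**Synthetic instruments.** `generator_config()` +
`sim_melting_curve()` / `sim_concentration_series()` /
`sim_titration_series()` / `sim_excision_timecourses()` /
`sim_mobility_lanes()` generate every input dialect with recorded ground
truth, so the whole pipeline is testable without laboratory data
(`write_simulated_inputs()` writes a complete file bundle plus manifest).

## Worked example

```r
library(duplexfit)

cfg   <- generator_config("nFluL", seed = 42)     # lesion with hexanoyl linker
curve <- sim_melting_curve(cfg, Ct = 20e-6)       # 20 uM total strands
fit_melting_curve(curve)
#> Two-state melting fit ('nFluL-sim')
#>   Tm = 55.47 C (derivative midpoint 55.50 C)
#>   dH = -119.4 kcal/mol, dS = -339 cal/(mol*K)
#>   hypochromicity = 13.40%, SSR = 0.000683 AU^2, converged: TRUE

series <- sim_concentration_series(cfg)           # 2.5-80 uM, noiseless
summarize_duplex(fit_vant_hoff(series), Ct_report = 20e-6, label = "nFluL")
#>   label   dS dH_kcal dG37_kcal    Tm_C ...
#> 1 nFluL -339  -119.4 -14.25915 55.5439 ...

bend_angle(0.99190)                               # gel mobility ratio
#> Bend estimate: interior angle 165.41 deg (deflection 14.59 deg, mobility ratio 0.99190)
```

Reading: a 16-mer duplex carrying this lesion melts near 55.5 °C at 20 μM
total strands with ΔH° ≈ −119 kcal/mol and ΔG°₃₇ ≈ −14.3 kcal/mol; the
fitted hypochromicity (~13.4 %) is the absorbance gained on strand
separation; a mobility ratio of 0.992 corresponds to an apparent interior
bend of ~165°, i.e. a modest but real kink at the lesion.

The methods vignette (`vignettes/duplex-biophysics.Rmd`) documents the
models, parameter conventions (calorie units, total-strand C~t~, the
ln(C~t~/4) molecularity factor), numerical choices and the limits of the
synthetic-data generator.

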