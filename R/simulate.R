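## Scenario presets: the three 16-mer duplexes of the study design.
## Thermodynamics in cal/mol and cal/(mol*K); hypochromicity and the 495 nm
## saturation effect in percent; quench as a fraction; excision rate in 1/min;
## interior bend angle in degrees.
scenario_presets <- list(
  NM = list(dH = -140.0e3, dS = -382, hypochromicity = 14.75,
            effect495 = 0, quench = 0, excision_k = NA_real_,
            bend_interior = 180),
  nFluL = list(dH = -119.4e3, dS = -339, hypochromicity = 13.5,
               effect495 = 20, quench = 0.15, excision_k = 0.01,
               bend_interior = 165.40),
  nFluS = list(dH = -103.5e3, dS = -295, hypochromicity = 14.3,
               effect495 = 40, quench = 0.50, excision_k = 0.02,
               bend_interior = 170.64)
)

#' Configuration of the synthetic-instrument generator
#'
#' Bundles a scenario preset (duplex thermodynamics, hypochromicity,
#' titration effects, excision kinetics, bend angle) with instrument noise
#' levels and acquisition grids. With the same seed and configuration every
#' generator is bit-reproducible.
#'
#' Scenario presets: `"NM"` (unmodified), `"nFluL"` (fluorescein adduct on a
#' hexanoyl linker) and `"nFluS"` (linker-free fluorescein adduct);
#' `"custom"` starts from the nFluL preset and expects overrides.
#'
#' @param scenario one of `"NM"`, `"nFluL"`, `"nFluS"`, `"custom"`.
#' @param seed integer seed for every stochastic generator.
#' @param ... overrides of any configuration field, e.g. `melt_sigma = 0`,
#'   `params = thermo_params(...)`, `effect495 = 0`, `excision_k = 0.05`.
#' @return Object of class `"generator_config"`. Fields: `params`
#'   ([thermo_params()]), `hypochromicity` (percent at Tm), `effect495`
#'   (percent, saturation hypochromic effect of the fluorophore band),
#'   `quench` (saturation quench fraction), `bend_interior` (degrees),
#'   `excision_k` (1/min, this scenario), `excision_rates` (1/min, both
#'   substrates, nFluS:nFluL = 2), `melt_sigma` (AU), `spectrum_sigma_rel`
#'   (fraction of the control peak), `band_sigma_rel` (relative band noise),
#'   `temp_grid` (C), `titration_conc` and `modified_conc` (mol/L),
#'   `excision_times` (min), `excision_plateau`, `excision_background`,
#'   `n_replicates`, `a260_hypo` (fractional 260 nm hypochromicity of the
#'   duplex contribution), `kd` (mol/L; `0` = stoichiometric tight binding).
#' @export
generator_config <- function(scenario = c("nFluL", "nFluS", "NM", "custom"),
                             seed = 1L, ...) {
  scenario <- match.arg(scenario)
  preset <- scenario_presets[[if (scenario == "custom") "nFluL" else scenario]]
  cfg <- list(
    scenario = scenario,
    seed = as.integer(seed),
    params = thermo_params(preset$dH, preset$dS),
    hypochromicity = preset$hypochromicity,
    effect495 = preset$effect495,
    quench = preset$quench,
    bend_interior = preset$bend_interior,
    excision_k = preset$excision_k,
    excision_rates = c(nFluL = scenario_presets$nFluL$excision_k,
                       nFluS = scenario_presets$nFluS$excision_k),
    melt_sigma = 0.002,
    spectrum_sigma_rel = 0.005,
    band_sigma_rel = 0.05,
    temp_grid = seq(5, 95, by = 0.5),
    titration_conc = c(1.25, 2.7, 4.05, 5.4) * 1e-6,
    modified_conc = 5.4e-6,
    excision_times = seq(0, 60, by = 10),
    excision_plateau = 1,
    excision_background = 0.02,
    n_replicates = 3L,
    a260_hypo = 0.14,
    kd = 0
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "generator_config")
}

#' Simulate a UV melting curve
#'
#' Forward model: two-state [model_absorbance()] of the scenario's
#' thermodynamics over the configured temperature grid, with linear baselines
#' anchored so that the single-strand baseline reads 1 AU at Tm and the
#' hypochromicity at Tm equals the scenario preset, plus i.i.d. Gaussian
#' noise of `melt_sigma` AU. The generating truth is attached as
#' `attr(curve, "truth")` so recovery tests never re-derive it from the data.
#'
#' @param cfg a [generator_config()].
#' @param Ct total strand concentration, mol/L.
#' @param ramp ramp direction label.
#' @return A [melting_curve()] with a `truth` attribute (list: `params`,
#'   `baselines`, `tm`, `hypochromicity`).
#' @export
sim_melting_curve <- function(cfg, Ct = 20e-6, ramp = "heating") {
  stopifnot(inherits(cfg, "generator_config"))
  tm <- predict_tm(cfg$params, Ct)
  m_ss <- 2e-4; m_ds <- 5e-4                     # AU/C, typical gentle slopes
  b_ss <- 1 - m_ss * tm                          # A_ss(Tm) = 1 AU
  b_ds <- (1 - cfg$hypochromicity / 100) - m_ds * tm
  bl <- baseline_pair(m_ds, b_ds, m_ss, b_ss)
  tt <- cfg$temp_grid
  a <- model_absorbance(cfg$params, bl, Ct, tt)
  if (cfg$melt_sigma > 0)
    a <- a + with_preserved_seed(cfg$seed, stats::rnorm(length(tt), 0, cfg$melt_sigma))
  curve <- melting_curve(tt, a, Ct = Ct, wavelength = 260, ramp = ramp,
                         label = paste0(cfg$scenario, "-sim"))
  curve <- preprocess_curve(curve)
  attr(curve, "truth") <- list(params = cfg$params, baselines = bl, tm = tm,
                               hypochromicity = cfg$hypochromicity)
  curve
}

#' Simulate a Tm concentration series
#'
#' Melting temperatures from the closed-form [predict_tm()] at each
#' concentration, plus optional Gaussian Tm noise. Noiseless output refits to
#' the generating enthalpy and entropy exactly.
#'
#' @param cfg a [generator_config()].
#' @param Ct total strand concentrations, mol/L.
#' @param tm_sigma Gaussian Tm noise, Celsius.
#' @return A [concentration_series()] with a `truth` attribute.
#' @export
sim_concentration_series <- function(cfg, Ct = c(2.5, 5, 10, 20, 40, 80) * 1e-6,
                                     tm_sigma = 0) {
  stopifnot(inherits(cfg, "generator_config"))
  tm <- vapply(Ct, function(ct) predict_tm(cfg$params, ct), numeric(1))
  if (tm_sigma > 0)
    tm <- tm + with_preserved_seed(cfg$seed, stats::rnorm(length(tm), 0, tm_sigma))
  s <- concentration_series(Ct, tm,
                            tm_err = if (tm_sigma > 0) rep(tm_sigma, length(tm)))
  attr(s, "truth") <- list(params = cfg$params)
  s
}

gaussian_band <- function(wl, center, width, amplitude) {
  amplitude * exp(-0.5 * ((wl - center) / width)^2)
}

## Fraction of the modified strand bound at a given complement concentration.
## Tight (stoichiometric) binding by default; a finite kd switches to the
## exact 1:1 isotherm root.
bound_fraction <- function(complement, modified, kd = 0) {
  if (kd <= 0) return(pmin(complement, modified) / modified)
  b <- modified + complement + kd
  (b - sqrt(b^2 - 4 * modified * complement)) / (2 * modified)
}

#' Simulate a spectral titration series
#'
#' Absorbance mode: a 260 nm nucleotide band growing with total strand
#' concentration (minus a duplex hypochromic term) and a 495 nm fluorophore
#' band scaled by `1 - effect495/100 * bound`, on a 220-600 nm grid.
#' Excitation / emission modes: a single fluorophore band (centered at 470 /
#' 525 nm over the 420-520 / 500-600 nm scan ranges) scaled by
#' `1 - quench * bound`. Bound fractions come from stoichiometric 1:1
#' binding (`kd = 0`) or the exact isotherm. Gaussian noise of
#' `spectrum_sigma_rel` times the control peak is added everywhere.
#'
#' @param cfg a [generator_config()].
#' @param mode `"absorbance"`, `"excitation"` or `"emission"`.
#' @return A [spectrum_series()] with a `truth` attribute (list: `effect495`,
#'   `quench`, `bound`).
#' @export
sim_titration_series <- function(cfg, mode = c("absorbance", "excitation",
                                               "emission")) {
  stopifnot(inherits(cfg, "generator_config"))
  mode <- match.arg(mode)
  comp <- cfg$titration_conc
  mod <- cfg$modified_conc
  bound <- bound_fraction(comp, mod, cfg$kd)
  make_abs <- function(comp_uM, bnd) {
    tot <- mod * 1e6 + comp_uM
    dup <- bnd * mod * 1e6
    a260 <- 0.05 * (tot - cfg$a260_hypo * 2 * dup)
    gaussian_band(wl, 260, 18, a260) +
      gaussian_band(wl, 495, 16, 0.08 * mod * 1e6 * (1 - cfg$effect495 / 100 * bnd))
  }
  if (mode == "absorbance") {
    wl <- 220:600
    control <- make_abs(0, 0)
    mat <- vapply(seq_along(comp),
                  function(j) make_abs(comp[j] * 1e6, bound[j]),
                  numeric(length(wl)))
    fixed <- NA_real_
  } else {
    if (mode == "excitation") { wl <- 420:520; center <- 470; fixed <- 548 }
    else { wl <- 500:600; center <- 525; fixed <- 533 }
    peak0 <- 1000
    control <- gaussian_band(wl, center, 20, peak0)
    mat <- vapply(seq_along(comp), function(j)
      gaussian_band(wl, center, 20, peak0 * (1 - cfg$quench * bound[j])),
      numeric(length(wl)))
  }
  if (cfg$spectrum_sigma_rel > 0) {
    sigma <- cfg$spectrum_sigma_rel * max(control)
    noise <- with_preserved_seed(cfg$seed + 1L,
      matrix(stats::rnorm(length(wl) * (length(comp) + 1L), 0, sigma),
             nrow = length(wl)))
    control <- control + noise[, 1]
    mat <- mat + noise[, -1, drop = FALSE]
  }
  s <- spectrum_series(wl, mat, comp, control, mode = mode,
                       modified_conc = mod, fixed_wavelength = fixed)
  attr(s, "truth") <- list(effect495 = cfg$effect495, quench = cfg$quench,
                           bound = bound)
  s
}

#' Simulate excision-product time courses for both substrates
#'
#' Saturating-exponential product accumulation
#' S(t) = A * (1 - exp(-k t)) + background per substrate, with the preset
#' rate ratio k(nFluS) / k(nFluL) = 2 and equal plateaus, multiplicative
#' Gaussian band noise, and `n_replicates` independent replicates per
#' substrate.
#'
#' @param cfg a [generator_config()].
#' @return Named list (`nFluL`, `nFluS`) of lists of
#'   [excision_timecourse()] replicates, with a `truth` attribute (list:
#'   `rates`, `rate_ratio`, `plateau`, `background`).
#' @export
sim_excision_timecourses <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  tt <- cfg$excision_times
  rates <- cfg$excision_rates
  out <- with_preserved_seed(cfg$seed + 2L, {
    lapply(rates, function(k) {
      clean <- cfg$excision_plateau * (1 - exp(-k * tt)) + cfg$excision_background
      lapply(seq_len(cfg$n_replicates), function(r) {
        noisy <- clean * (1 + stats::rnorm(length(tt), 0, cfg$band_sigma_rel))
        noisy[noisy < 0] <- 0
        excision_timecourse(tt, noisy, substrate = "sub", replicate = r)
      })
    })
  })
  for (s in names(out))
    for (r in seq_along(out[[s]])) out[[s]][[r]]$substrate <- s
  attr(out, "truth") <- list(rates = rates,
                             rate_ratio = unname(rates["nFluS"] / rates["nFluL"]),
                             plateau = cfg$excision_plateau,
                             background = cfg$excision_background)
  out
}

#' Simulate a gel lane table for bend-angle analysis
#'
#' Band migration distances for the unmodified reference duplex and the
#' scenario's modified duplex, constructed so that the mobility ratio equals
#' cos((180 - interior) / 2) for the preset interior bend angle, with
#' optional relative Gaussian position noise.
#'
#' @param cfg a [generator_config()].
#' @param reference_position reference-band migration distance, mm.
#' @param position_sigma_rel relative position noise (0 = noiseless).
#' @return A `data.frame` with columns `lane`, `position` and a `truth`
#'   attribute (list: `interior_angle`, `ratio`).
#' @export
sim_mobility_lanes <- function(cfg, reference_position = 45,
                               position_sigma_rel = 0) {
  stopifnot(inherits(cfg, "generator_config"))
  ratio <- cos((180 - cfg$bend_interior) / 2 * pi / 180)
  pos <- c(unmod = reference_position, mod = reference_position * ratio)
  if (position_sigma_rel > 0)
    pos <- pos * (1 + with_preserved_seed(cfg$seed + 3L,
                    stats::rnorm(2, 0, position_sigma_rel)))
  df <- data.frame(lane = c("unmod", "mod"), position = unname(pos),
                   stringsAsFactors = FALSE)
  attr(df, "truth") <- list(interior_angle = cfg$bend_interior, ratio = ratio)
  df
}
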