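#' A spectral titration series
#'
#' Spectra of samples holding the modified strand at a fixed concentration
#' while the complementary strand increases, plus a zero-complement control.
#' Used for the 260 nm trend, the fluorophore-band hypochromic effect and
#' fluorescence quenching of hybridization titrations.
#'
#' @param wavelength common wavelength grid, nm.
#' @param intensities matrix (wavelength x sample) of absorbances (AU) or
#'   fluorescence counts, one column per non-control sample.
#' @param complement_conc complement concentrations, mol/L, strictly
#'   increasing, one per column of `intensities`.
#' @param control intensities of the zero-complement control, same grid.
#' @param mode `"absorbance"`, `"excitation"` or `"emission"`.
#' @param modified_conc fixed concentration of the modified strand, mol/L.
#' @param fixed_wavelength for fluorescence scans, the fixed partner
#'   wavelength (emission wavelength of an excitation scan and vice versa);
#'   metadata only.
#' @return Object of class `"spectrum_series"`.
#' @export
spectrum_series <- function(wavelength, intensities, complement_conc, control,
                            mode = c("absorbance", "excitation", "emission"),
                            modified_conc = 5.4e-6, fixed_wavelength = NA_real_) {
  mode <- match.arg(mode)
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != length(wavelength))
    stop("intensity matrix and wavelength grid differ in length")
  if (ncol(intensities) != length(complement_conc))
    stop("one complement concentration per sample column is required")
  if (length(control) != length(wavelength))
    stop("control spectrum differs in length from the grid")
  if (any(diff(complement_conc) <= 0))
    stop("complement concentrations must be strictly increasing")
  if (any(complement_conc <= 0))
    stop("complement concentrations must be positive (the control holds the zero point)")
  structure(list(wavelength = as.numeric(wavelength),
                 intensities = intensities,
                 complement_conc = as.numeric(complement_conc),
                 control = as.numeric(control), mode = mode,
                 modified_conc = check_ct(modified_conc),
                 fixed_wavelength = fixed_wavelength),
            class = "spectrum_series")
}

#' Band intensity per sample
#'
#' The maximum intensity within `center +/- halfwidth`, one value per sample
#' plus the control. A windowed maximum (default +/- 5 nm) rather than a
#' single grid point keeps the readout robust to the small band shifts that
#' accompany environment changes on 1 nm instrument grids.
#'
#' @param series a [spectrum_series()].
#' @param center band center, nm.
#' @param halfwidth window half-width, nm.
#' @return List with `samples` (named by complement concentration in uM) and
#'   `control`.
#' @export
band_value <- function(series, center, halfwidth = 5) {
  stopifnot(inherits(series, "spectrum_series"))
  wl <- series$wavelength
  if (center - halfwidth < min(wl) || center + halfwidth > max(wl))
    stop("band window [", center - halfwidth, ", ", center + halfwidth,
         "] nm falls outside the measured grid")
  in_win <- wl >= center - halfwidth & wl <= center + halfwidth
  v <- apply(series$intensities[in_win, , drop = FALSE], 2, max)
  names(v) <- sprintf("%g", series$complement_conc * 1e6)
  list(samples = v, control = max(series$control[in_win]))
}

monotone_direction <- function(x, tol = 0) {
  d <- diff(x)
  if (all(d <= tol)) "decreasing" else if (all(d >= -tol)) "increasing" else "none"
}

#' Saturation hypochromic effect of a titration band
#'
#' Percent intensity lost at the highest complement concentration relative to
#' the zero-complement control,
#' effect = 100 * (V_control - V_saturation) / V_control,
#' with V from [band_value()]. Positive values mean intensity loss
#' (hypochromicity); no dilution correction is applied because the band
#' carrier (the modified strand) is at the same concentration in every
#' sample.
#'
#' @inheritParams band_value
#' @return Object of class `"titration_summary"`: `band_values` (control
#'   first, then samples in concentration order), `hypochromic_effect_pct`,
#'   `monotone_flag` (`"decreasing"`, `"increasing"` or `"none"`), `center`.
#' @export
hypochromic_effect <- function(series, center = 495, halfwidth = 5) {
  stopifnot(inherits(series, "spectrum_series"))
  if (ncol(series$intensities) < 2L)
    stop("at least 2 non-control samples are required")
  v <- band_value(series, center, halfwidth)
  vals <- c(control = v$control, v$samples)
  if (v$control <= 0) stop("control band value must be positive")
  eff <- 100 * (v$control - v$samples[[length(v$samples)]]) / v$control
  structure(list(band_values = vals,
                 hypochromic_effect_pct = eff,
                 monotone_flag = monotone_direction(vals),
                 center = center),
            class = "titration_summary")
}

#' @export
print.titration_summary <- function(x, ...) {
  cat(sprintf("Titration band at %g nm: saturation hypochromic effect %.1f%% (trend %s)\n",
              x$center, x$hypochromic_effect_pct, x$monotone_flag))
  invisible(x)
}

#' Fluorescence quenching fractions across a titration
#'
#' fraction_i = 1 - peak_i / peak_control, with the peak searched over the
#' full scan range of each fluorescence spectrum. Positive fractions mean
#' quenching on duplex formation; a monotone flag summarizes the trend over
#' the concentration series.
#'
#' @param series a fluorescence-mode [spectrum_series()].
#' @return List with `fractions` (named by complement concentration, uM),
#'   `control_peak`, `monotone_flag`.
#' @export
quench_fraction <- function(series) {
  stopifnot(inherits(series, "spectrum_series"))
  if (series$mode == "absorbance")
    stop("quench fractions are defined for excitation or emission scans")
  pc <- max(series$control)
  if (pc <= 0) stop("control peak intensity must be positive")
  peaks <- apply(series$intensities, 2, max)
  fr <- 1 - peaks / pc
  names(fr) <- sprintf("%g", series$complement_conc * 1e6)
  list(fractions = fr, control_peak = pc,
       monotone_flag = monotone_direction(c(0, fr)))
}

#' Total-DNA trend of the 260 nm band
#'
#' Band values at 260 nm against the total strand concentration
#' (fixed modified strand + complement), with a straight-line diagnostic:
#' absorbance at the nucleotide maximum should grow with total DNA, and
#' curvature beyond the line betrays a duplex hypochromic contribution.
#'
#' @param series an absorbance-mode [spectrum_series()].
#' @param halfwidth band window half-width, nm.
#' @return List with `values` (control first), `total_conc` (mol/L),
#'   `coefficients` of the line fit, `rss` (residual sum of squares, NA when
#'   fewer than 3 points), and `sublinear` (TRUE when the band grows more
#'   slowly than the proportional extrapolation from the control point —
#'   the signature of a duplex hypochromic contribution at 260 nm).
#' @export
a260_trend <- function(series, halfwidth = 2) {
  stopifnot(inherits(series, "spectrum_series"))
  if (series$mode != "absorbance")
    stop("the 260 nm trend is defined for absorbance series")
  v <- band_value(series, 260, halfwidth)
  vals <- c(v$control, v$samples)
  total <- series$modified_conc + c(0, series$complement_conc)
  if (length(vals) >= 3L) {
    fit <- stats::lm.fit(cbind(1, total), vals)
    rss <- sum(fit$residuals^2)
    coefs <- fit$coefficients
  } else {
    rss <- NA_real_
    coefs <- c(NA_real_, NA_real_)
  }
  pred <- vals[1] / total[1] * total      # proportional growth from control
  dev <- vals[-1] - pred[-1]
  list(values = vals, total_conc = total,
       coefficients = unname(coefs), rss = rss,
       sublinear = all(dev <= 1e-12) && any(dev < -1e-12))
}
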