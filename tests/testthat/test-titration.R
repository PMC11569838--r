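flat_series <- function(value = 0.7, mode = "absorbance") {
  wl <- 420:520
  conc <- c(1.25, 2.7, 4.05, 5.4) * 1e-6
  spectrum_series(wl, matrix(value, length(wl), length(conc)), conc,
                  rep(value, length(wl)), mode = mode)
}

test_that("band values take the windowed maximum", {
  s <- flat_series()
  bv <- band_value(s, 470, 10)
  expect_true(all(bv$samples == 0.7))
  expect_equal(bv$control, 0.7)
  # single Gaussian at 495: window centered there returns the amplitude
  wl <- 420:520
  g <- 0.9 * exp(-0.5 * ((wl - 495) / 8)^2)
  s2 <- spectrum_series(wl, matrix(rep(g, 4), ncol = 4),
                        c(1.25, 2.7, 4.05, 5.4) * 1e-6, g)
  expect_equal(unname(band_value(s2, 495, 10)$samples[1]), 0.9)
  # two peaks: only the taller one inside the window counts
  g2 <- g + 0.4 * exp(-0.5 * ((wl - 440) / 5)^2)
  s3 <- spectrum_series(wl, matrix(rep(g2, 4), ncol = 4),
                        c(1.25, 2.7, 4.05, 5.4) * 1e-6, g2)
  expect_equal(unname(band_value(s3, 440, 8)$samples[1]), 0.4,
               tolerance = 1e-3)
  expect_error(band_value(s, 415, 10), "outside")
})

test_that("hypochromic effect is the control-relative saturation loss", {
  wl <- 420:520
  conc <- c(1.25, 2.7, 4.05, 5.4) * 1e-6
  peak <- function(a) a * exp(-0.5 * ((wl - 495) / 10)^2)
  # band scaling 1.0 (control) down to 0.60 at saturation -> 40 %
  scales <- c(0.9, 0.78, 0.68, 0.60)
  s <- spectrum_series(wl, vapply(scales, peak, numeric(length(wl))),
                       conc, peak(1.0))
  eff <- hypochromic_effect(s, 495, 5)
  expect_equal(eff$hypochromic_effect_pct, 40, tolerance = 1e-9)
  expect_equal(eff$monotone_flag, "decreasing")
  # scaling to 0.80 -> 20 %
  s2 <- spectrum_series(wl, vapply(c(0.95, 0.9, 0.85, 0.8), peak,
                                   numeric(length(wl))), conc, peak(1.0))
  expect_equal(hypochromic_effect(s2, 495, 5)$hypochromic_effect_pct, 20,
               tolerance = 1e-9)
  # identical spectra -> 0 %
  expect_equal(hypochromic_effect(flat_series(), 470, 5)$hypochromic_effect_pct,
               0)
  # invariance under uniform positive rescaling
  s3 <- s; s3$intensities <- 7 * s$intensities; s3$control <- 7 * s$control
  expect_equal(hypochromic_effect(s3, 495, 5)$hypochromic_effect_pct, 40,
               tolerance = 1e-9)
})

test_that("quench fractions are control-relative peak losses", {
  wl <- 500:600
  conc <- c(1.25, 2.7, 4.05, 5.4) * 1e-6
  peak <- function(a) a * exp(-0.5 * ((wl - 525) / 15)^2)
  s <- spectrum_series(wl, vapply(c(0.85, 0.7, 0.58, 0.5), function(a)
    1000 * peak(a), numeric(length(wl))), conc, 1000 * peak(1), mode = "emission")
  q <- quench_fraction(s)
  expect_equal(unname(q$fractions[4]), 0.5, tolerance = 1e-9)
  expect_equal(q$monotone_flag, "increasing")
  # sample equal to control -> 0
  s0 <- flat_series(mode = "emission")
  expect_true(all(abs(quench_fraction(s0)$fractions) < 1e-12))
  # anti-quench series yields negative fractions
  s_up <- spectrum_series(wl, vapply(c(1.1, 1.2, 1.3, 1.4), function(a)
    1000 * peak(a), numeric(length(wl))), conc, 1000 * peak(1), mode = "emission")
  expect_true(all(quench_fraction(s_up)$fractions < 0))
  expect_error(quench_fraction(flat_series(mode = "absorbance")), "excitation")
})

test_that("the 260 nm band tracks total DNA, and duplex hypochromicity bends it", {
  # strictly proportional series: line fit residual is zero
  cfg0 <- generator_config("custom", seed = 1, spectrum_sigma_rel = 0,
                           a260_hypo = 0, effect495 = 0)
  tr0 <- a260_trend(sim_titration_series(cfg0, "absorbance"))
  expect_lt(tr0$rss, 1e-20)
  expect_true(all(diff(tr0$values) > 0))
  expect_false(tr0$sublinear)
  # a duplex hypochromic term makes growth lag the proportional
  # extrapolation from the control, whether binding is tight (linear lag) or
  # governed by a finite dissociation constant (curved lag, positive
  # line-fit residual)
  cfg_t <- generator_config("nFluS", seed = 1, spectrum_sigma_rel = 0)
  tr_t <- a260_trend(sim_titration_series(cfg_t, "absorbance"))
  expect_true(tr_t$sublinear)
  cfg1 <- generator_config("nFluS", seed = 1, spectrum_sigma_rel = 0,
                           kd = 2e-6)
  tr1 <- a260_trend(sim_titration_series(cfg1, "absorbance"))
  expect_gt(tr1$rss, 1e-12)
  expect_true(tr1$sublinear)
})

test_that("series construction enforces the shared grid and ordered concentrations", {
  wl <- 420:520
  expect_error(spectrum_series(wl, matrix(1, 50, 2), c(1e-6, 2e-6),
                               rep(1, length(wl))), "differ in length")
  expect_error(spectrum_series(wl, matrix(1, length(wl), 2), c(2e-6, 1e-6),
                               rep(1, length(wl))), "increasing")
  expect_error(spectrum_series(wl, matrix(1, length(wl), 2), c(1e-6, 2e-6),
                               rep(1, 3)), "control")
})
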