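test_that("scenario presets carry the published-scale study parameters", {
  for (sc in c("NM", "nFluL", "nFluS")) {
    cfg <- generator_config(sc, seed = 1)
    row <- table2[table2$label == paste0(sc, "-DNA"), ]
    expect_equal(cfg$params$dH / 1000, row$dH_kcal)
    expect_equal(cfg$params$dS, row$dS)
  }
  expect_equal(generator_config("NM")$hypochromicity, 14.75)
  expect_equal(generator_config("nFluL")$hypochromicity, 13.5)
  expect_equal(generator_config("nFluS")$hypochromicity, 14.3)
  expect_equal(generator_config("nFluS")$effect495, 40)
  expect_lte(generator_config("nFluL")$effect495, 20)
  r <- generator_config("nFluL")$excision_rates
  expect_equal(unname(r["nFluS"] / r["nFluL"]), 2)
  expect_error(generator_config("nFluL", nonsense = 1), "unknown configuration")
})

test_that("generators are bit-reproducible under a fixed seed", {
  c1 <- sim_melting_curve(generator_config("nFluL", seed = 5))
  c2 <- sim_melting_curve(generator_config("nFluL", seed = 5))
  expect_identical(c1$absorbance, c2$absorbance)
  c3 <- sim_melting_curve(generator_config("nFluL", seed = 6))
  expect_false(identical(c1$absorbance, c3$absorbance))
  s1 <- sim_titration_series(generator_config("nFluS", seed = 5), "absorbance")
  s2 <- sim_titration_series(generator_config("nFluS", seed = 5), "absorbance")
  expect_identical(s1$intensities, s2$intensities)
  t1 <- sim_excision_timecourses(generator_config("nFluS", seed = 5))
  t2 <- sim_excision_timecourses(generator_config("nFluS", seed = 5))
  expect_identical(t1$nFluL[[2]]$intensity, t2$nFluL[[2]]$intensity)
})

test_that("simulated melting curves carry their truth and the preset midpoint", {
  cfg <- generator_config("nFluL", seed = 2)
  cv <- sim_melting_curve(cfg, Ct = 20e-6)
  truth <- attr(cv, "truth")
  expect_equal(truth$tm, predict_tm(cfg$params, 20e-6))
  expect_equal(derivative_tm(cv), 55.6, tolerance = 1)
  # noiseless curve equals the forward model exactly
  cv0 <- sim_melting_curve(generator_config("nFluL", seed = 2, melt_sigma = 0))
  tr0 <- attr(cv0, "truth")
  expect_equal(cv0$absorbance,
               model_absorbance(tr0$params, tr0$baselines, cv0$Ct,
                                cv0$temperature),
               tolerance = 1e-14)
  # baselines anchored so hypochromicity at Tm equals the preset
  expect_equal(hypochromicity(tr0$baselines, tm = tr0$tm),
               cfg$hypochromicity, tolerance = 1e-9)
})

test_that("noiseless titration series reproduce the preset effects", {
  sS <- sim_titration_series(generator_config("nFluS", spectrum_sigma_rel = 0),
                             "absorbance")
  expect_equal(hypochromic_effect(sS, 495)$hypochromic_effect_pct, 40,
               tolerance = 1e-9)
  sL <- sim_titration_series(generator_config("nFluL", spectrum_sigma_rel = 0),
                             "absorbance")
  expect_lte(hypochromic_effect(sL, 495)$hypochromic_effect_pct, 20 + 1e-9)
  # zero-effect custom scenario: no 495 nm loss, no quench
  s0 <- sim_titration_series(generator_config("custom", spectrum_sigma_rel = 0,
                                              effect495 = 0, quench = 0),
                             "absorbance")
  expect_equal(hypochromic_effect(s0, 495)$hypochromic_effect_pct, 0,
               tolerance = 1e-9)
  e0 <- sim_titration_series(generator_config("custom", spectrum_sigma_rel = 0,
                                              quench = 0), "emission")
  expect_true(all(abs(quench_fraction(e0)$fractions) < 1e-12))
  # saturation quench equals the preset at full binding
  eS <- sim_titration_series(generator_config("nFluS", spectrum_sigma_rel = 0),
                             "emission")
  q <- quench_fraction(eS)
  expect_equal(unname(q$fractions[length(q$fractions)]), 0.5, tolerance = 1e-9)
})

test_that("noiseless excision courses follow the exponential ratio limits", {
  cfg <- generator_config("nFluS", band_sigma_rel = 0, n_replicates = 1L)
  tcs <- sim_excision_timecourses(cfg)
  er <- efficiency_ratio(lapply(tcs$nFluS, normalize_timecourse),
                         lapply(tcs$nFluL, normalize_timecourse),
                         n_boot = 50, seed = 1)
  k <- cfg$excision_rates["nFluL"]
  tt <- er$ratio_per_time$time
  # ratio of equal-plateau exponentials with rate ratio 2: 1 + exp(-k t)
  expect_equal(er$ratio_per_time$ratio, unname(1 + exp(-k * tt)),
               tolerance = 1e-9)
  # equal rates: ratio identically 1
  cfg_eq <- generator_config("custom", band_sigma_rel = 0, n_replicates = 1L,
                             excision_rates = c(nFluL = 0.01, nFluS = 0.01))
  tcs_eq <- sim_excision_timecourses(cfg_eq)
  er_eq <- efficiency_ratio(lapply(tcs_eq$nFluS, normalize_timecourse),
                            lapply(tcs_eq$nFluL, normalize_timecourse),
                            n_boot = 50, seed = 1)
  expect_equal(er_eq$ratio_per_time$ratio, rep(1, length(er_eq$ratio_per_time$ratio)),
               tolerance = 1e-12)
})

test_that("noisy concentration-series estimates cover the preset parameters", {
  cover <- 0; reps <- 100
  for (s in seq_len(reps)) {
    ser <- sim_concentration_series(generator_config("nFluS", seed = s),
                                    tm_sigma = 0.3)
    fit <- fit_vant_hoff(ser)
    if (abs(fit$params$dH - (-103.5e3)) <= 3 * fit$params$dH_err) cover <- cover + 1
  }
  expect_gte(cover / reps, 0.95)
})

test_that("a finite-Kd titration mode weakens but preserves the trend", {
  tight <- sim_titration_series(generator_config("nFluS", spectrum_sigma_rel = 0),
                                "absorbance")
  loose <- sim_titration_series(generator_config("nFluS", spectrum_sigma_rel = 0,
                                                 kd = 2e-6), "absorbance")
  et <- hypochromic_effect(tight, 495)$hypochromic_effect_pct
  el <- hypochromic_effect(loose, 495)$hypochromic_effect_pct
  expect_lt(el, et)
  expect_gt(el, 0)
})
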