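make_curve <- function(cfg = generator_config("nFluL", seed = 1, melt_sigma = 0),
                       Ct = 20e-6) sim_melting_curve(cfg, Ct = Ct)

test_that("preprocessing canonicalizes raw traces", {
  tt <- seq(95, 5, by = -0.5)
  a <- 0.8 + 0.002 * tt
  raw <- melting_curve(tt, a, Ct = 2e-5)
  out <- preprocess_curve(raw)
  # descending input comes back ascending with the same (T, A) pairs
  expect_true(all(diff(out$temperature) > 0))
  expect_equal(out$absorbance, rev(a))
  # zero reference channel is the identity
  rawz <- melting_curve(tt, a, Ct = 2e-5, reference = rep(0, length(tt)))
  expect_equal(preprocess_curve(rawz)$absorbance, out$absorbance)
  # constant 0.05 AU reference shifts every point down by 0.05
  raw5 <- melting_curve(tt, a, Ct = 2e-5, reference = rep(0.05, length(tt)))
  expect_equal(preprocess_curve(raw5)$absorbance, out$absorbance - 0.05)
  # duplicate temperatures are averaged
  dup <- melting_curve(c(tt, 50), c(a, 1), Ct = 2e-5)
  pp <- preprocess_curve(dup)
  expect_equal(sum(pp$temperature == 50), 1L)
  expect_equal(pp$absorbance[pp$temperature == 50],
               mean(c(a[tt == 50], 1)))
  # malformed inputs rejected
  expect_error(melting_curve(tt, a[-1], Ct = 2e-5), "length")
  expect_error(melting_curve(1:25, rnorm(25), Ct = 2e-5), "30 C")
})

test_that("model absorbance interpolates between the baselines", {
  bl <- baseline_pair(m_ds = 5e-4, b_ds = 0.83, m_ss = 2e-4, b_ss = 0.99)
  tm <- predict_tm(p_nfluL, 2e-5)
  tt <- seq(5, 95, by = 0.5)
  a <- model_absorbance(p_nfluL, bl, 2e-5, tt)
  lo <- bl$b_ds + bl$m_ds * tt
  hi <- bl$b_ss + bl$m_ss * tt
  expect_true(all(a >= lo - 1e-12 & a <= hi + 1e-12))
  # limits: duplex baseline at low T, single-strand baseline at high T
  expect_equal(model_absorbance(p_nfluL, bl, 2e-5, 5), lo[1], tolerance = 1e-6)
  expect_equal(model_absorbance(p_nfluL, bl, 2e-5, 95), hi[length(hi)],
               tolerance = 1e-6)
  # midpoint of the baselines at Tm (theta = 0.5)
  expect_equal(model_absorbance(p_nfluL, bl, 2e-5, tm),
               (bl$b_ds + bl$m_ds * tm + bl$b_ss + bl$m_ss * tm) / 2,
               tolerance = 1e-9)
})

test_that("derivative midpoint finds the transition and rejects featureless traces", {
  cv <- make_curve()
  truth <- attr(cv, "truth")
  expect_equal(derivative_tm(cv), truth$tm, tolerance = 0.5)
  # monotone linear trace: no transition
  tt <- seq(5, 95, by = 0.5)
  flat <- preprocess_curve(melting_curve(tt, 0.8 + 0.001 * tt, Ct = 2e-5))
  expect_error(derivative_tm(flat), "no.*transition|transition")
  # symmetric sigmoid with flat baselines peaks at its center
  sig <- preprocess_curve(melting_curve(tt, 1 / (1 + exp(-(tt - 50) / 3)),
                                        Ct = 2e-5))
  expect_equal(derivative_tm(sig), 50, tolerance = 0.5)
})

test_that("noiseless curves refit to the generating truth", {
  cv <- make_curve()
  truth <- attr(cv, "truth")
  fit <- fit_melting_curve(cv)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$dH - truth$params$dH) / abs(truth$params$dH), 0.005)
  expect_lt(abs(fit$tm - truth$tm), 0.05)
  expect_lt(fit$ssr, 1e-12)
  expect_equal(fit$hypochromicity, truth$hypochromicity, tolerance = 0.01)
  # fitted curve lies between the fitted baselines everywhere
  lo <- fit$baselines$b_ds + fit$baselines$m_ds * cv$temperature
  hi <- fit$baselines$b_ss + fit$baselines$m_ss * cv$temperature
  expect_true(all(fit$fitted >= lo - 1e-9 & fit$fitted <= hi + 1e-9))
})

test_that("initializing at the generating truth keeps the optimum", {
  cv <- make_curve()
  truth <- attr(cv, "truth")
  fit <- fit_melting_curve(cv, init = list(params = truth$params,
                                           baselines = truth$baselines),
                           n_restarts = 1L)
  expect_lt(fit$ssr, 1e-15)
  expect_lt(abs(fit$tm - truth$tm), 1e-3)
})

test_that("refitting a fit's own prediction is idempotent", {
  cv <- make_curve(generator_config("nFluS", seed = 4, melt_sigma = 0))
  fit1 <- fit_melting_curve(cv)
  cv2 <- cv
  cv2$absorbance <- fit1$fitted
  fit2 <- fit_melting_curve(cv2)
  expect_equal(fit2$params$dH, fit1$params$dH, tolerance = 1e-6)
  expect_equal(fit2$tm, fit1$tm, tolerance = 1e-6)
})

test_that("underdetermined and featureless inputs are rejected", {
  tt <- seq(5, 95, length.out = 20)
  cv <- preprocess_curve(melting_curve(tt, 0.8 + 0.001 * tt, Ct = 2e-5))
  expect_error(fit_melting_curve(cv), "transition")
  short <- cv; short$temperature <- tt[1:17]; short$absorbance <- cv$absorbance[1:17]
  expect_error(fit_melting_curve(short), "identifiable")
})

test_that("hypochromicity follows its defining arithmetic", {
  # A_ss(Tm) = 1.000, A_ds(Tm) = 0.8525 -> 14.75 %
  bl <- baseline_pair(m_ds = 0, b_ds = 0.8525, m_ss = 0, b_ss = 1.0)
  expect_equal(hypochromicity(bl, tm = 55), 14.75, tolerance = 1e-10)
  # A_ss = 0.900, A_ds = 0.7785 -> 13.5 %
  bl2 <- baseline_pair(0, 0.7785, 0, 0.900)
  expect_equal(hypochromicity(bl2, tm = 55), 13.5, tolerance = 1e-10)
  # identical baselines -> 0 %
  bl3 <- baseline_pair(1e-4, 0.9, 1e-4, 0.9)
  expect_equal(hypochromicity(bl3, tm = 55), 0)
  # non-positive single-strand baseline rejected
  bl4 <- baseline_pair(0, 0.5, 0, -1)
  expect_error(hypochromicity(bl4, tm = 55), "non-positive")
})

test_that("hysteresis between ramps is measured and flagged", {
  heat <- make_curve()
  cool_cfg <- cfg_from_tm(-119.4e3, attr(heat, "truth")$tm - 2, melt_sigma = 0)
  cool <- sim_melting_curve(cool_cfg)
  cool$ramp <- "cooling"
  expect_warning(d <- ramp_hysteresis(heat, cool), "hysteresis")
  expect_gt(d, 1)
  expect_silent(ramp_hysteresis(heat, heat))
})
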