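#' An optically recorded thermal denaturation trace
#'
#' @param temperature temperatures, degrees Celsius.
#' @param absorbance optical densities (AU), same length.
#' @param Ct total single-strand concentration, mol/L.
#' @param wavelength recording wavelength, nm (typically 260 or 270).
#' @param reference optional reference-channel absorbances (e.g. a 300 nm
#'   baseline channel), subtracted by [preprocess_curve()].
#' @param ramp `"heating"` or `"cooling"`.
#' @param label free-text sample label.
#' @return Object of class `"melting_curve"`.
#' @export
melting_curve <- function(temperature, absorbance, Ct,
                          wavelength = 260, reference = NULL,
                          ramp = c("heating", "cooling"), label = "") {
  ramp <- match.arg(ramp)
  if (length(temperature) != length(absorbance))
    stop("temperature and absorbance differ in length")
  if (!is.null(reference) && length(reference) != length(temperature))
    stop("reference channel differs in length from the trace")
  if (length(temperature) < 20L)
    stop("a melting curve needs at least 20 points for the fit to be identifiable")
  if (diff(range(temperature)) < 30)
    stop("the temperature range must span at least 30 C to anchor both baselines")
  structure(list(temperature = as.numeric(temperature),
                 absorbance = as.numeric(absorbance),
                 reference = if (is.null(reference)) NULL else as.numeric(reference),
                 Ct = check_ct(Ct), wavelength = wavelength,
                 ramp = ramp, label = label, preprocessed = FALSE),
            class = "melting_curve")
}

#' @export
print.melting_curve <- function(x, ...) {
  cat(sprintf("Melting curve '%s' (%s, %g nm): %d points, %.1f-%.1f C, Ct = %g M\n",
              x$label, x$ramp, x$wavelength, length(x$temperature),
              min(x$temperature), max(x$temperature), x$Ct))
  invisible(x)
}

#' Canonicalize a raw denaturation trace
#'
#' Subtracts the reference channel (if present), sorts by temperature and
#' averages duplicate temperature readings. Fitting functions require a
#' preprocessed curve.
#'
#' @param curve a [melting_curve()].
#' @return A preprocessed `"melting_curve"` (reference channel consumed).
#' @export
preprocess_curve <- function(curve) {
  stopifnot(inherits(curve, "melting_curve"))
  a <- curve$absorbance
  if (!is.null(curve$reference)) a <- a - curve$reference
  o <- order(curve$temperature)
  tt <- curve$temperature[o]; a <- a[o]
  if (anyDuplicated(tt)) {
    a <- as.numeric(tapply(a, tt, mean))
    tt <- sort(unique(tt))
  }
  curve$temperature <- tt
  curve$absorbance <- a
  curve$reference <- NULL
  curve$preprocessed <- TRUE
  curve
}

#' Hysteresis between a heating and a cooling ramp
#'
#' Compares the model-free midpoints ([derivative_tm()]) of the two ramps and
#' raises a warning when they differ by more than `tol` (default 1 C), the
#' classic sign that the ramp rate outruns re-equilibration. Returns the
#' absolute midpoint difference so callers can decide whether merging the
#' ramps is defensible.
#'
#' @param heating,cooling preprocessed [melting_curve()] objects.
#' @param tol hysteresis tolerance, degrees Celsius.
#' @return Absolute midpoint difference in degrees Celsius.
#' @export
ramp_hysteresis <- function(heating, cooling, tol = 1) {
  d <- abs(derivative_tm(heating) - derivative_tm(cooling))
  if (d > tol)
    warning(sprintf("hysteresis between heating and cooling midpoints: %.2f C", d))
  d
}

#' Linear duplex/single-strand baselines
#'
#' The two-state optical model brackets the transition between a duplex
#' (lower, hypochromic) and a single-strand (upper) baseline, each linear in
#' temperature: A_state(T) = b + m*T, T in Celsius.
#'
#' @param m_ds,b_ds duplex-state slope (AU/C) and intercept (AU).
#' @param m_ss,b_ss single-strand-state slope and intercept.
#' @return Object of class `"baseline_pair"`.
#' @export
baseline_pair <- function(m_ds, b_ds, m_ss, b_ss) {
  stopifnot(is.finite(m_ds), is.finite(b_ds), is.finite(m_ss), is.finite(b_ss))
  structure(list(m_ds = unname(m_ds), b_ds = unname(b_ds),
                 m_ss = unname(m_ss), b_ss = unname(b_ss)),
            class = "baseline_pair")
}

baseline_at <- function(baselines, T_C) {
  list(ds = baselines$b_ds + baselines$m_ds * T_C,
       ss = baselines$b_ss + baselines$m_ss * T_C)
}

#' Two-state model absorbance
#'
#' A(T) = theta(T) * A_ds(T) + (1 - theta(T)) * A_ss(T): the observed optical
#' density interpolates between the duplex and single-strand baselines with
#' the duplex fraction from [fraction_duplex()].
#'
#' @param params [thermo_params()].
#' @param baselines [baseline_pair()].
#' @param Ct total single-strand concentration, mol/L.
#' @param T_C temperature(s), Celsius.
#' @return Modelled absorbance(s), AU.
#' @export
model_absorbance <- function(params, baselines, Ct, T_C) {
  theta <- fraction_duplex(params, Ct, T_C + 273.15)
  b <- baseline_at(baselines, T_C)
  theta * b$ds + (1 - theta) * b$ss
}

## Smoothed dA/dT on a uniform grid (Savitzky-Golay local polynomial).
## Returns list(T, dA) restricted to the part of the grid where the filter
## window is fully interior.
smoothed_derivative <- function(curve, window = 11L, degree = 2L) {
  tt <- curve$temperature; a <- curve$absorbance
  dt <- diff(tt)
  if (max(dt) - min(dt) > 1e-6 * mean(dt)) {     # resample non-uniform grids
    grid <- seq(min(tt), max(tt), length.out = length(tt))
    a <- stats::approx(tt, a, xout = grid)$y
    tt <- grid
  }
  h <- mean(diff(tt))
  if (length(a) < window + 2L)
    stop("too few points for a window-", window, " derivative filter")
  dA <- signal::sgolayfilt(a, p = degree, n = window, m = 1L, ts = h)
  half <- (window - 1L) %/% 2L
  keep <- (half + 1L):(length(a) - half)
  list(T = tt[keep], dA = dA[keep])
}

#' Model-free melting midpoint from the derivative maximum
#'
#' Locates the maximum of a Savitzky-Golay smoothed dA/dT (window 11 points,
#' polynomial order 2). Used to initialize [fit_melting_curve()] and as a
#' quality-control cross-check; the reported Tm of a fit is the theta = 0.5
#' point of the fitted model, which differs slightly when baselines slope.
#'
#' @param curve a preprocessed [melting_curve()].
#' @param window,degree Savitzky-Golay filter window (odd) and polynomial order.
#' @return Temperature of the derivative maximum, degrees Celsius.
#' @export
derivative_tm <- function(curve, window = 11L, degree = 2L) {
  stopifnot(inherits(curve, "melting_curve"))
  d <- smoothed_derivative(curve, window, degree)
  i <- which.max(d$dA)
  if (i == 1L || i == length(d$dA))
    stop("no interior melting transition: derivative maximum sits on the range boundary")
  ## a real transition must rise clearly above the baseline-slope floor
  floor_level <- stats::median(d$dA)
  spread <- stats::mad(d$dA) + 1e-12
  if (d$dA[i] - floor_level < 3 * spread)
    stop("no interior melting transition: trace has no sigmoidal inflection")
  d$T[i]
}

## Fit parameterization: p = (Tm_K, dH, m_ds, b_ds, m_ss, b_ss).
## dS is tied to (Tm, dH) through the half-dissociation condition
## dS = dH/Tm - R*ln(Ct/4), so the reported Tm is theta = 0.5 of the fitted
## model by construction. Equivalent to fitting (dH, dS) directly but far
## better conditioned (Tm and dH are nearly orthogonal; dH and dS are not).
ds_from_tm <- function(dH, Tm_K, Ct) dH / Tm_K - RGAS * log(Ct / 4)

melt_ssr <- function(p, tt, a, Ct) {
  dH <- p[2]
  if (dH >= 0 || p[1] <= 0) return(1e10)
  dS <- ds_from_tm(dH, p[1], Ct)
  if (dS >= 0) return(1e10)
  theta <- {
    x <- exp(-(dH - (tt + 273.15) * dS) / (RGAS * (tt + 273.15))) * Ct
    th <- x / (x + 1 + sqrt(2 * x + 1)); th[!is.finite(x)] <- 1; th
  }
  model <- theta * (p[4] + p[3] * tt) + (1 - theta) * (p[6] + p[5] * tt)
  sum((a - model)^2)
}

## Initial estimates: Tm from the derivative peak, baselines from line fits
## to the outer 20% of the range, dH from the two-state slope identity
## d(theta)/dT at Tm = dH / (6 R Tm^2) for a bimolecular transition.
melt_init <- function(curve) {
  tt <- curve$temperature; a <- curve$absorbance
  tm0 <- derivative_tm(curve)
  rng <- range(tt); span <- diff(rng)
  lo <- tt <= rng[1] + 0.2 * span
  hi <- tt >= rng[2] - 0.2 * span
  f_ds <- stats::lm.fit(cbind(1, tt[lo]), a[lo])$coefficients
  f_ss <- stats::lm.fit(cbind(1, tt[hi]), a[hi])$coefficients
  ads <- f_ds[1] + f_ds[2] * tt
  ass <- f_ss[1] + f_ss[2] * tt
  theta_hat <- pmin(1, pmax(0, (ass - a) / pmax(ass - ads, 1e-6)))
  th_curve <- curve
  th_curve$absorbance <- theta_hat
  d <- smoothed_derivative(th_curve)
  slope <- min(d$dA)                       # d(theta)/dT < 0 at the transition
  dH0 <- 6 * RGAS * (tm0 + 273.15)^2 * slope
  dH0 <- min(max(dH0, -250e3), -40e3)
  c(Tm_K = tm0 + 273.15, dH = dH0,
    m_ds = unname(f_ds[2]), b_ds = unname(f_ds[1]),
    m_ss = unname(f_ss[2]), b_ss = unname(f_ss[1]))
}

#' Fit the two-state model to a melting curve
#'
#' Minimizes the sum of squared deviations between the measured trace and
#' [model_absorbance()] over six parameters (enthalpy, melting temperature,
#' and two linear baselines; the entropy is tied to Tm through the
#' half-dissociation condition) with a derivative-free Nelder-Mead simplex.
#' The simplex is restarted from its own endpoint until the SSR improvement
#' falls below `1e-14` AU^2, and the whole search is repeated from a set of
#' deterministically jittered initial guesses; the best SSR wins, with ties
#' broken by proximity of Tm to the model-free derivative midpoint.
#'
#' @param curve a preprocessed [melting_curve()].
#' @param init optional named list with any of `params` ([thermo_params()])
#'   and `baselines` ([baseline_pair()]) to override the automatic initials.
#' @param n_restarts number of jittered starts (default 5).
#' @param max_eval simplex evaluation budget per start.
#' @return Object of class `"melt_fit"`: `params`, `baselines`, `tm` (C,
#'   theta = 0.5 of the fit), `hypochromicity` (percent, baselines
#'   extrapolated to Tm), `ssr`, `converged` (FALSE when restarts disagree in
#'   Tm by more than 0.5 C), `n_restarts_used`, `fitted`, `residuals`.
#' @export
fit_melting_curve <- function(curve, init = NULL, n_restarts = 5L,
                              max_eval = 10000L) {
  stopifnot(inherits(curve, "melting_curve"))
  if (!curve$preprocessed) curve <- preprocess_curve(curve)
  tt <- curve$temperature; a <- curve$absorbance
  if (length(tt) < 18L)
    stop("fewer than 18 points: the 6-parameter fit is not identifiable")
  p0 <- melt_init(curve)              # errors here reject non-sigmoidal traces
  if (!is.null(init)) {
    if (!is.null(init$params)) {
      p <- init$params
      tmK <- predict_tm(p, curve$Ct) + 273.15
      p0[c("Tm_K", "dH")] <- c(tmK, p$dH)
    }
    if (!is.null(init$baselines)) {
      b <- init$baselines
      p0[c("m_ds", "b_ds", "m_ss", "b_ss")] <- c(b$m_ds, b$b_ds, b$m_ss, b$b_ss)
    }
  }
  ## deterministic jitter table: restart 1 is the plain initial guess
  tm_shift <- c(0, -1, 1, -2, 2, -3, 3, -4, 4, -5)
  dh_scale <- c(1, 0.8, 1.2, 0.65, 1.4, 0.9, 1.1, 0.5, 1.6, 0.75)
  scale <- c(1, max(abs(p0["dH"]), 1e4), 1e-3, 0.1, 1e-3, 0.1)
  runs <- vector("list", n_restarts)
  for (j in seq_len(n_restarts)) {
    pj <- p0
    k <- ((j - 1L) %% length(tm_shift)) + 1L
    pj["Tm_K"] <- pj["Tm_K"] + tm_shift[k]
    pj["dH"] <- pj["dH"] * dh_scale[k]
    best <- list(par = pj, value = melt_ssr(pj, tt, a, curve$Ct))
    for (cycle in 1:8) {
      o <- stats::optim(best$par, melt_ssr, tt = tt, a = a, Ct = curve$Ct,
                        method = "Nelder-Mead",
                        control = list(maxit = max_eval, reltol = 1e-13,
                                       parscale = scale))
      if (best$value - o$value < 1e-14) { best <- o; break }
      best <- o
    }
    runs[[j]] <- best
  }
  ssrs <- vapply(runs, `[[`, numeric(1), "value")
  tms <- vapply(runs, function(r) r$par[1], numeric(1)) - 273.15
  dtm_qc <- derivative_tm(curve)
  ord <- order(ssrs, abs(tms - dtm_qc))
  win <- runs[[ord[1]]]
  near <- ssrs <= min(ssrs) * (1 + 1e-4) + 1e-12
  converged <- (max(tms[near]) - min(tms[near])) <= 0.5
  p <- win$par
  dS <- ds_from_tm(p[2], p[1], curve$Ct)
  params <- thermo_params(p[2], dS)
  baselines <- baseline_pair(p[3], p[4], p[5], p[6])
  tm <- unname(p[1] - 273.15)
  fitted <- model_absorbance(params, baselines, curve$Ct, tt)
  res <- structure(list(params = params, baselines = baselines, tm = tm,
                        hypochromicity = NA_real_, ssr = unname(win$value),
                        converged = converged, n_restarts_used = n_restarts,
                        derivative_tm = dtm_qc,
                        fitted = fitted, residuals = a - fitted,
                        curve = curve),
                   class = "melt_fit")
  res$hypochromicity <- hypochromicity(res)
  res
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("Two-state melting fit ('%s')\n", x$curve$label))
  cat(sprintf("  Tm = %.2f C (derivative midpoint %.2f C)\n", x$tm, x$derivative_tm))
  cat(sprintf("  dH = %.1f kcal/mol, dS = %.0f cal/(mol*K)\n",
              x$params$dH / 1000, x$params$dS))
  cat(sprintf("  hypochromicity = %.2f%%, SSR = %.3g AU^2, converged: %s\n",
              x$hypochromicity, x$ssr, x$converged))
  invisible(x)
}

#' Hypochromic effect of duplex formation
#'
#' Percent absorbance lost on going from the single-strand to the duplex
#' state, both baselines extrapolated to the melting temperature:
#' h = 100 * (A_ss(Tm) - A_ds(Tm)) / A_ss(Tm).
#'
#' @param x a `"melt_fit"` or a [baseline_pair()].
#' @param tm evaluation temperature in Celsius (required for a bare
#'   baseline pair; taken from the fit otherwise).
#' @param ... unused.
#' @return Hypochromicity in percent.
#' @export
hypochromicity <- function(x, ...) UseMethod("hypochromicity")

#' @rdname hypochromicity
#' @export
hypochromicity.melt_fit <- function(x, ...) {
  hypochromicity(x$baselines, tm = x$tm)
}

#' @rdname hypochromicity
#' @export
hypochromicity.baseline_pair <- function(x, tm, ...) {
  b <- baseline_at(x, tm)
  if (b$ss <= 0)
    stop("single-strand baseline extrapolates to a non-positive absorbance at Tm")
  100 * (b$ss - b$ds) / b$ss
}
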