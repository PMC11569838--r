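#' A melting-temperature concentration series
#'
#' Tm measurements of one duplex at several total strand concentrations, the
#' input to [fit_vant_hoff()]. Fewer than 3 distinct concentrations, or a
#' concentration span under a factor of 8, leaves the regression with little
#' leverage and triggers a warning (an error, for < 3, at fit time).
#'
#' @param Ct total single-strand concentrations, mol/L.
#' @param Tm melting temperatures, Celsius.
#' @param tm_err optional one-sigma Tm uncertainties, Celsius.
#' @return Object of class `"concentration_series"`.
#' @export
concentration_series <- function(Ct, Tm, tm_err = NULL) {
  if (length(Ct) != length(Tm))
    stop("Ct and Tm differ in length")
  if (any(Ct <= 0)) stop("all concentrations must be positive")
  if (!is.null(tm_err) && length(tm_err) != length(Tm))
    stop("tm_err differs in length from Tm")
  nd <- length(unique(Ct))
  if (nd < 3L)
    warning("fewer than 3 distinct concentrations: van 't Hoff fit will be rejected")
  else if (max(Ct) / min(Ct) < 8)
    warning("concentration span below a factor of 8: low leverage on the slope")
  structure(list(Ct = as.numeric(Ct), Tm = as.numeric(Tm),
                 tm_err = if (is.null(tm_err)) NULL else as.numeric(tm_err)),
            class = "concentration_series")
}

#' Van 't Hoff fit of a Tm concentration series
#'
#' Least-squares regression of the reciprocal absolute melting temperature on
#' ln(Ct/4); under the two-state bimolecular model
#' 1/Tm = dS/dH + (R/dH) * ln(Ct/4),
#' so dH = R/slope and dS = intercept * dH. Uncertainties come from
#' first-order propagation of the slope/intercept covariance; the strong
#' anticorrelation between slope and intercept is what keeps the dG(37 C)
#' uncertainty far smaller than the individual dH and dS uncertainties.
#'
#' @param series a [concentration_series()].
#' @param weighting `"none"` (ordinary least squares, the default) or
#'   `"inverse_variance"` (weights 1/var(1/Tm) derived from `tm_err`).
#' @return Object of class `"vant_hoff_fit"` with elements `params`
#'   ([thermo_params()] carrying `dH_err`, `dS_err`), `slope`, `intercept`,
#'   `coef_vcov`, `r_squared`, `dG37`, `dG37_err` (kcal/mol), `n`, `series`.
#' @export
fit_vant_hoff <- function(series, weighting = c("none", "inverse_variance")) {
  stopifnot(inherits(series, "concentration_series"))
  weighting <- match.arg(weighting)
  if (length(unique(series$Ct)) < 3L)
    stop("van 't Hoff regression needs at least 3 distinct concentrations")
  TmK <- series$Tm + 273.15
  x <- log(series$Ct / 4)
  y <- 1 / TmK
  w <- NULL
  if (weighting == "inverse_variance") {
    if (is.null(series$tm_err))
      stop("inverse-variance weighting requires tm_err")
    w <- TmK^4 / pmax(series$tm_err, 1e-6)^2    # var(1/Tm) = var(Tm)/Tm^4
  }
  fit <- stats::lm(y ~ x, weights = w)
  co <- stats::coef(fit)
  ## zero-residual (noiseless) series are a designed use: silence
  ## summary.lm's perfect-fit warning here and below
  V <- suppressWarnings(stats::vcov(fit))
  s <- unname(co[2]); i <- unname(co[1])
  if (s >= 0)
    stop("sign anomaly: 1/Tm increases with ln(Ct/4), inconsistent with dH < 0")
  dH <- RGAS / s
  dS <- i * dH
  ## delta-method gradients wrt (intercept, slope)
  g_dH <- c(0, -RGAS / s^2)
  g_dS <- c(RGAS / s, -i * RGAS / s^2)
  T37 <- 310.15
  dG37 <- dH - T37 * dS                       # cal/mol
  g_dG <- g_dH - T37 * g_dS
  dH_err <- sqrt(drop(t(g_dH) %*% V %*% g_dH))
  dS_err <- sqrt(drop(t(g_dS) %*% V %*% g_dS))
  dG_err <- sqrt(drop(t(g_dG) %*% V %*% g_dG))
  structure(list(params = thermo_params(dH, dS, dH_err, dS_err),
                 slope = s, intercept = i, coef_vcov = V,
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 dG37 = dG37 / 1000, dG37_err = dG_err / 1000,
                 n = length(x), series = series),
            class = "vant_hoff_fit")
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat(sprintf("Van 't Hoff fit (n = %d, R^2 = %.5f)\n", x$n, x$r_squared))
  cat(sprintf("  dH = %.1f +/- %.1f kcal/mol\n",
              x$params$dH / 1000, x$params$dH_err / 1000))
  cat(sprintf("  dS = %.0f +/- %.0f cal/(mol*K)\n", x$params$dS, x$params$dS_err))
  cat(sprintf("  dG(37 C) = %.2f +/- %.2f kcal/mol\n", x$dG37, x$dG37_err))
  invisible(x)
}

#' Tabulate a fitted duplex at a reporting concentration
#'
#' One summary row in the conventional reporting units: entropy in
#' cal/(mol*K), enthalpy and dG(37 C) in kcal/mol, and the melting
#' temperature predicted at `Ct_report` (default 20 uM total strands), each
#' with its propagated one-sigma uncertainty.
#'
#' @param fit a `"vant_hoff_fit"`.
#' @param Ct_report reporting concentration, mol/L.
#' @param label row label.
#' @return A one-row `data.frame`.
#' @export
summarize_duplex <- function(fit, Ct_report = 20e-6, label = "") {
  stopifnot(inherits(fit, "vant_hoff_fit"))
  Ct_report <- check_ct(Ct_report)
  tm <- predict_tm(fit$params, Ct_report)
  ## 1/Tm = intercept + slope * ln(Ct/4); propagate to Tm
  xr <- log(Ct_report / 4)
  g <- c(1, xr)
  var_inv <- drop(t(g) %*% fit$coef_vcov %*% g)
  tm_err <- (tm + 273.15)^2 * sqrt(var_inv)
  data.frame(label = label,
             dS = fit$params$dS, dS_err = fit$params$dS_err,
             dH_kcal = fit$params$dH / 1000, dH_err_kcal = fit$params$dH_err / 1000,
             dG37_kcal = fit$dG37, dG37_err_kcal = fit$dG37_err,
             Tm_C = tm, Tm_err_C = tm_err,
             Ct_report_uM = Ct_report * 1e6,
             r_squared = fit$r_squared,
             stringsAsFactors = FALSE)
}

#' Internal-consistency check of tabulated duplex thermodynamics
#'
#' Published melting tables list dS, dH, dG(37 C) and Tm side by side even
#' though the last two are functions of the first two; transcription or
#' rounding slips make rows self-inconsistent. This check recomputes
#' dG37 = dH - 310.15*dS and the closed-form Tm at the reporting
#' concentration and flags rows whose printed values deviate beyond what
#' rounding of the printed dH and dS can explain.
#'
#' The default tolerances follow from propagating half-unit rounding of the
#' printed parameters (dH to 0.1 kcal/mol, dS to 1 cal/(mol*K)):
#' about 0.2 kcal/mol on dG37 and 0.7 C on Tm, padded to 0.3 and 1.0.
#'
#' @param table a `data.frame` with columns `label`, `dS` (cal/(mol*K)),
#'   `dH_kcal`, `dG37_kcal`, `Tm_C` (printed values).
#' @param Ct concentration at which the printed Tm applies, mol/L.
#' @param tol_dG,tol_tm consistency tolerances, kcal/mol and Celsius.
#' @return The table with recomputed `dG37_calc`, `Tm_calc` columns, the
#'   deviations, and logical flags `dG_consistent`, `tm_consistent`,
#'   `consistent`.
#' @export
check_thermo_consistency <- function(table, Ct = 20e-6,
                                     tol_dG = 0.3, tol_tm = 1.0) {
  need <- c("label", "dS", "dH_kcal", "dG37_kcal", "Tm_C")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  out <- table
  out$dG37_calc <- NA_real_
  out$Tm_calc <- NA_real_
  for (k in seq_len(nrow(table))) {
    p <- thermo_params(table$dH_kcal[k] * 1000, table$dS[k])
    out$dG37_calc[k] <- delta_g(p, 310.15)
    out$Tm_calc[k] <- predict_tm(p, Ct)
  }
  out$dG_dev <- out$dG37_calc - out$dG37_kcal
  out$tm_dev <- out$Tm_calc - out$Tm_C
  out$dG_consistent <- abs(out$dG_dev) <= tol_dG
  out$tm_consistent <- abs(out$tm_dev) <= tol_tm
  out$consistent <- out$dG_consistent & out$tm_consistent
  out
}
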