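## Gas constant in calorie units; the thermodynamic bookkeeping of this
## package is done in cal/mol throughout, with kcal only at reporting
## boundaries (the convention of the printed tables this pipeline mirrors).
RGAS <- 1.9872

#' Thermodynamic parameters of duplex formation
#'
#' Container for the van 't Hoff enthalpy and entropy of bimolecular duplex
#' formation (strands + strands -> duplex). Both must be negative: duplex
#' formation of short oligonucleotides is enthalpy-driven with an entropic
#' penalty. Internal units are cal/mol and cal/(mol*K); use
#' [delta_g()] for kcal-scale reporting.
#'
#' @param dH enthalpy change of duplex formation, cal/mol (negative).
#' @param dS entropy change, cal/(mol*K) (negative).
#' @param dH_err,dS_err optional one-sigma uncertainties, same units.
#' @return An object of class `"thermo_params"`.
#' @examples
#' thermo_params(dH = -119400, dS = -339)
#' @export
thermo_params <- function(dH, dS, dH_err = NA_real_, dS_err = NA_real_) {
  stopifnot(is.numeric(dH), length(dH) == 1L, is.finite(dH),
            is.numeric(dS), length(dS) == 1L, is.finite(dS))
  if (dH >= 0 || dS >= 0)
    stop("duplex formation requires dH < 0 and dS < 0 ",
         "(got dH = ", dH, " cal/mol, dS = ", dS, " cal/(mol*K))")
  structure(list(dH = as.numeric(dH), dS = as.numeric(dS),
                 dH_err = as.numeric(dH_err), dS_err = as.numeric(dS_err)),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf("Duplex formation thermodynamics\n  dH = %.1f kcal/mol", x$dH / 1000))
  if (is.finite(x$dH_err)) cat(sprintf(" +/- %.1f", x$dH_err / 1000))
  cat(sprintf("\n  dS = %.0f cal/(mol*K)", x$dS))
  if (is.finite(x$dS_err)) cat(sprintf(" +/- %.0f", x$dS_err))
  cat(sprintf("\n  dG(37 C) = %.2f kcal/mol\n", delta_g(x, 310.15)))
  invisible(x)
}

check_temperature_K <- function(T_K) {
  if (!is.numeric(T_K) || any(!is.finite(T_K)) || any(T_K <= 0))
    stop("absolute temperature must be positive and finite (Kelvin)")
  as.numeric(T_K)
}

check_ct <- function(Ct) {
  if (!is.numeric(Ct) || length(Ct) != 1L || !is.finite(Ct) || Ct <= 0)
    stop("total strand concentration Ct must be a single positive number (mol/L)")
  as.numeric(Ct)
}

#' Two-state equilibrium constant of duplex formation
#'
#' K(T) = exp(-(dH - T*dS) / (R*T)) for the association A + B <-> AB.
#' log K is affine in 1/T (van 't Hoff behaviour).
#'
#' @param params a [thermo_params()] object.
#' @param T_K absolute temperature(s), Kelvin.
#' @return Equilibrium constant(s), 1/M scale fixed by the standard state.
#' @export
equilibrium_constant <- function(params, T_K) {
  stopifnot(inherits(params, "thermo_params"))
  T_K <- check_temperature_K(T_K)
  exp(-(params$dH - T_K * params$dS) / (RGAS * T_K))
}

#' Free energy of duplex formation
#'
#' dG(T) = dH - T*dS, returned in kcal/mol (the reporting scale).
#'
#' @inheritParams equilibrium_constant
#' @return Free energy in kcal/mol.
#' @examples
#' p <- thermo_params(-119.4e3, -339)
#' delta_g(p, 310.15)   # about -14.3 kcal/mol at 37 C
#' @export
delta_g <- function(params, T_K) {
  stopifnot(inherits(params, "thermo_params"))
  T_K <- check_temperature_K(T_K)
  (params$dH - T_K * params$dS) / 1000
}

#' Fraction of strands in duplex form
#'
#' Solves the mass-action relation of the two-state bimolecular model for
#' non-self-complementary strands mixed equimolar,
#' K(T) * Ct * (1 - theta)^2 = 2 * theta,
#' where `Ct` is the TOTAL single-strand concentration (both strands summed).
#' The unique root in \[0, 1\] has the closed form
#' theta = a / (a + 1 + sqrt(2a + 1)) with a = K(T) * Ct, which is used here
#' (numerically stable for all a >= 0).
#'
#' @inheritParams equilibrium_constant
#' @param Ct total single-strand concentration, mol/L.
#' @return theta in \[0, 1\], vectorized over `T_K`.
#' @export
fraction_duplex <- function(params, Ct, T_K) {
  Ct <- check_ct(Ct)
  a <- equilibrium_constant(params, T_K) * Ct
  theta <- a / (a + 1 + sqrt(2 * a + 1))
  theta[!is.finite(a)] <- 1   # K overflow: fully duplexed limit
  theta
}

#' Concentration-dependent melting temperature
#'
#' Closed form of the two-state model for non-self-complementary duplexes:
#' at Tm half the strands are paired, which forces K(Tm) = 4/Ct and hence
#' Tm = dH / (dS + R * ln(Ct/4)). `Ct` is the total single-strand
#' concentration; the `/4` molecularity factor belongs to that convention.
#'
#' @inheritParams fraction_duplex
#' @return Melting temperature in degrees Celsius.
#' @examples
#' predict_tm(thermo_params(-119.4e3, -339), 20e-6)  # about 55.5 C
#' @export
predict_tm <- function(params, Ct) {
  stopifnot(inherits(params, "thermo_params"))
  Ct <- check_ct(Ct)
  denom <- params$dS + RGAS * log(Ct / 4)
  if (denom >= 0 || !(params$dH / denom > 0))
    stop("dS + R*ln(Ct/4) must share the sign of dH; ",
         "these parameters give no physical melting temperature")
  params$dH / denom - 273.15
}
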