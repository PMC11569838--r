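# Shared fixtures: the published-style thermodynamic table (label, dS in
# cal/(mol*K), dH/dG37 in kcal/mol, Tm at 20 uM in C) and small helpers.

table2 <- data.frame(
  label = c("NM-DNA", "nFluL-DNA", "nFluS-DNA"),
  dS = c(-382, -339, -295),
  dH_kcal = c(-140.0, -119.4, -103.5),
  dG37_kcal = c(-20.2, -14.3, -12.0),
  Tm_C = c(67.6, 55.6, 51.5),
  stringsAsFactors = FALSE
)

p_nfluL <- thermo_params(-119.4e3, -339)
p_nfluS <- thermo_params(-103.5e3, -295)
p_nm <- thermo_params(-140.0e3, -382)

# Independent mass-action oracle: bisection on K*Ct*(1-theta)^2 = 2*theta.
theta_bisect <- function(params, Ct, T_K, iter = 200L) {
  K <- exp(-(params$dH - T_K * params$dS) / (1.9872 * T_K))
  a <- K * Ct
  if (!is.finite(a)) return(1)
  f <- function(th) a * (1 - th)^2 - 2 * th
  lo <- 0; hi <- 1
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Custom-scenario config with thermodynamics set from (dH cal/mol, Tm C at Ct).
cfg_from_tm <- function(dH, tm_C, Ct = 20e-6, seed = 1L, ...) {
  dS <- dH / (tm_C + 273.15) - 1.9872 * log(Ct / 4)
  generator_config("custom", seed = seed, params = thermo_params(dH, dS), ...)
}
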