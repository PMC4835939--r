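#' Elementary rate laws of the hydrolysis/SSCF model
#'
#' The kinetic model is built from a small set of algebraic rate laws.
#' These are exported individually so that mass balances can be assembled,
#' inspected and tested term by term.
#'
#' * `equilibrium_adsorption()` — the adsorption capacity
#'   `E_eq = E_load * S0 / S`: as solids are consumed, the enzyme
#'   inventory redistributes over less residual material.
#' * `adsorption_rate()` — second-order approach to equilibrium,
#'   `dE_ad/dt = k_ad * (E_eq - E_ad)^2`, one-sided so adsorption never
#'   overshoots the capacity.
#' * `hydrolysis_rate()` — glucose-inhibited cellulose depolymerisation,
#'   `r_C = k * E_ad * C / (1 + G/K_G)`.
#' * `xylan_rate()` — xylan release proportional to the cellulose rate,
#'   `r_Xn = gamma * r_C`.
#' * `glucose_production_rate()` — ethanol inhibition of hydrolysis during
#'   SSCF, `r_G,prod = r_hydrolysis / (1 + EtOH/K_iEtOH)`.
#' * `glucose_uptake_rate()` — Monod uptake by the yeast,
#'   `r_G,cons = q_G * G/(K + G) * X`.
#' * `ethanol_production_rate()` — constant yield on consumed glucose,
#'   `r_EtOH = Y_EtOH * r_G,cons`.
#' * `cell_death_rate()` — ethanol-accelerated first-order death,
#'   `r_d = alpha * exp(beta*EtOH) * X`.
#'
#' @param enzyme_load_ref enzyme dose at the most recent (re)load, FPU per
#'   g solids.
#' @param solids_ref_mass total solids at the most recent (re)load, g.
#' @param wis_mass residual water-insoluble solids, g (> 0).
#' @param e_ad adsorbed enzyme, FPU per g residual WIS.
#' @param e_eq equilibrium adsorption capacity, FPU per g residual WIS.
#' @param k_ad adsorption rate constant, g solid FPU^-1 h^-1.
#' @param cellulose_conc residual cellulose concentration, g per kg broth.
#' @param glucose glucose concentration, g per kg broth.
#' @param k hydrolysis rate constant, g cellulose FPU^-1 h^-1.
#' @param K_G glucose inhibition constant, g per kg.
#' @param cellulose_rate cellulose hydrolysis rate, g kg^-1 h^-1.
#' @param gamma xylan/cellulose proportionality (dimensionless).
#' @param xylan_conc residual xylan concentration, g per kg broth; the
#'   xylan rate is smoothly clamped to zero as it is exhausted.
#' @param hydrolysis_rate cellulose hydrolysis rate, g kg^-1 h^-1.
#' @param ethanol ethanol concentration, g per kg broth.
#' @param K_iEtOH ethanol inhibition constant, g per kg.
#' @param viable_cells viable cell concentration, g per kg broth.
#' @param q_G maximum specific glucose uptake rate, g g^-1 h^-1.
#' @param K glucose saturation constant, g per kg.
#' @param uptake_rate glucose uptake rate, g kg^-1 h^-1.
#' @param Y_EtOH ethanol yield on glucose, g/g (<= 0.51).
#' @param alpha pre-exponential death factor, h^-1.
#' @param beta exponential death factor, kg g^-1.
#'
#' @return The rate (or capacity), a numeric scalar or vector.
#' @examples
#' e_eq <- equilibrium_adsorption(10, 100, 50)   # 20 FPU/g
#' adsorption_rate(0, 10, k_ad = 0.27)           # 27 FPU/(g h)
#' hydrolysis_rate(10, 100, 0, k = 0.016, K_G = 6.13)
#' @name rate_laws
NULL

#' @rdname rate_laws
#' @export
equilibrium_adsorption <- function(enzyme_load_ref, solids_ref_mass, wis_mass) {
  stopifnot(solids_ref_mass > 0)
  if (any(wis_mass <= 0))
    stop("degenerate state: residual WIS is zero, no adsorption capacity",
         call. = FALSE)
  enzyme_load_ref * solids_ref_mass / wis_mass
}

#' @rdname rate_laws
#' @export
adsorption_rate <- function(e_ad, e_eq, k_ad) {
  if (k_ad < 0) stop("k_ad must be >= 0", call. = FALSE)
  k_ad * pmax(e_eq - e_ad, 0)^2
}

#' @rdname rate_laws
#' @export
hydrolysis_rate <- function(e_ad, cellulose_conc, glucose, k, K_G) {
  if (k < 0 || K_G <= 0) stop("invalid rate constants", call. = FALSE)
  k * pmax(e_ad, 0) * pmax(cellulose_conc, 0) / (1 + pmax(glucose, 0) / K_G)
}

#' @rdname rate_laws
#' @export
xylan_rate <- function(cellulose_rate, gamma, xylan_conc = Inf) {
  r <- gamma * pmax(cellulose_rate, 0)
  # smooth exhaustion clamp (same form as the compiled model)
  xc <- pmax(xylan_conc, 0)
  r * ifelse(is.finite(xc), xc / (xc + 1e-6), 1)
}

#' @rdname rate_laws
#' @export
glucose_production_rate <- function(hydrolysis_rate, ethanol, K_iEtOH) {
  if (K_iEtOH <= 0) stop("K_iEtOH must be > 0", call. = FALSE)
  pmax(hydrolysis_rate, 0) / (1 + pmax(ethanol, 0) / K_iEtOH)
}

#' @rdname rate_laws
#' @export
glucose_uptake_rate <- function(glucose, viable_cells, q_G, K) {
  if (q_G < 0 || K <= 0) stop("invalid uptake constants", call. = FALSE)
  g <- pmax(glucose, 0)
  q_G * g / (K + g) * pmax(viable_cells, 0)
}

#' @rdname rate_laws
#' @export
ethanol_production_rate <- function(uptake_rate, Y_EtOH) {
  if (Y_EtOH > ETOH_MAX_YIELD)
    stop("Y_EtOH exceeds the stoichiometric maximum of 0.51 g/g",
         call. = FALSE)
  Y_EtOH * pmax(uptake_rate, 0)
}

#' @rdname rate_laws
#' @export
cell_death_rate <- function(ethanol, viable_cells, alpha, beta) {
  if (alpha < 0 || beta < 0) stop("invalid death constants", call. = FALSE)
  alpha * exp(beta * pmax(ethanol, 0)) * pmax(viable_cells, 0)
}
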