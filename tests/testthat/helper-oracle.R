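# Shared fixtures and an independent fixed-step RK4 integrator used as a
# brute-force oracle for the adaptive simulation path. The right-hand side
# here is a standalone arithmetic transcription of the model, deliberately
# not calling the package's derivative code.

fx <- sscf_fixtures()
wheat <- fx$lab_composition
table1 <- fx$params
TRUTH <- c(k_ad = 0.27, k = 0.016, K_G = 6.13, gamma = 0.028)

batch_dataset <- function(dose, sigma = 0, seed = 1L, duration = 96,
                          sampling = 6, initial_wis = 0.10,
                          params = table1, mode = "hydrolysis_only") {
  sc <- fit_scenario(initial_wis, dose, wheat, duration = duration,
                     mode = mode)
  generate_timecourse(sc, params,
                      noise_model("gaussian_relative", sigma, seed),
                      sampling_interval = sampling)
}

oracle_rhs <- function(y, p, w, e_load, s0, sscf) {
  S <- max(y[1], 1e-12); C <- max(y[2], 0); Xn <- max(y[3], 0)
  Ead <- max(y[4], 0); G <- max(y[5], 0); EtOH <- max(y[7], 0)
  X <- max(y[8], 0)
  de <- e_load * s0 / S - Ead
  dEad <- p[["k_ad"]] * (if (de > 0) de^2 else 0)
  rh <- p[["k"]] * Ead * (C / w * 1000) / (1 + G / p[["K_G"]])
  if (sscf) rh <- rh / (1 + EtOH / p[["K_iEtOH"]])
  xnc <- Xn / w * 1000
  rx <- p[["gamma"]] * rh * xnc / (xnc + 1e-6)
  rc <- if (sscf) p[["q_G"]] * G / (p[["K"]] + G) * X else 0
  rd <- if (sscf) p[["alpha"]] * exp(p[["beta"]] * EtOH) * X else 0
  c(-(rh + rx) * w / 1000, -rh * w / 1000, -rx * w / 1000, dEad,
    1.111 * rh - rc, 1.136 * rx, p[["Y_EtOH"]] * rc, -rd)
}

# classic fixed-step RK4 over a constant-mass span; returns the final
# state vector named like the simulation columns
rk4_final <- function(state, params, duration, mode, h = 0.001) {
  y <- c(state$wis_mass, state$cellulose_mass, state$xylan_mass,
         state$e_ad, state$glucose, state$xylose, state$ethanol,
         state$viable_cells)
  p <- unclass(params)
  w <- state$total_mass
  e_load <- state$enzyme_load_ref
  s0 <- state$solids_ref_mass
  sscf <- identical(mode, "sscf")
  n <- round(duration / h)
  for (i in seq_len(n)) {
    k1 <- oracle_rhs(y, p, w, e_load, s0, sscf)
    k2 <- oracle_rhs(y + h / 2 * k1, p, w, e_load, s0, sscf)
    k3 <- oracle_rhs(y + h / 2 * k2, p, w, e_load, s0, sscf)
    k4 <- oracle_rhs(y + h * k3, p, w, e_load, s0, sscf)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  names(y) <- c("wis_mass", "cellulose_mass", "xylan_mass", "e_ad",
                "glucose", "xylose", "ethanol", "viable_cells")
  y
}
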