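#' Reactor state snapshot
#'
#' A mass-basis snapshot of the broth. Masses are in g, dissolved species
#' in g per kg broth (numerically interchangeable with g/L at the assumed
#' broth density of 1 kg/L). The reference fields `solids_ref_mass`,
#' `cellulose_ref_mass` and `enzyme_load_ref` record the totals at the most
#' recent (re)load; they anchor the adsorption capacity and the
#' conversion-since-last-feed trigger.
#'
#' @param time process time, h.
#' @param total_mass total broth mass, g.
#' @param wis_mass residual water-insoluble solids, g.
#' @param cellulose_mass residual cellulose, g.
#' @param xylan_mass residual xylan, g.
#' @param enzyme_total enzyme in the reactor, FPU.
#' @param solids_ref_mass total solids at the most recent (re)load, g;
#'   defaults to `wis_mass`.
#' @param cellulose_ref_mass total cellulose right after the most recent
#'   feed, g; defaults to `cellulose_mass`.
#' @param enzyme_load_ref enzyme per g solids at the most recent (re)load,
#'   FPU/g; defaults to `enzyme_total / solids_ref_mass`.
#' @param e_ad adsorbed enzyme, FPU per g residual WIS.
#' @param glucose,xylose,ethanol,viable_cells dissolved/suspended species,
#'   g per kg broth.
#'
#' @return An object of class `"reactor_state"` (a named list).
#' @seealso [initial_state()] for building the state of a freshly charged
#'   reactor from a feedstock composition and dosing rules.
#' @export
reactor_state <- function(time = 0, total_mass, wis_mass, cellulose_mass,
                          xylan_mass = 0, enzyme_total = 0,
                          solids_ref_mass = wis_mass,
                          cellulose_ref_mass = cellulose_mass,
                          enzyme_load_ref = if (solids_ref_mass > 0)
                            enzyme_total / solids_ref_mass else 0,
                          e_ad = 0, glucose = 0, xylose = 0, ethanol = 0,
                          viable_cells = 0) {
  s <- list(time = time, total_mass = total_mass, wis_mass = wis_mass,
            cellulose_mass = cellulose_mass, xylan_mass = xylan_mass,
            enzyme_total = enzyme_total, solids_ref_mass = solids_ref_mass,
            cellulose_ref_mass = cellulose_ref_mass,
            enzyme_load_ref = enzyme_load_ref, e_ad = e_ad,
            glucose = glucose, xylose = xylose, ethanol = ethanol,
            viable_cells = viable_cells)
  s <- lapply(s, function(v) unname(as.numeric(v)))
  validate_state(s)
  structure(s, class = "reactor_state")
}

validate_state <- function(s) {
  num <- unlist(s)
  if (!all(is.finite(num)))
    stop("reactor state contains non-finite values", call. = FALSE)
  if (any(num[c("total_mass", "wis_mass", "cellulose_mass", "xylan_mass",
                "enzyme_total", "e_ad", "glucose", "xylose", "ethanol",
                "viable_cells")] < -1e-9))
    stop("reactor state contains negative masses or concentrations",
         call. = FALSE)
  if (s$cellulose_mass + s$xylan_mass > s$wis_mass * (1 + 1e-9) + 1e-9)
    stop("cellulose + xylan exceed total WIS", call. = FALSE)
  invisible(s)
}

#' @export
print.reactor_state <- function(x, ...) {
  cat(sprintf("Reactor state at t = %.2f h\n", x$time))
  cat(sprintf("  broth %.1f g; WIS %.2f g (%.2f %% w/w); cellulose %.2f g; xylan %.2f g\n",
              x$total_mass, x$wis_mass, 100 * x$wis_mass / x$total_mass,
              x$cellulose_mass, x$xylan_mass))
  cat(sprintf("  enzyme %.0f FPU (E_ad %.2f FPU/g); glucose %.2f, xylose %.2f, ethanol %.2f, cells %.3f g/kg\n",
              x$enzyme_total, x$e_ad, x$glucose, x$xylose, x$ethanol,
              x$viable_cells))
  invisible(x)
}

#' Build the state of a freshly charged reactor
#'
#' Assembles a [reactor_state()] for a reactor loaded to a target WIS
#' fraction from wet solid-fraction material plus dilution water. The
#' liquid carried with the solids contributes its sugars (unless the
#' composition says to treat it as water); enzyme is dosed per g WIS (or
#' given as an absolute amount) with adsorbed enzyme starting at zero;
#' cells are dosed per g WIS.
#'
#' @param total_mass total broth mass to charge, g.
#' @param wis_frac initial WIS fraction, w/w in (0, 1).
#' @param composition a [feedstock_composition()].
#' @param enzyme_dosage enzyme dose, FPU per g WIS charged.
#' @param enzyme_total absolute enzyme charge, FPU; overrides
#'   `enzyme_dosage` when given.
#' @param cell_dosage cell dose, g dry weight per g WIS charged.
#'
#' @return A `"reactor_state"`.
#' @examples
#' wheat <- sscf_fixtures()$lab_composition
#' s0 <- initial_state(1000, 0.10, wheat, enzyme_dosage = 10)
#' @export
initial_state <- function(total_mass, wis_frac, composition,
                          enzyme_dosage = 0, enzyme_total = NULL,
                          cell_dosage = 0) {
  stopifnot(total_mass > 0, wis_frac > 0, wis_frac < 1)
  wis <- wis_frac * total_mass
  wet <- wis / composition$wis_of_solid_feed
  if (wet > total_mass)
    stop("target WIS fraction exceeds the WIS content of the feed material",
         call. = FALSE)
  carried <- wet - wis                       # retained liquor, g
  etot <- if (is.null(enzyme_total)) enzyme_dosage * wis else enzyme_total
  reactor_state(
    time = 0, total_mass = total_mass, wis_mass = wis,
    cellulose_mass = composition$glucan_frac * wis,
    xylan_mass = composition$xylan_frac * wis,
    enzyme_total = etot, e_ad = 0,
    glucose = liquor_conc(composition, "glucose") * carried / total_mass,
    xylose = liquor_conc(composition, "xylose") * carried / total_mass,
    ethanol = 0,
    viable_cells = cell_dosage * wis / (total_mass / 1000))
}

# pack/unpack between reactor_state and the ODE state vector
state_to_y <- function(s) {
  c(S = s$wis_mass, C = s$cellulose_mass, Xn = s$xylan_mass, Ead = s$e_ad,
    G = s$glucose, Xl = s$xylose, EtOH = s$ethanol, X = s$viable_cells)
}

y_to_state <- function(y, template, time) {
  s <- template
  s$time <- time
  s$wis_mass <- max(unname(y["S"]), 0)
  s$cellulose_mass <- max(unname(y["C"]), 0)
  s$xylan_mass <- max(unname(y["Xn"]), 0)
  s$e_ad <- max(unname(y["Ead"]), 0)
  s$glucose <- max(unname(y["G"]), 0)
  s$xylose <- max(unname(y["Xl"]), 0)
  s$ethanol <- max(unname(y["EtOH"]), 0)
  s$viable_cells <- max(unname(y["X"]), 0)
  s
}
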