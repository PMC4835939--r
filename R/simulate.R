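#' Time derivative of the reactor state
#'
#' Assembles the mass balances from the elementary rate laws (see
#' [rate_laws]) for a given state. This is the reference R formulation of
#' the model; [sscf_simulate()] integrates an equivalent compiled version.
#' Between feed events the total broth mass is constant, so dissolved
#' species evolve as concentrations (g kg^-1 h^-1) and solid pools as
#' masses (g h^-1).
#'
#' In `"sscf"` mode the cellulose depolymerisation itself is additionally
#' inhibited by ethanol, glucose is consumed by Monod uptake, ethanol is
#' produced at constant yield, and viable cells die at an
#' ethanol-accelerated rate. In `"hydrolysis_only"` mode those fermentation
#' terms are absent.
#'
#' @param state a [reactor_state()].
#' @param params an [sscf_params()] set.
#' @param mode `"hydrolysis_only"` or `"sscf"`.
#'
#' @return Named numeric vector of derivatives: `wis_mass`,
#'   `cellulose_mass`, `xylan_mass` (g/h), `e_ad` (FPU g^-1 h^-1),
#'   `glucose`, `xylose`, `ethanol`, `viable_cells` (g kg^-1 h^-1).
#' @export
sscf_derivatives <- function(state, params, mode = c("hydrolysis_only", "sscf")) {
  mode <- match.arg(mode)
  params <- as_sscf_params(params)
  if (!all(is.finite(unlist(state[c("wis_mass", "cellulose_mass",
                                    "glucose", "ethanol")]))))
    stop("cannot evaluate derivatives: state contains non-finite values",
         call. = FALSE)
  w <- state$total_mass
  e_eq <- equilibrium_adsorption(state$enzyme_load_ref, state$solids_ref_mass,
                                 max(state$wis_mass, 1e-12))
  d_ead <- adsorption_rate(state$e_ad, e_eq, params["k_ad"])
  cc <- max(state$cellulose_mass, 0) / w * 1000
  r_h <- hydrolysis_rate(state$e_ad, cc, state$glucose,
                         params["k"], params["K_G"])
  if (mode == "sscf")
    r_h <- glucose_production_rate(r_h, state$ethanol, params["K_iEtOH"])
  xnc <- max(state$xylan_mass, 0) / w * 1000
  r_x <- xylan_rate(r_h, params["gamma"], xnc)
  r_cons <- if (mode == "sscf")
    glucose_uptake_rate(state$glucose, state$viable_cells,
                        params["q_G"], params["K"]) else 0
  r_d <- if (mode == "sscf")
    cell_death_rate(state$ethanol, state$viable_cells,
                    params["alpha"], params["beta"]) else 0
  c(wis_mass = unname(-(r_h + r_x) * w / 1000),
    cellulose_mass = unname(-r_h * w / 1000),
    xylan_mass = unname(-r_x * w / 1000),
    e_ad = unname(d_ead),
    glucose = unname(ANHYDRO_GLUCAN * r_h - r_cons),
    xylose = unname(ANHYDRO_XYLAN * r_x),
    ethanol = unname(ethanol_production_rate(r_cons, params["Y_EtOH"])),
    viable_cells = unname(-r_d))
}

# integrate one constant-mass span with the compiled model
integrate_span <- function(state, params, times, mode,
                           rtol = 1e-8, atol = 1e-10) {
  y0 <- state_to_y(state)
  p <- c(unclass(params),
         E_load = state$enzyme_load_ref, S0 = state$solids_ref_mass,
         w = state$total_mass, sscf = as.numeric(mode == "sscf"))
  out <- deSolve::ode(y = y0, times = times, func = "sscf_derivs",
                      parms = unname(p), dllname = "sscfkin",
                      initfunc = "sscf_initmod", method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0 || any(!is.finite(out)))
    stop(sprintf("ODE integration failed in [%g, %g] h (mode %s)",
                 min(times), max(times), mode), call. = FALSE)
  out
}

TC_COLUMNS <- c("time_h", "wis_pct", "glucose_g_per_kg", "xylose_g_per_kg",
                "ethanol_g_per_kg", "viable_cells_g_per_kg",
                "e_ad_fpu_per_g", "cum_wis_added_pct", "cellulose_g",
                "xylan_g", "total_mass_g")

timecourse_row <- function(state, wis_added) {
  c(state$time,
    100 * state$wis_mass / state$total_mass,
    state$glucose, state$xylose, state$ethanol, state$viable_cells,
    state$e_ad,
    100 * wis_added / state$total_mass,
    state$cellulose_mass, state$xylan_mass, state$total_mass)
}

rows_to_timecourse <- function(rows) {
  tc <- as.data.frame(do.call(rbind, rows))
  names(tc) <- TC_COLUMNS
  rownames(tc) <- NULL
  tc
}

#' Simulate hydrolysis or SSCF
#'
#' Integrates the kinetic model from a starting [reactor_state()] over a
#' time span, optionally applying a schedule of instantaneous feed events.
#' Uses an adaptive stiff-capable integrator (lsoda, relative tolerance
#' 1e-8, absolute 1e-10) over each constant-mass span between events.
#'
#' @param state starting [reactor_state()].
#' @param params an [sscf_params()] set.
#' @param duration time to simulate, h (> 0).
#' @param mode `"hydrolysis_only"` or `"sscf"`.
#' @param sampling_interval spacing of trajectory samples, h.
#' @param sample_times explicit sample times, h (within the span);
#'   overrides `sampling_interval` when given.
#' @param events optional list of [feed_event()]s (times within the span);
#'   each is applied instantaneously via [apply_feed()].
#' @param composition a [feedstock_composition()]; required when any event
#'   adds solids.
#' @param rtol,atol integrator tolerances.
#'
#' @return An object of class `"sscf_sim"`: a list with `state` (final
#'   [reactor_state()]), `timecourse` (data frame of sampled observables:
#'   time, WIS % w/w, glucose/xylose/ethanol/viable cells in g/kg, adsorbed
#'   enzyme in FPU/g, cumulative WIS added % w/w, plus residual polymer
#'   masses), `mode`, and `wis_added` (total dry WIS charged+fed, g).
#' @examples
#' wheat <- sscf_fixtures()$lab_composition
#' s0 <- initial_state(1000, 0.10, wheat, enzyme_dosage = 10)
#' sim <- sscf_simulate(s0, sscf_params(), duration = 96)
#' tail(sim$timecourse[, 1:4], 3)
#' @export
sscf_simulate <- function(state, params, duration,
                          mode = c("hydrolysis_only", "sscf"),
                          sampling_interval = 1, sample_times = NULL,
                          events = NULL, composition = NULL,
                          rtol = 1e-8, atol = 1e-10) {
  mode <- match.arg(mode)
  params <- as_sscf_params(params)
  stopifnot(duration > 0, sampling_interval > 0)
  t0 <- state$time
  t_end <- t0 + duration
  ev_times <- if (length(events)) vapply(events, `[[`, 0, "time") else numeric()
  if (any(diff(ev_times) < 0))
    stop("feed events must be ordered in time", call. = FALSE)
  if (any(ev_times < t0 - 1e-9 | ev_times > t_end + 1e-9))
    stop("feed-event times fall outside the simulated span", call. = FALSE)

  wis_added <- state$wis_mass
  rows <- list(timecourse_row(state, wis_added))
  # apply any events scheduled exactly at the start
  i <- 1
  while (i <= length(ev_times) && ev_times[i] <= t0 + 1e-9) {
    state <- apply_feed(state, events[[i]], composition)
    wis_added <- wis_added + feed_dry_wis(events[[i]], composition)
    i <- i + 1
  }
  breaks <- sort(unique(c(t0, ev_times[ev_times > t0 + 1e-9], t_end)))
  for (j in seq_len(length(breaks) - 1)) {
    a <- breaks[j]; b <- breaks[j + 1]
    samp <- if (is.null(sample_times)) seq(t0, t_end, by = sampling_interval)
            else sample_times
    times <- sort(unique(c(a, samp[samp > a + 1e-12 & samp < b - 1e-12], b)))
    out <- integrate_span(state, params, times, mode, rtol, atol)
    keep <- out[-1, , drop = FALSE]
    w <- state$total_mass
    for (r in seq_len(nrow(keep))) {
      v <- keep[r, ]
      rows[[length(rows) + 1]] <-
        c(v[["time"]], 100 * max(v[["S"]], 0) / w, max(v[["G"]], 0),
          max(v[["Xl"]], 0), max(v[["EtOH"]], 0), max(v[["X"]], 0),
          max(v[["Ead"]], 0), 100 * wis_added / w, max(v[["C"]], 0),
          max(v[["Xn"]], 0), w)
    }
    state <- y_to_state(out[nrow(out), -1], state, b)
    while (i <= length(ev_times) && ev_times[i] <= b + 1e-9) {
      state <- apply_feed(state, events[[i]], composition)
      wis_added <- wis_added + feed_dry_wis(events[[i]], composition)
      rows[[length(rows) + 1]] <- timecourse_row(state, wis_added)
      i <- i + 1
    }
  }
  tc <- rows_to_timecourse(rows)
  structure(list(state = state, timecourse = tc, mode = mode,
                 wis_added = wis_added, params = params),
            class = "sscf_sim")
}

#' @export
print.sscf_sim <- function(x, ...) {
  tc <- x$timecourse
  cat(sprintf("SSCF simulation (%s mode), %.0f h, %d samples\n",
              x$mode, max(tc$time_h) - min(tc$time_h), nrow(tc)))
  f <- x$state
  cat(sprintf("  final: WIS %.2f %%, glucose %.2f, xylose %.2f, ethanol %.2f g/kg\n",
              100 * f$wis_mass / f$total_mass, f$glucose, f$xylose, f$ethanol))
  invisible(x)
}

#' @export
plot.sscf_sim <- function(x, which = c("glucose_g_per_kg", "xylose_g_per_kg",
                                       "ethanol_g_per_kg", "wis_pct"), ...) {
  tc <- x$timecourse
  which <- intersect(which, names(tc))
  matplot(tc$time_h, as.matrix(tc[, which, drop = FALSE]), type = "l",
          lty = 1, xlab = "time (h)", ylab = "g/kg  (WIS in % w/w)", ...)
  legend("topleft", legend = which, col = seq_along(which), lty = 1,
         bty = "n", cex = 0.8)
  invisible(x)
}
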