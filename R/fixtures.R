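#' Packaged wheat-straw fixtures
#'
#' The optimised kinetic parameter set, the compositions of the lab and
#' demo batches of pre-treated wheat straw, and the operating plans of the
#' lab- and demo-scale multi-feed SSCF runs, loaded from the YAML files
#' shipped with the package.
#'
#' @return A list:
#' \describe{
#'   \item{params}{[sscf_params()] set (optimised wheat-straw values).}
#'   \item{param_ci}{matrix of 95 % confidence bounds for the four fitted
#'     constants.}
#'   \item{lab_composition, demo_composition}{[feedstock_composition()]s.}
#'   \item{lab_schedule, demo_schedule}{operating-plan metadata: feed
#'     times, total weight, cumulative WIS loading.}
#' }
#' @examples
#' fx <- sscf_fixtures()
#' fx$params["K_G"]
#' fx$lab_composition$glucan_frac
#' @export
sscf_fixtures <- function() {
  pfile <- system.file("extdata", "wheat_straw_params.yaml",
                       package = "sscfkin", mustWork = TRUE)
  cfile <- system.file("extdata", "wheat_straw_compositions.yaml",
                       package = "sscfkin", mustWork = TRUE)
  sfile <- system.file("extdata", "multifeed_schedules.yaml",
                       package = "sscfkin", mustWork = TRUE)
  py <- yaml::read_yaml(pfile)
  cy <- yaml::read_yaml(cfile)
  sy <- yaml::read_yaml(sfile)
  ci <- do.call(rbind, py$confidence_intervals)
  colnames(ci) <- c("lower", "upper")
  comp <- function(x)
    feedstock_composition(glucan_frac = x$glucan_frac,
                          xylan_frac = x$xylan_frac,
                          other_polymer_fracs = unlist(x$other_polymer_fracs),
                          wis_of_solid_feed = x$wis_of_solid_feed,
                          liquid_sugars = unlist(x$liquid_sugars),
                          liquid_inhibitors = unlist(x$liquid_inhibitors))
  list(params = do.call(sscf_params, py$params),
       param_ci = ci,
       lab_composition = comp(cy$lab),
       demo_composition = comp(cy$demo),
       lab_schedule = sy$lab,
       demo_schedule = sy$demo)
}

#' Reconstruct per-feed masses for a recorded operating plan
#'
#' The recorded operating plans give feed times and overall totals but not
#' the individual feed masses. This helper reconstructs a consistent
#' synthetic schedule by simulating the SSCF model and topping the
#' instantaneous WIS content up to `wis_ub` at each recorded solid-feed
#' time, then rescaling all masses so the final broth mass matches the
#' recorded total (the kinetics are intensive, so a uniform mass rescale
#' leaves all concentrations unchanged). The result is a reconstruction,
#' not recorded data.
#'
#' @param times solid-feed clock times, h (a feed at t = 0 is the initial
#'   charge and is skipped).
#' @param params an [sscf_params()] set.
#' @param composition a [feedstock_composition()].
#' @param final_mass recorded final broth mass, g.
#' @param initial_wis WIS fraction at t = 0 (w/w).
#' @param wis_ub WIS ceiling each feed tops up to (w/w).
#' @param enzyme_dosage FPU per g total WIS, charged at t = 0.
#' @param horizon simulated span, h.
#' @param mode `"sscf"` or `"hydrolysis_only"`.
#'
#' @return A list with `events` (list of [feed_event()]s),
#'   `initial_mass` (g), and `sim` (the rescaled `"sscf_sim"` of the
#'   reconstruction).
#' @export
reconstruct_schedule <- function(times, params, composition,
                                 final_mass = 1252, initial_wis = 0.07,
                                 wis_ub = 0.13, enzyme_dosage = 10,
                                 horizon = max(times) + 24,
                                 mode = "sscf") {
  times <- sort(unique(times[times > 0]))
  w0 <- 1000
  # iterate once: size feeds, then set the planned-total enzyme charge
  run <- function(etot) {
    st <- initial_state(w0, initial_wis, composition, enzyme_total = etot,
                        cell_dosage = 0.02)
    evs <- list(); wis_added <- st$wis_mass; t <- 0
    for (tf in times) {
      sim <- sscf_simulate(st, params, tf - t, mode = mode,
                           sampling_interval = max(tf - t, 1e-6))
      st <- sim$state; t <- tf
      sz <- solids_to_add(st, wis_ub, composition$wis_of_solid_feed)
      if (sz$wis_add > 0) {
        ev <- feed_event(tf, solid_wet_mass = sz$wet_mass)
        st <- apply_feed(st, ev, composition)
        evs[[length(evs) + 1]] <- ev
        wis_added <- wis_added + sz$wis_add
      }
    }
    list(events = evs, wis_added = wis_added, final = st)
  }
  r0 <- run(enzyme_dosage * initial_wis * w0)
  r <- run(enzyme_dosage * r0$wis_added)
  sim_full <- sscf_simulate(
    initial_state(w0, initial_wis, composition,
                  enzyme_total = enzyme_dosage * r$wis_added,
                  cell_dosage = 0.02),
    params, horizon, mode = mode, sampling_interval = 1,
    events = r$events, composition = composition)
  scale <- final_mass / sim_full$state$total_mass
  events <- lapply(r$events, function(e)
    feed_event(e$time, solid_wet_mass = scale * e$solid_wet_mass,
               enzyme_added = scale * e$enzyme_added,
               cells_added = scale * e$cells_added,
               liquid_mass = scale * e$liquid_mass))
  list(events = events, initial_mass = scale * w0, sim = sim_full)
}
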