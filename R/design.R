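#' Configuration of the model-based fed-batch design loop
#'
#' Parameters of the in-silico control loop that schedules solid feeds: a
#' sequence of short batch simulations is run; whenever the fraction of
#' cellulose degraded since the last feed exceeds the trigger `phi`, solids
#' are added to bring the instantaneous WIS content back up to the mixing
#' ceiling `wis_ub`.
#'
#' @param phi trigger fraction of cellulose degraded since the last feed,
#'   in (0, 1].
#' @param wis_ub instantaneous WIS upper bound, w/w fraction; the mixing
#'   ceiling of the reactor (empirically 0.12-0.13 for a stirred tank).
#' @param wis_solids WIS content of the wet solid feed material, w/w
#'   fraction; must exceed `wis_ub`.
#' @param check_interval spacing of in-silico trigger checks, h.
#' @param horizon design horizon, h.
#' @param initial_wis WIS fraction at t = 0, w/w; must not exceed `wis_ub`.
#' @param initial_mass broth mass charged at t = 0, g.
#' @param enzyme_dosage enzyme dose, FPU per g WIS.
#' @param cell_dosage cell dose, g dry weight per g WIS.
#' @param enzyme_mode `"all_initial"`: the enzyme for the whole planned WIS
#'   addition is charged at t = 0 (the planned total is derived from
#'   `cumulative_wis_target`, falling back to the initial WIS when no
#'   target is set); `"per_feed"`: dosed per g WIS at the start and at each
#'   solid feed.
#' @param cell_mode `"all_initial"` or `"scheduled"` (fresh cells at
#'   `cell_feed_times`, dosed per g WIS added since the previous cell feed).
#' @param cell_feed_times clock times of cell feeds, h (used when
#'   `cell_mode = "scheduled"`).
#' @param cumulative_wis_target overall WIS loading target, w/w fraction of
#'   final broth mass, or `NULL`; feeding stops once reached.
#' @param mode `"hydrolysis_only"` or `"sscf"`.
#' @param water_per_feed water co-fed at each solid feed, g.
#'
#' @return An object of class `"design_config"`.
#' @export
design_config <- function(phi = 0.6, wis_ub = 0.13, wis_solids = 0.40,
                          check_interval = 1, horizon = 120,
                          initial_wis = 0.07, initial_mass = 1000,
                          enzyme_dosage = 10, cell_dosage = 0.02,
                          enzyme_mode = c("all_initial", "per_feed"),
                          cell_mode = c("scheduled", "all_initial"),
                          cell_feed_times = c(0, 24, 48, 72, 96),
                          cumulative_wis_target = NULL,
                          mode = c("sscf", "hydrolysis_only"),
                          water_per_feed = 0) {
  enzyme_mode <- match.arg(enzyme_mode)
  cell_mode <- match.arg(cell_mode)
  mode <- match.arg(mode)
  if (!(phi > 0 && phi <= 1)) stop("phi must lie in (0, 1]", call. = FALSE)
  if (!(wis_ub > 0 && wis_ub < wis_solids && wis_solids <= 1))
    stop("need 0 < wis_ub < wis_solids <= 1", call. = FALSE)
  if (check_interval <= 0) stop("check_interval must be > 0", call. = FALSE)
  if (horizon < 0) stop("horizon must be >= 0", call. = FALSE)
  if (initial_wis > wis_ub + 1e-12)
    stop("infeasible configuration: initial_wis exceeds wis_ub", call. = FALSE)
  if (!is.null(cumulative_wis_target) &&
      (cumulative_wis_target <= 0 || cumulative_wis_target >= wis_solids))
    stop("cumulative_wis_target must lie in (0, wis_solids)", call. = FALSE)
  structure(list(phi = phi, wis_ub = wis_ub, wis_solids = wis_solids,
                 check_interval = check_interval, horizon = horizon,
                 initial_wis = initial_wis, initial_mass = initial_mass,
                 enzyme_dosage = enzyme_dosage, cell_dosage = cell_dosage,
                 enzyme_mode = enzyme_mode, cell_mode = cell_mode,
                 cell_feed_times = sort(unique(cell_feed_times)),
                 cumulative_wis_target = cumulative_wis_target,
                 mode = mode, water_per_feed = water_per_feed),
            class = "design_config")
}

#' Fraction of cellulose degraded since the last feed
#'
#' The trigger quantity of the design loop:
#' `(cellulose_ref_mass - cellulose_mass) / cellulose_ref_mass`, where the
#' reference is the total cellulose right after the previous addition.
#'
#' @param state a [reactor_state()].
#' @return Conversion fraction in \[0, 1\].
#' @export
conversion_since_last_feed <- function(state) {
  if (state$cellulose_ref_mass <= 0)
    stop("no feed basis: reference cellulose is zero", call. = FALSE)
  max(0, min(1, (state$cellulose_ref_mass - state$cellulose_mass) /
               state$cellulose_ref_mass))
}

#' Size a solid feed against the WIS ceiling
#'
#' Solves the mass balance for the dry-WIS addition that brings the
#' instantaneous WIS fraction exactly to `wis_ub` after the feed,
#' accounting for concurrent non-solid additions `w_adds`:
#' `wis_add = (wis_ub * (w + w_adds) - WIS) / (1 - wis_ub / wis_solids)`,
#' floored at zero.
#'
#' @param state a [reactor_state()] (`w` and `WIS` are taken from it).
#' @param wis_ub instantaneous WIS ceiling, w/w fraction.
#' @param wis_solids WIS content of the wet feed material, w/w fraction.
#' @param w_adds mass concurrently added by non-solid feeds, g.
#' @return A list with `wis_add` (dry WIS, g) and `wet_mass`
#'   (`wis_add / wis_solids`, g).
#' @examples
#' wheat <- sscf_fixtures()$lab_composition
#' s <- initial_state(1000, 0.07, wheat)
#' solids_to_add(s, 0.13, 0.40)   # 88.9 g dry / 222.2 g wet
#' @export
solids_to_add <- function(state, wis_ub, wis_solids, w_adds = 0) {
  if (wis_ub >= wis_solids)
    stop("wis_ub must be smaller than wis_solids", call. = FALSE)
  a <- (wis_ub * (state$total_mass + w_adds) - state$wis_mass) /
    (1 - wis_ub / wis_solids)
  a <- max(a, 0)
  list(wis_add = a, wet_mass = a / wis_solids)
}

# planned total dry WIS implied by a cumulative loading target
# (mass balance ignoring carrier liquids; used to size the all-initial
# enzyme charge)
planned_total_wis <- function(config) {
  w0 <- config$initial_mass
  wis0 <- config$initial_wis * w0
  tgt <- config$cumulative_wis_target
  if (is.null(tgt)) return(wis0)
  final_mass <- (w0 - wis0 / config$wis_solids) / (1 - tgt / config$wis_solids)
  tgt * final_mass
}

#' Design a fed-batch feed schedule from the kinetic model
#'
#' Runs the model-based control loop: repeated `check_interval`-hour batch
#' simulations; when the cellulose conversion since the last feed strictly
#' exceeds `phi` (and the cumulative loading target, if any, has not been
#' reached), a solid feed sized by [solids_to_add()] is applied, which tops
#' the instantaneous WIS content up to `wis_ub`. Enzyme and cells are
#' co-fed according to the configured modes; scheduled cell feeds fire at
#' fixed clock times.
#'
#' @param config a [design_config()].
#' @param params an [sscf_params()] set.
#' @param composition a [feedstock_composition()].
#' @param initial optional starting [reactor_state()]; built from the
#'   config when omitted.
#'
#' @return An object of class `"sscf_design"`: a list with `schedule`
#'   (list of [feed_event()]s, t = 0 charge excluded), `timecourse`,
#'   `state` (final), `wis_added` (g dry, incl. the initial charge),
#'   `cumulative_wis_loading_pct`, `max_wis_pct` (maximum instantaneous
#'   WIS over all samples and post-feed instants), `config` and `params`.
#' @examples
#' \donttest{
#' wheat <- sscf_fixtures()$lab_composition
#' d <- design_feeds(design_config(cumulative_wis_target = 0.22),
#'                   sscf_params(), wheat)
#' d$cumulative_wis_loading_pct
#' }
#' @export
design_feeds <- function(config, params, composition, initial = NULL) {
  stopifnot(inherits(config, "design_config"))
  params <- as_sscf_params(params)
  enzyme0 <- if (config$enzyme_mode == "all_initial")
    config$enzyme_dosage * planned_total_wis(config)
  else config$enzyme_dosage * config$initial_wis * config$initial_mass
  cells0 <- if (config$cell_mode == "all_initial" ||
                (config$cell_mode == "scheduled" && 0 %in% config$cell_feed_times))
    config$cell_dosage else 0
  state <- if (is.null(initial))
    initial_state(config$initial_mass, config$initial_wis, composition,
                  enzyme_total = enzyme0, cell_dosage = cells0)
  else initial
  wis_added <- state$wis_mass
  wis_since_cell_feed <- 0
  schedule <- list()
  rows <- list(timecourse_row(state, wis_added))
  max_wis <- state$wis_mass / state$total_mass
  t <- state$time
  n_checks <- if (config$horizon <= 0) 0 else
    ceiling((config$horizon - 1e-9) / config$check_interval)
  for (chk in seq_len(n_checks)) {
    t_next <- min(t + config$check_interval, config$horizon)
    sim <- sscf_simulate(state, params, t_next - t, mode = config$mode,
                         sampling_interval = config$check_interval)
    state <- sim$state
    t <- t_next
    rows[[length(rows) + 1]] <- timecourse_row(state, wis_added)
    max_wis <- max(max_wis, state$wis_mass / state$total_mass)

    # scheduled cell feeds at fixed clock times
    if (config$cell_mode == "scheduled" &&
        any(abs(config$cell_feed_times - t) < 1e-9) && t > 0) {
      dose <- config$cell_dosage * wis_since_cell_feed
      if (dose > 0) {
        ev <- feed_event(t, cells_added = dose)
        state <- apply_feed(state, ev, composition)
        schedule[[length(schedule) + 1]] <- ev
        rows[[length(rows) + 1]] <- timecourse_row(state, wis_added)
        wis_since_cell_feed <- 0
      }
    }

    target_open <- is.null(config$cumulative_wis_target) ||
      wis_added / state$total_mass < config$cumulative_wis_target
    if (t < config$horizon && target_open &&
        conversion_since_last_feed(state) > config$phi) {
      # non-solid masses co-fed at this event, known before sizing solids
      w_adds <- config$water_per_feed
      sz <- solids_to_add(state, config$wis_ub, config$wis_solids, w_adds)
      if (sz$wis_add > 0) {
        enz <- if (config$enzyme_mode == "per_feed")
          config$enzyme_dosage * sz$wis_add else 0
        ev <- feed_event(t, solid_wet_mass = sz$wet_mass,
                         enzyme_added = enz,
                         liquid_mass = config$water_per_feed)
        state <- apply_feed(state, ev, composition)
        schedule[[length(schedule) + 1]] <- ev
        wis_added <- wis_added + sz$wis_add
        wis_since_cell_feed <- wis_since_cell_feed + sz$wis_add
        rows[[length(rows) + 1]] <- timecourse_row(state, wis_added)
        max_wis <- max(max_wis, state$wis_mass / state$total_mass)
      }
    }
  }
  tc <- rows_to_timecourse(rows)
  structure(list(schedule = schedule, timecourse = tc, state = state,
                 wis_added = wis_added,
                 cumulative_wis_loading_pct = 100 * wis_added / state$total_mass,
                 max_wis_pct = 100 * max_wis,
                 config = config, params = params,
                 composition = composition),
            class = "sscf_design")
}

#' @export
print.sscf_design <- function(x, ...) {
  solid <- Filter(function(e) e$solid_wet_mass > 0, x$schedule)
  cat(sprintf("Model-based feed design (%s mode, phi = %.2f, WIS ceiling %.1f %%)\n",
              x$config$mode, x$config$phi, 100 * x$config$wis_ub))
  cat(sprintf("  %d solid feeds at t = %s h\n", length(solid),
              paste(vapply(solid, `[[`, 0, "time"), collapse = ", ")))
  cat(sprintf("  cumulative WIS loading %.1f %% w/w; max instantaneous WIS %.2f %%\n",
              x$cumulative_wis_loading_pct, x$max_wis_pct))
  cat(sprintf("  final ethanol %.1f g/kg in %.0f h\n", x$state$ethanol,
              x$state$time))
  invisible(x)
}

#' @export
plot.sscf_design <- function(x, ...) {
  tc <- x$timecourse
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  plot(tc$time_h, tc$wis_pct, type = "s", xlab = "time (h)",
       ylab = "WIS (% w/w)", ...)
  abline(h = 100 * x$config$wis_ub, lty = 2)
  lines(tc$time_h, tc$cum_wis_added_pct, col = 4)
  legend("topleft", c("instantaneous WIS", "cumulative loading", "ceiling"),
         col = c(1, 4, 1), lty = c(1, 1, 2), bty = "n", cex = 0.8)
  matplot(tc$time_h, tc[, c("glucose_g_per_kg", "ethanol_g_per_kg")],
          type = "l", lty = 1, col = c(2, 3), xlab = "time (h)",
          ylab = "g/kg")
  legend("topleft", c("glucose", "ethanol"), col = c(2, 3), lty = 1,
         bty = "n", cex = 0.8)
  invisible(x)
}

#' Cumulative WIS loading of a designed run
#'
#' The overall-loading summary statistic: all dry WIS charged and fed,
#' as a percentage of the final broth mass.
#'
#' @param x an `"sscf_design"` (or `"sscf_sim"`) object.
#' @return Percent w/w.
#' @export
cumulative_wis_loading <- function(x) {
  100 * x$wis_added / x$state$total_mass
}

#' Process performance metrics
#'
#' Yields and productivities of a simulated (or designed) run. The
#' hydrolysis sugar yields divide the released sugar by the total
#' anhydro-corrected polymeric sugar in all WIS charged and fed; the
#' ethanol yield divides the ethanol produced by 0.51 times the total
#' fermentable sugar (polymeric, anhydro-corrected, plus the liquor sugars
#' carried with the feed material).
#'
#' @param x an `"sscf_sim"` or `"sscf_design"` object.
#' @param composition the [feedstock_composition()] used in the run (taken
#'   from `x` when present).
#' @return A list: `glucose_yield_pct`, `xylose_yield_pct`,
#'   `ethanol_yield_pct_theoretical`, `final_ethanol_g_per_kg`,
#'   `volumetric_productivity_g_per_kg_h`.
#' @export
evaluate_performance <- function(x, composition = x$composition) {
  if (is.null(composition))
    stop("a feedstock composition is required", call. = FALSE)
  tc <- x$timecourse
  glucan_total <- composition$glucan_frac * x$wis_added
  xylan_total <- composition$xylan_frac * x$wis_added
  if (glucan_total <= 0)
    stop("zero sugar basis: no glucan in the run", call. = FALSE)
  final <- x$state
  released_glucose <- ANHYDRO_GLUCAN * (glucan_total - final$cellulose_mass)
  released_xylose <- ANHYDRO_XYLAN * (xylan_total - final$xylan_mass)
  wet_total <- x$wis_added / composition$wis_of_solid_feed
  carried <- wet_total - x$wis_added
  liq_glu <- liquor_conc(composition, "glucose") * carried / 1000
  liq_xyl <- liquor_conc(composition, "xylose") * carried / 1000
  fermentable <- ANHYDRO_GLUCAN * glucan_total + ANHYDRO_XYLAN * xylan_total +
    liq_glu + liq_xyl
  etoh_produced <- final$ethanol * final$total_mass / 1000
  elapsed <- max(tc$time_h) - min(tc$time_h)
  list(glucose_yield_pct = 100 * released_glucose / (ANHYDRO_GLUCAN * glucan_total),
       xylose_yield_pct = if (xylan_total > 0)
         100 * released_xylose / (ANHYDRO_XYLAN * xylan_total) else NA_real_,
       ethanol_yield_pct_theoretical =
         100 * etoh_produced / (ETOH_MAX_YIELD * fermentable),
       final_ethanol_g_per_kg = final$ethanol,
       volumetric_productivity_g_per_kg_h =
         if (elapsed > 0) final$ethanol / elapsed else NA_real_)
}
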