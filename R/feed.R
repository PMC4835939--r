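#' Feed event
#'
#' One instantaneous addition to the reactor: wet solid-fraction material,
#' enzyme, cells and/or liquid. Enzyme and cell doses are delivered in
#' carrier liquid whose mass is accounted for via the carrier factors of
#' [apply_feed()].
#'
#' @param time event time, h (>= 0).
#' @param solid_wet_mass wet solid-fraction material added, g.
#' @param enzyme_added enzyme added, FPU.
#' @param cells_added cells added, g dry weight.
#' @param liquid_mass water or liquor added, g.
#'
#' @return An object of class `"feed_event"`.
#' @export
feed_event <- function(time, solid_wet_mass = 0, enzyme_added = 0,
                       cells_added = 0, liquid_mass = 0) {
  v <- c(time, solid_wet_mass, enzyme_added, cells_added, liquid_mass)
  if (any(!is.finite(v)) || any(v < 0))
    stop("feed-event quantities must be finite and >= 0", call. = FALSE)
  structure(list(time = time, solid_wet_mass = solid_wet_mass,
                 enzyme_added = enzyme_added, cells_added = cells_added,
                 liquid_mass = liquid_mass),
            class = "feed_event")
}

#' @export
print.feed_event <- function(x, ...) {
  cat(sprintf("Feed at %.1f h: %.1f g wet solids, %.0f FPU, %.2f g cells DW, %.1f g liquid\n",
              x$time, x$solid_wet_mass, x$enzyme_added, x$cells_added,
              x$liquid_mass))
  invisible(x)
}

# dry WIS content of an event's solid feed
feed_dry_wis <- function(event, composition) {
  if (event$solid_wet_mass <= 0) return(0)
  event$solid_wet_mass * composition$wis_of_solid_feed
}

# total mass an event adds, including carrier liquid for enzyme and cells
feed_total_mass <- function(event, composition = NULL,
                            enzyme_carrier = 1 / 70, cell_carrier = 10) {
  event$solid_wet_mass + event$enzyme_added * enzyme_carrier +
    event$cells_added * cell_carrier + event$liquid_mass
}

#' Apply a feed event to the reactor state
#'
#' Instantaneous state update for a feed: the broth mass grows by
#' everything added (wet solids, enzyme and cell carrier liquid, water),
#' solid pools grow per the feedstock composition, dissolved species are
#' diluted with the liquor sugars of the feed material credited, and the
#' adsorption references are reset: `S0` and `E_load` take their
#' post-addition values, the adsorbed enzyme amount (FPU) is conserved so
#' `e_ad` is rescaled onto the new solids, and `cellulose_ref_mass`
#' becomes the post-addition cellulose (the basis of the next
#' conversion-trigger check).
#'
#' @param state a [reactor_state()].
#' @param event a [feed_event()].
#' @param composition a [feedstock_composition()]; required when the event
#'   adds solids.
#' @param enzyme_carrier carrier-liquid mass of the enzyme preparation,
#'   g per FPU (default 1/70: 1 g per 70 FPU).
#' @param cell_carrier carrier-slurry mass, g per g cell dry weight
#'   (default 10).
#'
#' @return The updated `"reactor_state"`.
#' @examples
#' wheat <- sscf_fixtures()$lab_composition
#' s <- initial_state(1000, 0.07, wheat, enzyme_dosage = 10)
#' s2 <- apply_feed(s, feed_event(0, solid_wet_mass = 222.2), wheat)
#' round(100 * s2$wis_mass / s2$total_mass, 2)   # topped up to ~13 % w/w
#' @export
apply_feed <- function(state, event, composition = NULL,
                       enzyme_carrier = 1 / 70, cell_carrier = 10) {
  stopifnot(inherits(event, "feed_event"))
  if (event$solid_wet_mass > 0 && is.null(composition))
    stop("a feedstock composition is required to feed solids", call. = FALSE)
  added <- feed_total_mass(event, composition, enzyme_carrier, cell_carrier)
  if (added <= 0) {
    # bookkeeping-only event
    state$cellulose_ref_mass <- state$cellulose_mass
    state$solids_ref_mass <- max(state$wis_mass, 1e-12)
    state$enzyme_load_ref <- state$enzyme_total / state$solids_ref_mass
    return(state)
  }
  w_old <- state$total_mass
  w_new <- w_old + added
  dry <- feed_dry_wis(event, composition)
  carried <- event$solid_wet_mass - dry      # liquor in the solid feed, g

  adsorbed_fpu <- state$e_ad * state$wis_mass

  state$total_mass <- w_new
  state$wis_mass <- state$wis_mass + dry
  if (dry > 0) {
    state$cellulose_mass <- state$cellulose_mass + composition$glucan_frac * dry
    state$xylan_mass <- state$xylan_mass + composition$xylan_frac * dry
  }
  # dilute dissolved species; credit liquor sugars of the feed material
  dil <- w_old / w_new
  state$glucose <- state$glucose * dil +
    (if (dry > 0) liquor_conc(composition, "glucose") * carried / w_new else 0)
  state$xylose <- state$xylose * dil +
    (if (dry > 0) liquor_conc(composition, "xylose") * carried / w_new else 0)
  state$ethanol <- state$ethanol * dil
  state$viable_cells <- state$viable_cells * dil +
    event$cells_added / (w_new / 1000)

  state$enzyme_total <- state$enzyme_total + event$enzyme_added
  state$solids_ref_mass <- max(state$wis_mass, 1e-12)
  state$enzyme_load_ref <- state$enzyme_total / state$solids_ref_mass
  state$e_ad <- if (state$wis_mass > 0) adsorbed_fpu / state$wis_mass else 0
  state$cellulose_ref_mass <- state$cellulose_mass
  validate_state(state)
  state
}
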