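#' Feedstock composition of pre-treated material
#'
#' Describes the solid fraction of a pre-treated lignocellulose slurry:
#' polymer mass fractions of the water-insoluble solids (WIS), the WIS
#' content of the wet solid-fraction material, and the sugar/inhibitor
#' concentrations of the liquid retained in it. Only glucan and xylan react
#' in the model; other polymers and inhibitors are carried for bookkeeping.
#'
#' @param glucan_frac glucan mass fraction of WIS (g per g WIS).
#' @param xylan_frac xylan mass fraction of WIS.
#' @param other_polymer_fracs named numeric vector of further polymer
#'   fractions (mannan, galactan, arabinan, ...); inert.
#' @param wis_of_solid_feed WIS mass fraction of the wet solid-fraction
#'   feed material, w/w in (0, 1].
#' @param liquid_sugars named concentrations (g per kg) of sugars in the
#'   retained/feed liquid; recognised names include `glucose` and `xylose`.
#' @param liquid_inhibitors named concentrations (g per kg) of inhibitors
#'   in the retained liquid; bookkeeping only.
#' @param liquor_as_water if `TRUE` the non-WIS part of the wet solid feed
#'   is treated as pure water instead of sugar-bearing retained liquor.
#'
#' @return An object of class `"feedstock_composition"` (a list of the
#'   validated fields).
#' @examples
#' wheat <- feedstock_composition(glucan_frac = 0.479, xylan_frac = 0.023,
#'                                liquid_sugars = c(glucose = 6.8, xylose = 12.8))
#' @export
feedstock_composition <- function(glucan_frac, xylan_frac,
                                  other_polymer_fracs = numeric(),
                                  wis_of_solid_feed = 0.40,
                                  liquid_sugars = c(glucose = 0, xylose = 0),
                                  liquid_inhibitors = numeric(),
                                  liquor_as_water = FALSE) {
  fr <- c(glucan_frac, xylan_frac, other_polymer_fracs)
  if (any(fr < 0) || any(fr > 1))
    stop("polymer fractions must lie in [0, 1]", call. = FALSE)
  if (sum(fr) > 1 + 1e-9)
    stop("polymer fractions sum to more than 1", call. = FALSE)
  if (wis_of_solid_feed <= 0 || wis_of_solid_feed > 1)
    stop("wis_of_solid_feed must lie in (0, 1]", call. = FALSE)
  if (any(liquid_sugars < 0) || any(unlist(liquid_inhibitors) < 0))
    stop("liquid-phase concentrations must be >= 0", call. = FALSE)
  structure(list(glucan_frac = glucan_frac,
                 xylan_frac = xylan_frac,
                 other_polymer_fracs = other_polymer_fracs,
                 wis_of_solid_feed = wis_of_solid_feed,
                 liquid_sugars = liquid_sugars,
                 liquid_inhibitors = liquid_inhibitors,
                 liquor_as_water = isTRUE(liquor_as_water)),
            class = "feedstock_composition")
}

#' @export
print.feedstock_composition <- function(x, ...) {
  cat("Feedstock composition (solid fraction):\n")
  cat(sprintf("  glucan %.3f, xylan %.3f of WIS; WIS of wet feed %.2f w/w\n",
              x$glucan_frac, x$xylan_frac, x$wis_of_solid_feed))
  if (length(x$liquid_sugars))
    cat("  retained-liquid sugars (g/kg):",
        paste(names(x$liquid_sugars), signif(x$liquid_sugars, 3),
              sep = "=", collapse = ", "), "\n")
  if (x$liquor_as_water)
    cat("  (retained liquid treated as pure water)\n")
  invisible(x)
}

# sugar concentration (g/kg) carried by the liquid part of the solid feed
liquor_conc <- function(composition, sugar) {
  if (isTRUE(composition$liquor_as_water)) return(0)
  v <- composition$liquid_sugars[sugar]
  if (is.na(v)) 0 else unname(v)
}
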