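#' Kinetic parameter set for hydrolysis and SSCF
#'
#' Bundles the ten kinetic constants of the hydrolysis/SSCF model and
#' validates them. Defaults are the optimised wheat-straw values; the first
#' four (`k_ad`, `k`, `K_G`, `gamma`) are the constants normally estimated
#' from hydrolysis time courses, the remainder are fermentation constants
#' taken as fixed.
#'
#' @param k_ad adsorption rate constant, g solid FPU^-1 h^-1.
#' @param k hydrolysis rate constant, g cellulose FPU^-1 h^-1.
#' @param K_G glucose inhibition constant of cellulose hydrolysis, g kg^-1.
#' @param gamma proportionality between xylan and cellulose degradation
#'   rates (dimensionless).
#' @param K_iEtOH ethanol inhibition constant of cellulose hydrolysis,
#'   g kg^-1.
#' @param q_G maximum specific glucose uptake rate of the yeast,
#'   g g^-1 h^-1.
#' @param K glucose saturation constant of uptake, g kg^-1.
#' @param Y_EtOH ethanol yield on glucose, g g^-1; must not exceed the
#'   stoichiometric maximum 0.51.
#' @param alpha pre-exponential factor of the ethanol-induced death rate,
#'   h^-1.
#' @param beta exponential factor of the ethanol-induced death rate,
#'   kg g^-1.
#'
#' @return An object of class `"sscf_params"`: a named numeric vector with
#'   the ten constants.
#' @examples
#' p <- sscf_params()
#' p["K_G"]
#' @export
sscf_params <- function(k_ad = 0.27, k = 0.016, K_G = 6.13, gamma = 0.028,
                        K_iEtOH = 16.6, q_G = 1.6, K = 0.01, Y_EtOH = 0.42,
                        alpha = 0.026, beta = 0.0037) {
  p <- c(k_ad = k_ad, k = k, K_G = K_G, gamma = gamma, K_iEtOH = K_iEtOH,
         q_G = q_G, K = K, Y_EtOH = Y_EtOH, alpha = alpha, beta = beta)
  if (!all(is.finite(p)))
    stop("all kinetic parameters must be finite numbers", call. = FALSE)
  if (any(p <= 0))
    stop("all kinetic parameters must be strictly positive; got: ",
         paste(names(p)[p <= 0], collapse = ", "), call. = FALSE)
  if (Y_EtOH > ETOH_MAX_YIELD)
    stop("Y_EtOH exceeds the stoichiometric maximum of 0.51 g/g",
         call. = FALSE)
  structure(p, class = "sscf_params")
}

#' @export
print.sscf_params <- function(x, ...) {
  cat("SSCF kinetic parameters:\n")
  print(unclass(x), ...)
  invisible(x)
}

as_sscf_params <- function(x) {
  if (inherits(x, "sscf_params")) return(x)
  if (is.numeric(x) && !is.null(names(x)))
    return(do.call(sscf_params, as.list(x)))
  if (is.list(x)) return(do.call(sscf_params, x))
  stop("cannot interpret 'params'; use sscf_params()", call. = FALSE)
}
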