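#' Measurement noise model
#'
#' Additive or relative Gaussian noise applied per observable when
#' generating synthetic time courses. `sigma` may be a single value for
#' all observables or a named vector keyed by time-course column name.
#'
#' @param kind `"gaussian_relative"` (sd proportional to the signal) or
#'   `"gaussian_additive"` (sd in the observable's units).
#' @param sigma noise level (relative fraction, or absolute in the
#'   observable's units); scalar or named per-observable vector, >= 0.
#' @param seed integer seed making the noise reproducible.
#'
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(kind = c("gaussian_relative", "gaussian_additive"),
                        sigma = 0.02, seed = 1L) {
  kind <- match.arg(kind)
  if (any(sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
  structure(list(kind = kind, sigma = sigma, seed = as.integer(seed)),
            class = "noise_model")
}

noise_sigma <- function(noise, column) {
  s <- noise$sigma
  if (length(s) == 1 && is.null(names(s))) return(unname(s))
  v <- s[column]
  if (is.na(v)) 0 else unname(v)
}

#' Scenario descriptor for a hydrolysis/SSCF experiment
#'
#' Describes how a reactor run is set up: initial loading, enzyme and cell
#' dosing, composition, operating mode and (for fed-batch) a feed
#' schedule. Used as the simulation recipe behind synthetic data
#' generation and parameter fitting.
#'
#' @param initial_wis WIS fraction at t = 0, w/w.
#' @param enzyme_dosage enzyme dose, FPU per g initial WIS.
#' @param composition a [feedstock_composition()].
#' @param total_mass broth mass at t = 0, g.
#' @param cell_dosage cell dose, g DW per g initial WIS.
#' @param mode `"hydrolysis_only"` or `"sscf"`.
#' @param duration run length, h.
#' @param events optional list of [feed_event()]s (fed-batch).
#'
#' @return An object of class `"fit_scenario"`.
#' @export
fit_scenario <- function(initial_wis, enzyme_dosage, composition,
                         total_mass = 1000, cell_dosage = 0,
                         mode = c("hydrolysis_only", "sscf"),
                         duration = 96, events = NULL) {
  mode <- match.arg(mode)
  structure(list(initial_wis = initial_wis, enzyme_dosage = enzyme_dosage,
                 composition = composition, total_mass = total_mass,
                 cell_dosage = cell_dosage, mode = mode,
                 duration = duration, events = events),
            class = "fit_scenario")
}

#' Simulate a scenario
#'
#' @param scenario a [fit_scenario()].
#' @param params an [sscf_params()] set.
#' @param sample_times explicit sample times, h; overrides
#'   `sampling_interval`.
#' @param sampling_interval sample spacing, h.
#' @return An `"sscf_sim"` object.
#' @export
simulate_scenario <- function(scenario, params, sample_times = NULL,
                              sampling_interval = 1) {
  s0 <- initial_state(scenario$total_mass, scenario$initial_wis,
                      scenario$composition,
                      enzyme_dosage = scenario$enzyme_dosage,
                      cell_dosage = scenario$cell_dosage)
  sscf_simulate(s0, params, scenario$duration, mode = scenario$mode,
                sampling_interval = sampling_interval,
                sample_times = sample_times, events = scenario$events,
                composition = scenario$composition)
}

# observable columns a fit can use
FIT_OBSERVABLES <- c("wis_pct", "glucose_g_per_kg", "xylose_g_per_kg",
                     "ethanol_g_per_kg", "viable_cells_g_per_kg",
                     "e_ad_fpu_per_g")

#' Bundle a scenario with observations
#'
#' @param scenario a [fit_scenario()].
#' @param observations data frame with a `time_h` column and at least one
#'   observable column (`wis_pct`, `glucose_g_per_kg`, `xylose_g_per_kg`,
#'   `ethanol_g_per_kg`, `viable_cells_g_per_kg`, `e_ad_fpu_per_g`);
#'   missing values allowed.
#' @return An object of class `"fit_dataset"`.
#' @export
fit_dataset <- function(scenario, observations) {
  stopifnot(inherits(scenario, "fit_scenario"), is.data.frame(observations))
  if (!"time_h" %in% names(observations))
    stop("observations need a time_h column", call. = FALSE)
  obs_cols <- intersect(FIT_OBSERVABLES, names(observations))
  if (!length(obs_cols))
    stop("observations contain no recognised observable column",
         call. = FALSE)
  if (is.unsorted(observations$time_h, strictly = TRUE))
    stop("observation times must be strictly increasing", call. = FALSE)
  if (max(observations$time_h) > scenario$duration + 1e-9)
    stop("observation times exceed the scenario duration", call. = FALSE)
  structure(list(scenario = scenario,
                 observations = observations[, c("time_h", obs_cols)],
                 observables = obs_cols),
            class = "fit_dataset")
}

#' Generate a synthetic time-course dataset
#'
#' Simulates a scenario, samples it (default every 6 h), perturbs each
#' observable with the configured noise, clips negatives to zero, and
#' returns the result as a [fit_dataset()]. Deterministic for a given
#' noise seed.
#'
#' @param scenario a [fit_scenario()].
#' @param params an [sscf_params()] set (the generating truth).
#' @param noise a [noise_model()]; use `sigma = 0` for noiseless data.
#' @param sampling_interval sample spacing, h.
#' @param observables which columns to keep as observations.
#'
#' @return A `"fit_dataset"`.
#' @examples
#' wheat <- sscf_fixtures()$lab_composition
#' sc <- fit_scenario(0.10, 10, wheat)
#' ds <- generate_timecourse(sc, sscf_params(), noise_model(sigma = 0.02))
#' head(ds$observations)
#' @export
generate_timecourse <- function(scenario, params,
                                noise = noise_model(sigma = 0),
                                sampling_interval = 6,
                                observables = c("wis_pct",
                                                "glucose_g_per_kg",
                                                "xylose_g_per_kg",
                                                "e_ad_fpu_per_g")) {
  sim <- simulate_scenario(scenario, params,
                           sampling_interval = sampling_interval)
  tc <- sim$timecourse
  # one row per sample time (drop duplicated post-feed rows)
  tc <- tc[!duplicated(tc$time_h, fromLast = TRUE), , drop = FALSE]
  obs <- tc[, c("time_h", observables), drop = FALSE]
  withr_seed <- noise$seed
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(withr_seed)
  for (col in observables) {
    sg <- noise_sigma(noise, col)
    if (sg > 0) {
      n <- nrow(obs)
      eps <- if (noise$kind == "gaussian_relative")
        rnorm(n, 0, sg) * obs[[col]] else rnorm(n, 0, sg)
      obs[[col]] <- pmax(obs[[col]] + eps, 0)
    }
  }
  fit_dataset(scenario, obs)
}
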