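#' Fit the hydrolysis model to time-course data
#'
#' Estimates the four hydrolysis constants (`k_ad`, `k`, `K_G`, `gamma`;
#' any subset can be freed) by minimising the sum over datasets and
#' observables of squared residuals, each observable normalised by its
#' per-dataset maximum absolute observation so that solids, sugars and
#' adsorbed enzyme contribute on comparable scales. Several datasets
#' (e.g. batches at different enzyme dosages) are fitted jointly.
#'
#' Optimisation uses bounded quasi-Newton search ([stats::nlminb]) on
#' start-scaled parameters, optionally from multiple seeded
#' Latin-hypercube starts to guard against local minima.
#'
#' @param datasets a [fit_dataset()] or list of them.
#' @param start named numeric vector of starting values for the free
#'   parameters (defaults to the packaged wheat-straw values).
#' @param lower,upper named bounds for the free parameters.
#' @param fixed full [sscf_params()] set supplying every constant not
#'   being estimated.
#' @param free names of the parameters to estimate.
#' @param n_starts number of optimisation starts; starts beyond the first
#'   are drawn by a seeded Latin hypercube within the bounds.
#' @param seed seed for the multi-start draw.
#' @param control passed to [stats::nlminb].
#'
#' @return An object of class `"sscf_fit"` with components `coefficients`,
#'   `params` (full parameter set at the estimate), `objective`,
#'   `convergence`/`iterations`/`message` (optimiser diagnostics; a
#'   non-converged fit is flagged, not an error), `datasets`, `scales`,
#'   `residuals` (long data frame), `r_squared` (per dataset and
#'   observable), `bounds`, `start` and `seed`. Methods: `print`,
#'   `summary`, `coef`, `predict`, `residuals`, `plot`, `simulate`,
#'   `confint` (residual bootstrap).
#' @examples
#' \donttest{
#' fx <- sscf_fixtures()
#' sc <- fit_scenario(0.10, 10, fx$lab_composition)
#' ds <- generate_timecourse(sc, fx$params, noise_model(sigma = 0))
#' fit <- fit_hydrolysis(ds, start = coef_start <- c(k_ad = 0.5, k = 0.03,
#'                                                   K_G = 12, gamma = 0.05))
#' coef(fit)
#' }
#' @export
fit_hydrolysis <- function(datasets,
                           start = c(k_ad = 0.27, k = 0.016, K_G = 6.13,
                                     gamma = 0.028),
                           lower = c(k_ad = 1e-4, k = 1e-4, K_G = 0.1,
                                     gamma = 0),
                           upper = c(k_ad = 10, k = 1, K_G = 100,
                                     gamma = 1),
                           fixed = sscf_params(),
                           free = names(start),
                           n_starts = 1, seed = 1L,
                           control = list(iter.max = 300, eval.max = 600)) {
  if (inherits(datasets, "fit_dataset")) datasets <- list(datasets)
  if (!length(datasets) || !all(vapply(datasets, inherits, TRUE, "fit_dataset")))
    stop("datasets must be fit_dataset objects", call. = FALSE)
  fixed <- as_sscf_params(fixed)
  start <- start[free]; lower <- lower[free]; upper <- upper[free]
  if (any(is.na(start)) || any(is.na(lower)) || any(is.na(upper)))
    stop("start and bounds must be named for every free parameter",
         call. = FALSE)
  if (any(start < lower - 1e-12) || any(start > upper + 1e-12))
    stop("starting values must lie within the bounds", call. = FALSE)

  scales <- lapply(datasets, function(d)
    vapply(d$observables, function(col) {
      m <- max(abs(d$observations[[col]]), na.rm = TRUE)
      if (!is.finite(m) || m == 0) 1 else m
    }, 0))

  # per-dataset context: initial state and sample grid do not depend on
  # the candidate parameters, so build them once
  ctxs <- lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    sc <- d$scenario
    s0 <- initial_state(sc$total_mass, sc$initial_wis, sc$composition,
                        enzyme_dosage = sc$enzyme_dosage,
                        cell_dosage = sc$cell_dosage)
    times <- sort(unique(c(0, d$observations$time_h)))
    list(d = d, s0 = s0, times = times,
         idx = match(round(d$observations$time_h, 9), round(times, 9)),
         obs = lapply(setNames(d$observables, d$observables),
                      function(col) d$observations[[col]]),
         scale = scales[[i]],
         simple = is.null(sc$events))
  })

  objective <- function(theta) {
    p <- fixed
    p[free] <- theta
    if (any(theta < lower - 1e-12) || any(theta > upper + 1e-12)) return(1e10)
    total <- 0
    for (ctx in ctxs) {
      sim_cols <- try(if (ctx$simple) {
        out <- integrate_span(ctx$s0, p, ctx$times, ctx$d$scenario$mode)
        w <- ctx$s0$total_mass
        list(wis_pct = 100 * out[, "S"] / w,
             glucose_g_per_kg = out[, "G"],
             xylose_g_per_kg = out[, "Xl"],
             ethanol_g_per_kg = out[, "EtOH"],
             viable_cells_g_per_kg = out[, "X"],
             e_ad_fpu_per_g = out[, "Ead"])
      } else {
        sim <- simulate_scenario(ctx$d$scenario, p,
                                 sample_times = ctx$d$observations$time_h)
        tc <- sim$timecourse
        j <- match(round(ctx$times, 9), round(tc$time_h, 9))
        lapply(setNames(FIT_OBSERVABLES, FIT_OBSERVABLES),
               function(col) tc[[col]][j])
      }, silent = TRUE)
      if (inherits(sim_cols, "try-error")) return(1e10)
      for (col in ctx$d$observables) {
        r <- (sim_cols[[col]][ctx$idx] - ctx$obs[[col]]) / ctx$scale[col]
        total <- total + sum(r^2, na.rm = TRUE)
      }
    }
    total
  }

  # optimise on start-scaled parameters so all free constants are O(1)
  ref <- ifelse(abs(start) > 0, abs(start), 1)
  obj_scaled <- function(th) objective(th * ref)
  starts <- list(start / ref)
  if (n_starts > 1) {
    if (any(!is.finite(lower)) || any(!is.finite(upper)))
      stop("finite bounds are required for multi-start", call. = FALSE)
    set.seed(seed)
    k <- length(free); m <- n_starts - 1
    # simple seeded Latin hypercube over the box
    u <- matrix(unlist(lapply(seq_len(k), function(j)
      (sample(m) - runif(m)) / m)), nrow = m)
    for (r in seq_len(m))
      starts[[r + 1]] <- (lower + u[r, ] * (upper - lower)) / ref
  }
  best <- NULL
  for (s0 in starts) {
    opt <- nlminb(s0, obj_scaled, lower = lower / ref, upper = upper / ref,
                  control = control)
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }

  est <- setNames(best$par * ref, free)
  p_hat <- fixed
  p_hat[free] <- est
  fit <- structure(
    list(coefficients = est, params = p_hat, free = free,
         objective = best$objective,
         convergence = best$convergence == 0,
         iterations = best$iterations, message = best$message,
         datasets = datasets, scales = scales,
         bounds = list(lower = lower, upper = upper),
         start = start, fixed = fixed, seed = seed,
         n_starts = n_starts, control = control, ci = NULL),
    class = "sscf_fit")
  fit$residuals <- residual_table(fit)
  fit$r_squared <- fit_r_squared(fit)
  fit
}

# simulated observables at the observation times of dataset i
fitted_observables <- function(fit, i, params = fit$params) {
  d <- fit$datasets[[i]]
  sim <- simulate_scenario(d$scenario, params,
                           sample_times = d$observations$time_h)
  tc <- sim$timecourse
  idx <- match(round(d$observations$time_h, 9), round(tc$time_h, 9))
  tc[idx, c("time_h", d$observables), drop = FALSE]
}

residual_table <- function(fit) {
  out <- list()
  for (i in seq_along(fit$datasets)) {
    d <- fit$datasets[[i]]
    sim <- fitted_observables(fit, i)
    for (col in d$observables) {
      out[[length(out) + 1]] <- data.frame(
        dataset = i, observable = col, time_h = d$observations$time_h,
        observed = d$observations[[col]], fitted = sim[[col]],
        residual = d$observations[[col]] - sim[[col]],
        normalized = (d$observations[[col]] - sim[[col]]) /
          fit$scales[[i]][col])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

fit_r_squared <- function(fit) {
  res <- fit$residuals
  keys <- unique(res[, c("dataset", "observable")])
  keys$r_squared <- vapply(seq_len(nrow(keys)), function(j) {
    sub <- res[res$dataset == keys$dataset[j] &
                 res$observable == keys$observable[j], ]
    ss_tot <- sum((sub$observed - mean(sub$observed))^2)
    if (ss_tot == 0) return(NA_real_)
    1 - sum(sub$residual^2) / ss_tot
  }, 0)
  keys
}

#' Coefficient of determination between simulated and observed series
#'
#' Interpolates the simulated series to the observation times and returns
#' `R^2 = 1 - SS_res / SS_tot`. Constant observations leave `SS_tot = 0`
#' and yield `NA` with a warning.
#'
#' @param simulated data frame with `time_h` and the observable column
#'   (e.g. an `"sscf_sim"` time course).
#' @param observed data frame with `time_h` and the observable column.
#' @param observable column name to compare.
#' @return `R^2` (numeric scalar, possibly `NA`).
#' @export
goodness_of_fit <- function(simulated, observed, observable) {
  if (inherits(simulated, "sscf_sim")) simulated <- simulated$timecourse
  y <- observed[[observable]]
  f <- approx(simulated$time_h, simulated[[observable]],
              xout = observed$time_h, rule = 2)$y
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warning("constant observations: R^2 undefined")
    return(NA_real_)
  }
  1 - sum((y - f)^2) / ss_tot
}
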