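#' @export
print.sscf_fit <- function(x, ...) {
  cat("Hydrolysis-model fit (", length(x$datasets), " dataset",
      if (length(x$datasets) > 1) "s", ", joint normalised least squares)\n",
      sep = "")
  print(signif(x$coefficients, 4))
  cat(sprintf("objective %.4g; %s after %d iterations\n", x$objective,
              if (x$convergence) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' @export
coef.sscf_fit <- function(object, ...) object$coefficients

#' @export
summary.sscf_fit <- function(object, ...) {
  est <- object$coefficients
  tab <- data.frame(estimate = est)
  if (!is.null(object$ci)) {
    tab$ci_lower <- object$ci[names(est), "lower"]
    tab$ci_upper <- object$ci[names(est), "upper"]
  }
  structure(list(coefficients = tab, r_squared = object$r_squared,
                 objective = object$objective,
                 convergence = object$convergence,
                 n_datasets = length(object$datasets)),
            class = "summary.sscf_fit")
}

#' @export
print.summary.sscf_fit <- function(x, ...) {
  cat("Joint hydrolysis-model fit over", x$n_datasets, "dataset(s)\n\n")
  print(signif(as.matrix(x$coefficients), 4))
  cat("\nR-squared per dataset and observable:\n")
  print(x$r_squared, row.names = FALSE)
  cat(sprintf("\nobjective %.4g (%s)\n", x$objective,
              if (x$convergence) "converged" else "not converged"))
  invisible(x)
}

#' Predicted observables of a fitted hydrolysis model
#'
#' Simulates the fitted model for one of the fitted datasets (or a new
#' scenario) and returns the observable columns.
#'
#' @param object an `"sscf_fit"`.
#' @param dataset index of the fitted dataset to predict for, or a
#'   [fit_scenario()] for a new prediction.
#' @param times sample times, h; defaults to the dataset's observation
#'   times.
#' @param ... unused.
#' @return Data frame of time and observables.
#' @export
predict.sscf_fit <- function(object, dataset = 1, times = NULL, ...) {
  if (inherits(dataset, "fit_scenario")) {
    sim <- simulate_scenario(dataset, object$params, sample_times = times,
                             sampling_interval = if (is.null(times)) 1 else 1)
    return(sim$timecourse)
  }
  d <- object$datasets[[dataset]]
  if (is.null(times)) times <- d$observations$time_h
  sim <- simulate_scenario(d$scenario, object$params, sample_times = times)
  tc <- sim$timecourse
  tc[match(round(times, 9), round(tc$time_h, 9)),
     c("time_h", d$observables), drop = FALSE]
}

#' @export
residuals.sscf_fit <- function(object, normalized = FALSE, ...) {
  if (normalized) object$residuals$normalized else object$residuals$residual
}

#' @export
plot.sscf_fit <- function(x, ...) {
  res <- x$residuals
  obs_cols <- unique(res$observable)
  op <- par(mfrow = c(length(obs_cols), 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  for (col in obs_cols) {
    sub <- res[res$observable == col, ]
    plot(sub$time_h, sub$observed, col = sub$dataset, pch = 1,
         xlab = "time (h)", ylab = col, ...)
    for (i in unique(sub$dataset)) {
      si <- sub[sub$dataset == i, ]
      lines(si$time_h, si$fitted, col = i)
    }
  }
  invisible(x)
}

#' Simulate replicate datasets from a fitted model
#'
#' Residual-resampling replicates: for each dataset and observable, the
#' fitted trajectory at the estimate is perturbed by residuals resampled
#' with replacement (the parametric bootstrap's data-generating step).
#' Negative values are clipped to zero.
#'
#' @param object an `"sscf_fit"`.
#' @param nsim number of replicate dataset lists.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of length `nsim`; each element is a list of
#'   [fit_dataset()]s parallel to `object$datasets`.
#' @export
simulate.sscf_fit <- function(object, nsim = 1, seed = 1L, ...) {
  set.seed(seed)
  lapply(seq_len(nsim), function(b) {
    lapply(seq_along(object$datasets), function(i) {
      d <- object$datasets[[i]]
      sim <- fitted_observables(object, i)
      obs <- d$observations
      for (col in d$observables) {
        r <- object$residuals
        ri <- r$residual[r$dataset == i & r$observable == col]
        obs[[col]] <- pmax(sim[[col]] + sample(ri, length(ri),
                                               replace = TRUE), 0)
      }
      fit_dataset(d$scenario, obs)
    })
  })
}

#' Bootstrap confidence intervals for a hydrolysis fit
#'
#' Residual-resampling bootstrap: `n_boot` replicate dataset lists are
#' drawn with [simulate.sscf_fit()], each refitted from the original
#' estimate, and per-parameter percentile intervals are taken from the
#' replicate estimates. Deterministic for a given seed.
#'
#' @param object an `"sscf_fit"` (should be converged).
#' @param parm parameters to report (default: all free).
#' @param level confidence level.
#' @param n_boot number of bootstrap replicates (>= 20).
#' @param seed integer seed.
#' @param ... unused.
#' @return Matrix with columns `lower` and `upper`; also stored in the
#'   fit when assigned back (`fit$ci`), plus the replicate estimates as
#'   attribute `"boot"`.
#' @export
confint.sscf_fit <- function(object, parm = object$free, level = 0.95,
                             n_boot = 200, seed = 1L, ...) {
  if (n_boot < 20)
    stop("n_boot must be at least 20 for percentile intervals",
         call. = FALSE)
  if (!object$convergence)
    warning("bootstrapping a fit that did not converge")
  reps <- simulate(object, nsim = n_boot, seed = seed)
  est <- matrix(NA_real_, n_boot, length(object$free),
                dimnames = list(NULL, object$free))
  for (b in seq_len(n_boot)) {
    refit <- fit_hydrolysis(reps[[b]], start = object$coefficients,
                            lower = object$bounds$lower,
                            upper = object$bounds$upper,
                            fixed = object$fixed, free = object$free,
                            n_starts = 1, control = object$control)
    est[b, ] <- refit$coefficients
  }
  a <- (1 - level) / 2
  ci <- t(apply(est, 2, quantile, probs = c(a, 1 - a), names = FALSE))
  colnames(ci) <- c("lower", "upper")
  ci <- ci[parm, , drop = FALSE]
  attr(ci, "boot") <- est
  ci
}
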