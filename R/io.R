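#' Read and write time-course files
#'
#' Time courses are exchanged as plain CSV with columns `time_h`,
#' `wis_pct`, `glucose_g_per_kg`, `xylose_g_per_kg`, `ethanol_g_per_kg`,
#' `viable_cells_g_per_kg`, `e_ad_fpu_per_g` (missing observables may be
#' absent or empty) plus any extra columns a simulation adds.
#'
#' @param tc time-course data frame (e.g. `sscf_sim$timecourse` or
#'   `fit_dataset$observations`).
#' @param path file path.
#' @return `read_timecourse()` returns the validated data frame;
#'   `write_timecourse()` returns `path` invisibly.
#' @export
write_timecourse <- function(tc, path) {
  if (inherits(tc, "sscf_sim")) tc <- tc$timecourse
  write.csv(tc, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  if (!file.exists(path))
    stop("time-course file not found: ", path, call. = FALSE)
  tc <- read.csv(path)
  if (!"time_h" %in% names(tc))
    stop("time-course file lacks a time_h column: ", path, call. = FALSE)
  if (is.unsorted(tc$time_h))
    stop("time-course times must be non-decreasing: ", path, call. = FALSE)
  tc
}

schedule_frame <- function(schedule, composition = NULL) {
  if (!length(schedule))
    return(data.frame(time_h = numeric(), solid_wet_g = numeric(),
                      wis_dry_g = numeric(), enzyme_fpu = numeric(),
                      cells_g = numeric(), liquid_g = numeric()))
  data.frame(
    time_h = vapply(schedule, `[[`, 0, "time"),
    solid_wet_g = vapply(schedule, `[[`, 0, "solid_wet_mass"),
    wis_dry_g = vapply(schedule, function(e)
      if (is.null(composition)) NA_real_ else feed_dry_wis(e, composition), 0),
    enzyme_fpu = vapply(schedule, `[[`, 0, "enzyme_added"),
    cells_g = vapply(schedule, `[[`, 0, "cells_added"),
    liquid_g = vapply(schedule, `[[`, 0, "liquid_mass"))
}

#' Write a feed schedule
#'
#' @param x an `"sscf_design"` or a list of [feed_event()]s.
#' @param path output path; `.json` writes JSON (with a provenance block
#'   for designs), anything else CSV.
#' @param composition used to report the dry-WIS column.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(x, path, composition = NULL) {
  if (inherits(x, "sscf_design")) {
    if (is.null(composition)) composition <- x$composition
    events <- x$schedule
  } else events <- x
  df <- schedule_frame(events, composition)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- list(events = df)
    if (inherits(x, "sscf_design"))
      payload$provenance <- list(
        config = unclass(x$config),
        params = as.list(unclass(x$params)),
        cumulative_wis_loading_pct = x$cumulative_wis_loading_pct,
        max_wis_pct = x$max_wis_pct)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
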