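#' Exposure schedules
#'
#' An exposure schedule lists the interruption points of the segmented
#' model: each exposure has a persistent step indicator that switches on
#' at `step_date`, and optionally a slope "clock" that counts days from
#' `slope_start` (0 on the start date itself, so the step coefficient
#' alone carries the level at the peak day).
#'
#' @param label character vector of unique exposure labels.
#' @param step_date dates (ISO strings or `Date`) at which each step
#'   indicator turns on.
#' @param slope_start dates at which each slope clock starts, or `NA`
#'   for step-only exposures. Must not precede the step date.
#' @return A data.frame of class `exposure_schedule` with columns
#'   `label`, `step_date`, `slope_start`, ordered by `step_date`.
#' @export
exposure_schedule <- function(label, step_date, slope_start = NA) {
  label <- as.character(label)
  if (anyDuplicated(label)) validation_error("exposure labels must be unique")
  if (!length(label)) validation_error("schedule needs at least one exposure")
  step_date <- parse_date(as.character(step_date), "step_date")
  slope_start <- rep_len(as.character(slope_start), length(label))
  ss <- as.Date(rep(NA, length(label)))
  has <- !is.na(slope_start)
  if (any(has)) ss[has] <- parse_date(slope_start[has], "slope_start")
  if (any(has & ss < step_date)) {
    validation_error(sprintf(
      "slope_start before step_date for exposure(s): %s",
      paste(label[has & ss < step_date], collapse = ", ")
    ))
  }
  out <- data.frame(label = label, step_date = step_date,
                    slope_start = ss, stringsAsFactors = FALSE)
  out <- out[order(out$step_date, out$label), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("exposure_schedule", "data.frame")
  out
}

#' Default five-exposure COVID-19 schedule
#'
#' The built-in schedule of the five pandemic exposures used throughout:
#' the estimated start of the first wave (step 2019-12-31), the
#' human-to-human-transmission announcement / lockdown window (step
#' 2020-01-25 with a decline clock from the 2020-01-25 search peak), the
#' Beijing outbreak (step 2020-06-11, clock from the 2020-06-17 peak),
#' the Qingdao outbreak (step and clock 2020-10-12), and the
#' Shijiazhuang outbreak (step 2021-01-03, clock from 2021-01-07).
#'
#' @return An [exposure_schedule()].
#' @export
default_schedule <- function() {
  exposure_schedule(
    label = c("covid", "covid1", "covid2", "covid3", "covid4"),
    step_date = c("2019-12-31", "2020-01-25", "2020-06-11",
                  "2020-10-12", "2021-01-03"),
    slope_start = c(NA, "2020-01-25", "2020-06-17",
                    "2020-10-12", "2021-01-07")
  )
}

#' Read an exposure schedule from YAML or JSON
#'
#' The file holds a list of records with keys `label`, `step_date` and
#' optional `slope_start_date`. A missing or `NULL` path returns the
#' default five-exposure schedule.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` schedule file, or
#'   `NULL` for the default.
#' @return An [exposure_schedule()].
#' @export
read_schedule <- function(path = NULL) {
  if (is.null(path) || !nzchar(path)) return(default_schedule())
  if (!file.exists(path)) io_error(sprintf("schedule file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!length(raw)) return(default_schedule())
  lab <- vapply(raw, function(r) as.character(r$label), "")
  sd <- vapply(raw, function(r) as.character(r$step_date), "")
  ss <- vapply(raw, function(r) {
    v <- r$slope_start_date %||% r$slope_start
    if (is.null(v)) NA_character_ else as.character(v)
  }, "")
  exposure_schedule(lab, sd, ss)
}

#' @export
print.exposure_schedule <- function(x, ...) {
  cat("Exposure schedule (", nrow(x), " exposures)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
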