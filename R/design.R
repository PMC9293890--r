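#' Segment covariates for an exposure schedule
#'
#' For each date, computes the study-time clock `T` (days since
#' `study_start`, 0 on the start date), one persistent 0/1 step
#' indicator per exposure (1 from `step_date` on), and one slope clock
#' per exposure with a slope start (days since `slope_start`, 0 on the
#' start date and before).
#'
#' @param schedule an [exposure_schedule()].
#' @param dates a vector of `Date`s (or ISO strings).
#' @param study_start the study origin; must not be after the earliest
#'   date.
#' @return data.frame with columns `date`, `tdays`, `step_<label>` and
#'   `clock_<label>` (the latter only for exposures with a slope).
#' @export
build_segments <- function(schedule, dates, study_start) {
  if (!inherits(schedule, "exposure_schedule")) {
    config_error("schedule must be an exposure_schedule")
  }
  if (!length(dates)) validation_error("dates must be nonempty")
  if (!inherits(dates, "Date")) dates <- parse_date(as.character(dates))
  study_start <- stopifnot_scalar_date(study_start, "study_start")
  if (any(dates < study_start)) {
    validation_error("dates before study_start are not allowed")
  }
  out <- data.frame(date = dates, tdays = as.numeric(dates - study_start))
  for (i in seq_len(nrow(schedule))) {
    lab <- schedule$label[i]
    out[[paste0("step_", lab)]] <- as.numeric(dates >= schedule$step_date[i])
    if (!is.na(schedule$slope_start[i])) {
      out[[paste0("clock_", lab)]] <-
        pmax(0, as.numeric(dates - schedule$slope_start[i]))
    }
  }
  out
}

#' Standardize a covariate across provinces
#'
#' Z-scores with the sample (n-1) standard deviation, so one unit of
#' the standardized covariate is one SD across provinces.
#'
#' @param x numeric vector (at least two distinct values).
#' @return numeric vector with mean 0 and sample SD 1.
#' @export
standardize <- function(x) {
  x <- as.numeric(x)
  if (any(is.na(x))) validation_error("cannot standardize: missing values")
  s <- stats::sd(x)
  if (length(unique(x)) < 2L || s == 0) {
    validation_error("cannot standardize a covariate with zero variance")
  }
  (x - mean(x)) / s
}

#' Tertile categorization of a continuous province covariate
#'
#' Convenience for synthetic metadata: splits provinces into
#' low/middle/high by rank. Ties are broken by province name order.
#' `sizes` forces the group sizes (ordered low, middle, high), e.g.
#' `c(10, 13, 8)` to mirror the published 31-province grouping; the
#' default is an even tertile split.
#'
#' @param values numeric covariate per province.
#' @param provinces province names (tie-break order).
#' @param sizes optional integer triple summing to `length(values)`.
#' @return character vector of categories aligned with `values`.
#' @export
categorize_by_tertile <- function(values, provinces = NULL, sizes = NULL) {
  n <- length(values)
  if (n < 3L) validation_error("need at least 3 provinces to form tertiles")
  if (is.null(provinces)) provinces <- as.character(seq_len(n))
  if (is.null(sizes)) {
    base <- n %/% 3L; extra <- n %% 3L
    sizes <- rep(base, 3L) + c(extra >= 1L, extra >= 2L, 0L)
  }
  if (length(sizes) != 3L || sum(sizes) != n) {
    config_error("sizes must be a triple summing to the number of provinces")
  }
  ord <- order(values, provinces)
  cats <- rep(HDI_LEVELS, times = sizes)
  out <- character(n)
  out[ord] <- cats
  out
}

#' Build the fixed- and random-effects design for the segmented model
#'
#' Categorical mode reproduces the stratified segmented
#' parameterization: intercept; `hdi_middle`/`hdi_high` main effects;
#' secular trend `T` plus `T_hdi_middle`/`T_hdi_high` interactions
#' (low is the trend reference); for every exposure one step column per
#' stratum (`step_<label>_<stratum>`) and, where a slope clock exists,
#' one slope column per stratum (`slope_<label>_<stratum>`), so each
#' stratum's effect is directly estimable; 11 month-of-year dummies
#' (January reference) and 6 day-of-week dummies (Friday reference).
#' Seasonal dummy columns for calendar levels absent from the panel are
#' dropped (they would be identically zero), and stratum columns are
#' emitted only for strata present in the panel (the first present
#' level acts as reference), so single-stratum panels remain valid.
#'
#' Continuous mode replaces the stratification by a z-scored province
#' covariate `z`: main effect `z`, trend `T` and `T_z`, and per
#' exposure `step_<label>`, `step_<label>_z` (and slope analogues).
#'
#' The random-effects design has a per-province intercept and study
#' time, carried as `tdays` and the province blocking factor.
#'
#' @param panel a `search_panel`.
#' @param meta a `province_meta` covering all panel provinces.
#' @param schedule an [exposure_schedule()].
#' @param study_start study origin for `T` (default: earliest panel
#'   date).
#' @param hdi_mode `"categorical"` or one of `"continuous:hdi"`,
#'   `"continuous:gnppp"`, `"continuous:education"`,
#'   `"continuous:life_expectancy"`.
#' @return list of class `its_design`: `X` (named numeric matrix),
#'   `y` (log index), `province` (blocking factor), `tdays`, `dates`,
#'   plus the mode and schedule used.
#' @export
build_design <- function(panel, meta, schedule = default_schedule(),
                         study_start = NULL,
                         hdi_mode = "categorical") {
  panel <- search_panel(panel)
  meta <- province_meta(meta)
  miss <- setdiff(unique(panel$province), meta$province)
  if (length(miss)) {
    validation_error(sprintf("no metadata for province(s): %s",
                             paste(miss, collapse = ", ")))
  }
  study_start <- if (is.null(study_start)) min(panel$date) else
    stopifnot_scalar_date(study_start, "study_start")
  seg <- build_segments(schedule, panel$date, study_start)
  n <- nrow(panel)
  m <- match(panel$province, meta$province)

  has_slope <- !is.na(schedule$slope_start)
  month <- month_of(panel$date)
  wday <- wday_of(panel$date)

  cols <- list(`(Intercept)` = rep(1, n))
  if (identical(hdi_mode, "categorical")) {
    cat_i <- meta$hdi_category[m]
    present <- HDI_LEVELS[HDI_LEVELS %in% unique(cat_i)]
    strat <- lapply(present, function(s) as.numeric(cat_i == s))
    names(strat) <- present
    # main effects and trend interactions: first present level is the
    # reference (low, when it is in the panel)
    for (s in present[-1]) cols[[paste0("hdi_", s)]] <- strat[[s]]
    cols$T <- seg$tdays
    for (s in present[-1]) {
      cols[[paste0("T_hdi_", s)]] <- seg$tdays * strat[[s]]
    }
    for (i in seq_len(nrow(schedule))) {
      lab <- schedule$label[i]
      for (s in present) {
        cols[[paste0("step_", lab, "_", s)]] <-
          seg[[paste0("step_", lab)]] * strat[[s]]
      }
      if (has_slope[i]) {
        for (s in present) {
          cols[[paste0("slope_", lab, "_", s)]] <-
            seg[[paste0("clock_", lab)]] * strat[[s]]
        }
      }
    }
  } else if (grepl("^continuous:", hdi_mode)) {
    field <- sub("^continuous:", "", hdi_mode)
    field <- switch(field, hdi = "hdi", gnppp = "gnppp",
                    education = "education_years",
                    life_expectancy = "life_expectancy",
                    config_error(sprintf("unknown hdi_mode: %s", hdi_mode)))
    v <- meta[[field]]
    if (any(is.na(v[meta$province %in% panel$province]))) {
      validation_error(sprintf(
        "continuous mode needs '%s' for every panel province", field))
    }
    z_prov <- standardize(v)
    z <- z_prov[m]
    cols$z <- z
    cols$T <- seg$tdays
    cols$T_z <- seg$tdays * z
    for (i in seq_len(nrow(schedule))) {
      lab <- schedule$label[i]
      st <- seg[[paste0("step_", lab)]]
      cols[[paste0("step_", lab)]] <- st
      cols[[paste0("step_", lab, "_z")]] <- st * z
      if (has_slope[i]) {
        ck <- seg[[paste0("clock_", lab)]]
        cols[[paste0("slope_", lab)]] <- ck
        cols[[paste0("slope_", lab, "_z")]] <- ck * z
      }
    }
  } else {
    config_error(sprintf("unknown hdi_mode: %s", hdi_mode))
  }

  for (mm in 2:12) {
    v <- as.numeric(month == mm)
    if (any(v > 0)) cols[[paste0("month_", MONTH_LABELS[mm])]] <- v
  }
  for (dlab in DOW_NONREF) {
    v <- as.numeric(wday == DOW_LABELS[[dlab]])
    if (any(v > 0)) cols[[paste0("dow_", dlab)]] <- v
  }

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  zero <- colSums(abs(X)) == 0
  if (any(zero)) {
    validation_error(sprintf(
      "design column(s) identically zero (exposure outside the panel window?): %s",
      paste(colnames(X)[zero], collapse = ", ")))
  }
  structure(list(
    X = X, y = log(panel$index),
    province = factor(panel$province), tdays = seg$tdays,
    dates = panel$date, hdi_mode = hdi_mode, schedule = schedule,
    study_start = study_start
  ), class = "its_design")
}

#' @export
print.its_design <- function(x, ...) {
  cat("Segmented ITS design: ", nrow(x$X), " rows x ", ncol(x$X),
      " fixed-effect columns, ", nlevels(x$province), " provinces, mode=",
      x$hdi_mode, "\n", sep = "")
  invisible(x)
}
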