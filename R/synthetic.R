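#' Simulation configuration for synthetic search panels
#'
#' The generator draws a daily log-normal search index per province
#' from the same segmented model the fitter estimates:
#' `ln(Index_it) = x_it' beta + b0_i + b1_i * T_it + eps_it`, where
#' `(b0_i, b1_i) ~ N(0, G)` are province random intercepts/slopes (per
#' day), and `eps_it` is a stationary AR(1) process with marginal
#' variance `sigma2` and lag-1 correlation `rho` (innovation variance
#' `sigma2 * (1 - rho^2)`; the first day is drawn from the stationary
#' distribution, so no burn-in is needed).
#'
#' Defaults state the emulated world: 31 provinces in the published
#' 10/13/8 low/middle/high split, daily data 2017-01-01..2021-03-15,
#' the published exposure effect sizes as ground truth, mild
#' month-of-year and day-of-week cycles, `sigma2 = 0.04` (about 20%
#' day-to-day noise on the index), `rho = 0.6`, random intercept SD 0.5
#' and random slope SD 2e-4 per day (about 7.6% per year). `sigma2 = 0`
#' and `G = 0` are accepted for noise-free degenerate checks.
#'
#' @param n_provinces_per_category named counts for low/middle/high.
#' @param date_range inclusive ISO-date pair.
#' @param true_coefficients named log-scale coefficients; names must be
#'   design columns of the categorical model for `schedule`
#'   (unspecified columns are zero).
#' @param month_effects 11 log-scale offsets for Feb..Dec (January 0).
#' @param dow_effects 6 log-scale offsets in the order
#'   sat, sun, mon, tue, wed, thu (Friday 0).
#' @param sigma2 residual marginal variance (>= 0).
#' @param rho AR(1) coefficient in (-1, 1).
#' @param G 2x2 positive-semidefinite covariance of (intercept,
#'   slope-per-day) random effects.
#' @param seed integer RNG seed.
#' @param round_to_integer round indices to integers clamped at 1.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(
    n_provinces_per_category = c(low = 10, middle = 13, high = 8),
    date_range = c("2017-01-01", "2021-03-15"),
    true_coefficients = default_truth_from_table2(),
    month_effects = 0.1 * sin(2 * pi * (1:11) / 12),
    dow_effects = c(sat = -0.05, sun = -0.07, mon = 0.02, tue = 0.01,
                    wed = 0, thu = 0),
    sigma2 = 0.04, rho = 0.6,
    G = diag(c(0.25, (2e-4)^2)),
    seed = 1L, round_to_integer = FALSE) {
  n <- n_provinces_per_category
  if (!all(HDI_LEVELS %in% names(n)) || any(n[HDI_LEVELS] < 0)) {
    config_error("n_provinces_per_category needs nonnegative low/middle/high counts")
  }
  d0 <- stopifnot_scalar_date(date_range[1], "date_range start")
  d1 <- stopifnot_scalar_date(date_range[2], "date_range end")
  if (d0 >= d1) config_error("date_range start must precede end")
  if (!is.numeric(sigma2) || sigma2 < 0) config_error("sigma2 must be >= 0")
  if (!is.numeric(rho) || abs(rho) >= 1) config_error("rho must be in (-1, 1)")
  G <- as.matrix(G)
  if (!isTRUE(all.equal(G, t(G))) || any(eigen(G, symmetric = TRUE,
                                               only.values = TRUE)$values < -1e-12)) {
    config_error("G must be symmetric positive-semidefinite")
  }
  if (length(month_effects) != 11L) config_error("month_effects must have length 11 (Feb..Dec)")
  if (length(dow_effects) != 6L) config_error("dow_effects must have length 6 (non-Friday days)")
  structure(list(
    n_provinces_per_category = n[HDI_LEVELS],
    date_range = c(d0, d1),
    true_coefficients = true_coefficients,
    month_effects = as.numeric(month_effects),
    dow_effects = as.numeric(dow_effects),
    sigma2 = sigma2, rho = rho, G = G,
    seed = as.integer(seed), round_to_integer = isTRUE(round_to_integer)
  ), class = "simulation_config")
}

#' Published effect sizes as simulation ground truth
#'
#' Packages the published stratified rate ratios as log-scale
#' coefficients on the design's column naming: immediate step effects
#' as `ln(RR)`, weekly slope RRs divided back to per-day scale
#' (`ln(RR)/7`), and yearly pre-trend RRs as `ln(RR)/365` (low stratum
#' as the trend reference, interactions as differences). Baseline
#' levels (intercept and stratum mains), which the published table does
#' not report, default to log medians on the order of the descriptive
#' pre-period levels.
#'
#' @return named numeric vector of log-scale coefficients.
#' @export
default_truth_from_table2 <- function() {
  steps <- list(
    covid  = c(low = 1.41,   middle = 1.62,   high = 1.58),
    covid1 = c(low = 106.80, middle = 124.55, high = 125.31),
    covid2 = c(low = 1.91,   middle = 1.34,   high = 2.12),
    covid3 = c(low = 1.31,   middle = 1.34,   high = 1.41),
    covid4 = c(low = 2.00,   middle = 2.67,   high = 2.45)
  )
  slopes_weekly <- list(
    covid1 = c(low = 0.90, middle = 0.89, high = 0.89),
    covid2 = c(low = 0.96, middle = 1.02, high = 0.94),
    covid3 = c(low = 1.01, middle = 1.02, high = 1.02),
    covid4 = c(low = 0.83, middle = 0.80, high = 0.78)
  )
  trend_yearly <- c(low = 1.10, middle = 1.11, high = 1.13)
  out <- c(
    `(Intercept)` = log(230), hdi_middle = log(320 / 230),
    hdi_high = log(620 / 230),
    T = log(trend_yearly[["low"]]) / 365,
    T_hdi_middle = (log(trend_yearly[["middle"]]) - log(trend_yearly[["low"]])) / 365,
    T_hdi_high = (log(trend_yearly[["high"]]) - log(trend_yearly[["low"]])) / 365
  )
  for (lab in names(steps)) {
    v <- log(steps[[lab]])
    names(v) <- paste0("step_", lab, "_", names(v))
    out <- c(out, v)
  }
  for (lab in names(slopes_weekly)) {
    v <- log(slopes_weekly[[lab]]) / 7
    names(v) <- paste0("slope_", lab, "_", names(v))
    out <- c(out, v)
  }
  out
}

#' Default 31-province metadata
#'
#' The 31 mainland provinces with the published low/middle/high
#' grouping (10/13/8). The continuous columns (`hdi`, `gnppp`,
#' `education_years`, `life_expectancy`) are SYNTHETIC placeholders —
#' the source tables do not print per-province values — chosen to
#' increase strictly from the low to the high category so continuous
#' and categorical analyses are directionally consistent. Override
#' from a metadata CSV for real analyses.
#'
#' @return a `province_meta` in published table order (grouped low,
#'   middle, high).
#' @export
make_default_metadata <- function() {
  low <- c("Tibet", "Yunnan", "Guizhou", "Gansu", "Qinghai", "Xinjiang",
           "Guangxi", "Sichuan", "Anhui", "Ningxia")
  middle <- c("Jiangxi", "Henan", "Hebei", "Hunan", "Shanxi", "Hainan",
              "Chongqing", "Heilongjiang", "Shaanxi", "Hubei", "Fujian",
              "Inner Mongolia", "Jilin")
  high <- c("Shandong", "Guangdong", "Liaoning", "Zhejiang", "Jiangsu",
            "Tianjin", "Shanghai", "Beijing")
  province_meta(data.frame(
    province = c(low, middle, high),
    hdi_category = rep(HDI_LEVELS, times = c(10, 13, 8)),
    hdi = c(0.630 + 0.004 * (0:9), 0.700 + 0.005 * (0:12), 0.780 + 0.009 * (0:7)),
    gnppp = c(35000 + 1500 * (0:9), 55000 + 2500 * (0:12), 90000 + 6000 * (0:7)),
    education_years = c(7.5 + 0.1 * (0:9), 9.0 + 0.1 * (0:12), 10.5 + 0.2 * (0:7)),
    life_expectancy = c(70 + 0.3 * (0:9), 73.5 + 0.25 * (0:12), 77 + 0.4 * (0:7))
  ))
}

#' Simulate a provincial daily search-index panel
#'
#' Draws one panel from the generative model described in
#' [simulation_config()]: per selected province, random effects
#' `(b0, b1) ~ N(0, G)`, a stationary AR(1) log-scale residual series,
#' and the deterministic segmented mean built with [build_design()]
#' from the supplied schedule. Provinces are processed in alphabetical
#' order so identical seeds give bit-identical panels.
#'
#' @param config a [simulation_config()].
#' @param schedule an [exposure_schedule()] (default: the five-exposure
#'   schedule).
#' @param meta a `province_meta`; the first requested number of
#'   provinces per category (in metadata order) is used.
#' @return list with `panel` (a `search_panel`) and `truth`
#'   (per-province realized random effects, the full coefficient
#'   vector, and the seed).
#' @export
simulate_panel <- function(config, schedule = default_schedule(),
                           meta = make_default_metadata()) {
  if (!inherits(config, "simulation_config")) {
    config_error("config must come from simulation_config()")
  }
  meta <- province_meta(meta)
  pick <- unlist(lapply(HDI_LEVELS, function(s) {
    idx <- which(meta$hdi_category == s)
    need <- config$n_provinces_per_category[[s]]
    if (length(idx) < need) {
      config_error(sprintf("metadata has %d '%s' provinces; %d requested",
                           length(idx), s, need))
    }
    idx[seq_len(need)]
  }), use.names = FALSE)
  meta <- meta[pick, , drop = FALSE]
  class(meta) <- c("province_meta", "data.frame")
  provinces <- sort(meta$province)  # alphabetical draw order
  dates <- seq(config$date_range[1], config$date_range[2], by = "day")
  nd <- length(dates)

  skeleton <- search_panel(data.frame(
    province = rep(provinces, each = nd),
    date = rep(dates, times = length(provinces)),
    index = 1
  ))
  des <- build_design(skeleton, meta, schedule,
                      study_start = config$date_range[1])
  beta <- numeric(ncol(des$X))
  names(beta) <- colnames(des$X)
  tc <- config$true_coefficients
  unknown <- setdiff(names(tc), names(beta))
  if (length(unknown)) {
    config_error(sprintf(
      "true_coefficients name(s) not in the design for this schedule: %s",
      paste(unknown, collapse = ", ")))
  }
  beta[names(tc)] <- tc
  mcols <- paste0("month_", MONTH_LABELS[2:12])
  pres <- mcols %in% names(beta)
  beta[mcols[pres]] <- config$month_effects[pres]
  dcols <- paste0("dow_", DOW_NONREF)
  pres <- dcols %in% names(beta)
  beta[dcols[pres]] <- config$dow_effects[pres]

  lp <- drop(des$X %*% beta)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  # random effects: factor G = F F' (eigen handles the PSD/zero cases)
  eg <- eigen(config$G, symmetric = TRUE)
  Fm <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), 2)
  b <- t(Fm %*% matrix(stats::rnorm(2 * length(provinces)), 2))
  colnames(b) <- c("b0", "b1")

  sd_e <- sqrt(config$sigma2)
  rho <- config$rho
  log_index <- numeric(length(provinces) * nd)
  for (k in seq_along(provinces)) {
    rows <- ((k - 1) * nd + 1):(k * nd)
    eps <- stats::rnorm(nd)
    if (nd > 1) {
      innov_sd <- sqrt(1 - rho^2)
      eps[1] <- eps[1]
      for (t in 2:nd) eps[t] <- rho * eps[t - 1] + innov_sd * eps[t]
    }
    eps <- sd_e * eps
    log_index[rows] <- lp[rows] + b[k, 1] + b[k, 2] * des$tdays[rows] + eps
  }
  idx <- exp(log_index)
  if (config$round_to_integer) idx <- pmax(1, round(idx))

  panel <- search_panel(data.frame(
    province = skeleton$province, date = skeleton$date, index = idx))
  truth <- list(
    random_effects = data.frame(province = provinces, b0 = b[, 1], b1 = b[, 2]),
    coefficients = beta, seed = config$seed,
    sigma2 = config$sigma2, rho = rho, G = config$G
  )
  list(panel = panel, truth = truth)
}

#' Read a simulation configuration from YAML
#'
#' Recognized keys mirror the [simulation_config()] arguments;
#' `true_coefficients` is a mapping from coefficient name to value and
#' `G` a 2x2 nested list. Missing keys fall back to the defaults.
#'
#' @param path YAML file.
#' @return a `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) io_error(sprintf("config not found: %s", path))
  raw <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(raw$n_provinces_per_category)) {
    args$n_provinces_per_category <- unlist(raw$n_provinces_per_category)
  }
  if (!is.null(raw$date_range)) args$date_range <- unlist(raw$date_range)
  if (!is.null(raw$true_coefficients)) {
    args$true_coefficients <- unlist(raw$true_coefficients)
  }
  for (key in c("month_effects", "dow_effects", "sigma2", "rho", "seed",
                "round_to_integer")) {
    if (!is.null(raw[[key]])) args[[key]] <- unlist(raw[[key]])
  }
  if (!is.null(raw$G)) args$G <- matrix(unlist(raw$G), 2, 2, byrow = TRUE)
  do.call(simulation_config, args)
}
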