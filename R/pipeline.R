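#' Run configuration for the end-to-end pipeline
#'
#' @param panel path to a panel CSV, or `NULL` to simulate one.
#' @param meta path to a metadata CSV, or `NULL` for the built-in
#'   31-province metadata.
#' @param schedule path to a schedule YAML/JSON, or `NULL` for the
#'   default five-exposure schedule.
#' @param out_dir output directory (created if missing).
#' @param hdi_mode stratification mode, as in [build_design()].
#' @param method `"ml"` or `"reml"`.
#' @param seed integer seed (used for simulation when `panel` is
#'   `NULL`).
#' @param sim optional [simulation_config()] overriding the default
#'   simulated world.
#' @param study_window inclusive ISO-date pair for reading panels.
#' @param trend_timescale,slope_timescale reporting scales for
#'   [effects_table()].
#' @param alpha Holm family-wise error rate.
#' @param n_starts,fit_control optimizer settings for [fit_lnlmm()].
#' @return a validated `run_config` list.
#' @export
run_config <- function(panel = NULL, meta = NULL, schedule = NULL,
                       out_dir = "its_out", hdi_mode = "categorical",
                       method = "ml", seed = 1L, sim = NULL,
                       study_window = DEFAULT_STUDY_WINDOW,
                       trend_timescale = "per_year",
                       slope_timescale = "per_week", alpha = 0.05,
                       n_starts = 3, fit_control = list()) {
  if (!is_count(abs(seed) + 1)) config_error("seed must be an integer")
  paths <- c(panel, meta, schedule)
  if (length(paths) && anyDuplicated(paths)) {
    config_error("input paths must be distinct")
  }
  structure(list(
    panel = panel, meta = meta, schedule = schedule, out_dir = out_dir,
    hdi_mode = hdi_mode, method = method, seed = as.integer(seed),
    sim = sim, study_window = study_window,
    trend_timescale = trend_timescale, slope_timescale = slope_timescale,
    alpha = alpha, n_starts = n_starts, fit_control = fit_control
  ), class = "run_config")
}

#' Run the full pipeline
#'
#' Simulate (or read) a panel, compute the descriptive table, fit the
#' segmented AR(1) log-normal mixed model, summarize effects, and write
#' all artifacts to `out_dir`: `descriptives.csv`,
#' `model_coefficients.csv`, `model_effects.csv`, `model_fit.json`,
#' `effects.md`, `run.log`, and (when simulating) `panel.csv` plus
#' `truth.json`. Identical config and seed give identical artifacts.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the fitted objects and artifact
#'   paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  logline <- function(...) {
    cat(sprintf(...), "\n", sep = "", file = logf, append = TRUE)
  }
  cat("", file = logf)
  logline("searchits %s | seed %d | mode %s | method %s",
          as.character(utils::packageVersion("searchits")),
          config$seed, config$hdi_mode, config$method)

  schedule <- read_schedule(config$schedule)
  truth <- NULL
  if (is.null(config$panel)) {
    sim_cfg <- config$sim %||% simulation_config(seed = config$seed)
    meta <- if (is.null(config$meta)) make_default_metadata() else
      read_metadata(config$meta)
    sim <- simulate_panel(sim_cfg, schedule, meta)
    panel <- sim$panel
    truth <- sim$truth
    meta <- meta[meta$province %in% panel$province, , drop = FALSE]
    class(meta) <- c("province_meta", "data.frame")
    write_panel(panel, file.path(config$out_dir, "panel.csv"))
    jsonlite::write_json(list(
      coefficients = as.list(truth$coefficients),
      random_effects = truth$random_effects,
      sigma2 = truth$sigma2, rho = truth$rho, G = truth$G,
      seed = truth$seed
    ), file.path(config$out_dir, "truth.json"), auto_unbox = TRUE,
    digits = NA)
    logline("simulated panel: %d provinces x %d days",
            length(unique(panel$province)), length(unique(panel$date)))
  } else {
    panel <- read_panel(config$panel, config$study_window)
    meta <- if (is.null(config$meta)) make_default_metadata() else
      read_metadata(config$meta)
    logline("read panel: %d rows", nrow(panel))
  }

  desc <- descriptives_table(panel, meta)
  data.table::fwrite(desc, file.path(config$out_dir, "descriptives.csv"))

  design <- build_design(panel, meta, schedule,
                         study_start = min(panel$date),
                         hdi_mode = config$hdi_mode)
  fit <- fit_model(design, method = config$method,
                   n_starts = config$n_starts,
                   control = config$fit_control)
  logline("fit: converged=%s logLik=%.3f AIC=%.3f BIC=%.3f rho=%.3f sigma2=%.5f",
          fit$converged, fit$loglik, fit$aic, fit$bic, fit$vc$rho,
          fit$vc$sigma2)

  effects <- NULL
  if (identical(config$hdi_mode, "categorical")) {
    effects <- effects_table(fit, config$trend_timescale,
                             config$slope_timescale, config$alpha,
                             include_trend = TRUE)
    writeLines(render_effects_md(effects),
               file.path(config$out_dir, "effects.md"))
  } else {
    fams <- c("trend", schedule$label)
    effects <- do.call(rbind, c(
      lapply(fams, function(lab) {
        per_sd_contrast(fit, lab,
                        type = if (lab == "trend") "trend" else "step",
                        timescale = config$slope_timescale)
      }),
      lapply(schedule$label[!is.na(schedule$slope_start)], function(lab) {
        per_sd_contrast(fit, lab, type = "slope",
                        timescale = config$slope_timescale)
      })))
    names(effects)[names(effects) == "ratio_rr"] <- "rr"
    effects$stratum <- effects$stratum_num
  }
  paths <- write_results(fit, effects,
                         file.path(config$out_dir, "model"))
  logline("artifacts written to %s", config$out_dir)
  invisible(list(panel = panel, meta = meta, truth = truth, fit = fit,
                 descriptives = desc, effects = effects,
                 paths = c(paths,
                           descriptives = file.path(config$out_dir,
                                                    "descriptives.csv"),
                           log = logf)))
}

#' Reduced-scale simulation preset for recovery experiments
#'
#' The stated world of the parameter-recovery harness: 9 provinces (3
#' per stratum), daily data 2019-01-01..2021-03-15, `sigma2 = 0.04`,
#' `rho = 0.6`, small random effects (intercept SD 0.1, slope SD 5e-5
#' per day), and the published effect sizes as ground truth.
#'
#' @param seed integer seed.
#' @return a [simulation_config()].
#' @export
recovery_config <- function(seed = 1L) {
  simulation_config(
    n_provinces_per_category = c(low = 3, middle = 3, high = 3),
    date_range = c("2019-01-01", "2021-03-15"),
    sigma2 = 0.04, rho = 0.6,
    G = diag(c(0.01, (5e-5)^2)),
    seed = seed
  )
}

#' Parameter-recovery experiment
#'
#' Simulates `n_replicates` panels from a known-truth configuration,
#' fits the full model to each, and reports per coefficient the truth,
#' mean estimate, bias, and empirical 95% Wald CI coverage across
#' replicates. Non-convergent replicates are excluded and counted.
#'
#' @param n_replicates number of replicates (>= 1).
#' @param seeds integer seeds, one per replicate (default
#'   `1:n_replicates`).
#' @param config_fn function(seed) returning a [simulation_config()];
#'   default [recovery_config()].
#' @param schedule exposure schedule (default five-exposure).
#' @param meta metadata (default built-in).
#' @param method,n_starts,control passed to the fitter.
#' @return list: `table` (data.frame coefficient, truth, mean_estimate,
#'   bias, coverage), `n_converged`, `n_excluded`, `fits` (the fit
#'   objects).
#' @export
recovery_experiment <- function(n_replicates = 5, seeds = NULL,
                                config_fn = recovery_config,
                                schedule = default_schedule(),
                                meta = make_default_metadata(),
                                method = "ml", n_starts = 3,
                                control = list()) {
  if (n_replicates < 1) config_error("n_replicates must be >= 1")
  seeds <- seeds %||% seq_len(n_replicates)
  fits <- list(); truths <- list()
  for (k in seq_len(n_replicates)) {
    cfg <- config_fn(seeds[k])
    sim <- simulate_panel(cfg, schedule, meta)
    sel <- meta[meta$province %in% sim$panel$province, , drop = FALSE]
    class(sel) <- c("province_meta", "data.frame")
    design <- build_design(sim$panel, sel, schedule,
                           study_start = cfg$date_range[1])
    fit <- fit_model(design, method = method, n_starts = n_starts,
                     control = control)
    fits[[k]] <- fit
    truths[[k]] <- sim$truth$coefficients
  }
  ok <- vapply(fits, `[[`, TRUE, "converged")
  used <- which(ok)
  if (!length(used)) config_error("no replicate converged")
  cn <- names(truths[[1]])
  est <- sapply(used, function(k) fits[[k]]$beta[cn])
  se <- sapply(used, function(k) sqrt(diag(fits[[k]]$cov_beta))[cn])
  truth <- truths[[1]][cn]
  z <- z975()
  cover <- rowMeans(abs(est - truth) <= z * se)
  tab <- data.frame(
    coefficient = cn, truth = unname(truth),
    mean_estimate = unname(rowMeans(est)),
    bias = unname(rowMeans(est) - truth),
    coverage = unname(cover)
  )
  list(table = tab, n_converged = sum(ok), n_excluded = sum(!ok),
       fits = fits)
}
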