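#' Search-index panels and province metadata
#'
#' A search panel is a long-format data.frame with one row per province
#' and day: columns `province` (character), `date` (`Date`) and `index`
#' (strictly positive numeric, so its logarithm exists). Metadata holds
#' one row per province with its socioeconomic stratum (`hdi_category`
#' in low/middle/high) and optional continuous indicators (`hdi`,
#' `gnppp`, `education_years`, `life_expectancy`).
#'
#' @name panel_io
NULL

DEFAULT_STUDY_WINDOW <- c("2017-01-01", "2021-03-15")

#' Validate a long-format search panel
#'
#' @param df data.frame with columns `province`, `date`, `index`.
#' @return the validated panel (class `search_panel`), sorted by
#'   province then date.
#' @export
search_panel <- function(df) {
  need <- c("province", "date", "index")
  if (!all(need %in% names(df))) {
    format_error(sprintf("panel must have columns %s", paste(need, collapse = ", ")))
  }
  df <- as.data.frame(df)[need]
  df$province <- as.character(df$province)
  if (!inherits(df$date, "Date")) df$date <- parse_date(as.character(df$date))
  df$index <- as.numeric(df$index)
  bad <- !is.finite(df$index) | df$index <= 0
  if (any(bad)) {
    validation_error(sprintf(
      "index must be strictly positive; offending rows e.g. %s",
      paste(utils::head(sprintf("%s/%s=%s", df$province[bad],
                                format(df$date[bad]), df$index[bad]), 5L),
            collapse = "; ")
    ), rows = which(bad))
  }
  key <- paste(df$province, df$date)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    validation_error(sprintf("duplicate (province, date) pairs: %s",
                             paste(utils::head(dup, 5L), collapse = "; ")))
  }
  df <- df[order(df$province, df$date), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("search_panel", "data.frame")
  df
}

#' Read a search panel from CSV
#'
#' Expects header `province,date,index` with ISO-8601 dates. Rows
#' outside the study window are dropped with a message; nonpositive
#' index values and duplicate (province, date) pairs are validation
#' errors.
#'
#' @param path CSV path.
#' @param study_window inclusive ISO-date pair; defaults to the
#'   2017-01-01..2021-03-15 study period.
#' @return a `search_panel`.
#' @export
read_panel <- function(path, study_window = DEFAULT_STUDY_WINDOW) {
  if (!file.exists(path)) io_error(sprintf("panel not found: %s", path))
  df <- data.table::fread(path, colClasses = list(character = "province"),
                          data.table = FALSE)
  if (!all(c("province", "date", "index") %in% names(df))) {
    format_error("panel CSV must have header province,date,index")
  }
  df$date <- parse_date(as.character(df$date))
  w <- c(stopifnot_scalar_date(study_window[1], "study window start"),
         stopifnot_scalar_date(study_window[2], "study window end"))
  inside <- df$date >= w[1] & df$date <= w[2]
  if (any(!inside)) {
    message(sum(!inside), " row(s) outside study window ",
            format(w[1]), "..", format(w[2]), " dropped")
    df <- df[inside, , drop = FALSE]
  }
  search_panel(df)
}

#' Write a search panel to CSV
#' @param panel a `search_panel`.
#' @param path output CSV path.
#' @export
write_panel <- function(panel, path) {
  out <- data.frame(province = panel$province,
                    date = format(panel$date, "%Y-%m-%d"),
                    index = panel$index)
  data.table::fwrite(out, path)
  invisible(path)
}

#' Validate province metadata
#'
#' @param df data.frame with columns `province`, `hdi_category` and
#'   optionally `hdi`, `gnppp`, `education_years`, `life_expectancy`.
#' @return class `province_meta` data.frame keyed by province.
#' @export
province_meta <- function(df) {
  if (!all(c("province", "hdi_category") %in% names(df))) {
    format_error("metadata must have columns province and hdi_category")
  }
  df <- as.data.frame(df)
  df$province <- as.character(df$province)
  if (anyDuplicated(df$province)) {
    validation_error(sprintf("province repeated in metadata: %s",
                             paste(unique(df$province[duplicated(df$province)]),
                                   collapse = ", ")))
  }
  df$hdi_category <- tolower(trimws(as.character(df$hdi_category)))
  bad <- !df$hdi_category %in% HDI_LEVELS
  if (any(bad)) {
    validation_error(sprintf("unknown hdi_category label(s): %s",
                             paste(unique(df$hdi_category[bad]), collapse = ", ")))
  }
  for (col in c("hdi", "gnppp", "education_years", "life_expectancy")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
    df[[col]] <- as.numeric(df[[col]])
  }
  df <- df[c("province", "hdi", "hdi_category", "gnppp",
             "education_years", "life_expectancy")]
  rownames(df) <- NULL
  class(df) <- c("province_meta", "data.frame")
  df
}

#' Read province metadata from CSV
#'
#' Header `province,hdi,hdi_category,gnppp,education_years,life_expectancy`
#' (continuous columns optional). Category labels are normalized to
#' lower case.
#'
#' @param path CSV path.
#' @return a `province_meta`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) io_error(sprintf("metadata not found: %s", path))
  df <- data.table::fread(path, data.table = FALSE)
  province_meta(df)
}

#' Write province metadata to CSV
#' @param meta a `province_meta`.
#' @param path output CSV path.
#' @export
write_metadata <- function(meta, path) {
  data.table::fwrite(as.data.frame(meta), path)
  invisible(path)
}

#' Write fit and effects results
#'
#' Writes three artifacts: `<stem>_coefficients.csv` (coefficient,
#' estimate, SE), `<stem>_effects.csv` (label, stratum, timescale, rr,
#' ci_low, ci_high, p, holm_significant) and `<stem>_fit.json`
#' (variance components, log-likelihood, AIC/BIC, convergence).
#'
#' @param fit an `its_fit` from [fit_lnlmm()].
#' @param effects an effects table from [effects_table()] (may have
#'   zero rows).
#' @param stem output path stem (directory must exist).
#' @return invisibly, the three paths written.
#' @export
write_results <- function(fit, effects, stem) {
  dir <- dirname(stem)
  if (!dir.exists(dir)) io_error(sprintf("output directory not found: %s", dir))
  p_coef <- paste0(stem, "_coefficients.csv")
  p_eff <- paste0(stem, "_effects.csv")
  p_fit <- paste0(stem, "_fit.json")
  se <- sqrt(diag(fit$cov_beta))
  coef_df <- data.frame(coefficient = names(fit$beta),
                        estimate = unname(fit$beta), se = se)
  # 15 significant digits so a CSV round-trip reproduces values
  data.table::fwrite(format_sig(coef_df, c("estimate", "se")), p_coef)
  eff <- as.data.frame(effects)
  keep <- c("label", "stratum", "timescale", "rr", "ci_low", "ci_high",
            "p", "holm_significant")
  keep <- keep[keep %in% names(eff)]
  data.table::fwrite(format_sig(eff[keep],
                                intersect(c("rr", "ci_low", "ci_high", "p"),
                                          keep)), p_eff)
  jsonlite::write_json(list(
    sigma2 = fit$vc$sigma2, rho = fit$vc$rho, G = fit$vc$G,
    loglik = fit$loglik, aic = fit$aic, bic = fit$bic,
    n_obs = fit$n_obs, n_params = fit$n_params,
    method = fit$method, converged = fit$converged
  ), p_fit, auto_unbox = TRUE, digits = NA)
  invisible(c(coefficients = p_coef, effects = p_eff, fit = p_fit))
}

format_sig <- function(df, cols) {
  for (col in cols) df[[col]] <- formatC(df[[col]], digits = 15, format = "g")
  df
}
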