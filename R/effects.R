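#' Effect summaries on the rate-ratio scale
#'
#' Fitted coefficients of the log-scale model are reported as rate
#' ratios: `RR = exp(beta)` for immediate level changes, and
#' `RR = exp(k * beta_day)` for slopes at a reporting timescale of `k`
#' days (week 7, month 30, year 365). Contrasts between strata are
#' ratios of RRs, `exp(beta_num - beta_ref)`, with the Wald variance of
#' the difference taken from the full fixed-effect covariance.
#'
#' @name effects
NULL

TIMESCALE_DAYS <- c(per_day = 1, per_week = 7, per_month = 30, per_year = 365)

z975 <- function() stats::qnorm(0.975)

wald_rr <- function(est, se, k = 1) {
  z <- z975()
  p <- if (se == 0) {
    if (est == 0) 1 else 0
  } else {
    2 * stats::pnorm(-abs(est / se))
  }
  data.frame(rr = exp(k * est), ci_low = exp(k * (est - z * se)),
             ci_high = exp(k * (est + z * se)), p = p)
}

# Weight vector over fit$beta for an effect; trend uses the reference
# parameterization (low = T, middle/high add their interaction).
effect_weights <- function(fit, label, stratum, type) {
  w <- numeric(length(fit$beta))
  names(w) <- names(fit$beta)
  pick <- function(nm) {
    if (!nm %in% names(w)) {
      validation_error(sprintf("coefficient '%s' not in fit", nm))
    }
    nm
  }
  if (type == "trend") {
    w[pick("T")] <- 1
    if (stratum != "low") w[pick(paste0("T_hdi_", stratum))] <- 1
  } else {
    w[pick(paste0(type, "_", label, "_", stratum))] <- 1
  }
  w
}

combo_est <- function(fit, w) {
  est <- sum(w * fit$beta)
  se <- sqrt(drop(t(w) %*% fit$cov_beta %*% w))
  c(est = est, se = se)
}

check_categorical <- function(fit) {
  if (!identical(fit$hdi_mode %||% "categorical", "categorical")) {
    config_error("this summary needs a categorical-mode fit")
  }
}

#' Immediate level-change rate ratio
#'
#' @param fit a categorical-mode `its_fit`.
#' @param exposure exposure label (e.g. `"covid"`).
#' @param stratum `"low"`, `"middle"` or `"high"`.
#' @return one-row data.frame: label, stratum, timescale, rr, ci_low,
#'   ci_high, p.
#' @export
level_change_rr <- function(fit, exposure, stratum) {
  check_categorical(fit)
  es <- combo_est(fit, effect_weights(fit, exposure, stratum, "step"))
  cbind(data.frame(label = exposure, stratum = stratum,
                   timescale = "immediate"),
        wald_rr(es["est"], es["se"]))
}

#' Slope (trend-change) rate ratio at a reporting timescale
#'
#' @param fit a categorical-mode `its_fit`.
#' @param segment exposure label with a slope clock, or `"trend"` for
#'   the pre-pandemic secular trend.
#' @param stratum `"low"`, `"middle"` or `"high"`.
#' @param timescale one of `"per_day"`, `"per_week"`, `"per_month"`,
#'   `"per_year"`.
#' @return one-row data.frame as in [level_change_rr()].
#' @export
slope_rr <- function(fit, segment, stratum, timescale = "per_week") {
  check_categorical(fit)
  if (!timescale %in% names(TIMESCALE_DAYS)) {
    config_error(sprintf("unknown timescale: %s", timescale))
  }
  k <- TIMESCALE_DAYS[[timescale]]
  type <- if (identical(segment, "trend")) "trend" else "slope"
  es <- combo_est(fit, effect_weights(fit, segment, stratum, type))
  cbind(data.frame(label = segment, stratum = stratum, timescale = timescale),
        wald_rr(es["est"], es["se"], k))
}

#' Ratio of rate ratios between two strata
#'
#' Tests whether an effect differs between strata:
#' `exp(k * (beta_num - beta_ref))` with the Wald SE of the difference
#' using the full coefficient covariance.
#'
#' @param fit a categorical-mode `its_fit`.
#' @param label exposure label or `"trend"`.
#' @param stratum_num numerator stratum.
#' @param stratum_ref reference stratum (default `"low"`).
#' @param type `"step"`, `"slope"` or `"trend"` (inferred as `"step"`
#'   for exposures and `"trend"` for `label = "trend"` when omitted).
#' @param timescale reporting timescale for slopes/trends (ignored for
#'   steps).
#' @return one-row data.frame: label, type, stratum_num, stratum_ref,
#'   timescale, ratio_rr, ci_low, ci_high, p.
#' @export
ratio_of_rr <- function(fit, label, stratum_num, stratum_ref = "low",
                        type = NULL, timescale = "per_week") {
  check_categorical(fit)
  if (identical(stratum_num, stratum_ref)) {
    config_error("numerator and reference strata are identical")
  }
  type <- type %||% if (identical(label, "trend")) "trend" else "step"
  k <- if (type == "step") 1 else TIMESCALE_DAYS[[timescale]]
  w <- effect_weights(fit, label, stratum_num, type) -
    effect_weights(fit, label, stratum_ref, type)
  es <- combo_est(fit, w)
  wr <- wald_rr(es["est"], es["se"], k)
  data.frame(label = label, type = type, stratum_num = stratum_num,
             stratum_ref = stratum_ref,
             timescale = if (type == "step") "immediate" else timescale,
             ratio_rr = wr$rr, ci_low = wr$ci_low, ci_high = wr$ci_high,
             p = wr$p)
}

#' Point-estimate ratio of two rate ratios
#'
#' The arithmetic identity `exp(ln RR_num - ln RR_ref) = RR_num /
#' RR_ref`, useful for checking published contrast columns from the
#' published stratum RRs.
#'
#' @param rr_num,rr_ref positive rate ratios.
#' @return their ratio.
#' @export
rr_ratio <- function(rr_num, rr_ref) {
  if (any(c(rr_num, rr_ref) <= 0)) config_error("rate ratios must be positive")
  exp(log(rr_num) - log(rr_ref))
}

#' Per-SD contrast from a continuous-mode fit
#'
#' In continuous mode the stratification is replaced by a z-scored
#' province covariate, so the interaction coefficient is the log ratio
#' of RRs between two provinces one standard deviation apart:
#' `ratio = exp(k * beta_z)` (SD = 1 after standardization).
#'
#' @param fit a continuous-mode `its_fit`.
#' @param label exposure label or `"trend"`.
#' @param type `"step"`, `"slope"` or `"trend"`.
#' @param timescale reporting timescale for slopes/trends.
#' @return one-row data.frame as in [ratio_of_rr()] with
#'   `stratum_num = "+1 SD"`.
#' @export
per_sd_contrast <- function(fit, label, type = NULL,
                            timescale = "per_week") {
  if (!grepl("^continuous:", fit$hdi_mode %||% "")) {
    config_error("per_sd_contrast needs a continuous-mode fit")
  }
  type <- type %||% if (identical(label, "trend")) "trend" else "step"
  nm <- switch(type,
               trend = "T_z",
               step = paste0("step_", label, "_z"),
               slope = paste0("slope_", label, "_z"),
               config_error("type must be step, slope or trend"))
  if (!nm %in% names(fit$beta)) {
    validation_error(sprintf("coefficient '%s' not in fit", nm))
  }
  k <- if (type == "step") 1 else TIMESCALE_DAYS[[timescale]]
  w <- numeric(length(fit$beta)); names(w) <- names(fit$beta); w[nm] <- 1
  es <- combo_est(fit, w)
  wr <- wald_rr(es["est"], es["se"], k)
  data.frame(label = label, type = type, stratum_num = "+1 SD",
             stratum_ref = "mean",
             timescale = if (type == "step") "immediate" else timescale,
             ratio_rr = wr$rr, ci_low = wr$ci_low, ci_high = wr$ci_high,
             p = wr$p)
}

#' Holm-Bonferroni step-down adjustment
#'
#' P-values are ranked ascending; the test at rank `r` of `m` is
#' compared to `alpha / (m - r + 1)` and rejection proceeds until the
#' first failure, so the rejection set is always a prefix of the sorted
#' order and contains the plain Bonferroni set.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param ids optional test identifiers.
#' @param alpha family-wise error rate (default 0.05).
#' @return data.frame (sorted by p): id, p, rank, threshold, reject.
#' @export
holm_bonferroni <- function(p, ids = NULL, alpha = 0.05) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    validation_error("p-values must be in [0, 1]")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    config_error("alpha must be in (0, 1)")
  }
  m <- length(p)
  ids <- ids %||% as.character(seq_len(m))
  ord <- order(p)
  thr <- alpha / (m - seq_len(m) + 1)
  ps <- p[ord]
  pass <- ps <= thr
  reject <- cumall(pass)
  data.frame(id = ids[ord], p = ps, rank = seq_len(m), threshold = thr,
             reject = reject, stringsAsFactors = FALSE)
}

cumall <- function(x) {
  out <- logical(length(x))
  ok <- TRUE
  for (i in seq_along(x)) {
    ok <- ok && x[i]
    out[i] <- ok
  }
  out
}

#' Full stratified effects report
#'
#' One row per (effect family x stratum): for every exposure in the
#' fit's schedule, its immediate step and (where present) post-peak
#' slope — with the default five-exposure schedule that is 9 families x
#' 3 strata = 27 effect rows and 18 contrasts. `include_trend = TRUE`
#' prepends the pre-pandemic secular trend family. Middle/high rows
#' carry the ratio-of-RR contrast against the low stratum;
#' Holm-Bonferroni flags are computed over the declared family
#' (default: all contrast tests in the run).
#'
#' @param fit a categorical-mode `its_fit` from [fit_model()].
#' @param trend_timescale reporting scale for the secular trend
#'   (default `"per_year"`).
#' @param slope_timescale reporting scale for post-peak slopes
#'   (default `"per_week"`).
#' @param alpha family-wise error rate for the Holm adjustment.
#' @param include_trend also report the pre-pandemic trend family.
#' @return data.frame of class `effects_table`.
#' @export
effects_table <- function(fit, trend_timescale = "per_year",
                          slope_timescale = "per_week", alpha = 0.05,
                          include_trend = FALSE) {
  check_categorical(fit)
  schedule <- fit$schedule
  if (is.null(schedule)) config_error("fit carries no schedule; use fit_model()")
  fams <- if (include_trend) {
    list(list(label = "trend", type = "trend", timescale = trend_timescale))
  } else {
    list()
  }
  for (i in seq_len(nrow(schedule))) {
    lab <- schedule$label[i]
    fams <- c(fams, list(list(label = lab, type = "step",
                              timescale = "immediate")))
    if (!is.na(schedule$slope_start[i])) {
      fams <- c(fams, list(list(label = lab, type = "slope",
                                timescale = slope_timescale)))
    }
  }
  rows <- list(); contrasts <- list()
  for (f in fams) {
    for (s in HDI_LEVELS) {
      est <- if (f$type == "step") {
        level_change_rr(fit, f$label, s)
      } else {
        slope_rr(fit, f$label, s, f$timescale)
      }
      est$type <- f$type
      rows[[length(rows) + 1L]] <- est
      if (s != "low") {
        ct <- ratio_of_rr(fit, f$label, s, "low", type = f$type,
                          timescale = f$timescale)
        ct$key <- paste(f$label, f$type, s, sep = ":")
        contrasts[[length(contrasts) + 1L]] <- ct
      }
    }
  }
  eff <- do.call(rbind, rows)
  ctr <- do.call(rbind, contrasts)
  holm <- holm_bonferroni(ctr$p, ids = ctr$key, alpha = alpha)
  ctr$holm_significant <- holm$reject[match(ctr$key, holm$id)]
  key <- paste(eff$label, eff$type, eff$stratum, sep = ":")
  mi <- match(key, ctr$key)
  eff$ratio_rr <- ctr$ratio_rr[mi]
  eff$ratio_ci_low <- ctr$ci_low[mi]
  eff$ratio_ci_high <- ctr$ci_high[mi]
  eff$ratio_p <- ctr$p[mi]
  eff$holm_significant <- ctr$holm_significant[mi]
  rownames(eff) <- NULL
  class(eff) <- c("effects_table", "data.frame")
  eff
}

format_p <- function(p) ifelse(p < 1e-4, "<0.0001", sprintf("%.4f", p))

#' Render an effects table as Markdown
#'
#' A compact Markdown rendering in the published style: one block per
#' effect family, RR (95% CI) and p per stratum, ratio-of-RR columns
#' against the low stratum, p-values floored at `<0.0001`.
#'
#' @param effects an `effects_table`.
#' @return character vector of Markdown lines.
#' @export
render_effects_md <- function(effects) {
  lines <- c("| Effect | Stratum | RR (95% CI) | p | Ratio of RR (95% CI) | p | Holm sig. |",
             "|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(effects))) {
    r <- effects[i, ]
    rrc <- sprintf("%.2f (%.2f, %.2f)", r$rr, r$ci_low, r$ci_high)
    ratio <- if (is.na(r$ratio_rr)) "Reference" else
      sprintf("%.2f (%.2f, %.2f)", r$ratio_rr, r$ratio_ci_low, r$ratio_ci_high)
    rp <- if (is.na(r$ratio_p)) "" else format_p(r$ratio_p)
    hs <- if (is.na(r$holm_significant)) "" else
      ifelse(r$holm_significant, "yes", "no")
    lines <- c(lines, sprintf(
      "| %s (%s, %s) | %s | %s | %s | %s | %s | %s |",
      r$label, r$type, r$timescale, r$stratum, rrc, format_p(r$p),
      ratio, rp, hs))
  }
  lines
}

#' @export
print.effects_table <- function(x, ...) {
  need <- c("label", "type", "timescale", "stratum", "rr", "ci_low",
            "ci_high", "p", "ratio_rr", "ratio_p", "holm_significant")
  if (all(need %in% names(x))) {
    cat(render_effects_md(x), sep = "\n")
  } else {
    print.data.frame(x, ...)
  }
  invisible(x)
}
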