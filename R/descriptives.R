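#' Descriptive pre/post comparison of the search index
#'
#' Reproduces the descriptive table: per-province and national medians
#' and interquartile ranges for the pre-outbreak period (through
#' 2019-12-30) and the outbreak period (from 2019-12-31), plus the
#' crude relative change in medians.
#'
#' @name descriptives
NULL

#' Split a panel at the outbreak boundary
#'
#' @param panel a `search_panel`.
#' @param pre_end last day of the pre period (default 2019-12-30).
#' @param post_start first day of the post period (default 2019-12-31).
#' @return list with `pre` and `post` panels (disjoint, exhaustive for
#'   rows up to any later window end).
#' @export
split_periods <- function(panel, pre_end = "2019-12-30",
                          post_start = "2019-12-31") {
  panel <- search_panel(panel)
  pre_end <- stopifnot_scalar_date(pre_end, "pre_end")
  post_start <- stopifnot_scalar_date(post_start, "post_start")
  list(pre = panel[panel$date <= pre_end, , drop = FALSE],
       post = panel[panel$date >= post_start, , drop = FALSE])
}

#' Median and interquartile range
#'
#' Linear-interpolation quantiles (the standard type-7 convention);
#' IQR is Q3 - Q1.
#'
#' @param values nonempty numeric vector.
#' @return named vector `c(median, iqr)`.
#' @export
median_iqr <- function(values) {
  if (!length(values)) validation_error("median_iqr of empty vector")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(median = q[2], iqr = q[3] - q[1])
}

#' Crude relative change in medians, in percent
#'
#' `round(100 * (post/pre - 1))`, half away from zero.
#'
#' @param pre_median pre-period median (> 0).
#' @param post_median post-period median.
#' @return integer percent change.
#' @export
relative_change <- function(pre_median, post_median) {
  if (any(pre_median <= 0)) validation_error("pre-period median must be > 0")
  as.integer(round_half_away(100 * (post_median / pre_median - 1)))
}

#' Province-level and national descriptive table
#'
#' One row per province, grouped by stratum in metadata order (low,
#' middle, high), plus a national row computed on the day-wise sum of
#' the index across provinces (the natural aggregate of a volume
#' index).
#'
#' @param panel a `search_panel`.
#' @param meta a `province_meta` covering the panel's provinces; row
#'   order within stratum is preserved.
#' @param pre_end,post_start period boundary, as in [split_periods()].
#' @return data.frame: province, hdi_category, pre_median, pre_iqr,
#'   post_median, post_iqr, relative_change_pct.
#' @export
descriptives_table <- function(panel, meta, pre_end = "2019-12-30",
                               post_start = "2019-12-31") {
  panel <- search_panel(panel)
  meta <- province_meta(meta)
  sp <- split_periods(panel, pre_end, post_start)
  provs <- meta$province[meta$province %in% panel$province]
  provs <- provs[order(match(meta$hdi_category[match(provs, meta$province)],
                             HDI_LEVELS))]
  one <- function(prov, cat) {
    pre <- median_iqr(sp$pre$index[sp$pre$province == prov])
    post <- median_iqr(sp$post$index[sp$post$province == prov])
    data.frame(province = prov, hdi_category = cat,
               pre_median = pre["median"], pre_iqr = pre["iqr"],
               post_median = post["median"], post_iqr = post["iqr"],
               relative_change_pct = relative_change(pre["median"],
                                                     post["median"]))
  }
  rows <- lapply(provs, function(p) {
    one(p, meta$hdi_category[match(p, meta$province)])
  })
  nat_pre <- stats::aggregate(index ~ date, data = sp$pre, FUN = sum)
  nat_post <- stats::aggregate(index ~ date, data = sp$post, FUN = sum)
  pre <- median_iqr(nat_pre$index); post <- median_iqr(nat_post$index)
  rows[[length(rows) + 1L]] <- data.frame(
    province = "national", hdi_category = "all",
    pre_median = pre["median"], pre_iqr = pre["iqr"],
    post_median = post["median"], post_iqr = post["iqr"],
    relative_change_pct = relative_change(pre["median"], post["median"]))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
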