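# Internal helpers: classed conditions, date handling, rounding.

its_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "its_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

validation_error <- function(message, ...) its_error("its_validation_error", message, ...)
config_error <- function(message, ...) its_error("its_config_error", message, ...)
format_error <- function(message, ...) its_error("its_format_error", message, ...)
io_error <- function(message, ...) its_error("its_io_error", message, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Strict ISO date parsing: NA in, or unparseable, is a format error.
parse_date <- function(x, what = "date") {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- is.na(d) & !is.na(x)
  bad <- bad | is.na(x)
  if (any(bad)) {
    format_error(sprintf(
      "unparseable %s value(s): %s", what,
      paste(utils::head(unique(as.character(x)[bad]), 5L), collapse = ", ")
    ))
  }
  d
}

# Month-of-year (1..12) and day-of-week (0=Sunday..6) without locale dependence.
month_of <- function(d) as.POSIXlt(d)$mon + 1L
wday_of <- function(d) as.POSIXlt(d)$wday

MONTH_LABELS <- c("jan", "feb", "mar", "apr", "may", "jun",
                  "jul", "aug", "sep", "oct", "nov", "dec")
# Order used for dummy columns; Friday (wday 5) is the reference level.
DOW_LABELS <- c(sun = 0L, mon = 1L, tue = 2L, wed = 3L, thu = 4L,
                fri = 5L, sat = 6L)
DOW_NONREF <- c("sat", "sun", "mon", "tue", "wed", "thu")

HDI_LEVELS <- c("low", "middle", "high")

# Round half away from zero (printed tables use this, not banker's rounding).
round_half_away <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x) && x >= 1

stopifnot_scalar_date <- function(x, what) {
  d <- tryCatch(parse_date(as.character(x), what), error = function(e) NULL)
  if (is.null(d) || length(d) != 1L) format_error(sprintf("%s must be a single ISO date", what))
  d
}
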