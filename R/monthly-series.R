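# Monthly abundance series.
#
# A series lives on a strictly consecutive monthly grid; gaps are explicit NA
# entries, never silently dropped months. We reuse the base `ts`
# representation (frequency 12) so `stats::cycle()` gives calendar months and
# `window()`/`time()` behave as users expect.

#' Construct a monthly abundance time series
#'
#' @param values numeric vector of abundances (cells per litre), one per
#'   consecutive month; `NA` marks a missing month.
#' @param start length-2 integer vector `c(year, month)` of the first entry.
#' @param allow_negative logical; abundances must be non-negative, but
#'   derived series (surrogates, residual diagnostics) may go below zero.
#' @return A `ts` object with frequency 12.
#' @examples
#' monthly_series(c(10, 20, NA, 40), start = c(1992, 10))
#' @export
monthly_series <- function(values, start = c(1, 1), allow_negative = FALSE) {
  if (!is.numeric(values)) stop("invalid value: abundances must be numeric")
  if (length(start) != 2L || start[2] < 1 || start[2] > 12) {
    stop("broken grid: start must be c(year, month)")
  }
  if (!allow_negative && any(values < 0, na.rm = TRUE)) {
    stop("invalid value: negative abundance")
  }
  stats::ts(as.numeric(values), start = as.integer(start), frequency = 12)
}

#' Coerce to a monthly series
#'
#' Accepts a frequency-12 `ts` or a plain numeric vector (assigned a
#' nominal grid starting January of year 1).
#'
#' @param x numeric vector or monthly `ts`.
#' @return A `ts` with frequency 12.
#' @export
as_monthly_series <- function(x) {
  if (stats::is.ts(x)) {
    if (stats::frequency(x) != 12) stop("broken grid: series must be monthly")
    return(x)
  }
  if (is.numeric(x)) {
    return(stats::ts(as.numeric(x), start = c(1, 1), frequency = 12))
  }
  stop("invalid value: cannot interpret as a monthly series")
}

#' Calendar month (1 = January) of each entry
#' @param x monthly series.
#' @return Integer vector of calendar months.
#' @keywords internal
calendar_month <- function(x) as.integer(stats::cycle(as_monthly_series(x)))

# "1992-10"-style labels for a grid of n months starting at `start`.
month_labels <- function(start, n) {
  year <- start[1] + (start[2] - 1 + seq_len(n) - 1) %/% 12
  mon <- (start[2] - 1 + seq_len(n) - 1) %% 12 + 1
  sprintf("%04d-%02d", year, mon)
}

# Inverse of month_labels for a single label; NULL if unparseable.
parse_month_label <- function(label) {
  m <- regmatches(label, regexec("^([0-9]{4})-([0-9]{2})$", label))[[1]]
  if (length(m) != 3L) return(NULL)
  c(as.integer(m[2]), as.integer(m[3]))
}

# Months elapsed between two c(year, month) stamps.
month_index <- function(ym) ym[1] * 12L + (ym[2] - 1L)
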