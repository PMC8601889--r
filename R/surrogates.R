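# Seasonal-climatology surrogates.
#
# The null hypothesis: observed forecast skill reflects nothing beyond the
# repeating seasonal cycle. A surrogate keeps each calendar month's mean but
# destroys anomaly dynamics by shuffling residuals across the whole series.

#' Climatological seasonal cycle of a monthly series
#'
#' Averages all observations of each calendar month (all Januaries, all
#' Februaries, ...) across years.
#'
#' @param series monthly series.
#' @return Object of class `"climatology"`: list with `monthly_means`
#'   (length 12, January first) and `counts` (observations per calendar
#'   month).
#' @export
seasonal_climatology <- function(series) {
  x <- as_monthly_series(series)
  v <- as.numeric(x)
  mon <- calendar_month(x)
  counts <- vapply(1:12, function(m) sum(!is.na(v[mon == m])), integer(1))
  if (any(counts == 0L)) {
    stop(sprintf("undefined climatology month: %s",
                 paste(month.abb[counts == 0L], collapse = ", ")))
  }
  means <- vapply(1:12, function(m) mean(v[mon == m], na.rm = TRUE), double(1))
  names(means) <- names(counts) <- month.abb
  structure(list(monthly_means = means, counts = counts),
            class = "climatology")
}

#' @export
print.climatology <- function(x, ...) {
  cat("seasonal climatology (cells/L):\n")
  print(round(x$monthly_means, 3))
  invisible(x)
}

#' Build one seasonal surrogate series
#'
#' Subtracts the climatology to obtain residuals (anomalies), permutes the
#' residuals uniformly without replacement across all observed months, and
#' adds them back onto the tiled climatology. Missing months stay missing,
#' so surrogate and original share identical support. The residual multiset
#' is conserved exactly; surrogate values can dip below zero when a large
#' negative anomaly lands on a lean month.
#'
#' @param series monthly series.
#' @param climatology optional precomputed [seasonal_climatology()].
#' @param rng_seed integer seed for the permutation.
#' @return A monthly `ts` on the same grid as `series`.
#' @export
make_surrogate <- function(series, climatology = NULL, rng_seed = 1L) {
  x <- as_monthly_series(series)
  if (is.null(climatology)) climatology <- seasonal_climatology(x)
  v <- as.numeric(x)
  clim <- climatology$monthly_means[calendar_month(x)]
  obs <- which(!is.na(v))
  resid <- v[obs] - clim[obs]
  perm <- with_seed(rng_seed, sample.int(length(obs)))
  out <- rep(NA_real_, length(v))
  out[obs] <- clim[obs] + resid[perm]
  stats::ts(out, start = stats::start(x), frequency = 12)
}

#' Seasonality-only forecast skill (surrogate null)
#'
#' Generates `n_surrogates` surrogate series (independent sub-seeds derived
#' from `rng_seed`, so surrogate `i` is regenerable in isolation), runs
#' [select_embedding()] on each, and summarises the null skill
#' distribution. Surrogates on which the forecast is undefined (for example
#' zero variance in the targets) are recorded as failed and excluded from
#' the mean.
#'
#' @param series monthly series.
#' @param n_surrogates number of surrogate series (study design: 100).
#' @param config an [embedding_config()].
#' @param rng_seed master seed.
#' @return List with `mean_rho`, `rhos` (per surrogate, `NA` where failed),
#'   `n_failed`, and `seeds` (the derived sub-seeds).
#' @export
surrogate_skill <- function(series, n_surrogates = 100L,
                            config = embedding_config(), rng_seed = 1L) {
  n_surrogates <- as.integer(n_surrogates)
  if (n_surrogates < 1L) stop("invalid value: n_surrogates must be >= 1")
  x <- as_monthly_series(series)
  clim <- seasonal_climatology(x)
  seeds <- vapply(seq_len(n_surrogates), function(i) derive_subseed(rng_seed, i),
                  integer(1))
  rhos <- vapply(seeds, function(s) {
    surr <- make_surrogate(x, climatology = clim, rng_seed = s)
    tryCatch(select_embedding(surr, config)$rho,
             error = function(e) NA_real_)
  }, double(1))
  list(mean_rho = mean(rhos, na.rm = TRUE), rhos = rhos,
       n_failed = sum(is.na(rhos)), seeds = seeds)
}
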