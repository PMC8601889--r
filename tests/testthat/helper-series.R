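# Toy series builders shared across tests.

# Seasonal sine lifted to [0, 2A], optional Gaussian noise.
seasonal_sine <- function(n = 240, phase = 0, A = 1, noise_sd = 0,
                          seed = NULL) {
  t <- seq_len(n)
  x <- A * sin(2 * pi * t / 12 + phase) + A
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    x <- pmax(x + rnorm(n, 0, noise_sd), 0)
  }
  monthly_series(x)
}

# Seasonal cycle plus AR(1) anomalies (positive autocorrelation =
# genuinely forecastable dynamics beyond seasonality).
seasonal_ar1 <- function(n = 240, phi = 0.8, innov_sd = 0.3, seed = 1) {
  set.seed(seed)
  anom <- as.numeric(stats::arima.sim(list(ar = phi), n, sd = innov_sd))
  stats::ts(sin(2 * pi * seq_len(n) / 12) + 1 + anom, start = c(1, 1),
            frequency = 12)
}

# Tiny hand-checkable community table.
toy_table <- function(abund = rbind(a = c(1, 2, 3), b = c(4, 5, 6)),
                      groups = c("diatom", "dinoflagellate"),
                      radii = c(3, 10), start = c(2000, 1)) {
  community_table(abund,
                  data.frame(taxon_id = rownames(abund),
                             functional_group = groups,
                             cell_radius_um = radii,
                             stringsAsFactors = FALSE),
                  start = start)
}

# Lag-k autocorrelation as an aligned correlation (unbiased by series
# length, unlike stats::acf's divisor-n estimator).
lag_cor <- function(v, k) {
  v <- as.numeric(v); n <- length(v)
  stats::cor(v[1:(n - k)], v[(k + 1):n], use = "complete.obs")
}
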