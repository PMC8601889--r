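# Delay embedding of a univariate series.

#' Embedding and forecast configuration
#'
#' Bundles the knobs of the univariate simplex analysis: the range of
#' embedding dimensions scanned, the lag, and the prediction horizon.
#' The neighbour count follows the classic `E + 1` simplex rule and is not
#' configurable.
#'
#' @param E_min,E_max integer range of embedding dimensions scanned
#'   (defaults 1 and 10).
#' @param tau lag between embedding coordinates, in months (default 1).
#' @param tp prediction horizon in months (default 1).
#' @return An object of class `"embedding_config"`.
#' @export
embedding_config <- function(E_min = 1L, E_max = 10L, tau = 1L, tp = 1L) {
  E_min <- as.integer(E_min); E_max <- as.integer(E_max)
  tau <- as.integer(tau); tp <- as.integer(tp)
  if (E_min < 1L || E_max < E_min) stop("invalid dimension: need 1 <= E_min <= E_max")
  if (tau < 1L) stop("invalid dimension: tau must be >= 1")
  if (tp < 1L) stop("invalid dimension: tp must be >= 1")
  structure(list(E_min = E_min, E_max = E_max, tau = tau, tp = tp),
            class = "embedding_config")
}

# All lag vectors, one row per month t (row t = (x_t, x_{t-tau}, ...,
# x_{t-(E-1)tau})); rows whose lags fall before the series start, or that
# touch a missing month, contain NA. Internal: keeps row/time alignment.
embedding_matrix <- function(v, E, tau) {
  n <- length(v)
  out <- matrix(NA_real_, nrow = n, ncol = E)
  for (j in seq_len(E)) {
    shift <- (j - 1L) * tau
    if (shift < n) out[(shift + 1L):n, j] <- v[seq_len(n - shift)]
  }
  out
}

#' Lagged delay embedding of a monthly series
#'
#' Reconstructs state-space points `(x_t, x_{t-tau}, ..., x_{t-(E-1)tau})`
#' for every month `t` at which all `E` coordinates are observed. Points
#' touching a missing month are omitted (no interpolation).
#'
#' @param series monthly series (see [as_monthly_series()]).
#' @param E embedding dimension (number of lags), `E >= 1`.
#' @param tau lag in months.
#' @return A numeric matrix with `E` columns `lag0, lag1, ...`; row names
#'   give the month index `t` (1-based position in the series) of each point.
#' @examples
#' lagged_embedding(c(1, 2, 3, 4), E = 2)
#' @export
lagged_embedding <- function(series, E, tau = 1L) {
  v <- as.numeric(as_monthly_series(series))
  E <- as.integer(E); tau <- as.integer(tau)
  if (E < 1L) stop("invalid dimension: E must be >= 1")
  if (length(v) < E * tau + 1L) stop("insufficient length")
  m <- embedding_matrix(v, E, tau)
  keep <- which(stats::complete.cases(m))
  out <- m[keep, , drop = FALSE]
  dimnames(out) <- list(as.character(keep), paste0("lag", seq_len(E) - 1L))
  out
}
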