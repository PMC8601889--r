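# Simplex projection with leave-one-out cross-validation.
#
# Forecasts are distance-weighted averages of the forward trajectories of the
# E + 1 nearest neighbours in the delay-embedded state space. Skill is the
# raw Pearson correlation between observations and predictions; it is NOT
# clamped at zero, so poor forecasts can report negative skill and averaging
# over Monte-Carlo trials stays unbiased.

#' One-step simplex forecast at a fixed embedding dimension
#'
#' For every embedding point whose `tp`-ahead target is observed, predicts
#' the target from the `E + 1` nearest neighbours (Euclidean distance in the
#' embedding space) among all *other* points with observed targets
#' (leave-one-out). Neighbour weights are `exp(-d / d_min)` with `d_min` the
#' distance to the closest neighbour. When exact duplicates of the target
#' pattern exist (`d_min = 0`) every duplicate is kept with weight 1 — the
#' neighbour set may then exceed `E + 1` — and any remaining neighbours are
#' weighted `exp(-d / d~)` with `d~` the smallest nonzero selected distance.
#'
#' @param series monthly series.
#' @param E embedding dimension.
#' @param config an [embedding_config()] (supplies `tau` and `tp`).
#' @return An object of class `"simplex_result"`: list with elements
#'   `E`, `rho` (Pearson skill, may be negative), `n_pairs`, and `pairs`
#'   (data frame `time` — month index of the predicted value — `observed`,
#'   `predicted`).
#' @seealso [select_embedding()] for scanning E.
#' @export
simplex_forecast <- function(series, E, config = embedding_config()) {
  E <- as.integer(E)
  if (E < 1L) stop("invalid dimension: E must be >= 1")
  v <- as.numeric(as_monthly_series(series))
  tau <- config$tau; tp <- config$tp
  n <- length(v)
  if (n < E * tau + 1L) stop("insufficient length")

  emb <- embedding_matrix(v, E, tau)
  target <- c(v[(tp + 1L):n], rep(NA_real_, tp))
  usable <- stats::complete.cases(emb) & !is.na(target)
  idx <- which(usable)
  # each target needs E + 1 leave-one-out neighbours => E + 2 usable points
  if (length(idx) < E + 2L) stop("insufficient predictions")

  M <- emb[idx, , drop = FALSE]
  y <- target[idx]
  D <- as.matrix(stats::dist(M))
  k <- E + 1L
  preds <- vapply(seq_along(idx), function(i) {
    d <- D[i, -i]
    ord <- order(d)                 # ties resolved by time order (stable)
    sel <- ord[seq_len(k)]
    if (d[sel[1L]] > 0) {
      w <- exp(-d[sel] / d[sel[1L]])
    } else {
      zero <- which(d == 0)         # all exact duplicates join the simplex
      if (length(zero) < k) {
        nz <- ord[!(ord %in% zero)]
        sel <- c(zero, nz[seq_len(k - length(zero))])
      } else {
        sel <- zero
      }
      dsel <- d[sel]
      w <- rep(1, length(sel))
      if (any(dsel > 0)) {
        dtilde <- min(dsel[dsel > 0])
        w[dsel > 0] <- exp(-dsel[dsel > 0] / dtilde)
      }
    }
    sum(w * y[-i][sel]) / sum(w)
  }, double(1))

  if (stats::sd(y) == 0) stop("undefined correlation")
  rho <- stats::cor(y, preds)
  if (!is.finite(rho)) stop("undefined correlation")
  structure(list(E = E, rho = rho, n_pairs = length(idx),
                 pairs = data.frame(time = idx + tp, observed = y,
                                    predicted = preds)),
            class = "simplex_result")
}

#' @export
print.simplex_result <- function(x, ...) {
  cat(sprintf("simplex forecast: E = %d, rho = %.4f, n pairs = %d\n",
              x$E, x$rho, x$n_pairs))
  invisible(x)
}

#' Select the embedding dimension maximising prediction skill
#'
#' Runs [simplex_forecast()] for every feasible `E` in
#' `config$E_min : config$E_max` and returns the result with the highest
#' Pearson skill. Near-ties (within 1e-9) resolve toward the smallest `E`.
#' Dimensions that are infeasible on this series (too short, too few
#' complete lag vectors) are skipped.
#'
#' @inheritParams simplex_forecast
#' @return A `"simplex_result"` for the optimal `E`.
#' @export
select_embedding <- function(series, config = embedding_config()) {
  series <- as_monthly_series(series)
  candidates <- list()
  for (E in config$E_min:config$E_max) {
    r <- tryCatch(simplex_forecast(series, E, config),
                  error = function(e) e)
    if (!inherits(r, "error")) candidates[[length(candidates) + 1L]] <- r
  }
  if (length(candidates) == 0L) stop("series unusable")
  rhos <- vapply(candidates, `[[`, double(1), "rho")
  best <- which(rhos >= max(rhos) - 1e-9)[1L]
  candidates[[best]]
}
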