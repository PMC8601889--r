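# Independent brute-force simplex oracle: explicit loops, full pairwise
# distance enumeration, explicit sort. Shares no code with the package
# implementation; used to pin down neighbour sets and predictions.

oracle_simplex <- function(v, E, tau = 1, tp = 1) {
  n <- length(v)
  pts <- list()
  for (t in seq_len(n)) {
    lags <- t - (0:(E - 1)) * tau
    if (min(lags) >= 1 && !anyNA(v[lags]) &&
        t + tp <= n && !is.na(v[t + tp])) {
      pts[[length(pts) + 1]] <- list(t = t, coord = v[lags], target = v[t + tp])
    }
  }
  if (length(pts) < E + 2) stop("oracle: too few points")
  obs <- pred <- times <- numeric(0)
  for (i in seq_along(pts)) {
    d <- tgt <- numeric(0)
    for (j in seq_along(pts)) {
      if (j == i) next
      acc <- 0                       # scalar double accumulation
      for (k in seq_len(E)) acc <- acc + (pts[[i]]$coord[k] - pts[[j]]$coord[k])^2
      d <- c(d, sqrt(acc))
      tgt <- c(tgt, pts[[j]]$target)
    }
    ord <- order(d)
    k <- E + 1
    if (d[ord[1]] > 0) {
      sel <- ord[1:k]
      w <- exp(-d[sel] / d[sel[1]])
    } else {
      zero <- which(d == 0)
      sel <- if (length(zero) >= k) zero else
        c(zero, setdiff(ord, zero)[seq_len(k - length(zero))])
      w <- rep(1, length(sel))
      nz <- d[sel] > 0
      if (any(nz)) w[nz] <- exp(-d[sel][nz] / min(d[sel][nz]))
    }
    obs <- c(obs, pts[[i]]$target)
    pred <- c(pred, sum(w * tgt[sel]) / sum(w))
    times <- c(times, pts[[i]]$t + tp)
  }
  list(time = times, observed = obs, predicted = pred,
       rho = stats::cor(obs, pred))
}
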