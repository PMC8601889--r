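# Monte-Carlo assemblage experiments: sampling strategies, predictability
# curves across assemblage size, and the exclusion filters used to test
# whether a few dominant taxa drive the aggregation benefit.

# Resolve a strategy string to the vector of candidate taxon ids.
# Strategies: "random"; "functional_group:<g>" with g one of diatom,
# dinoflagellate, coccolithophore, phytoflagellate; "size_class:<c>" with c
# one of small (<5 um), medium (5-12 um, bounds inclusive), large (>12 um).
strategy_pool <- function(table, strategy) {
  md <- table$metadata
  if (identical(strategy, "random")) return(md$taxon_id)
  parts <- strsplit(strategy, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("invalid strategy")
  kind <- parts[1]; arg <- parts[2]
  if (kind == "functional_group") {
    # "other" is a singleton catch-all, never a groupable category
    if (!arg %in% setdiff(FUNCTIONAL_GROUPS, "other")) stop("invalid strategy")
    return(md$taxon_id[md$functional_group == arg])
  }
  if (kind == "size_class") {
    r <- md$cell_radius_um
    pool <- switch(arg,
                   small = md$taxon_id[r < 5],
                   medium = md$taxon_id[r >= 5 & r <= 12],
                   large = md$taxon_id[r > 12],
                   stop("invalid strategy"))
    return(pool)
  }
  stop("invalid strategy")
}

#' Draw random assemblages of a given size
#'
#' Each trial draws `size` distinct taxa uniformly without replacement from
#' the strategy's candidate pool, so every pool member has equal inclusion
#' probability. Trials are independent; combinations may repeat across
#' trials. Trial `i` at size `s` uses the sub-seed
#' `derive_subseed(rng_seed, s, i)` and is regenerable in isolation.
#'
#' @param table a [community_table()].
#' @param size number of member taxa per assemblage.
#' @param n_trials number of independent draws.
#' @param strategy `"random"`, `"functional_group:<group>"`, or
#'   `"size_class:<small|medium|large>"` (small < 5 um; medium 5-12 um,
#'   bounds inclusive; large > 12 um).
#' @param rng_seed master seed.
#' @return List of `"assemblage"` objects, one per trial.
#' @export
sample_assemblages <- function(table, size, n_trials, strategy = "random",
                               rng_seed = 1L) {
  size <- as.integer(size)
  pool <- strategy_pool(table, strategy)
  if (size < 1L) stop("empty assemblage")
  if (size > length(pool)) stop("pool exhausted")
  lapply(seq_len(n_trials), function(i) {
    members <- with_seed(derive_subseed(rng_seed, size, i),
                         sample(pool, size))
    aggregate_taxa(table, members)
  })
}

#' Predictability as a function of assemblage size
#'
#' For each assemblage size: draw `n_trials` random assemblages under the
#' strategy, forecast each aggregate with [select_embedding()], and
#' summarise the skill distribution as mean rho with `se = sd / sqrt(n)`
#' and a 95% CI half-width of `1.96 * se`. Optionally runs the seasonal
#' surrogate null ([surrogate_skill()]) on every trial aggregate. Trials on
#' which the forecast is undefined are excluded from the summaries and
#' counted in `n_failed`.
#'
#' @param table a [community_table()].
#' @param sizes integer vector of assemblage sizes.
#' @param n_trials Monte-Carlo trials per size (study design: 1000).
#' @param n_surrogates surrogates per trial (study design: 100); 0 disables
#'   the null comparison.
#' @param strategy see [sample_assemblages()].
#' @param config an [embedding_config()].
#' @param rng_seed master seed; trial sub-seeds derive from (seed, size,
#'   trial) and surrogate sub-seeds from (seed, size, trial, 1).
#' @return Data frame (one row per size) with columns `size`, `strategy`,
#'   `n_trials`, `mean_rho`, `se`, `ci95_half_width`, `mean_surrogate_rho`
#'   (`NA` when disabled) and `n_failed`.
#' @export
predictability_curve <- function(table, sizes, n_trials = 1000L,
                                 n_surrogates = 0L, strategy = "random",
                                 config = embedding_config(), rng_seed = 1L) {
  rows <- lapply(sizes, function(size) {
    trials <- sample_assemblages(table, size, n_trials, strategy, rng_seed)
    rhos <- vapply(trials, function(a) {
      tryCatch(select_embedding(a$series, config)$rho,
               error = function(e) NA_real_)
    }, double(1))
    surr <- NA_real_
    if (n_surrogates > 0L) {
      srhos <- vapply(seq_along(trials), function(i) {
        if (is.na(rhos[i])) return(NA_real_)
        surrogate_skill(trials[[i]]$series, n_surrogates, config,
                        rng_seed = derive_subseed(rng_seed, size, i, 1L))$mean_rho
      }, double(1))
      surr <- mean(srhos, na.rm = TRUE)
    }
    ok <- rhos[!is.na(rhos)]
    if (length(ok) == 0L) {
      return(data.frame(size = size, strategy = strategy, n_trials = n_trials,
                        mean_rho = NA_real_, se = NA_real_,
                        ci95_half_width = NA_real_,
                        mean_surrogate_rho = surr,
                        n_failed = n_trials, valid = FALSE))
    }
    se <- if (length(ok) > 1L) stats::sd(ok) / sqrt(length(ok)) else 0
    data.frame(size = size, strategy = strategy, n_trials = n_trials,
               mean_rho = mean(ok), se = se, ci95_half_width = 1.96 * se,
               mean_surrogate_rho = surr,
               n_failed = n_trials - length(ok), valid = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Remove the most abundant or most predictable taxa
#'
#' Ranks taxa by mean abundance over observed months
#' (`criterion = "abundance"`) or by univariate simplex skill
#' (`criterion = "predictability"`), and removes the top
#' `ceiling(fraction * N)`. Ranking ties break by taxon id; taxa whose
#' skill is undefined rank last (never removed).
#'
#' @param table a [community_table()].
#' @param criterion `"abundance"` or `"predictability"`.
#' @param fraction fraction removed, in (0, 1); the study's design point is
#'   0.25.
#' @param config an [embedding_config()] (used for `"predictability"`).
#' @return The filtered [community_table()].
#' @export
exclusion_filter <- function(table, criterion = c("abundance", "predictability"),
                             fraction = 0.25, config = embedding_config()) {
  criterion <- match.arg(criterion)
  if (!(fraction > 0 && fraction < 1)) stop("invalid value: fraction in (0,1)")
  N <- n_taxa(table)
  n_drop <- ceiling(fraction * N)
  if (n_drop >= N) stop("filter too aggressive")
  ids <- rownames(table$abundance)
  score <- if (criterion == "abundance") {
    apply(table$abundance, 1L, mean, na.rm = TRUE)
  } else {
    vapply(ids, function(id) {
      tryCatch(select_embedding(taxon_series(table, id), config)$rho,
               error = function(e) -Inf)
    }, double(1))
  }
  ord <- order(-score, ids)
  keep <- ids[!(ids %in% ids[ord[seq_len(n_drop)]])]
  subset_taxa(table, keep)
}
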