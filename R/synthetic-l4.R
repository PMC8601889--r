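# Synthetic community generator.
#
# Emulates the *shape* of a long-term coastal monitoring phytoplankton
# dataset — 198 taxa in fixed functional-group and size-class proportions,
# a 267-month grid (Oct 1992 - Dec 2014) with 10 shared missing months,
# recurrent annual blooms of varying timing and sharpness, lognormally
# spread abundance scales, and multiplicative noise — without reproducing
# any real taxon or abundance value. Everything is drawn from a seed; no
# data files are involved.

#' Configuration of the synthetic community generator
#'
#' Defaults mirror the monitored community's composition: 198 taxa split
#' 130/37/16/14/1 across diatoms, dinoflagellates, coccolithophores,
#' phytoflagellates and a singleton "other"; cell-size classes (radius
#' < 5 um, 5-12 um, > 12 um) holding 68/63/67 taxa overall and 44/40/46
#' within the diatoms; 267 consecutive months of which 10 (shared across
#' all taxa) are missing.
#'
#' @param n_taxa total taxa.
#' @param group_counts named counts per functional group (must sum to
#'   `n_taxa`).
#' @param size_class_counts named counts per size class, all taxa.
#' @param diatom_size_counts named counts per size class within diatoms.
#' @param start first month, `c(year, month)`.
#' @param n_months grid length.
#' @param n_missing_months number of shared missing months.
#' @param log10_scale_range range of log10 mean-abundance scales across
#'   taxa (default 1..5: four decades, cells per litre).
#' @param noise_sd_range range of per-taxon lognormal noise sd (log scale).
#' @param bloom_sharpness_range range of the bloom concentration parameter
#'   (higher = sharper annual bloom).
#' @return Object of class `"synthetic_l4_config"`.
#' @export
synthetic_l4_config <- function(n_taxa = 198L,
                                group_counts = c(diatom = 130L,
                                                 dinoflagellate = 37L,
                                                 coccolithophore = 16L,
                                                 phytoflagellate = 14L,
                                                 other = 1L),
                                size_class_counts = c(small = 68L, medium = 63L,
                                                      large = 67L),
                                diatom_size_counts = c(small = 44L, medium = 40L,
                                                       large = 46L),
                                start = c(1992L, 10L), n_months = 267L,
                                n_missing_months = 10L,
                                log10_scale_range = c(1, 5),
                                noise_sd_range = c(0.4, 1.2),
                                bloom_sharpness_range = c(1, 4)) {
  if (sum(group_counts) != n_taxa) stop("invalid value: group counts must sum to n_taxa")
  if (sum(size_class_counts) != n_taxa) stop("invalid value: size counts must sum to n_taxa")
  if (sum(diatom_size_counts) != group_counts[["diatom"]]) {
    stop("invalid value: diatom size counts must sum to the diatom count")
  }
  if (any(diatom_size_counts > size_class_counts)) {
    stop("invalid value: diatom size counts exceed class totals")
  }
  if (n_missing_months >= n_months) stop("invalid value: too many missing months")
  structure(list(n_taxa = as.integer(n_taxa), group_counts = group_counts,
                 size_class_counts = size_class_counts,
                 diatom_size_counts = diatom_size_counts,
                 start = as.integer(start), n_months = as.integer(n_months),
                 n_missing_months = as.integer(n_missing_months),
                 log10_scale_range = log10_scale_range,
                 noise_sd_range = noise_sd_range,
                 bloom_sharpness_range = bloom_sharpness_range),
            class = "synthetic_l4_config")
}

# Radius intervals backing the size classes (um).
SIZE_CLASS_BOUNDS <- list(small = c(0.5, 5), medium = c(5, 12), large = c(12, 30))

# von-Mises-style annual bloom shape, peak value 1 at `peak` (month of
# year, continuous), sharpness kappa.
bloom_shape <- function(month_of_year, peak, kappa) {
  exp(kappa * (cos(2 * pi * (month_of_year - peak) / 12) - 1))
}

# Bloom timing: wrapped normal around a late-spring mode. Temperate coastal
# blooms are seasonally coherent (spring/early-summer, a few autumn
# bloomers), not uniform over the year; coherence is what lets an
# aggregate retain a seasonal signal. Consumes RNG.
draw_bloom_peaks <- function(n, mode = 5, sd = 2) {
  (mode + stats::rnorm(n, 0, sd)) %% 12
}

#' Generate a synthetic community table
#'
#' Assigns each taxon a functional group and a cell radius consistent with
#' the configured size-class counts (diatom counts honoured exactly; the
#' remaining classes are distributed over the other groups), a log-uniform
#' abundance scale, a bloom month and sharpness, and a per-taxon
#' multiplicative lognormal noise level. The same `n_missing_months`
#' months — one shared sampling calendar — are missing in every series.
#'
#' @param config a [synthetic_l4_config()].
#' @param rng_seed integer seed.
#' @return A [community_table()].
#' @export
generate_l4_like <- function(config = synthetic_l4_config(), rng_seed = 1L) {
  stopifnot(inherits(config, "synthetic_l4_config"))
  gc <- config$group_counts
  n <- config$n_taxa
  groups <- rep(names(gc), times = gc)
  ids <- sprintf("taxon_%03d", seq_len(n))

  with_seed(rng_seed, {
    # size classes: diatoms get their exact per-class counts; the remaining
    # class slots are shuffled over the non-diatom taxa
    size_class <- character(n)
    is_diatom <- groups == "diatom"
    size_class[is_diatom] <- sample(rep(names(config$diatom_size_counts),
                                        times = config$diatom_size_counts))
    rest <- config$size_class_counts - config$diatom_size_counts
    size_class[!is_diatom] <- sample(rep(names(rest), times = rest))
    radius <- vapply(size_class, function(cl) {
      b <- SIZE_CLASS_BOUNDS[[cl]]
      stats::runif(1, b[1], b[2] - 1e-6)
    }, double(1))

    scale <- 10^stats::runif(n, config$log10_scale_range[1],
                             config$log10_scale_range[2])
    peak <- draw_bloom_peaks(n)
    kappa <- stats::runif(n, config$bloom_sharpness_range[1],
                          config$bloom_sharpness_range[2])
    sigma <- stats::runif(n, config$noise_sd_range[1], config$noise_sd_range[2])

    moy <- as.integer(stats::cycle(stats::ts(seq_len(config$n_months),
                                             start = config$start,
                                             frequency = 12)))
    x <- matrix(NA_real_, nrow = n, ncol = config$n_months)
    for (i in seq_len(n)) {
      shape <- bloom_shape(moy, peak[i], kappa[i])
      # normalise so `scale` is the expected mean abundance
      base <- scale[i] * shape / mean(shape)
      x[i, ] <- base * exp(stats::rnorm(config$n_months, 0, sigma[i]) -
                             sigma[i]^2 / 2)
    }
    gaps <- sample(config$n_months, config$n_missing_months)
    x[, gaps] <- NA_real_
    rownames(x) <- ids
    meta <- data.frame(taxon_id = ids, functional_group = groups,
                       cell_radius_um = unname(radius),
                       stringsAsFactors = FALSE)
    tab <- community_table(x, meta, start = config$start)
    attr(tab, "truth") <- data.frame(taxon_id = ids, size_class = size_class,
                                     scale = scale, peak = peak, kappa = kappa,
                                     noise_sd = sigma,
                                     stringsAsFactors = FALSE)
    tab
  })
}

#' Inject a known predictability gradient into a community table
#'
#' Replaces every taxon's dynamics with a freshly drawn seasonal signal:
#' a designated fraction becomes low-noise (strong recurrent bloom, ~10%
#' multiplicative noise) and the rest high-noise (weak seasonality
#' dominated by heavy multiplicative noise). Abundance scales are drawn
#' over a single decade so no taxon dominates aggregates. Ground-truth
#' labels are recorded so exclusion experiments can be validated against
#' known answers. The table's missing-month pattern is preserved.
#'
#' @param table a [community_table()].
#' @param fraction_predictable fraction of taxa made predictable, in
#'   \[0, 1\].
#' @param rng_seed integer seed.
#' @return A [community_table()] whose `"truth"` attribute carries a
#'   logical `predictable` column.
#' @export
inject_predictability_gradient <- function(table, fraction_predictable,
                                           rng_seed = 1L) {
  if (fraction_predictable < 0 || fraction_predictable > 1) {
    stop("invalid value: fraction_predictable in [0,1]")
  }
  n <- n_taxa(table)
  Tm <- n_months(table)
  ids <- rownames(table$abundance)
  moy <- as.integer(stats::cycle(stats::ts(seq_len(Tm), start = table$start,
                                           frequency = 12)))
  missing_mask <- is.na(table$abundance)
  k <- round(fraction_predictable * n)
  with_seed(rng_seed, {
    chosen <- if (k > 0) sample(ids, k) else character(0)
    predictable <- ids %in% chosen
    # abundant taxa are the well-sampled, seasonally coherent ones:
    # relative counting noise shrinks with abundance, so the predictable
    # taxa sit higher on the (one-decade) abundance ladder
    scale <- 10^ifelse(predictable, stats::runif(n, 3.6, 4.4),
                       stats::runif(n, 3.0, 4.0))
    peak <- draw_bloom_peaks(n)
    x <- matrix(NA_real_, nrow = n, ncol = Tm, dimnames = list(ids, NULL))
    for (i in seq_len(n)) {
      kappa <- if (predictable[i]) 3 else 0.5
      sigma <- if (predictable[i]) 0.1 else 1.3
      shape <- bloom_shape(moy, peak[i], kappa)
      base <- scale[i] * shape / mean(shape)   # scale = expected mean
      x[i, ] <- base * exp(stats::rnorm(Tm, 0, sigma) - sigma^2 / 2)
    }
    x[missing_mask] <- NA_real_
    out <- community_table(x, table$metadata, start = table$start)
    attr(out, "truth") <- data.frame(taxon_id = ids, predictable = predictable,
                                     scale = scale, peak = peak,
                                     stringsAsFactors = FALSE)
    out
  })
}
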