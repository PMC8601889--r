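# End-to-end experiment orchestration: input (CSV, simulator, or synthetic
# generator) -> predictability curves (optionally with the surrogate null)
# -> results CSV + provenance JSON. A results file plus its sidecar fully
# determine the run: re-running the sidecar's configuration with the same
# seed reproduces the CSV byte for byte.

#' Experiment configuration
#'
#' Defaults follow the study design: embedding dimensions 1-10, one-month
#' horizon, 1000 trials per assemblage size, 100 surrogates per trial.
#' Desk-scale runs override `n_trials`/`n_surrogates` downward.
#'
#' @param input one of: `list(abundance = path, metadata = path)` to read
#'   CSVs; `list(simulator = "noise", ...)` or
#'   `list(simulator = "community", ...)` with parameter overrides passed
#'   to [noise_model_params()] / [community_model_params()]; or
#'   `list(synthetic = TRUE, ...)` for [generate_l4_like()]. May also be a
#'   named list of such lists under `variants` to run several model
#'   parameterisations into one results file.
#' @param sizes assemblage sizes to scan.
#' @param strategy sampling strategy (see [sample_assemblages()]).
#' @param n_trials Monte-Carlo trials per size.
#' @param n_surrogates surrogates per trial (0 disables the null).
#' @param embedding an [embedding_config()].
#' @param seed master seed, recorded in every artifact.
#' @param out_dir output directory (created if absent).
#' @return Object of class `"experiment_config"`.
#' @export
experiment_config <- function(input, sizes, strategy = "random",
                              n_trials = 1000L, n_surrogates = 100L,
                              embedding = embedding_config(), seed = 1L,
                              out_dir = tempdir()) {
  structure(list(input = input, sizes = sizes, strategy = strategy,
                 n_trials = as.integer(n_trials),
                 n_surrogates = as.integer(n_surrogates),
                 embedding = embedding, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "experiment_config")
}

#' Preset experiment designs
#'
#' `"noise_levels"`: the observational-noise model at its three noise
#' treatments (gamma 0, 0.5, 1), one curve each. `"community_treatments"`:
#' the Lotka-Volterra model over the 2x2 factorial of interactions
#' (alpha 0 / 0.25) and process noise (gamma_p 0 / 1), four curves.
#'
#' @param name preset name.
#' @param sizes assemblage sizes (default a short ramp to the community
#'   size).
#' @param n_trials,n_surrogates Monte-Carlo scale (defaults are
#'   desk-scale: 25 trials, no surrogates; pass the full design values to
#'   reproduce the study scale).
#' @param seed master seed.
#' @param out_dir output directory.
#' @return An [experiment_config()] with a `variants` input.
#' @export
experiment_preset <- function(name = c("noise_levels", "community_treatments"),
                              sizes = c(1, 10, 50, 100), n_trials = 25L,
                              n_surrogates = 0L, seed = 1L,
                              out_dir = tempdir()) {
  name <- match.arg(name)
  variants <- switch(name,
    noise_levels = list(
      none = list(simulator = "noise", gamma_obs = 0),
      low  = list(simulator = "noise", gamma_obs = 0.5),
      high = list(simulator = "noise", gamma_obs = 1)),
    community_treatments = list(
      a0_g0 = list(simulator = "community", alpha = 0, gamma_p = 0),
      a0_g1 = list(simulator = "community", alpha = 0, gamma_p = 1),
      a25_g0 = list(simulator = "community", alpha = 0.25, gamma_p = 0),
      a25_g1 = list(simulator = "community", alpha = 0.25, gamma_p = 1)))
  experiment_config(input = list(variants = variants), sizes = sizes,
                    n_trials = n_trials, n_surrogates = n_surrogates,
                    seed = seed, out_dir = out_dir)
}

# Materialise one input description into a community table.
resolve_input <- function(input, seed) {
  if (!is.null(input$abundance)) {
    return(read_community_csv(input$abundance, input$metadata))
  }
  if (!is.null(input$simulator)) {
    extra <- input[setdiff(names(input), "simulator")]
    if (input$simulator == "noise") {
      return(simulate_noise_model(do.call(noise_model_params, extra),
                                  rng_seed = seed))
    }
    if (input$simulator == "community") {
      return(simulate_community_model(do.call(community_model_params, extra),
                                      rng_seed = seed))
    }
    stop("invalid strategy: unknown simulator")
  }
  if (isTRUE(input$synthetic)) {
    extra <- input[setdiff(names(input), "synthetic")]
    return(generate_l4_like(do.call(synthetic_l4_config, extra),
                            rng_seed = seed))
  }
  stop("malformed table: unrecognised input description")
}

#' Run a configured experiment end to end
#'
#' Loads or simulates the input, runs [predictability_curve()] for each
#' variant, and writes `results.csv` plus `provenance.json` (full
#' configuration, seed, package version) to `out_dir`.
#'
#' @param config an [experiment_config()].
#' @param verbose print per-variant progress.
#' @return The combined results data frame, invisibly.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  variants <- config$input$variants
  if (is.null(variants)) variants <- list(default = config$input)
  pieces <- lapply(names(variants), function(vn) {
    if (verbose) message("variant: ", vn)
    tab <- resolve_input(variants[[vn]],
                         seed = derive_subseed(config$seed, match(vn, names(variants))))
    res <- predictability_curve(tab, sizes = config$sizes,
                                n_trials = config$n_trials,
                                n_surrogates = config$n_surrogates,
                                strategy = config$strategy,
                                config = config$embedding,
                                rng_seed = config$seed)
    cbind(variant = vn, res, stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, pieces)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_results(results, file.path(config$out_dir, "results.csv"))
  prov <- list(package = "planktonEDM",
               version = as.character(utils::packageVersion("planktonEDM")),
               seed = config$seed, sizes = config$sizes,
               strategy = config$strategy, n_trials = config$n_trials,
               n_surrogates = config$n_surrogates,
               embedding = unclass(config$embedding),
               input = config$input)
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}
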