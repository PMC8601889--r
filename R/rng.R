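# Seed plumbing shared by all stochastic operations.
#
# Every stochastic entry point takes an explicit `rng_seed`; the global RNG
# state is saved and restored so package calls never perturb a user's stream.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministically combines a master seed with index components (for
#' example assemblage size and trial number) so that any single Monte-Carlo
#' trial or surrogate can be regenerated in isolation. The result is always
#' a valid 32-bit integer seed.
#'
#' @param master integer master seed.
#' @param ... additional integer components.
#' @return An integer in \[0, 2^31 - 2\].
#' @export
derive_subseed <- function(master, ...) {
  parts <- c(as.double(master), vapply(list(...), as.double, double(1)))
  h <- 0
  for (p in parts) {
    # 69069: classic LCG multiplier; arithmetic stays below 2^53 exactly
    h <- (h * 69069 + (p %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h)
}
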