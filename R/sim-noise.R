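# Seasonal signal + observational noise model.
#
# Each model species is a phase-shifted sine of period 12 months, lifted to
# be non-negative, with i.i.d. Gaussian observation noise scaled by
# gamma_obs:
#
#   x_{i,t} = A sin(w t + phi_i) + A + gamma * eps_{i,t} + beta_i
#
# beta_i = -min_t(gamma * eps_{i,t}) shifts each species' realised noise
# path so its smallest noise contribution is exactly zero, which is what
# keeps every abundance non-negative.

#' Parameters of the observational-noise model
#'
#' @param n_species number of model species (study design: 100).
#' @param n_months series length in months (study design: 240).
#' @param gamma_obs noise scaling factor; the study's treatments are 0
#'   (none), 0.5 (low) and 1 (high).
#' @param A sine amplitude (1).
#' @param omega angular frequency, rad per month (2*pi/12: annual cycle).
#' @param phase_range span of the uniform species phase shift, rad.
#' @return Object of class `"noise_model_params"`.
#' @export
noise_model_params <- function(n_species = 100L, n_months = 240L,
                               gamma_obs = 0, A = 1, omega = 2 * pi / 12,
                               phase_range = c(-1, 1)) {
  if (n_months < 24L) stop("invalid value: need n_months >= 24")
  if (gamma_obs < 0 || A <= 0) stop("invalid value: gamma_obs >= 0 and A > 0")
  structure(list(n_species = as.integer(n_species),
                 n_months = as.integer(n_months), gamma_obs = gamma_obs,
                 A = A, omega = omega, phase_range = phase_range),
            class = "noise_model_params")
}

#' Simulate the observational-noise community
#'
#' Draws one phase per species (uniform on `phase_range`) and one noise
#' value per species-month (standard normal), then assembles the series as
#' above. With `gamma_obs = 0` every series is an exact 12-month-periodic
#' shifted sine with range `[0, 2A]`.
#'
#' @param params a [noise_model_params()].
#' @param rng_seed integer seed.
#' @return A [community_table()] (`n_species` x `n_months`, placeholder
#'   metadata: group `"other"`, radius 1).
#' @export
simulate_noise_model <- function(params, rng_seed = 1L) {
  stopifnot(inherits(params, "noise_model_params"))
  n <- params$n_species; Tm <- params$n_months
  draws <- with_seed(rng_seed, {
    phi <- stats::runif(n, params$phase_range[1], params$phase_range[2])
    eps <- matrix(stats::rnorm(n * Tm), nrow = n)
    list(phi = phi, eps = eps)
  })
  t_mon <- seq_len(Tm)
  noise <- params$gamma_obs * draws$eps
  beta <- -apply(noise, 1L, min)               # pins min noise term at 0
  x <- params$A * sin(outer(draws$phi, params$omega * t_mon, `+`)) +
    params$A + noise + beta
  rownames(x) <- sprintf("sim%03d", seq_len(n))
  meta <- data.frame(taxon_id = rownames(x), functional_group = "other",
                     cell_radius_um = 1, stringsAsFactors = FALSE)
  community_table(x, meta, start = c(1, 1))
}
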