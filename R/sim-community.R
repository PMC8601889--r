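# Stochastic Lotka-Volterra community model.
#
# dx_i/dt = r_i(t) x_i (1 - sum_j a_ij x_j / K(t))
#
# with a seasonal carrying capacity K(t) = K (A sin(w t) + delta), realised
# growth rates r_i(t) = mu_i A sin(w t) + mu_i + gamma_p eps_{i,m} + beta_i
# (process noise redrawn monthly and held within the month), self-limitation
# a_ii = 1, and sparse random competition: each species interacts with a
# fixed quarter of the community, the strengths redrawn every month from
# U(-alpha, alpha). Forward-Euler stepping at the model's native 6-hour
# step on a 360-day calendar (30-day months); output is the mean of the 120
# within-month states. A hard abundance floor prevents extinction.

#' Parameters of the Lotka-Volterra community model
#'
#' @param n_species number of species (study design: 100).
#' @param years simulated years of 360 days (study design: 20).
#' @param alpha interaction-strength limit; treatments 0 (no interactions)
#'   and 0.25 (strong interactions).
#' @param gamma_p process-noise scale; treatments 0 (none) and 1 (high).
#' @param mu_range range of the basal physiological growth rate, per day.
#' @param K carrying-capacity scale, cells per litre (30,000).
#' @param A seasonal amplitude (1).
#' @param omega angular frequency, rad per day (2*pi/360: annual cycle).
#' @param delta carrying-capacity offset, `A + 0.1`, keeping `K(t) > 0`.
#' @param dt Euler step in days (0.25 = 6 hours).
#' @param interaction_fraction fraction of the community each species
#'   interacts with (1/4).
#' @param abundance_floor minimum abundance, cells per litre (1e-10).
#' @param init_frac range of initial abundances as a fraction of `K`.
#' @return Object of class `"community_model_params"`.
#' @export
community_model_params <- function(n_species = 100L, years = 20L,
                                   alpha = 0, gamma_p = 0,
                                   mu_range = c(0.8, 1.2), K = 30000,
                                   A = 1, omega = 2 * pi / 360,
                                   delta = A + 0.1, dt = 0.25,
                                   interaction_fraction = 0.25,
                                   abundance_floor = 1e-10,
                                   init_frac = c(0.1, 0.5)) {
  if (delta <= A) stop("invalid value: delta must exceed A so K(t) > 0")
  if (abundance_floor <= 0) stop("invalid value: abundance floor must be > 0")
  if (n_species < 4L) stop("invalid value: need n_species >= 4")
  if (abs(30 / dt - round(30 / dt)) > 1e-9) {
    stop("invalid value: dt must divide the 30-day month")
  }
  structure(list(n_species = as.integer(n_species), years = as.integer(years),
                 alpha = alpha, gamma_p = gamma_p, mu_range = mu_range,
                 K = K, A = A, omega = omega, delta = delta, dt = dt,
                 interaction_fraction = interaction_fraction,
                 abundance_floor = abundance_floor, init_frac = init_frac),
            class = "community_model_params")
}

#' Seasonal carrying capacity
#'
#' `K(t) = K (A sin(omega t) + delta)`; with the default `delta = A + 0.1`
#' this oscillates between `0.1 K` and `2.1 K`, strictly positive.
#'
#' @param t_day time in days.
#' @param params a [community_model_params()].
#' @return Carrying capacity, cells per litre.
#' @export
seasonal_carrying_capacity <- function(t_day, params) {
  params$K * (params$A * sin(params$omega * t_day) + params$delta)
}

#' Realised per-capita growth rate
#'
#' `r = mu A sin(omega t) + mu + gamma_p eps + beta_p`. The offset
#' `beta_p = -min` over the species' realised monthly noise draws pins the
#' smallest noise contribution at zero, so `r >= 0` always (the seasonal
#' part bottoms out at exactly zero when `sin = -1`).
#'
#' @param mu basal growth rate, per day.
#' @param t_day time in days.
#' @param params a [community_model_params()].
#' @param eps this month's standard-normal process-noise draw.
#' @param beta_p the species' noise offset (`-min` of its realised
#'   `gamma_p * eps` path; 0 when `gamma_p = 0`).
#' @return Growth rate, per day.
#' @export
realized_growth_rate <- function(mu, t_day, params, eps = 0, beta_p = 0) {
  mu * params$A * sin(params$omega * t_day) + mu + params$gamma_p * eps + beta_p
}

#' Draw a monthly interaction matrix
#'
#' Diagonal fixed at 1 (self-limitation); for each species its fixed
#' partner set of `floor(n_species/4)` other species receives strengths
#' drawn fresh from `U(-alpha, alpha)`; all other entries are zero. Partner
#' topology is decided once per simulation — only strengths vary monthly.
#'
#' @param n_species community size.
#' @param alpha interaction-strength limit (0 gives the identity matrix).
#' @param partner_sets list of partner index vectors, one per species, as
#'   produced inside [simulate_community_model()]; if `NULL`, partner sets
#'   are drawn here (seeded).
#' @param rng_seed integer seed.
#' @return `n_species` x `n_species` numeric matrix.
#' @export
draw_interaction_matrix <- function(n_species, alpha, partner_sets = NULL,
                                    rng_seed = 1L) {
  n <- as.integer(n_species)
  if (n < 4L) stop("invalid value: need n_species >= 4")
  with_seed(rng_seed, {
    if (is.null(partner_sets)) partner_sets <- draw_partner_sets(n, 0.25)
    interaction_matrix_impl(n, alpha, partner_sets)
  })
}

# Fixed interaction topology: each species i gets floor(n * frac) distinct
# partners drawn uniformly from the other species. Consumes RNG.
draw_partner_sets <- function(n, frac) {
  k <- floor(n * frac)
  lapply(seq_len(n), function(i) sample((seq_len(n))[-i], k))
}

# Strength redraw on a fixed topology. Consumes RNG.
interaction_matrix_impl <- function(n, alpha, partner_sets) {
  m <- diag(1, n)
  for (i in seq_len(n)) {
    m[i, partner_sets[[i]]] <- stats::runif(length(partner_sets[[i]]),
                                            -alpha, alpha)
  }
  m
}

#' Simulate the Lotka-Volterra community
#'
#' Integrates the model by forward Euler at `dt` over `years` 360-day
#' years. Interaction strengths and process-noise draws refresh at each
#' 30-day month boundary; after every step any abundance below the floor is
#' reset to the floor. Output is the within-month mean state, one value per
#' species per month (240 months for the default 20-year run). Initial
#' abundances are uniform on `init_frac * K`; no burn-in is discarded.
#'
#' @param params a [community_model_params()].
#' @param rng_seed integer seed.
#' @return A [community_table()] (placeholder metadata), `n_species` rows x
#'   `12 * years` columns.
#' @export
simulate_community_model <- function(params, rng_seed = 1L) {
  stopifnot(inherits(params, "community_model_params"))
  n <- params$n_species
  n_month <- 12L * params$years
  steps_per_month <- as.integer(round(30 / params$dt))

  draws <- with_seed(rng_seed, {
    mu <- stats::runif(n, params$mu_range[1], params$mu_range[2])
    partner_sets <- draw_partner_sets(n, params$interaction_fraction)
    eps <- matrix(stats::rnorm(n * n_month), nrow = n)
    x0 <- stats::runif(n, params$init_frac[1] * params$K,
                       params$init_frac[2] * params$K)
    alphas <- lapply(seq_len(n_month), function(m) {
      interaction_matrix_impl(n, params$alpha, partner_sets)
    })
    list(mu = mu, eps = eps, x0 = x0, alphas = alphas)
  })

  beta <- -apply(params$gamma_p * draws$eps, 1L, min)  # r >= 0 guard
  x <- draws$x0
  out <- matrix(NA_real_, nrow = n, ncol = n_month)
  step <- 0L
  for (m in seq_len(n_month)) {
    amat <- draws$alphas[[m]]
    gnoise <- params$gamma_p * draws$eps[, m] + beta
    acc <- numeric(n)
    for (s in seq_len(steps_per_month)) {
      t_day <- step * params$dt
      r <- draws$mu * params$A * sin(params$omega * t_day) + draws$mu + gnoise
      Kt <- seasonal_carrying_capacity(t_day, params)
      x <- x + params$dt * r * x * (1 - as.numeric(amat %*% x) / Kt)
      if (any(!is.finite(x))) {
        stop(sprintf("integration diverged at step %d (month %d)", step + 1L, m))
      }
      x[x < params$abundance_floor] <- params$abundance_floor
      acc <- acc + x
      step <- step + 1L
    }
    out[, m] <- acc / steps_per_month
  }
  rownames(out) <- sprintf("sim%03d", seq_len(n))
  meta <- data.frame(taxon_id = rownames(out), functional_group = "other",
                     cell_radius_um = 1, stringsAsFactors = FALSE)
  community_table(out, meta, start = c(1, 1))
}
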