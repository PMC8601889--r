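test_that("noiseless species are shifted sines on [0, 2A], 12-periodic", {
  tab <- simulate_noise_model(noise_model_params(n_species = 20, gamma_obs = 0),
                              rng_seed = 3)
  expect_equal(dim(tab$abundance), c(20L, 240L))
  expect_true(all(tab$abundance >= 0))
  expect_lt(max(abs(range(tab$abundance) - c(0, 2))), 0.05)
  a12 <- apply(tab$abundance, 1, lag_cor, k = 12)
  expect_true(all(a12 >= 0.999))
})

test_that("the noise offset pins each species' minimum noise term at zero", {
  p <- noise_model_params(n_species = 10, gamma_obs = 1)
  tab <- simulate_noise_model(p, rng_seed = 5)
  expect_true(all(tab$abundance >= 0))
  # reconstruct the realised noise path from the same seed
  draws <- planktonEDM:::with_seed(5, {
    phi <- runif(10, -1, 1); eps <- matrix(rnorm(10 * 240), nrow = 10)
    list(phi = phi, eps = eps)
  })
  noise <- 1 * draws$eps
  shifted <- noise - apply(noise, 1, min)
  expect_equal(apply(shifted, 1, min), rep(0, 10))
  signal <- sin(outer(draws$phi, 2 * pi / 12 * (1:240), `+`)) + 1
  expect_equal(unname(tab$abundance), unname(signal + shifted),
               tolerance = 1e-12)
})

test_that("simulators are bit-deterministic in (params, seed)", {
  p <- noise_model_params(n_species = 5, n_months = 48, gamma_obs = 0.5)
  expect_identical(simulate_noise_model(p, 11)$abundance,
                   simulate_noise_model(p, 11)$abundance)
  cp <- community_model_params(n_species = 6, years = 2, alpha = 0.25,
                               gamma_p = 1)
  expect_identical(simulate_community_model(cp, 11)$abundance,
                   simulate_community_model(cp, 11)$abundance)
  expect_false(identical(simulate_community_model(cp, 11)$abundance,
                         simulate_community_model(cp, 12)$abundance))
})

test_that("interaction matrices have the prescribed topology and limits", {
  m <- draw_interaction_matrix(100, alpha = 0.25, rng_seed = 9)
  expect_equal(unname(diag(m)), rep(1, 100))
  off <- m - diag(diag(m))
  expect_equal(unname(rowSums(off != 0)), rep(25, 100))  # quarter of community
  expect_true(all(abs(off) < 0.25))

  id <- draw_interaction_matrix(8, alpha = 0, rng_seed = 9)
  expect_equal(unname(id), diag(8))
})

test_that("monthly redraws vary strengths on a fixed partner topology", {
  sets <- planktonEDM:::with_seed(1, planktonEDM:::draw_partner_sets(12, 0.25))
  m1 <- draw_interaction_matrix(12, 0.25, partner_sets = sets, rng_seed = 2)
  m2 <- draw_interaction_matrix(12, 0.25, partner_sets = sets, rng_seed = 3)
  expect_equal(which(m1 != 0), which(m2 != 0))
  expect_false(identical(m1, m2))
})

test_that("seasonal carrying capacity oscillates between 0.1K and 2.1K", {
  p <- community_model_params()
  t_trough <- 270                                # sin = -1 on the 360-day year
  expect_equal(seasonal_carrying_capacity(t_trough, p), 3000)
  expect_equal(seasonal_carrying_capacity(90, p), 63000)
  t <- seq(0, 720, by = 0.25)
  expect_true(all(seasonal_carrying_capacity(t, p) > 0))
})

test_that("realised growth rate cancels exactly at the seasonal trough", {
  p <- community_model_params(gamma_p = 0)
  expect_equal(realized_growth_rate(1.1, 270, p), 0)
  expect_equal(realized_growth_rate(1.1, 90, p), 2.2)
  # with process noise, the offset pins the realised minimum at zero
  p1 <- community_model_params(gamma_p = 1)
  set.seed(8); eps <- rnorm(240)
  beta <- -min(1 * eps)
  r <- vapply(seq_along(eps), function(m)
    realized_growth_rate(1, (m - 1) * 30, p1, eps[m], beta),
    double(1))
  expect_gte(min(r), 0)
  expect_equal(min(eps + beta), 0)
})

test_that("the community run has the right shape, floor, and periodicity", {
  p <- community_model_params(n_species = 10, years = 6, alpha = 0, gamma_p = 0)
  tab <- simulate_community_model(p, rng_seed = 17)
  expect_equal(dim(tab$abundance), c(10L, 72L))
  expect_true(all(tab$abundance >= 1e-10))
  post <- tab$abundance[, 25:72]                 # drop 2-year transient
  a12 <- apply(post, 1, lag_cor, k = 12)
  expect_true(all(a12 >= 0.999))
})

test_that("Euler at the native 6-h step matches a 10x finer integration", {
  p6 <- community_model_params(n_species = 5, years = 4, alpha = 0,
                               gamma_p = 0, dt = 0.25)
  pf <- community_model_params(n_species = 5, years = 4, alpha = 0,
                               gamma_p = 0, dt = 0.025)
  a <- simulate_community_model(p6, rng_seed = 23)$abundance
  b <- simulate_community_model(pf, rng_seed = 23)$abundance
  expect_lt(max(abs(a - b) / b), 0.01)
})

test_that("strong interactions keep abundances finite and floored", {
  p <- community_model_params(n_species = 20, years = 3, alpha = 0.25,
                              gamma_p = 1)
  tab <- simulate_community_model(p, rng_seed = 29)
  expect_true(all(is.finite(tab$abundance)))
  expect_true(all(tab$abundance >= 1e-10))
})
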