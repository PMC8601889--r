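test_that("aggregation sums members and propagates missing months", {
  tab <- toy_table()
  one <- aggregate_taxa(tab, "a")
  expect_equal(as.numeric(one$series), c(1, 2, 3))
  both <- aggregate_taxa(tab, c("b", "a"))
  expect_equal(as.numeric(both$series), c(5, 7, 9))
  expect_equal(both$member_ids, c("a", "b"))     # summation order sorted

  ab <- rbind(a = c(1, 2, 3), b = c(4, NA, 6))
  tab2 <- toy_table(abund = ab)
  expect_equal(as.numeric(aggregate_taxa(tab2, c("a", "b"))$series),
               c(5, NA, 9))
})

test_that("aggregation errors on unknown or empty member sets", {
  tab <- toy_table()
  expect_error(aggregate_taxa(tab, "zebra"), "member not found")
  expect_error(aggregate_taxa(tab, character(0)), "empty assemblage")
})

test_that("aggregation conserves the member sum at every month", {
  tab <- generate_l4_like(rng_seed = 14)
  ids <- sample(rownames(tab$abundance), 40)
  agg <- aggregate_taxa(tab, ids)
  manual <- colSums(tab$abundance[sort(ids), ])
  expect_identical(as.numeric(agg$series), unname(manual))  # bit-level
})

test_that("strategy pools respect groups and size-class boundaries", {
  ab <- matrix(1, 4, 3, dimnames = list(letters[1:4], NULL))
  tab <- community_table(ab, data.frame(
    taxon_id = letters[1:4],
    functional_group = c("diatom", "diatom", "phytoflagellate", "other"),
    cell_radius_um = c(3, 5, 12, 13)), start = c(2000, 1))
  pool <- function(s) sort(planktonEDM:::strategy_pool(tab, s))
  expect_equal(pool("random"), letters[1:4])
  expect_equal(pool("functional_group:diatom"), c("a", "b"))
  # 5 um and 12 um belong to the middle class (bounds inclusive)
  expect_equal(pool("size_class:small"), "a")
  expect_equal(pool("size_class:medium"), c("b", "c"))
  expect_equal(pool("size_class:large"), "d")
  # the singleton catch-all group is not a valid grouping target
  expect_error(sample_assemblages(tab, 1, 1, "functional_group:other"),
               "invalid strategy")
  expect_error(sample_assemblages(tab, 1, 1, "size_class:tiny"),
               "invalid strategy")
  expect_error(sample_assemblages(tab, 3, 1, "functional_group:diatom"),
               "pool exhausted")
})

test_that("a size-15 draw from a 14-taxon group pool is exhausted", {
  tab <- generate_l4_like(rng_seed = 14)
  expect_equal(sum(tab$metadata$functional_group == "phytoflagellate"), 14L)
  expect_error(sample_assemblages(tab, 15, 1, "functional_group:phytoflagellate"),
               "pool exhausted")
  ok <- sample_assemblages(tab, 14, 2, "functional_group:phytoflagellate")
  expect_length(ok[[1]]$member_ids, 14)
})

test_that("full-pool draws return the one possible assemblage every trial", {
  tab <- toy_table()
  trials <- sample_assemblages(tab, 2, 5, "random", rng_seed = 3)
  for (tr in trials) expect_equal(tr$member_ids, c("a", "b"))
})

test_that("every pool member has equal inclusion probability", {
  ab <- matrix(1, 10, 3, dimnames = list(paste0("t", 1:10), NULL))
  tab <- community_table(ab, data.frame(taxon_id = paste0("t", 1:10),
                                        functional_group = "diatom",
                                        cell_radius_um = 5), c(2000, 1))
  counts <- integer(10); names(counts) <- paste0("t", 1:10)
  for (i in seq_len(10000)) {
    m <- planktonEDM:::with_seed(derive_subseed(5, 2, i),
                                 sample(paste0("t", 1:10), 2))
    counts[m] <- counts[m] + 1L
  }
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.001)
})

test_that("trials are regenerable from (master seed, size, index)", {
  tab <- generate_l4_like(rng_seed = 14)
  trials <- sample_assemblages(tab, 5, 4, rng_seed = 77)
  redo <- planktonEDM:::with_seed(derive_subseed(77, 5, 3),
                                  sample(rownames(tab$abundance), 5))
  expect_equal(sort(redo), trials[[3]]$member_ids)
})

test_that("CV is zero for constants and antiphase cancellation", {
  expect_equal(coefficient_of_variation(monthly_series(rep(4, 24))), 0)
  t <- 1:48
  two <- rbind(a = sin(2 * pi * t / 12) + 2, b = -sin(2 * pi * t / 12) + 2)
  tab <- toy_table(abund = two, groups = c("diatom", "diatom"), radii = c(3, 3))
  expect_equal(coefficient_of_variation(aggregate_taxa(tab, c("a", "b"))), 0,
               tolerance = 1e-12)
  expect_error(coefficient_of_variation(monthly_series(rep(0, 24))),
               "undefined CV")
})

test_that("aggregate CV shrinks like 1/sqrt(M) for i.i.d. members", {
  set.seed(31)
  n_mon <- 360
  pool <- matrix(abs(5 + rnorm(64 * n_mon)), nrow = 64,
                 dimnames = list(sprintf("m%02d", 1:64), NULL))
  tab <- community_table(pool, data.frame(taxon_id = rownames(pool),
                                          functional_group = "diatom",
                                          cell_radius_um = 5), c(2000, 1))
  cv1 <- mean(vapply(rownames(pool)[1:16], function(id)
    coefficient_of_variation(taxon_series(tab, id)), double(1)))
  for (M in c(4, 16, 64)) {
    cvM <- coefficient_of_variation(aggregate_taxa(tab, rownames(pool)[1:M]))
    expect_lt(abs(cvM / (cv1 / sqrt(M)) - 1), 0.2)
  }
})

test_that("curve summaries report 1.96 SE intervals and zero spread at full pool", {
  tab <- simulate_noise_model(noise_model_params(n_species = 12, n_months = 120,
                                                 gamma_obs = 1), rng_seed = 2)
  cv <- predictability_curve(tab, sizes = c(2, 12), n_trials = 8, rng_seed = 4)
  expect_equal(cv$ci95_half_width, 1.96 * cv$se)
  expect_equal(cv$se[cv$size == 12], 0)          # single possible assemblage
  expect_true(all(cv$n_failed == 0))
})

test_that("exclusion filter removes the top fraction with ceiling rounding", {
  ab <- rbind(w = rep(10, 24), x = rep(20, 24), y = rep(30, 24), z = rep(40, 24))
  tab <- toy_table(abund = ab, groups = rep("diatom", 4), radii = rep(5, 4))
  kept <- exclusion_filter(tab, "abundance", 0.25)
  expect_equal(sort(rownames(kept$abundance)), c("w", "x", "y"))
  expect_error(exclusion_filter(tab, "abundance", 0.9), "filter too aggressive")
})

test_that("a quarter of 198 taxa means 50 removed", {
  tab <- generate_l4_like(rng_seed = 14)
  kept <- exclusion_filter(tab, "abundance", 0.25)
  expect_equal(n_taxa(kept), 148L)
  means <- apply(tab$abundance, 1, mean, na.rm = TRUE)
  expect_equal(sort(rownames(kept$abundance)),
               sort(names(sort(means)[1:148])))
})

test_that("predictability exclusion removes a perfectly forecastable taxon", {
  set.seed(6)
  n_mon <- 120
  ab <- rbind(sine = as.numeric(seasonal_sine(n_mon)) + 0.5,
              n1 = abs(rnorm(n_mon, 5)), n2 = abs(rnorm(n_mon, 5)),
              n3 = abs(rnorm(n_mon, 5)))
  tab <- toy_table(abund = ab, groups = rep("diatom", 4), radii = rep(5, 4))
  kept <- exclusion_filter(tab, "predictability", 0.25)
  expect_false("sine" %in% rownames(kept$abundance))
})
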