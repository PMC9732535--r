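test_that("asymptotic chi-square matches direct arithmetic on the cross data", {
  # independent oracle: direct sum over E = N * C(8,k) / 256
  E <- 83 * choose(8, 0:8) / 256
  stat_oracle <- sum((female_counts - E)^2 / E)

  g <- gof_test(female_dist, null_model)
  expect_equal(g$statistic, stat_oracle, tolerance = 1e-12)
  expect_equal(g$df, 8L)
  expect_lt(abs(g$statistic - 139.3), 0.1)
  expect_lt(g$p_value, 5e-5)  # prints as 0.0000 at 4 dp

  gm <- gof_test(male_dist, null_model)
  expect_lt(gm$p_value, 5e-5)
})

test_that("a perfectly fitting cohort gives statistic 0 and p 1", {
  counts <- 256 * transmission_pmf(null_model)  # integer by construction
  d <- count_distribution(counts, 8)
  g <- gof_test(d, null_model)
  expect_equal(g$statistic, 0)
  expect_equal(g$p_value, 1)
})

test_that("tail pooling raises every expected bin to the threshold", {
  g <- gof_test(female_dist, null_model, pool_below = 5)
  expect_true(all(g$expected >= 5))
  expect_lt(g$df, 8L)
  expect_equal(sum(g$observed), 83)
  expect_lt(abs(sum(g$expected) - 83), 1e-9)
  expect_match(g$pooled_bins, "pooled")
  # pooling never invents signal in a perfect fit
  perfect <- count_distribution(256 * transmission_pmf(null_model), 8)
  expect_equal(gof_test(perfect, null_model, pool_below = 5)$statistic, 0)
})

test_that("Monte-Carlo p-value is reproducible and matches exact enumeration", {
  g1 <- gof_test(male_dist, null_model, method = "monte_carlo",
                 n_resamples = 5000, seed = 42)
  g2 <- gof_test(male_dist, null_model, method = "monte_carlo",
                 n_resamples = 5000, seed = 42)
  expect_identical(g1$p_value, g2$p_value)
  expect_gt(g1$p_value, 0)  # add-one estimator never returns 0

  # reduced case small enough for exhaustive multinomial enumeration:
  # 3 trivalents, 10 offspring
  small_model <- segregation_model(3, 0.5)
  obs <- count_distribution(c(4, 3, 2, 1), 3)
  p_exact <- enum_gof_tail(c(4, 3, 2, 1), transmission_pmf(small_model))
  B <- 100000
  g <- gof_test(obs, small_model, method = "monte_carlo",
                n_resamples = B, seed = 7)
  mc_se <- sqrt(p_exact * (1 - p_exact) / B)
  expect_lt(abs(g$p_value - p_exact), 3 * mc_se + 2 / B)
})

test_that("asymptotic and Monte-Carlo p agree when expected counts are large", {
  # cohort big enough that pooled expected counts all exceed 5
  off <- simulate_offspring(sim_config(drive = 0.53, n_offspring = 500,
                                       seed = 9))
  d <- observed_distribution(off)
  ga <- gof_test(d, null_model, pool_below = 5)
  B <- 20000
  gm <- gof_test(d, null_model, method = "monte_carlo", pool_below = 5,
                 n_resamples = B, seed = 10)
  mc_se <- sqrt(max(gm$p_value * (1 - gm$p_value), 1 / B) / B)
  expect_lt(abs(ga$p_value - gm$p_value), 3 * mc_se + 0.01)
})

test_that("normal-approximation proportion test matches hand arithmetic", {
  r <- proportion_test(5, 6, 0.5, "greater")
  expect_equal(r$z, (5 / 6 - 0.5) / sqrt(0.25 / 6), tolerance = 1e-12)
  expect_equal(round_half_up(r$z, 3), 1.633)
  expect_equal(round_half_up(r$p_value, 4), 0.0512)

  r0 <- proportion_test(3, 6, 0.5, "greater")
  expect_equal(r0$z, 0)
  expect_equal(r0$p_value, 0.5)

  # two-sided is twice the smaller one-sided tail
  r2 <- proportion_test(5, 6, 0.5, "two_sided")
  expect_equal(r2$p_value, 2 * r$p_value)
})

test_that("exact binomial p-values match arbitrary-precision tail sums", {
  r <- proportion_test(5, 6, 0.5, "greater", "exact_binomial")
  expect_equal(r$p_value, 7 / 64)  # C(6,5)/64 + C(6,6)/64

  # cross-check against stats::binom.test over a grid
  for (n in c(1, 7, 18, 30)) {
    for (x in 0:n) {
      mine <- proportion_test(x, n, 0.4, "greater", "exact_binomial")
      ref <- stats::binom.test(x, n, 0.4, alternative = "greater")
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
      mine_l <- proportion_test(x, n, 0.4, "less", "exact_binomial")
      ref_l <- stats::binom.test(x, n, 0.4, alternative = "less")
      expect_equal(mine_l$p_value, ref_l$p.value, tolerance = 1e-12)
    }
  }
})

test_that("Wilson interval matches the score interval from prop.test", {
  for (case in list(c(5, 6), c(256, 664), c(0, 10), c(10, 10), c(7, 23))) {
    ref <- suppressWarnings(
      stats::prop.test(case[1], case[2], correct = FALSE)$conf.int)
    expect_equal(wilson_ci(case[1], case[2]), as.numeric(ref),
                 tolerance = 1e-9)
  }
})

test_that("transmission estimates treat trivalent segregations as trials", {
  fem <- estimate_transmission(female_dist)
  expect_equal(fem$estimate, 256 / 664)
  expect_equal(round_half_up(100 * fem$estimate, 1), 38.6)
  expect_true(fem$assumes_independence)

  mal <- estimate_transmission(male_dist)
  expect_equal(mal$estimate, 228 / 448)

  all_max <- count_distribution(c(rep(0, 8), 10), 8)
  expect_equal(estimate_transmission(all_max)$estimate, 1)
  expect_error(estimate_transmission(count_distribution(rep(0, 9), 8)),
               "empty")
})

test_that("pooled two-proportion comparison separates the parental sexes", {
  cmp <- compare_transmission(female_dist, male_dist)
  # oracle: pooled phat = 484/1112
  pp <- 484 / 1112
  z_oracle <- (256 / 664 - 228 / 448) /
    sqrt(pp * (1 - pp) * (1 / 664 + 1 / 448))
  expect_equal(cmp$z, z_oracle, tolerance = 1e-12)
  expect_lt(abs(abs(cmp$z) - 4.07), 0.01)
  expect_lt(cmp$p_value, 0.01)

  same <- compare_transmission(female_dist, female_dist)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
})

test_that("dispersion test flags the cross data as overdispersed", {
  d <- dispersion_test(female_dist, null_model, n_resamples = 2000,
                       seed = 3)
  expect_gt(d$statistic, 1)

  # binomial data at large N have variance ratio near 1
  off <- simulate_offspring(sim_config(n_offspring = 5000, seed = 21))
  dn <- dispersion_test(observed_distribution(off), null_model,
                        n_resamples = 2000, seed = 4)
  expect_lt(abs(dn$statistic - 1), 0.1)

  degenerate <- count_distribution(c(0, 0, 12, rep(0, 6)), 8)
  expect_error(dispersion_test(degenerate, null_model), "variance")
})
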