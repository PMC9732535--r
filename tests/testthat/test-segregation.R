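test_that("transmission pmf matches exhaustive gamete enumeration", {
  cases <- list(
    rep(0.5, 8),
    c(0.7, rep(0.5, 7)),
    c(0.1, 0.9, 0.5, 0.3),
    runif_cases <- {set.seed(11); runif(12)},
    rep(0.25, 3))
  for (p in cases) {
    model <- segregation_model(length(p), p)
    pmf <- transmission_pmf(model)
    expect_lt(max(abs(pmf - enum_pmf(p))), 1e-12)
    expect_lt(abs(sum(pmf) - 1), 1e-12)
  }
})

test_that("Mendelian null reproduces the published binomial table at 2 dp", {
  pct <- round_half_up(100 * transmission_pmf(null_model), 2)
  expect_equal(unname(pct),
               c(0.39, 3.13, 10.94, 21.88, 27.34, 21.88, 10.94, 3.13, 0.39))
  expect_equal(unname(pct), rev(unname(pct)))  # symmetric in k
})

test_that("degenerate transmission probabilities give point masses", {
  pmf1 <- transmission_pmf(segregation_model(8, 1))
  expect_equal(unname(pmf1), c(rep(0, 8), 1))
  pmf0 <- transmission_pmf(segregation_model(8, 0))
  expect_equal(unname(pmf0), c(1, rep(0, 8)))
})

test_that("expected counts scale the pmf linearly and exactly", {
  e56 <- expected_counts(null_model, 56)
  expect_equal(unname(e56[5]), 15.3125)
  expect_lt(abs(sum(e56) - 56), 1e-9)

  e83 <- expected_counts(null_model, 83)
  expect_equal(unname(e83[5]), 83 * 70 / 256)  # 22.695 by exact rationals
  expect_lt(abs(sum(e83) - 83), 1e-9)

  expect_equal(unname(expected_counts(null_model, 0)), rep(0, 9))
  # linearity: E(N)/N independent of N
  expect_equal(expected_counts(null_model, 17) / 17,
               expected_counts(null_model, 391) / 391)
  expect_error(expected_counts(null_model, -1), "non-negative")
})

test_that("observed distributions tabulate the packaged cross data", {
  off <- rb_example_offspring()
  fem <- observed_distribution(off, "female")
  expect_equal(unname(fem$counts), female_counts)
  expect_equal(fem$N, 83)
  mal <- observed_distribution(off, "male")
  expect_equal(unname(mal$counts), male_counts)
  expect_equal(mal$N, 56)
  # totals preserved under filtering
  expect_equal(observed_distribution(off, "all")$N, nrow(off))

  empty <- observed_distribution(off[0, , drop = FALSE], "all")
  expect_equal(unname(empty$counts), rep(0L, 9))

  bad <- data.frame(animal_id = "x", het_parent_sex = "male",
                    rb_count = 9L, diploid_n = 31L)
  expect_error(observed_distribution(bad), "outside 0")
})

test_that("cohort summaries give published totals, means and fractions", {
  expect_equal(total_rb(female_dist), 256)
  expect_equal(total_rb(male_dist), 228)
  expect_equal(round_half_up(mean_rb(female_dist), 2), 3.08)
  expect_equal(round_half_up(mean_rb(male_dist), 2), 4.07)
  expect_equal(round_half_up(100 * fraction_of_max(female_dist), 1), 38.6)

  all_zero <- count_distribution(c(5, rep(0, 8)), 8)
  expect_equal(total_rb(all_zero), 0)
  expect_equal(fraction_of_max(all_zero), 0)

  empty <- count_distribution(rep(0, 9), 8)
  expect_error(mean_rb(empty), "empty")
  expect_error(fraction_of_max(empty), "empty")
})

test_that("consensus karyotype is the plate mode, erring on ties", {
  expect_equal(consensus_rb_count(c(3, 3, 3, 3, 3, 3, 3, 2, 3, 3)), 3L)
  expect_equal(consensus_rb_count(rep(5L, 10)), 5L)
  expect_error(consensus_rb_count(c(2, 2, 2, 3, 3, 3)),
               class = "rb_ambiguous_karyotype")
})

test_that("karyotype consistency check enforces 2n = base - rb_count", {
  recs <- data.frame(
    animal_id = c("A", "hom", "bad", "out"),
    het_parent_sex = "male",
    rb_count = c(3L, 0L, 8L, 9L),
    diploid_n = c(37L, 40L, 37L, 31L))
  v <- validate_record(recs)
  expect_equal(v$pass, c(TRUE, TRUE, FALSE, FALSE))
  expect_match(v$reason[3], "diploid_n")
  expect_match(v$reason[4], "outside")
  # alternative base parameterization
  v2 <- validate_record(recs[1, ], telocentric_base = 39)
  expect_false(v2$pass)
})
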