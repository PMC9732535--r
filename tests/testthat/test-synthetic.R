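test_that("simulated offspring respect the configured ground truth", {
  # full drive: every trivalent transmits its metacentric
  off1 <- simulate_offspring(sim_config(drive = 1, n_offspring = 50,
                                        seed = 1))
  expect_true(all(off1$rb_count == 8))
  expect_true(all(off1$diploid_n == 32))

  # Mendelian null at large N: mean fraction near 0.5
  big <- simulate_offspring(sim_config(n_offspring = 10000, seed = 2))
  frac <- fraction_of_max(observed_distribution(big))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / (8 * 10000)))

  # every simulated record is karyotype-consistent
  expect_true(all(validate_record(big)$pass))
  # plate counts reduce to the recorded karyotype
  plates <- parse_plate_counts(off1$plate_counts)
  expect_true(all(vapply(plates, consensus_rb_count, integer(1)) ==
                    off1$rb_count))
})

test_that("same seed gives identical datasets; litters are non-empty", {
  cfg <- sim_config(n_offspring = 200, mean_litter_size = 4.4, seed = 33)
  a <- simulate_offspring(cfg)
  b <- simulate_offspring(cfg)
  expect_identical(a, b)
  sizes <- table(a$litter_id)
  expect_true(all(sizes >= 1))
  expect_equal(sum(sizes), 200)
})

test_that("homogeneous drive converges to the binomial distribution", {
  off <- simulate_offspring(sim_config(drive = 0.35, n_offspring = 100000,
                                       seed = 6))
  d <- observed_distribution(off)
  g <- gof_test(d, segregation_model(8, 0.35), pool_below = 5)
  expect_gt(g$p_value, 0.001)
})

test_that("viability distortion is detectable by the gof test", {
  # class-level viability reshaping the distribution at near-Mendelian
  # mean: power >= 90% at the experiment's female cohort size
  viab <- c(1, 1, 2, 0.4, 1, 1, 0.2, 0, 1)
  rejections <- 0L
  replicates <- 500L
  for (r in seq_len(replicates)) {
    off <- simulate_offspring(sim_config(viability = viab, n_offspring = 83,
                                         seed = 5000 + r))
    g <- gof_test(observed_distribution(off), null_model)
    if (g$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections / replicates, 0.9)

  expect_error(sim_config(viability = rep(0, 9)), "not all zero")
  expect_error(
    simulate_offspring(sim_config(drive = 1,
                                  viability = c(rep(1, 8), 0))),
    "remove all")
})

test_that("measurement simulator honours its noise model", {
  clean <- simulate_measurements(30, n_plates = 10,
                                 chromosomes_per_plate = 4,
                                 compaction_cv = 0.5, measurement_cv = 0,
                                 seed = 4)
  expect_equal(normalized_ratio(clean), rep(30, 40), tolerance = 1e-12)
  expect_equal(nrow(clean), 40)
  expect_error(simulate_measurements(30, n_plates = 0), "at least one")
  expect_error(simulate_measurements(0, n_plates = 5), "true_ratio_pct")
  expect_error(simulate_measurements(30, measurement_cv = -1), ">= 0")
})

test_that("transmission estimation recovers simulated drive", {
  rec <- parameter_recovery(0.7, n_offspring = 200, replicates = 60,
                            seed = 100)
  expect_lt(abs(rec$bias), 0.01)
  expect_gte(rec$coverage, 0.85)

  # null symmetry
  rec5 <- parameter_recovery(0.5, n_offspring = 200, replicates = 60,
                             seed = 200)
  expect_lt(abs(rec5$bias), 0.01)

  # Wilson interval holds up near the boundary at small cohorts
  rec95 <- parameter_recovery(0.95, n_offspring = 50, replicates = 100,
                              seed = 300)
  expect_gte(rec95$coverage, 0.9)
})
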