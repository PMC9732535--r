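#' Configuration for the trivalent-segregation simulator
#'
#' Bundles the ground-truth parameters of a simulated cross between a
#' multiple-Rb heterozygote and an all-telocentric homozygote. Defaults
#' reproduce the design of the motivating experiment: 8 trivalents,
#' Mendelian transmission, a female heterozygous parent with 83 offspring
#' in litters averaging 4.4 pups, all-telocentric base 2n = 40.
#'
#' @param n_trivalents Number of trivalents in the heterozygous parent.
#' @param drive Per-trivalent transmission probability of the Rb
#'   metacentric (scalar recycled, or vector of length `n_trivalents`).
#'   0.5 is Mendelian; values above favour the metacentric.
#' @param viability Optional relative survival weight for each offspring
#'   Rb-count class k = 0..n (length n + 1, non-negative, not all zero).
#'   `NULL` means uniform viability. Selection acts on the offspring's
#'   genotype class, the minimal mechanism producing shape distortion with
#'   a near-Mendelian mean.
#' @param n_offspring Number of surviving offspring to generate.
#' @param mean_litter_size Mean litter size; litters are
#'   zero-truncated Poisson.
#' @param het_parent_sex `"female"` or `"male"`.
#' @param telocentric_base Diploid number of the all-telocentric
#'   karyotype (default 40).
#' @param n_plates Metaphase plates counted per animal (default 10).
#' @param miscount_rate Probability that any one plate count is off by one
#'   (technical miscount); default 0.
#' @param seed Integer seed; fully determines the simulated dataset.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_trivalents = 8, drive = 0.5, viability = NULL,
                       n_offspring = 83, mean_litter_size = 4.4,
                       het_parent_sex = c("female", "male"),
                       telocentric_base = 40, n_plates = 10,
                       miscount_rate = 0, seed = 1L) {
  het_parent_sex <- match.arg(het_parent_sex)
  model <- segregation_model(n_trivalents, drive)  # validates drive
  if (!is.null(viability)) {
    if (length(viability) != n_trivalents + 1L) {
      stop("`viability` must have length n_trivalents + 1", call. = FALSE)
    }
    if (anyNA(viability) || any(viability < 0) || all(viability == 0)) {
      stop("`viability` weights must be non-negative and not all zero",
           call. = FALSE)
    }
  }
  if (n_offspring < 1) stop("`n_offspring` must be >= 1", call. = FALSE)
  if (mean_litter_size <= 0) stop("`mean_litter_size` must be > 0",
                                  call. = FALSE)
  if (miscount_rate < 0 || miscount_rate > 1) {
    stop("`miscount_rate` must be in [0, 1]", call. = FALSE)
  }
  structure(list(n_trivalents = model$n_trivalents, drive = model$p,
                 viability = viability, n_offspring = as.integer(n_offspring),
                 mean_litter_size = mean_litter_size,
                 het_parent_sex = het_parent_sex,
                 telocentric_base = as.integer(telocentric_base),
                 n_plates = as.integer(n_plates),
                 miscount_rate = miscount_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate offspring karyotypes from a heterozygous x homozygous cross
#'
#' Each offspring's Rb count k is drawn from the distribution proportional
#' to PoissonBinomial(k; drive) * viability\[k\]; its diploid number is
#' `telocentric_base - k`; its plate counts are `n_plates` replicates of k,
#' each independently off by one with probability `miscount_rate` (clipped
#' to 0..n). Offspring are grouped into litters of zero-truncated
#' Poisson(`mean_litter_size`) size. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Offspring table: data frame with columns `animal_id`,
#'   `het_parent_sex`, `rb_count`, `diploid_n`, `plate_counts`
#'   (semicolon-joined) and `litter_id`, with an `n_trivalents` attribute.
#'   Compatible with [observed_distribution()], [validate_record()] and
#'   [write_offspring_table()].
#' @examples
#' off <- simulate_offspring(sim_config(n_offspring = 20, seed = 42))
#' observed_distribution(off)
#' @export
simulate_offspring <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_trivalents
  with_rb_seed(config$seed, {
    pmf <- transmission_pmf(segregation_model(n, config$drive))
    if (!is.null(config$viability)) {
      pmf <- pmf * config$viability
      if (sum(pmf) == 0) {
        stop("viability weights remove all reachable Rb-count classes",
             call. = FALSE)
      }
    }
    pmf <- pmf / sum(pmf)
    N <- config$n_offspring
    k <- sample(0:n, N, replace = TRUE, prob = pmf)

    # zero-truncated Poisson litters covering all N offspring
    sizes <- integer(0)
    while (sum(sizes) < N) {
      draw <- stats::rpois(N, config$mean_litter_size)
      sizes <- c(sizes, draw[draw >= 1])
    }
    sizes <- sizes[seq_len(which(cumsum(sizes) >= N)[1])]
    litter <- rep(seq_along(sizes), sizes)[seq_len(N)]

    plates <- vapply(k, function(ki) {
      p <- rep(ki, config$n_plates)
      flip <- stats::runif(config$n_plates) < config$miscount_rate
      if (any(flip)) {
        shift <- sample(c(-1L, 1L), sum(flip), replace = TRUE)
        p[flip] <- pmin(pmax(p[flip] + shift, 0L), n)
      }
      paste(p, collapse = ";")
    }, character(1))

    out <- data.frame(
      animal_id = sprintf("sim%04d", seq_len(N)),
      het_parent_sex = config$het_parent_sex,
      rb_count = as.integer(k),
      diploid_n = config$telocentric_base - as.integer(k),
      plate_counts = plates,
      litter_id = sprintf("L%03d", litter),
      stringsAsFactors = FALSE)
    attr(out, "n_trivalents") <- n
    out
  })
}

#' Simulate chromosome length measurements with known true ratio
#'
#' Emulates the morphometry design: per metaphase plate a compaction
#' factor is drawn (lognormal, coefficient of variation `compaction_cv`)
#' that scales all lengths of that plate jointly; each chromatid length
#' and the pericentromeric length then receive independent multiplicative
#' lognormal noise (cv = `measurement_cv`). With zero measurement noise
#' every measurement's CL/TL ratio equals `true_ratio_pct` exactly,
#' whatever the compaction; with noise, the expected ratio carries a small
#' positive bias below `0.5 * measurement_cv^2 * true_ratio_pct` (from noise in the
#' denominator chromatid mean).
#'
#' @param true_ratio_pct Ground-truth CL/TL percentage, in (0, 100\].
#' @param n_plates Number of metaphase plates (>= 1).
#' @param chromosomes_per_plate Rb chromosomes measured per plate.
#' @param compaction_cv,measurement_cv Coefficients of variation (>= 0).
#' @param seed Integer seed.
#' @param animal_id Id written on every measurement.
#' @param base_length_px Nominal chromatid length in pixels before
#'   compaction (default 400, a typical digitized metaphase scale).
#' @return Measurement data frame with columns `animal_id`, `plate_id`,
#'   `chromosome_id`, `chromatid_len_1`, `chromatid_len_2`,
#'   `pericentromeric_len`.
#' @export
simulate_measurements <- function(true_ratio_pct, n_plates = 20,
                                  chromosomes_per_plate = 8,
                                  compaction_cv = 0.3,
                                  measurement_cv = 0.05, seed = 1L,
                                  animal_id = "sim",
                                  base_length_px = 400) {
  if (true_ratio_pct <= 0 || true_ratio_pct > 100) {
    stop("`true_ratio_pct` must be in (0, 100]", call. = FALSE)
  }
  if (compaction_cv < 0 || measurement_cv < 0) {
    stop("coefficients of variation must be >= 0", call. = FALSE)
  }
  if (n_plates < 1 || chromosomes_per_plate < 1) {
    stop("need at least one plate and one chromosome per plate",
         call. = FALSE)
  }
  # lognormal with unit mean and given cv
  rln1 <- function(m, cv) {
    if (cv == 0) return(rep(1, m))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(m, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  with_rb_seed(seed, {
    m <- n_plates * chromosomes_per_plate
    compaction <- rep(rln1(n_plates, compaction_cv),
                      each = chromosomes_per_plate)
    tl_true <- base_length_px * compaction
    cl_true <- tl_true * true_ratio_pct / 100
    data.frame(
      animal_id = animal_id,
      plate_id = sprintf("P%03d", rep(seq_len(n_plates),
                                      each = chromosomes_per_plate)),
      chromosome_id = sprintf("chr%02d", rep(seq_len(chromosomes_per_plate),
                                             n_plates)),
      chromatid_len_1 = tl_true * rln1(m, measurement_cv),
      chromatid_len_2 = tl_true * rln1(m, measurement_cv),
      pericentromeric_len = cl_true * rln1(m, measurement_cv),
      stringsAsFactors = FALSE)
  })
}

#' Validate transmission estimation by parameter recovery
#'
#' Simulates `replicates` independent cohorts with a homogeneous known
#' drive, runs [estimate_transmission()] on each, and reports the mean
#' estimate, bias, and the coverage of the Wilson 95% interval.
#'
#' @param drive_true True per-trivalent transmission probability (0, 1).
#' @param n_offspring Offspring per simulated cohort.
#' @param replicates Number of cohorts.
#' @param seed Integer seed; replicate r uses seed + r.
#' @param n_trivalents Trivalent count (default 8).
#' @return An object of class `rb_recovery`: list with `drive_true`,
#'   `estimates`, `mean_estimate`, `bias`, `coverage`, `replicates`.
#' @export
parameter_recovery <- function(drive_true, n_offspring, replicates,
                               seed = 1L, n_trivalents = 8) {
  if (drive_true <= 0 || drive_true >= 1) {
    stop("`drive_true` must be strictly inside (0, 1)", call. = FALSE)
  }
  est <- numeric(replicates)
  cover <- logical(replicates)
  for (r in seq_len(replicates)) {
    cfg <- sim_config(n_trivalents = n_trivalents, drive = drive_true,
                      n_offspring = n_offspring, seed = seed + r)
    d <- observed_distribution(simulate_offspring(cfg))
    fit <- estimate_transmission(d)
    est[r] <- fit$estimate
    cover[r] <- fit$conf_int[1] <= drive_true &&
      drive_true <= fit$conf_int[2]
  }
  structure(list(drive_true = drive_true, estimates = est,
                 mean_estimate = mean(est), bias = mean(est) - drive_true,
                 coverage = mean(cover), replicates = replicates),
            class = "rb_recovery")
}

#' @export
print.rb_recovery <- function(x, ...) {
  cat("Transmission parameter recovery (", x$replicates, " replicates)\n",
      sep = "")
  cat("  true drive:", x$drive_true,
      " mean estimate:", format(x$mean_estimate, digits = 4),
      " bias:", format(x$bias, digits = 3), "\n")
  cat("  Wilson 95% CI coverage:", format(x$coverage, digits = 3), "\n")
  invisible(x)
}
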