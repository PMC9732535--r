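#' Goodness-of-fit test of observed Rb counts against a segregation model
#'
#' Tests whether the observed distribution of inherited Rb counts is
#' consistent with the expected Poisson-binomial (under the Mendelian null,
#' binomial) distribution. The `asymptotic` method is the classical
#' chi-square test, statistic \eqn{\sum_k (O_k - E_k)^2 / E_k} with
#' df = bins - 1 and the upper chi-square tail. Because tail bins of a
#' Binomial(8, 0.5) null have expected counts well below 5 at realistic
#' cohort sizes, the asymptotic p-value can be anticonservative; the
#' `monte_carlo` method instead resamples cohorts as multinomial(N, pmf)
#' draws and reports the add-one estimate
#' p = (1 + #\{resampled statistic >= observed\}) / (1 + n_resamples),
#' which is never exactly zero. `pool_below` optionally merges adjacent
#' tail bins inward until every retained bin's expected count reaches the
#' threshold, reducing the degrees of freedom accordingly.
#'
#' @param observed A [count_distribution()].
#' @param model A [segregation_model()] with matching `n_trivalents`.
#' @param method `"asymptotic"` (default) or `"monte_carlo"`.
#' @param pool_below Optional expected-count threshold; tail bins with
#'   expected counts below it are pooled into their inward neighbour
#'   before the statistic and df are computed. `NULL` (default) keeps all
#'   bins, reproducing the unpooled df = n chi-square convention used in
#'   published karyotype-segregation analyses.
#' @param n_resamples Number of multinomial resamples for `monte_carlo`
#'   (>= 1000).
#' @param seed Seed for the Monte-Carlo resampling (required for
#'   reproducibility; ignored by the asymptotic method).
#' @return An object of class `rb_gof` with fields `statistic`, `df`
#'   (asymptotic only), `p_value`, `observed`, `expected`, `method`,
#'   `n_resamples`, `seed` and `pooled_bins`.
#' @examples
#' male <- count_distribution(c(2, 1, 5, 14, 14, 10, 5, 1, 4), 8, "male")
#' gof_test(male, segregation_model(8, 0.5))
#' @export
gof_test <- function(observed, model,
                     method = c("asymptotic", "monte_carlo"),
                     pool_below = NULL, n_resamples = 10000, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(observed, "count_distribution"),
            inherits(model, "segregation_model"))
  if (observed$n_trivalents != model$n_trivalents) {
    stop("distribution and model disagree on the number of trivalents",
         call. = FALSE)
  }
  if (observed$N < 1) stop("empty distribution", call. = FALSE)
  if (method == "monte_carlo" && n_resamples < 1000) {
    stop("`n_resamples` must be at least 1000", call. = FALSE)
  }

  pmf <- transmission_pmf(model)
  expected <- observed$N * pmf
  pooling <- pool_tail_bins(expected, pool_below)
  O <- pool_counts(observed$counts, pooling$groups)
  E <- pool_counts(expected, pooling$groups)

  if (any(E == 0 & O > 0)) {
    stat <- Inf
  } else {
    nz <- E > 0
    stat <- sum((O[nz] - E[nz])^2 / E[nz])
  }

  if (method == "asymptotic") {
    df <- length(E) - 1L
    p <- if (is.finite(stat)) stats::pchisq(stat, df, lower.tail = FALSE)
         else 0
    res <- list(statistic = stat, df = df, p_value = p,
                observed = O, expected = E, method = "asymptotic",
                n_resamples = NA_integer_, seed = NULL,
                pooled_bins = pooling$description)
  } else {
    sim_stat <- with_rb_seed(seed, {
      sims <- stats::rmultinom(n_resamples, observed$N, pmf)
      sims <- apply(sims, 2, pool_counts, groups = pooling$groups)
      if (is.null(dim(sims))) sims <- matrix(sims, nrow = 1L)
      nz <- E > 0
      s <- colSums((sims[nz, , drop = FALSE] - E[nz])^2 / E[nz])
      if (any(!nz)) {
        s[colSums(sims[!nz, , drop = FALSE] > 0) > 0] <- Inf
      }
      s
    })
    p <- (1 + sum(sim_stat >= stat)) / (1 + n_resamples)
    res <- list(statistic = stat, df = NA_integer_, p_value = p,
                observed = O, expected = E, method = "monte_carlo",
                n_resamples = as.integer(n_resamples), seed = seed,
                pooled_bins = pooling$description)
  }
  structure(res, class = "rb_gof")
}

# Merge tail bins whose expected count falls below `threshold` into their
# inward neighbour, working from each end toward the centre. Returns the
# group index of each original bin plus a human-readable description.
pool_tail_bins <- function(expected, threshold) {
  m <- length(expected)
  groups <- seq_len(m)
  if (is.null(threshold)) {
    return(list(groups = groups, description = "none"))
  }
  lo <- 1L
  while (lo < m && sum(expected[seq_len(lo)]) < threshold) lo <- lo + 1L
  hi <- m
  while (hi > lo && sum(expected[hi:m]) < threshold) hi <- hi - 1L
  groups[seq_len(m) <= lo] <- lo
  groups[seq_len(m) >= hi] <- hi
  groups <- match(groups, unique(groups))
  desc <- c(if (lo > 1L) sprintf("k<=%d pooled", lo - 1L),
            if (hi < m) sprintf("k>=%d pooled", hi - 1L))
  list(groups = groups,
       description = if (length(desc)) paste(desc, collapse = "; ")
                     else "none")
}

pool_counts <- function(x, groups) {
  as.numeric(tapply(x, groups, sum))
}

#' @export
print.rb_gof <- function(x, ...) {
  cat("Goodness-of-fit to segregation null (", x$method, ")\n", sep = "")
  cat("  statistic =", format(x$statistic, digits = 6))
  if (x$method == "asymptotic") cat(", df =", x$df)
  cat(", p-value =", fmt_p(x$p_value), "\n")
  if (x$method == "monte_carlo") {
    cat("  resamples =", x$n_resamples,
        if (!is.null(x$seed)) paste0("(seed ", x$seed, ")"), "\n")
  }
  cat("  bin pooling:", x$pooled_bins, "\n")
  invisible(x)
}

#' One-sample binomial proportion test
#'
#' Tests an observed proportion against a null value `p0`. The
#' `normal_approx` method uses the score z statistic
#' \eqn{z = (\hat p - p_0) / \sqrt{p_0 (1 - p_0) / n}} without continuity
#' correction; the `exact_binomial` method uses binomial tail sums. The
#' two-sided p-value is twice the smaller one-sided tail, capped at 1.
#' A two-sided Wilson score interval at `conf_level` is always attached.
#'
#' @param successes,trials Observed successes out of trials (trials >= 1).
#' @param p0 Null proportion, strictly inside (0, 1).
#' @param alternative `"greater"`, `"less"` or `"two_sided"`.
#' @param method `"normal_approx"` (default) or `"exact_binomial"`.
#' @param conf_level Confidence level for the Wilson interval.
#' @return An object of class `rb_proportion` with fields `estimate`, `z`
#'   (`NA` for the exact method), `p_value`, `method`, `alternative`,
#'   `conf_int`, `successes`, `trials`, `p0`.
#' @examples
#' proportion_test(5, 6, 0.5, "greater")                     # p = 0.0512
#' proportion_test(5, 6, 0.5, "greater", "exact_binomial")   # p = 7/64
#' @export
proportion_test <- function(successes, trials, p0 = 0.5,
                            alternative = c("greater", "less", "two_sided"),
                            method = c("normal_approx", "exact_binomial"),
                            conf_level = 0.95) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  stopifnot(trials >= 1, successes >= 0, successes <= trials,
            p0 > 0, p0 < 1)
  phat <- successes / trials
  if (method == "normal_approx") {
    z <- (phat - p0) / sqrt(p0 * (1 - p0) / trials)
    p <- switch(alternative,
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z),
      two_sided = min(1, 2 * stats::pnorm(-abs(z))))
  } else {
    z <- NA_real_
    p_hi <- stats::pbinom(successes - 1, trials, p0, lower.tail = FALSE)
    p_lo <- stats::pbinom(successes, trials, p0)
    p <- switch(alternative,
      greater = p_hi, less = p_lo,
      two_sided = min(1, 2 * min(p_hi, p_lo)))
  }
  structure(list(estimate = phat, z = z, p_value = p, method = method,
                 alternative = alternative,
                 conf_int = wilson_ci(successes, trials, conf_level),
                 successes = successes, trials = trials, p0 = p0),
            class = "rb_proportion")
}

#' @export
print.rb_proportion <- function(x, ...) {
  cat("Binomial proportion test (", x$method, ", ", x$alternative,
      ")\n", sep = "")
  cat("  ", x$successes, "/", x$trials, " = ",
      fmt_pct(100 * x$estimate), "% vs p0 = ", x$p0, "\n", sep = "")
  if (!is.na(x$z)) cat("  z =", format(x$z, digits = 4), "")
  cat("  p-value =", fmt_p(x$p_value), "\n")
  cat("  95% Wilson CI: [", fmt_pct(100 * x$conf_int[1]), "%, ",
      fmt_pct(100 * x$conf_int[2]), "%]\n", sep = "")
  invisible(x)
}

#' Estimate the per-trivalent transmission proportion
#'
#' Treats each of the `n_trivalents * N` trivalent segregations in a
#' cohort as an independent Bernoulli trial and estimates the probability
#' that a trivalent transmits its Rb metacentric: total Rb count over
#' maximum possible. A Wilson 95% interval and a two-sided normal test
#' against the Mendelian 0.5 are attached. The trial count assumes
#' independence across trivalents and across littermates; littermate
#' correlation would make the interval anticonservative.
#'
#' @param dist A [count_distribution()] with N >= 1.
#' @return An `rb_proportion` (see [proportion_test()]) with an
#'   `assumes_independence` flag.
#' @examples
#' fem <- count_distribution(c(6, 7, 22, 10, 20, 15, 2, 0, 1), 8)
#' estimate_transmission(fem)$estimate  # 256/664
#' @export
estimate_transmission <- function(dist) {
  stopifnot(inherits(dist, "count_distribution"))
  if (dist$N < 1) stop("empty distribution", call. = FALSE)
  res <- proportion_test(total_rb(dist), dist$n_trivalents * dist$N,
                         p0 = 0.5, alternative = "two_sided",
                         method = "normal_approx")
  res$assumes_independence <- TRUE
  res
}

#' Compare transmission proportions between two cohorts
#'
#' Pooled two-proportion z-test on aggregated trivalent-level outcomes:
#' cohort i contributes `total_rb` successes out of `n_trivalents * N_i`
#' trials. The z statistic is signed for cohort A minus cohort B; the
#' p-value is two-sided. Assumes independent trivalent segregations
#' within and between offspring.
#'
#' @param dist_a,dist_b Two [count_distribution()]s with N >= 1.
#' @return An object of class `rb_two_proportion` with `estimate_a`,
#'   `estimate_b`, `z`, `p_value`, `conf_int` (Wald 95% CI on the
#'   difference) and labels.
#' @export
compare_transmission <- function(dist_a, dist_b) {
  stopifnot(inherits(dist_a, "count_distribution"),
            inherits(dist_b, "count_distribution"))
  if (dist_a$N < 1 || dist_b$N < 1) stop("empty distribution", call. = FALSE)
  x1 <- total_rb(dist_a); n1 <- dist_a$n_trivalents * dist_a$N
  x2 <- total_rb(dist_b); n2 <- dist_b$n_trivalents * dist_b$N
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se_pooled <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se_pooled == 0) 0 else (p1 - p2) / se_pooled
  p <- if (z == 0) 1 else min(1, 2 * stats::pnorm(-abs(z)))
  se_wald <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  zc <- stats::qnorm(0.975)
  structure(list(estimate_a = p1, estimate_b = p2, z = z, p_value = p,
                 conf_int = (p1 - p2) + c(-1, 1) * zc * se_wald,
                 label_a = dist_a$label, label_b = dist_b$label,
                 trials = c(n1, n2), successes = c(x1, x2)),
            class = "rb_two_proportion")
}

#' @export
print.rb_two_proportion <- function(x, ...) {
  cat("Two-proportion comparison of Rb transmission\n")
  cat("  ", x$label_a, ": ", x$successes[1], "/", x$trials[1], " = ",
      fmt_pct(100 * x$estimate_a), "%\n", sep = "")
  cat("  ", x$label_b, ": ", x$successes[2], "/", x$trials[2], " = ",
      fmt_pct(100 * x$estimate_b), "%\n", sep = "")
  cat("  z =", format(x$z, digits = 4),
      " two-sided p =", fmt_p(x$p_value), "\n")
  invisible(x)
}

#' Dispersion test: is the spread of Rb counts binomial?
#'
#' A cohort can match the Mendelian mean yet still deviate in shape (e.g.
#' excess of extreme karyotypes). This test compares the sample variance
#' of the per-offspring Rb count with the binomial variance implied by the
#' fitted mean: statistic = var(k) / (n * phat * (1 - phat)), phat the
#' fitted per-trivalent transmission fraction. The two-sided p-value comes
#' from a parametric bootstrap under Binomial(n, phat): each resampled
#' cohort is refitted, and p = 2 * min(add-one upper tail, add-one lower
#' tail), capped at 1. Values > 1 indicate overdispersion.
#'
#' @param dist A [count_distribution()] with N >= 2 and non-degenerate
#'   counts (an all-one-k cohort has no defined variance ratio).
#' @param model A [segregation_model()]; only `n_trivalents` is used (the
#'   null transmission is refitted from the data).
#' @param n_resamples Bootstrap replicates (default 10000).
#' @param seed RNG seed.
#' @return An object of class `rb_gof` with `method = "monte_carlo"`.
#' @export
dispersion_test <- function(dist, model, n_resamples = 10000, seed = NULL) {
  stopifnot(inherits(dist, "count_distribution"),
            inherits(model, "segregation_model"))
  if (dist$N < 2) stop("need at least two offspring", call. = FALSE)
  n <- model$n_trivalents
  ks <- rep(0:dist$n_trivalents, dist$counts)
  if (stats::var(ks) == 0) {
    stop("all offspring share one Rb count; variance ratio undefined",
         call. = FALSE)
  }
  disp <- function(k) {
    ph <- mean(k) / n
    denom <- n * ph * (1 - ph)
    if (denom == 0) return(NA_real_)
    stats::var(k) / denom
  }
  stat <- disp(ks)
  sim <- with_rb_seed(seed, {
    phat <- mean(ks) / n
    draws <- matrix(stats::rbinom(n_resamples * dist$N, n, phat),
                    nrow = dist$N)
    apply(draws, 2, disp)
  })
  sim <- sim[!is.na(sim)]
  B <- length(sim)
  p_hi <- (1 + sum(sim >= stat)) / (1 + B)
  p_lo <- (1 + sum(sim <= stat)) / (1 + B)
  structure(list(statistic = stat, df = NA_integer_,
                 p_value = min(1, 2 * min(p_hi, p_lo)),
                 observed = dist$counts, expected = NULL,
                 method = "monte_carlo", n_resamples = as.integer(B),
                 seed = seed, pooled_bins = "none"),
            class = "rb_gof")
}
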