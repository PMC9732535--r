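# Observed offspring Rb-count distributions from the packaged cross data
# (83 offspring of heterozygous mothers, 56 of heterozygous fathers),
# built in code so tests do not depend on the reader under test.
female_counts <- c(6, 7, 22, 10, 20, 15, 2, 0, 1)
male_counts <- c(2, 1, 5, 14, 14, 10, 5, 1, 4)
female_dist <- count_distribution(female_counts, 8, "female")
male_dist <- count_distribution(male_counts, 8, "male")
null_model <- segregation_model(8, 0.5)

offspring_schema <- c("animal_id", "het_parent_sex", "rb_count",
                      "diploid_n", "plate_counts")

# Independent oracle: Poisson-binomial pmf by exhaustive enumeration of
# all 2^n gamete outcomes with product weights.
enum_pmf <- function(p) {
  n <- length(p)
  pmf <- numeric(n + 1)
  for (code in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(n)]
    w <- prod(ifelse(bits == 1, p, 1 - p))
    k <- sum(bits)
    pmf[k + 1] <- pmf[k + 1] + w
  }
  pmf
}

# Independent oracle: exact multinomial tail probability
# P(chi-square statistic >= stat_obs) by enumerating every composition
# of N over the bins of `pmf`.
enum_gof_tail <- function(observed, pmf) {
  N <- sum(observed)
  E <- N * pmf
  stat <- function(o) sum((o - E)^2 / E)
  s_obs <- stat(observed)
  m <- length(pmf)
  tail_p <- 0
  recurse <- function(prefix, remaining) {
    if (length(prefix) == m - 1L) {
      o <- c(prefix, remaining)
      if (stat(o) >= s_obs - 1e-12) {
        tail_p <<- tail_p + stats::dmultinom(o, prob = pmf)
      }
      return(invisible())
    }
    for (v in 0:remaining) recurse(c(prefix, v), remaining - v)
  }
  recurse(integer(0), N)
  tail_p
}
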