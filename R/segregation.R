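#' Segregation model for Robertsonian trivalents
#'
#' A segregation model describes meiosis in a multiple-Rb heterozygote as
#' `n_trivalents` independent trivalents, each transmitting its metacentric
#' Rb chromosome to a gamete with probability `p[i]` (and the two homologous
#' telocentrics otherwise). The Mendelian null is `p = 0.5` for every
#' trivalent; per-trivalent deviations model meiotic drive.
#'
#' @param n_trivalents Number of trivalents formed in the heterozygous
#'   parent (8 for a CD1 x Milano II F1 heterozygote).
#' @param p Per-trivalent transmission probability of the metacentric.
#'   A scalar is recycled to all trivalents; a vector must have length
#'   `n_trivalents` and every element in \[0, 1\].
#' @return An object of class `segregation_model` with fields
#'   `n_trivalents` and `p`.
#' @examples
#' segregation_model(8, 0.5)                  # Mendelian null
#' segregation_model(8, c(0.7, rep(0.5, 7)))  # drive on one trivalent
#' @export
segregation_model <- function(n_trivalents = 8, p = 0.5) {
  if (length(n_trivalents) != 1L || is.na(n_trivalents) ||
      n_trivalents < 1 || n_trivalents != round(n_trivalents)) {
    stop("`n_trivalents` must be a single positive integer", call. = FALSE)
  }
  n_trivalents <- as.integer(n_trivalents)
  if (length(p) == 1L) p <- rep(as.numeric(p), n_trivalents)
  if (length(p) != n_trivalents) {
    stop("`p` must be a scalar or a vector of length `n_trivalents`",
         call. = FALSE)
  }
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("every transmission probability must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_trivalents = n_trivalents, p = as.numeric(p)),
            class = "segregation_model")
}

#' @export
print.segregation_model <- function(x, ...) {
  cat("Trivalent segregation model\n")
  cat("  trivalents:", x$n_trivalents, "\n")
  if (length(unique(x$p)) == 1L) {
    cat("  transmission p:", format(x$p[1]), "(homogeneous)\n")
  } else {
    cat("  transmission p:", paste(format(x$p), collapse = " "), "\n")
  }
  invisible(x)
}

#' Distribution of the number of transmitted Rb chromosomes
#'
#' Probability mass function of the number of Rb metacentrics transmitted
#' across all trivalents, i.e. the Poisson-binomial distribution of the sum
#' of independent Bernoulli(`p[i]`) trials. Computed by exact iterative
#' convolution in O(n^2); when all `p[i]` are equal this reduces to
#' Binomial(`n_trivalents`, p).
#'
#' @param model A [segregation_model()].
#' @return Numeric vector of length `n_trivalents + 1`; element `k + 1` is
#'   P(k Rb chromosomes transmitted). Sums to 1 to within 1e-12.
#' @examples
#' round(100 * transmission_pmf(segregation_model(8, 0.5)), 2)
#' @export
transmission_pmf <- function(model) {
  stopifnot(inherits(model, "segregation_model"))
  pmf <- 1
  for (p_i in model$p) {
    pmf <- c(pmf * (1 - p_i), 0) + c(0, pmf * p_i)
  }
  names(pmf) <- 0:model$n_trivalents
  pmf
}

#' Expected offspring frequencies under a segregation model
#'
#' Scales the transmission pmf to a cohort of `N` offspring, giving the
#' expected number of offspring carrying each possible Rb count.
#'
#' @param model A [segregation_model()].
#' @param N Number of offspring (non-negative).
#' @return Numeric vector over k = 0..n summing to `N`.
#' @examples
#' expected_counts(segregation_model(8, 0.5), 56)[5]  # 15.3125 at k = 4
#' @export
expected_counts <- function(model, N) {
  if (length(N) != 1L || is.na(N) || N < 0) {
    stop("`N` must be a single non-negative number", call. = FALSE)
  }
  N * transmission_pmf(model)
}

#' Observed distribution of inherited Rb counts
#'
#' Tabulates an offspring table into counts of offspring indexed by the
#' number of Rb chromosomes inherited (k = 0..n), optionally restricted to
#' the offspring of heterozygous mothers or fathers.
#'
#' @param records Offspring table as returned by [read_offspring_table()]
#'   or [simulate_offspring()]: a data frame with at least columns
#'   `het_parent_sex` and `rb_count`.
#' @param sex `"female"`, `"male"` or `"all"`: which heterozygous-parent
#'   sex to keep.
#' @param n_trivalents Number of trivalents; defaults to the table's
#'   `n_trivalents` attribute, else 8.
#' @param label Free-text label stored on the result (defaults to `sex`).
#' @return A `count_distribution`: list with `n_trivalents`, integer
#'   `counts` (length n + 1, named 0..n), `N` and `label`.
#' @export
observed_distribution <- function(records, sex = c("all", "female", "male"),
                                  n_trivalents = NULL, label = NULL) {
  sex <- match.arg(sex)
  if (is.null(n_trivalents)) {
    n_trivalents <- attr(records, "n_trivalents")
    if (is.null(n_trivalents)) n_trivalents <- 8L
  }
  keep <- if (sex == "all") rep(TRUE, nrow(records)) else
    records$het_parent_sex == sex
  k <- records$rb_count[keep]
  if (anyNA(k) || any(k < 0 | k > n_trivalents)) {
    stop("rb_count outside 0..", n_trivalents, " in offspring table",
         call. = FALSE)
  }
  counts <- tabulate(k + 1L, nbins = n_trivalents + 1L)
  count_distribution(counts, n_trivalents,
                     label = if (is.null(label)) sex else label)
}

#' Construct a count distribution of offspring Rb counts
#'
#' @param counts Non-negative integer vector of length `n_trivalents + 1`;
#'   element k + 1 is the number of offspring that inherited k Rb
#'   chromosomes.
#' @param n_trivalents Number of trivalents (maximum inheritable count).
#' @param label Free text (e.g. the heterozygous parent's sex).
#' @return An object of class `count_distribution`.
#' @examples
#' count_distribution(c(6, 7, 22, 10, 20, 15, 2, 0, 1), 8, "female")
#' @export
count_distribution <- function(counts, n_trivalents = length(counts) - 1L,
                               label = "") {
  n_trivalents <- as.integer(n_trivalents)
  if (length(counts) != n_trivalents + 1L) {
    stop("`counts` must have length n_trivalents + 1", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("`counts` must be non-negative integers", call. = FALSE)
  }
  counts <- as.integer(round(counts))
  names(counts) <- 0:n_trivalents
  structure(list(n_trivalents = n_trivalents, counts = counts,
                 N = sum(counts), label = label),
            class = "count_distribution")
}

#' @export
print.count_distribution <- function(x, ...) {
  cat("Offspring Rb-count distribution",
      if (nzchar(x$label)) paste0("(", x$label, ")"), "\n")
  print(x$counts)
  cat("N =", x$N, "  total Rb =", total_rb(x), "\n")
  invisible(x)
}

#' Summary statistics of an Rb-count distribution
#'
#' `total_rb()` is the total number of Rb chromosomes carried by the
#' cohort, `mean_rb()` the mean per offspring, and `fraction_of_max()` the
#' total as a fraction of the maximum possible (`n_trivalents * N`) —
#' i.e. the pooled per-trivalent transmission proportion.
#'
#' @param dist A [count_distribution()].
#' @return `total_rb()` an integer; the others a real number
#'   (`fraction_of_max()` in \[0, 1\]).
#' @examples
#' d <- count_distribution(c(6, 7, 22, 10, 20, 15, 2, 0, 1), 8)
#' total_rb(d)          # 256
#' round(mean_rb(d), 2) # 3.08
#' @export
total_rb <- function(dist) {
  stopifnot(inherits(dist, "count_distribution"))
  sum(0:dist$n_trivalents * dist$counts)
}

#' @rdname total_rb
#' @export
mean_rb <- function(dist) {
  stopifnot(inherits(dist, "count_distribution"))
  if (dist$N < 1) stop("mean undefined for an empty distribution",
                       call. = FALSE)
  total_rb(dist) / dist$N
}

#' @rdname total_rb
#' @export
fraction_of_max <- function(dist) {
  stopifnot(inherits(dist, "count_distribution"))
  if (dist$N < 1) stop("fraction undefined for an empty distribution",
                       call. = FALSE)
  total_rb(dist) / (dist$n_trivalents * dist$N)
}

#' Consensus Rb count from repeated metaphase-plate counts
#'
#' Karyotyping counts Rb chromosomes in several metaphase plates per
#' animal (typically 10); the animal's karyotype is the modal plate count.
#' A tie for the mode is an ambiguous karyotype and raises an error of
#' class `rb_ambiguous_karyotype` — the plates must be re-examined rather
#' than silently tie-broken.
#'
#' @param plate_counts Integer vector of per-plate Rb counts (length >= 1).
#' @return The modal count, as an integer.
#' @examples
#' consensus_rb_count(c(3, 3, 3, 3, 3, 3, 3, 2, 3, 3))  # 3
#' @export
consensus_rb_count <- function(plate_counts) {
  if (length(plate_counts) < 1L || anyNA(plate_counts)) {
    stop("at least one non-missing plate count is required", call. = FALSE)
  }
  tab <- table(plate_counts)
  modes <- names(tab)[tab == max(tab)]
  if (length(modes) > 1L) {
    stop(structure(class = c("rb_ambiguous_karyotype", "error", "condition"),
                   list(message = paste0(
                     "ambiguous karyotype: plate counts tie between ",
                     paste(modes, collapse = " and "),
                     "; re-examine the metaphase plates"),
                     call = sys.call(-1))))
  }
  as.integer(modes)
}

#' Karyotype consistency check for offspring records
#'
#' For this cross design every Rb fusion reduces the diploid number by one
#' from the all-telocentric base (2n = 40), so a record is internally
#' consistent iff `diploid_n == telocentric_base - rb_count` and the Rb
#' count lies in 0..n. Vectorized over the rows of an offspring table;
#' returns a per-row report rather than failing.
#'
#' @param records Offspring table (data frame with `animal_id`, `rb_count`,
#'   `diploid_n`).
#' @param telocentric_base Diploid number of the all-telocentric karyotype
#'   (default 40).
#' @param n_trivalents Maximum inheritable Rb count (default from the
#'   table attribute, else 8).
#' @return Data frame with columns `animal_id`, `pass` (logical) and
#'   `reason` (`NA` when passing).
#' @examples
#' validate_record(data.frame(animal_id = "A", het_parent_sex = "male",
#'                            rb_count = 3, diploid_n = 37))
#' @export
validate_record <- function(records, telocentric_base = 40,
                            n_trivalents = NULL) {
  if (is.null(n_trivalents)) {
    n_trivalents <- attr(records, "n_trivalents")
    if (is.null(n_trivalents)) n_trivalents <- 8L
  }
  in_range <- records$rb_count >= 0 & records$rb_count <= n_trivalents
  consistent <- records$diploid_n == telocentric_base - records$rb_count
  pass <- in_range & consistent
  reason <- rep(NA_character_, nrow(records))
  reason[!in_range] <- sprintf("rb_count %d outside 0..%d",
                               records$rb_count[!in_range], n_trivalents)
  bad2n <- in_range & !consistent
  reason[bad2n] <- sprintf("diploid_n %d != %d - %d",
                           records$diploid_n[bad2n], telocentric_base,
                           records$rb_count[bad2n])
  data.frame(animal_id = records$animal_id, pass = pass, reason = reason,
             stringsAsFactors = FALSE)
}
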