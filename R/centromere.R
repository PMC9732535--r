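#' Compaction-normalized pericentromeric length (CL/TL x 100)
#'
#' The pericentromeric heterochromatin block of an Rb metacentric is
#' measured in pixels (CL) alongside both sister chromatids. The
#' chromosome's total length TL is taken as the average of the two
#' chromatid lengths, and the reported metric is 100 * CL / TL. Because
#' chromosome compaction scales all lengths of a plate jointly, the ratio
#' is invariant to compaction differences between plates.
#'
#' Vectorized: pass either a measurement data frame (columns
#' `chromatid_len_1`, `chromatid_len_2`, `pericentromeric_len`) or the
#' three length vectors.
#'
#' @param measurements Measurement data frame, or the first chromatid
#'   length vector.
#' @param chromatid_len_2,pericentromeric_len Remaining lengths when not
#'   passing a data frame.
#' @return Numeric vector of CL/TL percentages.
#' @examples
#' normalized_ratio(90, 110, 21.51)  # TL = 100, ratio 21.51
#' @export
normalized_ratio <- function(measurements, chromatid_len_2 = NULL,
                             pericentromeric_len = NULL) {
  if (is.data.frame(measurements)) {
    c1 <- measurements$chromatid_len_1
    c2 <- measurements$chromatid_len_2
    cl <- measurements$pericentromeric_len
  } else {
    c1 <- measurements; c2 <- chromatid_len_2; cl <- pericentromeric_len
  }
  if (anyNA(c(c1, c2, cl)) || any(c1 <= 0) || any(c2 <= 0) || any(cl <= 0)) {
    stop("all lengths must be positive", call. = FALSE)
  }
  100 * cl / ((c1 + c2) / 2)
}

#' Per-animal summary of normalized pericentromeric lengths
#'
#' `summarize_animal()` reduces one animal's chromosome measurements to
#' the mean and sd of the CL/TL percentage; `summarize_animals()` does so
#' for every animal in a table.
#'
#' @param measurements Measurement data frame (see [normalized_ratio()]),
#'   with an `animal_id` column.
#' @param animal_id Animal to summarize (must have >= 1 measurement).
#' @return A one-row (or per-animal) data frame with `animal_id`,
#'   `n_measurements`, `mean_ratio_pct`, `sd_ratio_pct`.
#' @export
summarize_animal <- function(measurements, animal_id) {
  m <- measurements[measurements$animal_id == animal_id, , drop = FALSE]
  if (nrow(m) < 1L) {
    stop("no measurements for animal ", animal_id, call. = FALSE)
  }
  r <- normalized_ratio(m)
  data.frame(animal_id = animal_id, n_measurements = length(r),
             mean_ratio_pct = mean(r),
             sd_ratio_pct = if (length(r) > 1) stats::sd(r) else 0,
             stringsAsFactors = FALSE)
}

#' @rdname summarize_animal
#' @export
summarize_animals <- function(measurements) {
  ids <- unique(measurements$animal_id)
  do.call(rbind, lapply(ids, summarize_animal, measurements = measurements))
}

#' Count animals whose pericentromeric metric exceeds a reference
#'
#' Counts the summaries whose mean CL/TL percentage is strictly greater
#' than `reference_pct` (typically the heterozygous parent's own mean over
#' its full Rb complement).
#'
#' @param summaries Per-animal summary data frame
#'   (see [summarize_animals()] or [rb_example_centromere_summary()]).
#' @param reference_pct Reference CL/TL percentage.
#' @return Integer count.
#' @examples
#' s <- data.frame(animal_id = LETTERS[1:3],
#'                 mean_ratio_pct = c(21.1, 25.6, 21.7))
#' count_exceeding(s, 21.51)  # 2
#' @export
count_exceeding <- function(summaries, reference_pct) {
  stopifnot(nrow(summaries) >= 1, length(reference_pct) == 1)
  sum(summaries$mean_ratio_pct > reference_pct)
}

#' Test whether exceedance of the parental reference is more than chance
#'
#' Under random inheritance of pericentromeric size, each descendant's
#' mean CL/TL is equally likely to fall above or below the parental
#' reference; the exceedance count is then Binomial(n, 0.5). Delegates to
#' [proportion_test()] with a one-sided (greater) alternative.
#'
#' @inheritParams count_exceeding
#' @param method `"normal_approx"` (default) or `"exact_binomial"`.
#' @return An `rb_proportion` (see [proportion_test()]).
#' @export
exceedance_test <- function(summaries, reference_pct,
                            method = c("normal_approx", "exact_binomial")) {
  method <- match.arg(method)
  proportion_test(count_exceeding(summaries, reference_pct),
                  nrow(summaries), p0 = 0.5,
                  alternative = "greater", method = method)
}
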