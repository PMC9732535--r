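offspring_cols <- c("animal_id", "het_parent_sex", "rb_count", "diploid_n",
                    "plate_counts")
measurement_cols <- c("animal_id", "plate_id", "chromosome_id",
                      "chromatid_len_1", "chromatid_len_2",
                      "pericentromeric_len")

#' Read and write offspring karyotype tables
#'
#' Tab-separated text with header
#' `animal_id het_parent_sex rb_count diploid_n plate_counts`
#' (`plate_counts` a semicolon-joined integer list or empty; extra columns
#' such as `litter_id` are preserved). On read, every row is checked for
#' integer counts, a valid parent sex, an Rb count in 0..n, and the
#' karyotype consistency `diploid_n == telocentric_base - rb_count`;
#' failures are reported with their file line numbers, as an error when
#' `strict = TRUE` (default) or a warning otherwise.
#'
#' @param path File path.
#' @param n_trivalents Maximum inheritable Rb count (default 8).
#' @param telocentric_base All-telocentric diploid number (default 40).
#' @param strict Treat row-level validation failures as errors (default)
#'   rather than warnings.
#' @return `read_offspring_table()`: offspring data frame with an
#'   `n_trivalents` attribute. `write_offspring_table()`: `path`,
#'   invisibly. The two round-trip losslessly.
#' @examples
#' off <- read_offspring_table(rb_example_path("offspring_counts.tsv"))
#' nrow(off)  # 139
#' @export
read_offspring_table <- function(path, n_trivalents = 8,
                                 telocentric_base = 40, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  if (!identical(names(tab)[seq_along(offspring_cols)], offspring_cols)) {
    stop("malformed header in ", path, ": expected columns ",
         paste(offspring_cols, collapse = ", "), call. = FALSE)
  }
  line_no <- seq_len(nrow(tab)) + 1L  # header is line 1
  problems <- character(0)

  rb <- suppressWarnings(as.integer(tab$rb_count))
  dn <- suppressWarnings(as.integer(tab$diploid_n))
  bad <- is.na(rb) | is.na(dn)
  problems <- c(problems, sprintf("line %d: non-integer rb_count/diploid_n",
                                  line_no[bad]))
  bad_sex <- !tab$het_parent_sex %in% c("female", "male")
  problems <- c(problems,
                sprintf("line %d: het_parent_sex must be female or male",
                        line_no[bad_sex]))
  ok <- !bad & !bad_sex
  out <- data.frame(animal_id = tab$animal_id,
                    het_parent_sex = tab$het_parent_sex,
                    rb_count = rb, diploid_n = dn,
                    plate_counts = tab$plate_counts,
                    stringsAsFactors = FALSE)
  extra <- setdiff(names(tab), offspring_cols)
  for (col in extra) out[[col]] <- tab[[col]]
  attr(out, "n_trivalents") <- as.integer(n_trivalents)

  v <- validate_record(out[ok, , drop = FALSE],
                       telocentric_base = telocentric_base,
                       n_trivalents = n_trivalents)
  problems <- c(problems,
                sprintf("line %d: %s", line_no[ok][!v$pass],
                        v$reason[!v$pass]))
  if (length(problems)) {
    msg <- paste0("invalid offspring rows in ", path, ":\n  ",
                  paste(problems, collapse = "\n  "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  out
}

#' @rdname read_offspring_table
#' @param records Offspring data frame to write.
#' @export
write_offspring_table <- function(records, path) {
  stopifnot(all(offspring_cols %in% names(records)))
  ord <- c(offspring_cols, setdiff(names(records), offspring_cols))
  utils::write.table(records[, ord, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write chromosome measurement tables
#'
#' Tab-separated text with header `animal_id plate_id chromosome_id
#' chromatid_len_1 chromatid_len_2 pericentromeric_len`, lengths in
#' pixels.
#'
#' @param path File path.
#' @return `read_measurement_table()`: measurement data frame.
#' @export
read_measurement_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, check.names = FALSE)
  if (!identical(names(tab)[seq_along(measurement_cols)],
                 measurement_cols)) {
    stop("malformed header in ", path, ": expected columns ",
         paste(measurement_cols, collapse = ", "), call. = FALSE)
  }
  num <- c("chromatid_len_1", "chromatid_len_2", "pericentromeric_len")
  for (col in num) tab[[col]] <- as.numeric(tab[[col]])
  bad <- which(Reduce(`|`, lapply(tab[num], function(x) is.na(x) | x <= 0)))
  if (length(bad)) {
    stop("non-positive or missing lengths at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
  }
  tab
}

#' @rdname read_measurement_table
#' @param measurements Measurement data frame to write.
#' @export
write_measurement_table <- function(measurements, path) {
  stopifnot(all(measurement_cols %in% names(measurements)))
  utils::write.table(measurements[, measurement_cols, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse semicolon-joined plate counts
#'
#' @param plate_counts Character vector of semicolon-joined integer lists
#'   (`"3;3;2"`) as stored in offspring tables; empty strings give
#'   zero-length results.
#' @return List of integer vectors.
#' @export
parse_plate_counts <- function(plate_counts) {
  lapply(strsplit(as.character(plate_counts), ";", fixed = TRUE),
         function(x) as.integer(x[nzchar(x)]))
}

#' Packaged example data
#'
#' `rb_example_path()` resolves a file shipped under `inst/extdata/`.
#' Two datasets from a published reciprocal-cross experiment in
#' *Mus musculus domesticus* are included:
#'
#' * `offspring_counts.tsv` — 139 offspring of heterozygotes carrying 8
#'   Rb metacentrics crossed to all-telocentric homozygotes (83 from
#'   heterozygous mothers, 56 from heterozygous fathers), one row per
#'   animal with its inherited Rb count and diploid number.
#' * `pericentromere_summary.tsv` — per-animal mean CL/TL percentages for
#'   one family: a heterozygous father (8 Rb chromosomes, mean 21.51) and
#'   six sons A–F. Summary-level only; the underlying per-chromosome
#'   measurements were not published. The source report's exceedance
#'   table lists 26.61 for descendant B where its karyotype table lists
#'   25.61; the fixture carries 25.61 (the exceedance count over the
#'   21.51 reference is 5 of 6 either way).
#'
#' @param file File name under `extdata`; with no argument, lists the
#'   available files.
#' @return A file path (or file listing).
#' @examples
#' rb_example_path()
#' @export
rb_example_path <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "rbdrive")))
  }
  p <- system.file("extdata", file, package = "rbdrive", mustWork = TRUE)
  p
}

#' @rdname rb_example_path
#' @export
rb_example_offspring <- function() {
  read_offspring_table(rb_example_path("offspring_counts.tsv"))
}

#' @rdname rb_example_path
#' @export
rb_example_centromere_summary <- function() {
  tab <- utils::read.delim(rb_example_path("pericentromere_summary.tsv"))
  tab$mean_ratio_pct <- as.numeric(tab$mean_ratio_pct)
  tab
}

#' Run the complete drive analysis as one pipeline
#'
#' Reads an offspring table, tabulates the Rb-count distributions per
#' heterozygous-parent sex, tests each against the Mendelian
#' Binomial(n, 0.5) null, estimates and compares transmission
#' proportions, and (when a centromere summary is supplied) tests
#' exceedance of the parental pericentromeric reference.
#'
#' @param offspring_path Path to an offspring table
#'   (see [read_offspring_table()]).
#' @param centromere_summary Optional per-animal centromere summary data
#'   frame with a `role` column marking one `reference` row, or a path to
#'   such a table; `NULL` omits the centromere section.
#' @param model Segregation null (default Binomial over the table's
#'   trivalent count with p = 0.5).
#' @param gof_method,pool_below,n_resamples,seed Passed to [gof_test()].
#' @return An object of class `rb_report`: list with `distributions`,
#'   `summaries` (per-sex N/total/mean/fraction), `pooled` (total,
#'   maximum, fraction), `gof`, `comparison`, `centromere` (or `NULL`)
#'   and `provenance`.
#' @examples
#' rep <- run_full_analysis(rb_example_path("offspring_counts.tsv"),
#'                          rb_example_centromere_summary())
#' print(rep)
#' @export
run_full_analysis <- function(offspring_path, centromere_summary = NULL,
                              model = NULL,
                              gof_method = "asymptotic", pool_below = NULL,
                              n_resamples = 10000, seed = 1L) {
  records <- read_offspring_table(offspring_path)
  n <- attr(records, "n_trivalents")
  if (is.null(model)) model <- segregation_model(n, 0.5)

  sexes <- intersect(c("female", "male"), unique(records$het_parent_sex))
  dists <- lapply(sexes, function(s) observed_distribution(records, s))
  names(dists) <- sexes

  summaries <- lapply(dists, function(d) {
    list(N = d$N, counts = d$counts, total_rb = total_rb(d),
         mean_rb = mean_rb(d), fraction = fraction_of_max(d),
         transmission = estimate_transmission(d))
  })
  pooled_total <- sum(vapply(dists, total_rb, numeric(1)))
  pooled_max <- n * nrow(records)

  gof <- lapply(dists, gof_test, model = model, method = gof_method,
                pool_below = pool_below, n_resamples = n_resamples,
                seed = seed)
  comparison <- if (length(dists) == 2L)
    compare_transmission(dists[[1]], dists[[2]]) else NULL

  centro <- NULL
  if (!is.null(centromere_summary)) {
    if (is.character(centromere_summary)) {
      centromere_summary <- utils::read.delim(centromere_summary)
    }
    if (!"role" %in% names(centromere_summary) ||
        sum(centromere_summary$role == "reference") != 1L) {
      stop("centromere summary needs exactly one `role == \"reference\"` row",
           call. = FALSE)
    }
    ref <- centromere_summary[centromere_summary$role == "reference", ]
    desc <- centromere_summary[centromere_summary$role != "reference", ]
    centro <- list(reference_pct = ref$mean_ratio_pct,
                   reference_id = ref$animal_id,
                   n_descendants = nrow(desc),
                   n_exceeding = count_exceeding(desc, ref$mean_ratio_pct),
                   test = exceedance_test(desc, ref$mean_ratio_pct))
  }

  structure(list(n_trivalents = n, distributions = dists,
                 summaries = summaries,
                 pooled = list(total_rb = pooled_total,
                               max_rb = pooled_max,
                               fraction = pooled_total / pooled_max),
                 gof = gof, comparison = comparison, centromere = centro,
                 provenance = list(
                   offspring_path = offspring_path,
                   gof_method = gof_method, seed = seed,
                   package_version =
                     as.character(utils::packageVersion("rbdrive")),
                   timestamp = format(Sys.time(), tz = "UTC"))),
            class = "rb_report")
}

#' @export
print.rb_report <- function(x, ...) {
  cat("Rb transmission analysis (", x$n_trivalents, " trivalents)\n",
      sep = "")
  for (s in names(x$summaries)) {
    sm <- x$summaries[[s]]
    cat(sprintf(
      "  het %s parent: N = %d, total Rb = %d, mean = %s, fraction = %s%%\n",
      s, sm$N, sm$total_rb, fmt_pct(sm$mean_rb),
      fmt_pct(100 * sm$fraction)))
    cat(sprintf("    gof vs Binomial(%d, 0.5): %s p = %s [%s]\n",
                x$n_trivalents,
                if (x$gof[[s]]$method == "asymptotic")
                  sprintf("chi-square = %.2f, df = %d,",
                          x$gof[[s]]$statistic, x$gof[[s]]$df)
                else sprintf("statistic = %.2f,", x$gof[[s]]$statistic),
                fmt_p(x$gof[[s]]$p_value), x$gof[[s]]$method))
  }
  cat(sprintf("  pooled: %d of %d possible Rb chromosomes (%s%%)\n",
              x$pooled$total_rb, x$pooled$max_rb,
              fmt_pct(100 * x$pooled$fraction)))
  if (!is.null(x$comparison)) {
    cat(sprintf("  %s vs %s transmission: z = %.2f, two-sided p = %s\n",
                x$comparison$label_a, x$comparison$label_b,
                x$comparison$z, fmt_p(x$comparison$p_value)))
  }
  if (!is.null(x$centromere)) {
    ce <- x$centromere
    cat(sprintf(
      "  pericentromeric CL/TL: %d of %d descendants exceed %s%% (p = %s)\n",
      ce$n_exceeding, ce$n_descendants, fmt_pct(ce$reference_pct),
      fmt_p(ce$test$p_value)))
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Writes `report.txt` (the human-readable rendering of
#' `print.rb_report`) and `report.tsv` (one row per test: stage, label,
#' statistic, df, p-value, method, seed). Deterministic given the same
#' inputs and seeds.
#'
#' @param report An `rb_report` from [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "rb_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  txt <- file.path(dir, "report.txt")
  con <- file(txt, "w")
  sink(con); print(report); sink()
  close(con)

  rows <- list()
  for (s in names(report$gof)) {
    g <- report$gof[[s]]
    rows[[length(rows) + 1L]] <- data.frame(
      stage = "gof", label = s, statistic = g$statistic, df = g$df,
      p_value = g$p_value, method = g$method,
      seed = if (is.null(g$seed)) NA_integer_ else g$seed)
  }
  if (!is.null(report$comparison)) {
    cm <- report$comparison
    rows[[length(rows) + 1L]] <- data.frame(
      stage = "compare_transmission",
      label = paste(cm$label_a, "vs", cm$label_b), statistic = cm$z,
      df = NA_integer_, p_value = cm$p_value, method = "pooled_z",
      seed = NA_integer_)
  }
  if (!is.null(report$centromere)) {
    te <- report$centromere$test
    rows[[length(rows) + 1L]] <- data.frame(
      stage = "centromere_exceedance",
      label = sprintf("%d/%d", report$centromere$n_exceeding,
                      report$centromere$n_descendants),
      statistic = te$z, df = NA_integer_, p_value = te$p_value,
      method = te$method, seed = NA_integer_)
  }
  utils::write.table(do.call(rbind, rows), file.path(dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
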