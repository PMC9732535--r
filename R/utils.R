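#' Half-up rounding to a fixed number of decimals
#'
#' Published karyotype tables round half away from zero (21.875 prints as
#' 21.88), unlike R's banker's rounding. Used by every formatter so printed
#' tables are byte-stable.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(21.875, 2)  # 21.88
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# shared formatting policy: 2 dp for means/percents, 4 dp for p-values
fmt_pct <- function(x) sprintf("%.2f", round_half_up(x, 2))
fmt_p <- function(x) sprintf("%.4f", round_half_up(x, 4))

#' Wilson score interval for a binomial proportion
#'
#' @param successes,trials Observed successes out of trials.
#' @param conf_level Two-sided confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`, both in \[0, 1\].
#' @examples
#' wilson_ci(5, 6)
#' @export
wilson_ci <- function(successes, trials, conf_level = 0.95) {
  stopifnot(trials >= 1, successes >= 0, successes <= trials)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  phat <- successes / trials
  denom <- 1 + z^2 / trials
  centre <- (phat + z^2 / (2 * trials)) / denom
  half <- z * sqrt(phat * (1 - phat) / trials + z^2 / (4 * trials^2)) / denom
  ci <- c(centre - half, centre + half)
  pmin(pmax(ci, 0), 1)
}

# Seeding rule for every stochastic routine in the package: R's
# Mersenne-Twister with inversion normals, so a seed fully determines
# output across platforms. Restores the caller's RNG state on exit.
with_rb_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  expr
}
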