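# Two-arm binomial design power: Monte-Carlo power of the two-sided Fisher
# exact test, plus the normal-approximation closed form.

#' Monte-Carlo power of the two-sided Fisher exact test
#'
#' Simulates `reps` two-arm binomial trials and computes the rejection
#' proportion of `fisher.test` at level `alpha`. Only the distinct observed
#' count pairs are tested (the p-value is a function of the 2x2 table), so
#' 10,000 replicates run in seconds. Note that the exact conditional test
#' is conservative: its true size is below `alpha`, and its power sits a few
#' points below the normal-approximation value (see
#' [power_two_proportions()]).
#'
#' @param n_high,n_low Arm sizes.
#' @param p_high,p_low True response probabilities in (0,1), or equal
#'   probabilities for a null (size) run.
#' @param alpha Two-sided significance level.
#' @param reps Number of simulated trials (>= 1000).
#' @param seed Optional integer seed for reproducibility.
#' @return A one-row tibble: `power`, `mc_se` (binomial standard error of
#'   the estimate), `reps`, and the design parameters.
#' @export
power_simulation <- function(n_high, n_low, p_high, p_low, alpha = 0.05,
                             reps = 10000, seed = NULL) {
  stopifnot(n_high >= 1, n_low >= 1, reps >= 1000, alpha > 0, alpha < 1)
  if (any(c(p_high, p_low) <= 0) || any(c(p_high, p_low) >= 1)) {
    abort("response probabilities must lie in (0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  x <- rbinom(reps, n_high, p_high)
  y <- rbinom(reps, n_low, p_low)
  pairs <- dplyr::count(tibble::tibble(x = x, y = y), x, y)
  pairs$p <- purrr::map2_dbl(pairs$x, pairs$y, function(xi, yi) {
    fisher.test(matrix(c(xi, n_high - xi, yi, n_low - yi), 2, byrow = TRUE))$p.value
  })
  power <- sum(pairs$n * (pairs$p <= alpha)) / reps
  tibble::tibble(
    power = power, mc_se = sqrt(power * (1 - power) / reps), reps = reps,
    n_high = n_high, n_low = n_low, p_high = p_high, p_low = p_low,
    alpha = alpha
  )
}

#' Normal-approximation power for comparing two proportions
#'
#' Closed-form two-sided power of the unpooled z-test, the usual a-priori
#' design calculation. Because the Fisher exact test is conservative, its
#' simulated power is somewhat below this value for small trials.
#'
#' @inheritParams power_simulation
#' @return Power as a single number.
#' @export
power_two_proportions <- function(n_high, n_low, p_high, p_low, alpha = 0.05) {
  se <- sqrt(p_high * (1 - p_high) / n_high + p_low * (1 - p_low) / n_low)
  z <- abs(p_high - p_low) / se
  za <- qnorm(1 - alpha / 2)
  pnorm(z - za) + pnorm(-z - za)
}
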