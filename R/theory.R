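#' Probability that a cytosine site is monomorphic in a sample
#'
#' Under the symmetric two-state (Cavender-Farris-Neyman) epimutation model
#' at stationarity, the population frequency of the methylated state follows
#' a Beta(theta_m, theta_m) distribution, and the probability that all `n`
#' sampled chromosomes carry one *particular* state is
#' `Gamma(2*theta) * Gamma(theta + n) / (Gamma(theta) * Gamma(2*theta + n))`.
#' The probability that the site segregates is therefore
#' `1 - 2 * monomorphic_prob(theta, n)`.  With `states = 4` the analogous
#' symmetric Dirichlet result for a four-state (Jukes-Cantor-like) model is
#' returned, with the Dirichlet concentration `theta / 3` chosen so that
#' `theta` is the pairwise substitution rate parameter in both cases; the
#' probability of segregation is then `1 - 4 * monomorphic_prob(...)`.
#'
#' @param theta Per-site scaled epimutation rate, `4 * N * mu`, > 0.
#'   Vectorised.
#' @param n Sample size (integer >= 2).
#' @param states Number of site states: 2 (methylation, default) or 4
#'   (nucleotide).
#' @return Probability that the site is fixed for one specific state.
#' @examples
#' ## n = 2 closed form: (theta + 1) / (2 * (2 * theta + 1))
#' monomorphic_prob(0.1, 2)
#' @export
monomorphic_prob <- function(theta, n, states = 2) {
  if (any(!is.finite(theta)) || any(theta <= 0)) {
    stop("`theta` must be positive", call. = FALSE)
  }
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  states <- match.arg(as.character(states), c("2", "4"))
  k <- as.numeric(states)
  b <- if (k == 2) theta else theta / 3
  exp(lgamma(k * b) - lgamma(b) + lgamma(b + n) - lgamma(k * b + n))
}

#' Expected segregating-site proportion and pairwise diversity
#'
#' Second-order (Pade-type) approximations to the expectations of the two
#' locus summaries under neutrality when the per-site rate is gamma
#' distributed with shape `alpha` and mean `mean_theta`:
#' `E(sm) = a1 * tb / (1 + c1 * k * tb)` and
#' `E(pim) = tb / (1 + 2 * k * tb)` with `k = (alpha + 1) / alpha` and
#' `tb = mean_theta`.  For `states = 4` the four-state constants
#' (`c1_mod`, pairwise factor 4/3) are used instead.
#'
#' @param mean_theta Mean of the per-site scaled epimutation rate (>= 0).
#' @param alpha Gamma shape parameter of among-site rate variation (> 0).
#' @inheritParams monomorphic_prob
#' @return A one-row tibble with columns `E_sm` and `E_pim`.
#' @examples
#' expected_summaries(0.1, alpha = 0.5, n = 60)
#' @export
expected_summaries <- function(mean_theta, alpha, n, states = 2) {
  stopifnot(mean_theta >= 0, alpha > 0)
  cs <- sample_constants(n)
  k <- (alpha + 1) / alpha
  if (identical(as.numeric(states), 4)) {
    c1 <- cs$c1_mod
    pw <- 4 / 3
  } else {
    c1 <- cs$c1
    pw <- 2
  }
  tibble::tibble(
    E_sm  = cs$a1 * mean_theta / (1 + c1 * k * mean_theta),
    E_pim = mean_theta / (1 + pw * k * mean_theta)
  )
}
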