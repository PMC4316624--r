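#' Sample-size constants for the D-family neutrality tests
#'
#' Computes the harmonic-sum constants that enter the theta estimators and
#' the variance normalisation of Tajima's D and its finite-site relatives.
#' `a1`, `a2` are the usual harmonic sums over `1..(n-1)`; `a3` and `c1`
#' are the finite-site correction constants of the two-state test
#' (`c1 = 2*a1 - 3*a3/a1`, equivalently `(a1^2 + 3*a2) / (2*a1)`);
#' `b1`, `b2`, `c3`, `c4`, `e1`, `e2` are the classic variance constants of
#' Tajima (1989).  `c1_mod` is the analogous second-order constant for a
#' symmetric four-state (nucleotide) model, `(3*a1^2 + 5*a2) / (6*a1)`,
#' used by the modified test of Misawa and Tajima (2000).
#'
#' @param n Integer sample size, at least 2.
#' @return A one-row tibble with columns `n`, `a1`, `a2`, `a3`, `c1`,
#'   `c1_mod`, `b1`, `b2`, `c3`, `c4`, `e1`, `e2`.
#' @examples
#' sample_constants(60)
#' @export
sample_constants <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 2 || n != round(n)) {
    stop("`n` must be a single integer >= 2", call. = FALSE)
  }
  n <- as.integer(n)
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  a3 <- (a1^2 - a2) / 2
  c1 <- 2 * a1 - 3 * a3 / a1
  c1_mod <- (3 * a1^2 + 5 * a2) / (6 * a1)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c3 <- b1 - 1 / a1
  c4 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c3 / a1
  e2 <- c4 / (a1^2 + a2)
  tibble::tibble(
    n = n, a1 = a1, a2 = a2, a3 = a3, c1 = c1, c1_mod = c1_mod,
    b1 = b1, b2 = b2, c3 = c3, c4 = c4, e1 = e1, e2 = e2
  )
}
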