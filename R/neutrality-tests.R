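#' Theta estimators from locus summaries
#'
#' Estimates the mean per-site rate from either locus summary by undoing
#' the second-order expectations of [expected_summaries()], in one of two
#' functional forms (see `form`).  With `k = (alpha + 1) / alpha`, the
#' default series form is `theta_s_hat = (s_m/a1) * (1 + c1*k*s_m/a1)` and
#' `theta_pi_hat = pi_m * (1 + 2*k*pi_m)`; the inversion form is
#' `s_m / (a1 - c1*k*s_m)` and `pi_m / (1 - 2*k*pi_m)`, with non-positive
#' denominators returned as `NaN` and flagged undefined (never silently
#' truncated).  `states = 4` uses the four-state constants (`c1_mod`,
#' factor 4/3).
#'
#' @param summary A one-row tibble from [locus_summary()] (or any list with
#'   `n`, `s_m`, `pi_m`).
#' @param alpha Gamma shape of among-site rate variation (> 0).
#' @param states 2 (methylation) or 4 (nucleotide constants).
#' @param form `"series"` (default): the first-order series inverses
#'   `theta_s_hat = (s_m/a1) * (1 + c1*k*s_m/a1)` and
#'   `theta_pi_hat = pi_m * (1 + 2*k*pi_m)`, which are pole-free, always
#'   defined, and progressively underestimate at large rates (the
#'   finite-site saturation behaviour discussed in the methods vignette);
#'   `"inversion"`: the exact algebraic inverses of the second-order
#'   expectations, which satisfy the round-trip identity
#'   `theta_hat(E_sm, E_pim) = theta` exactly but have poles (flagged
#'   undefined) when an observed summary reaches the correction scale.
#' @return A one-row tibble with `theta_pi_hat`, `theta_s_hat`,
#'   `pi_defined`, `s_defined`.
#' @examples
#' theta_hats(locus_summary(state_matrix(rbind(c(0, 1), c(1, 0)))), alpha = 0.5)
#' @export
theta_hats <- function(summary, alpha, states = 2,
                       form = c("series", "inversion")) {
  stopifnot(alpha > 0)
  form <- match.arg(form)
  cs <- sample_constants(summary$n)
  k <- (alpha + 1) / alpha
  if (identical(as.numeric(states), 4)) {
    c1 <- cs$c1_mod; pw <- 4 / 3
  } else {
    c1 <- cs$c1; pw <- 2
  }
  if (form == "series") {
    return(tibble::tibble(
      theta_pi_hat = summary$pi_m * (1 + pw * k * summary$pi_m),
      theta_s_hat  = (summary$s_m / cs$a1) * (1 + c1 * k * summary$s_m / cs$a1),
      pi_defined   = TRUE,
      s_defined    = TRUE
    ))
  }
  den_s <- cs$a1 - c1 * k * summary$s_m
  den_p <- 1 - pw * k * summary$pi_m
  tibble::tibble(
    theta_pi_hat = ifelse(den_p > 0, summary$pi_m / den_p, NaN),
    theta_s_hat  = ifelse(den_s > 0, summary$s_m / den_s, NaN),
    pi_defined   = den_p > 0,
    s_defined    = den_s > 0
  )
}

d_family_result <- function(test, value, th_pi, th_s, defined) {
  tibble::tibble(
    test = test,
    statistic = ifelse(defined, value, NaN),
    theta_pi_hat = th_pi,
    theta_s_hat = th_s,
    defined = defined
  )
}

as_locus_summary <- function(x, states = 2) {
  if (inherits(x, "state_matrix") || is.matrix(x)) {
    if (identical(as.numeric(states), 4)) nucleotide_summary(x) else locus_summary(x)
  } else {
    x
  }
}

finite_site_d <- function(summary, alpha, states, test_name,
                          s_hat_scale = c("estimator", "raw"),
                          form = c("series", "inversion")) {
  s_hat_scale <- match.arg(s_hat_scale)
  cs <- sample_constants(summary$n)
  th <- theta_hats(summary, alpha, states = states, form = match.arg(form))
  ok <- summary$S >= 1L && th$pi_defined && th$s_defined
  if (!ok) {
    return(d_family_result(test_name, NaN, th$theta_pi_hat, th$theta_s_hat, FALSE))
  }
  L <- summary$L
  S_hat <- if (s_hat_scale == "estimator") cs$a1 * th$theta_s_hat * L else summary$S
  v <- cs$e1 * S_hat + cs$e2 * S_hat * (S_hat - 1)
  num <- (th$theta_pi_hat - th$theta_s_hat) * L
  if (!is.finite(v) || v <= 0) {
    # n <= 3 binary data: numerator and variance are both identically zero
    if (is.finite(num) && abs(num) < 1e-9) {
      return(d_family_result(test_name, 0, th$theta_pi_hat, th$theta_s_hat, TRUE))
    }
    return(d_family_result(test_name, NaN, th$theta_pi_hat, th$theta_s_hat, FALSE))
  }
  d_family_result(test_name, num / sqrt(v), th$theta_pi_hat, th$theta_s_hat, TRUE)
}

#' The Dm neutrality test for methylation polymorphism
#'
#' Computes the two-state finite-site neutrality statistic: the difference
#' between the pairwise-diversity and segregating-site estimators of the
#' epimutation rate, scaled by the locus length and normalised by the
#' Tajima variance evaluated at the estimated segregating-site count
#' `S_hat = a1 * theta_s_hat * L`:
#' `Dm = (theta_pi_hat - theta_s_hat) * L / sqrt(e1 * S_hat + e2 * S_hat * (S_hat - 1))`.
#' Under neutrality its mean is approximately 0 and its variance
#' approximately 1.  Monomorphic loci and loci where an estimator inversion
#' or the variance term is non-positive yield `defined = FALSE` and a `NaN`
#' statistic.
#'
#' @param x A [state_matrix()] (methylation mode) or a [locus_summary()] row.
#' @param alpha Gamma shape of among-site epimutation-rate variation.
#' @param s_hat_scale Scale of the segregating-site count used inside the
#'   variance term: `"estimator"` (default, `a1 * theta_s_hat * L`) or
#'   `"raw"` (the observed `S`).
#' @param form Estimator functional form, as in [theta_hats()].
#' @return A one-row tibble with `test`, `statistic`, `theta_pi_hat`,
#'   `theta_s_hat`, `defined`.
#' @seealso [tajima_d()], [dmod_statistic()], [smp_test()]
#' @examples
#' m <- state_matrix(rbind(c(0, 0, 1), c(0, 1, 1), c(0, 1, 0), c(1, 1, 0)))
#' dm_statistic(m, alpha = 0.5)
#' @export
dm_statistic <- function(x, alpha, s_hat_scale = c("estimator", "raw"),
                         form = c("series", "inversion")) {
  summary <- as_locus_summary(x)
  finite_site_d(summary, alpha, states = 2, test_name = "Dm",
                s_hat_scale = match.arg(s_hat_scale), form = match.arg(form))
}

#' Modified Tajima's D for a four-state finite-site model
#'
#' The nucleotide analogue of [dm_statistic()] in the style of Misawa and
#' Tajima (2000): identical construction, but the estimator inversions use
#' the four-state constants (`c1_mod` and pairwise factor 4/3).  Used here
#' mainly as a comparator on methylation data.
#'
#' @inheritParams dm_statistic
#' @param states Number of states the summaries were computed from (2 to
#'   apply the test to SMP matrices, 4 for true nucleotide matrices; the
#'   correction constants are the four-state ones in both cases).
#' @return A one-row tibble as in [dm_statistic()].
#' @export
dmod_statistic <- function(x, alpha, states = 2,
                           s_hat_scale = c("estimator", "raw"),
                           form = c("series", "inversion")) {
  summary <- as_locus_summary(x, states = states)
  finite_site_d(summary, alpha, states = 4, test_name = "Dmod",
                s_hat_scale = match.arg(s_hat_scale), form = match.arg(form))
}

#' Tajima's D
#'
#' The classic infinite-site statistic `D = (pi - S / a1) / sqrt(e1 * S +
#' e2 * S * (S - 1))` (Tajima 1989), computed from a binary SMP matrix or a
#' nucleotide matrix; `pi` is the average pairwise difference over the
#' whole locus and `S` the raw segregating-site count.
#'
#' @inheritParams dmod_statistic
#' @return A one-row tibble as in [dm_statistic()] (`theta_pi_hat` and
#'   `theta_s_hat` are the per-site infinite-site estimates `pi_m` and
#'   `s_m / a1`).
#' @export
tajima_d <- function(x, states = 2) {
  summary <- as_locus_summary(x, states = states)
  cs <- sample_constants(summary$n)
  th_pi <- summary$pi_m
  th_s <- summary$s_m / cs$a1
  S <- summary$S
  if (S < 1L) return(d_family_result("D", NaN, th_pi, th_s, FALSE))
  v <- cs$e1 * S + cs$e2 * S * (S - 1)
  num <- summary$pi_m * summary$L - S / cs$a1
  if (v <= 0) {
    # n <= 3 binary data: pi equals S/a1 exactly and the variance is zero
    if (abs(num) < 1e-9) return(d_family_result("D", 0, th_pi, th_s, TRUE))
    return(d_family_result("D", NaN, th_pi, th_s, FALSE))
  }
  d_family_result("D", num / sqrt(v), th_pi, th_s, TRUE)
}

#' All three neutrality tests (and optionally alpha) for one locus
#'
#' Convenience wrapper computing `Dm`, `Dmod` and `D` on one SMP matrix,
#' optionally estimating the gamma shape `alpha` from the data first
#' (see [estimate_alpha()]).
#'
#' @param x A [state_matrix()] in methylation mode.
#' @param alpha Gamma shape; `NULL` (default) estimates it from `x`.
#' @param locus_id Optional locus label carried into the output.
#' @param s_hat_scale Passed to [dm_statistic()] and [dmod_statistic()].
#' @return A one-row tibble with locus summaries, `alpha_used`, the three
#'   statistics (`Dm`, `Dmod`, `D`), their estimator columns and defined
#'   flags.
#' @examples
#' m <- simulate_dataset(n = 12, L = 200, mean_theta = 0.1, alpha = 0.5,
#'                       reps = 1, seed = 1)[[1]]
#' smp_test(m)
#' @export
smp_test <- function(x, alpha = NULL, locus_id = NA_character_,
                     s_hat_scale = c("estimator", "raw")) {
  s_hat_scale <- match.arg(s_hat_scale)
  summary <- locus_summary(x)
  if (is.null(alpha)) alpha <- estimate_alpha(x)$alpha
  dm <- dm_statistic(summary, alpha, s_hat_scale = s_hat_scale)
  dmod <- dmod_statistic(summary, alpha, s_hat_scale = s_hat_scale)
  d <- tajima_d(summary)
  dplyr::bind_cols(
    tibble::tibble(locus_id = locus_id),
    summary,
    tibble::tibble(
      alpha_used = alpha,
      Dm = dm$statistic, Dm_defined = dm$defined,
      theta_pi_hat = dm$theta_pi_hat, theta_s_hat = dm$theta_s_hat,
      Dmod = dmod$statistic, Dmod_defined = dmod$defined,
      D = d$statistic, D_defined = d$defined
    )
  )
}
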