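#' Null distribution of the neutrality statistics
#'
#' Simulates the standard neutral model (no recombination, selection or
#' demography) and collects the per-replicate `Dm`, `Dmod` and `D`
#' values.  Undefined statistics are dropped from the sorted values and
#' counted.
#'
#' @inheritParams simulate_dataset
#' @param alpha_used Gamma shape used when computing the statistics
#'   (default: the simulated `alpha`).
#' @return A list of class `dm_null` with sorted numeric vectors `Dm`,
#'   `Dmod`, `D`, the per-test count of dropped (undefined) replicates,
#'   and the simulation settings.
#' @examples
#' nd <- null_distribution(n = 10, L = 100, reps = 50, seed = 2)
#' @export
null_distribution <- function(n = 60, L = 1000, mean_theta = 0.1, alpha = 0.5,
                              reps = 1000, seed = 1, alpha_used = alpha) {
  fn <- function(m) {
    s <- locus_summary(m)
    tibble::tibble(Dm = dm_statistic(s, alpha_used)$statistic,
                   Dmod = dmod_statistic(s, alpha_used)$statistic,
                   D = tajima_d(s)$statistic)
  }
  st <- simulate_stats(n = n, L = L, mean_theta = mean_theta, alpha = alpha,
                       reps = reps, seed = seed, fn = fn)
  keep <- function(v) sort(v[is.finite(v)])
  structure(list(Dm = keep(st$Dm), Dmod = keep(st$Dmod), D = keep(st$D),
                 n_dropped = vapply(st[c("Dm", "Dmod", "D")],
                                    function(v) sum(!is.finite(v)), integer(1)),
                 settings = list(n = n, L = L, mean_theta = mean_theta,
                                 alpha = alpha, reps = reps, seed = seed)),
            class = "dm_null")
}

#' @export
print.dm_null <- function(x, ...) {
  cat(sprintf("<dm_null: %d replicates (n=%d, L=%d, theta=%g, alpha=%g)>\n",
              x$settings$reps, x$settings$n, x$settings$L,
              x$settings$mean_theta, x$settings$alpha))
  cat(sprintf("  dropped: Dm=%d Dmod=%d D=%d\n",
              x$n_dropped[1], x$n_dropped[2], x$n_dropped[3]))
  invisible(x)
}

#' One-sided test power against an empirical null
#'
#' The critical value is the empirical `level` quantile of the null
#' (lower tail) or the `1 - level` quantile (upper tail), with type-7
#' interpolation; power is the fraction of alternative statistics
#' strictly beyond it.  Undefined (non-finite) values never enter the
#' denominator.
#'
#' @param null_stats Numeric vector of null statistic values (or a
#'   `dm_null`, with `test` selecting the statistic).
#' @param alt_stats Numeric vector of statistic values under the
#'   alternative.
#' @param tail `"lower"` or `"upper"`.
#' @param level Tail probability (default 0.05).
#' @param test Which statistic to take from a `dm_null`.
#' @return A one-row tibble: `test`, `tail`, `level`, `critical`,
#'   `n_reps`, `n_defined`, `power`.
#' @export
test_power <- function(null_stats, alt_stats, tail = c("lower", "upper"),
                       level = 0.05, test = "Dm") {
  tail <- match.arg(tail)
  if (inherits(null_stats, "dm_null")) null_stats <- null_stats[[test]]
  null_stats <- null_stats[is.finite(null_stats)]
  if (!length(null_stats) || !length(alt_stats)) {
    stop("empty statistic vectors", call. = FALSE)
  }
  crit <- if (tail == "lower") {
    stats::quantile(null_stats, level, type = 7, names = FALSE)
  } else {
    stats::quantile(null_stats, 1 - level, type = 7, names = FALSE)
  }
  ok <- is.finite(alt_stats)
  hits <- if (tail == "lower") alt_stats[ok] < crit else alt_stats[ok] > crit
  tibble::tibble(test = test, tail = tail, level = level, critical = crit,
                 n_reps = length(alt_stats), n_defined = sum(ok),
                 power = mean(hits))
}

#' Empirical-null outlier scan over many loci
#'
#' Flags loci whose statistic falls below the `level` quantile or above
#' the `1 - level` quantile of the empirical distribution formed by the
#' loci themselves (the genome-wide empirical-null approach that absorbs
#' demography and pervasive selection).  Empirical p is the rank
#' proportion in the corresponding tail.
#'
#' @param stats_tbl A data frame with at least a statistic column, or a
#'   bare numeric vector.
#' @param statistic Name of the statistic column (default `"Dm"`).
#' @param level Tail probability per side (default 0.05).
#' @return The input as a tibble with added columns `empirical_p_lower`,
#'   `empirical_p_upper` and `tail_flag` (`"lower"`, `"upper"` or
#'   `"none"`).  Loci with undefined statistics get `NA` flags.
#' @export
empirical_scan <- function(stats_tbl, statistic = "Dm", level = 0.05) {
  if (is.numeric(stats_tbl)) stats_tbl <- tibble::tibble(!!statistic := stats_tbl)
  stats_tbl <- tibble::as_tibble(stats_tbl)
  v <- stats_tbl[[statistic]]
  ok <- is.finite(v)
  nv <- sum(ok)
  if (nv < 100) {
    rlang::warn(sprintf("empirical null built from only %d loci; quantiles will be noisy", nv))
  }
  lo <- stats::quantile(v[ok], level, type = 7, names = FALSE)
  hi <- stats::quantile(v[ok], 1 - level, type = 7, names = FALSE)
  r_lo <- r_hi <- rep(NA_real_, length(v))
  r_lo[ok] <- rank(v[ok], ties.method = "max") / nv
  r_hi[ok] <- rank(-v[ok], ties.method = "max") / nv
  flag <- rep(NA_character_, length(v))
  flag[ok] <- "none"
  flag[ok & v < lo] <- "lower"
  flag[ok & v > hi] <- "upper"
  dplyr::mutate(stats_tbl,
                empirical_p_lower = r_lo,
                empirical_p_upper = r_hi,
                tail_flag = flag)
}

#' Expected SNP/SMP outlier overlap under independence
#'
#' Given the numbers of genes in the 5% tails of the SMP-based and
#' SNP-based statistics among `n_total` genes, computes the expected
#' number of genes flagged at both levels if the two kinds of selection
#' act independently, and an exact binomial test of the observed overlap
#' against that expectation.
#'
#' @param n_total Total genes tested on both data types.
#' @param smp_tail_counts Integer vector (lower, upper) of SMP outlier
#'   counts.
#' @param snp_tail_counts Integer vector (lower, upper) of SNP outlier
#'   counts.
#' @param observed_overlap Observed number of genes flagged in both.
#' @return A one-row tibble: `n_total`, `expected` (rounded), `expected_raw`,
#'   `observed`, `p_value` (two-sided exact binomial).
#' @examples
#' overlap_expectation(21885, c(1312, 1028), c(1079, 1201), 220)
#' @export
overlap_expectation <- function(n_total, smp_tail_counts, snp_tail_counts,
                                observed_overlap) {
  stopifnot(n_total > 0, sum(smp_tail_counts) <= n_total,
            sum(snp_tail_counts) <= n_total)
  p_both <- (sum(smp_tail_counts) / n_total) * (sum(snp_tail_counts) / n_total)
  if (p_both <= 0) stop("zero tail totals", call. = FALSE)
  expected <- p_both * n_total
  bt <- stats::binom.test(observed_overlap, n_total, p_both)
  tibble::tibble(n_total = n_total,
                 expected = round(expected),
                 expected_raw = expected,
                 observed = observed_overlap,
                 p_value = bt$p.value)
}
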