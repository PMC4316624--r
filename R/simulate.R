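#' Demographic scenarios for the coalescent simulator
#'
#' Constructors for the three demographic histories the simulator
#' understands.  Time is measured backwards from the present in units of
#' `4N` generations, matching the usual `ms` conventions (a sample pair
#' under constant size coalesces after mean time 0.5).
#'
#' * `demography_constant()`: constant population size.
#' * `demography_size_change(factor, time)`: the population size changed
#'   instantaneously at `time` so that the present size is `factor` times
#'   the older size (`factor = 100` is a 100-fold expansion, `factor =
#'   1/100` a 100-fold shrinkage).
#' * `demography_island(M, sample_sizes)`: two demes of equal size with
#'   symmetric migration at scaled rate `M = 4*N*m`; `sample_sizes` gives
#'   the number of samples drawn from each deme.
#'
#' @param factor Ratio of present to ancestral population size (> 0).
#' @param time Time of the instantaneous change, in 4N units (>= 0).
#' @param M Scaled migration rate `4*N*m` (> 0).
#' @param sample_sizes Integer vector `c(n1, n2)` of per-deme sample sizes.
#' @return A list of class `demography`.
#' @export
demography_constant <- function() {
  structure(list(kind = "constant"), class = "demography")
}

#' @rdname demography_constant
#' @export
demography_size_change <- function(factor, time) {
  stopifnot(factor > 0, time >= 0)
  structure(list(kind = "size_change", factor = factor, time = time),
            class = "demography")
}

#' @rdname demography_constant
#' @export
demography_island <- function(M, sample_sizes) {
  stopifnot(M > 0, length(sample_sizes) == 2, all(sample_sizes >= 0))
  structure(list(kind = "island", M = M,
                 sample_sizes = as.integer(sample_sizes)),
            class = "demography")
}

new_genealogy <- function(n, parent, blen) {
  structure(list(n = n, parent = parent, blen = blen), class = "genealogy")
}

#' Simulate a coalescent genealogy
#'
#' Kingman coalescent for `n` samples under a [demography][demography_constant()],
#' with branch lengths in units of `4N` generations: `k` active lineages
#' coalesce at total rate `k * (k - 1)` (pairwise rate 2), rescaled by the
#' inverse relative population size in the older epoch of a size change,
#' and restricted to within-deme pairs under the island model (lineages
#' migrate at rate `M / 2` each).
#'
#' @param n Sample size (>= 2); for the island model it must equal
#'   `sum(sample_sizes)`.
#' @param demography A [demography][demography_constant()] object.
#' @param seed Optional integer seed.
#' @return A `genealogy`: leaves are nodes `1..n`, internal nodes
#'   `(n+1)..(2n-1)` with the root last, `parent` / `blen` vectors indexed
#'   by node (root parent is 0).
#' @examples
#' g <- simulate_genealogy(5, seed = 1)
#' @export
simulate_genealogy <- function(n, demography = demography_constant(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  nn <- 2L * n - 1L
  parent <- integer(nn)
  blen <- numeric(nn)
  node_time <- numeric(nn)
  if (demography$kind == "island") {
    if (sum(demography$sample_sizes) != n) {
      stop("sum(sample_sizes) must equal n", call. = FALSE)
    }
    deme <- rep(c(1L, 2L), demography$sample_sizes)
  } else {
    deme <- rep(1L, n)
  }
  active <- seq_len(n)
  ademe <- deme
  t <- 0
  nxt <- n + 1L
  while (length(active) > 1L) {
    k <- length(active)
    if (demography$kind == "island") {
      k1 <- sum(ademe == 1L)
      k2 <- k - k1
      r_c1 <- k1 * (k1 - 1)
      r_c2 <- k2 * (k2 - 1)
      r_m <- k * demography$M / 2
      tot <- r_c1 + r_c2 + r_m
      t <- t + stats::rexp(1, tot)
      u <- stats::runif(1, 0, tot)
      if (u < r_m) {
        i <- sample(k, 1L)
        ademe[i] <- 3L - ademe[i]
        next
      }
      d <- if (u < r_m + r_c1) 1L else 2L
      idx <- which(ademe == d)
      pair <- idx[sample.int(length(idx), 2L)]
    } else {
      base <- k * (k - 1)
      if (demography$kind == "size_change") {
        f <- demography$factor
        tau <- demography$time
        if (t >= tau) {
          t <- t + stats::rexp(1, base * f)
        } else {
          w <- stats::rexp(1, base)
          if (t + w <= tau) t <- t + w else t <- tau + stats::rexp(1, base * f)
        }
      } else {
        t <- t + stats::rexp(1, base)
      }
      pair <- sample.int(k, 2L)
    }
    a <- active[pair[1L]]
    b <- active[pair[2L]]
    node_time[nxt] <- t
    parent[a] <- nxt
    parent[b] <- nxt
    blen[a] <- t - node_time[a]
    blen[b] <- t - node_time[b]
    if (demography$kind == "island") {
      ademe <- c(ademe[-pair], ademe[pair[1L]])
    }
    active <- c(active[-pair], nxt)
    nxt <- nxt + 1L
  }
  new_genealogy(n, parent, blen)
}

#' Draw gamma-distributed per-site epimutation rates
#'
#' `L` independent draws from `Gamma(shape = alpha, scale = mean_theta /
#' alpha)`, so the mean rate is `mean_theta` and the variance
#' `mean_theta^2 / alpha`; small `alpha` means strong among-site rate
#' heterogeneity.
#'
#' @param L Number of sites.
#' @param mean_theta Mean scaled rate `4*N*mu` per site (>= 0).
#' @param alpha Gamma shape (> 0).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `L`.
#' @export
draw_site_rates <- function(L, mean_theta, alpha, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(alpha > 0, mean_theta >= 0)
  if (mean_theta == 0) return(numeric(L))
  stats::rgamma(L, shape = alpha, scale = mean_theta / alpha)
}

cfn_flip_prob <- function(theta, t) 0.5 * (1 - exp(-2 * theta * t))

## Evolve binary states along one tree for a block of sites.
## rates: per-site theta; returns n x L matrix of 0/1.
evolve_block <- function(tree, rates, root_states) {
  n <- tree$n
  nn <- 2L * n - 1L
  L <- length(rates)
  st <- matrix(0L, nn, L)
  st[nn, ] <- root_states
  for (v in (nn - 1L):1L) {
    p <- tree$parent[v]
    pf <- cfn_flip_prob(rates, tree$blen[v])
    st[v, ] <- bitwXor(st[p, ], as.integer(stats::runif(L) < pf))
  }
  st[seq_len(n), , drop = FALSE]
}

## Four-state (Jukes-Cantor-like) analogue used in nucleotide mode.
evolve_block_nuc <- function(tree, rates, root_states) {
  n <- tree$n
  nn <- 2L * n - 1L
  L <- length(rates)
  st <- matrix(0L, nn, L)
  st[nn, ] <- root_states
  for (v in (nn - 1L):1L) {
    p <- tree$parent[v]
    pch <- 0.75 * (1 - exp(-(4 / 3) * rates * tree$blen[v]))
    ch <- stats::runif(L) < pch
    new <- st[p, ]
    if (any(ch)) {
      shift <- sample.int(3L, sum(ch), replace = TRUE)
      new[ch] <- (new[ch] + shift) %% 4L
    }
    st[v, ] <- new
  }
  st[seq_len(n), , drop = FALSE]
}

#' Evolve methylation states along a genealogy
#'
#' Simulates the symmetric two-state (CFN) epimutation process site by site
#' along a genealogy (or a set of per-interval marginal genealogies from a
#' recombination run).  The root state of each site is drawn from
#' `root_freqs` and the state flips along a branch of length `T` (4N units)
#' with probability `(1 - exp(-2 * theta * T)) / 2` at per-site rate
#' `theta`.  In nucleotide mode a symmetric four-state model is used with
#' change probability `(3/4) * (1 - exp(-(4/3) * theta * T))`.
#'
#' @param genealogy A `genealogy` or a list of marginal genealogies, each a
#'   list with `from`, `to` (site interval) and `tree`.
#' @param site_rates Per-site scaled rates (length `L`).
#' @param root_freqs Initial-state distribution; default `c(0.5, 0.5)`.
#' @param mode `"methylation"` or `"nucleotide"`.
#' @param seed Optional integer seed.
#' @return A [state_matrix()].
#' @export
evolve_states <- function(genealogy, site_rates, root_freqs = c(0.5, 0.5),
                          mode = c("methylation", "nucleotide"), seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  L <- length(site_rates)
  marginal <- !inherits(genealogy, "genealogy")
  blocks <- if (marginal) genealogy else list(list(from = 1L, to = L, tree = genealogy))
  n <- blocks[[1L]]$tree$n
  out <- matrix(0L, n, L)
  for (b in blocks) {
    idx <- b$from:b$to
    if (mode == "methylation") {
      roots <- as.integer(stats::runif(length(idx)) < root_freqs[2L])
      out[, idx] <- evolve_block(b$tree, site_rates[idx], roots)
    } else {
      roots <- sample.int(4L, length(idx), replace = TRUE) - 1L
      out[, idx] <- evolve_block_nuc(b$tree, site_rates[idx], roots)
    }
  }
  state_matrix(out, mode = mode)
}

derive_rep_seeds <- function(seed, reps) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, reps)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

#' Simulate replicate SMP matrices under neutrality or demography
#'
#' The full neutral generator: for each replicate, draw a genealogy under
#' the given demography, draw gamma per-site rates and evolve two-state
#' methylation states along the tree (no recombination).  Replicates are
#' seeded from per-replicate substreams derived from `seed`, so any
#' replicate is independently reproducible.
#'
#' @param n Samples per replicate.
#' @param L Sites per replicate.
#' @param mean_theta Mean per-site scaled epimutation rate.
#' @param alpha Gamma shape of among-site rate variation.
#' @param demography A [demography][demography_constant()] object.
#' @param reps Number of replicates.
#' @param seed Master seed (integer).
#' @return A list of `reps` [state_matrix()] objects.
#' @examples
#' ms <- simulate_dataset(n = 10, L = 100, mean_theta = 0.1, alpha = 0.5,
#'                        reps = 2, seed = 7)
#' @export
simulate_dataset <- function(n = 60, L = 1000, mean_theta = 0.1, alpha = 0.5,
                             demography = demography_constant(),
                             reps = 1, seed = 1) {
  rs <- derive_rep_seeds(seed, reps)
  lapply(seq_len(reps), function(i) {
    set.seed(rs[i])
    g <- simulate_genealogy(n, demography)
    rates <- draw_site_rates(L, mean_theta, alpha)
    evolve_states(g, rates)
  })
}

#' Apply a statistic to simulated replicates without storing matrices
#'
#' Memory-light driver used by the power machinery: generates each
#' replicate exactly as [simulate_dataset()] would and immediately reduces
#' it with `fn`.
#'
#' @inheritParams simulate_dataset
#' @param fn Function taking a [state_matrix()] and returning a one-row
#'   tibble (default: [smp_test()] with `alpha` fixed at the simulated
#'   value).
#' @return A tibble with one row per replicate (column `rep` first).
#' @export
simulate_stats <- function(n = 60, L = 1000, mean_theta = 0.1, alpha = 0.5,
                           demography = demography_constant(),
                           reps = 1, seed = 1, fn = NULL) {
  if (is.null(fn)) fn <- function(m) smp_test(m, alpha = alpha)
  rs <- derive_rep_seeds(seed, reps)
  purrr::map_dfr(seq_len(reps), function(i) {
    set.seed(rs[i])
    g <- simulate_genealogy(n, demography)
    rates <- draw_site_rates(L, mean_theta, alpha)
    m <- evolve_states(g, rates)
    dplyr::bind_cols(tibble::tibble(rep = i), fn(m))
  })
}
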