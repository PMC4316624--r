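#' Pairwise mismatch distances between samples
#'
#' Proportion of complete-case sites at which two samples carry different
#' states; the input to neighbor-joining tree construction.
#'
#' @param x A [state_matrix()].
#' @return A symmetric `dist`-compatible matrix with zero diagonal.
#' @export
smp_distance <- function(x) {
  m <- as.matrix(x)
  keep <- colSums(is.na(m)) == 0L
  if (!any(keep)) stop("empty locus: no site has complete calls", call. = FALSE)
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- mean(m[i, ] != m[j, ])
    }
  }
  d
}

#' Neighbor-joining tree of the samples
#'
#' Saitou-Nei neighbor joining on the mismatch distances (via
#' [ape::nj()]); only the topology is consumed downstream by the parsimony
#' change counts.  All-zero distances yield a valid (star-like) tree with
#' zero branch lengths.  Deterministic for a given matrix.
#'
#' @param x A [state_matrix()] or a distance matrix from [smp_distance()].
#' @return An [ape::phylo] tree (unrooted).
#' @export
nj_tree <- function(x) {
  d <- if (inherits(x, "state_matrix") || (is.matrix(x) && !isSymmetric(unname(x)))) {
    smp_distance(x)
  } else {
    as.matrix(x)
  }
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 samples for a tree", call. = FALSE)
  if (n == 3L) {
    # the unique unrooted topology on three taxa
    lab <- rownames(d)
    if (is.null(lab)) lab <- paste0("s", 1:3)
    v <- c((d[1, 2] + d[1, 3] - d[2, 3]) / 2,
           (d[1, 2] + d[2, 3] - d[1, 3]) / 2,
           (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
    tr <- list(edge = cbind(4L, 1:3), edge.length = pmax(v, 0),
               tip.label = lab, Nnode = 1L)
    class(tr) <- "phylo"
    attr(tr, "order") <- "cladewise"
    return(tr)
  }
  ape::nj(d)
}

#' Minimum parsimony change counts per site on a tree
#'
#' Exact small-parsimony (Fitch) counts of the minimum number of binary
#' state changes needed on the tree to explain each site's leaf states,
#' computed by two-state dynamic programming over an arbitrary rooting
#' (the count is root-invariant).
#'
#' @param tree An [ape::phylo] tree whose tip labels match the sample ids.
#' @param states Either a vector of one 0/1 state per leaf (ordered as
#'   `tree$tip.label` or named by them), or an `n x L` matrix / `state_matrix`
#'   of sites in columns.
#' @return Integer vector of per-site minimum change counts.
#' @export
fitch_site_changes <- function(tree, states) {
  if (is.null(dim(states))) states <- matrix(states, ncol = 1L)
  m <- as.matrix(states)
  storage.mode(m) <- "integer"
  if (!is.null(rownames(m)) && all(tree$tip.label %in% rownames(m))) {
    m <- m[tree$tip.label, , drop = FALSE]
  }
  ntip <- length(tree$tip.label)
  if (nrow(m) != ntip) stop("one state row per leaf required", call. = FALSE)
  if (anyNA(m)) stop("leaf without a called state", call. = FALSE)
  L <- ncol(m)
  nnode <- ntip + tree$Nnode
  big <- L + 1L  # effectively infinite cost
  c0 <- matrix(0L, nnode, L)
  c1 <- matrix(0L, nnode, L)
  c0[seq_len(ntip), ] <- ifelse(m == 0L, 0L, big)
  c1[seq_len(ntip), ] <- ifelse(m == 1L, 0L, big)
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1L]
    ch <- tree$edge[e, 2L]
    c0[p, ] <- pmin.int(c0[p, ] + c0[ch, ], c0[p, ] + c1[ch, ] + 1L)
    c1[p, ] <- pmin.int(c1[p, ] + c1[ch, ], c1[p, ] + c0[ch, ] + 1L)
  }
  root <- ntip + 1L
  as.integer(pmin.int(c0[root, ], c1[root, ]))
}

#' Per-site change-count tally for a locus
#'
#' Builds the neighbor-joining tree of the samples and counts the minimum
#' number of inferred state changes `k` at every retained site, capping
#' counts above `cap_at - 1` at `cap_at` (default: exact for `k <= 5`, all
#' larger counts recorded as 6).
#'
#' @param x A [state_matrix()] with at least 3 samples.
#' @param cap_at Cap value for large change counts (default 6).
#' @return A tibble with columns `k` (0..`cap_at`) and `N_k` (site counts).
#' @export
site_change_tally <- function(x, cap_at = 6L) {
  m <- as.matrix(x)
  keep <- colSums(is.na(m)) == 0L
  m <- m[, keep, drop = FALSE]
  if (nrow(m) < 3L) stop("need at least 3 samples", call. = FALSE)
  tr <- nj_tree(state_matrix(m))
  k <- fitch_site_changes(tr, m)
  k <- pmin.int(k, cap_at)
  tibble::tibble(k = 0:cap_at,
                 N_k = vapply(0:cap_at, function(v) sum(k == v), integer(1)))
}

#' Estimate the gamma shape of among-site epimutation-rate variation
#'
#' Method-of-moments estimator: if the per-site change rate is gamma
#' distributed with shape `alpha`, the minimum parsimony change counts `k`
#' across sites are approximately negative binomial, so with sample mean
#' `m` and (population) variance `s2` of `k`,
#' `alpha = m^2 / (s2 - m)`.  Two special cases: `s2 = 0` returns
#' `alpha = 1e6` (effectively rate homogeneity), and `s2 < m`
#' (underdispersion, where the moment estimate would be negative) uses the
#' substitution `1 - m/s2 = exp(-m/s2)`, giving
#' `alpha = m^2 / (s2 * exp(-m/s2))`.
#'
#' @inheritParams site_change_tally
#' @return A one-row tibble with `alpha`, `m`, `s2`, `L`, `n` and the rule
#'   used (`"moment"`, `"zero_variance"` or `"underdispersed"`).
#' @examples
#' m <- simulate_dataset(n = 10, L = 300, mean_theta = 0.1, alpha = 0.5,
#'                       reps = 1, seed = 3)[[1]]
#' estimate_alpha(m)
#' @export
estimate_alpha <- function(x, cap_at = 6L) {
  mm <- as.matrix(x)
  keep <- colSums(is.na(mm)) == 0L
  mm <- mm[, keep, drop = FALSE]
  if (nrow(mm) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (ncol(mm) < 2L) stop("need at least 2 retained sites", call. = FALSE)
  tr <- nj_tree(state_matrix(mm))
  k <- pmin.int(fitch_site_changes(tr, mm), cap_at)
  L <- length(k)
  m <- mean(k)
  s2 <- mean((k - m)^2)  # population variance, denominator L
  if (s2 == 0) {
    alpha <- 1e6
    rule <- "zero_variance"
  } else if (s2 < m) {
    alpha <- m^2 / (s2 * exp(-m / s2))
    rule <- "underdispersed"
  } else {
    alpha <- m^2 / (s2 - m)
    rule <- "moment"
  }
  tibble::tibble(alpha = alpha, m = m, s2 = s2, L = L, n = nrow(mm), rule = rule)
}
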