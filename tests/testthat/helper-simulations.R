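# Shared, lazily computed simulation results reused across test files.
# Everything is seeded, so the cache only avoids recomputation.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

stat_fn <- function(alpha) {
  function(m) {
    s <- dmtest::locus_summary(m)
    tibble::tibble(
      Dm = dmtest::dm_statistic(s, alpha)$statistic,
      Dmod = dmtest::dmod_statistic(s, alpha)$statistic,
      D = dmtest::tajima_d(s)$statistic,
      Dm_inv = dmtest::dm_statistic(s, alpha, form = "inversion")$statistic,
      pi_m = s$pi_m, s_m = s$s_m, S = s$S)
  }
}

# the study-condition neutral run: n=60, L=1000, mean theta 0.1, alpha 0.5
neutral_null <- function() {
  cached("neutral_null",
         dmtest::simulate_stats(n = 60, L = 1000, mean_theta = 0.1,
                                alpha = 0.5, reps = 5000, seed = 20140901,
                                fn = stat_fn(0.5)))
}

neutral_run <- function(mean_theta, alpha, reps, seed) {
  key <- sprintf("neutral_%g_%g_%d_%d", mean_theta, alpha, reps, seed)
  cached(key, dmtest::simulate_stats(n = 60, L = 1000,
                                     mean_theta = mean_theta, alpha = alpha,
                                     reps = reps, seed = seed,
                                     fn = stat_fn(alpha)))
}

selection_run <- function(scenario, init, reps, seed, hold = 0) {
  key <- sprintf("sel_%s_%s_%d_%d_%g", scenario, init, reps, seed, hold)
  cached(key, dmtest::simulate_selected_stats(
    scenario, init = init, reps = reps, seed = seed, hold = hold, N = 500,
    fn = stat_fn(0.5)))
}

random_state_matrix <- function(n, L, p = 0.5) {
  dmtest::state_matrix(matrix(as.integer(stats::runif(n * L) < p), n, L))
}

# independent reference implementation of Tajima's D: explicit pair loops
# and harmonic sums, sharing no code with the package internals
tajima_d_reference <- function(m) {
  m <- unclass(m)
  n <- nrow(m); L <- ncol(m)
  S <- 0L; pi_total <- 0
  for (j in seq_len(L)) {
    col <- m[, j]
    if (length(unique(col)) > 1L) S <- S + 1L
    d <- 0L
    for (a in 1:(n - 1)) for (b in (a + 1):n) if (col[a] != col[b]) d <- d + 1L
    pi_total <- pi_total + d / choose(n, 2)
  }
  if (S == 0L) return(NaN)
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# exhaustive small-parsimony: minimum over all internal-state assignments
parsimony_bruteforce <- function(tree, states) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  edges <- tree$edge
  best <- Inf
  for (mask in 0:(2^nint - 1)) {
    assign_int <- as.integer(intToBits(mask))[seq_len(nint)]
    full <- c(states, assign_int)
    cost <- sum(full[edges[, 1]] != full[edges[, 2]])
    best <- min(best, cost)
  }
  best
}
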