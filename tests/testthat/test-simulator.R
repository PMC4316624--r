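test_that("pairwise coalescence time has mean 0.5 in 4N units", {
  set.seed(12)
  tm <- replicate(3000, simulate_genealogy(2)$blen[1])
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 0.5), 3 * se)
})

test_that("segregating sites match the Watterson expectation at small rates", {
  st <- neutral_run(mean_theta = 0.01, alpha = 1e6, reps = 400, seed = 21)
  # finite-site expectation at homogeneous small theta
  exp_s <- expected_summaries(0.01, 1e6, 60)$E_sm
  se <- sd(st$s_m) / sqrt(nrow(st))
  expect_lt(abs(mean(st$s_m) - exp_s), 4 * se + 0.001)
})

test_that("gamma site rates have the right moments and degenerate limit", {
  r1 <- draw_site_rates(1e5, 0.1, 1e6, seed = 5)
  expect_lt(sd(r1) / mean(r1), 0.01)
  r2 <- draw_site_rates(1e5, 0.2, 0.5, seed = 6)
  expect_lt(abs(mean(r2) - 0.2), 2 * sd(r2) / sqrt(1e5))
  expect_equal(var(r2), 0.2^2 / 0.5, tolerance = 0.05)
})

test_that("state evolution follows the two-state transition probabilities", {
  # two samples separated by total time T: differ with prob (1-exp(-2*theta*T))/2
  n <- 2
  tree <- structure(list(n = 2L, parent = c(3L, 3L, 0L),
                         blen = c(0.4, 0.6, 0)), class = "genealogy")
  theta <- 0.8
  m <- evolve_states(tree, rep(theta, 2e4), seed = 9)
  frac <- mean(m[1, ] != m[2, ])
  expected <- 0.5 * (1 - exp(-2 * theta * 1.0))
  expect_equal(frac, expected, tolerance = 0.02)

  # zero branch length: child identical to parent side
  tree0 <- structure(list(n = 2L, parent = c(3L, 3L, 0L),
                          blen = c(0, 0, 0)), class = "genealogy")
  m0 <- evolve_states(tree0, rep(0.5, 500), seed = 10)
  expect_true(all(m0[1, ] == m0[2, ]))

  # very long separation: flip probability saturates at 1/2
  treeL <- structure(list(n = 2L, parent = c(3L, 3L, 0L),
                          blen = c(50, 50, 0)), class = "genealogy")
  mL <- evolve_states(treeL, rep(1, 2e4), seed = 11)
  expect_equal(mean(mL[1, ] != mL[2, ]), 0.5, tolerance = 0.02)
})

test_that("transition matrix rows sum to 1 and Chapman-Kolmogorov holds", {
  P <- function(t, th) {
    p <- 0.5 * (1 - exp(-2 * th * t))
    matrix(c(1 - p, p, p, 1 - p), 2, 2)
  }
  th <- 0.7
  expect_equal(rowSums(P(0.3, th)), c(1, 1))
  expect_equal(P(0.2, th) %*% P(0.5, th), P(0.7, th), tolerance = 1e-12)
})

test_that("marginal methylation frequency is balanced under the symmetric model", {
  st <- cached("freq_check", {
    ms <- simulate_dataset(n = 20, L = 500, mean_theta = 0.5, alpha = 1,
                           reps = 30, seed = 13)
    mean(vapply(ms, function(m) mean(m == 1L), 0))
  })
  expect_equal(st, 0.5, tolerance = 0.05)
})

test_that("simulation is bitwise reproducible under a fixed seed", {
  a <- simulate_dataset(n = 8, L = 50, reps = 3, seed = 77)
  b <- simulate_dataset(n = 8, L = 50, reps = 3, seed = 77)
  expect_identical(a, b)
  # per-replicate substreams: a later replicate alone matches the batch run
  one <- simulate_dataset(n = 8, L = 50, reps = 3, seed = 77)[[3]]
  expect_identical(unclass(one), unclass(b[[3]]))
})

test_that("population expansion shifts the statistics negative, shrinkage positive", {
  null <- neutral_null()
  grow <- cached("demog_grow", dmtest::simulate_stats(
    demography = demography_size_change(100, 0.05),
    reps = 300, seed = 41, fn = stat_fn(0.5)))
  shrink <- cached("demog_shrink", dmtest::simulate_stats(
    demography = demography_size_change(1 / 100, 0.05),
    reps = 300, seed = 42, fn = stat_fn(0.5)))
  for (k in c("Dm", "Dmod", "D")) {
    expect_lt(mean(grow[[k]], na.rm = TRUE), mean(null[[k]], na.rm = TRUE))
    expect_gt(mean(shrink[[k]], na.rm = TRUE), mean(null[[k]], na.rm = TRUE))
  }
  # extreme shrinkage saturates diversity beyond the inversion-form poles:
  # every replicate is flagged undefined in that mode
  expect_equal(sum(is.finite(shrink$Dm_inv)), 0)
})

test_that("island-model sampling scheme shifts the spectrum as expected", {
  even <- cached("island_even", dmtest::simulate_stats(
    demography = demography_island(0.1, c(30, 30)),
    reps = 250, seed = 43, fn = stat_fn(0.5)))
  biased <- cached("island_biased", dmtest::simulate_stats(
    demography = demography_island(0.1, c(59, 1)),
    reps = 250, seed = 44, fn = stat_fn(0.5)))
  for (k in c("Dm", "Dmod", "D")) {
    expect_gt(mean(even[[k]], na.rm = TRUE), mean(biased[[k]], na.rm = TRUE))
  }
})
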