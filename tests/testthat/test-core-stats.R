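test_that("locus summaries count segregating sites and pairwise differences", {
  s <- locus_summary(state_matrix(rbind(c(0, 0, 1), c(0, 1, 1))))
  expect_equal(s$S, 1L)
  expect_equal(s$s_m, 1 / 3)
  expect_equal(s$pi_m, 1 / 3)

  # 4 samples, one site [0,0,1,1]: 4 discordant pairs of 6
  s2 <- locus_summary(state_matrix(matrix(c(0, 0, 1, 1), ncol = 1)))
  expect_equal(s2$pi_m, 4 / 6)
  expect_equal(s2$S, 1L)

  s3 <- locus_summary(state_matrix(matrix(1L, 5, 8)))
  expect_equal(s3$S, 0L)
  expect_equal(s3$pi_m, 0)
})

test_that("missing data is handled complete-case and empty loci error", {
  m <- rbind(c(0L, NA, 1L), c(1L, 0L, 1L), c(0L, 1L, 1L))
  s <- locus_summary(state_matrix(m))
  expect_equal(s$L, 2L)  # middle site dropped
  expect_equal(s$S, 1L)
  all_na <- matrix(NA_integer_, 3, 2)
  expect_error(locus_summary(state_matrix(all_na)), "empty locus")
})

test_that("pi_m <= s_m for binary matrices (property)", {
  set.seed(71)
  for (i in 1:40) {
    m <- random_state_matrix(sample(2:20, 1), sample(1:50, 1),
                             p = runif(1, 0.1, 0.9))
    s <- locus_summary(m)
    expect_lte(s$pi_m, s$s_m + 1e-12)
  }
})

test_that("monomorphic probability matches the n=2 closed form and limits", {
  th <- 0.1
  expect_equal(monomorphic_prob(th, 2), (th + 1) / (2 * (2 * th + 1)))
  # no epimutation: site monomorphic, two equiprobable states
  expect_equal(monomorphic_prob(1e-12, 7), 0.5, tolerance = 1e-9)
  # small-theta slope of P(segregating) is a1
  for (n in 2:10) {
    sl <- (1 - 2 * monomorphic_prob(1e-8, n)) / 1e-8
    expect_equal(sl, sample_constants(n)$a1, tolerance = 1e-5)
  }
  expect_error(monomorphic_prob(-0.1, 5), "positive")
})

test_that("expected summaries: zero rate, n=2 identity, and the gamma-mixture integral", {
  e0 <- expected_summaries(0, alpha = 1, n = 10)
  expect_equal(unlist(e0), c(E_sm = 0, E_pim = 0))

  # at n=2 both summaries are the pairwise difference (a1 = 1, c1 = 2)
  for (th in c(0.05, 0.2)) for (al in c(0.3, 2)) {
    e <- expected_summaries(th, al, 2)
    expect_equal(e$E_sm, e$E_pim)
  }

  # point-rate limit: alpha -> Inf, n = 2, theta 0.1 -> 0.1/1.2
  e <- expected_summaries(0.1, alpha = 1e6, n = 2)
  expect_equal(e$E_pim, 0.1 / 1.2, tolerance = 1e-4)

  # oracle: numeric integral of P(segregating) over the gamma density;
  # the second-order approximation is good to a few percent over the
  # validity range and reaches ~6.5% at the (0.1, 0.5, 60) corner
  for (n in c(10, 60)) for (al in c(0.5, 2)) for (tb in c(0.02, 0.1)) {
    exact <- integrate(function(x)
      (1 - 2 * monomorphic_prob(pmax(x, 1e-14), n)) *
        dgamma(x, shape = al, scale = tb / al), 0, Inf)$value
    appr <- expected_summaries(tb, al, n)$E_sm
    expect_lt(abs(appr - exact), 0.07 * exact)
  }
})

test_that("theta estimators invert the expectations to 10 significant digits", {
  grid <- expand.grid(theta = c(0.001, 0.05, 0.1, 0.3),
                      alpha = c(0.2, 0.5, 1, 10),
                      n = c(2, 10, 60))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    e <- expected_summaries(g$theta, g$alpha, g$n)
    h <- theta_hats(list(n = g$n, s_m = e$E_sm, pi_m = e$E_pim), g$alpha,
                    form = "inversion")
    expect_equal(h$theta_s_hat, g$theta, tolerance = 1e-10)
    expect_equal(h$theta_pi_hat, g$theta, tolerance = 1e-10)
    e4 <- expected_summaries(g$theta, g$alpha, g$n, states = 4)
    h4 <- theta_hats(list(n = g$n, s_m = e4$E_sm, pi_m = e4$E_pim),
                     g$alpha, states = 4, form = "inversion")
    expect_equal(h4$theta_s_hat, g$theta, tolerance = 1e-10)
    expect_equal(h4$theta_pi_hat, g$theta, tolerance = 1e-10)
  }
})

test_that("inversion at zero and undefined denominators are flagged", {
  for (f in c("series", "inversion")) {
    h <- theta_hats(list(n = 10, s_m = 0, pi_m = 0), alpha = 0.5, form = f)
    expect_equal(h$theta_s_hat, 0)
    expect_equal(h$theta_pi_hat, 0)
  }
  # pi_m beyond the inversion pole: flagged, NaN, not truncated
  h2 <- theta_hats(list(n = 10, s_m = 0.1, pi_m = 0.4), alpha = 0.5,
                   form = "inversion")
  expect_false(h2$pi_defined)
  expect_true(is.nan(h2$theta_pi_hat))
  # the series form stays defined there
  h3 <- theta_hats(list(n = 10, s_m = 0.1, pi_m = 0.4), alpha = 0.5)
  expect_true(h3$pi_defined && is.finite(h3$theta_pi_hat))
})

test_that("large-alpha limit of the pi estimator", {
  h <- theta_hats(list(n = 60, s_m = 0.2, pi_m = 0.09), alpha = 1e6,
                  form = "inversion")
  expect_equal(h$theta_pi_hat, 0.09 / (1 - 0.18), tolerance = 1e-4)
})
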