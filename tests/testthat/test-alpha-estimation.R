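test_that("mismatch distances: identical, complementary and mixed rows", {
  m <- state_matrix(rbind(a = c(0L, 0L), b = c(0L, 1L), c = c(1L, 1L)))
  d <- smp_distance(m)
  expect_equal(unname(d["a", "b"]), 0.5)
  expect_equal(unname(d["a", "c"]), 1.0)
  expect_equal(unname(d["b", "c"]), 0.5)
  expect_true(all(diag(d) == 0))
  same <- state_matrix(matrix(rep(c(0L, 1L), each = 4), 4, 2))
  expect_true(all(smp_distance(same) == 0))
})

test_that("neighbor joining recovers an additive four-taxon topology", {
  # distances generated from the tree ((a,b),(c,d)) with internal edge 0.3
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  bl <- c(a = 0.1, b = 0.2, c = 0.15, d = 0.25)
  for (i in 1:3) for (j in (i + 1):4) {
    extra <- if ((i <= 2) != (j <= 2)) 0.3 else 0
    d[i, j] <- d[j, i] <- bl[i] + bl[j] + extra
  }
  tr <- nj_tree(d)
  # a,b must be sisters in the unrooted tree
  pair_ab <- ape::getMRCA(ape::root(tr, "d"), c("a", "b"))
  desc <- ape::extract.clade(ape::root(tr, "d"), pair_ab)$tip.label
  expect_setequal(desc, c("a", "b"))
})

test_that("three taxa give the unique unrooted topology, deterministically", {
  m <- state_matrix(rbind(a = c(0L, 0L, 1L), b = c(0L, 1L, 1L), c = c(1L, 1L, 1L)))
  t1 <- nj_tree(m)
  t2 <- nj_tree(m)
  expect_s3_class(t1, "phylo")
  expect_equal(length(t1$tip.label), 3L)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("parsimony change counts: trivial cases", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(fitch_site_changes(tr, c(a = 0, b = 0, c = 0, d = 0)), 0L)
  expect_equal(fitch_site_changes(tr, c(a = 1, b = 0, c = 0, d = 0)), 1L)
  expect_equal(fitch_site_changes(tr, c(a = 1, b = 0, c = 1, d = 0)), 2L)
  expect_error(fitch_site_changes(tr, c(a = 1, b = NA, c = 1, d = 0)), "state")
})

test_that("parsimony counts equal exhaustive enumeration on random trees", {
  set.seed(55)
  for (k in c(4, 5, 6, 7)) {
    for (rep in 1:8) {
      tr <- ape::rtree(k)
      st <- sample(0:1, k, replace = TRUE)
      names(st) <- tr$tip.label
      got <- fitch_site_changes(tr, st)
      ref <- parsimony_bruteforce(tr, st[tr$tip.label])
      expect_equal(got, as.integer(ref))
    }
  }
})

test_that("parsimony counts agree with phangorn and are root-invariant", {
  skip_if_not_installed("phangorn")
  set.seed(18)
  tr <- ape::rtree(12)
  m <- matrix(sample(0:1, 12 * 40, replace = TRUE), 12, 40,
              dimnames = list(tr$tip.label, NULL))
  got <- fitch_site_changes(tr, m)
  pd <- phangorn::phyDat(m, type = "USER", levels = c(0, 1))
  ref <- attr(phangorn::parsimony(tr, pd, site = "site"), "pscore")
  if (is.null(ref)) ref <- phangorn::parsimony(tr, pd, site = "site")
  expect_equal(got, as.integer(ref))
  # rooting must not change the counts
  tr2 <- ape::root(tr, tr$tip.label[5], resolve.root = TRUE)
  expect_equal(fitch_site_changes(tr2, m), got)
})

test_that("alpha special cases are exact", {
  # all sites with identical inferred change counts: zero variance
  m <- state_matrix(cbind(c(0L, 1L, 1L, 1L), c(1L, 0L, 0L, 0L)))
  a <- estimate_alpha(m)
  expect_equal(a$s2, 0)
  expect_equal(a$alpha, 1e6)
  expect_equal(a$rule, "zero_variance")

  # the underdispersed substitution formula: m=1, s2=0.5 -> 1/(0.5 e^-2)
  expect_equal(1^2 / (0.5 * exp(-1 / 0.5)), 14.7781122, tolerance = 1e-6)
})

test_that("alpha estimation is invariant to sample and site order", {
  set.seed(4)
  m <- simulate_dataset(n = 12, L = 200, mean_theta = 0.1, alpha = 0.5,
                        reps = 1, seed = 44)[[1]]
  a0 <- estimate_alpha(m)$alpha
  perm_samples <- unclass(m)[sample(nrow(m)), ]
  perm_sites <- unclass(m)[, sample(ncol(m))]
  expect_equal(estimate_alpha(state_matrix(perm_samples))$alpha, a0)
  expect_equal(estimate_alpha(state_matrix(perm_sites))$alpha, a0)
})

test_that("alpha estimates rank-correlate with the simulated shape", {
  # recovery is tested in the low-alpha regime the estimator is built for;
  # near rate homogeneity the underdispersed-branch formula saturates and
  # estimates become bimodal (the moment method is known to be inaccurate
  # there)
  alphas <- c(0.2, 0.5, 1)
  res <- purrr::map_dfr(seq_along(alphas), function(ai) {
    st <- dmtest::simulate_stats(n = 30, L = 600, mean_theta = 0.1,
                                 alpha = alphas[ai], reps = 15,
                                 seed = 301,
                                 fn = function(m) estimate_alpha(m)["alpha"])
    tibble::tibble(truth = alphas[ai], est = st$alpha)
  })
  rho <- cor(res$truth, res$est, method = "spearman")
  expect_gt(rho, 0.8)
  # smaller true alpha (more heterogeneity) -> stochastically smaller estimates
  med <- tapply(res$est, res$truth, median)
  expect_true(med["0.2"] < med["1"])
})
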