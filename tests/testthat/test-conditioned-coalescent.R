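tree_height <- function(tree) {
  # leaf-to-root time, leaves contemporaneous
  h <- 0; v <- 1L
  while (tree$parent[v] != 0L) { h <- h + tree$blen[v]; v <- tree$parent[v] }
  h
}

test_that("a trajectory pinned at frequency 1 reduces to the neutral coalescent", {
  set.seed(61)
  t_cond <- replicate(600, {
    cg <- conditioned_genealogies(rep(1, 10), n = 6, rho = 0, L = 10,
                                  selected_index = 5, N = 100)
    tree_height(cg$blocks[[1]]$tree)
  })
  t_neut <- replicate(600, {
    g <- simulate_genealogy(6)
    tree_height(g)
  })
  ks <- suppressWarnings(ks.test(t_cond, t_neut))
  expect_gt(ks$p.value, 0.01)
})

test_that("no recombination gives a single marginal tree; rho adds blocks", {
  cg0 <- conditioned_genealogies(rep(1, 5), n = 12, rho = 0, L = 200,
                                 selected_index = 100, seed = 3)
  expect_length(cg0$blocks, 1L)
  expect_equal(cg0$blocks[[1]]$from, 1L)
  expect_equal(cg0$blocks[[1]]$to, 200L)

  set.seed(64)
  nb <- replicate(40, length(conditioned_genealogies(
    rep(1, 5), n = 40, rho = 2, L = 500, selected_index = 250)$blocks))
  expect_gt(mean(nb), 2)
})

test_that("marginal trees are well formed and cover the sites", {
  tr <- gs_model1_trajectory(gs_preset("model1-r0.5-t0.1", "old"))
  cg <- conditioned_genealogies(tr$p2, n = 20, rho = 0.8, L = 300,
                                selected_index = 150, N = 500, seed = 9)
  covered <- integer(0)
  for (b in cg$blocks) {
    t <- b$tree
    expect_equal(t$n, 20L)
    expect_true(all(t$blen[-(2 * 20 - 1)] >= 0))
    # every non-root node has a later-numbered parent
    expect_true(all(t$parent[1:(2 * 20 - 2)] > seq_len(2 * 20 - 2)))
    covered <- c(covered, b$from:b$to)
  }
  expect_equal(sort(covered), 1:300)
})

test_that("sampled class counts follow the sampling-time frequency", {
  tr <- gs_model1_trajectory(gs_preset("model1-r0.5-t0.1", "old"))
  x <- tr$p2[nrow(tr)]  # 0.8907
  set.seed(15)
  nn <- replicate(300, conditioned_genealogies(tr$p2, n = 60, rho = 0,
                                               L = 10, selected_index = 5,
                                               N = 500)$n_new)
  se <- sd(nn) / sqrt(length(nn))
  expect_lt(abs(mean(nn) - 60 * x), 4 * se)
})

test_that("a sweep-like scenario leaves a rare-variant excess (negative Dm)", {
  st <- selection_run("model1-r0.5-t0.1", "old", reps = 120, seed = 71)
  expect_gt(mean(is.finite(st$Dm)), 0.95)
  expect_lt(mean(st$Dm, na.rm = TRUE), -1)
})

test_that("power ordering across scenario types is directional", {
  # Type-1-like (large rare excess) more negative than Type-2-like (mild),
  # which is no more negative than neutral
  s1 <- selection_run("model1-r0.5-t0.1", "old", reps = 120, seed = 71)
  s2 <- selection_run("model1-r0.5-t0.1", "new", reps = 120, seed = 72)
  nn <- neutral_null()
  m1 <- mean(s1$Dm, na.rm = TRUE)
  m2 <- mean(s2$Dm, na.rm = TRUE)
  m0 <- mean(nn$Dm, na.rm = TRUE)
  expect_lt(m1, m2)
  expect_lt(m2, m0 + 0.1)
})

test_that("the focal site carries the class-coded states", {
  ms <- simulate_selected_dataset("model1-r0.5-t0.1", init = "old", n = 15,
                                  L = 60, rho = 0, selected_index = 30,
                                  N = 500, reps = 1, seed = 5)
  m <- ms[[1]]
  cg_col <- m[, 30]
  expect_true(all(cg_col %in% c(0L, 1L)))
})
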