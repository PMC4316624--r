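## Trajectory-conditioned structured coalescent with recombination
## (mssel-style).  Two allelic classes at a focal site: the "new" class
## whose frequency follows a given forward-time trajectory (rising from 0),
## and the ancestral class.  Backwards in time, lineages coalesce only
## within their class at rate inversely proportional to the class
## frequency; recombination detaches the background of a lineage, which is
## re-sampled from the population; when the new class's frequency reaches
## zero (origination), its remaining lineages merge into a single lineage
## that joins the ancestral class.

#' Conditioned genealogies at and around a selected site
#'
#' Simulates the genealogy of `n` sampled chromosomes at `L` linked sites
#' when the allelic class at the focal site followed a deterministic
#' frequency trajectory.  Continuous (exponential-rate) dynamics are used
#' while class frequencies are constant (the equilibrium hold phase and
#' the pre-origination neutral phase); the per-generation transient is
#' simulated generation by generation with parent sampling in a
#' population of `2 * N` sequences, which handles the very fast frequency
#' changes of epiallele trajectories exactly.  Time is returned in `4N`
#' units.
#'
#' @param trajectory Forward-time vector of the new class's frequency per
#'   generation (element 1 = founding generation; last element = frequency
#'   at sampling).  Typically a column of a [gs_model1_trajectory()] /
#'   [gs_model2_trajectory()] result.
#' @param n Sample size.
#' @param n_new Number of sampled chromosomes carrying the new class
#'   (`NULL`: binomial draw from the sampling-time frequency).
#' @param rho Total scaled recombination rate `4*N*r*(L-1)` across the
#'   locus.
#' @param L Number of sites.
#' @param selected_index Site index of the focal (selected) site.
#' @param hold Time (4N units) the equilibrium was maintained before
#'   sampling (prepended as a constant-frequency segment).
#' @param N Diploid population size used to convert generations to
#'   coalescent time (one generation = `1 / (4 * N)` units).
#' @param seed Optional integer seed.
#' @return A list with `blocks` (marginal genealogies: `from`, `to`,
#'   `tree`), `n_new`, and `classes` (per-leaf class, 1 = new class).
#'   Leaves `1..n_new` are the new-class samples.
#' @export
conditioned_genealogies <- function(trajectory, n, n_new = NULL, rho = 0,
                                    L = 1000, selected_index = 500,
                                    hold = 0, N = 1e4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x_samp <- trajectory[length(trajectory)]
  if (is.null(n_new)) n_new <- stats::rbinom(1, n, x_samp)
  if (x_samp <= 0) n_new <- 0L
  if (x_samp >= 1) n_new <- n
  n_new <- as.integer(n_new)

  ## mutable simulation state
  ev <- new.env(parent = emptyenv())
  ev$events <- vector("list", 4L * n)
  ev$nev <- 0L
  ev$next_id <- n + 1L
  push <- function(e) {
    ev$nev <- ev$nev + 1L
    if (ev$nev > length(ev$events)) ev$events <- c(ev$events, vector("list", length(ev$events)))
    ev$events[[ev$nev]] <- e
  }
  ## active lineages
  id <- seq_len(n)
  cls <- c(rep(1L, n_new), rep(2L, n - n_new))
  lo <- rep(1L, n)
  hi <- rep(L, n)
  tnow <- 0

  do_coal <- function(i, j, time) {
    new <- ev$next_id; ev$next_id <- ev$next_id + 1L
    push(list(type = "coal", time = time, a = id[i], b = id[j], new = new))
    id[i] <<- new
    cls[i] <<- cls[i]
    lo[i] <<- min(lo[i], lo[j]); hi[i] <<- max(hi[i], hi[j])
    id <<- id[-j]; cls <<- cls[-j]; lo <<- lo[-j]; hi <<- hi[-j]
  }
  do_rec <- function(i, time, x_now) {
    if (hi[i] <= lo[i]) return(invisible())
    bp <- lo[i] + sample.int(hi[i] - lo[i], 1L) - 1L  # in lo..hi-1
    lid <- ev$next_id; rid <- ev$next_id + 1L
    ev$next_id <- ev$next_id + 2L
    push(list(type = "rec", time = time, u = id[i], left = lid, right = rid, bp = bp))
    focal_left <- selected_index <= bp
    newcls_left <- if (focal_left) cls[i] else
      if (stats::runif(1) < x_now) 1L else 2L
    newcls_right <- if (!focal_left) cls[i] else
      if (stats::runif(1) < x_now) 1L else 2L
    ohi <- hi[i]
    id[i] <<- lid; cls[i] <<- newcls_left; hi[i] <<- bp
    id <<- c(id, rid); cls <<- c(cls, newcls_right)
    lo <<- c(lo, bp + 1L); hi <<- c(hi, ohi)
  }
  merge_class1 <- function(time) {
    # origination: remaining new-class lineages coalesce, join ancestral class
    repeat {
      w <- which(cls == 1L)
      if (length(w) <= 1L) break
      do_coal(w[1L], w[2L], time)
    }
    cls[cls == 1L] <<- 2L
  }

  rec_rate <- function() if (rho > 0) rho * (hi - lo) / (L - 1) else numeric(length(id))

  ## continuous-time phase with constant class frequencies x1 (new), until
  ## duration elapses (Inf = run to single lineage)
  run_const <- function(x1, duration) {
    tend <- if (is.finite(duration)) tnow + duration else Inf
    repeat {
      k1 <- sum(cls == 1L); k2 <- length(id) - k1
      if (length(id) <= 1L) { if (is.finite(tend)) tnow <<- tend; return(TRUE) }
      r1 <- if (x1 > 0) k1 * (k1 - 1) / x1 else 0
      r2 <- if (x1 < 1) k2 * (k2 - 1) / (1 - x1) else 0
      rr <- rec_rate()
      tot <- r1 + r2 + sum(rr)
      if (tot <= 0) { tnow <<- tend; return(FALSE) }
      w <- stats::rexp(1, tot)
      if (tnow + w > tend) { tnow <<- tend; return(FALSE) }
      tnow <<- tnow + w
      u <- stats::runif(1, 0, tot)
      if (u < r1) {
        idx <- which(cls == 1L); pr <- idx[sample.int(k1, 2L)]
        do_coal(pr[1L], pr[2L], tnow)
      } else if (u < r1 + r2) {
        idx <- which(cls == 2L); pr <- idx[sample.int(k2, 2L)]
        do_coal(pr[1L], pr[2L], tnow)
      } else {
        i <- which(cumsum(rr) >= u - r1 - r2)[1L]
        do_rec(i, tnow, x1)
      }
    }
  }

  ## equilibrium hold
  if (hold > 0 && length(id) > 1L) run_const(x_samp, hold)

  ## transient: generation-by-generation, backwards through the trajectory
  G <- length(trajectory)
  dt <- 1 / (4 * N)
  g <- G
  while (g >= 1L && length(id) > 1L) {
    x <- trajectory[g]
    if (x <= 0) break
    tnow <- tnow + dt
    for (c0 in c(1L, 2L)) {
      w <- which(cls == c0)
      if (length(w) < 2L) next
      xc <- if (c0 == 1L) x else 1 - x
      M <- max(1L, round(2 * N * xc))
      par <- sample.int(M, length(w), replace = TRUE)
      # lineages drawing the same parent coalesce; work with ids because
      # active-lineage indices shift as lineages are removed
      dup <- unique(par[duplicated(par)])
      if (length(dup)) {
        ids_here <- id[w]
        for (pp in dup) {
          grp_ids <- ids_here[par == pp]
          for (j in seq_along(grp_ids)[-1L]) {
            i1 <- match(grp_ids[1L], id)
            i2 <- match(grp_ids[j], id)
            do_coal(i1, i2, tnow)
            grp_ids[1L] <- id[i1]
          }
        }
      }
    }
    if (rho > 0 && length(id) > 1L) {
      pr <- rec_rate() * dt
      hit <- which(stats::runif(length(pr)) < pr)
      for (i in rev(hit)) do_rec(i, tnow, x)
    }
    g <- g - 1L
  }
  ## origination: the new class's frequency reached zero backwards, so its
  ## remaining lineages descend from the founding copy and must coalesce.
  ## If instead the trajectory was exhausted while still polymorphic, the
  ## conditioning is dropped and the lineages continue neutrally.
  originated <- g >= 1L && trajectory[g] <= 0
  if (originated && any(cls == 1L)) merge_class1(tnow)
  cls[] <- 2L
  ## neutral phase before the trajectory
  if (length(id) > 1L) run_const(0, Inf)

  build_marginals(ev$events[seq_len(ev$nev)], n, L, n_new)
}

## Assemble per-interval marginal genealogies from the event log.
build_marginals <- function(events, n, L, n_new) {
  bps <- sort(unique(vapply(events, function(e)
    if (e$type == "rec") e$bp else NA_integer_, NA_integer_)))
  bps <- bps[!is.na(bps) & bps < L]
  starts <- c(1L, bps + 1L)
  ends <- c(bps, L)
  blocks <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    s <- starts[b]
    map_ids <- seq_len(n)     # lineage id -> tree node
    map_nodes <- seq_len(n)
    node_time <- numeric(2L * n - 1L)
    parent <- integer(2L * n - 1L)
    nxt <- n + 1L
    for (e in events) {
      if (e$type == "coal") {
        ia <- match(e$a, map_ids)
        ib <- match(e$b, map_ids)
        if (!is.na(ia) && !is.na(ib)) {
          node_time[nxt] <- e$time
          parent[map_nodes[ia]] <- nxt
          parent[map_nodes[ib]] <- nxt
          keep <- -c(ia, ib)
          map_ids <- c(map_ids[keep], e$new)
          map_nodes <- c(map_nodes[keep], nxt)
          nxt <- nxt + 1L
        } else if (!is.na(ia)) {
          map_ids[ia] <- e$new
        } else if (!is.na(ib)) {
          map_ids[ib] <- e$new
        }
      } else {
        iu <- match(e$u, map_ids)
        if (!is.na(iu)) {
          map_ids[iu] <- if (s <= e$bp) e$left else e$right
        }
      }
    }
    if (length(map_ids) != 1L) stop("marginal tree did not fully coalesce")
    blen <- numeric(2L * n - 1L)
    for (v in seq_len(2L * n - 2L)) blen[v] <- node_time[parent[v]] - node_time[v]
    blocks[[b]] <- list(from = s, to = ends[b],
                        tree = new_genealogy(n, parent, blen))
  }
  list(blocks = blocks, n_new = n_new,
       classes = c(rep(1L, n_new), rep(2L, n - n_new)))
}
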