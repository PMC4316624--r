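#' Simulate SMP (or nucleotide) matrices under a selection scenario
#'
#' Full selection pipeline: take a deterministic epiallele (or allele)
#' frequency trajectory, draw the sampled-class configuration binomially
#' from the sampling-time frequency, simulate the trajectory-conditioned
#' structured coalescent with recombination, evolve neutral states along
#' the marginal trees, and overwrite the focal site with the class-coded
#' states.  Defaults reproduce the epigenetic-sequence setting: `L =
#' 1000`, focal site 500, `rho = 0.7992`, `mean_theta = 0.1`, `alpha =
#' 0.5`; nucleotide mode uses `L = 4000`, focal site 2000, `rho = 3.1992`.
#'
#' @param scenario A [gs_preset()] name, a `gs_trajectory`, or a numeric
#'   forward-time frequency trajectory of the focal (new) class.
#' @param n Samples per replicate.
#' @param L Sites.
#' @param mean_theta,alpha Neutral epimutation-rate model for non-focal
#'   sites.
#' @param rho Scaled recombination rate `4*N*r*(L-1)` (0 disables
#'   recombination).
#' @param selected_index Focal site index.
#' @param hold Equilibrium hold time before sampling, in 4N units.
#' @param N Diploid population size for generation-to-coalescent-time
#'   conversion.
#' @param reps Number of replicates.
#' @param seed Master seed.
#' @param mode `"methylation"` or `"nucleotide"`.
#' @param focal_state_new State assigned to new-class samples at the
#'   focal site (ancestral-class samples get 0; default 1, i.e. the new
#'   epiallele is methylated).
#' @param init Passed to [gs_preset()] when `scenario` is a Model-1
#'   preset name.
#' @return A list of [state_matrix()] objects (`simulate_selected_dataset`)
#'   or a tibble of per-replicate statistics (`simulate_selected_stats`).
#' @examples
#' m <- simulate_selected_dataset("model1-r0.5-t0.1", init = "old",
#'                                n = 12, L = 100, rho = 0, reps = 1,
#'                                seed = 5)[[1]]
#' @export
simulate_selected_dataset <- function(scenario, n = 60, L = 1000,
                                      mean_theta = 0.1, alpha = 0.5,
                                      rho = 0.7992, selected_index = 500,
                                      hold = 0, N = 1e4, reps = 1, seed = 1,
                                      mode = c("methylation", "nucleotide"),
                                      focal_state_new = 1L,
                                      init = c("old", "new")) {
  simulate_selected_stats(scenario, n = n, L = L, mean_theta = mean_theta,
                          alpha = alpha, rho = rho,
                          selected_index = selected_index, hold = hold,
                          N = N, reps = reps, seed = seed, mode = mode,
                          focal_state_new = focal_state_new, init = init,
                          fn = identity)
}

#' @rdname simulate_selected_dataset
#' @param fn Reducer applied to each replicate matrix (default:
#'   [smp_test()] with the simulated `alpha`); `identity` returns the
#'   matrices themselves.
#' @export
simulate_selected_stats <- function(scenario, n = 60, L = 1000,
                                    mean_theta = 0.1, alpha = 0.5,
                                    rho = 0.7992, selected_index = 500,
                                    hold = 0, N = 1e4, reps = 1, seed = 1,
                                    mode = c("methylation", "nucleotide"),
                                    focal_state_new = 1L,
                                    init = c("old", "new"), fn = NULL) {
  mode <- match.arg(mode)
  init <- match.arg(init)
  traj <- scenario_trajectory(scenario, init, mode)
  keep_matrices <- identical(fn, identity)
  if (is.null(fn)) fn <- function(m) smp_test(m, alpha = alpha)
  rs <- derive_rep_seeds(seed, reps)
  one <- function(i) {
    set.seed(rs[i])
    cg <- conditioned_genealogies(traj, n = n, rho = rho, L = L,
                                  selected_index = selected_index,
                                  hold = hold, N = N)
    rates <- draw_site_rates(L, mean_theta, alpha)
    m <- evolve_states(cg$blocks, rates, mode = mode)
    focal <- ifelse(cg$classes == 1L, as.integer(focal_state_new), 0L)
    m[, selected_index] <- focal
    m
  }
  if (keep_matrices) return(lapply(seq_len(reps), one))
  purrr::map_dfr(seq_len(reps), function(i)
    dplyr::bind_cols(tibble::tibble(rep = i), fn(one(i))))
}

## Resolve a scenario argument to a forward-time frequency trajectory of
## the focal ("new") class.
scenario_trajectory <- function(scenario, init = "old", mode = "methylation") {
  if (is.numeric(scenario)) return(scenario)
  if (is.character(scenario)) {
    p <- gs_preset(scenario, init = if (startsWith(scenario, "model1")) init else "new")
    scenario <- if (p$model == 1) gs_model1_trajectory(p) else gs_model2_trajectory(p)
  }
  stopifnot(inherits(scenario, "gs_trajectory"))
  p <- attr(scenario, "params")
  if (p$model == 1) {
    # the focal class is the epiallele that started absent
    if (p$p0[1] == 0) scenario$p1 else scenario$p2
  } else {
    if (mode == "nucleotide") scenario$P_a else scenario$ep2
  }
}
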