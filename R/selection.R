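#' Population-epigenetic selection models (Geoghegan-Spencer style)
#'
#' Deterministic recursions for epiallele frequencies at a single locus in
#' an infinite population living in two environments.  Each generation:
#' offspring disperse into environment 1 with probability `r` (else
#' environment 2); with probability `t` their epiallele is reset to the
#' state induced by the environment they reside in (environment j induces
#' epiallele j); viability selection then acts and mating is random.
#' Model 1 follows one locus with two epialleles under diploid epigenotype
#' selection; Model 2 follows a biallelic locus whose gametes carry both
#' an allele (A/a) and an epiallele (1/2), under multiplicative
#' gamete-level fitness with allele-by-epiallele interaction.
#'
#' `gs_params()` builds a parameter object; `gs_preset()` returns the
#' named scenario presets whose fitness settings are calibrated so that
#' the recursions reproduce the published equilibrium frequencies of the
#' scenarios they emulate (see the methods vignette).
#'
#' @param model 1 or 2.
#' @param r Frequency of environment 1 (0..1).
#' @param t Epigenetic resetting probability per generation (0..1).
#' @param w For model 1, epigenotype fitnesses `c(w11, w12, w22)`; for
#'   model 2, gamete fitness factors `c(A1, A2, a1, a2)` (multiplicative
#'   across the two gametes of a diploid).
#' @param p0 Initial frequencies: model 1 `c(p1, p2)`; model 2
#'   `c(A1, A2, a1, a2)`.
#' @param max_generations Iteration cap.
#' @param tol Convergence tolerance on the frequency change.
#' @return A list of class `gs_params`.
#' @export
gs_params <- function(model, r, t, w, p0, max_generations = 100000, tol = 1e-10) {
  stopifnot(model %in% c(1, 2), r >= 0, r <= 1, t >= 0, t <= 1,
            all(w > 0), all(p0 >= 0), abs(sum(p0) - 1) < 1e-8)
  if (model == 1) stopifnot(length(w) == 3, length(p0) == 2)
  if (model == 2) stopifnot(length(w) == 4, length(p0) == 4)
  structure(list(model = model, r = r, t = t, w = w, p0 = p0,
                 max_generations = max_generations, tol = tol),
            class = "gs_params")
}

## Diploid selection map for model 1: post-selection frequency of
## epiallele 1 given pre-selection frequency q and fitnesses w=(w11,w12,w22).
## Unnormalised class frequencies q_i * (marginal fitness); their sum is the
## population mean fitness.
gs1_select <- function(q, w) {
  p1s <- q * (q * w[1] + (1 - q) * w[2])
  p2s <- (1 - q) * (q * w[2] + (1 - q) * w[3])
  wbar <- p1s + p2s
  list(p = p1s / wbar, wbar = wbar)
}

#' Epiallele frequency trajectory under selection Model 1
#'
#' Iterates the reset-then-select recursion
#' `q = (1 - t) * p + t * r`; `p' = q * (q*w11 + (1-q)*w12) / wbar(q)`
#' until the change in `p` falls below `tol` or `max_generations` is
#' reached (non-convergence is flagged, with the partial path returned).
#'
#' @param params A [gs_params()] with `model = 1`, or a preset name for
#'   [gs_preset()].
#' @return A tibble of class `gs_trajectory` with one row per generation
#'   (`generation`, `p1`, `p2`, `w_bar`) and attributes `converged`,
#'   `equilibrium` (final `c(p1, p2)`) and `params`.
#' @examples
#' tr <- gs_model1_trajectory(gs_preset("model1-r0.5-t0.1", init = "new"))
#' attr(tr, "equilibrium")
#' @export
gs_model1_trajectory <- function(params) {
  if (is.character(params)) params <- gs_preset(params)
  stopifnot(inherits(params, "gs_params"), params$model == 1)
  p <- params$p0[1]
  path <- numeric(params$max_generations + 1L)
  wb <- numeric(params$max_generations + 1L)
  path[1L] <- p
  wb[1L] <- gs1_select(p, params$w)$wbar
  conv <- FALSE
  g <- 0L
  while (g < params$max_generations) {
    g <- g + 1L
    q <- (1 - params$t) * p + params$t * params$r
    s <- gs1_select(q, params$w)
    path[g + 1L] <- s$p
    wb[g + 1L] <- s$wbar
    if (abs(s$p - p) < params$tol) { conv <- TRUE; p <- s$p; break }
    p <- s$p
  }
  out <- tibble::tibble(generation = 0:g, p1 = path[1:(g + 1L)],
                        p2 = 1 - path[1:(g + 1L)], w_bar = wb[1:(g + 1L)])
  structure(out, converged = conv, equilibrium = c(p1 = p, p2 = 1 - p),
            params = params,
            class = c("gs_trajectory", class(out)))
}

#' Allele/epiallele frequency trajectory under selection Model 2
#'
#' Four gamete classes (A1, A2, a1, a2).  Resetting moves epialleles
#' within each allele background toward the environment-induced state;
#' selection is gamete-multiplicative, so class frequencies follow
#' `p' = q_k * f_k / sum(q * f)` with `f` the gamete fitness factors.
#' The reported mean fitness is the sum of the unnormalised
#' post-selection class frequencies.
#'
#' @param params A [gs_params()] with `model = 2`, or a preset name.
#' @return A tibble of class `gs_trajectory` with columns `generation`,
#'   `p1..p4`, `P_A`, `P_a`, `ep2` (total new-epiallele frequency) and
#'   `w_bar`, plus the attributes described in [gs_model1_trajectory()].
#' @export
gs_model2_trajectory <- function(params) {
  if (is.character(params)) params <- gs_preset(params)
  stopifnot(inherits(params, "gs_params"), params$model == 2)
  p <- params$p0
  f <- params$w
  t <- params$t
  r <- params$r
  rows <- vector("list", 0L)
  conv <- FALSE
  g <- 0L
  record <- function(g, p, wbar) list(generation = g, p1 = p[1], p2 = p[2],
                                      p3 = p[3], p4 = p[4],
                                      P_A = p[1] + p[2], P_a = p[3] + p[4],
                                      ep2 = p[2] + p[4], w_bar = wbar)
  rows[[1L]] <- record(0L, p, sum(p * f))
  while (g < params$max_generations) {
    g <- g + 1L
    PA <- p[1] + p[2]
    Pa <- p[3] + p[4]
    q <- c((1 - t) * p[1] + t * r * PA,
           (1 - t) * p[2] + t * (1 - r) * PA,
           (1 - t) * p[3] + t * r * Pa,
           (1 - t) * p[4] + t * (1 - r) * Pa)
    ps <- q * f
    wbar <- sum(ps)
    pn <- ps / wbar
    rows[[g + 1L]] <- record(g, pn, wbar)
    if (max(abs(pn - p)) < params$tol) { conv <- TRUE; p <- pn; break }
    p <- pn
  }
  out <- dplyr::bind_rows(rows)
  structure(out, converged = conv,
            equilibrium = c(p1 = p[1], p2 = p[2], p3 = p[3], p4 = p[4]),
            params = params,
            class = c("gs_trajectory", class(out)))
}

## Solve the model-1 fitness scalar so the recursion's equilibrium equals
## p_eq for given (r, t).  Directional selection with the favoured
## epigenotype's homozygote advantaged (fitness x), other genotypes 1.
gs1_calibrate <- function(r, t, p_eq) {
  r <- unname(r); t <- unname(t); p_eq <- unname(p_eq)
  q <- (1 - t) * p_eq + t * r
  if (q > p_eq) {
    # selection must push epiallele 1 down: advantage to the 2-2 homozygote
    x <- 1 + (q / p_eq - 1) / (1 - q)^2
    c(1, 1, x)
  } else {
    # selection must push epiallele 1 up: advantage to the 1-1 homozygote;
    # the map for w = (x,1,1) is p' = q(1+q(x-1))/(1+q^2(x-1)), so
    # q + q^2 y = p + p q^2 y  =>  y = (p - q) / (q^2 (1 - p))
    y <- (p_eq - q) / (q^2 * (1 - p_eq))
    c(1 + y, 1, 1)
  }
}

## Model-2 epiallele fitness ratio on the favoured-allele background such
## that, after the allele fixes, the within-background epiallele
## equilibrium equals ep2_eq.
gs2_calibrate_rho <- function(r, t, ep2_eq) {
  q2 <- (1 - t) * ep2_eq + t * (1 - r)
  (ep2_eq * (1 - q2)) / (q2 * (1 - ep2_eq))
}

#' Named scenario presets for the selection models
#'
#' Ready-made [gs_params()] for the simulation scenarios: five Model-1
#' `(r, t)` combinations and two Model-2 scenarios ("typeI", "typeII").
#' Fitness settings are calibrated so the recursions reach the published
#' equilibrium epiallele frequencies of the corresponding scenarios
#' (Model 1: p1 = 0.1093, 0.413, 0.5103, 0.0552, 0.9378; Model 2: new
#' epiallele 0.9972 and 0.2436 as one allele fixes).  `init` selects the
#' starting state: `"new"` starts with epiallele 1 absent (it rises to
#' equilibrium), `"old"` starts with epiallele 1 fixed (it declines).
#'
#' @param name One of `"model1-r0.5-t0.1"`, `"model1-r0.5-t0.5"`,
#'   `"model1-r0.5-t0.9"`, `"model1-r0.1-t0.5"`, `"model1-r0.9-t0.5"`,
#'   `"model2-typeI"`, `"model2-typeII"`.
#' @param init `"new"` or `"old"` (Model 1 only; Model 2 always starts
#'   with the new epiallele absent and allele a at frequency 0.8).
#' @return A [gs_params()] object.
#' @examples
#' attr(gs_model1_trajectory(gs_preset("model1-r0.1-t0.5")), "equilibrium")
#' @export
gs_preset <- function(name, init = c("new", "old")) {
  init <- match.arg(init)
  m1 <- list(
    "model1-r0.5-t0.1" = c(r = 0.5, t = 0.1, p_eq = 0.1093),
    "model1-r0.5-t0.5" = c(r = 0.5, t = 0.5, p_eq = 0.413),
    "model1-r0.5-t0.9" = c(r = 0.5, t = 0.9, p_eq = 0.5103),
    "model1-r0.1-t0.5" = c(r = 0.1, t = 0.5, p_eq = 0.0552),
    "model1-r0.9-t0.5" = c(r = 0.9, t = 0.5, p_eq = 0.9378)
  )
  if (name %in% names(m1)) {
    z <- m1[[name]]
    w <- gs1_calibrate(z["r"], z["t"], z["p_eq"])
    p0 <- if (init == "new") c(0, 1) else c(1, 0)
    return(gs_params(1, z[["r"]], z[["t"]], w, p0))
  }
  if (name == "model2-typeI") {
    r <- 0.1; t <- 0.2
    rho <- gs2_calibrate_rho(r, t, 0.9972)
    # gamete factors (A1, A2, a1, a2): allele a advantaged, new epiallele
    # (2) favoured on the a background only
    f <- c(1, 0.2, 1.1, 1.1 * rho)
    return(gs_params(2, r, t, f, c(0.2, 0, 0.8, 0)))
  }
  if (name == "model2-typeII") {
    r <- 0.33; t <- 0.2
    rho <- gs2_calibrate_rho(r, t, 0.2436)
    f <- c(1, 0.2, 1.1, 1.1 * rho)
    return(gs_params(2, r, t, f, c(0.2, 0, 0.8, 0)))
  }
  stop("unknown preset '", name, "'", call. = FALSE)
}
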