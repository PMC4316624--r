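#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for null distributions and trajectories
#'
#' `tidy()` returns one row per simulated value (null distributions) or
#' per generation and class (trajectories); `glance()` returns one-row
#' summaries.
#'
#' @param x A `dm_null` or `gs_trajectory` object.
#' @param ... Unused.
#' @return A tibble.
#' @name dmtest-tidiers
NULL

#' @rdname dmtest-tidiers
#' @export
tidy.dm_null <- function(x, ...) {
  purrr::map_dfr(c("Dm", "Dmod", "D"), function(k)
    tibble::tibble(test = k, statistic = x[[k]]))
}

#' @rdname dmtest-tidiers
#' @export
glance.dm_null <- function(x, ...) {
  purrr::map_dfr(c("Dm", "Dmod", "D"), function(k)
    tibble::tibble(test = k,
                   n = length(x[[k]]),
                   n_dropped = x$n_dropped[[k]],
                   mean = mean(x[[k]]),
                   variance = stats::var(x[[k]]),
                   q05 = stats::quantile(x[[k]], 0.05, names = FALSE),
                   q95 = stats::quantile(x[[k]], 0.95, names = FALSE)))
}

#' @rdname dmtest-tidiers
#' @export
tidy.gs_trajectory <- function(x, ...) {
  cols <- intersect(c("p1", "p2", "p3", "p4", "P_A", "P_a", "ep2"), names(x))
  tidyr::pivot_longer(tibble::as_tibble(x)[c("generation", cols)],
                      -"generation",
                      names_to = "class", values_to = "frequency")
}

#' @rdname dmtest-tidiers
#' @export
glance.gs_trajectory <- function(x, ...) {
  eq <- attr(x, "equilibrium")
  tibble::tibble(model = attr(x, "params")$model,
                 generations = max(x$generation),
                 converged = attr(x, "converged"),
                 !!!as.list(eq),
                 w_bar = x$w_bar[nrow(x)])
}

#' Diagnostic plots
#'
#' `autoplot()` methods: histogram of the three null distributions
#' (`dm_null`) and epiallele frequency paths (`gs_trajectory`).
#'
#' @param object A `dm_null` or `gs_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name dmtest-autoplot
NULL

#' @rdname dmtest-autoplot
#' @export
autoplot.dm_null <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey30") +
    ggplot2::facet_wrap(ggplot2::vars(.data$test), scales = "free_y") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "red") +
    ggplot2::labs(x = "statistic", y = "replicates",
                  title = "Neutral null distributions")
}

#' @rdname dmtest-autoplot
#' @export
autoplot.gs_trajectory <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$generation, y = .data$frequency,
                                  colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "generation", y = "frequency",
                  title = "Deterministic selection trajectory")
}
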