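#' Construct a methylation (or nucleotide) state matrix
#'
#' The central data container: an `n x L` integer matrix of site states for
#' `n` sampled chromosomes at `L` cytosine sites.  Methylation mode uses
#' states 0 (unmethylated) and 1 (methylated); nucleotide mode uses 0..3.
#' `NA` marks missing calls.  Genomic coordinates are optional and only
#' needed for region extraction.
#'
#' @param states Integer matrix, samples in rows, sites in columns.
#' @param positions Optional numeric vector of 1-based site coordinates
#'   (length `ncol(states)`).
#' @param chrom Optional chromosome name (single string or per-site vector).
#' @param sample_ids Optional row labels.
#' @param mode `"methylation"` (binary) or `"nucleotide"` (0..3).
#' @return An object of class `state_matrix` (an integer matrix with
#'   attributes `positions`, `chrom` and `mode`).
#' @examples
#' state_matrix(rbind(c(0, 0, 1), c(0, 1, 1)))
#' @export
state_matrix <- function(states, positions = NULL, chrom = NULL,
                         sample_ids = NULL, mode = c("methylation", "nucleotide")) {
  mode <- match.arg(mode)
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (nrow(states) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (ncol(states) < 1L) stop("need at least 1 site", call. = FALSE)
  ok <- if (mode == "methylation") states %in% c(0L, 1L, NA_integer_) else
    states %in% c(0L, 1L, 2L, 3L, NA_integer_)
  if (!all(ok)) stop("invalid state values for mode '", mode, "'", call. = FALSE)
  if (!is.null(positions)) {
    if (length(positions) != ncol(states)) {
      stop("`positions` must have one entry per site", call. = FALSE)
    }
  }
  if (!is.null(sample_ids)) rownames(states) <- sample_ids
  if (is.null(rownames(states))) {
    rownames(states) <- paste0("s", seq_len(nrow(states)))
  }
  structure(states,
            positions = positions,
            chrom = chrom,
            mode = mode,
            class = c("state_matrix", "matrix", "array"))
}

#' @export
print.state_matrix <- function(x, ...) {
  cat(sprintf("<state_matrix: %d samples x %d sites, mode=%s>\n",
              nrow(x), ncol(x), attr(x, "mode")))
  miss <- sum(is.na(x))
  if (miss > 0) cat(sprintf("  missing cells: %d\n", miss))
  invisible(x)
}

#' Per-locus summaries of a state matrix
#'
#' Applies complete-case filtering (a site is retained only when every
#' sample has a called state), then computes the segregating-site count
#' `S`, the proportion of segregating sites `s_m = S / L`, and the average
#' pairwise state difference per site `pi_m` (per-site discordant sample
#' pairs divided by `n * (n - 1) / 2`, averaged over the `L` retained
#' sites).  For binary states `pi_m <= s_m` always holds.
#'
#' @param x A [state_matrix()] in methylation mode (binary states).
#' @return A one-row tibble with columns `n`, `L`, `S`, `s_m`, `pi_m`.
#' @examples
#' locus_summary(state_matrix(rbind(c(0, 0, 1), c(0, 1, 1))))
#' @export
locus_summary <- function(x) {
  if (!inherits(x, "state_matrix")) x <- state_matrix(x)
  if (attr(x, "mode") != "methylation") {
    stop("locus_summary() expects a methylation-mode matrix; use nucleotide_summary() for 0..3 states",
         call. = FALSE)
  }
  keep <- colSums(is.na(x)) == 0L
  if (!any(keep)) stop("empty locus: no site has complete calls", call. = FALSE)
  m <- x[, keep, drop = FALSE]
  n <- nrow(m)
  L <- ncol(m)
  ones <- colSums(m)
  seg <- ones > 0L & ones < n
  npairs <- n * (n - 1) / 2
  pi_site <- ones * (n - ones) / npairs
  tibble::tibble(
    n = n, L = L, S = as.integer(sum(seg)),
    s_m = sum(seg) / L,
    pi_m = sum(pi_site) / L
  )
}

#' Per-locus summaries of a four-state nucleotide matrix
#'
#' Same quantities as [locus_summary()] but for 0..3 states: a site
#' segregates when more than one state is present and the per-site pairwise
#' difference counts discordant sample pairs across all states.
#'
#' @param x A [state_matrix()] in nucleotide mode (or any 0..3 matrix).
#' @return A one-row tibble with columns `n`, `L`, `S`, `s_m`, `pi_m`.
#' @export
nucleotide_summary <- function(x) {
  m <- as.matrix(x)
  keep <- colSums(is.na(m)) == 0L
  if (!any(keep)) stop("empty locus: no site has complete calls", call. = FALSE)
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  L <- ncol(m)
  npairs <- n * (n - 1) / 2
  counts <- vapply(0:3, function(s) colSums(m == s), numeric(L))
  if (L == 1L) counts <- matrix(counts, nrow = 1L)
  seg <- rowSums(counts > 0L) > 1L
  same_pairs <- rowSums(counts * (counts - 1) / 2)
  pi_site <- (npairs - same_pairs) / npairs
  tibble::tibble(
    n = n, L = L, S = as.integer(sum(seg)),
    s_m = sum(seg) / L,
    pi_m = sum(pi_site) / L
  )
}
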