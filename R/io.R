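#' Read and write methylation state matrices
#'
#' The on-disk dialect is tab-separated text with one row per cytosine
#' site: columns `chrom`, `pos` (1-based), then one column per sample
#' with cells in `{0, 1, NA}` (methylation mode) or `{A, C, G, T, N}`
#' (nucleotide mode, `N` = missing).  `read_state_matrix()` and
#' [write_state_matrix()] round-trip exactly; malformed cells are
#' rejected with the offending row and column named.
#'
#' @param path File path.
#' @param mode `"methylation"` or `"nucleotide"`.
#' @return A [state_matrix()] with positions and chromosome attributes.
#' @export
read_state_matrix <- function(path, mode = c("methylation", "nucleotide")) {
  mode <- match.arg(mode)
  tb <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_double(),
    .default = readr::col_character()), progress = FALSE)
  if (!all(c("chrom", "pos") %in% names(tb))) {
    stop("state-matrix file must start with 'chrom' and 'pos' columns", call. = FALSE)
  }
  samples <- setdiff(names(tb), c("chrom", "pos"))
  if (!length(samples)) stop("no sample columns found", call. = FALSE)
  cells <- as.matrix(tb[samples])
  if (mode == "methylation") {
    bad <- !(cells %in% c("0", "1") | is.na(cells))
    parsed <- suppressWarnings(matrix(as.integer(cells), nrow(cells), ncol(cells)))
  } else {
    map <- c(A = 0L, C = 1L, G = 2L, T = 3L)
    bad <- !(cells %in% c(names(map), "N") | is.na(cells))
    parsed <- matrix(map[cells], nrow(cells), ncol(cells))
  }
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid cell '%s' at line %d (site %s:%s), sample '%s'",
                 cells[w[1L], w[2L]], w[1L] + 1L, tb$chrom[w[1L]],
                 format(tb$pos[w[1L]], scientific = FALSE), samples[w[2L]]),
         call. = FALSE)
  }
  state_matrix(t(parsed), positions = tb$pos, chrom = tb$chrom,
               sample_ids = samples, mode = mode)
}

#' @rdname read_state_matrix
#' @param x A [state_matrix()].
#' @export
write_state_matrix <- function(x, path) {
  mode <- attr(x, "mode")
  pos <- attr(x, "positions")
  if (is.null(pos)) pos <- seq_len(ncol(x))
  chrom <- attr(x, "chrom")
  if (is.null(chrom)) chrom <- "chr1"
  cells <- t(unclass(x))
  if (mode == "nucleotide") {
    lut <- c("A", "C", "G", "T")
    cells <- matrix(ifelse(is.na(cells), "N", lut[cells + 1L]),
                    nrow(cells), ncol(cells))
  }
  tb <- tibble::as_tibble(as.data.frame(cells))
  names(tb) <- rownames(x)
  tb <- dplyr::bind_cols(tibble::tibble(chrom = chrom, pos = pos), tb)
  readr::write_tsv(tb, path, progress = FALSE)
  invisible(path)
}

#' Convert 450K-style beta values to diploid pseudo-haplotype states
#'
#' Discretises array beta values into two pseudo-haplotypes per
#' individual: `beta < 0.33` becomes `(0, 0)` (unmethylated homozygote),
#' `beta > 0.66` becomes `(1, 1)`, and intermediate values become
#' `(0, 1)`; the boundaries belong to the heterozygous band (strict
#' inequalities).  Missing betas give `(NA, NA)`.
#'
#' @param beta A numeric matrix (individuals x sites) or data frame of
#'   beta values in `[0, 1]`.
#' @param positions,chrom Optional coordinates, as in [state_matrix()].
#' @return A [state_matrix()] with `2 * nrow(beta)` pseudo-haplotype
#'   rows, named `<id>_1` / `<id>_2`.
#' @examples
#' beta_to_diploid_states(rbind(a = c(0.2, 0.5), b = c(0.9, 0.66)))
#' @export
beta_to_diploid_states <- function(beta, positions = NULL, chrom = NULL) {
  beta <- as.matrix(beta)
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]", call. = FALSE)
  }
  ids <- rownames(beta)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(beta)))
  h1 <- ifelse(is.na(beta), NA_integer_, ifelse(beta > 0.66, 1L, 0L))
  h2 <- ifelse(is.na(beta), NA_integer_, ifelse(beta < 0.33, 0L, 1L))
  out <- matrix(NA_integer_, 2L * nrow(beta), ncol(beta))
  out[seq(1L, by = 2L, length.out = nrow(beta)), ] <- h1
  out[seq(2L, by = 2L, length.out = nrow(beta)), ] <- h2
  rn <- as.vector(rbind(paste0(ids, "_1"), paste0(ids, "_2")))
  state_matrix(out, positions = positions, chrom = chrom, sample_ids = rn)
}

#' Read a gene annotation from GFF or BED
#'
#' Thin wrapper over [rtracklayer::import()] returning the 1-based
#' inclusive coordinate convention used throughout the package (BED
#' half-open intervals are converted on read by rtracklayer).
#'
#' @param path GFF/GTF or BED file.
#' @param feature For GFF input, which feature type to keep (default
#'   `"gene"`; `NULL` keeps everything).
#' @return A tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_annotation <- function(path, feature = "gene") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading annotations requires the rtracklayer package", call. = FALSE)
  }
  gr <- rtracklayer::import(path)
  md <- as.data.frame(gr)
  if (!is.null(feature) && "type" %in% names(md)) {
    md <- md[md$type == feature, , drop = FALSE]
  }
  id <- if ("gene_id" %in% names(md)) md$gene_id
        else if ("ID" %in% names(md)) md$ID
        else if ("Name" %in% names(md)) md$Name
        else if ("name" %in% names(md)) md$name
        else paste0("gene", seq_len(nrow(md)))
  tibble::tibble(gene_id = as.character(id),
                 chrom = as.character(md$seqnames),
                 start = md$start, end = md$end,
                 strand = as.character(md$strand))
}

#' Extract the sites of one gene from a state matrix
#'
#' Keeps the sites whose coordinate lies within the gene body,
#' `start <= pos <= end` on the gene's chromosome (1-based inclusive;
#' strand is ignored because methylation state is per cytosine).
#'
#' @param x A [state_matrix()] with positions.
#' @param annotation A tibble as from [read_gene_annotation()].
#' @param gene_id Gene to extract.
#' @return A [state_matrix()] restricted to the gene's sites.
#' @export
extract_region_matrix <- function(x, annotation, gene_id) {
  pos <- attr(x, "positions")
  if (is.null(pos)) stop("state matrix has no positions", call. = FALSE)
  g <- annotation[annotation$gene_id == gene_id, , drop = FALSE]
  if (!nrow(g)) stop("unknown gene '", gene_id, "'", call. = FALSE)
  chrom <- attr(x, "chrom")
  on_chrom <- if (is.null(chrom)) rep(TRUE, length(pos)) else {
    ch <- if (length(chrom) == 1L) rep(chrom, length(pos)) else chrom
    ch == g$chrom[1L]
  }
  keep <- on_chrom & pos >= g$start[1L] & pos <= g$end[1L]
  if (!any(keep)) stop("gene '", gene_id, "' spans no sites", call. = FALSE)
  state_matrix(unclass(x)[, keep, drop = FALSE],
               positions = pos[keep],
               chrom = g$chrom[1L],
               sample_ids = rownames(x),
               mode = attr(x, "mode"))
}

#' Randomly sample unlinked genes
#'
#' Greedy random sample of genes that (i) carry at least one SMP and
#' (ii) are pairwise separated by at least `min_distance_bp` on the same
#' chromosome, measured end-to-start (the gap between the nearer gene
#' ends).  Genes are visited in random order and kept when compatible
#' with all previously kept genes.
#'
#' @param annotation A tibble as from [read_gene_annotation()].
#' @param per_gene_smp_counts Named integer vector of SMP counts per
#'   gene id.
#' @param min_distance_bp Minimum gap in base pairs (default 25000).
#' @param seed Optional integer seed.
#' @return Character vector of retained gene ids.
#' @export
sample_unlinked_genes <- function(annotation, per_gene_smp_counts,
                                  min_distance_bp = 25000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(min_distance_bp >= 0)
  cnt <- per_gene_smp_counts[annotation$gene_id]
  cand <- annotation[!is.na(cnt) & cnt >= 1L, , drop = FALSE]
  if (!nrow(cand)) return(character(0))
  ord <- sample.int(nrow(cand))
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (cand$chrom[i] != cand$chrom[j]) next
      gap <- max(cand$start[i], cand$start[j]) - min(cand$end[i], cand$end[j])
      if (gap < min_distance_bp) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  cand$gene_id[sort(kept)]
}

#' Read a VCF into a haplotype state matrix (SNP mode)
#'
#' Expands phased or unphased genotypes of biallelic SNPs into haplotype
#' rows coded 0 (reference) / 1 (alternate), for use with [tajima_d()].
#' Multiallelic sites are skipped (their count is reported as an
#' attribute).
#'
#' @param path VCF file (may be gzipped).
#' @return A [state_matrix()] of haplotypes by sites, with attribute
#'   `n_multiallelic_skipped`.
#' @export
read_vcf_states <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF input requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  bi <- !grepl(",", alt) & nzchar(alt)
  n_skip <- sum(!bi)
  gt <- vcfR::extract.gt(v[bi, ], element = "GT")
  split_gt <- function(g) {
    a <- strsplit(g, "[/|]")
    vapply(a, function(z) {
      z <- suppressWarnings(as.integer(z))
      if (length(z) != 2L) z <- c(z, NA_integer_)[1:2]
      z
    }, integer(2))
  }
  n_sites <- nrow(gt)
  ids <- colnames(gt)
  out <- matrix(NA_integer_, 2L * length(ids), n_sites)
  for (j in seq_along(ids)) {
    h <- split_gt(gt[, j])
    out[2L * j - 1L, ] <- h[1L, ]
    out[2L * j, ] <- h[2L, ]
  }
  out[!(out %in% c(0L, 1L))] <- NA_integer_
  pos <- as.numeric(vcfR::getPOS(v))[bi]
  chrom <- vcfR::getCHROM(v)[bi]
  sm <- state_matrix(out, positions = pos, chrom = chrom,
                     sample_ids = as.vector(rbind(paste0(ids, "_1"),
                                                  paste0(ids, "_2"))))
  attr(sm, "n_multiallelic_skipped") <- n_skip
  sm
}
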