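#' Count reads per gene from a 5'-end track
#'
#' For the RNA assay a read is counted for a gene when its 5' end lies in
#' the gene body (`[start, end)` on the gene's strand). For the RPF assay
#' the 5' end is first shifted by `asite_offset` toward 3' on the coding
#' strand, and the resulting A-site is counted when it falls within codons
#' 6 to L/3 - 5 of the gene, excluding the first and last 5 codons to
#' eliminate initiation and termination effects. Genes shorter than 11
#' codons cannot hold that window and are counted as 0 with a warning.
#'
#' @param track An [fp_track()].
#' @param genes Gene annotation data frame with columns `gene_id`, `start`,
#'   `end`, `strand` (0-based half-open coordinates).
#' @param assay `"RNA"` or `"RPF"`.
#' @param asite_offset 5'-end to A-site shift used for the RPF assay.
#' @return A named numeric vector of per-gene counts.
#' @export
count_reads_per_gene <- function(track, genes, assay = c("RNA", "RPF"),
                                 asite_offset = 17L) {
  assay <- match.arg(assay)
  stopifnot(inherits(track, "fp_track"))
  if (any(genes$start < 0) || any(genes$end > track$genome_length)) {
    stop2("gene extends beyond track bounds")
  }
  if (assay == "RPF") {
    if (asite_offset < 0) stop2("asite_offset must be non-negative")
    track <- asite_track(track, asite_offset)
  }
  n <- nrow(genes)
  out <- numeric(n)
  short <- character(0)
  for (g in seq_len(n)) {
    if (assay == "RNA") {
      out[g] <- track_window_sum(track, genes$start[g], genes$end[g], genes$strand[g])
    } else {
      n_cod <- (genes$end[g] - genes$start[g]) %/% 3L
      if (n_cod < 11L) {
        short <- c(short, genes$gene_id[g])
        out[g] <- 0
      } else {
        # codons 6 .. n_cod - 5  <=>  trim 15 nt from each end
        out[g] <- track_window_sum(track, genes$start[g] + 15L,
                                   genes$end[g] - 15L, genes$strand[g])
      }
    }
  }
  if (length(short) > 0) {
    warning(sprintf("RPF counting: %d gene(s) shorter than 11 codons counted as 0 (%s)",
                    length(short), paste(short, collapse = ", ")), call. = FALSE)
  }
  stats::setNames(out, genes$gene_id)
}

#' Assemble a gene x sample count table
#'
#' @param tracks A named list of [fp_track()] objects (names become sample
#'   ids; unnamed lists use the tracks' `library` fields).
#' @param genes Gene annotation data frame (see [count_reads_per_gene()]).
#' @param conditions Character or factor of per-sample condition labels.
#' @inheritParams count_reads_per_gene
#' @return An object of class `count_table`: list with `counts` (matrix),
#'   `samples` (data frame with `sample`, `condition`) and `assay`.
#' @export
count_table <- function(tracks, genes, conditions, assay = c("RNA", "RPF"),
                        asite_offset = 17L) {
  assay <- match.arg(assay)
  ids <- names(tracks) %||% vapply(tracks, function(t) t$library, character(1))
  if (anyDuplicated(ids)) stop2("sample ids must be unique")
  counts <- vapply(tracks, count_reads_per_gene, numeric(nrow(genes)),
                   genes = genes, assay = assay, asite_offset = asite_offset)
  counts <- matrix(counts, nrow = nrow(genes),
                   dimnames = list(genes$gene_id, ids))
  structure(list(counts = counts,
                 samples = data.frame(sample = ids,
                                      condition = as.character(conditions),
                                      stringsAsFactors = FALSE),
                 assay = assay),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %s assay: %d genes x %d samples (conditions: %s)\n",
              x$assay, nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$condition), collapse = ", ")))
  invisible(x)
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = (1e9 * reads mapped to the gene) / (total mapped reads * gene
#' length)`. "Total mapped reads" defaults to the per-sample column sum of
#' the count table (genic total); pass `totals` to use library-wide totals
#' instead.
#'
#' @param counts A `count_table` or a gene x sample count matrix.
#' @param gene_lengths Named vector of gene lengths in nt.
#' @param totals Optional per-sample total mapped reads; defaults to
#'   `colSums(counts)`.
#' @return A gene x sample matrix of RPKM values with attribute `"totals"`.
#' @export
compute_rpkm <- function(counts, gene_lengths, totals = NULL) {
  m <- if (inherits(counts, "count_table")) counts$counts else as.matrix(counts)
  if (is.null(totals)) totals <- colSums(m)
  if (any(totals <= 0)) {
    bad <- colnames(m)[totals <= 0] %||% which(totals <= 0)
    stop2(sprintf("zero total mapped reads in sample(s): %s",
                  paste(bad, collapse = ", ")))
  }
  len <- if (!is.null(rownames(m)) && !is.null(names(gene_lengths))) {
    gene_lengths[rownames(m)]
  } else {
    gene_lengths
  }
  if (anyNA(len) || any(len <= 0)) stop2("gene lengths must be positive for all genes")
  out <- 1e9 * sweep(m, 2, totals, "/") / len
  attr(out, "totals") <- totals
  out
}

#' Median-of-ratios size factors
#'
#' The per-sample factor is the median, over genes expressed in every
#' sample, of the ratio of the gene's count to its geometric mean across
#' samples; factors are rescaled to have geometric mean 1. Columns that
#' are exact scalar multiples of a common base recover those scalars up to
#' the common rescaling.
#'
#' @param counts A `count_table` or count matrix (genes x samples).
#' @return Named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "count_table")) counts$counts else as.matrix(counts)
  if (ncol(m) < 1) stop2("need at least one sample")
  keep <- rowSums(m > 0) == ncol(m)
  if (!any(keep)) stop2("no gene has nonzero counts in all samples")
  lg <- log(m[keep, , drop = FALSE])
  ratios <- lg - rowMeans(lg)
  f <- exp(apply(ratios, 2, stats::median))
  f <- f / geometric_mean(f)
  stats::setNames(f, colnames(m))
}

#' Simple differential expression between two conditions
#'
#' Counts are normalized by [size_factors()]; the log2 fold change is
#' computed on condition-mean normalized counts with a pseudocount of 1.
#' The p-value comes from a two-sided binomial rate-ratio test on the
#' summed normalized counts of the two conditions (the null expected share
#' reflects unequal replicate numbers), adjusted by Benjamini-Hochberg.
#' A gene is flagged significant when `p_adj < alpha` and
#' `|log2FC| > lfc_threshold`.
#'
#' @param counts A `count_table`, or a count matrix plus `conditions`.
#' @param conditions Per-sample condition labels (exactly two levels);
#'   taken from the `count_table` when omitted.
#' @param alpha Adjusted-p significance level (default 0.01).
#' @param lfc_threshold Absolute log2 fold-change threshold (default 1).
#' @param pseudocount Added to normalized condition means before log2.
#' @return Data frame with columns `gene`, `baseMean`, `log2FC`, `p`,
#'   `p_adj`, `significant`. Fold changes are condition 2 vs condition 1
#'   in the order of the condition labels.
#' @export
differential_expression <- function(counts, conditions = NULL, alpha = 0.01,
                                    lfc_threshold = 1, pseudocount = 1) {
  if (inherits(counts, "count_table")) {
    conditions <- conditions %||% counts$samples$condition
    m <- counts$counts
  } else {
    m <- as.matrix(counts)
  }
  if (ncol(m) < 2) stop2("need at least 2 samples")
  conditions <- as.character(conditions)
  lev <- unique(conditions)
  if (length(lev) != 2) stop2("exactly two conditions are required")
  f <- size_factors(m)
  norm <- sweep(m, 2, f, "/")
  i1 <- conditions == lev[1]
  i2 <- conditions == lev[2]
  m1 <- rowMeans(norm[, i1, drop = FALSE])
  m2 <- rowMeans(norm[, i2, drop = FALSE])
  lfc <- log2((m2 + pseudocount) / (m1 + pseudocount))
  s1 <- rowSums(norm[, i1, drop = FALSE])
  s2 <- rowSums(norm[, i2, drop = FALSE])
  p0 <- sum(i2) / (sum(i1) + sum(i2))
  p <- vapply(seq_len(nrow(m)), function(g) {
    x2 <- round(s2[g])
    n <- round(s1[g]) + x2
    if (n == 0) return(1)
    stats::binom.test(x2, n, p = p0)$p.value
  }, numeric(1))
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(
    gene = rownames(m) %||% as.character(seq_len(nrow(m))),
    baseMean = (m1 + m2) / 2, log2FC = lfc, p = p, p_adj = p_adj,
    significant = p_adj < alpha & abs(lfc) > lfc_threshold,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
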