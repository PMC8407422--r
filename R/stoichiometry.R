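#' Coefficient of variation of subunit expression
#'
#' `CV = sample SD / mean * 100` (percent), the standard diagnostic for
#' how evenly the subunits of an enzyme complex or the genes of an operon
#' are translated. Scale-invariant: multiplying all values by a positive
#' constant leaves the CV unchanged.
#'
#' @param x Numeric vector of at least two expression values (e.g.
#'   RPKM_RPF of the subunit genes).
#' @return CV in percent.
#' @export
subunit_cv <- function(x) {
  if (length(x) < 2) stop2("need at least 2 values")
  if (any(!is.finite(x)) || any(x < 0)) stop2("values must be finite and non-negative")
  m <- mean(x)
  if (m == 0) stop2("mean is zero; CV undefined")
  100 * stats::sd(x) / m
}

#' Correlation between subunit copy numbers and translation levels
#'
#' For each complex, the Pearson correlation between subunit copy numbers
#' and translation levels (RPKM_RPF), the proportionality slope through
#' the origin, and for two-subunit complexes the estimated copy-number
#' ratio. Complexes with constant copy numbers have an undefined r and
#' are flagged. A pooled correlation and regression across all subunits
#' is also reported.
#'
#' @param complexes Data frame with columns `complex_id`, `gene_id`,
#'   `copy_number` (and optionally `order`).
#' @param rpkm Named numeric vector of translation levels per gene.
#' @return A list with `per_complex` (data frame: `complex_id`, `n`, `r`,
#'   `slope`, `ratio`, `flagged`) and `pooled` (list with `r`, `p`,
#'   `slope`, `n`).
#' @export
stoichiometry_correlation <- function(complexes, rpkm) {
  missing <- setdiff(complexes$gene_id, names(rpkm))
  if (length(missing) > 0) {
    stop2(sprintf("genes absent from the expression table: %s",
                  paste(missing, collapse = ", ")))
  }
  per <- lapply(split(complexes, complexes$complex_id), function(cx) {
    x <- cx$copy_number
    y <- unname(rpkm[cx$gene_id])
    flagged <- stats::sd(x) == 0
    r <- if (flagged) NA_real_ else suppressWarnings(stats::cor(x, y))
    slope <- sum(x * y) / sum(x * x)
    ratio <- if (nrow(cx) == 2 && x[1] != x[2]) {
      y[which.max(x)] / y[which.min(x)]
    } else {
      NA_real_
    }
    data.frame(complex_id = cx$complex_id[1], n = nrow(cx), r = r,
               slope = slope, ratio = ratio, flagged = flagged,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  x <- complexes$copy_number
  y <- unname(rpkm[complexes$gene_id])
  pooled <- if (length(x) >= 3 && stats::sd(x) > 0 && stats::sd(y) > 0) {
    ct <- stats::cor.test(x, y)
    list(r = unname(ct$estimate), p = ct$p.value,
         slope = sum(x * y) / sum(x * x), n = length(x))
  } else {
    list(r = NA_real_, p = NA_real_, slope = sum(x * y) / sum(x * x), n = length(x))
  }
  list(per_complex = per, pooled = pooled)
}

#' Correlation of translation levels between first and second operon genes
#'
#' Pairs the expression of the first and second gene of every operon with
#' at least two expressed members and reports the Pearson correlation on
#' the log10 scale; proportionate synthesis of operon-encoded subunits
#' shows up as r near 1.
#'
#' @param genes Gene annotation data frame with `gene_id`, `operon_id` and
#'   `operon_pos` columns.
#' @param rpkm Named numeric vector of expression values per gene.
#' @return List with `r`, `p`, `n_operons` and `pairs` (data frame with
#'   `operon_id`, `first`, `second` expression values).
#' @export
first_second_gene_correlation <- function(genes, rpkm) {
  rows <- list()
  for (op in unique(genes$operon_id)) {
    gx <- genes[genes$operon_id == op, , drop = FALSE]
    if (nrow(gx) < 2) next
    gx <- gx[order(gx$operon_pos), , drop = FALSE]
    v1 <- rpkm[gx$gene_id[1]]
    v2 <- rpkm[gx$gene_id[2]]
    if (is.na(v1) || is.na(v2) || v1 <= 0 || v2 <= 0) next
    rows[[length(rows) + 1]] <- data.frame(operon_id = op, first = unname(v1),
                                           second = unname(v2),
                                           stringsAsFactors = FALSE)
  }
  if (length(rows) < 3) stop2("need at least 3 operons with two expressed genes")
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  ct <- stats::cor.test(log10(pairs$first), log10(pairs$second))
  list(r = unname(ct$estimate), p = ct$p.value, n_operons = nrow(pairs),
       pairs = pairs)
}

#' Compare expression between two gene groups
#'
#' Two-tailed Wilcoxon rank-sum comparison of expression levels between
#' two gene groups (e.g. pathway branches), reporting group medians and
#' the direction of the shift.
#'
#' @param x,y Numeric vectors of expression values for the two groups.
#' @return List with `median_x`, `median_y`, `median_difference` and `p`.
#' @export
group_comparison <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) stop2("each group needs at least 2 values")
  wt <- stats::wilcox.test(x, y, exact = length(x) <= 25 && length(y) <= 25)
  list(median_x = stats::median(x), median_y = stats::median(y),
       median_difference = stats::median(x) - stats::median(y), p = wt$p.value)
}
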