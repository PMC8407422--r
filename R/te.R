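#' Translation efficiency per gene and condition
#'
#' TE is the ratio of the RPF level to the mRNA level in arbitrary units:
#' `TE = RPKM_RPF / RPKM_RNA`. Genes whose mRNA RPKM falls below the
#' expression floor in a condition are undefined (`NA`) there and excluded
#' from downstream classification.
#'
#' @param rpkm_rpf,rpkm_rna Gene x condition matrices of condition-mean
#'   RPKM values with identical dimnames.
#' @param floor Minimum RPKM_RNA for a defined TE (default 1).
#' @return A list with `te` (gene x condition matrix, `NA` where
#'   undefined) and, when there are at least two conditions,
#'   `log2_te_change` (condition 2 vs condition 1; `NA` when TE is
#'   undefined in either condition).
#' @export
compute_te <- function(rpkm_rpf, rpkm_rna, floor = 1) {
  rpkm_rpf <- as.matrix(rpkm_rpf)
  rpkm_rna <- as.matrix(rpkm_rna)
  if (!identical(dim(rpkm_rpf), dim(rpkm_rna)) ||
      !identical(rownames(rpkm_rpf), rownames(rpkm_rna))) {
    stop2("RPF and RNA tables must cover the same genes and conditions")
  }
  te <- rpkm_rpf / rpkm_rna
  te[rpkm_rna < floor] <- NA_real_
  te[is.nan(te)] <- NA_real_
  out <- list(te = te)
  if (ncol(te) >= 2) {
    out$log2_te_change <- log2(te[, 2] / te[, 1])
  }
  out
}

#' Classify TE changes with a Gaussian one-SD fold-change threshold
#'
#' Fits the location mu and scale sigma of the log2 TE-change distribution
#' by the sample mean and standard deviation (optionally trimmed) and
#' labels each gene `high` when its change exceeds `mu + sigma`, `low`
#' when it falls below `mu - sigma`, and `neutral` otherwise; undefined
#' changes (`NA`) are labeled `undefined`.
#'
#' @param log2_te_change Named numeric vector of log2 TE changes (`NA` for
#'   undefined genes).
#' @param trim Trimming fraction for the moment estimates (0 = plain
#'   mean/SD; a trimmed alternative is available behind this flag).
#' @return An object of class `te_fit` with elements `mu`, `sigma`,
#'   `thresholds`, `class` (factor per gene), `counts` and `fractions`
#'   (computed both over all genes and over defined genes).
#' @export
classify_te_changes <- function(log2_te_change, trim = 0) {
  x <- log2_te_change
  ok <- !is.na(x)
  if (sum(ok) < 10) stop2("need at least 10 defined log2 TE changes")
  xs <- x[ok]
  if (trim > 0) {
    q <- stats::quantile(xs, c(trim, 1 - trim))
    core <- xs[xs >= q[1] & xs <= q[2]]
    mu <- mean(core)
    sigma <- stats::sd(core)
  } else {
    mu <- mean(xs)
    sigma <- stats::sd(xs)
  }
  if (!is.finite(sigma) || sigma == 0) {
    stop2("degenerate TE-change distribution (sigma = 0)")
  }
  cls <- rep("undefined", length(x))
  cls[ok & x > mu + sigma] <- "high"
  cls[ok & x < mu - sigma] <- "low"
  cls[ok & cls == "undefined"] <- "neutral"
  cls <- factor(cls, levels = c("high", "neutral", "low", "undefined"))
  names(cls) <- names(x)
  counts <- table(cls)
  structure(list(
    mu = mu, sigma = sigma,
    thresholds = c(low = mu - sigma, high = mu + sigma),
    class = cls, counts = counts,
    fractions = list(of_all = counts / length(x),
                     of_defined = counts[1:3] / sum(ok)),
    n = length(x), n_defined = sum(ok),
    log2_te_change = x
  ), class = "te_fit")
}

#' @export
print.te_fit <- function(x, ...) {
  cat(sprintf("<te_fit> n=%d (%d defined): mu=%.3f sigma=%.3f (log2)\n",
              x$n, x$n_defined, x$mu, x$sigma))
  cat(sprintf("  thresholds: low < %.3f, high > %.3f\n",
              x$thresholds["low"], x$thresholds["high"]))
  cat(sprintf("  high %d (%.1f%%), neutral %d, low %d (%.1f%%), undefined %d\n",
              x$counts["high"], 100 * x$fractions$of_all["high"],
              x$counts["neutral"], x$counts["low"],
              100 * x$fractions$of_all["low"], x$counts["undefined"]))
  invisible(x)
}

#' @export
summary.te_fit <- function(object, ...) {
  out <- list(mu = object$mu, sigma = object$sigma,
              thresholds = object$thresholds,
              counts = object$counts, fractions = object$fractions)
  class(out) <- "summary.te_fit"
  out
}

#' @export
print.summary.te_fit <- function(x, ...) {
  cat("Gaussian fit of log2 TE changes\n")
  cat(sprintf("  mu = %.4f, sigma = %.4f\n", x$mu, x$sigma))
  cat(sprintf("  class thresholds: (%.4f, %.4f)\n",
              x$thresholds["low"], x$thresholds["high"]))
  print(x$counts)
  invisible(x)
}

#' @export
coef.te_fit <- function(object, ...) {
  c(mu = object$mu, sigma = object$sigma)
}

#' Classify new log2 TE changes against a fitted threshold
#'
#' @param object A `te_fit`.
#' @param newdata Numeric vector of log2 TE changes; defaults to the
#'   training values.
#' @param ... Unused.
#' @return Factor of class labels.
#' @export
predict.te_fit <- function(object, newdata = NULL, ...) {
  x <- newdata %||% object$log2_te_change
  cls <- rep("undefined", length(x))
  ok <- !is.na(x)
  cls[ok & x > object$thresholds["high"]] <- "high"
  cls[ok & x < object$thresholds["low"]] <- "low"
  cls[ok & cls == "undefined"] <- "neutral"
  factor(cls, levels = levels(object$class))
}

#' @export
plot.te_fit <- function(x, breaks = 50, ...) {
  xs <- x$log2_te_change[!is.na(x$log2_te_change)]
  h <- graphics::hist(xs, breaks = breaks, freq = FALSE,
                      main = "log2 TE change", xlab = "log2 TE change", ...)
  grid <- seq(min(xs), max(xs), length.out = 256)
  graphics::lines(grid, stats::dnorm(grid, x$mu, x$sigma), col = "red", lwd = 2)
  graphics::abline(v = x$thresholds, lty = 2)
  invisible(h)
}

#' Translational-buffering correlation
#'
#' Pearson correlation between per-gene mRNA log2 fold changes and TE log2
#' fold changes; a negative coefficient indicates translational buffering
#' (TE changes oppose mRNA changes).
#'
#' @param mrna_log2fc,te_log2fc Paired numeric vectors; pairs with `NA` in
#'   either are dropped.
#' @return A list with `r`, `p`, and `n`.
#' @export
buffering_correlation <- function(mrna_log2fc, te_log2fc) {
  if (length(mrna_log2fc) != length(te_log2fc)) stop2("inputs must be paired")
  ok <- is.finite(mrna_log2fc) & is.finite(te_log2fc)
  x <- mrna_log2fc[ok]
  y <- te_log2fc[ok]
  if (length(x) < 3) stop2("need at least 3 finite pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop2("zero variance in input vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Gene-set enrichment by the hypergeometric test
#'
#' For each set, the p-value is the hypergeometric upper-tail probability
#' of drawing at least the observed overlap between the set and the query
#' list from the gene universe; correction is Bonferroni (p times the
#' number of sets, capped at 1), as is conventional for curated pathway
#' panels.
#'
#' @param query Character vector of genes of interest (e.g. the high-TE
#'   class), a subset of `universe`.
#' @param geneset_map Data frame with columns `set` and `gene`, or a named
#'   list of gene vectors.
#' @param universe Character vector of all genes considered.
#' @return Data frame with `set`, `size`, `overlap`, `p`, `p_bonferroni`,
#'   sorted by p.
#' @export
geneset_enrichment <- function(query, geneset_map, universe) {
  if (length(universe) == 0) stop2("empty gene universe")
  if (is.data.frame(geneset_map)) {
    geneset_map <- split(geneset_map$gene, geneset_map$set)
  }
  query <- intersect(unique(query), universe)
  N <- length(universe)
  n <- length(query)
  res <- lapply(names(geneset_map), function(s) {
    set <- intersect(unique(geneset_map[[s]]), universe)
    K <- length(set)
    k <- length(intersect(set, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = s, size = K, overlap = k, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out[order(out$p), , drop = FALSE]
}
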