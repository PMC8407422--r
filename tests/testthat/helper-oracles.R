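# Independent oracles used by both the unit and the acceptance suites.
# These re-derive expected results by direct rule evaluation / exhaustive
# enumeration, structurally independent of the package implementation.

# Literal restatement of the TSS categorization rules, evaluated per TSS.
categorize_oracle <- function(tss, genes, upstream = 300, downstream = 100) {
  out <- character(nrow(tss))
  for (i in seq_len(nrow(tss))) {
    cats <- "N"
    for (g in seq_len(nrow(genes))) {
      gs <- genes[g, ]
      anchor <- if (gs$strand == "+") gs$start else gs$end - 1
      d <- if (gs$strand == "+") tss$pos[i] - anchor else anchor - tss$pos[i]
      if (tss$strand[i] == gs$strand && d > -upstream && d <= downstream) {
        dd_all <- if (gs$strand == "+") tss$pos - anchor else anchor - tss$pos
        rivals <- which(tss$strand == gs$strand & dd_all > -upstream & dd_all <= downstream)
        dens <- tss$peak_density[rivals]
        best <- rivals[dens == max(dens)]
        if (length(best) > 1) best <- best[which.min(dd_all[best])]
        cats <- c(cats, if (i == best) "P" else "S")
      } else if (tss$pos[i] >= gs$start && tss$pos[i] < gs$end) {
        cats <- c(cats, if (tss$strand[i] == gs$strand) "I" else "A")
      }
    }
    out[i] <- c("P", "S", "I", "A", "N")[min(match(cats, c("P", "S", "I", "A", "N")))]
  }
  out
}

# Exhaustive recursion over nested structures (minimum hairpin loop 3),
# no memoization: maximum attainable base-pair count.
enumerate_max_pairs <- function(seq) {
  b <- strsplit(toupper(chartr("T", "U", seq)), "")[[1]]
  ok <- function(x, y) paste0(x, y) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  rec <- function(i, j) {
    if (j - i < 4) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + 4L):j) {
      if (ok(b[i], b[k])) {
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    best
  }
  if (length(b) < 5) 0L else rec(1L, length(b))
}

# Random TSS/gene layout generator shared by categorization checks.
random_layout <- function() {
  n_genes <- sample(2:5, 1)
  starts <- sort(sample(seq(200, 4000, by = 50), n_genes))
  genes <- do.call(rbind, lapply(seq_len(n_genes), function(k) {
    gene_row(sprintf("g%d", k), starts[k], starts[k] + sample(c(150, 300, 600), 1),
             strand = sample(c("+", "-"), 1))
  }))
  genes <- genes[genes$end < 5000, , drop = FALSE]
  tss <- data.frame(pos = sample(0:4999, 8), strand = sample(c("+", "-"), 8, TRUE),
                    enrichment_ratio = 5, peak_density = stats::runif(8, 1, 100),
                    libraries = "l1", stringsAsFactors = FALSE)
  list(genes = genes, tss = tss)
}
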