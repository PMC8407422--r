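test_that("RPF counting excludes the first and last five codons", {
  # 100-codon gene at [300, 600) on the plus strand; offset 17
  genes <- gene_row("g1", 300, 600)
  L <- 1000L
  # one read whose A-site falls in codon 3 -> excluded
  tr <- track_from_positions(plus_pos = 300 + 2 * 3 - 17, L = L)
  expect_equal(unname(count_reads_per_gene(tr, genes, "RPF")), 0)
  # one read per codon 1..100 -> 90 counted
  asites <- 300 + 3 * (0:99)
  tr <- track_from_positions(plus_pos = asites - 17, L = L)
  expect_equal(unname(count_reads_per_gene(tr, genes, "RPF")), 90)
  # minus-strand mirror image
  genes_m <- gene_row("g1", 300, 600, strand = "-")
  asites_m <- 599 - 3 * (0:99)
  tr_m <- track_from_positions(minus_pos = asites_m + 17, L = L)
  expect_equal(unname(count_reads_per_gene(tr_m, genes_m, "RPF")), 90)
})

test_that("RNA counting uses half-open gene bodies on the coding strand", {
  genes <- gene_row("g1", 300, 600)
  expect_equal(unname(count_reads_per_gene(
    track_from_positions(plus_pos = 300), genes, "RNA")), 1)
  expect_equal(unname(count_reads_per_gene(
    track_from_positions(plus_pos = 600), genes, "RNA")), 0)
  expect_equal(unname(count_reads_per_gene(
    track_from_positions(minus_pos = 300), genes, "RNA")), 0)
  expect_error(count_reads_per_gene(track_from_positions(L = 500), genes, "RNA"),
               "bounds")
  short <- gene_row("tiny", 0, 30)
  expect_warning(cnt <- count_reads_per_gene(
    track_from_positions(plus_pos = 10, L = 100), short, "RPF"), "11 codons")
  expect_equal(unname(cnt), 0)
})

test_that("RPKM equals the closed-form definition and its invariances", {
  counts <- matrix(c(10, 0, 50), ncol = 1, dimnames = list(c("a", "b", "c"), "s1"))
  lens <- c(a = 1000, b = 200, c = 500)
  r <- compute_rpkm(counts, lens, totals = 1e6)
  expect_equal(unname(r["a", 1]), 10)
  expect_equal(unname(r["b", 1]), 0)
  r2 <- compute_rpkm(matrix(c(50), 1, 1, dimnames = list("c", "s1")),
                     c(c = 500), totals = 2e6)
  expect_equal(unname(r2[1, 1]), 50)
  # duplicating every read leaves RPKM unchanged
  cc <- matrix(rpois(30, 40), 10, 3, dimnames = list(sprintf("g%d", 1:10), NULL))
  ll <- stats::setNames(sample(200:2000, 10), rownames(cc))
  expect_equal(compute_rpkm(2 * cc, ll, totals = 2 * colSums(cc)),
               compute_rpkm(cc, ll, totals = colSums(cc)),
               ignore_attr = TRUE)
  expect_error(compute_rpkm(matrix(0, 2, 1, dimnames = list(c("x", "y"), "bad")),
                            c(x = 10, y = 10)), "bad")
})

test_that("size factors recover scalar multiples and match DESeq2", {
  base <- matrix(rpois(100, 60), 50, 2, dimnames = list(sprintf("g%d", 1:50), c("A", "B")))
  base[, 2] <- base[, 1]
  f <- size_factors(base)
  expect_equal(unname(f), c(1, 1))
  m <- cbind(A = base[, 1], B = 2 * base[, 1])
  f2 <- size_factors(m)
  expect_equal(unname(f2["B"] / f2["A"]), 2)

  set.seed(42)
  rnd <- matrix(rnbinom(200, mu = 80, size = 5), 50, 4,
                dimnames = list(sprintf("g%d", 1:50), sprintf("s%d", 1:4)))
  mine <- size_factors(rnd)
  # direct median-of-ratios formula, coded independently
  gm <- apply(rnd, 1, function(x) if (all(x > 0)) exp(mean(log(x))) else NA)
  oracle <- apply(rnd, 2, function(col) stats::median(col / gm, na.rm = TRUE))
  oracle <- oracle / exp(mean(log(oracle)))
  # the implementation interpolates even-count medians on the log scale
  # (DESeq2 convention); the linear-median oracle agrees to that tie rule
  expect_equal(mine, oracle, tolerance = 1e-3)
  if (requireNamespace("DESeq2", quietly = TRUE)) {
    ds <- DESeq2::estimateSizeFactorsForMatrix(rnd)
    ds <- ds / exp(mean(log(ds)))
    expect_equal(unname(mine), unname(ds), tolerance = 1e-8)
  }
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2, 2)), "nonzero")
})

test_that("differential expression: null, planted fold change, thresholds", {
  m <- matrix(rep(c(40, 40, 40, 40), each = 20), 20, 4,
              dimnames = list(sprintf("g%d", 1:20), NULL))
  de <- differential_expression(m, c("h", "h", "a", "a"))
  expect_true(all(de$log2FC == 0))
  expect_false(any(de$significant))
  expect_equal(de$p_adj, stats::p.adjust(de$p, "BH"))

  # one gene planted at a true 8-fold change among stable genes, deep
  # coverage: estimated log2 FC within +/- 0.3 of 3, and flagged
  set.seed(7)
  mu <- stats::runif(100, 500, 5000)
  tab <- cbind(rpois(100, mu), rpois(100, mu), rpois(100, mu), rpois(100, mu))
  tab[1, 3:4] <- rpois(2, 8 * mu[1])
  rownames(tab) <- sprintf("g%d", 1:100)
  de2 <- differential_expression(tab, c("h", "h", "a", "a"))
  expect_lt(abs(de2$log2FC[1] - 3), 0.3)
  expect_true(de2$significant[1])
  expect_error(differential_expression(m[, 1, drop = FALSE], "h"), "2 samples")
  expect_error(differential_expression(m, c("a", "b", "c", "c")), "two conditions")
})

test_that("significance flag is monotone in |log2FC| at fixed p", {
  # the flag rule itself: p_adj fixed below alpha, increasing |lfc| can
  # only turn on, never off
  de <- data.frame(p_adj = 0.001, log2FC = seq(0, 3, by = 0.25))
  flag <- de$p_adj < 0.01 & abs(de$log2FC) > 1
  expect_true(all(diff(flag) >= 0))
})
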