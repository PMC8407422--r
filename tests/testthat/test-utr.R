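test_that("A-site shifting is strand-aware, conservative and reversible", {
  L <- 3000L
  tr <- track_from_positions(plus_pos = 1000, minus_pos = 2000, L = L)
  a <- asite_track(tr, 17)
  expect_equal(which(a$plus > 0) - 1, 1017)
  expect_equal(which(a$minus > 0) - 1, 1983)
  expect_equal(track_total(a), track_total(tr))
  expect_equal(attr(a, "dropped"), 0)
  # reverse shift restores the original (up to dropped edge reads)
  back <- fp_track(a$minus, a$plus)          # swap strands to reuse the shift
  restored <- asite_track(back, 17)
  expect_equal(fp_track(restored$minus, restored$plus), tr, ignore_attr = TRUE)
  # reads shifted off the contig are dropped and logged
  edge <- track_from_positions(plus_pos = L - 5, minus_pos = 3, L = L)
  ae <- asite_track(edge, 17)
  expect_equal(track_total(ae), 0)
  expect_equal(attr(ae, "dropped"), 2)
})

test_that("metagene profiles: flat RNA input and empty annotation error", {
  genes <- rbind(gene_row("a", 100, 400), gene_row("b", 600, 1200, strand = "-"))
  flat <- fp_track(rep(2, 1500), rep(2, 1500))
  mg <- metagene(flat, genes)
  expect_true(all(abs(mg$start_profile - 1) < 1e-12))
  expect_equal(unname(mg$frame_fractions), rep(1 / 3, 3))
  expect_error(metagene(flat, genes[0, ]), "empty annotation")
})

test_that("UTR occupancy densities and ratios are as constructed", {
  genes <- gene_row("g1", 100, 400)
  utrs <- data.frame(gene_id = "g1", tss_pos = 60, strand = "+", length = 40,
                     sequence = strrep("A", 40), leaderless = FALSE,
                     stringsAsFactors = FALSE)
  L <- 600L
  rna <- fp_track(rep(10, L), numeric(L))     # uniform density 10
  rpf <- fp_track(c(rep(5, 100), rep(20, 500)), numeric(L))
  occ <- utr_occupancy(rpf, rna, utrs, genes)
  rec <- occ$records
  expect_equal(rec$utr_ratio, 0.5)       # 5/10
  expect_equal(rec$cds_ratio, 2)         # 20/10
  expect_equal(occ$median_ratio_of_ratios, 0.25)
  ident <- utr_occupancy(rna, rna, utrs, genes)
  expect_equal(ident$records$utr_ratio, 1)
  expect_equal(ident$records$cds_ratio, 1)
  expect_equal(ident$wilcoxon_p, 1)
  expect_error(utr_occupancy(rpf, rna, utrs[0, ], genes), "qualifying")
})

test_that("planted condition difference in UTR occupancy is recovered", {
  cfg <- tiny_config(n_genes = 20L, mean_operon_size = 1, library_depth = 2e5,
                     utr_median = 60, dispersion = 0.05, seed = 19L)
  g <- generate_genome(cfg)
  utrs <- data.frame(gene_id = g$truth$tss$gene_id,
                     length = g$truth$tss$utr_length, stringsAsFactors = FALSE)
  ratio <- sapply(1:2, function(cc) {
    rpf <- asite_track(simulate_riboseq(g, cc, cfg)[[1]], cfg$asite_offset)
    rna <- simulate_rnaseq(g, cc, cfg)[[1]]
    utr_occupancy(rpf, rna, utrs, g$genes)$median_ratio_of_ratios
  })
  # planted per-condition UTR/CDS relative densities 0.48 and 1.38
  expect_lt(abs(ratio[2] / ratio[1] - 1.38 / 0.48), 0.2 * 1.38 / 0.48)
  expect_lt(abs(ratio[1] - 0.48), 0.15)
  expect_lt(abs(ratio[2] - 1.38), 0.35)
})

test_that("Nussinov engine: hand cases and enumeration oracle", {
  expect_equal(fold_mfe("ACGU")$energy, 0)
  f <- fold_mfe("GGGAAAACCC")
  expect_equal(nrow(f$pairs), 3)
  expect_equal(f$energy, -3)
  expect_error(fold_mfe("ACGX"), "invalid")
  set.seed(6)
  for (i in 1:100) {
    n <- sample(1:12, 1)
    s <- paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
    f <- fold_mfe(s)
    expect_equal(nrow(f$pairs), enumerate_max_pairs(s), info = s)
    # pairs nested and non-crossing with hairpin >= 3
    if (nrow(f$pairs) > 1) {
      for (a in seq_len(nrow(f$pairs) - 1)) for (bb in (a + 1):nrow(f$pairs)) {
        p <- f$pairs[a, ]; q <- f$pairs[bb, ]
        crossing <- (p[1] < q[1] && q[1] < p[2] && p[2] < q[2]) ||
          (q[1] < p[1] && p[1] < q[2] && q[2] < p[2])
        expect_false(crossing)
      }
    }
    if (nrow(f$pairs) > 0) expect_true(all(f$pairs[, 2] - f$pairs[, 1] >= 4))
  }
})

test_that("pair count does not decrease when complementary flanks are added", {
  set.seed(7)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "U"), sample(5:15, 1), TRUE), collapse = "")
    inner <- nrow(fold_mfe(s)$pairs)
    outer <- nrow(fold_mfe(paste0("GGG", s, "CCC"))$pairs)
    expect_gte(outer, inner)
  }
})

test_that("external folding engine plugs in (RNAfold when available)", {
  eng <- rnafold_engine()
  if (is.null(eng)) {
    # pluggable interface still works with a user-supplied function
    eng <- function(seq) list(energy = -1.5, structure = strrep(".", nchar(seq)))
  }
  f <- fold_mfe("GGGGAAAACCCC", engine = eng)
  expect_equal(f$engine, "external")
  expect_true(is.numeric(f$energy))
  expect_lte(f$energy, 0)
})

test_that("structured UTRs show the planted TE shift; degenerate splits error", {
  set.seed(8)
  n <- 200
  energies <- stats::setNames(runif(n, -60, 0), sprintf("g%d", 1:n))
  te <- stats::setNames(rnorm(n, 0, 0.8), names(energies))
  te[energies < -30] <- te[energies < -30] - 1   # planted: structure lowers TE
  res <- te_by_mfe(energies, te, threshold = -30)
  expect_lt(res$p, 0.05)
  expect_lt(res$median_difference, 0)
  # identical distributions: median difference near zero, not significant
  te0 <- stats::setNames(rnorm(n, 0, 0.8), names(energies))
  res0 <- te_by_mfe(energies, te0)   # median split
  expect_lt(abs(res0$median_difference), 0.4)
  expect_error(te_by_mfe(energies, te, threshold = -100), "at least 3")
})

test_that("SD scoring: canonical motif, null sequence, planted cohorts", {
  utr_sd <- paste0(strrep("C", 20), "AGGAGG", strrep("C", 8))  # motif at -14..-9
  expect_equal(unname(sd_score(c(x = utr_sd))$scores), 6)
  expect_equal(unname(sd_score(c(x = strrep("C", 30)))$scores), 0)
  short <- sd_score(c(x = "ACG"))
  expect_true(short$flagged)

  set.seed(9)
  rand_utr <- function() paste(sample(c("A", "C", "G", "U"), 30, TRUE), collapse = "")
  high <- vapply(1:40, function(i) {
    s <- strsplit(rand_utr(), "")[[1]]
    s[17:22] <- strsplit("AGGAGG", "")[[1]]  # -14..-9 relative to start
    paste(s, collapse = "")
  }, character(1))
  low <- vapply(1:40, function(i) rand_utr(), character(1))
  sh <- sd_score(high)
  sl <- sd_score(low)
  expect_gt(mean(sh$scores) - mean(sl$scores), 2)
  # SD columns are more informative in the seeded cohort
  sd_cols <- as.character(-14:-9)
  expect_gt(mean(sh$information[sd_cols]), mean(sl$information[sd_cols]) + 0.5)
})
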