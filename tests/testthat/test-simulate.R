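test_that("RNA-Seq counts are proportional to abundance x length", {
  cfg <- tiny_config(n_genes = 12L, mean_operon_size = 1, dispersion = 0,
                     library_depth = 2e5, utr_median = 20, seed = 5L)
  g <- generate_genome(cfg)
  # equalize all planted abundances; Poisson noise only
  g$truth$mrna[, ] <- 1
  tr <- simulate_rnaseq(g, 1, cfg)[[1]]
  units <- ribotrans:::transcription_units(g)
  cnt <- count_reads_per_gene(tr, g$genes, "RNA")
  # per-nt density over the gene body should be flat across genes:
  # expected density = depth / total transcript length, 3-SE Poisson bound
  dens <- cnt / g$genes$length
  expected <- cfg$library_depth / sum(units$tx_length)
  se <- 3 * sqrt(expected * g$genes$length) / g$genes$length
  expect_true(all(abs(dens - expected) <= se))
})

test_that("a zero-abundance transcription unit yields zero reads", {
  cfg <- tiny_config(n_genes = 10L, mean_operon_size = 1, seed = 6L)
  g <- generate_genome(cfg)
  g$truth$mrna[3, ] <- 0
  tr <- simulate_rnaseq(g, 1, cfg)[[1]]
  cnt <- count_reads_per_gene(tr, g$genes, "RNA")
  expect_equal(unname(cnt[3]), 0)
  expect_gt(sum(cnt), 0)
  cfg0 <- cfg
  cfg0$library_depth <- 0
  expect_error(simulate_rnaseq(g, 1, cfg0), "library_depth")
})

test_that("doubling library depth doubles mean counts (Monte-Carlo)", {
  cfg1 <- tiny_config(genome_length = 20000L, n_genes = 6L, dispersion = 0,
                      library_depth = 2000, replicates_per_condition = 1, seed = 1L)
  g <- generate_genome(cfg1)
  totals <- function(depth, seeds) {
    vapply(seeds, function(s) {
      cfg <- cfg1
      cfg$library_depth <- depth
      cfg$seed <- s
      sum(count_reads_per_gene(simulate_rnaseq(g, 1, cfg)[[1]], g$genes, "RNA"))
    }, numeric(1))
  }
  m1 <- mean(totals(2000, 1:100))
  m2 <- mean(totals(4000, 101:200))
  # ratio of means, Poisson SEs ~ sqrt(mu/n): generous 4-SE band
  expect_lt(abs(m2 / m1 - 2), 0.05)
})

test_that("Ribo-Seq frame periodicity follows frame0_fraction", {
  cfg <- tiny_config(n_genes = 15L, frame0_fraction = 1, dispersion = 0,
                     library_depth = 1e5, seed = 8L)
  g <- generate_genome(cfg)
  a <- asite_track(simulate_riboseq(g, 1, cfg)[[1]], cfg$asite_offset)
  mg <- metagene(a, g$genes)
  expect_equal(unname(mg$frame_fractions["f0"]), 1)

  cfg3 <- tiny_config(n_genes = 15L, frame0_fraction = 1 / 3, dispersion = 0,
                      library_depth = 1e5, seed = 8L)
  a3 <- asite_track(simulate_riboseq(g, 1, cfg3)[[1]], cfg3$asite_offset)
  f <- metagene(a3, g$genes)$frame_fractions
  # binomial 3-sigma bound at n ~ 1e5 in-ORF A-sites
  expect_true(all(abs(f - 1 / 3) < 3 * sqrt((1 / 3) * (2 / 3) / 5e4)))

  bad <- cfg
  bad$frame0_fraction <- 0.2
  expect_error(simulate_riboseq(g, 1, bad), "frame0")
})

test_that("doubling one gene's TE doubles its expected footprint density", {
  cfg <- tiny_config(n_genes = 8L, mean_operon_size = 1, seed = 9L)
  g <- generate_genome(cfg)
  base <- simulate_riboseq(g, 1, cfg, noise = FALSE)[[1]]
  g2 <- g
  g2$truth$te[2, ] <- g2$truth$te[2, ] * 2
  doubled <- simulate_riboseq(g2, 1, cfg, noise = FALSE)[[1]]
  c1 <- count_reads_per_gene(base, g$genes, "RPF")
  c2 <- count_reads_per_gene(doubled, g$genes, "RPF")
  # normalize by a reference gene to remove the library-size renormalization
  expect_equal((c2[2] / c2[5]) / (c1[2] / c1[5]), c(g0002 = 2), tolerance = 1e-9)
})

test_that("dRNA-Seq enrichment structure is as planted", {
  cfg <- tiny_config(n_genes = 10L, mean_operon_size = 1, seed = 10L)
  g <- generate_genome(cfg)
  pair <- simulate_drnaseq(g, 1, cfg, noise = FALSE)
  tss <- g$truth$tss
  for (i in seq_len(nrow(tss))) {
    v_plus <- if (tss$strand[i] == "+") pair$rpp_plus$plus else pair$rpp_plus$minus
    v_minus <- if (tss$strand[i] == "+") pair$rpp_minus$plus else pair$rpp_minus$minus
    expect_equal(v_plus[tss$pos[i] + 1] / v_minus[tss$pos[i] + 1],
                 cfg$tss_enrichment, tolerance = 1e-12)
    # noise-free argmax of the local ratio sits exactly at the planted TSS
    win <- (tss$pos[i] - 10):(tss$pos[i] + 10) + 1
    expect_equal(win[which.max(v_plus[win] / v_minus[win])] - 1, tss$pos[i])
  }
  # background positions have ratio 1 in expectation
  bgpos <- 3  # upstream margin, no gene or TSS there
  expect_equal(pair$rpp_plus$plus[bgpos] / pair$rpp_minus$plus[bgpos], 1)
  bad <- cfg
  bad$tss_enrichment <- 1
  expect_error(simulate_drnaseq(g, 1, bad), "tss_enrichment")
})

test_that("simulators are deterministic under a fixed seed", {
  cfg <- tiny_config(seed = 77L)
  g <- generate_genome(cfg)
  r1 <- simulate_rnaseq(g, 1, cfg)
  r2 <- simulate_rnaseq(g, 1, cfg)
  expect_identical(r1, r2)
  b1 <- simulate_riboseq(g, 2, cfg)
  b2 <- simulate_riboseq(g, 2, cfg)
  expect_identical(b1, b2)
  d1 <- simulate_drnaseq(g, 1, cfg)
  d2 <- simulate_drnaseq(g, 1, cfg)
  expect_identical(d1, d2)
  # replicates and conditions use distinct child streams
  expect_false(identical(r1[[1]], r1[[2]]))
  expect_false(identical(simulate_rnaseq(g, 1, cfg)[[1]],
                         simulate_rnaseq(g, 2, cfg)[[1]]))
})
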