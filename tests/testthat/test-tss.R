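test_that("track pairs normalize to equal counts-per-million totals", {
  set.seed(11)
  a <- fp_track(rpois(500, 2), rpois(500, 2))
  b <- fp_track(rpois(500, 4), rpois(500, 4))
  nt <- normalize_tracks(a, b)
  expect_equal(track_total(nt$rpp_plus), 1e6)
  expect_equal(track_total(nt$rpp_minus), 1e6)
  # double-depth library gets half the factor
  expect_equal(unname(nt$factors["rpp_plus"] / nt$factors["rpp_minus"]),
               track_total(b) / track_total(a))
  same <- normalize_tracks(a, a)
  expect_equal(unname(diff(same$factors)), 0)
  expect_error(normalize_tracks(a, fp_track(numeric(500), numeric(500))), "empty")
})

test_that("candidate calling applies ratio and density rules", {
  L <- 200L
  p <- numeric(L)
  m <- numeric(L)
  p[51] <- 10; m[51] <- 4    # ratio 10.5/4.5 = 2.33 -> candidate
  p[101] <- 4; m[101] <- 4   # ratio < 2 -> rejected
  p[151] <- 40; m[151] <- 1  # candidate
  cand <- call_tss(fp_track(p, numeric(L)), fp_track(m, numeric(L)))
  expect_equal(cand$pos, c(50, 150))
  expect_equal(cand$enrichment_ratio[1], 10.5 / 4.5)
  # density floor
  p2 <- numeric(L); p2[51] <- 8
  expect_equal(nrow(call_tss(fp_track(p2, numeric(L)),
                             fp_track(numeric(L), numeric(L)))), 0)
  expect_error(call_tss(fp_track(p, numeric(L)), fp_track(m, numeric(L)),
                        min_ratio = 1), "min_ratio")
  # only the local maximum within +/-4 nt survives
  p3 <- numeric(L); p3[100] <- 50; p3[103] <- 30
  cand3 <- call_tss(fp_track(p3, numeric(L)), fp_track(numeric(L), numeric(L)))
  expect_equal(cand3$pos, 99)
})

test_that("merging collapses within 4 nt, is idempotent, keeps separation", {
  mk <- function(pos, dens = 10, strand = "+", lib = "l1") {
    data.frame(pos = pos, strand = strand, enrichment_ratio = 5,
               peak_density = dens, libraries = lib, stringsAsFactors = FALSE)
  }
  m1 <- merge_tss(list(mk(100, 10, lib = "l1"), mk(103, 20, lib = "l2")))
  expect_equal(nrow(m1), 1)
  expect_equal(m1$pos, 103)             # highest density wins
  expect_equal(m1$peak_density, 30)     # densities summed
  expect_equal(m1$libraries, "l1,l2")
  m2 <- merge_tss(list(mk(100), mk(106)))
  expect_equal(nrow(m2), 2)
  expect_equal(nrow(merge_tss(list())), 0)

  set.seed(21)
  for (i in 1:50) {
    cand <- do.call(rbind, lapply(1:3, function(l) {
      mk(sort(sample(0:300, 20)), dens = stats::runif(20, 1, 50),
         strand = sample(c("+", "-"), 1), lib = sprintf("l%d", l))
    }))
    once <- merge_tss(cand)
    twice <- merge_tss(once)
    expect_equal(twice$pos, once$pos)
    expect_equal(twice$peak_density, once$peak_density)
    for (st in unique(once$strand)) {
      pos <- sort(once$pos[once$strand == st])
      if (length(pos) > 1) expect_true(all(diff(pos) > 4))
    }
  }
})

test_that("TSS categorization follows the positional rules", {
  genes <- gene_row("g1", 1000, 1600)
  tss <- data.frame(pos = c(750, 950, 1050, 1300, 2500, 1200),
                    strand = c("+", "+", "+", "+", "+", "-"),
                    enrichment_ratio = 5,
                    peak_density = c(50, 30, 20, 10, 10, 10),
                    libraries = "l1", stringsAsFactors = FALSE)
  out <- categorize_tss(tss, genes)
  expect_equal(out$category, c("P", "S", "S", "I", "N", "A"))
  expect_equal(out$associated_gene[c(1, 2, 4, 6)], rep("g1", 4))
})

test_that("categorization matches an independent rule oracle on random layouts", {
  set.seed(31)
  seen <- character(0)
  for (rep in 1:100) {
    lay <- random_layout()
    got <- categorize_tss(lay$tss, lay$genes)$category
    want <- categorize_oracle(lay$tss, lay$genes)
    expect_equal(got, want)
    seen <- union(seen, got)
  }
  expect_setequal(seen, c("P", "S", "I", "A", "N"))
})

test_that("UTR assignment is strand-aware and flags leaderless starts", {
  genes <- rbind(gene_row("gp", 200, 500), gene_row("gm", 700, 1000, strand = "-"))
  genome <- paste(rep("A", 1200), collapse = "")
  tss <- data.frame(pos = c(150, 200, 1049), strand = c("+", "+", "-"),
                    enrichment_ratio = 5, peak_density = c(10, 5, 8),
                    libraries = "l1",
                    category = c("P", "P", "P"),
                    associated_gene = c("gp", "gp", "gm"),
                    stringsAsFactors = FALSE)
  utr <- assign_utr(tss, genes, genome)
  expect_equal(utr$length, c(50, 0, 50))
  expect_equal(utr$leaderless, c(FALSE, TRUE, FALSE))
  expect_equal(nchar(utr$sequence), utr$length)
  expect_true(all(strsplit(utr$sequence[3], "")[[1]] == "U"))  # revcomp of poly-A
  tss_bad <- tss[1, ]
  tss_bad$pos <- 300  # downstream of the start codon
  expect_warning(out <- assign_utr(tss_bad, genes, genome), "skipped")
  expect_equal(nrow(out), 0)
})

test_that("promoter extraction reports planted boxes and matches enumeration", {
  g <- generate_genome(tiny_config(seed = 41L))
  tss <- g$truth$tss
  prom <- extract_promoters(tss, g)
  expect_true(all(nchar(prom$sequences) == 50))
  # every planted TSS carries TATAAT with its 3' end 7 nt upstream
  m10 <- prom$hits[prom$hits$motif == "minus10" & prom$hits$mismatches == 0, ]
  for (i in seq_len(nrow(tss))) {
    expect_true(any(m10$tss_pos == tss$pos[i] & m10$offset == -12))
  }
  # minus-strand promoter sequence is the reverse complement of the genome slice
  mi <- which(tss$strand == "-")[1]
  slice <- substr(g$sequence, tss$pos[mi] + 2, tss$pos[mi] + 51)
  expect_identical(unname(prom$sequences[paste0(tss$pos[mi], ":-")]),
                   ribotrans:::revcomp(slice))

  # random-sequence scan equals windowed mismatch enumeration done by hand
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  got <- ribotrans:::motif_scan(s, "TATAAT", 1)
  want <- Filter(Negate(is.null), lapply(1:45, function(j) {
    mm <- sum(strsplit(substr(s, j, j + 5), "")[[1]] != strsplit("TATAAT", "")[[1]])
    if (mm <= 1) c(j, mm) else NULL
  }))
  expect_equal(got$window, vapply(want, `[`, numeric(1), 1))
  expect_equal(got$mismatches, as.integer(vapply(want, `[`, numeric(1), 2)))
})
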