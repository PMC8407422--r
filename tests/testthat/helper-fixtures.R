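# Shared fixtures: all test data are generated in code.

# Small, fast simulation configuration for unit tests.
tiny_config <- function(...) {
  args <- list(genome_length = 60000L, n_genes = 30L, library_depth = 5e4,
               seed = 101L)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# A track with single 5'-end counts at given 0-based positions.
track_from_positions <- function(plus_pos = integer(0), minus_pos = integer(0),
                                 L = 1000L, counts_plus = 1, counts_minus = 1) {
  plus <- numeric(L)
  minus <- numeric(L)
  for (i in seq_along(plus_pos)) plus[plus_pos[i] + 1] <- plus[plus_pos[i] + 1] + counts_plus
  for (i in seq_along(minus_pos)) minus[minus_pos[i] + 1] <- minus[minus_pos[i] + 1] + counts_minus
  fp_track(plus, minus)
}

# Minimal gene annotation rows.
gene_row <- function(id, start, end, strand = "+", operon = id, pos = 1L,
                     copy = 1L) {
  data.frame(gene_id = id, start = as.integer(start), end = as.integer(end),
             strand = strand, length = as.integer(end - start),
             n_codons = as.integer((end - start) %/% 3),
             operon_id = operon, operon_pos = as.integer(pos),
             complex_id = NA_character_, copy_number = as.integer(copy),
             stringsAsFactors = FALSE)
}

# Condition-mean RPKM matrices from simulated tracks.
condition_mean_rpkm <- function(sim, rna, ribo) {
  conds <- rep(sprintf("cond%d", seq_along(rna)),
               each = length(rna[[1]]))
  tr <- unlist(rna, recursive = FALSE)
  tp <- unlist(ribo, recursive = FALSE)
  names(tr) <- vapply(tr, function(t) t$library, character(1))
  names(tp) <- vapply(tp, function(t) t$library, character(1))
  lens <- stats::setNames(sim$genes$length, sim$genes$gene_id)
  ct_rna <- count_table(tr, sim$genes, conds, "RNA")
  ct_rpf <- count_table(tp, sim$genes, conds, "RPF",
                        asite_offset = sim$config$asite_offset)
  rk_rna <- compute_rpkm(ct_rna, lens)
  rk_rpf <- compute_rpkm(ct_rpf, lens)
  list(
    rna = vapply(unique(conds), function(cc) {
      rowMeans(rk_rna[, conds == cc, drop = FALSE])
    }, numeric(nrow(sim$genes))),
    rpf = vapply(unique(conds), function(cc) {
      rowMeans(rk_rpf[, conds == cc, drop = FALSE])
    }, numeric(nrow(sim$genes)))
  )
}

# Balanced accuracy of an estimated class factor against truth labels.
balanced_accuracy <- function(truth, est) {
  lev <- c("high", "neutral", "low")
  tab <- table(factor(truth, lev), factor(as.character(est), lev))
  mean(diag(tab) / rowSums(tab), na.rm = TRUE)
}

# TSS sensitivity/precision of called positions against planted truth.
tss_recovery <- function(called, truth_tss) {
  truekey <- paste(truth_tss$pos, truth_tss$strand)
  callkey <- paste(called$pos, called$strand)
  tp <- sum(callkey %in% truekey)
  c(sensitivity = tp / length(truekey), precision = tp / max(1, length(callkey)))
}
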