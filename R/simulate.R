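#' Simulate RNA-Seq 5'-end tracks
#'
#' Generates one [fp_track()] per replicate for one condition. Each
#' transcription unit receives an expected read count proportional to its
#' planted mRNA abundance times its transcript length; replicate counts
#' are drawn negative-binomially with the configured dispersion
#' (`dispersion = 0` gives Poisson), and read 5' ends are placed uniformly
#' along the transcript, emulating fragmentation of the full transcript.
#'
#' @param sim A [generate_genome()] result (or a list with the same
#'   `genes`, `truth`, `genome_length` fields).
#' @param condition Condition index (column of `truth$mrna`).
#' @param config A [sim_config()]; defaults to the one stored in `sim`.
#' @param noise If `FALSE`, return a single track holding the expected
#'   (real-valued) per-position densities instead of sampled counts.
#' @return A list of `fp_track` objects (length `replicates_per_condition`),
#'   or a one-element list when `noise = FALSE`.
#' @export
simulate_rnaseq <- function(sim, condition = 1L, config = sim$config, noise = TRUE) {
  units <- transcription_units(sim)
  if (config$library_depth <= 0) stop2("library_depth must be positive")
  L <- sim$genome_length
  ab <- unit_abundance(sim, condition)
  w <- ab * units$tx_length
  if (nrow(units) > 0 && sum(w) == 0) stop2("no transcription unit has positive abundance")
  lambda <- if (nrow(units) == 0) numeric(0) else config$library_depth * w / sum(w)

  make_one <- function(rep_id, sample_noise) {
    plus <- numeric(L)
    minus <- numeric(L)
    for (i in seq_len(nrow(units))) {
      len <- units$tx_length[i]
      if (sample_noise) {
        k <- rcounts(1, lambda[i], config$dispersion)
        if (k == 0) next
        pos <- units$tx_start[i] + sample.int(len, k, replace = TRUE) - 1L
        if (units$strand[i] == "+") {
          plus <- track_add(plus, pos, L)
        } else {
          minus <- track_add(minus, pos, L)
        }
      } else {
        span <- (units$tx_start[i] + 1):units$tx_end[i]
        if (units$strand[i] == "+") {
          plus[span] <- plus[span] + lambda[i] / len
        } else {
          minus[span] <- minus[span] + lambda[i] / len
        }
      }
    }
    fp_track(plus, minus, library = sprintf("rna_c%d_r%d", condition, rep_id))
  }

  if (!noise) return(list(make_one(1L, FALSE)))
  lapply(seq_len(config$replicates_per_condition), function(r) {
    with_seed(child_seed(config$seed, sprintf("rnaseq/c%d/r%d", condition, r)),
              make_one(r, TRUE))
  })
}

#' Simulate Ribo-Seq (RPF) 5'-end tracks
#'
#' Expected footprint counts per gene are proportional to planted mRNA
#' abundance x TE x CDS length. A-sites are placed uniformly over codons;
#' with probability `frame0_fraction` the A-site falls on the first
#' nucleotide of its codon (frame 0), otherwise on frame 1 or 2 with equal
#' probability. The recorded 5' end sits `asite_offset` nt upstream of the
#' A-site on the coding strand. Leader genes additionally receive 5'-UTR
#' footprints at a per-condition density relative to their CDS density
#' (`utr_rpf_relative`), emulating condition-dependent ribosome occupancy
#' of 5' UTRs.
#'
#' @inheritParams simulate_rnaseq
#' @return A list of `fp_track` objects as in [simulate_rnaseq()].
#' @export
simulate_riboseq <- function(sim, condition = 1L, config = sim$config, noise = TRUE) {
  if (config$frame0_fraction < 1 / 3) stop2("frame0_fraction must be >= 1/3")
  if (config$library_depth <= 0) stop2("library_depth must be positive")
  genes <- sim$genes
  L <- sim$genome_length
  off <- config$asite_offset
  mrna <- sim$truth$mrna[, condition]
  te <- sim$truth$te[, condition]
  rel <- config$utr_rpf_relative[condition]
  utr_len <- sim$truth$utr_length
  utr_len[is.na(utr_len)] <- 0

  w_cds <- mrna * te * genes$length
  w_utr <- mrna * te * rel * utr_len
  tot <- sum(w_cds) + sum(w_utr)
  if (nrow(genes) > 0 && tot == 0) stop2("no gene has positive footprint rate")
  lam_cds <- config$library_depth * w_cds / tot
  lam_utr <- config$library_depth * w_utr / tot
  p_frame <- c(config$frame0_fraction,
               (1 - config$frame0_fraction) / 2,
               (1 - config$frame0_fraction) / 2)

  five_prime <- function(asite, strand) if (strand == "+") asite - off else asite + off

  make_one <- function(rep_id, sample_noise) {
    plus <- numeric(L)
    minus <- numeric(L)
    emit <- function(pos, strand, amount = NULL) {
      if (is.null(amount)) {
        if (strand == "+") plus <<- track_add(plus, pos, L)
        else minus <<- track_add(minus, pos, L)
      } else {
        idx <- (pos %% L) + 1L
        if (strand == "+") plus[idx] <<- plus[idx] + amount
        else minus[idx] <<- minus[idx] + amount
      }
    }
    for (g in seq_len(nrow(genes))) {
      st <- genes$strand[g]
      n_cod <- genes$n_codons[g]
      codon_start <- if (st == "+") {
        genes$start[g] + 3L * (seq_len(n_cod) - 1L)
      } else {
        genes$end[g] - 1L - 3L * (seq_len(n_cod) - 1L)
      }
      dirsign <- if (st == "+") 1L else -1L
      if (sample_noise) {
        k <- rcounts(1, lam_cds[g], config$dispersion)
        if (k > 0) {
          cs <- codon_start[sample.int(n_cod, k, replace = TRUE)]
          fr <- sample.int(3L, k, replace = TRUE, prob = p_frame) - 1L
          emit(five_prime(cs + dirsign * fr, st), st)
        }
      } else if (lam_cds[g] > 0) {
        for (f in 0:2) {
          emit(five_prime(codon_start + dirsign * f, st), st,
               amount = lam_cds[g] * p_frame[f + 1] / n_cod)
        }
      }
      if (lam_utr[g] > 0) {
        ulen <- utr_len[g]
        upos <- if (st == "+") {
          (genes$start[g] - ulen):(genes$start[g] - 1L)
        } else {
          (genes$end[g]):(genes$end[g] + ulen - 1L)
        }
        if (sample_noise) {
          k <- rcounts(1, lam_utr[g], config$dispersion)
          if (k > 0) {
            emit(five_prime(upos[sample.int(ulen, k, replace = TRUE)], st), st)
          }
        } else {
          emit(five_prime(upos, st), st, amount = lam_utr[g] / ulen)
        }
      }
    }
    fp_track(plus, minus, library = sprintf("rpf_c%d_r%d", condition, rep_id))
  }

  if (!noise) return(list(make_one(1L, FALSE)))
  lapply(seq_len(config$replicates_per_condition), function(r) {
    with_seed(child_seed(config$seed, sprintf("riboseq/c%d/r%d", condition, r)),
              make_one(r, TRUE))
  })
}

#' Simulate a paired dRNA-Seq library (RPP+ / RPP-)
#'
#' The untreated (RPP-) library places `tss_fraction` of its expected mass
#' at the planted TSS positions (split evenly) and the remainder as a
#' uniform background of processed 5' ends over both strands of the whole
#' genome. The pyrophosphatase-treated (RPP+) library has the same
#' expected background but `tss_enrichment` times the RPP- expected
#' density at every true TSS, so the raw expected RPP+/RPP- ratio at a TSS
#' equals `tss_enrichment` exactly and is 1 elsewhere.
#'
#' @inheritParams simulate_rnaseq
#' @return A list with elements `rpp_plus` and `rpp_minus`, both
#'   [fp_track()] objects.
#' @export
simulate_drnaseq <- function(sim, condition = 1L, config = sim$config, noise = TRUE) {
  if (config$tss_enrichment <= 1) stop2("tss_enrichment must exceed 1 (no signal)")
  if (config$library_depth <= 0) stop2("library_depth must be positive")
  tss <- sim$truth$tss
  if (nrow(tss) == 0) stop2("no planted TSS positions to simulate")
  L <- sim$genome_length
  D <- config$library_depth
  bg <- (1 - config$tss_fraction) * D / (2 * L)
  peak <- config$tss_fraction * D / nrow(tss)
  mu_minus_tss <- bg + peak
  mu_plus_tss <- config$tss_enrichment * mu_minus_tss

  build <- function(mu_tss, lib) {
    if (noise) {
      plus <- rcounts(L, bg, config$dispersion)
      minus <- rcounts(L, bg, config$dispersion)
    } else {
      plus <- rep(bg, L)
      minus <- rep(bg, L)
    }
    for (i in seq_len(nrow(tss))) {
      idx <- tss$pos[i] + 1L
      val <- if (noise) rcounts(1, mu_tss, config$dispersion) else mu_tss
      if (tss$strand[i] == "+") plus[idx] <- val else minus[idx] <- val
    }
    fp_track(plus, minus, library = lib)
  }

  run <- function() {
    list(rpp_plus = build(mu_plus_tss, sprintf("drna_rppplus_c%d", condition)),
         rpp_minus = build(mu_minus_tss, sprintf("drna_rppminus_c%d", condition)))
  }
  if (!noise) return(run())
  with_seed(child_seed(config$seed, sprintf("drnaseq/c%d", condition)), run())
}

#' Simulate a full multi-library experiment
#'
#' Convenience wrapper: generates the genome and, for every condition, the
#' RNA-Seq and Ribo-Seq replicate tracks plus one dRNA-Seq RPP+/RPP- pair.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genome` (the [generate_genome()] result),
#'   `rna`, `ribo` (lists of per-condition replicate track lists) and
#'   `drna` (list of per-condition RPP pairs).
#' @export
simulate_experiment <- function(config) {
  genome <- generate_genome(config)
  conds <- seq_len(config$n_conditions)
  list(
    genome = genome,
    rna = lapply(conds, function(cc) simulate_rnaseq(genome, cc, config)),
    ribo = lapply(conds, function(cc) simulate_riboseq(genome, cc, config)),
    drna = lapply(conds, function(cc) simulate_drnaseq(genome, cc, config))
  )
}

unit_abundance <- function(sim, condition) {
  units <- transcription_units(sim)
  if (nrow(units) == 0) return(numeric(0))
  leader <- match(units$gene_id, rownames(sim$truth$mrna))
  sim$truth$mrna[leader, condition]
}
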