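#' Generate a synthetic annotated genome with planted ground truth
#'
#' Builds a circular genome carrying non-overlapping protein-coding genes
#' organized into operons of 1-10 genes on both strands. Each operon is a
#' transcription unit with one planted primary TSS upstream of its first
#' gene; the 5'-UTR length (TSS to start codon) follows a geometric law
#' with configurable median. Sigma-70 style promoter hexamers (TATAAT at
#' -10, TTGACA at -35 relative to the TSS) are written into the upstream
#' sequence, and a Shine-Dalgarno hexamer is planted upstream of start
#' codons of genes in the high-TE class. The returned truth records the
#' planted per-gene mRNA abundances, translation efficiencies, TE
#' fold-change classes, TSS positions, UTR lengths and complex subunit
#' copy numbers used by the read simulators and by recovery tests.
#'
#' All coordinates are internal 0-based half-open; gene `length = end -
#' start` is divisible by 3 and includes the stop codon. Gene placement
#' avoids wrapping the replication origin.
#'
#' @param config A [sim_config()].
#' @return An object of class `synthetic_genome`: a list with elements
#'   `sequence` (character scalar), `genome_length`, `circular`, `genes`
#'   (data frame), `truth` (list; see Details) and `config`.
#' @details `truth` holds `mrna` and `te` (gene x condition matrices of
#'   arbitrary-unit abundances), `log2_mrna_change` and `log2_te_change`
#'   (condition 2 vs 1, per gene), `te_class` (high/neutral/low per the
#'   planted threshold `te_mean +/- te_sd`), `tss` (planted TSS table),
#'   `utr_length` (per gene; NA for non-leader genes) and `complexes`
#'   (subunit copy-number table). The truth list is a plain, documented
#'   structure: tests and users may modify its fields (e.g. to impose a
#'   specific TE or copy-number pattern) before passing it to the
#'   simulators.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  L <- config$genome_length

  if (config$n_genes == 0) {
    seq <- with_seed(child_seed(config$seed, "genome"), random_dna(L))
    return(new_synthetic_genome(seq, empty_genes(), empty_truth(config), config))
  }

  with_seed(child_seed(config$seed, "genome"), {
    n <- config$n_genes

    # --- operon structure -------------------------------------------------
    sizes <- integer(0)
    while (sum(sizes) < n) {
      s <- 1L + stats::rpois(1, max(config$mean_operon_size - 1, 0))
      s <- min(s, config$max_operon_size, n - sum(sizes))
      sizes <- c(sizes, s)
    }
    n_op <- length(sizes)
    op_of_gene <- rep(seq_len(n_op), sizes)
    op_pos <- sequence(sizes)

    n_codons <- config$codon_range[1] +
      sample.int(config$codon_range[2] - config$codon_range[1] + 1L, n,
                 replace = TRUE) - 1L
    cds_len <- 3L * n_codons
    strand_op <- sample(c("+", "-"), n_op, replace = TRUE)
    p_geom <- 1 - 2^(-1 / (config$utr_median + 0.5))
    utr_op <- stats::rgeom(n_op, p_geom)

    # --- linear layout (promoter margin upstream of every TSS) ------------
    promoter_margin <- 60L
    start <- integer(n)
    end <- integer(n)
    strand <- character(n)
    tss_pos <- integer(n_op)
    cursor <- 50L
    for (u in seq_len(n_op)) {
      k <- sizes[u]
      idx <- which(op_of_gene == u)
      gaps <- if (k > 1) sample(20:60, k - 1, replace = TRUE) else integer(0)
      span <- utr_op[u] + sum(cds_len[idx]) + sum(gaps)
      b <- cursor + promoter_margin
      if (b + span + 50L > L) {
        stop2(sprintf(
          "infeasible packing: %d genes in %d operons do not fit in a %d nt genome",
          n, n_op, L))
      }
      if (strand_op[u] == "+") {
        tss_pos[u] <- b
        at <- b + utr_op[u]
        for (j in seq_len(k)) {
          g <- idx[j]
          start[g] <- at
          end[g] <- at + cds_len[g]
          at <- end[g] + if (j < k) gaps[j] else 0L
        }
      } else {
        tss_pos[u] <- b + span - 1L
        at <- b + span - utr_op[u]           # one past the 5'-most gene end
        for (j in seq_len(k)) {
          g <- idx[j]
          end[g] <- at
          start[g] <- at - cds_len[g]
          at <- start[g] - if (j < k) gaps[j] else 0L
        }
      }
      strand[idx] <- strand_op[u]
      cursor <- b + span + sample(80:150, 1)
    }

    # --- planted expression truth ----------------------------------------
    ncond <- config$n_conditions
    a_base <- 2^stats::rnorm(n_op, 3, 1.2)
    te_base <- 2^stats::rnorm(n_op, 0, 0.5)
    mrna_op <- matrix(a_base, n_op, ncond)
    te_op <- matrix(te_base, n_op, ncond)
    dm_op <- rep(0, n_op)
    dte_op <- rep(0, n_op)
    if (ncond >= 2) {
      for (cc in 2:ncond) {
        dm <- stats::rnorm(n_op, 0, config$mrna_lfc_sd)
        comp <- sample(c("high", "low", "neutral"), n_op, replace = TRUE,
                       prob = c(config$high_fraction, config$low_fraction,
                                1 - config$high_fraction - config$low_fraction))
        mix <- config$te_mean +
          ifelse(comp == "high", 2 * config$te_sd,
                 ifelse(comp == "low", -2 * config$te_sd, 0)) +
          stats::rnorm(n_op, 0, ifelse(comp == "neutral", config$neutral_sd,
                                       config$spike_sd))
        dte <- config$buffering * dm + mix
        mrna_op[, cc] <- a_base * 2^dm
        te_op[, cc] <- te_base * 2^dte
        if (cc == 2) {
          dm_op <- dm
          dte_op <- dte
        }
      }
    }

    # complex membership and subunit copy numbers
    copy_number <- rep(1L, n)
    complex_id <- rep(NA_character_, n)
    for (u in which(sizes >= 2)) {
      idx <- which(op_of_gene == u)
      if (stats::runif(1) > config$equimolar_fraction) {
        copy_number[idx] <- sample(config$copy_levels, length(idx), replace = TRUE)
      }
      complex_id[idx] <- sprintf("cpx%03d", u)
    }

    gene_noise <- 2^stats::rnorm(n, 0, config$te_gene_sd)
    mrna <- mrna_op[op_of_gene, , drop = FALSE]
    te <- te_op[op_of_gene, , drop = FALSE] * copy_number * gene_noise
    dte_gene <- dte_op[op_of_gene]
    dm_gene <- dm_op[op_of_gene]
    thr <- planted_te_threshold(config)
    te_class <- ifelse(dte_gene > thr["mean"] + thr["sd"], "high",
                       ifelse(dte_gene < thr["mean"] - thr["sd"], "low", "neutral"))

    gene_id <- sprintf("g%04d", seq_len(n))
    utr_gene <- ifelse(op_pos == 1L, utr_op[op_of_gene], NA_integer_)
    genes <- data.frame(
      gene_id = gene_id, start = start, end = end, strand = strand,
      length = cds_len, n_codons = n_codons,
      operon_id = sprintf("op%03d", op_of_gene), operon_pos = op_pos,
      complex_id = complex_id, copy_number = copy_number,
      stringsAsFactors = FALSE
    )

    # --- genome sequence ---------------------------------------------------
    chars <- random_dna_chars(L)
    sense_codons <- setdiff(all_codons(), c("TAA", "TAG", "TGA"))
    for (g in seq_len(n)) {
      body <- sample(sense_codons, n_codons[g] - 2L, replace = TRUE)
      cds <- paste0("ATG", paste(body, collapse = ""), "TAA")
      chars <- write_sequence(chars, start[g], cds, strand[g])
    }
    for (u in seq_len(n_op)) {
      chars <- plant_upstream(chars, tss_pos[u], strand_op[u], "TATAAT", 6L)
      chars <- plant_upstream(chars, tss_pos[u], strand_op[u], "TTGACA", 31L)
    }
    # SD hexamer at -12..-7 of the start codon of high-TE genes (leader
    # genes only when the UTR can hold it).
    for (g in which(te_class == "high")) {
      if (op_pos[g] == 1L && utr_gene[g] < 13L) next
      anchor <- if (strand[g] == "+") start[g] else end[g] - 1L
      chars <- plant_upstream(chars, anchor, strand[g], config$sd_motif, 6L)
    }
    seq <- paste(chars, collapse = "")

    tss <- data.frame(
      tss_id = sprintf("tss%03d", seq_len(n_op)),
      pos = tss_pos, strand = strand_op,
      operon_id = sprintf("op%03d", seq_len(n_op)),
      gene_id = gene_id[op_pos == 1L][order(op_of_gene[op_pos == 1L])],
      utr_length = utr_op, category = "P",
      stringsAsFactors = FALSE
    )

    cpx <- genes[!is.na(genes$complex_id),
                 c("complex_id", "gene_id", "copy_number", "operon_pos")]
    names(cpx)[4] <- "order"
    rownames(cpx) <- NULL

    truth <- list(
      mrna = structure(mrna, dimnames = list(gene_id, cond_names(ncond))),
      te = structure(te, dimnames = list(gene_id, cond_names(ncond))),
      log2_mrna_change = stats::setNames(dm_gene, gene_id),
      log2_te_change = stats::setNames(dte_gene, gene_id),
      te_class = stats::setNames(te_class, gene_id),
      te_threshold = thr,
      tss = tss,
      utr_length = stats::setNames(utr_gene, gene_id),
      complexes = cpx
    )
    new_synthetic_genome(seq, genes, truth, config)
  })
}

cond_names <- function(k) sprintf("cond%d", seq_len(k))

#' Planted one-SD classification threshold of the TE-change law
#'
#' Closed-form mean and standard deviation of the generative log2
#' TE-change distribution (buffering term plus high/neutral/low mixture);
#' the planted class labels use `mean +/- sd` of this law so that they are
#' consistent, at scale, with the one-SD rule applied to the realized
#' distribution.
#'
#' @param config A [sim_config()].
#' @return Named numeric vector `c(mean, sd)`.
#' @export
planted_te_threshold <- function(config) {
  hf <- config$high_fraction
  lf <- config$low_fraction
  nf <- 1 - hf - lf
  mu <- config$te_mean + 2 * config$te_sd * (hf - lf)
  centres <- config$te_mean + c(2, -2, 0) * config$te_sd
  wts <- c(hf, lf, nf)
  var_mix <- sum(wts * (centres - mu)^2) +
    (hf + lf) * config$spike_sd^2 + nf * config$neutral_sd^2
  var_tot <- config$buffering^2 * config$mrna_lfc_sd^2 + var_mix
  c(mean = mu, sd = sqrt(var_tot))
}

new_synthetic_genome <- function(sequence, genes, truth, config) {
  structure(
    list(sequence = sequence, genome_length = nchar(sequence), circular = TRUE,
         genes = genes, truth = truth, config = config),
    class = "synthetic_genome"
  )
}

empty_genes <- function() {
  data.frame(gene_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), length = integer(0), n_codons = integer(0),
             operon_id = character(0), operon_pos = integer(0),
             complex_id = character(0), copy_number = integer(0),
             stringsAsFactors = FALSE)
}

empty_truth <- function(config) {
  k <- config$n_conditions
  list(mrna = matrix(numeric(0), 0, k, dimnames = list(NULL, cond_names(k))),
       te = matrix(numeric(0), 0, k, dimnames = list(NULL, cond_names(k))),
       log2_mrna_change = numeric(0), log2_te_change = numeric(0),
       te_class = character(0),
       te_threshold = planted_te_threshold(config),
       tss = data.frame(tss_id = character(0), pos = integer(0),
                        strand = character(0), operon_id = character(0),
                        gene_id = character(0), utr_length = integer(0),
                        category = character(0), stringsAsFactors = FALSE),
       utr_length = numeric(0),
       complexes = data.frame(complex_id = character(0), gene_id = character(0),
                              copy_number = integer(0), order = integer(0),
                              stringsAsFactors = FALSE))
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome> %d nt (circular), %d genes in %d operons, %d planted TSSs\n",
              x$genome_length, nrow(x$genes),
              length(unique(x$genes$operon_id)), nrow(x$truth$tss)))
  invisible(x)
}

random_dna_chars <- function(L) sample(c("A", "C", "G", "T"), L, replace = TRUE)

random_dna <- function(L) paste(random_dna_chars(L), collapse = "")

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

# Write `seq` onto the coding strand at 0-based position `start` (the
# plus-strand slice receives the reverse complement for minus-strand
# features).
write_sequence <- function(chars, start, seq, strand) {
  if (strand == "-") seq <- revcomp(seq)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  chars[(start + 1):(start + length(s))] <- s
  chars
}

# Plant `motif` on the coding strand with `gap3` bases between its 3' end
# and the anchor position: gap3 = 6 puts a hexamer at -12..-7 relative to
# the anchor.
plant_upstream <- function(chars, anchor, strand, motif, gap3) {
  w <- nchar(motif)
  if (strand == "+") {
    start <- anchor - gap3 - w
    if (start < 0) return(chars)
    write_sequence(chars, start, motif, "+")
  } else {
    start <- anchor + gap3 + 1L
    if (start + w > length(chars)) return(chars)
    write_sequence(chars, start, motif, "-")
  }
}

# Transcription-unit table: one row per operon with the transcript interval
# [tx_start, tx_end) on the genome, the TSS and the member genes.
transcription_units <- function(sim) {
  genes <- sim$genes
  tss <- sim$truth$tss
  if (nrow(genes) == 0) return(tss[0, ])
  units <- tss
  units$tx_start <- NA_integer_
  units$tx_end <- NA_integer_
  for (i in seq_len(nrow(units))) {
    idx <- genes$operon_id == units$operon_id[i]
    if (units$strand[i] == "+") {
      units$tx_start[i] <- units$pos[i]
      units$tx_end[i] <- max(genes$end[idx])
    } else {
      units$tx_start[i] <- min(genes$start[idx])
      units$tx_end[i] <- units$pos[i] + 1L
    }
  }
  units$tx_length <- units$tx_end - units$tx_start
  units
}
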