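#' Metagene profile and reading-frame periodicity
#'
#' Averages length-normalized A-site densities across genes in windows
#' anchored at the start and stop codons, and computes the fraction of
#' A-sites in each reading frame within the codon-trimmed ORF windows
#' (codons 6 to L/3 - 5). A 3-nt periodic signal with an elevated frame-0
#' fraction is the classic signature of translating ribosomes.
#'
#' @param track An A-site-shifted [fp_track()] (see [asite_track()]).
#' @param genes Gene annotation data frame.
#' @param window Integer pair: offsets relative to the anchor codon's
#'   first nucleotide (default `c(-30, 60)`).
#' @return An object of class `metagene_profile`: list with `offsets`,
#'   `start_profile`, `stop_profile` (mean normalized density per offset),
#'   `frame_fractions` (named f0/f1/f2) and `n_genes`.
#' @export
metagene <- function(track, genes, window = c(-30L, 60L)) {
  if (nrow(genes) == 0) stop2("empty annotation")
  offs <- seq(window[1], window[2])
  L <- track$genome_length
  start_acc <- numeric(length(offs))
  stop_acc <- numeric(length(offs))
  used <- 0L
  frame_counts <- c(0, 0, 0)
  for (g in seq_len(nrow(genes))) {
    glen <- genes$end[g] - genes$start[g]
    if (glen <= window[2]) next
    st <- genes$strand[g]
    v <- if (st == "+") track$plus else track$minus
    if (st == "+") {
      start_anchor <- genes$start[g]
      stop_anchor <- genes$end[g] - 3L
      start_idx <- start_anchor + offs
      stop_idx <- stop_anchor + offs
    } else {
      start_anchor <- genes$end[g] - 1L
      stop_anchor <- genes$start[g] + 2L
      start_idx <- start_anchor - offs
      stop_idx <- stop_anchor - offs
    }
    gene_mean <- mean(v[(genes$start[g] + 1):genes$end[g]])
    if (gene_mean == 0) next
    grab <- function(idx) {
      ok <- idx >= 0 & idx < L
      out <- numeric(length(idx))
      out[ok] <- v[idx[ok] + 1L]
      out / gene_mean
    }
    start_acc <- start_acc + grab(start_idx)
    stop_acc <- stop_acc + grab(stop_idx)
    used <- used + 1L
    # frame composition inside the trimmed ORF
    n_cod <- glen %/% 3L
    if (n_cod >= 11L) {
      tw <- (genes$start[g] + 15L):(genes$end[g] - 15L - 1L)
      cnt <- v[tw + 1L]
      fr <- if (st == "+") (tw - genes$start[g]) %% 3L else (genes$end[g] - 1L - tw) %% 3L
      for (f in 0:2) frame_counts[f + 1] <- frame_counts[f + 1] + sum(cnt[fr == f])
    }
  }
  if (used == 0) stop2("no gene is longer than the metagene window")
  ff <- if (sum(frame_counts) > 0) frame_counts / sum(frame_counts) else rep(NA_real_, 3)
  structure(list(offsets = offs,
                 start_profile = start_acc / used,
                 stop_profile = stop_acc / used,
                 frame_fractions = stats::setNames(ff, c("f0", "f1", "f2")),
                 n_genes = used),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("<metagene_profile> %d genes, offsets %d..%d; frames f0=%.3f f1=%.3f f2=%.3f\n",
              x$n_genes, min(x$offsets), max(x$offsets),
              x$frame_fractions[1], x$frame_fractions[2], x$frame_fractions[3]))
  invisible(x)
}

#' @export
plot.metagene_profile <- function(x, ...) {
  graphics::plot(x$offsets, x$start_profile, type = "h",
                 xlab = "offset from start codon (nt)",
                 ylab = "mean normalized A-site density", ...)
  graphics::abline(v = 0, col = "red", lty = 2)
  invisible(x)
}

#' Ribosome occupancy of 5' UTRs relative to coding sequences
#'
#' For each gene with an assigned 5' UTR of at least `min_utr` nt,
#' computes per-nt RPF and RNA densities in the UTR (TSS to start codon,
#' excluding the start codon itself) and in the CDS (codon-trimmed window
#' for RPF, full ORF for RNA), their RPF/RNA ratios, and compares UTR
#' vs CDS ratios by a paired two-tailed Wilcoxon signed-rank test.
#'
#' @param rpf_track A-site-shifted Ribo-Seq [fp_track()].
#' @param rna_track RNA-Seq 5'-end [fp_track()].
#' @param utrs UTR table from [assign_utr()] (or the truth's TSS table
#'   with `gene_id` and `length`).
#' @param genes Gene annotation data frame.
#' @param min_utr Minimum UTR length in nt (default 10).
#' @return A list with `records` (per-gene data frame), `median_utr_ratio`,
#'   `median_cds_ratio`, `median_ratio_of_ratios` and `wilcoxon_p`.
#' @export
utr_occupancy <- function(rpf_track, rna_track, utrs, genes, min_utr = 10L) {
  utrs <- utrs[!is.na(utrs$length) & utrs$length >= min_utr, , drop = FALSE]
  if (nrow(utrs) == 0) stop2("no qualifying UTRs (length >= min_utr)")
  rec <- list()
  for (i in seq_len(nrow(utrs))) {
    g <- match(utrs$gene_id[i], genes$gene_id)
    if (is.na(g)) next
    st <- genes$strand[g]
    ulen <- utrs$length[i]
    if (st == "+") {
      u0 <- genes$start[g] - ulen
      u1 <- genes$start[g]
    } else {
      u0 <- genes$end[g]
      u1 <- genes$end[g] + ulen
    }
    glen <- genes$end[g] - genes$start[g]
    n_cod <- glen %/% 3L
    if (n_cod < 11L) next
    utr_rpf <- track_window_sum(rpf_track, u0, u1, st) / ulen
    utr_rna <- track_window_sum(rna_track, u0, u1, st) / ulen
    cds_rpf <- track_window_sum(rpf_track, genes$start[g] + 15L,
                                genes$end[g] - 15L, st) / (glen - 30L)
    cds_rna <- track_window_sum(rna_track, genes$start[g], genes$end[g], st) / glen
    if (utr_rna <= 0 || cds_rna <= 0) next
    rec[[length(rec) + 1]] <- data.frame(
      gene_id = genes$gene_id[g], utr_length = ulen,
      utr_rpf_density = utr_rpf, utr_rna_density = utr_rna,
      cds_rpf_density = cds_rpf, cds_rna_density = cds_rna,
      utr_ratio = utr_rpf / utr_rna, cds_ratio = cds_rpf / cds_rna,
      stringsAsFactors = FALSE)
  }
  if (length(rec) == 0) stop2("no gene with positive RNA density in both regions")
  records <- do.call(rbind, rec)
  rownames(records) <- NULL
  diffs <- records$utr_ratio - records$cds_ratio
  p <- if (all(diffs == 0)) 1 else {
    suppressWarnings(stats::wilcox.test(records$utr_ratio, records$cds_ratio,
                                        paired = TRUE,
                                        exact = nrow(records) <= 25)$p.value)
  }
  list(records = records,
       median_utr_ratio = stats::median(records$utr_ratio),
       median_cds_ratio = stats::median(records$cds_ratio),
       median_ratio_of_ratios = stats::median(records$utr_ratio / records$cds_ratio),
       wilcoxon_p = p)
}

#' Fold an RNA sequence (Nussinov base-pair maximization or external engine)
#'
#' The internal engine maximizes the number of nested base pairs (AU, GC
#' and GU wobble) with a minimum hairpin loop of 3 nt, reporting the
#' negated pair count as an energy proxy. An external engine can be
#' supplied as a function taking the sequence and returning a list with
#' `energy` (kcal/mol) and optionally `structure` (dot-bracket);
#' [rnafold_engine()] wraps the ViennaRNA `RNAfold` binary when it is on
#' the PATH.
#'
#' @param sequence RNA (or DNA; T is read as U) sequence string.
#' @param engine `"internal"` or a function (see above).
#' @return An object of class `fold_result`: list with `sequence`,
#'   `energy`, `pairs` (2-column matrix of 1-based paired positions,
#'   nested and non-crossing), `structure` (dot-bracket) and `engine`.
#' @export
fold_mfe <- function(sequence, engine = "internal") {
  seq <- toupper(dna_to_rna(sequence))
  if (nchar(seq) < 1) stop2("sequence must have length >= 1")
  if (grepl("[^ACGU]", seq)) stop2("invalid characters in RNA sequence")
  if (is.function(engine)) {
    res <- engine(seq)
    pairs <- res$pairs %||% dotbracket_pairs(res$structure %||% strrep(".", nchar(seq)))
    return(structure(list(sequence = seq, energy = res$energy, pairs = pairs,
                          structure = res$structure %||% pairs_dotbracket(pairs, nchar(seq)),
                          engine = "external"),
                     class = "fold_result"))
  }
  n <- nchar(seq)
  b <- strsplit(seq, "")[[1]]
  can_pair <- function(x, y) {
    paste0(x, y) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  dp <- matrix(0L, n, n)
  if (n >= 5) {
    for (span in 4:(n - 1)) {
      for (i in 1:(n - span)) {
        j <- i + span
        best <- dp[i + 1, j]  # i unpaired
        ks <- (i + 4):j
        for (k in ks) {
          if (can_pair(b[i], b[k])) {
            inner <- if (k - i >= 5) dp[i + 1, k - 1] else 0L
            outer <- if (k < j) dp[k + 1, j] else 0L
            best <- max(best, 1L + inner + outer)
          }
        }
        dp[i, j] <- best
      }
    }
  }
  # traceback
  pairs <- matrix(integer(0), 0, 2)
  stack <- list(c(1L, n))
  while (length(stack) > 0 && n >= 2) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (j - i < 4) next
    if (dp[i, j] == dp[i + 1, j]) {
      stack[[length(stack) + 1]] <- c(i + 1L, j)
      next
    }
    for (k in (i + 4):j) {
      if (can_pair(b[i], b[k])) {
        inner <- if (k - i >= 5) dp[i + 1, k - 1] else 0L
        outer <- if (k < j) dp[k + 1, j] else 0L
        if (dp[i, j] == 1L + inner + outer) {
          pairs <- rbind(pairs, c(i, k))
          if (k - i >= 5) stack[[length(stack) + 1]] <- c(i + 1L, k - 1L)
          if (k < j) stack[[length(stack) + 1]] <- c(k + 1L, j)
          break
        }
      }
    }
  }
  structure(list(sequence = seq, energy = -nrow(pairs), pairs = pairs,
                 structure = pairs_dotbracket(pairs, n), engine = "internal"),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("<fold_result> %s engine: %d nt, %d pair(s), energy %.2f\n%s\n%s\n",
              x$engine, nchar(x$sequence), nrow(x$pairs), x$energy,
              x$sequence, x$structure))
  invisible(x)
}

pairs_dotbracket <- function(pairs, n) {
  s <- rep(".", n)
  if (nrow(pairs) > 0) {
    s[pairs[, 1]] <- "("
    s[pairs[, 2]] <- ")"
  }
  paste(s, collapse = "")
}

dotbracket_pairs <- function(db) {
  v <- strsplit(db, "")[[1]]
  stack <- integer(0)
  pairs <- matrix(integer(0), 0, 2)
  for (i in seq_along(v)) {
    if (v[i] == "(") stack <- c(stack, i)
    if (v[i] == ")") {
      pairs <- rbind(pairs, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  pairs
}

#' ViennaRNA RNAfold external engine
#'
#' Returns a folding function for [fold_mfe()] that shells out to the
#' `RNAfold` binary (thermodynamic minimum free energy in kcal/mol), or
#' `NULL` when the binary is not on the PATH.
#'
#' @return A function, or `NULL` when RNAfold is unavailable.
#' @export
rnafold_engine <- function() {
  if (Sys.which("RNAfold") == "") return(NULL)
  function(seq) {
    out <- system2("RNAfold", args = "--noPS", input = seq, stdout = TRUE)
    line <- out[2]
    m <- regmatches(line, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1]]
    list(structure = m[2], energy = as.numeric(m[3]))
  }
}

#' Compare TE changes between structured and unstructured 5' UTRs
#'
#' Splits genes by 5'-UTR folding energy at a fixed threshold (e.g. -30
#' kcal/mol with a thermodynamic engine) or, when `threshold` is `NULL`,
#' at the cohort median (appropriate for the internal pair-count proxy),
#' and compares the TE-change distributions of the two groups with a
#' two-tailed Wilcoxon rank-sum test.
#'
#' @param energies Named numeric vector of per-gene folding energies.
#' @param te_changes Named numeric vector of log2 TE changes for the same
#'   genes.
#' @param threshold Energy threshold; values strictly below it form the
#'   "structured" group. `NULL` (default) uses the median.
#' @return List with `threshold`, group sizes, group medians,
#'   `median_difference` (structured - unstructured) and `p` (Wilcoxon).
#' @export
te_by_mfe <- function(energies, te_changes, threshold = NULL) {
  common <- intersect(names(energies), names(te_changes))
  if (length(common) > 0) {
    energies <- energies[common]
    te_changes <- te_changes[common]
  }
  if (length(energies) != length(te_changes)) stop2("gene sets must match")
  ok <- is.finite(energies) & is.finite(te_changes)
  energies <- energies[ok]
  te_changes <- te_changes[ok]
  thr <- threshold %||% stats::median(energies)
  structured <- energies < thr
  if (sum(structured) < 3 || sum(!structured) < 3) {
    stop2("each folding-energy group needs at least 3 genes")
  }
  a <- te_changes[structured]
  bq <- te_changes[!structured]
  wt <- stats::wilcox.test(a, bq, exact = length(a) <= 25 && length(bq) <= 25)
  list(threshold = thr, n_structured = sum(structured),
       n_unstructured = sum(!structured),
       median_structured = stats::median(a),
       median_unstructured = stats::median(bq),
       median_difference = stats::median(a) - stats::median(bq),
       p = wt$p.value)
}

#' Shine-Dalgarno complementarity score and position-frequency matrix
#'
#' Scores each sequence window upstream of the start codon by the longest
#' contiguous run of Watson-Crick or G:U wobble pairs formed against the
#' 16S rRNA 3' tail (anti-SD, written 3'->5' so it aligns base-by-base
#' with the mRNA read 5'->3') over all alignment offsets inside the
#' window. A perfect AGGAGG scores 6. Also builds the cohort
#' position-frequency matrix over the window, aligned at the start codon,
#' with per-column information content in bits.
#'
#' @param sequences Named character vector of sequences upstream of start
#'   codons, each given 5'->3' with its last base immediately preceding
#'   the start codon (e.g. UTRs from [assign_utr()], or fixed-width
#'   windows).
#' @param window Start-relative window `c(from, to)` scanned for the
#'   anti-SD match (default `c(-20, -5)`; positions are negative,
#'   -1 = base before the AUG).
#' @param anti_sd The anti-SD sequence written 3'->5' (default
#'   `"AUUCCUCCAC"`, the 16S 3' terminus).
#' @return List with `scores` (per-sequence max run length), `flagged`
#'   (sequences shorter than the window, scored on the available span),
#'   `pfm` (4 x window nucleotide counts) and `information` (bits per
#'   column).
#' @export
sd_score <- function(sequences, window = c(-20L, -5L), anti_sd = "AUUCCUCCAC") {
  sequences <- toupper(dna_to_rna(sequences))
  anti <- strsplit(toupper(dna_to_rna(anti_sd)), "")[[1]]
  pairs_ok <- function(m, a) {
    paste0(m, a) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  wfrom <- window[1]
  wto <- window[2]
  wlen <- wto - wfrom + 1L
  scores <- numeric(length(sequences))
  flagged <- logical(length(sequences))
  pfm <- matrix(0L, 4, wlen,
                dimnames = list(c("A", "C", "G", "U"), as.character(wfrom:wto)))
  for (i in seq_along(sequences)) {
    s <- strsplit(sequences[i], "")[[1]]
    n <- length(s)
    # start-relative coordinates: last base is -1
    rel <- seq(-n, -1L)
    keep <- rel >= wfrom & rel <= wto
    win <- s[keep]
    flagged[i] <- sum(keep) < wlen
    if (length(win) == 0) { scores[i] <- 0; next }
    best <- 0L
    la <- length(anti)
    for (off in (-la + 1L):(length(win) - 1L)) {
      run <- 0L
      for (k in seq_len(la)) {
        j <- off + k
        hit <- j >= 1L && j <= length(win) && pairs_ok(win[j], anti[k])
        if (hit) {
          run <- run + 1L
          best <- max(best, run)
        } else {
          run <- 0L
        }
      }
    }
    scores[i] <- best
    cols <- match(as.character(rel[keep]), colnames(pfm))
    for (k in seq_along(win)) {
      if (win[k] %in% rownames(pfm)) {
        pfm[win[k], cols[k]] <- pfm[win[k], cols[k]] + 1L
      }
    }
  }
  names(scores) <- names(sequences)
  csum <- colSums(pfm)
  info <- vapply(seq_len(ncol(pfm)), function(j) {
    if (csum[j] == 0) return(0)
    p <- (pfm[, j] + 0.25) / (csum[j] + 1)   # pseudocounted
    2 + sum(p * log2(p))
  }, numeric(1))
  names(info) <- colnames(pfm)
  list(scores = scores, flagged = flagged, pfm = pfm, information = info)
}
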