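#' Scale a dRNA-Seq track pair to counts per million
#'
#' Each library is scaled so its total 5'-end count equals 1e6, putting
#' the pyrophosphatase-treated (RPP+) and untreated (RPP-) profiles on a
#' common density scale before ratio computation.
#'
#' @param rpp_plus,rpp_minus [fp_track()] objects for the treated and
#'   untreated library.
#' @return A list with scaled `rpp_plus`, `rpp_minus` and the applied
#'   `factors` (per-library multipliers).
#' @export
normalize_tracks <- function(rpp_plus, rpp_minus) {
  t1 <- track_total(rpp_plus)
  t2 <- track_total(rpp_minus)
  if (t1 == 0 || t2 == 0) stop2("cannot normalize an empty track")
  f <- c(rpp_plus = 1e6 / t1, rpp_minus = 1e6 / t2)
  scale_track <- function(tr, s) {
    out <- fp_track(tr$plus * s, tr$minus * s, library = tr$library)
    out
  }
  list(rpp_plus = scale_track(rpp_plus, f[1]),
       rpp_minus = scale_track(rpp_minus, f[2]),
       factors = f)
}

#' Call candidate TSSs from a normalized dRNA-Seq pair
#'
#' A position is a candidate TSS when the pseudocounted density ratio
#' `(RPP+ + eps) / (RPP- + eps)` exceeds `min_ratio` and the RPP+ density
#' is at least `min_density`; candidates are then reduced to local maxima
#' of RPP+ density within a +/- `window` nt neighborhood per strand (ties
#' keep the most upstream position).
#'
#' @param rpp_plus,rpp_minus Normalized [fp_track()] objects (see
#'   [normalize_tracks()]).
#' @param min_ratio Minimum RPP+/RPP- ratio (strict; default 2).
#' @param min_density Minimum RPP+ density in counts per million
#'   (default 10).
#' @param eps Pseudo-density added to both tracks before the ratio.
#' @param window Local-maximum neighborhood half-width in nt.
#' @param library Label recorded as the supporting library.
#' @return Data frame of candidate TSS records: `pos`, `strand`,
#'   `enrichment_ratio`, `peak_density`, `libraries`.
#' @export
call_tss <- function(rpp_plus, rpp_minus, min_ratio = 2, min_density = 10,
                     eps = 0.5, window = 4L, library = NULL) {
  if (min_ratio <= 1) stop2("min_ratio must exceed 1")
  if (rpp_plus$genome_length != rpp_minus$genome_length) {
    stop2("track pair must cover the same genome")
  }
  lib <- library %||% rpp_plus$library %||% "lib1"
  one_strand <- function(p, m, strand) {
    ratio <- (p + eps) / (m + eps)
    cand <- which(ratio > min_ratio & p >= min_density)
    if (length(cand) == 0) return(NULL)
    L <- length(p)
    keep <- logical(length(cand))
    for (i in seq_along(cand)) {
      j <- cand[i]
      lo <- max(1L, j - window)
      hi <- min(L, j + window)
      wmax <- max(p[lo:hi])
      # local maximum; on plateaus keep the leftmost index
      keep[i] <- p[j] == wmax && !any(p[lo:(j - 1)][seq_len(j - lo)] == wmax)
    }
    cand <- cand[keep]
    if (length(cand) == 0) return(NULL)
    data.frame(pos = cand - 1L, strand = strand,
               enrichment_ratio = ratio[cand], peak_density = p[cand],
               libraries = lib, stringsAsFactors = FALSE)
  }
  out <- rbind(one_strand(rpp_plus$plus, rpp_minus$plus, "+"),
               one_strand(rpp_plus$minus, rpp_minus$minus, "-"))
  if (is.null(out)) out <- empty_tss_calls()
  rownames(out) <- NULL
  out[order(out$strand, out$pos), , drop = FALSE]
}

empty_tss_calls <- function() {
  data.frame(pos = integer(0), strand = character(0),
             enrichment_ratio = numeric(0), peak_density = numeric(0),
             libraries = character(0), stringsAsFactors = FALSE)
}

#' Merge TSS candidates across libraries
#'
#' Candidates on the same strand within +/- `window` nt are collapsed by
#' single-linkage clustering into one record positioned at the coordinate
#' with the highest summed peak density (ties keep the most upstream
#' coordinate). Densities are summed over the cluster; the enrichment
#' ratio reported is the density-weighted mean; supporting libraries are
#' unioned. Merging is idempotent and the output never contains two
#' records on the same strand within `window` nt of each other.
#'
#' @param candidates A data frame as returned by [call_tss()], or a list
#'   of such data frames (one per library).
#' @param window Merge half-width in nt (default 4).
#' @return A merged candidate data frame with the same columns plus
#'   `n_support`.
#' @export
merge_tss <- function(candidates, window = 4L) {
  if (is.data.frame(candidates)) candidates <- list(candidates)
  x <- do.call(rbind, candidates)
  if (is.null(x) || nrow(x) == 0) {
    out <- empty_tss_calls()
    out$n_support <- integer(0)
    return(out)
  }
  x <- x[order(x$strand, x$pos), , drop = FALSE]
  res <- list()
  for (st in unique(x$strand)) {
    xs <- x[x$strand == st, , drop = FALSE]
    # upstream means 5'-most in transcription direction
    up_order <- if (st == "+") order(xs$pos) else order(-xs$pos)
    cluster <- cumsum(c(1L, diff(xs$pos) > window))
    for (cl in unique(cluster)) {
      xc <- xs[cluster == cl, , drop = FALSE]
      dens <- tapply(xc$peak_density, xc$pos, sum)
      positions <- as.integer(names(dens))
      best <- positions[dens == max(dens)]
      pos <- if (st == "+") min(best) else max(best)
      res[[length(res) + 1]] <- data.frame(
        pos = pos, strand = st,
        enrichment_ratio = sum(xc$enrichment_ratio * xc$peak_density) /
          sum(xc$peak_density),
        peak_density = sum(xc$peak_density),
        libraries = paste(sort(unique(unlist(strsplit(xc$libraries, ",")))),
                          collapse = ","),
        n_support = length(unique(unlist(strsplit(xc$libraries, ",")))),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$strand, out$pos), , drop = FALSE]
}

#' Categorize TSSs against a gene annotation
#'
#' Among the TSSs lying within `upstream` nt upstream (strict) to
#' `downstream` nt downstream of a gene's start on the same strand, the
#' one with the highest peak density is the gene's primary TSS (`P`) and
#' the others are secondary (`S`); ties for primary go to the most
#' upstream TSS. A TSS inside a gene body on the same strand (beyond the
#' downstream window) is internal (`I`); one inside a gene on the opposite
#' strand is antisense (`A`); anything else is intergenic (`N`). When a
#' TSS qualifies for several categories the priority is P > S > I > A > N.
#'
#' @param tss Candidate data frame (see [merge_tss()]).
#' @param genes Gene annotation data frame.
#' @param upstream,downstream Window around gene starts defining
#'   primary/secondary association (defaults 300 and 100 nt).
#' @return The input with `category` and `associated_gene` columns.
#' @export
categorize_tss <- function(tss, genes, upstream = 300L, downstream = 100L) {
  n <- nrow(tss)
  category <- rep("N", n)
  gene_of <- rep(NA_character_, n)
  if (n == 0) {
    tss$category <- character(0)
    tss$associated_gene <- character(0)
    return(tss)
  }
  rank <- c(P = 1, S = 2, I = 3, A = 4, N = 5)
  propose <- function(i, cat, gene) {
    if (rank[cat] < rank[category[i]]) {
      category[i] <<- cat
      gene_of[i] <<- gene
    }
  }
  for (g in seq_len(nrow(genes))) {
    gstart <- if (genes$strand[g] == "+") genes$start[g] else genes$end[g] - 1L
    same <- tss$strand == genes$strand[g]
    # signed distance from gene start in transcription direction
    d <- if (genes$strand[g] == "+") tss$pos - gstart else gstart - tss$pos
    inwin <- same & d > -upstream & d <= downstream
    if (any(inwin)) {
      idx <- which(inwin)
      best <- idx[tss$peak_density[idx] == max(tss$peak_density[idx])]
      if (length(best) > 1) {
        best <- best[which.min(d[best])]  # most upstream wins ties
      }
      for (i in idx) {
        propose(i, if (i == best) "P" else "S", genes$gene_id[g])
      }
    }
    inside <- tss$pos >= genes$start[g] & tss$pos < genes$end[g]
    for (i in which(inside & same & !inwin)) propose(i, "I", genes$gene_id[g])
    for (i in which(inside & !same)) propose(i, "A", genes$gene_id[g])
  }
  tss$category <- category
  tss$associated_gene <- gene_of
  tss
}

#' Assign 5' UTRs from primary TSSs
#'
#' The UTR length is the strand-aware distance from the TSS to the
#' annotated start codon; the sequence is extracted from the coding strand
#' and transcribed to the RNA alphabet. TSSs downstream of the start codon
#' are skipped with a warning. UTRs too short to hold a Shine-Dalgarno
#' window are flagged leaderless.
#'
#' @param tss Categorized TSS data frame; only `category == "P"` rows are
#'   used.
#' @param genes Gene annotation data frame.
#' @param genome A `synthetic_genome` or a genome sequence string.
#' @param leaderless_below UTR lengths below this are flagged leaderless
#'   (default 5 nt, the minimum SD window span).
#' @return Data frame with `gene_id`, `tss_pos`, `strand`, `length`,
#'   `sequence` (RNA alphabet) and `leaderless`.
#' @export
assign_utr <- function(tss, genes, genome, leaderless_below = 5L) {
  seqstr <- if (inherits(genome, "synthetic_genome")) genome$sequence else genome
  prim <- tss[tss$category == "P", , drop = FALSE]
  out <- list()
  skipped <- 0
  for (i in seq_len(nrow(prim))) {
    g <- match(prim$associated_gene[i], genes$gene_id)
    if (is.na(g)) next
    if (genes$strand[g] == "+") {
      len <- genes$start[g] - prim$pos[i]
      if (len < 0) { skipped <- skipped + 1; next }
      seq <- substr(seqstr, prim$pos[i] + 1L, genes$start[g])
    } else {
      len <- prim$pos[i] - (genes$end[g] - 1L)
      if (len < 0) { skipped <- skipped + 1; next }
      seq <- revcomp(substr(seqstr, genes$end[g] + 1L, prim$pos[i] + 1L))
    }
    out[[length(out) + 1]] <- data.frame(
      gene_id = genes$gene_id[g], tss_pos = prim$pos[i],
      strand = genes$strand[g], length = len,
      sequence = dna_to_rna(seq), leaderless = len < leaderless_below,
      stringsAsFactors = FALSE)
  }
  if (skipped > 0) {
    warning(sprintf("%d primary TSS record(s) downstream of the start codon skipped",
                    skipped), call. = FALSE)
  }
  res <- if (length(out) > 0) do.call(rbind, out) else {
    data.frame(gene_id = character(0), tss_pos = integer(0),
               strand = character(0), length = integer(0),
               sequence = character(0), leaderless = logical(0),
               stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Extract promoter regions upstream of TSSs and scan for sigma-70 boxes
#'
#' Extracts `length` nt of coding-strand sequence immediately upstream of
#' each TSS (wrapping across the origin for circular genomes; shortened
#' and flagged on linear contigs) and scans every window against the -10
#' (TATAAT) and -35 (TTGACA) consensus hexamers, reporting hits with at
#' most `max_mismatch` mismatches.
#'
#' @param tss TSS data frame with `pos` and `strand` columns.
#' @param genome A `synthetic_genome` or genome sequence string.
#' @param length Promoter length in nt (default 50).
#' @param max_mismatch Maximum mismatches per consensus hit (default 1).
#' @param circular Treat the genome as circular (default taken from the
#'   genome object, else `TRUE`).
#' @return A list with `sequences` (named character vector; names are
#'   `pos:strand`), `truncated` (logical per sequence) and `hits` (data
#'   frame with `tss_pos`, `strand`, `motif`, `offset`, `mismatches`;
#'   `offset` is the position of the motif's 5' base relative to the TSS,
#'   e.g. -12 means the hexamer occupies -12..-7).
#' @export
extract_promoters <- function(tss, genome, length = 50L, max_mismatch = 1L,
                              circular = NULL) {
  seqstr <- if (inherits(genome, "synthetic_genome")) genome$sequence else genome
  circular <- circular %||%
    (if (inherits(genome, "synthetic_genome")) genome$circular else TRUE)
  L <- nchar(seqstr)
  motifs <- c(minus10 = "TATAAT", minus35 = "TTGACA")
  seqs <- character(nrow(tss))
  truncated <- logical(nrow(tss))
  hits <- list()
  for (i in seq_len(nrow(tss))) {
    if (tss$strand[i] == "+") {
      from <- tss$pos[i] - length
      idx <- from:(tss$pos[i] - 1L)
    } else {
      idx <- (tss$pos[i] + length):(tss$pos[i] + 1L)
    }
    if (circular) {
      idx <- idx %% L
    } else {
      drop <- idx < 0 | idx >= L
      truncated[i] <- any(drop)
      idx <- idx[!drop]
    }
    s <- paste(substring(seqstr, idx + 1L, idx + 1L), collapse = "")
    if (tss$strand[i] == "-") s <- chartr("ACGT", "TGCA", s)
    seqs[i] <- s
    for (m in names(motifs)) {
      mm <- motif_scan(s, motifs[[m]], max_mismatch)
      if (nrow(mm) > 0) {
        # window j (1-based in the upstream sequence) starts at TSS-offset
        mm$offset <- mm$window - nchar(s) - 1L
        hits[[length(hits) + 1]] <- data.frame(
          tss_pos = tss$pos[i], strand = tss$strand[i], motif = m,
          offset = mm$offset, mismatches = mm$mismatches,
          stringsAsFactors = FALSE)
      }
    }
  }
  names(seqs) <- paste0(tss$pos, ":", tss$strand)
  hits <- if (length(hits) > 0) do.call(rbind, hits) else {
    data.frame(tss_pos = integer(0), strand = character(0), motif = character(0),
               offset = integer(0), mismatches = integer(0), stringsAsFactors = FALSE)
  }
  rownames(hits) <- NULL
  list(sequences = seqs, truncated = truncated, hits = hits)
}

# Sliding-window mismatch scan; returns 1-based window starts and
# mismatch counts for windows with <= max_mismatch mismatches.
motif_scan <- function(seq, motif, max_mismatch) {
  w <- nchar(motif)
  n <- nchar(seq)
  if (n < w) return(data.frame(window = integer(0), mismatches = integer(0)))
  sv <- strsplit(seq, "")[[1]]
  mv <- strsplit(motif, "")[[1]]
  res <- vapply(seq_len(n - w + 1L), function(j) {
    sum(sv[j:(j + w - 1L)] != mv)
  }, numeric(1))
  keep <- which(res <= max_mismatch)
  data.frame(window = keep, mismatches = as.integer(res[keep]))
}
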