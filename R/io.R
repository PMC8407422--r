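# File formats: FASTA via Biostrings, GFF3 and bedGraph via rtracklayer,
# tabular data as TSV with a header row and '#' comment lines.
# Conventions: internal coordinates are 0-based half-open; GFF3 is 1-based
# closed; bedGraph is 0-based half-open; strands live in separate
# .plus/.minus bedGraph files.

SEQNAME <- "chr"

#' Write / read a genome FASTA
#'
#' @param genome A `synthetic_genome` or a sequence string.
#' @param path Output file.
#' @return `write_genome_fasta` the path, invisibly; `read_genome_fasta`
#'   the sequence string (first record).
#' @export
write_genome_fasta <- function(genome, path) {
  seqstr <- if (inherits(genome, "synthetic_genome")) genome$sequence else genome
  x <- Biostrings::DNAStringSet(seqstr)
  names(x) <- SEQNAME
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  as.character(x[[1]])
}

#' Write a gene annotation as GFF3
#'
#' Internal 0-based half-open records become 1-based closed CDS features;
#' operon and copy-number metadata travel in the attribute column.
#'
#' @param genes Gene annotation data frame.
#' @param path Output file.
#' @param genome_length Genome length for the sequence-region header.
#' @return The path, invisibly.
#' @export
write_annotation <- function(genes, path, genome_length) {
  gr <- GenomicRanges::GRanges(
    seqnames = SEQNAME,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- genes$gene_id
  gr$operon <- genes$operon_id
  gr$operon_pos <- genes$operon_pos
  gr$copy_number <- genes$copy_number
  GenomeInfoDb_safe_seqlengths(gr, genome_length)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# Setting seqlengths requires GenomeInfoDb which rtracklayer loads; keep
# it best-effort since the export does not strictly need it.
GenomeInfoDb_safe_seqlengths <- function(gr, genome_length) {
  try(suppressWarnings({
    GenomeInfoDb::seqlengths(gr) <- stats::setNames(genome_length, SEQNAME)
  }), silent = TRUE)
  gr
}

#' Read a GFF3 gene annotation
#'
#' CDS (or gene) features become gene records with internal 0-based
#' half-open coordinates.
#'
#' @param path GFF3 file.
#' @return A gene annotation data frame (`gene_id`, `start`, `end`,
#'   `strand`, `length`, `n_codons`, `operon_id`, `operon_pos`,
#'   `copy_number`).
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) return(empty_genes()[, c("gene_id", "start", "end", "strand",
                                                "length", "n_codons", "operon_id",
                                                "operon_pos", "copy_number")])
  types <- as.character(gr$type)
  keep <- types %in% c("CDS", "gene")
  if (any(keep)) gr <- gr[keep]
  start1 <- GenomicRanges::start(gr)
  end1 <- GenomicRanges::end(gr)
  if (any(end1 < start1)) stop2("malformed annotation: end < start")
  meta <- as.data.frame(S4Vectors::mcols(gr))
  df <- data.frame(
    gene_id = as.character(gr$ID %||% sprintf("g%04d", seq_along(gr))),
    start = start1 - 1L, end = end1,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  df$length <- df$end - df$start
  df$n_codons <- df$length %/% 3L
  df$operon_id <- if ("operon" %in% names(meta)) as.character(meta$operon) else df$gene_id
  df$operon_pos <- if ("operon_pos" %in% names(meta)) as.integer(meta$operon_pos) else 1L
  df$copy_number <- if ("copy_number" %in% names(meta)) as.integer(meta$copy_number) else 1L
  df
}

#' Write / read a per-strand 5'-end track as bedGraph
#'
#' One bedGraph file per strand (suffixes `.plus.bedgraph` and
#' `.minus.bedgraph`), 0-based half-open intervals with run-length
#' collapsed counts; zero runs are omitted. `read_track(write_track(x))`
#' reproduces the per-position counts exactly.
#'
#' @param track An [fp_track()].
#' @param prefix Output path prefix.
#' @return `write_track` the two paths, invisibly; `read_track` an
#'   `fp_track`.
#' @export
write_track <- function(track, prefix) {
  paths <- paste0(prefix, c(".plus.bedgraph", ".minus.bedgraph"))
  for (i in 1:2) {
    v <- if (i == 1) track$plus else track$minus
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    df <- data.frame(chrom = SEQNAME, start = starts[keep], end = ends[keep],
                     value = r$values[keep])
    writeLines(
      c(sprintf("track type=bedGraph name=%s", paste0(track$library %||% "track",
                                                      c("+", "-")[i])),
        sprintf("%s\t%d\t%d\t%s", df$chrom, df$start, df$end,
                format(df$value, trim = TRUE, scientific = FALSE))),
      paths[i])
  }
  invisible(paths)
}

#' @rdname write_track
#' @param genome_length Genome length of the track to reconstruct.
#' @param library Library label for the reconstructed track.
#' @export
read_track <- function(prefix, genome_length, library = NA_character_) {
  paths <- paste0(prefix, c(".plus.bedgraph", ".minus.bedgraph"))
  vecs <- lapply(paths, function(p) {
    v <- numeric(genome_length)
    gr <- rtracklayer::import(p, format = "bedGraph")
    if (length(gr) > 0) {
      s <- GenomicRanges::start(gr) - 1L  # back to 0-based half-open
      e <- GenomicRanges::end(gr)
      if (is.unsorted(s)) stop2("bedGraph intervals must be sorted")
      for (i in seq_along(gr)) {
        if (e[i] > genome_length) stop2("bedGraph interval outside genome")
        idx <- (s[i] + 1L):e[i]
        if (any(v[idx] != 0)) stop2("overlapping bedGraph intervals")
        v[idx] <- gr$score[i]
      }
    }
    v
  })
  fp_track(vecs[[1]], vecs[[2]], library = library)
}

#' Write / read a TSV table
#'
#' Tab-separated with a header row; lines starting with `#` are comments.
#'
#' @param df Data frame.
#' @param path File path.
#' @param comment Optional character vector of comment lines (written
#'   without the leading `#`).
#' @return `write_tsv` the path invisibly; `read_tsv` a data frame.
#' @export
write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write / read the simulation truth tables
#'
#' Serializes the planted truth (expression, TE classes, TSSs, UTRs,
#' complexes) as a set of TSV files that round-trip exactly.
#'
#' @param truth The `truth` element of a [generate_genome()] result.
#' @param dir Output directory (created if needed).
#' @return `write_truth` the directory invisibly; `read_truth` a truth
#'   list.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- data.frame(gene_id = rownames(truth$mrna),
                     truth$mrna, truth$te,
                     check.names = FALSE, stringsAsFactors = FALSE)
  names(expr) <- c("gene_id", paste0("mrna_", colnames(truth$mrna)),
                   paste0("te_", colnames(truth$te)))
  expr$log2_mrna_change <- unname(truth$log2_mrna_change)
  expr$log2_te_change <- unname(truth$log2_te_change)
  expr$te_class <- unname(truth$te_class)
  expr$utr_length <- unname(truth$utr_length)
  write_tsv(expr, file.path(dir, "truth_genes.tsv"))
  write_tsv(truth$tss, file.path(dir, "truth_tss.tsv"))
  write_tsv(truth$complexes, file.path(dir, "truth_complexes.tsv"))
  write_tsv(data.frame(key = names(truth$te_threshold),
                       value = unname(truth$te_threshold)),
            file.path(dir, "truth_threshold.tsv"))
  invisible(dir)
}

#' @rdname write_truth
#' @export
read_truth <- function(dir) {
  expr <- read_tsv(file.path(dir, "truth_genes.tsv"))
  mcols <- grep("^mrna_", names(expr), value = TRUE)
  tcols <- grep("^te_cond", names(expr), value = TRUE)
  mrna <- as.matrix(expr[, mcols, drop = FALSE])
  te <- as.matrix(expr[, tcols, drop = FALSE])
  dimnames(mrna) <- list(expr$gene_id, sub("^mrna_", "", mcols))
  dimnames(te) <- list(expr$gene_id, sub("^te_", "", tcols))
  thr <- read_tsv(file.path(dir, "truth_threshold.tsv"))
  list(
    mrna = mrna, te = te,
    log2_mrna_change = stats::setNames(expr$log2_mrna_change, expr$gene_id),
    log2_te_change = stats::setNames(expr$log2_te_change, expr$gene_id),
    te_class = stats::setNames(expr$te_class, expr$gene_id),
    te_threshold = stats::setNames(thr$value, thr$key),
    tss = read_tsv(file.path(dir, "truth_tss.tsv")),
    utr_length = stats::setNames(expr$utr_length, expr$gene_id),
    complexes = read_tsv(file.path(dir, "truth_complexes.tsv"))
  )
}

#' Write TSS records as BED6
#'
#' `name` is the category, `score` the enrichment ratio x 100 truncated,
#' single-base intervals in 0-based half-open BED convention.
#'
#' @param tss Categorized TSS data frame.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_tss_bed <- function(tss, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", SEQNAME, tss$pos, tss$pos + 1L,
                   tss$category %||% "N",
                   pmin(1000L, as.integer(trunc(tss$enrichment_ratio * 100))),
                   tss$strand)
  writeLines(lines, path)
  invisible(path)
}
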