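#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. Defaults describe
#' a small two-condition (heterotrophic vs autotrophic style) experiment
#' with biological duplicates, negative-binomial count noise, 3-nt
#' Ribo-Seq periodicity with a 17-nt 5'-end-to-A-site offset, dRNA-Seq TSS
#' enrichment of 8-fold, and a geometric 5'-UTR length law with median
#' 49 nt.
#'
#' @param genome_length Genome size in nt (circular; gene placement avoids
#'   the origin).
#' @param n_genes Number of protein-coding genes to place.
#' @param n_conditions Number of growth conditions (2).
#' @param replicates_per_condition Biological replicates per condition.
#' @param library_depth Expected total reads per library.
#' @param dispersion Negative-binomial overdispersion alpha
#'   (variance = mu + alpha mu^2); 0 gives Poisson counts.
#' @param frame0_fraction Probability that a footprint's A-site falls in
#'   frame 0 of its codon; must lie in \[1/3, 1\].
#' @param asite_offset 5'-end to A-site distance in nt.
#' @param tss_enrichment Expected RPP+/RPP- fold enrichment at true TSSs
#'   (must exceed 1).
#' @param tss_fraction Fraction of the RPP- library mass concentrated at
#'   true TSS positions; the remainder is a uniform background of
#'   processed 5' ends over both strands of the genome.
#' @param utr_median Median of the geometric 5'-UTR length distribution (nt).
#' @param te_mean,te_sd Centre and scale (log2) of the planted TE-change
#'   mixture; the planted class threshold is the analytic one-SD band of
#'   the full generative law (see [planted_te_threshold()]).
#' @param high_fraction,low_fraction Planted fractions of transcription
#'   units whose TE-change component is shifted to `te_mean + 2*te_sd`
#'   (high) or `te_mean - 2*te_sd` (low).
#' @param neutral_sd Log2 SD of the neutral TE-change component.
#' @param spike_sd Log2 SD around the high/low mixture centres.
#' @param buffering Planted translational-buffering coefficient: the TE
#'   log2 fold change receives `buffering * mrna_lfc` in addition to the
#'   mixture component.
#' @param mrna_lfc_sd Log2 SD of planted mRNA fold changes. The default
#'   1.62 makes the population Pearson correlation between mRNA change and
#'   TE change equal the buffering coefficient -0.5 exactly.
#' @param te_gene_sd Log2 SD of per-gene TE scatter within an operon.
#' @param utr_rpf_relative Per-condition ratio of 5'-UTR footprint density
#'   to CDS footprint density (length `n_conditions`).
#' @param mean_operon_size,max_operon_size Operon size law: sizes are
#'   `1 + Poisson(mean_operon_size - 1)` truncated at `max_operon_size`.
#' @param codon_range Range (codons, including the stop codon) of CDS
#'   lengths, drawn uniformly.
#' @param equimolar_fraction Probability that a multi-gene operon forms an
#'   equimolar (all copy numbers 1) complex; otherwise per-subunit copy
#'   numbers are sampled from `copy_levels`.
#' @param copy_levels Candidate subunit copy numbers for non-equimolar
#'   complexes.
#' @param sd_motif Shine-Dalgarno hexamer planted upstream of start codons
#'   of high-TE genes.
#' @param seed Master seed; all per-library seeds derive from it
#'   deterministically.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 400000L,
                       n_genes = 200L,
                       n_conditions = 2L,
                       replicates_per_condition = 2L,
                       library_depth = 1e6,
                       dispersion = 0.1,
                       frame0_fraction = 0.7,
                       asite_offset = 17L,
                       tss_enrichment = 8,
                       tss_fraction = 0.05,
                       utr_median = 49,
                       te_mean = 0.1,
                       te_sd = 1.4,
                       high_fraction = 0.16,
                       low_fraction = 0.08,
                       neutral_sd = 0.5,
                       spike_sd = 0.3,
                       buffering = -0.5,
                       mrna_lfc_sd = 1.62,
                       te_gene_sd = 0.1,
                       utr_rpf_relative = c(0.48, 1.38),
                       mean_operon_size = 2,
                       max_operon_size = 10L,
                       codon_range = c(60L, 200L),
                       equimolar_fraction = 0.6,
                       copy_levels = c(1L, 2L, 3L, 4L),
                       sd_motif = "AGGAGG",
                       seed = 1L) {
  cfg <- list(
    genome_length = as.integer(genome_length), n_genes = as.integer(n_genes),
    n_conditions = as.integer(n_conditions),
    replicates_per_condition = as.integer(replicates_per_condition),
    library_depth = library_depth, dispersion = dispersion,
    frame0_fraction = frame0_fraction, asite_offset = as.integer(asite_offset),
    tss_enrichment = tss_enrichment, tss_fraction = tss_fraction,
    utr_median = utr_median, te_mean = te_mean, te_sd = te_sd,
    high_fraction = high_fraction, low_fraction = low_fraction,
    neutral_sd = neutral_sd, spike_sd = spike_sd, buffering = buffering,
    mrna_lfc_sd = mrna_lfc_sd, te_gene_sd = te_gene_sd,
    utr_rpf_relative = utr_rpf_relative,
    mean_operon_size = mean_operon_size,
    max_operon_size = as.integer(max_operon_size),
    codon_range = as.integer(codon_range),
    equimolar_fraction = equimolar_fraction,
    copy_levels = as.integer(copy_levels),
    sd_motif = toupper(sd_motif), seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$genome_length <= 0) stop2("genome_length must be positive")
  if (cfg$n_genes < 0) stop2("n_genes must be non-negative")
  if (cfg$n_conditions < 1) stop2("n_conditions must be >= 1")
  if (cfg$replicates_per_condition < 1) stop2("replicates_per_condition must be >= 1")
  if (cfg$dispersion < 0) stop2("dispersion must be non-negative")
  if (cfg$frame0_fraction < 1 / 3 || cfg$frame0_fraction > 1) {
    stop2("frame0_fraction must lie in [1/3, 1]")
  }
  if (cfg$asite_offset < 0) stop2("asite_offset must be non-negative")
  if (cfg$tss_fraction <= 0 || cfg$tss_fraction >= 1) {
    stop2("tss_fraction must lie in (0, 1)")
  }
  if (length(cfg$utr_rpf_relative) != cfg$n_conditions) {
    stop2("utr_rpf_relative must have one entry per condition")
  }
  if (cfg$high_fraction + cfg$low_fraction >= 1) {
    stop2("high_fraction + low_fraction must be < 1")
  }
  if (cfg$codon_range[1] < 11) stop2("codon_range minimum must be >= 11 codons")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome %d nt, %d genes, %d condition(s) x %d replicate(s)\n",
              x$genome_length, x$n_genes, x$n_conditions, x$replicates_per_condition))
  cat(sprintf("  depth %.3g, dispersion %.3g, frame0 %.2f, A-site offset %d nt\n",
              x$library_depth, x$dispersion, x$frame0_fraction, x$asite_offset))
  cat(sprintf("  TSS enrichment %.1fx, UTR median %.0f nt, TE mixture mu=%.2f sd=%.2f, seed %d\n",
              x$tss_enrichment, x$utr_median, x$te_mean, x$te_sd, x$seed))
  invisible(x)
}
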