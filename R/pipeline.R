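#' Load a pipeline configuration from YAML
#'
#' The YAML file holds [sim_config()] fields plus optional analysis
#' overrides (`min_ratio`, `min_density`, `merge_window`, `upstream`,
#' `downstream`, `te_floor`, `promoter_length`).
#'
#' @param path YAML file.
#' @return A list with `sim` (a `sim_config`) and `params` (analysis
#'   parameters with defaults filled in).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop2(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  sim_fields <- intersect(names(y), names(formals(sim_config)))
  sim <- do.call(sim_config, y[sim_fields])
  params <- analysis_params(y)
  list(sim = sim, params = params)
}

analysis_params <- function(y = list()) {
  list(min_ratio = y$min_ratio %||% 2,
       min_density = y$min_density %||% 10,
       merge_window = y$merge_window %||% 4L,
       upstream = y$upstream %||% 300L,
       downstream = y$downstream %||% 100L,
       te_floor = y$te_floor %||% 1,
       promoter_length = y$promoter_length %||% 50L)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Simulates an experiment, writes the raw inputs (FASTA, GFF3, bedGraph
#' tracks, truth tables), then runs quantification, differential
#' expression, TE classification, TSS calling/merging/categorization,
#' 5'-UTR assignment and analysis, promoter extraction and stoichiometry
#' diagnostics, writing one TSV per stage plus a JSON manifest with the
#' parameters, seed and per-stage row counts. Identical config and seed
#' give byte-identical outputs.
#'
#' @param config A [sim_config()], a list as returned by [load_config()],
#'   or a path to a YAML config file.
#' @param outdir Output directory (created; existing files overwritten).
#' @param seed Optional master seed overriding the config's.
#' @return Invisibly, a list with the principal in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config, outdir, seed = NULL) {
  if (is.character(config)) config <- load_config(config)
  if (inherits(config, "sim_config")) config <- list(sim = config,
                                                     params = analysis_params())
  cfg <- config$sim
  par <- config$params
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  exp <- simulate_experiment(cfg)
  genome <- exp$genome
  genes <- genome$genes

  # ---- raw inputs -------------------------------------------------------
  write_genome_fasta(genome, file.path(outdir, "genome.fasta"))
  write_annotation(genes, file.path(outdir, "annotation.gff3"), genome$genome_length)
  write_truth(genome$truth, file.path(outdir, "truth"))
  for (cc in seq_len(cfg$n_conditions)) {
    for (r in seq_along(exp$rna[[cc]])) {
      write_track(exp$rna[[cc]][[r]],
                  file.path(outdir, sprintf("rna_c%d_r%d", cc, r)))
      write_track(exp$ribo[[cc]][[r]],
                  file.path(outdir, sprintf("rpf_c%d_r%d", cc, r)))
    }
    write_track(exp$drna[[cc]]$rpp_plus, file.path(outdir, sprintf("drna_rppplus_c%d", cc)))
    write_track(exp$drna[[cc]]$rpp_minus, file.path(outdir, sprintf("drna_rppminus_c%d", cc)))
  }

  # ---- quantification ---------------------------------------------------
  flat <- function(tl) {
    out <- list()
    for (cc in seq_along(tl)) for (r in seq_along(tl[[cc]])) {
      out[[tl[[cc]][[r]]$library]] <- tl[[cc]][[r]]
    }
    out
  }
  rna_tracks <- flat(exp$rna)
  rpf_tracks <- flat(exp$ribo)
  cond_of <- function(tracks) sub(".*_c(\\d+)_r\\d+$", "cond\\1", names(tracks))
  ct_rna <- count_table(rna_tracks, genes, cond_of(rna_tracks), assay = "RNA")
  ct_rpf <- count_table(rpf_tracks, genes, cond_of(rpf_tracks), assay = "RPF",
                        asite_offset = cfg$asite_offset)
  lens <- stats::setNames(genes$length, genes$gene_id)
  rpkm_rna <- compute_rpkm(ct_rna, lens)
  rpkm_rpf <- compute_rpkm(ct_rpf, lens)
  write_tsv(data.frame(gene_id = genes$gene_id, ct_rna$counts, check.names = FALSE),
            file.path(outdir, "counts_rna.tsv"))
  write_tsv(data.frame(gene_id = genes$gene_id, ct_rpf$counts, check.names = FALSE),
            file.path(outdir, "counts_rpf.tsv"))
  write_tsv(data.frame(gene_id = genes$gene_id, round(rpkm_rna, 4), check.names = FALSE),
            file.path(outdir, "rpkm_rna.tsv"))
  write_tsv(data.frame(gene_id = genes$gene_id, round(rpkm_rpf, 4), check.names = FALSE),
            file.path(outdir, "rpkm_rpf.tsv"))

  de_rna <- differential_expression(ct_rna)
  de_rpf <- differential_expression(ct_rpf)
  write_tsv(de_rna, file.path(outdir, "de_rna.tsv"))
  write_tsv(de_rpf, file.path(outdir, "de_rpf.tsv"))

  # ---- translation efficiency -------------------------------------------
  cond_mean <- function(rpkm, conds) {
    vapply(unique(conds), function(cc) {
      rowMeans(rpkm[, conds == cc, drop = FALSE])
    }, numeric(nrow(rpkm)))
  }
  mrna_mean <- cond_mean(rpkm_rna, ct_rna$samples$condition)
  rpf_mean <- cond_mean(rpkm_rpf, ct_rpf$samples$condition)
  te <- compute_te(rpf_mean, mrna_mean, floor = par$te_floor)
  te_fit <- classify_te_changes(te$log2_te_change)
  mrna_lfc <- log2(mrna_mean[, 2] / mrna_mean[, 1])
  buf <- buffering_correlation(mrna_lfc, te$log2_te_change)
  write_tsv(data.frame(gene_id = rownames(te$te), round(te$te, 4),
                       log2_te_change = round(te$log2_te_change, 4),
                       class = as.character(te_fit$class), check.names = FALSE),
            file.path(outdir, "te.tsv"))

  # ---- TSS calling ------------------------------------------------------
  cand <- lapply(seq_len(cfg$n_conditions), function(cc) {
    nt <- normalize_tracks(exp$drna[[cc]]$rpp_plus, exp$drna[[cc]]$rpp_minus)
    call_tss(nt$rpp_plus, nt$rpp_minus, min_ratio = par$min_ratio,
             min_density = par$min_density, library = sprintf("cond%d", cc))
  })
  tss <- merge_tss(cand, window = par$merge_window)
  tss <- categorize_tss(tss, genes, upstream = par$upstream,
                        downstream = par$downstream)
  utrs <- assign_utr(tss, genes, genome)
  promoters <- extract_promoters(tss, genome, length = par$promoter_length)
  write_tss_bed(tss, file.path(outdir, "tss.bed"))
  write_tsv(tss, file.path(outdir, "tss.tsv"))
  write_tsv(utrs, file.path(outdir, "utr.tsv"))
  writeLines(paste0(">", names(promoters$sequences), "\n", promoters$sequences),
             file.path(outdir, "promoters.fasta"))

  # ---- UTR / metagene analyses ------------------------------------------
  pool <- function(tracks) {
    plus <- Reduce(`+`, lapply(tracks, function(t) t$plus))
    minus <- Reduce(`+`, lapply(tracks, function(t) t$minus))
    fp_track(plus, minus, library = "pooled")
  }
  occ <- list()
  mg <- list()
  for (cc in seq_len(cfg$n_conditions)) {
    ribo_pool <- asite_track(pool(exp$ribo[[cc]]), cfg$asite_offset)
    rna_pool <- pool(exp$rna[[cc]])
    mg[[cc]] <- metagene(ribo_pool, genes)
    occ[[cc]] <- utr_occupancy(ribo_pool, rna_pool, utrs, genes)
  }
  folds <- vapply(utrs$sequence[utrs$length >= 5], function(s) fold_mfe(s)$energy,
                  numeric(1))
  names(folds) <- utrs$gene_id[utrs$length >= 5]
  sd <- sd_score(stats::setNames(utrs$sequence, utrs$gene_id))
  write_tsv(data.frame(gene_id = names(folds), energy = unname(folds),
                       sd_score = unname(sd$scores[names(folds)])),
            file.path(outdir, "utr_features.tsv"))
  occ_df <- do.call(rbind, lapply(seq_along(occ), function(cc) {
    data.frame(condition = sprintf("cond%d", cc),
               median_utr_ratio = occ[[cc]]$median_utr_ratio,
               median_cds_ratio = occ[[cc]]$median_cds_ratio,
               median_ratio_of_ratios = occ[[cc]]$median_ratio_of_ratios,
               wilcoxon_p = occ[[cc]]$wilcoxon_p)
  }))
  write_tsv(occ_df, file.path(outdir, "utr_occupancy.tsv"))

  # ---- stoichiometry ----------------------------------------------------
  rpf_lvl <- rpf_mean[, min(2, ncol(rpf_mean))]
  cpx <- genome$truth$complexes
  stoich <- NULL
  if (nrow(cpx) > 0) {
    stoich <- stoichiometry_correlation(cpx, rpf_lvl)
    cvs <- vapply(split(cpx$gene_id, cpx$complex_id), function(gid) {
      subunit_cv(rpf_lvl[gid])
    }, numeric(1))
    write_tsv(data.frame(complex_id = names(cvs), cv_percent = round(unname(cvs), 2)),
              file.path(outdir, "complex_cv.tsv"))
    write_tsv(stoich$per_complex, file.path(outdir, "stoichiometry.tsv"))
  }
  fs <- tryCatch(first_second_gene_correlation(genes, rpf_lvl), error = function(e) NULL)

  # ---- manifest ---------------------------------------------------------
  outputs <- sort(setdiff(list.files(outdir, recursive = TRUE), "manifest.json"))
  manifest <- list(
    package = "ribotrans",
    version = as.character(utils::packageVersion("ribotrans")),
    seed = cfg$seed,
    parameters = c(unclass(cfg), par),
    stages = list(
      genes = nrow(genes), tss_called = nrow(tss), utrs = nrow(utrs),
      de_rna_significant = sum(de_rna$significant),
      de_rpf_significant = sum(de_rpf$significant),
      te_high = unname(te_fit$counts["high"]),
      te_low = unname(te_fit$counts["low"]),
      buffering_r = buf$r
    ),
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(outdir, outputs))), outputs))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(genome = genome, counts = list(rna = ct_rna, rpf = ct_rpf),
                 rpkm = list(rna = rpkm_rna, rpf = rpkm_rpf),
                 de = list(rna = de_rna, rpf = de_rpf),
                 te = te, te_fit = te_fit, buffering = buf,
                 tss = tss, utrs = utrs, promoters = promoters,
                 metagene = mg, occupancy = occ, folds = folds, sd = sd,
                 stoichiometry = stoich, first_second = fs,
                 manifest = manifest))
}
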