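# ribotrans

Gene-level analysis of condition-paired bacterial **RNA-Seq**, **ribosome
profiling (Ribo-Seq)** and **differential RNA-Seq (dRNA-Seq)** data, with a
synthetic-data generator that plants known ground truth for end-to-end
validation.

## The scientific problem

Bacteria growing under energy limitation (the classic contrast is
heterotrophic growth on a sugar versus autotrophic growth on H₂ + CO₂ in
acetogens) reallocate their translational capacity: the same transcript can
be translated at very different rates under the two conditions. Detecting
that regulation requires integrating three layers of sequencing data:

* **RNA-Seq** measures the mRNA level of each gene,
  `RPKM = 10⁹ · reads_gene / (total mapped reads · gene length)`.
* **Ribo-Seq** measures the translation level from ribosome-protected
  fragments (RPFs). Footprint 5′ ends are shifted a fixed 17 nt downstream
  to the ribosomal A-site; A-sites in the first and last 5 codons are
  excluded to remove initiation/termination artifacts. The 3-nt
  periodicity of A-sites (frame-0 fraction) is the standard quality
  signature of genuine elongating ribosomes.
* **dRNA-Seq** compares 5′-pyrophosphatase-treated (RPP⁺) and untreated
  (RPP⁻) libraries. Primary transcript 5′ ends (5′-PPP) are enriched in
  RPP⁺, so positions where the normalized density ratio RPP⁺/RPP⁻ exceeds 2
  mark transcription start sites (TSSs), which are then categorized as
  primary/secondary/internal/antisense/intergenic against the annotation
  and yield 5′-UTR coordinates.

From these layers the package computes, per gene *g* and condition *c*:

* translation efficiency `TE_g,c = RPKM_RPF / RPKM_RNA`;
* the log₂ TE change between conditions, classified **high** / **neutral**
  / **low** with a Gaussian fit: genes beyond μ ± 1σ of the fitted log₂
  TE-change distribution are translationally regulated;
* translational buffering, the Pearson correlation between mRNA log₂ fold
  change and TE log₂ fold change (negative r = buffering);
* 5′-UTR diagnostics: ribosome occupancy (RPF/RNA density ratio) in UTRs
  versus coding sequences, minimum-free-energy folding (Nussinov base-pair
  maximization internally, ViennaRNA `RNAfold` as a pluggable
  thermodynamic engine), and Shine–Dalgarno anti-SD complementarity
  scores;
* operon/complex stoichiometry: subunit coefficient of variation
  (SD/mean·100), correlation of translation levels with subunit copy
  numbers, and first-versus-second operon gene correlation.

Normalization between samples uses DESeq2-style median-of-ratios size
factors; simple differential-expression calls use a two-sided binomial
rate-ratio test with Benjamini–Hochberg correction and the conventional
thresholds `p_adj < 0.01` and `|log₂ FC| > 1`.

## Worked example

```r
library(ribotrans)

cfg <- sim_config(n_genes = 100, library_depth = 1e6, seed = 42)
exp <- simulate_experiment(cfg)          # genome + RNA/Ribo/dRNA tracks
g   <- exp$genome
#> <synthetic_genome> 400000 nt (circular), 100 genes in 51 operons, 51 planted TSSs

# quantification -> condition-mean RPKM -> TE classification
conds <- rep(c("cond1", "cond2"), each = 2)
tr <- unlist(exp$rna,  recursive = FALSE); names(tr) <- sapply(tr, `[[`, "library")
tp <- unlist(exp$ribo, recursive = FALSE); names(tp) <- sapply(tp, `[[`, "library")
lens   <- setNames(g$genes$length, g$genes$gene_id)
rk_rna <- compute_rpkm(count_table(tr, g$genes, conds, "RNA"), lens)
rk_rpf <- compute_rpkm(count_table(tp, g$genes, conds, "RPF"), lens)
mm <- sapply(unique(conds), function(cc) rowMeans(rk_rna[, conds == cc]))
pm <- sapply(unique(conds), function(cc) rowMeans(rk_rpf[, conds == cc]))
te  <- compute_te(pm, mm)
fit <- classify_te_changes(te$log2_te_change)
fit
#> <te_fit> n=100 (100 defined): mu=0.470 sigma=1.855 (log2)
#>   thresholds: low < -1.385, high > 2.324
#>   high 16 (16.0%), neutral 72, low 12 (12.0%), undefined 0

buffering_correlation(log2(mm[, 2] / mm[, 1]), te$log2_te_change)$r
#> [1] -0.6975817    # negative: translational buffering

# dRNA-Seq TSS calling and 5' UTRs
nt  <- normalize_tracks(exp$drna[[1]]$rpp_plus, exp$drna[[1]]$rpp_minus)
tss <- categorize_tss(merge_tss(call_tss(nt$rpp_plus, nt$rpp_minus)), g$genes)
table(tss$category)
#>  P
#> 50                  # 50 of the 51 planted TSSs, all primary
utrs <- assign_utr(tss, g$genes, g)
median(utrs$length)
#> [1] 62              # nt; the generator's length law has median 49

# Ribo-Seq periodicity
metagene(asite_track(exp$ribo[[1]][[1]], 17), g$genes)
#> <metagene_profile> 100 genes, offsets -30..60; frames f0=0.701 f1=0.150 f2=0.149
```

The fitted mu/sigma, the ~16% high-TE tail, the negative buffering
correlation and the 0.70 frame-0 fraction all recover the parameters the
generator planted. `run_pipeline(cfg, "out/")` executes every stage and
writes TSV/BED/FASTA outputs plus a JSON manifest; reruns with the same
seed are byte-identical. A YAML-driven command-line wrapper is installed
at `inst/scripts/pipeline.R`.

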