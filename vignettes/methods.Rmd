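---
title: "Models and methods behind ribotrans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ribotrans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ribotrans analyses condition-paired bacterial transcriptome/translatome
experiments: RNA-Seq for mRNA levels, ribosome profiling (Ribo-Seq) for
translation levels, and differential RNA-Seq (dRNA-Seq) for transcription
start sites (TSSs) and 5′ UTRs. This vignette documents the statistical
models, the tunable parameters, the synthetic-data generator, and the
numerical decisions taken where a choice was genuinely open.

## Quantification model

All coordinates are 0-based half-open internally; GFF3 (1-based closed)
and bedGraph (0-based half-open) conventions are converted at the I/O
boundary, and the conversions are bijective.

**Counting.** An RNA-Seq read is assigned to a gene when its 5′ end falls
in the gene body on the coding strand. A Ribo-Seq footprint is assigned by
its ribosomal A-site — the 5′ end shifted `asite_offset` (default 17 nt,
the empirical distance between bacterial footprint 5′ ends and the A-site)
toward 3′ on the coding strand — and is counted only when the A-site lies
in codons 6 … L/3 − 5, excluding five codons at each end to remove
initiation and termination peaks. Genes shorter than 11 codons cannot hold
that window and count 0 with a warning. Counting by A-site (rather than by
raw 5′ end) is the choice consistent with the 17-nt adjustment; it is what
makes the codon-exclusion window meaningful.

**RPKM.** `RPKM = 10⁹·n_gene/(N·L)` with `N` the per-sample total. The
definition of "total mapped reads" is ambiguous between genome-wide and
genic totals; the package defaults to the column sum of the gene count
table (genic total) and lets the caller pass library-wide totals. RPKM is
invariant to duplicating every read, and zero iff the count is zero.

**Normalization and differential calls.** Between-sample normalization is
the median-of-ratios size factor: the median over genes expressed in every
sample of the count divided by the gene's geometric mean, rescaled to
geometric mean 1. Even-count medians are interpolated on the log scale,
the convention of the reference Bioconductor implementation (the linear
interpolation differs only in ties); tests verify exact agreement with
DESeq2's `estimateSizeFactorsForMatrix`. Differential expression uses a
deliberately simple, fully documented test instead of a negative-binomial
GLM: normalized counts are summed per condition and compared with a
two-sided binomial rate-ratio test whose null share reflects the replicate
numbers, followed by Benjamini–Hochberg adjustment. Significance requires
`p_adj < 0.01` and `|log₂ FC| > 1` (pseudocount 1 on the normalized scale
before the fold change). The binomial test is anti-conservative relative
to a dispersion-aware GLM when biological variability is large; it is kept
because the package's inferential load rests on effect sizes and
thresholds, not on borderline p-values, and because replicate-aware GLM
machinery is out of scope by design.

## Translation efficiency

`TE = RPKM_RPF / RPKM_RNA` per condition, computed on condition-mean RPKM
across replicates (per-replicate TEs remain available for diagnostics).
Genes with `RPKM_RNA` below an expression floor (default 1; low mRNA makes
the ratio unstable) are `undefined` and excluded downstream. The log₂ TE
change (condition 2 vs 1) is classified by a Gaussian one-standard-
deviation rule: μ and σ are estimated by the sample mean and SD (the
deterministic equivalent of fitting a Gaussian curve; a trimmed variant is
available behind the `trim` flag), and genes beyond μ ± σ are `high` or
`low`. Under a pure normal distribution this labels ≈15.9% of genes high,
which is why empirical high fractions near 16% are the expected outcome of
the rule rather than a biological constant. Classification is invariant
under a constant shift of all changes; both "fraction of all genes" and
"fraction of defined genes" are reported since the denominator convention
is ambiguous.

Translational buffering is the Pearson correlation between mRNA log₂
changes and TE log₂ changes; gene-set enrichment on user-supplied sets is
a hypergeometric upper tail with Bonferroni correction (the convention for
small curated pathway panels).

## TSS calling from dRNA-Seq

Both libraries are scaled to counts per million (CPM). A position is a
candidate TSS when `(RPP⁺ + ε)/(RPP⁻ + ε) > min_ratio` (default 2) and the
RPP⁺ density is at least `min_density` (default 10 CPM). The pseudocount
ε = 0.5 handles RPP⁻ = 0 positions; the density floor replaces the manual
curation a human analyst would apply. Candidates reduce to local maxima of
RPP⁺ density within ±4 nt (plateau ties keep the most upstream
coordinate). Candidates from multiple libraries merge by single-linkage
clustering at ±4 nt — chains longer than 9 nt are not split, a documented
choice — with the merged record at the position of highest summed density;
the output never contains two records within 4 nt on one strand, and
merging is idempotent.

Categorization against the annotation: among same-strand TSSs from
< 300 nt upstream to ≤ 100 nt downstream of a gene start, the densest is
primary (P; density ties go to the most upstream), the rest secondary (S);
TSSs inside a gene body beyond that window are internal (I) on the same
strand or antisense (A) opposite; everything else is intergenic (N).
Because the raw rules overlap, a fixed priority P > S > I > A > N makes
the partition total — every TSS gets exactly one category. 5′ UTRs run
from a primary TSS to the start codon (length 0 = leaderless; records
upstream-of-start only, the downstream window rule absorbs the rest), and
promoter analysis extracts 50 nt upstream of each TSS and scans for the
σ⁷⁰ −10 (TATAAT) and −35 (TTGACA) hexamers with ≤ 1 mismatch — a consensus
scan, not de-novo motif discovery.

## 5′-UTR analyses

**Occupancy.** Per-gene RPF and RNA densities (counts per nt) are computed
in the UTR (TSS to start codon, excluding the start codon) and in the CDS
(codon-trimmed window for RPF, full ORF for RNA — matching the counting
module), from the same libraries. The per-nt density convention (rather
than raw counts) and the per-gene (rather than pooled) medians are the
two places the published procedure is under-specified; both choices are
recorded here. UTR and CDS RPF/RNA ratios are compared with a paired
two-tailed Wilcoxon signed-rank test; `stats::wilcox.test` already
implements the exact-small-n/normal-approximation policy, so it is used
rather than reimplemented, with p = 1 returned for the degenerate all-zero
difference case.

**Folding.** The internal engine is Nussinov base-pair maximization
(pairs AU/GC/GU, minimum hairpin loop 3 nt, O(n³) dynamic program with
traceback) reporting −(pair count) as an energy proxy — deliberately not
kcal/mol. A thermodynamic engine plugs in as a function; `rnafold_engine()`
wraps ViennaRNA's RNAfold when the binary is on the PATH. The fixed
−30 kcal/mol "structured UTR" threshold is only meaningful with a
thermodynamic engine; with the internal proxy the cohort median is used as
the split. Group TE-change comparisons use the two-tailed Wilcoxon
rank-sum test and require ≥ 3 genes per group.

**Shine–Dalgarno.** The anti-SD is the 16S rRNA 3′ tail written 3′→5′
(`AUUCCUCCAC`) so it aligns base-by-base with the mRNA read 5′→3′; the
score is the longest contiguous run of Watson–Crick or G:U pairs over all
alignment offsets within the −20…−5 window (AGGAGG scores 6, poly-C
scores 0). Sequences shorter than the window are scored on the available
span and flagged. Cohort position-frequency matrices use a 0.25
pseudocount per base for the information content.

## Stoichiometry diagnostics

Subunit balance uses the ordinary coefficient of variation, sample
(n−1) SD / mean × 100 — "SD of the mean × 100" in the informal phrasing —
which is scale-invariant. Copy-number proportionality is the Pearson
correlation and through-origin slope of (copy number, RPKM_RPF) per
complex, with the two-subunit ratio reported directly; complexes with
constant copy numbers are flagged rather than given an undefined r.
First/second operon-gene correlation is computed on log₁₀ expression,
matching how such data are conventionally displayed.

## The synthetic-data generator

The generator is first-class, tested code: it plants a complete ground
truth and every recovery analysis in the package is validated against it.

* **Genome**: circular, default 400 kb with 200 genes (CDS 60–200 codons,
  uniform) in operons of 1 + Poisson(1) genes (≤ 10); placement avoids
  wrapping the origin for simplicity. Start/stop codons sit exactly at the
  annotated bounds; σ⁷⁰ boxes are written at −12…−7 and −37…−32 of every
  TSS, and an AGGAGG hexamer at −12…−7 of start codons of high-TE genes.
* **Expression**: genes in an operon share one transcript abundance
  (polycistronic mRNA); translation efficiency carries per-gene signal
  (subunit copy numbers, small log-normal scatter). mRNA log₂ fold changes
  are N(0, 1.62²); TE log₂ fold changes are `buffering·Δmrna + mixture`
  with buffering −0.5 and a mixture of neutral N(0.1, 0.5²) and high/low
  spikes at 0.1 ± 2·1.4 (fractions 16%/8%, spike SD 0.3). The mRNA SD
  1.62 is derived so the population Pearson correlation between mRNA and
  TE change equals the buffering coefficient −0.5 exactly:
  r = b·σ_m/√(b²σ_m² + σ_mix²) = −0.5 requires σ_mix² = 3·b²σ_m².
  The planted class threshold is the analytic one-SD band of this full
  generative law (`planted_te_threshold()`), so planted labels and the
  fitted one-SD rule agree at scale. The realized one-SD rule labels
  ≈16% high but ≈12–13% low — the buffering term and the neutral tail
  leak asymmetrically across the shifted thresholds — so the high/low
  asymmetry of real data is only partly reproduced.
* **Counts**: library depth is apportioned to genes by abundance × length
  (RNA) or abundance × TE × CDS length (Ribo); realized counts are
  negative binomial with variance μ + αμ² (α = 0.1 by default; α = 0 is
  Poisson), positions uniform within the transcript (RNA) or uniform over
  codons with the A-site in frame 0 with probability `frame0_fraction`
  (default 0.7) and the 5′ end written 17 nt upstream. Leader genes also
  receive 5′-UTR footprints at a per-condition density relative to CDS
  (defaults 0.48 and 1.38 — UTR ribosome occupancy roughly half the CDS
  under the reference condition and ~2.9-fold higher under the second).
* **dRNA-Seq**: the untreated library puts 5% of its mass on TSS peaks
  and the rest as a uniform background of processed 5′ ends over both
  strands of the whole genome (the background distribution is unknown;
  uniform is the assumption). The treated library has the same expected
  background and `tss_enrichment` (default 8) times the untreated
  expected density at each TSS, so the raw expected ratio at a TSS equals
  the enrichment exactly. The 5% TSS share and the 400 kb/10⁶-read default
  scale come from a ratio-noise analysis: after CPM normalization the
  observed TSS ratio is E/(1 + f(E−1)) ≈ 5.9, about 2.4 multiplicative
  SDs above the >2 cutoff under α = 0.1 noise, while the background
  (≈1.2 CPM) stays far below the 10-CPM density floor. Genomes much
  smaller than ~400 kb necessarily push the uniform background toward the
  density floor, and TSS calling becomes noisy — visible in any small demo.
* **UTR lengths** are geometric with exact median 49 nt (configurable).
* **Determinism**: every library draws from a child seed derived from the
  master seed and a stream label, so identical configurations are
  bit-identical regardless of caller RNG state, and the full pipeline is
  byte-deterministic.

What the generator does **not** emulate: sequencing errors, adapters, rRNA
contamination or read-level artifacts (tracks, not FASTQ, are the entry
point); non-uniform coverage biases along transcripts; processed-end
hotspots in the RPP⁻ library; condition-specific TSS switching; overlap
between genes. Passing recovery tests therefore demonstrates correctness
of the estimators under the stated noise model, not robustness to every
artifact of real libraries.

## Validation conditions and problem sizes

The validation suite runs at sizes chosen to make each check informative:
TSS recovery at 200 single-gene transcription units, 10⁶ reads, 8-fold
enrichment and NB dispersion 0.1 (sensitivity/precision ≥ 0.95); TE and
stoichiometry recovery at 10⁶ reads in the Poisson limit (dispersion 0) —
biological overdispersion is a depth-independent noise floor (CV ≈ √α per
measurement, ≈0.63 log₂ units across the four RPKM terms of a TE change
with two replicates), so estimator-accuracy checks that should be limited
by sequencing depth are run without it, while the TSS check keeps α = 0.1
because peak calling must tolerate it; periodicity at planted frame-0
fraction 0.7 and 10⁶ reads; folding against exhaustive enumeration for all
tested sequences up to 12 nt; categorization against an independently
coded rule oracle on 1 000 random layouts. The demo pipeline (100 genes,
400 kb, 10⁶ reads per library) runs in about a minute on one CPU.

## Known limitations

* The binomial rate-ratio test ignores biological dispersion; with α ≈ 0.1
  and duplicate libraries its p-values are optimistic. Thresholded calls
  at |log₂ FC| > 1 remain conservative in practice, but users needing
  calibrated inference should feed the count tables to a NB GLM.
* The internal folding proxy ranks structure content but is not an energy;
  the −30 kcal/mol literature threshold applies only with RNAfold.
* dRNA-Seq merging is single-linkage; a dense run of candidates can chain
  beyond ±4 nt of the extremes (kept, flagged in the documentation).
* TE values depend multiplicatively on library composition (e.g. the
  share of footprints in UTRs), which shifts all log₂ TE changes by a
  constant; the one-SD rule is invariant to such shifts, but absolute TE
  values are in arbitrary units by construction.
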