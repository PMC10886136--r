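---
title: "The cgpkit decision engine: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cgpkit decision engine: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgpkit)
```

# Scope

`cgpkit` implements the decision layer of a tumor-normal comprehensive
genomic profiling (CGP) assay built on a hybridization panel of 473
cancer-relevant genes with a 1.7 Mb coding footprint, together with a
personalized circulating tumor DNA (ctDNA) tracking arm. The package starts
*after* alignment, duplicate marking, variant calling and annotation: its
inputs are annotated variant calls (VCF), the panel definition (BED),
binned depth profiles (TSV), microsatellite repeat-length count tables
(TSV), breakpoint-spanning read evidence (TSV) and ultra-deep plasma
amplicon pileups (TSV). Every input can be produced, with a known truth, by
the package's own seeded generators, so the full engine is testable offline.

# Sample QC gate

A tumor sample enters analysis only when its mean on-target depth is at
least 150X **and** at least 75% of panel bases are covered at 100X or more;
both comparisons are inclusive (`qc_gate()`). Samples failing the gate are
reported with a QC-only block — downstream biomarkers are withheld rather
than emitted as negatives.

# Tumor mutational burden

TMB is the count of eligible somatic variants divided by the effective
panel size in megabases. A variant is eligible when it (1) passed caller
filters, (2) is not a likely germline variant (population-database flag),
(3) lies in a coding region, (4) is non-synonymous, and (5) has VAF ≥ 5%,
allele depth ≥ 5 reads and total depth ≥ 15 reads — all bounds inclusive.
The effective panel size counts coding panel bases with total depth ≥ 15X,
so a poorly covered sample is penalized in the denominator rather than
diluted to an artificially low score; a zero effective size is an error,
never a TMB of 0. Samples classify TMB-High at ≥ 10 mutations/Mb. The
score is computed as `count * 1e6 / bases` (integers first) so that
boundary cases such as 17 mutations over 1,700,000 bases give exactly 10.0
rather than a value a few ulps below the threshold.

## In-silico dilution experiment

`tmb_stability_experiment()` emulates mixing tumor sequencing material with
matched-normal material at ratios 3:1, 1:1, 2:3, 3:7, 1:4 and 1:9 (tumor
fractions 75% down to 10%), then downsampling to a grid of mean depths.
Mixing operates on per-site allele counts: the sampled depth at a site is
split binomially between the two source pools at the tumor fraction, and
alleles are drawn without replacement (hypergeometrically) from each pool's
observed alt/ref reads, so a planted VAF scales by the tumor fraction in
expectation with binomial sampling noise. Requesting more reads than a
source pool holds is an error — the dilution fixture therefore carries a
deep source depth (5000X per site).

The stability fixture plants 51 eligible variants (truth TMB 30 on 1.7 Mb)
at tissue VAFs uniform on 0.20–0.40, the range typical of clonal somatic
variants in a tumor-rich FFPE section; at a 30% tumor fraction these dilute
to 6–12%, which keeps them above the 5% eligibility cutoff up to binomial
dropout. That choice makes the qualitative behaviour reproducible: TMB
stays within 20% of truth for tumor fraction ≥ 0.30 at ≥ 150X, while
variants planted at tissue VAF 0.10 dilute to 1% at fraction 0.10 and the
score collapses toward zero. Coverage for the dilution grid is simulated on
500 bp windows with negative-binomial noise (size 20), a mild
over-dispersion chosen to emulate FFPE coverage variability; the acceptance
grid uses 10–20 replicates per point.

# Microsatellite instability

The NGS caller works from tumor and normal repeat-length read-count
distributions per microsatellite locus. The per-locus decision is a
deliberate, testable surrogate for the behaviour of dedicated MSI callers
(whose internals are not part of this package's contract): a locus is
unstable when a two-sample chi-squared test on the two length histograms
rejects at `alpha = 0.05` **and** the tumor modal length differs from the
normal modal length. Adjacent length bins are merged until every expected
cell count reaches 5, the standard validity condition for the chi-squared
approximation; a locus collapsing to a single bin is stable. The modal-shift
requirement suppresses false rejections from dispersion-only differences.
Loci with fewer than 20 reads in either sample are "not detected" and are
excluded from both numerator and denominator — the MSI proportion is taken
over *detected* loci. A sample is MSI-High when ≥ 20% (inclusive) of
detected loci are unstable; zero detected loci give `uncallable`, never MSS.

The orthogonal PCR classifier takes the five mononucleotide markers
(BAT-25, BAT-26, MONO-27, NR-21, NR-24) and calls MSI-High at ≥ 2 altered
markers.

# Copy-number amplification

Ninety normal (white blood cell) coverage profiles on a 100 bp bin grid
build the panel-of-normals baseline: each sample is library-size normalized
(scaled to equal total on-target coverage), the per-bin reference level is
the median across normals and the dispersion its MAD; bins with zero median
are masked. A tumor sample is normalized the same way and divided by the
baseline level to give a linear-scale copy ratio, which is then re-centered
on its median over unmasked bins. Re-centering matters: pure library-size
scaling deflates every ratio when an amplified region inflates the
sample's total, and the median over a mostly diploid panel is the robust
estimate of the neutral level (the approach used by panel CNV callers
generally). Each gene forms a single segment spanning its panel bins — no
change-point segmentation, since calls are reported at gene level — and is
amplified when the segment mean ratio is ≥ 2.0 (inclusive). The ratio is
linear, not log2: at full purity 2.0 corresponds to 4 copies, which makes
+3-copy reference standards (expected ratio 2.5) callable with margin.
Genes whose bins are all masked are `uncallable`. Deletions are flagged at
ratio ≤ 0.5 for information only; the amplification threshold is the
validated contract. Tumor purity is a known confounder: ratios are not
purity-corrected.

# Gene fusions

Fusion detection is DNA-level, from probes tiling selected introns of six
commonly fused gene pairs; evidence records are soft-clipped reads whose
clipped remainder re-aligns at a partner locus. Reads with clips shorter
than 20 bp or loci outside panel genes are discarded, intra-gene events are
excluded, and both read orientations collapse onto the alphabetically
ordered gene pair. Evidence is grouped by transitive closure when both
partner breakpoints agree within 5 bp (the clustering tolerance and minimum
clip length are configuration with these stated defaults — they are not
printed assay constants); the consensus breakpoint is the modal position
and the spanning-read count is the number of distinct read identifiers. A
fusion is reported at ≥ 2 breakpoint-spanning reads (inclusive).

# ctDNA / MRD tracking

Tumor-derived variants are ranked by an explicit composite score — a
weighted sum of five terms in [0, 1]:

| term | transform | default weight |
|---|---|---|
| tissue VAF | `min(vaf / 0.5, 1)` | 0.30 |
| pathogenicity | as annotated | 0.25 |
| mutation type | 1.0 truncating; 0.8 hotspot missense; 0.6 missense; 0.3 other | 0.15 |
| database recurrence | `min(log10(1 + n) / 3, 1)` | 0.20 |
| internal whitelist | 0/1 | 0.10 |

The production ranking algorithms behind such assays are proprietary; the
weighted-sum form and these weights are this package's own concretization,
and the weights are configuration — the tested contract is the ordering
logic (monotonicity in each term, deterministic tie-breaks by VAF then
coordinates), not the exact weights. The log recurrence term saturates at
999 database reports; a missing annotation contributes 0 with a warning,
never an error. The top 2–5 candidates per patient form the tracking set;
fewer than 2 available candidates still return a set, flagged insufficient.

Each tracked variant is measured by an ultra-deep amplicon (average
100,000X). Amplicons under 10,000X are unsuccessful and excluded. A plasma
timepoint is ctDNA-positive when at least one evaluable amplicon has VAF
strictly above 0.05% (`>`; the evaluability bound is `>=`); all amplicons
unsuccessful gives `uncallable`. The positivity rule is applied per
variant, with no background-error subtraction by default — at a per-read
error rate of 1e-4 the 0.05% threshold sits far in the binomial tail at
100,000X, so the plain threshold already controls false positives. cfDNA
input adequacy (≥ 0.15 ng/µL or ≥ 3 ng) is recorded as a pre-analytic flag,
not a computational gate. Longitudinal tracking orders timepoints by
collection date and derives *clearance* (positive → negative) and
*molecular relapse* (negative → positive) events.

# Validation statistics

`confusion()` matches calls to a truth set that declares both positive and
negative sites by exact chromosome/position/ref/alt after parsimonious
left-alignment of indels (alleles are trimmed from the right, then from the
left, advancing the position); calls outside the declared universe are
ignored so the four counts partition it exactly. The limit of detection is
the minimum tested VAF level detected in ≥ 95% of technical replicates
(inclusive), undefined when no level qualifies. Concordance is the fraction
of paired samples with identical categorical calls. Linearity is ordinary
least squares through `stats::lm()` with `R² = 1 − SSres/SStot`, defined as
0 for a constant response.

# Synthetic data generator

The generators produce every input with a known truth under a fixed seed
(byte-identical outputs per seed). The default study conditions mirror the
assay's validation material: a 473-gene, 1.7 Mb panel whose first symbols
are the amplification (ERBB2, FGFR3, MYC, EGFR, MET, MYCN, +3 copies each)
and fusion (TPM3–NTRK1, QKI–NTRK2, ETV6–NTRK3, EML4–ALK, CCDC6–RET,
SLC34A2–ROS1) standard genes; a 228-variant somatic truth set (211 SNVs,
17 indels) at VAF ≥ 5% observed at 500X; 90 normals for the CNV baseline at
150X per bin; 800 microsatellite loci with a configurable unstable
fraction, unstable loci shifted by 3 repeat units (deletion-biased) over a
5-length stutter pattern; plasma amplicons at 100,000X with per-read error
1e-4. Depths are negative-binomial (size 20) around their means — Poisson
with mild over-dispersion — and site alt counts are binomial at the truth
VAF. A planted variant is *called* when it reaches 3 alt reads, a simple
caller detection floor; negative reference sites are called falsely only
when background error reads reach that floor at ≥ 1% observed VAF.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: sequence-context error profiles and FFPE
deamination artifacts (errors are i.i.d. binomial), alignment and mapping
ambiguity, GC-dependent coverage waves (the CNV baseline hook for GC
correction exists but fixtures are GC-neutral), polymerase stutter beyond a
fixed symmetric pattern, tumor subclonality, and contamination. Performance
figures on fixtures are therefore upper bounds of the idealized model, not
estimates for clinical material.

# Numerical and degenerate-input choices

* Coordinates: BED and coverage TSVs are 0-based half-open; VCF positions
  1-based; internal interval arithmetic uses `GenomicRanges` (1-based
  closed) with conversion at the boundaries.
* All printed thresholds compare inclusively (`>=`) except ctDNA
  positivity, which is strictly above 0.05% by its definition.
* TMB uses integer-first arithmetic (see above); `uncallable`/error states
  are distinct from negative results throughout (zero effective panel,
  zero evaluable MSI loci, all-masked genes, all-shallow amplicons).
* Multi-allelic VCF sites are decomposed one record per ALT with per-allele
  depths from the `AD` ordering; an explicit VAF tag takes precedence over
  recomputation from depths.
* The clustered-events artifact filter discards all variants in any 10 bp
  window containing more than 2 calls (window and count configurable).
* Breakpoint clustering is transitive single-linkage; test oracles re-derive
  the grouping by BFS.

# Problem sizes

The test suite and the acceptance script run the full 473-gene panel for
fixture realism but scale replicate counts to desk size: 50 random
instances per brute-force oracle comparison, 20–50 tumor replicates for
amplification sensitivity, 3 fusion replicates, 10–20 replicates per
dilution grid point, 100–200 plasma simulations. These sizes were chosen as
the smallest that make the binomial tolerances in the tests meaningful.

# Known limitations

* MSI per-locus calling is a surrogate statistic, not a re-implementation
  of any specific production caller; its trained-baseline (tumor-only) mode
  is out of scope.
* Fusion detection consumes pre-computed supplementary alignments of the
  clipped segment; k-mer breakpoint reconstruction is out of scope.
* No purity/ploidy modelling, no allele-specific copy number, no UMI error
  correction, no tumor-only TMB mode.
* The engine accepts caller `FILTER` status and annotations as given; their
  semantics are the upstream pipeline's contract.
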