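# cgpkit

Decision engine for tumor-normal **comprehensive genomic profiling (CGP)**
panels with a personalized **ctDNA / minimal-residual-disease (MRD)**
tracking arm.

Targeted panel assays over hundreds of cancer genes report, from one pair
of tumor and matched-normal libraries, the biomarkers that drive therapy
selection: somatic SNVs/indels, gene amplification and fusion, tumor
mutational burden (TMB) and microsatellite instability (MSI) for
immunotherapy, and — for selected cancers — a patient-specific set of
tumor mutations tracked in plasma at ultra-high depth to detect residual
disease and molecular relapse. `cgpkit` implements the decision layer of
such an assay for bioinformaticians building or validating one: the QC
gate, every biomarker's scoring and classification rule, the
analytical-validation statistics, an in-silico tumor-fraction dilution
experiment, and a seeded synthetic-data generator that produces every
input format with a known truth.

## The rules at the core

* **Sample QC**: analyze only if mean depth ≥ 150X **and** ≥ 75% of panel
  bases ≥ 100X.
* **TMB** = eligible somatic variants / effective panel Mb, where eligible
  means PASS, non-germline (dbSNP-negative), coding, non-synonymous,
  VAF ≥ 5%, alt reads ≥ 5, depth ≥ 15X; effective size counts coding bases
  ≥ 15X. TMB-High at ≥ 10 mut/Mb.
* **MSI (NGS)**: per-locus chi-squared on tumor vs normal repeat-length
  histograms plus a modal-shift requirement; MSI-High when ≥ 20% of
  detected loci are unstable. **MSI (PCR)**: MSI-High at ≥ 2 of 5
  mononucleotide markers altered.
* **Amplification**: 100 bp bins, library-size normalization against a
  90-normal panel-of-normals median baseline, median re-centered linear
  copy ratio; gene amplified at segment mean ≥ 2.0.
* **Fusion**: breakpoint-spanning (soft-clipped, re-aligned) reads
  clustered within 5 bp at both loci; reported at ≥ 2 spanning reads.
* **ctDNA**: top 2–5 composite-ranked tumor variants per patient, measured
  by ~100,000X amplicons (evaluable at ≥ 10,000X); a timepoint is positive
  when any evaluable variant has VAF **strictly above 0.05%**.

See `vignettes/cgp-decision-engine.Rmd` for the full model description,
parameter rationale and limitations.

## Worked example

Everything below runs offline from the package's own generators:

```r
library(cgpkit)

panel <- generate_panel()                      # 473 genes, 1.7 Mb coding
som   <- generate_somatic_fixture(panel, seed = 42)

profile_qc(som$depth_profile, panel)
#> Sample QC: mean depth 500.6X, 100.0% of bases >= 100X -> PASS

compute_tmb(som$variants, som$depth_profile, panel)
#> TMB: 210 eligible variants / 1.7000 Mb = 123.53 mut/Mb -> TMB-H (threshold 10.0, inclusive)

msi <- generate_msi_fixture(n_loci = 800, unstable_fraction = 0.25, seed = 42)
classify_msi(msi$profiles)
#> MSI: 200/800 detected loci unstable (25.0%) -> MSI-H (threshold 20%, inclusive)

cnv <- generate_cnv_fixture(panel, n_normals = 90, seed = 42)
call_amplification(cnv$tumor, build_baseline(cnv$normals), panel)
#> Copy ratio track: 17268 bins, 473 genes; amplified (segment mean >= 2.0):
#>   EGFR, ERBB2, FGFR3, MET, MYC, MYCN

fus <- generate_fusion_fixture(panel, seed = 42)
calls <- detect_fusions(fus$evidence, panel)
calls[calls$reported, c("gene_a", "gene_b", "spanning_reads")]
#>   gene_a  gene_b spanning_reads
#> 1    ALK    EML4              5
#> 2  CCDC6     RET              5
#> 3   ETV6   NTRK3              5
#> 4  NTRK1    TPM3              5
#> 5  NTRK2     QKI              5
#> 6   ROS1 SLC34A2              5

plasma <- generate_plasma_series(paste0("v", 1:4),
  list("pre-op" = 0.30, "post-op" = 0, "post-CRT" = 0.15), seed = 42)
track_longitudinal(plasma)
#> Longitudinal ctDNA trajectory:
#>  index    label positive max_vaf_pct
#>      1   pre-op     TRUE       0.307
#>      2  post-op    FALSE       0.012
#>      3 post-CRT     TRUE       0.167
#> Events:
#>              event after_label at_label at_index
#>          clearance      pre-op  post-op        2
#>  molecular_relapse     post-op post-CRT        3
#> Summary: molecular-relapse
```

Reading the output: the sample clears the depth gate; the TMB of 123.5
mut/Mb is far above the 10 mut/Mb immunotherapy threshold (this fixture
plants 211 SNVs + 17 indels on 1.7 Mb, a hypermutated profile); 25% of
microsatellite loci shifted means MSI-High; the six genes planted with +3
copies (expected linear ratio 2.5) are called amplified; all six planted
intron fusions are reported; and the plasma series shows ctDNA clearance
after surgery followed by molecular relapse after chemoradiotherapy — the
surveillance pattern the MRD arm exists to catch.

A thin command-line wrapper with per-stage subcommands lives at
`inst/cli/cgpkit.R`:

```sh
Rscript inst/cli/cgpkit.R tmb --vcf tumor.vcf.gz --panel panel.bed --depth depth.tsv
Rscript inst/cli/cgpkit.R msi-pcr --markers "BAT-25:1,BAT-26:1,MONO-27:0,NR-21:0,NR-24:0"
```

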