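Package: cgpkit
Title: Comprehensive Genomic Profiling and ctDNA Residual-Disease Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision engine for tumor-normal comprehensive genomic profiling
    (CGP) panels: sample quality-control gating, tumor mutational burden (TMB)
    scoring and classification, microsatellite instability (MSI) calling from
    tumor/normal repeat-length distributions and from the 5-marker PCR panel,
    gene-amplification calling against a panel-of-normals coverage baseline,
    DNA-level gene-fusion detection from breakpoint-spanning read evidence,
    and a personalized circulating tumor DNA (ctDNA) tracking arm with
    composite mutation ranking, ultra-deep amplicon variant calling and
    longitudinal minimal-residual-disease (MRD) positivity. Includes the
    analytical-validation statistics used to characterize such assays
    (sensitivity/specificity, limit of detection, concordance, linear fits),
    an in-silico tumor-fraction dilution experiment for TMB stability, and a
    seeded synthetic-fixture generator producing every input format the
    pipeline consumes with a known truth manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
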