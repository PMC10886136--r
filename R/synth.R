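#' Synthetic fixture generation with known truth
#'
#' Seeded generators producing every input format the pipeline consumes —
#' panel BED, somatic VCF, depth and coverage TSVs, microsatellite locus
#' tables, breakpoint-evidence TSVs and plasma amplicon pileups — together
#' with a truth manifest, so every stage is testable without external data.
#'
#' @name synth
#' @keywords internal
NULL

.AMP_GENES <- c("ERBB2", "FGFR3", "MYC", "EGFR", "MET", "MYCN")
.FUSION_PAIRS <- matrix(c("TPM3", "NTRK1", "QKI", "NTRK2", "ETV6", "NTRK3",
                          "EML4", "ALK", "CCDC6", "RET", "SLC34A2", "ROS1"),
                        ncol = 2L, byrow = TRUE)

#' Generate a synthetic cancer gene panel
#'
#' Emulates a hybridization panel of 473 cancer-relevant genes with a total
#' coding footprint of 1.7 Mb: coding exon intervals for every gene, plus
#' non-coding (intron-targeted) intervals for the 12 genes of the six common
#' fusion pairs. The first gene symbols are the amplification and fusion
#' genes used by the reference standards; the rest are placeholders.
#'
#' @param n_genes Number of genes (default 473).
#' @param total_coding_bp Total coding bases across the panel
#'   (default 1,700,000).
#' @param intron_bp Length of each fusion gene's non-coding interval
#'   (default 2000).
#' @return A panel `GRanges` (see [panel_granges()]).
#' @export
generate_panel <- function(n_genes = 473L, total_coding_bp = 1.7e6,
                           intron_bp = 2000L) {
  named <- unique(c(.AMP_GENES, as.vector(t(.FUSION_PAIRS))))
  genes <- c(named, sprintf("GENE%03d", seq_len(max(0L, n_genes - length(named)))))
  genes <- genes[seq_len(n_genes)]
  base_len <- floor(total_coding_bp / n_genes)
  lens <- rep(base_len, n_genes)
  extra <- total_coding_bp - sum(lens)
  if (extra > 0) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
  chrom <- paste0("chr", (seq_len(n_genes) - 1L) %% 22L + 1L)
  slot <- (seq_len(n_genes) - 1L) %/% 22L
  start <- 1e6 * slot + 10000L
  end <- start + lens
  is_fusion <- genes %in% as.vector(.FUSION_PAIRS)
  pan <- panel_granges(c(chrom, chrom[is_fusion]),
                       c(start, end[is_fusion] + 500L),
                       c(end, end[is_fusion] + 500L + intron_bp),
                       gene = c(genes, genes[is_fusion]),
                       is_coding = c(rep(TRUE, n_genes),
                                     rep(FALSE, sum(is_fusion))))
  sort(pan)
}

#' Tile a panel into fixed-width coverage bins
#'
#' @param panel Panel `GRanges`.
#' @param width Bin width in bp (default 100, the CNV segmentation bin).
#' @return A coverage-grid `data.frame` (`chrom`, `start`, `end`, `gene`,
#'   `is_coding`), 0-based half-open, ordered like the panel.
#' @export
panel_bins <- function(panel, width = 100L) {
  wins <- unlist(GenomicRanges::slidingWindows(panel, width = width, step = width))
  idx <- rep(seq_along(panel), ceiling(GenomicRanges::width(panel) / width))
  data.frame(chrom = as.character(GenomicRanges::seqnames(wins)),
             start = GenomicRanges::start(wins) - 1L,
             end = GenomicRanges::end(wins),
             gene = panel$gene[idx],
             is_coding = panel$is_coding[idx],
             stringsAsFactors = FALSE)
}

# negative-binomial depths with a Poisson limit as size -> Inf
.rdepth <- function(n, mu, dispersion) {
  if (is.infinite(dispersion)) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = dispersion)
}

#' Generate a somatic tumor fixture (variants + depth profile)
#'
#' Plants `n_snv` SNVs and `n_indel` indels at coding panel positions with
#' truth VAFs drawn from `vaf_levels`; observed alt counts are binomial at
#' the site depth, which is negative-binomial around `mean_depth` (the
#' default composition, 211 SNVs + 17 indels, mirrors a commercial
#' multi-variant reference standard). Ineligible decoys (synonymous,
#' population-database and sub-threshold-VAF variants) can be planted
#' alongside. A planted variant is emitted as *called* only when its
#' observed alt count reaches `min_call_alt` reads, emulating a caller's
#' detection floor.
#'
#' @param panel Panel `GRanges`.
#' @param n_snv,n_indel Number of eligible SNVs / indels to plant.
#' @param vaf_levels Truth VAF levels sampled uniformly (default
#'   `c(0.05, 0.075, 0.10, 0.15, 0.20, 0.30, 0.40, 0.50)`).
#' @param n_synonymous,n_germline,n_lowvaf Ineligible decoy counts.
#' @param lowvaf_range Truth-VAF range for the sub-threshold decoys
#'   (default `c(0.01, 0.04)`).
#' @param mean_depth Mean site/bin depth (default 500).
#' @param dispersion Negative-binomial size (default 20; `Inf` = Poisson).
#' @param min_call_alt Detection floor in alt reads (default 3).
#' @param seed RNG seed.
#' @param out_dir Optional directory; when given, writes `tumor.vcf.gz`,
#'   `panel.bed`, `depth.tsv` and `truth.json`.
#' @return List with `variants` (called records), `truth` (all planted
#'   records with `truth_vaf`, `eligible`, `called`), `depth_profile`
#'   (`GRanges`), `panel`, and `paths` when written.
#' @export
generate_somatic_fixture <- function(panel,
                                     n_snv = 211L, n_indel = 17L,
                                     vaf_levels = c(0.05, 0.075, 0.10, 0.15,
                                                    0.20, 0.30, 0.40, 0.50),
                                     n_synonymous = 10L, n_germline = 10L,
                                     n_lowvaf = 5L,
                                     lowvaf_range = c(0.01, 0.04),
                                     mean_depth = 500, dispersion = 20,
                                     min_call_alt = 3L, seed = 1L,
                                     out_dir = NULL) {
  if (any(vaf_levels <= 0 | vaf_levels > 1)) stop("vaf_levels must lie in (0, 1]")
  set.seed(seed)
  coding <- panel[panel$is_coding]
  n_total <- n_snv + n_indel + n_synonymous + n_germline + n_lowvaf
  iv <- sample(seq_along(coding), n_total, replace = TRUE,
               prob = GenomicRanges::width(coding))
  pos <- GenomicRanges::start(coding)[iv] +
    floor(stats::runif(n_total) * GenomicRanges::width(coding)[iv])
  chrom <- as.character(GenomicRanges::seqnames(coding))[iv]
  # unique sites
  dup <- duplicated(paste(chrom, pos))
  while (any(dup)) {
    pos[dup] <- pos[dup] + 1L
    dup <- duplicated(paste(chrom, pos))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_total, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  is_indel <- c(rep(FALSE, n_snv), rep(TRUE, n_indel),
                rep(FALSE, n_synonymous + n_germline + n_lowvaf))
  ins <- is_indel & stats::runif(n_total) < 0.5
  ref[is_indel & !ins] <- paste0(ref[is_indel & !ins],
                                 replicate(sum(is_indel & !ins),
                                           paste(sample(bases, sample(1:3, 1L), TRUE), collapse = "")))
  alt[is_indel & !ins] <- substr(ref[is_indel & !ins], 1L, 1L)
  alt[ins] <- paste0(ref[ins],
                     replicate(sum(ins),
                               paste(sample(bases, sample(1:3, 1L), TRUE), collapse = "")))
  kind <- rep(c("eligible_snv", "eligible_indel", "synonymous", "germline", "lowvaf"),
              c(n_snv, n_indel, n_synonymous, n_germline, n_lowvaf))
  truth_vaf <- sample(vaf_levels, n_total, replace = TRUE)
  truth_vaf[kind == "lowvaf"] <- stats::runif(n_lowvaf, lowvaf_range[1L],
                                              lowvaf_range[2L])
  depth <- pmax(1L, .rdepth(n_total, mean_depth, dispersion))
  altd <- stats::rbinom(n_total, depth, truth_vaf)
  truth <- variant_records(
    chrom, pos, ref, alt, alt_depth = altd, total_depth = depth,
    consequence = ifelse(kind == "synonymous", "synonymous",
                  ifelse(is_indel, "frameshift", "missense")),
    in_dbsnp = kind == "germline"
  )
  truth$truth_vaf <- truth_vaf
  truth$kind <- kind
  truth$eligible <- kind %in% c("eligible_snv", "eligible_indel")
  truth$called <- truth$alt_depth >= min_call_alt
  variants <- truth[truth$called,
                    setdiff(names(truth), c("truth_vaf", "kind", "eligible", "called"))]
  rownames(variants) <- NULL
  bins <- panel_bins(panel)
  bin_depth <- .rdepth(nrow(bins), mean_depth, dispersion)
  profile <- depth_granges(bins$chrom, bins$start, bins$end, bin_depth)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      vcf = write_variants(variants, file.path(out_dir, "tumor.vcf")),
      panel = write_panel_bed(panel, file.path(out_dir, "panel.bed")),
      depth = file.path(out_dir, "depth.tsv"),
      manifest = file.path(out_dir, "truth.json")
    )
    data.table::fwrite(data.frame(chrom = bins$chrom, start = bins$start,
                                  end = bins$end, depth = bin_depth),
                       paths$depth, sep = "\t")
    jsonlite::write_json(
      list(seed = seed, n_snv = n_snv, n_indel = n_indel,
           n_eligible = sum(truth$eligible), mean_depth = mean_depth,
           truth = truth),
      paths$manifest, auto_unbox = TRUE, digits = NA)
  }
  list(variants = variants, truth = truth, depth_profile = profile,
       panel = panel, paths = paths)
}

#' Generate negative (variant-free) reference sites
#'
#' Emulates a negative reference standard: panel positions verified to carry
#' no variant, observed with a per-read background error rate. A site is
#' falsely called when error reads reach the detection floor.
#'
#' @param panel Panel `GRanges`.
#' @param n_sites Number of negative positions (default 250).
#' @param mean_depth,dispersion Site depth model.
#' @param error_rate Per-read background error rate (default 1e-4).
#' @param min_call_alt,min_call_vaf Detection floor (default 3 reads, 1%).
#' @param seed RNG seed.
#' @return List with `truth` (negative site table) and `calls` (false
#'   positives, usually empty).
#' @export
generate_negative_sites <- function(panel, n_sites = 250L, mean_depth = 500,
                                    dispersion = 20, error_rate = 1e-4,
                                    min_call_alt = 3L, min_call_vaf = 0.01,
                                    seed = 1L) {
  set.seed(seed)
  coding <- panel[panel$is_coding]
  iv <- sample(seq_along(coding), n_sites, replace = TRUE,
               prob = GenomicRanges::width(coding))
  pos <- GenomicRanges::start(coding)[iv] +
    floor(stats::runif(n_sites) * GenomicRanges::width(coding)[iv])
  chrom <- as.character(GenomicRanges::seqnames(coding))[iv]
  dup <- duplicated(paste(chrom, pos))
  while (any(dup)) { pos[dup] <- pos[dup] + 1L; dup <- duplicated(paste(chrom, pos)) }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  depth <- pmax(1L, .rdepth(n_sites, mean_depth, dispersion))
  altd <- stats::rbinom(n_sites, depth, error_rate)
  truth <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      truth = "negative", total_depth = depth,
                      alt_depth = altd, stringsAsFactors = FALSE)
  called <- altd >= min_call_alt & altd / depth >= min_call_vaf
  list(truth = truth, calls = truth[called, c("chrom", "pos", "ref", "alt")])
}

#' Generate microsatellite locus profiles
#'
#' Stable loci share the normal repeat-length distribution (a stutter
#' pattern around the modal length); unstable loci get the tumor modal
#' length shifted by at least `shift` repeat units (deletion-biased, the
#' usual MSI signature). Read counts are multinomial at `reads` reads per
#' locus per sample.
#'
#' @param n_loci Number of microsatellite loci (default 800, the scale of
#'   an NGS microsatellite site list).
#' @param unstable_fraction Fraction of loci planted unstable (default 0.2).
#' @param reads Reads per locus per sample (default 100).
#' @param shift Modal-length shift for unstable loci in repeat units
#'   (default 3).
#' @param seed RNG seed.
#' @param out_dir Optional directory; writes `msi_tumor.tsv`,
#'   `msi_normal.tsv` and `msi_truth.json`.
#' @return List with `profiles` (long-format locus table) and `truth`
#'   (`locus_id`, `unstable`).
#' @export
generate_msi_fixture <- function(n_loci = 800L, unstable_fraction = 0.2,
                                 reads = 100L, shift = 3L, seed = 1L,
                                 out_dir = NULL) {
  set.seed(seed)
  n_unstable <- round(n_loci * unstable_fraction)
  unstable <- c(rep(TRUE, n_unstable), rep(FALSE, n_loci - n_unstable))
  modal <- sample(15:30, n_loci, replace = TRUE)
  stutter <- c(0.08, 0.12, 0.6, 0.12, 0.08)  # offsets -2..+2 around modal
  units <- c("A", "T", "AC", "AG")
  rows <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    lens_n <- modal[i] + (-2:2)
    cn <- stats::rmultinom(1L, reads, stutter)[, 1L]
    modal_t <- if (unstable[i]) modal[i] - shift else modal[i]
    lens_t <- modal_t + (-2:2)
    ct <- stats::rmultinom(1L, reads, stutter)[, 1L]
    rows[[i]] <- data.frame(
      locus_id = sprintf("MS%04d", i),
      chrom = paste0("chr", (i - 1L) %% 22L + 1L),
      pos = 5e6 + i * 1000L,
      repeat_unit = units[(i - 1L) %% length(units) + 1L],
      sample = rep(c("normal", "tumor"), each = 5L),
      length = c(lens_n, lens_t),
      count = c(cn, ct),
      stringsAsFactors = FALSE
    )
  }
  profiles <- do.call(rbind, rows)
  profiles <- profiles[profiles$count > 0L, ]
  rownames(profiles) <- NULL
  truth <- data.frame(locus_id = sprintf("MS%04d", seq_len(n_loci)),
                      unstable = unstable)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(profiles[profiles$sample == "tumor", ],
                       file.path(out_dir, "msi_tumor.tsv"), sep = "\t")
    data.table::fwrite(profiles[profiles$sample == "normal", ],
                       file.path(out_dir, "msi_normal.tsv"), sep = "\t")
    jsonlite::write_json(list(seed = seed, n_loci = n_loci,
                              unstable_fraction = unstable_fraction,
                              truth = truth),
                         file.path(out_dir, "msi_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(profiles = profiles, truth = truth)
}

#' Generate a panel-of-normals + tumor CNV coverage fixture
#'
#' Bin depths are Poisson/negative-binomial around `mean_bin_depth` (scaled
#' by bin width for ragged edge bins). Amplified genes carry `extra_copies`
#' additional copies, i.e. an expected linear copy ratio of
#' `(2 + extra_copies) / 2` (2.5 for the +3-copy reference standards).
#'
#' @param panel Panel `GRanges`.
#' @param amplified_genes Genes planted amplified (default the six genes of
#'   the CNV reference standards).
#' @param extra_copies Additional copies planted (default 3).
#' @param n_normals Normal samples in the baseline (default 90).
#' @param mean_bin_depth Mean depth per full-width bin (default 150).
#' @param dispersion Negative-binomial size (default `Inf` = Poisson).
#' @param bin_width Bin width (default 100).
#' @param seed RNG seed.
#' @param out_dir Optional directory; writes `normals/normal_###.tsv` and
#'   `tumor_coverage.tsv`.
#' @return List with `normals` (list of coverage frames), `tumor`, `grid`,
#'   `truth` (amplified genes and expected ratio).
#' @export
generate_cnv_fixture <- function(panel, amplified_genes = .AMP_GENES,
                                 extra_copies = 3, n_normals = 90L,
                                 mean_bin_depth = 150, dispersion = Inf,
                                 bin_width = 100L, seed = 1L, out_dir = NULL) {
  set.seed(seed)
  bins <- panel_bins(panel, width = bin_width)
  w <- (bins$end - bins$start) / bin_width
  mu <- mean_bin_depth * w
  normals <- lapply(seq_len(n_normals), function(i)
    data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
               depth = .rdepth(nrow(bins), mu, dispersion)))
  ratio <- ifelse(bins$gene %in% amplified_genes, (2 + extra_copies) / 2, 1)
  tumor <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                      depth = .rdepth(nrow(bins), mu * ratio, dispersion))
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "normals"), recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n_normals))
      data.table::fwrite(normals[[i]],
                         file.path(out_dir, "normals", sprintf("normal_%03d.tsv", i)),
                         sep = "\t")
    data.table::fwrite(tumor, file.path(out_dir, "tumor_coverage.tsv"), sep = "\t")
  }
  list(normals = normals, tumor = tumor, grid = bins,
       truth = list(amplified_genes = amplified_genes,
                    expected_ratio = (2 + extra_copies) / 2))
}

#' Generate breakpoint-spanning read evidence for planted fusions
#'
#' Each planted fusion junction gets `reads_per_fusion` spanning reads whose
#' breakpoints jitter within `jitter` bp of the junction; optional decoys
#' are intra-gene events and short-clip reads, which detection must discard.
#'
#' @param panel Panel `GRanges` (breakpoints are placed inside the partner
#'   genes' panel intervals, intron intervals preferred).
#' @param pairs Two-column character matrix of partner genes (default the
#'   six fusions of the pan-cancer fusion reference standard).
#' @param reads_per_fusion Spanning reads per junction (default 5).
#' @param jitter Breakpoint jitter in bp (default 2).
#' @param n_intragene,n_shortclip Decoy read counts (defaults 0).
#' @param seed RNG seed.
#' @param out_dir Optional directory; writes `fusion_evidence.tsv`.
#' @return List with `evidence` (`data.frame`) and `truth` (planted pairs
#'   and junction positions).
#' @export
generate_fusion_fixture <- function(panel, pairs = .FUSION_PAIRS,
                                    reads_per_fusion = 5L, jitter = 2L,
                                    n_intragene = 0L, n_shortclip = 0L,
                                    seed = 1L, out_dir = NULL) {
  set.seed(seed)
  gene_anchor <- function(g) {
    iv <- panel[panel$gene == g]
    if (!length(iv)) stop("gene ", g, " not in panel")
    noncod <- iv[!iv$is_coding]
    iv <- if (length(noncod)) noncod[1L] else iv[1L]
    list(chrom = as.character(GenomicRanges::seqnames(iv))[1L],
         pos = GenomicRanges::start(iv) + round(GenomicRanges::width(iv) / 2))
  }
  ev <- list(); truth <- list(); rid <- 0L
  for (k in seq_len(nrow(pairs))) {
    a <- gene_anchor(pairs[k, 1L]); b <- gene_anchor(pairs[k, 2L])
    for (r in seq_len(reads_per_fusion)) {
      rid <- rid + 1L
      ev[[length(ev) + 1L]] <- data.frame(
        read_id = sprintf("read%05d", rid),
        chrom_a = a$chrom, pos_a = a$pos + sample(-jitter:jitter, 1L),
        strand_a = "+",
        chrom_b = b$chrom, pos_b = b$pos + sample(-jitter:jitter, 1L),
        strand_b = sample(c("+", "-"), 1L),
        clip_len = sample(30:80, 1L), stringsAsFactors = FALSE)
    }
    truth[[k]] <- data.frame(gene_a = min(pairs[k, ]), gene_b = max(pairs[k, ]),
                             pos_a = a$pos, pos_b = b$pos,
                             stringsAsFactors = FALSE)
  }
  for (d in seq_len(n_intragene)) {
    rid <- rid + 1L
    g <- gene_anchor(sample(panel$gene[nzchar(panel$gene)], 1L))
    ev[[length(ev) + 1L]] <- data.frame(
      read_id = sprintf("read%05d", rid),
      chrom_a = g$chrom, pos_a = g$pos, strand_a = "+",
      chrom_b = g$chrom, pos_b = g$pos + 50L, strand_b = "+",
      clip_len = sample(30:80, 1L), stringsAsFactors = FALSE)
  }
  for (d in seq_len(n_shortclip)) {
    rid <- rid + 1L
    a <- gene_anchor(sample(panel$gene[nzchar(panel$gene)], 1L))
    b <- gene_anchor(sample(panel$gene[nzchar(panel$gene)], 1L))
    ev[[length(ev) + 1L]] <- data.frame(
      read_id = sprintf("read%05d", rid),
      chrom_a = a$chrom, pos_a = a$pos, strand_a = "+",
      chrom_b = b$chrom, pos_b = b$pos, strand_b = "+",
      clip_len = sample(5:15, 1L), stringsAsFactors = FALSE)
  }
  evidence <- if (length(ev)) do.call(rbind, ev) else
    data.frame(read_id = character(), chrom_a = character(), pos_a = integer(),
               strand_a = character(), chrom_b = character(), pos_b = integer(),
               strand_b = character(), clip_len = integer())
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(evidence, file.path(out_dir, "fusion_evidence.tsv"),
                       sep = "\t")
  }
  list(evidence = evidence, truth = do.call(rbind, truth))
}

#' Generate a plasma amplicon pileup for one timepoint
#'
#' Alt reads per amplicon are binomial at the planted ctDNA VAF plus a
#' per-read background error rate, at the stated amplicon coverage
#' (ultra-deep, default 100,000X).
#'
#' @param variant_ids Tracked variant identifiers.
#' @param vaf_pct Planted ctDNA VAF per variant, in percent (0 for a
#'   ctDNA-free plasma).
#' @param coverage Amplicon coverage, recycled (default 1e5).
#' @param error_rate Per-read background error rate (default 1e-4).
#' @param seed RNG seed.
#' @return A measurements `data.frame` (`variant_id`, `coverage`,
#'   `alt_reads`).
#' @export
generate_plasma_pileup <- function(variant_ids, vaf_pct, coverage = 1e5,
                                   error_rate = 1e-4, seed = 1L) {
  set.seed(seed)
  n <- length(variant_ids)
  vaf_pct <- rep_len(vaf_pct, n)
  coverage <- rep_len(as.integer(round(coverage)), n)
  p <- pmin(vaf_pct / 100 + error_rate, 1)
  data.frame(variant_id = variant_ids, coverage = coverage,
             alt_reads = stats::rbinom(n, coverage, p),
             stringsAsFactors = FALSE)
}

#' Generate a longitudinal plasma series
#'
#' @param variant_ids Tracked variant identifiers.
#' @param timepoints Named list mapping collection label to the planted
#'   ctDNA VAF (percent) at that timepoint — a scalar or one value per
#'   variant.
#' @param coverage,error_rate,seed See [generate_plasma_pileup()].
#' @param out_dir Optional directory; writes `plasma_<label>.tsv`.
#' @return List of `plasma_timepoint` objects in order.
#' @export
generate_plasma_series <- function(variant_ids, timepoints, coverage = 1e5,
                                   error_rate = 1e-4, seed = 1L,
                                   out_dir = NULL) {
  out <- vector("list", length(timepoints))
  for (i in seq_along(timepoints)) {
    pu <- generate_plasma_pileup(variant_ids, timepoints[[i]],
                                 coverage = coverage, error_rate = error_rate,
                                 seed = seed + i)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      data.table::fwrite(pu, file.path(out_dir, sprintf(
        "plasma_%s.tsv", gsub("[^A-Za-z0-9]+", "_", names(timepoints)[i]))),
        sep = "\t")
    }
    out[[i]] <- call_plasma(pu, label = names(timepoints)[i])
  }
  out
}

#' Generate a deep-source tumor fixture for the TMB dilution experiment
#'
#' Plants `n_eligible` TMB-eligible variants at clonal tissue VAFs (default
#' uniform on 0.2–0.4, typical for clonal somatic variants in a tumor-rich
#' FFPE section) observed at a deep source depth, so mixed/downsampled
#' replicates can be drawn from the material without replacement.
#'
#' @param panel Panel `GRanges`.
#' @param n_eligible Number of eligible variants (default 51, i.e. truth TMB
#'   30 on a 1.7 Mb effective panel).
#' @param vaf_range Tissue VAF range (default `c(0.2, 0.4)`).
#' @param source_depth Source material depth per site (default 5000).
#' @param seed RNG seed.
#' @return List with `variants` (source records at exact truth VAFs) and
#'   `truth_tmb` (given a fully covered coding panel).
#' @export
generate_tmb_stability_fixture <- function(panel, n_eligible = 51L,
                                           vaf_range = c(0.2, 0.4),
                                           source_depth = 5000L, seed = 1L) {
  set.seed(seed)
  coding <- panel[panel$is_coding]
  iv <- sample(seq_along(coding), n_eligible, replace = TRUE,
               prob = GenomicRanges::width(coding))
  pos <- GenomicRanges::start(coding)[iv] +
    floor(stats::runif(n_eligible) * GenomicRanges::width(coding)[iv])
  chrom <- as.character(GenomicRanges::seqnames(coding))[iv]
  dup <- duplicated(paste(chrom, pos))
  while (any(dup)) { pos[dup] <- pos[dup] + 1L; dup <- duplicated(paste(chrom, pos)) }
  vafs <- stats::runif(n_eligible, vaf_range[1L], vaf_range[2L])
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_eligible, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  variants <- variant_records(chrom, pos, ref, alt,
                              alt_depth = round(vafs * source_depth),
                              total_depth = source_depth,
                              consequence = "missense")
  coding_bp <- sum(GenomicRanges::width(GenomicRanges::reduce(GenomicRanges::granges(coding))))
  list(variants = variants, truth_tmb = n_eligible / (coding_bp / 1e6))
}
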