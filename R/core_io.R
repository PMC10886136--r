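#' Panel, depth-profile and variant input/output plus the sample QC gate
#'
#' @name core-io
#' @keywords internal
NULL

.CONSEQUENCES <- c("synonymous", "missense", "nonsense", "frameshift",
                   "inframe_indel", "splice", "noncoding")

#' Construct a validated table of variant records
#'
#' A variant record is one somatic or germline call: coordinates, alleles,
#' depths, allele fraction, filter status and the annotation flags consumed by
#' downstream eligibility rules. Invariants enforced: `ref != alt`,
#' `alt_depth <= total_depth`, `vaf` in `[0, 1]` and, when `total_depth > 0`,
#' consistent with `alt_depth / total_depth` up to a `2 / total_depth`
#' rounding allowance.
#'
#' @param chrom Chromosome names.
#' @param pos 1-based positions.
#' @param ref,alt Reference and alternate allele strings.
#' @param alt_depth,total_depth Read counts supporting the alternate allele
#'   and covering the site.
#' @param vaf Variant allele fraction in `[0, 1]`; recomputed from depths
#'   when `NA`.
#' @param filter_pass Logical; did the call pass the caller's filters.
#' @param in_dbsnp Logical likely-germline flag (population-database hit).
#' @param consequence One of `synonymous`, `missense`, `nonsense`,
#'   `frameshift`, `inframe_indel`, `splice`, `noncoding`.
#' @param is_coding Logical; defaults to `consequence != "noncoding"`.
#' @param variant_class `"SNV"` or `"INDEL"`; inferred from allele lengths
#'   when `NA`.
#'
#' @return A `data.frame` with one row per variant record.
#' @export
variant_records <- function(chrom, pos, ref, alt,
                            alt_depth, total_depth,
                            vaf = NA_real_,
                            filter_pass = TRUE,
                            in_dbsnp = FALSE,
                            consequence = "missense",
                            is_coding = NULL,
                            variant_class = NA_character_) {
  n <- length(pos)
  df <- data.frame(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = as.character(ref),
    alt = as.character(alt),
    vaf = rep_len(as.numeric(vaf), n),
    alt_depth = as.integer(alt_depth),
    total_depth = as.integer(total_depth),
    filter_pass = rep_len(as.logical(filter_pass), n),
    in_dbsnp = rep_len(as.logical(in_dbsnp), n),
    consequence = rep_len(as.character(consequence), n),
    variant_class = rep_len(as.character(variant_class), n),
    stringsAsFactors = FALSE
  )
  df$is_coding <- if (is.null(is_coding)) df$consequence != "noncoding"
                  else rep_len(as.logical(is_coding), n)
  validate_variants(df)
}

validate_variants <- function(df) {
  need <- c("chrom", "pos", "ref", "alt", "vaf", "alt_depth", "total_depth",
            "filter_pass", "in_dbsnp", "consequence", "is_coding")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("variant table missing columns: ", paste(miss, collapse = ", "))
  if (any(df$ref == df$alt))
    stop("ref and alt alleles must differ")
  if (any(df$alt_depth < 0L) || any(df$total_depth < 0L))
    stop("read depths must be non-negative")
  if (any(df$alt_depth > df$total_depth))
    stop("alt_depth exceeds total_depth")
  bad <- !df$consequence %in% .CONSEQUENCES
  if (any(bad))
    stop("unknown consequence: ", paste(unique(df$consequence[bad]), collapse = ", "))
  recompute <- is.na(df$vaf) & df$total_depth > 0L
  df$vaf[recompute] <- df$alt_depth[recompute] / df$total_depth[recompute]
  df$vaf[is.na(df$vaf)] <- 0
  if (any(df$vaf < 0 | df$vaf > 1))
    stop("vaf must lie in [0, 1]")
  pos_depth <- df$total_depth > 0L
  drift <- abs(df$vaf - df$alt_depth / df$total_depth)
  if (any(pos_depth & drift > 2 / df$total_depth + 1e-9))
    stop("vaf inconsistent with alt_depth/total_depth beyond rounding allowance")
  if (is.null(df$variant_class) || anyNA(df$variant_class)) {
    inferred <- ifelse(nchar(df$ref) == 1L & nchar(df$alt) == 1L, "SNV", "INDEL")
    if (is.null(df$variant_class)) df$variant_class <- inferred
    else df$variant_class[is.na(df$variant_class)] <- inferred[is.na(df$variant_class)]
  }
  df
}

empty_variants <- function() {
  variant_records(character(), integer(), character(), character(),
                  integer(), integer())
}

#' Read a panel definition from BED
#'
#' Expects BED 3+2: `chrom`, `start` (0-based), `end` (exclusive), `gene`,
#' `coding_flag` (0/1). Gzipped input is accepted. Intervals are returned as a
#' `GRanges` (1-based closed, the native Bioconductor convention) with `gene`
#' and `is_coding` metadata columns.
#'
#' @param path Path to the BED file (optionally `.gz`).
#' @return A [GenomicRanges::GRanges] panel object.
#' @export
read_panel_bed <- function(path) {
  bed <- data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE)
  if (ncol(bed) < 5L)
    stop("panel BED must have 5 columns: chrom, start, end, gene, coding_flag")
  names(bed)[1:5] <- c("chrom", "start", "end", "gene", "coding")
  panel_granges(bed$chrom, bed$start, bed$end, bed$gene, as.logical(bed$coding))
}

#' Build a panel GRanges from 0-based half-open intervals
#'
#' @param chrom,start,end Interval coordinates, BED convention (0-based
#'   half-open).
#' @param gene Gene symbol per interval ("" where none).
#' @param is_coding Logical coding flag per interval.
#' @return A [GenomicRanges::GRanges].
#' @export
panel_granges <- function(chrom, start, end, gene = "", is_coding = TRUE) {
  if (any(start >= end)) stop("interval start must be < end")
  if (any(!nzchar(chrom))) stop("chrom must be non-empty")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  S4Vectors::mcols(gr)$gene <- rep_len(as.character(gene), length(gr))
  S4Vectors::mcols(gr)$is_coding <- rep_len(as.logical(is_coding), length(gr))
  gr
}

#' Write a panel GRanges as BED 3+2
#'
#' @param panel Panel `GRanges` with `gene` and `is_coding` metadata.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_bed <- function(panel, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(panel)),
    start = GenomicRanges::start(panel) - 1L,
    end = GenomicRanges::end(panel),
    gene = panel$gene,
    coding = as.integer(panel$is_coding)
  )
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a depth profile from TSV
#'
#' Expects columns `chrom`, `start` (0-based), `end`, `depth`; one row per
#' base or per fixed-width bin. Gzipped input is accepted.
#'
#' @param path Path to the TSV.
#' @return A `GRanges` with a `depth` metadata column.
#' @export
read_depth_profile <- function(path) {
  dt <- data.table::fread(path, data.table = FALSE)
  need <- c("chrom", "start", "end", "depth")
  if (!all(need %in% names(dt))) {
    if (ncol(dt) >= 4L) names(dt)[1:4] <- need
    else stop("depth profile needs columns chrom, start, end, depth")
  }
  depth_granges(dt$chrom, dt$start, dt$end, dt$depth)
}

#' @rdname read_depth_profile
#' @param chrom,start,end Bin coordinates, 0-based half-open.
#' @param depth Non-negative integer depth per bin.
#' @export
depth_granges <- function(chrom, start, end, depth) {
  if (any(depth < 0)) stop("depth values must be >= 0")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  S4Vectors::mcols(gr)$depth <- as.numeric(depth)
  gr
}

#' Sample-level sequencing quality-control gate
#'
#' A tumor sample passes QC when its mean on-target depth is at least 150X
#' and at least 75 percent of panel bases are covered at 100X or more. Both
#' comparisons are inclusive.
#'
#' @param mean_depth Mean on-target depth (X), non-negative.
#' @param pct_cov_100x Percent of panel bases with depth >= 100, in `[0, 100]`.
#' @param min_mean_depth,min_pct_100x Gate thresholds (defaults 150 and 75).
#' @return An object of class `sample_qc`: list with `mean_depth`,
#'   `pct_cov_100x`, `passed`.
#' @examples
#' qc_gate(500, 98)$passed   # TRUE
#' qc_gate(149.9, 100)$passed # FALSE
#' @export
qc_gate <- function(mean_depth, pct_cov_100x,
                    min_mean_depth = 150, min_pct_100x = 75) {
  if (!is.numeric(mean_depth) || length(mean_depth) != 1L || mean_depth < 0)
    stop("mean_depth must be a single non-negative number")
  if (!is.numeric(pct_cov_100x) || length(pct_cov_100x) != 1L ||
      pct_cov_100x < 0 || pct_cov_100x > 100)
    stop("pct_cov_100x must lie in [0, 100]")
  structure(
    list(mean_depth = mean_depth,
         pct_cov_100x = pct_cov_100x,
         passed = mean_depth >= min_mean_depth && pct_cov_100x >= min_pct_100x),
    class = "sample_qc"
  )
}

#' @export
print.sample_qc <- function(x, ...) {
  cat(sprintf("Sample QC: mean depth %.1fX, %.1f%% of bases >= 100X -> %s\n",
              x$mean_depth, x$pct_cov_100x, if (x$passed) "PASS" else "FAIL"))
  invisible(x)
}

#' Summarize a depth profile into the QC gate inputs
#'
#' Mean depth and percent of panel bases at >= 100X are computed
#' length-weighted over the profile bins restricted to the panel.
#'
#' @param depth_profile Depth `GRanges` (see [read_depth_profile()]).
#' @param panel Optional panel `GRanges`; when given, only profile bases
#'   inside panel intervals count.
#' @inheritParams qc_gate
#' @return A `sample_qc` object.
#' @export
profile_qc <- function(depth_profile, panel = NULL,
                       min_mean_depth = 150, min_pct_100x = 75) {
  gr <- depth_profile
  if (!is.null(panel)) {
    hits <- GenomicRanges::findOverlaps(gr, GenomicRanges::reduce(GenomicRanges::granges(panel)))
    ov <- GenomicRanges::pintersect(gr[S4Vectors::queryHits(hits)],
                                    GenomicRanges::reduce(GenomicRanges::granges(panel))[S4Vectors::subjectHits(hits)])
    w <- GenomicRanges::width(ov)
    d <- gr$depth[S4Vectors::queryHits(hits)]
  } else {
    w <- GenomicRanges::width(gr)
    d <- gr$depth
  }
  if (sum(w) == 0) stop("depth profile does not overlap the panel")
  qc_gate(sum(w * d) / sum(w), 100 * sum(w[d >= 100]) / sum(w),
          min_mean_depth = min_mean_depth, min_pct_100x = min_pct_100x)
}

#' Effective panel size for TMB
#'
#' Counts coding-region panel bases whose sequencing depth meets the minimum
#' total depth (default 15X). Non-coding panel bases never count. The result
#' is the denominator (after division by 1e6) of the TMB score.
#'
#' @param depth_profile Depth `GRanges` covering the panel.
#' @param panel Panel `GRanges` with `is_coding`.
#' @param min_depth Minimum total depth for a base to count (default 15).
#' @return Integer count of qualifying bases.
#' @export
effective_panel_size <- function(depth_profile, panel, min_depth = 15) {
  coding <- GenomicRanges::reduce(GenomicRanges::granges(panel[panel$is_coding]))
  if (length(coding) == 0L) return(0L)
  covered <- GenomicRanges::reduce(GenomicRanges::granges(depth_profile))
  uncov <- GenomicRanges::setdiff(coding, covered)
  if (length(uncov) > 0L) {
    show <- utils::head(sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(uncov)),
                                GenomicRanges::start(uncov) - 1L, GenomicRanges::end(uncov)), 5L)
    stop("depth profile does not cover panel coding intervals: ",
         paste(show, collapse = ", "),
         if (length(uncov) > 5L) sprintf(" (and %d more)", length(uncov) - 5L) else "")
  }
  deep <- depth_profile[depth_profile$depth >= min_depth]
  if (length(deep) == 0L) return(0L)
  deep <- GenomicRanges::reduce(GenomicRanges::granges(deep))
  sum(GenomicRanges::width(GenomicRanges::intersect(deep, coding)))
}

#' Read variant calls from VCF
#'
#' Parses a VCF (v4.2, optionally gzipped) carrying `AD`/`DP` depth fields in
#' the first sample column and the annotation tags written by
#' [write_variants()]: `CONSEQ` (consequence), `CODING` (0/1), `DB`
#' (population-database flag), `CLASS` (SNV/INDEL), `VAF`. Multi-allelic
#' sites are decomposed into one record per ALT allele, with per-allele
#' depths taken from the `AD` ordering. When no explicit VAF tag is present
#' the fraction is recomputed as `alt_depth / total_depth`.
#'
#' @param path Path to the VCF file.
#' @return A variant `data.frame` (see [variant_records()]).
#' @export
read_variants <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L) return(empty_variants())
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L)
    stop("VCF has no sample column with depth fields")
  ad <- vcfR::extract.gt(v, element = "AD")[, 1L]
  dp <- suppressWarnings(as.integer(vcfR::extract.gt(v, element = "DP")[, 1L]))
  info_get <- function(key) {
    m <- regmatches(fix[, "INFO"],
                    regexec(paste0("(?:^|;)", key, "=([^;]+)"), fix[, "INFO"]))
    vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, "")
  }
  conseq <- info_get("CONSEQ")
  coding <- info_get("CODING")
  vclass <- info_get("CLASS")
  vaf_tag <- info_get("VAF")
  in_db <- grepl("(?:^|;)DB(?:;|$)", fix[, "INFO"])
  pass <- unname(fix[, "FILTER"] == "PASS")
  pass[is.na(pass)] <- FALSE
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    if (is.na(ad[i]))
      stop("VCF record ", fix[i, "CHROM"], ":", fix[i, "POS"],
           " is missing the AD depth field")
    ads <- as.integer(strsplit(ad[i], ",", fixed = TRUE)[[1L]])
    if (length(ads) < length(alts) + 1L)
      stop("VCF record ", fix[i, "CHROM"], ":", fix[i, "POS"],
           " has fewer AD values than alleles")
    total <- if (!is.na(dp[i])) dp[i] else sum(ads)
    conseq_i <- strsplit(if (is.na(conseq[i])) "missense" else conseq[i], ",")[[1L]]
    vaf_i <- if (is.na(vaf_tag[i])) rep(NA_real_, length(alts))
             else as.numeric(strsplit(vaf_tag[i], ",")[[1L]])
    class_i <- if (is.na(vclass[i])) rep(NA_character_, length(alts))
               else strsplit(vclass[i], ",")[[1L]]
    out[[i]] <- data.frame(
      chrom = fix[i, "CHROM"],
      pos = as.integer(fix[i, "POS"]),
      ref = fix[i, "REF"],
      alt = alts,
      vaf = rep_len(vaf_i, length(alts)),
      alt_depth = ads[seq_along(alts) + 1L],
      total_depth = total,
      filter_pass = pass[i],
      in_dbsnp = in_db[i],
      consequence = rep_len(conseq_i, length(alts)),
      variant_class = rep_len(class_i, length(alts)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  df <- do.call(rbind, out)
  df$is_coding <- if (all(!is.na(coding)))
    rep(as.logical(as.integer(coding)), vapply(out, nrow, 1L))
  else df$consequence != "noncoding"
  validate_variants(df)
}

#' Write variant records to VCF
#'
#' Emits a VCF v4.2 with one row per record (already decomposed), `AD`/`DP`
#' in a single `TUMOR` sample column, and the annotation tags `CONSEQ`,
#' `CODING`, `CLASS`, `VAF` and flag `DB` in INFO. Output is bgzip-style
#' gzipped; a `.gz` suffix is appended when absent. Round-trips through
#' [read_variants()] field-exactly.
#'
#' @param variants Variant `data.frame`.
#' @param path Output path (`.vcf.gz`).
#' @return The path written, invisibly.
#' @export
write_variants <- function(variants, path) {
  variants <- validate_variants(variants)
  if (!grepl("\\.gz$", path)) path <- paste0(path, ".gz")
  meta <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CONSEQ,Number=A,Type=String,Description=\"Predicted consequence\">",
    "##INFO=<ID=CODING,Number=1,Type=Integer,Description=\"1 if variant lies in a coding region\">",
    "##INFO=<ID=CLASS,Number=A,Type=String,Description=\"Variant class (SNV or INDEL)\">",
    "##INFO=<ID=VAF,Number=A,Type=Float,Description=\"Variant allele fraction\">",
    "##INFO=<ID=DB,Number=0,Type=Flag,Description=\"Population database (likely germline) flag\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">"
  )
  n <- nrow(variants)
  info <- sprintf("CONSEQ=%s;CODING=%d;CLASS=%s;VAF=%s%s",
                  variants$consequence, as.integer(variants$is_coding),
                  variants$variant_class,
                  formatC(variants$vaf, format = "g", digits = 17),
                  ifelse(variants$in_dbsnp, ";DB", ""))
  fix <- cbind(CHROM = variants$chrom,
               POS = as.character(variants$pos),
               ID = rep(".", n),
               REF = variants$ref,
               ALT = variants$alt,
               QUAL = rep(".", n),
               FILTER = ifelse(variants$filter_pass, "PASS", "artifact"),
               INFO = info)
  gt <- cbind(FORMAT = rep("GT:AD:DP", n),
              TUMOR = sprintf("0/1:%d,%d:%d",
                              variants$total_depth - variants$alt_depth,
                              variants$alt_depth, variants$total_depth))
  if (n == 0L) {
    fix <- matrix(character(), 0L, 8L,
                  dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                          "QUAL", "FILTER", "INFO")))
    gt <- matrix(character(), 0L, 2L, dimnames = list(NULL, c("FORMAT", "TUMOR")))
  }
  obj <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(obj, file = path)
  invisible(path)
}

#' Remove clustered events (FFPE artifact filter)
#'
#' Tissue-processing artifacts tend to appear as dense local clusters of
#' calls. Any window of `window` bases containing more than `max_per_window`
#' variants on the same chromosome has all of its variants discarded.
#'
#' @param variants Variant `data.frame`.
#' @param max_per_window Maximum calls tolerated within one window (default 2).
#' @param window Window width in bases (default 10).
#' @return The filtered variant `data.frame`.
#' @export
filter_clustered_events <- function(variants, max_per_window = 2L, window = 10L) {
  if (nrow(variants) == 0L) return(variants)
  keep <- rep(TRUE, nrow(variants))
  for (chr in unique(variants$chrom)) {
    idx <- which(variants$chrom == chr)
    pos <- sort(unique(variants$pos[idx]))
    bad_pos <- numeric(0)
    for (p in pos) {
      inwin <- variants$pos[idx] >= p & variants$pos[idx] <= p + window - 1L
      if (sum(inwin) > max_per_window)
        bad_pos <- c(bad_pos, variants$pos[idx][inwin])
    }
    if (length(bad_pos))
      keep[idx[variants$pos[idx] %in% bad_pos]] <- FALSE
  }
  variants[keep, , drop = FALSE]
}
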