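#' Combined comprehensive-genomic-profiling report
#'
#' Runs the full decision engine on one tumor-normal sample: QC gate, TMB,
#' MSI, amplification and fusion calls, and optionally the ctDNA/MRD
#' tracking block. When the sample fails the QC gate only the QC block is
#' populated (the assay removes QC-failing samples from analysis) unless
#' `force = TRUE`. Each block echoes its decision threshold; "uncallable"
#' results are reported as such, never as negative.
#'
#' @param variants Somatic variant `data.frame`.
#' @param depth_profile Depth `GRanges`.
#' @param panel Panel `GRanges`.
#' @param msi_profiles Optional MSI locus table (see [read_msi_profiles()]).
#' @param tumor_coverage,baseline Optional CNV inputs (see
#'   [call_amplification()]).
#' @param fusion_evidence Optional breakpoint evidence `data.frame`.
#' @param plasma_timepoints Optional list of `plasma_timepoint` objects for
#'   the MRD block.
#' @param config Named list overriding thresholds: `tmb_threshold`,
#'   `msi_threshold_pct`, `amp_threshold`, `fusion_min_reads`,
#'   `ctdna_threshold_pct`, `min_mean_depth`, `min_pct_100x`.
#' @param force Run downstream stages even when QC fails.
#' @return An object of class `cgp_profile` (nested list).
#' @export
profile_sample <- function(variants, depth_profile, panel,
                           msi_profiles = NULL,
                           tumor_coverage = NULL, baseline = NULL,
                           fusion_evidence = NULL,
                           plasma_timepoints = NULL,
                           config = list(), force = FALSE) {
  cfg <- modifyList(list(tmb_threshold = 10, msi_threshold_pct = 20,
                         amp_threshold = 2.0, fusion_min_reads = 2L,
                         ctdna_threshold_pct = 0.05,
                         min_mean_depth = 150, min_pct_100x = 75), config)
  qc <- profile_qc(depth_profile, panel,
                   min_mean_depth = cfg$min_mean_depth,
                   min_pct_100x = cfg$min_pct_100x)
  report <- list(qc = unclass(qc), config = cfg, version = as.character(
    utils::packageVersion("cgpkit")))
  if (!qc$passed && !force) {
    report$status <- "qc_failed"
    class(report) <- "cgp_profile"
    return(report)
  }
  report$status <- "ok"
  report$tmb <- unclass(compute_tmb(variants, depth_profile, panel,
                                    threshold = cfg$tmb_threshold))
  if (!is.null(msi_profiles))
    report$msi <- unclass(classify_msi(msi_profiles,
                                       threshold_pct = cfg$msi_threshold_pct))
  if (!is.null(tumor_coverage) && !is.null(baseline)) {
    amp <- call_amplification(tumor_coverage, baseline, panel,
                              threshold = cfg$amp_threshold)
    report$amplification <- amp$genes[which(amp$genes$amplified | !amp$genes$callable), ,
                                      drop = FALSE]
  }
  if (!is.null(fusion_evidence)) {
    fus <- detect_fusions(fusion_evidence, panel,
                          min_reads = cfg$fusion_min_reads)
    report$fusions <- fus[fus$reported, , drop = FALSE]
  }
  if (!is.null(plasma_timepoints))
    report$mrd <- unclass(track_longitudinal(plasma_timepoints))
  class(report) <- "cgp_profile"
  report
}

#' @export
print.cgp_profile <- function(x, ...) {
  cat(sprintf("CGP profile (v%s) — QC: mean depth %.1fX, %.1f%% >= 100X -> %s\n",
              x$version, x$qc$mean_depth, x$qc$pct_cov_100x,
              if (x$qc$passed) "PASS" else "FAIL"))
  if (identical(x$status, "qc_failed")) {
    cat("Sample failed QC; downstream analysis withheld.\n")
    return(invisible(x))
  }
  if (!is.null(x$tmb))
    cat(sprintf("TMB: %.2f mut/Mb -> %s\n", x$tmb$score, x$tmb$status))
  if (!is.null(x$msi))
    cat(sprintf("MSI: %.1f%% unstable -> %s\n", x$msi$proportion, x$msi$status))
  if (!is.null(x$amplification))
    cat("Amplified genes:",
        paste(x$amplification$gene[which(x$amplification$amplified)],
              collapse = ", "), "\n")
  if (!is.null(x$fusions) && nrow(x$fusions))
    cat("Fusions:", paste(paste0(x$fusions$gene_a, "-", x$fusions$gene_b),
                          collapse = ", "), "\n")
  if (!is.null(x$mrd)) cat("MRD summary:", x$mrd$summary, "\n")
  invisible(x)
}

#' Serialize a profile report to JSON
#'
#' @param report A `cgp_profile`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
profile_to_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
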