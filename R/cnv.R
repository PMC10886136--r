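#' Gene amplification from binned coverage (panel-of-normals baseline)
#'
#' @name cnv
#' @keywords internal
NULL

#' Read a binned coverage table
#'
#' Expects a TSV with columns `chrom`, `start` (0-based), `end`, `depth` on
#' the panel's fixed-width (100 bp) bin grid.
#'
#' @param path Path to the TSV (optionally gzipped).
#' @return A `data.frame` with the four columns.
#' @export
read_coverage_tsv <- function(path) {
  dt <- data.table::fread(path, data.table = FALSE)
  if (!all(c("chrom", "start", "end", "depth") %in% names(dt)))
    names(dt)[1:4] <- c("chrom", "start", "end", "depth")
  dt[c("chrom", "start", "end", "depth")]
}

.check_grid <- function(a, b) {
  identical(a$chrom, b$chrom) && identical(a$start, b$start) &&
    identical(a$end, b$end)
}

# library-size normalization: scale bin depths to mean 1 over the grid
.libnorm <- function(depth) {
  tot <- sum(depth)
  if (tot <= 0) stop("coverage profile has zero total depth")
  depth / tot * length(depth)
}

#' Build a panel-of-normals coverage baseline
#'
#' Each normal sample's bin coverage is library-size normalized (scaled to an
#' equal total across the panel), and the per-bin reference level is the
#' median across normals with the median absolute deviation as the per-bin
#' dispersion. Bins whose median normalized coverage is zero are masked and
#' excluded from downstream segment means.
#'
#' @param normal_coverages List of coverage `data.frame`s (see
#'   [read_coverage_tsv()]) on an identical bin grid; at least 2 (the assay
#'   baseline used 90 white-blood-cell samples).
#' @return An object of class `cnv_baseline`: the bin grid plus `level`,
#'   `dispersion`, `masked` columns.
#' @export
build_baseline <- function(normal_coverages) {
  if (length(normal_coverages) < 2L)
    stop("at least 2 normal samples are required to build a baseline")
  grid <- normal_coverages[[1L]][c("chrom", "start", "end")]
  for (nc in normal_coverages[-1L])
    if (!.check_grid(grid, nc))
      stop("normal coverage profiles are not on an identical bin grid")
  mat <- vapply(normal_coverages, function(nc) .libnorm(nc$depth),
                numeric(nrow(grid)))
  level <- apply(mat, 1L, stats::median)
  disp <- apply(mat, 1L, stats::mad)
  out <- grid
  out$level <- level
  out$dispersion <- disp
  out$masked <- level <= 0
  class(out) <- c("cnv_baseline", "data.frame")
  out
}

#' Write / read a serialized baseline
#'
#' @param baseline A `cnv_baseline`.
#' @param path TSV path.
#' @return `path` (write) or the baseline (read).
#' @export
write_baseline <- function(baseline, path) {
  data.table::fwrite(as.data.frame(baseline), path, sep = "\t")
  invisible(path)
}

#' @rdname write_baseline
#' @export
read_baseline <- function(path) {
  out <- data.table::fread(path, data.table = FALSE)
  out$masked <- as.logical(out$masked)
  class(out) <- c("cnv_baseline", "data.frame")
  out
}

#' Call gene amplifications from a sample coverage profile
#'
#' The sample's bin coverage is library-size normalized, divided by the
#' baseline level to give a linear-scale copy ratio per bin, and the ratios
#' are re-centered on their median over unmasked bins (so the mostly-diploid
#' panel background sits at ratio 1 even when amplified regions inflate the
#' library total). Bins are
#' assigned to genes through the panel, each gene forms a single segment,
#' and its `segment_mean` is the mean bin ratio over unmasked bins. A gene
#' is called amplified when `segment_mean >= threshold` (default 2.0,
#' inclusive; at full purity a ratio of 2.0 corresponds to 4 copies, so
#' +3-copy reference standards at ratio 2.5 are callable). Genes whose bins
#' are all masked are reported uncallable, not negative. Ratios below
#' `loss_threshold` are flagged as loss for information only.
#'
#' @param sample_coverage Coverage `data.frame` on the baseline's grid.
#' @param baseline A `cnv_baseline` from [build_baseline()].
#' @param panel Panel `GRanges` with `gene` metadata.
#' @param threshold Amplification threshold on the segment mean (default 2.0).
#' @param loss_threshold Informational loss threshold (default 0.5).
#' @return An object of class `copy_ratio_track`: list with `bins` (the grid
#'   plus `ratio`) and `genes` (per-gene `n_bins`, `segment_mean`,
#'   `amplified`, `loss`, `callable`).
#' @export
call_amplification <- function(sample_coverage, baseline, panel,
                               threshold = 2.0, loss_threshold = 0.5) {
  if (!.check_grid(baseline, sample_coverage))
    stop("sample coverage is not on the baseline's bin grid")
  norm <- .libnorm(sample_coverage$depth)
  ratio <- ifelse(baseline$masked, NA_real_, norm / baseline$level)
  center <- stats::median(ratio, na.rm = TRUE)
  if (!is.na(center) && center > 0) ratio <- ratio / center
  bins <- baseline[c("chrom", "start", "end")]
  bins$ratio <- ratio
  bin_gr <- GenomicRanges::GRanges(bins$chrom,
                                   IRanges::IRanges(bins$start + 1L, bins$end))
  hits <- GenomicRanges::findOverlaps(bin_gr, panel)
  gene_of_bin <- rep(NA_character_, nrow(bins))
  gene_of_bin[S4Vectors::queryHits(hits)] <- panel$gene[S4Vectors::subjectHits(hits)]
  genes <- sort(unique(stats::na.omit(gene_of_bin)))
  genes <- genes[nzchar(genes)]
  res <- lapply(genes, function(g) {
    r <- ratio[which(gene_of_bin == g)]
    usable <- r[!is.na(r)]
    if (!length(usable))
      return(data.frame(gene = g, n_bins = length(r), segment_mean = NA_real_,
                        amplified = NA, loss = NA, callable = FALSE))
    sm <- mean(usable)
    data.frame(gene = g, n_bins = length(r), segment_mean = sm,
               amplified = sm >= threshold, loss = sm <= loss_threshold,
               callable = TRUE)
  })
  structure(
    list(bins = bins, genes = do.call(rbind, res), threshold = threshold),
    class = "copy_ratio_track"
  )
}

#' @export
print.copy_ratio_track <- function(x, ...) {
  amp <- x$genes$gene[which(x$genes$amplified)]
  cat(sprintf("Copy ratio track: %d bins, %d genes; amplified (segment mean >= %.1f): %s\n",
              nrow(x$bins), nrow(x$genes), x$threshold,
              if (length(amp)) paste(amp, collapse = ", ") else "none"))
  invisible(x)
}
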