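#' DNA-level gene-fusion detection from breakpoint-spanning reads
#'
#' @name fusion
#' @keywords internal
NULL

#' Read breakpoint evidence from TSV
#'
#' One row per soft-clipped read whose clipped remainder re-aligns at a
#' second locus: `read_id`, `chrom_a`, `pos_a`, `strand_a`, `chrom_b`,
#' `pos_b`, `strand_b`, `clip_len`.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` of breakpoint evidence.
#' @export
read_fusion_evidence <- function(path) {
  dt <- data.table::fread(path, data.table = FALSE)
  need <- c("read_id", "chrom_a", "pos_a", "strand_a",
            "chrom_b", "pos_b", "strand_b", "clip_len")
  if (!all(need %in% names(dt)))
    stop("fusion evidence needs columns: ", paste(need, collapse = ", "))
  dt
}

.modal_pos <- function(pos) {
  tab <- table(pos)
  as.integer(names(tab)[which.max(tab)])
}

# transitive single-linkage grouping: two reads join when both their A and B
# breakpoints agree within `tolerance` bp (same chromosomes). O(n^2) union-find;
# evidence sets per candidate junction are small.
.cluster_evidence <- function(ev, tolerance) {
  n <- nrow(ev)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    if (ev$chrom_a[i] == ev$chrom_a[j] && ev$chrom_b[i] == ev$chrom_b[j] &&
        abs(ev$pos_a[i] - ev$pos_a[j]) <= tolerance &&
        abs(ev$pos_b[i] - ev$pos_b[j]) <= tolerance) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, 1L)
}

#' Cluster breakpoint evidence into fusion calls
#'
#' Evidence records are grouped when both partner loci agree within
#' `tolerance` bases (transitive closure), the consensus breakpoint is the
#' modal position in each cluster, the spanning-read count is the number of
#' distinct read identifiers, and a call is reported when it is supported by
#' at least `min_reads` breakpoint-spanning reads (default 2, inclusive).
#'
#' @param evidence Breakpoint evidence `data.frame`
#'   (see [read_fusion_evidence()]); optionally carrying `gene_a`/`gene_b`.
#' @param tolerance Breakpoint clustering tolerance in bp (default 5).
#' @param min_reads Reporting threshold on spanning reads (default 2).
#' @return A `data.frame` of fusion calls: `gene_a`, `gene_b` (when
#'   available), `chrom_a`, `breakpoint_a`, `chrom_b`, `breakpoint_b`,
#'   `spanning_reads`, `reported`. Empty input yields an empty frame.
#' @export
cluster_breakpoints <- function(evidence, tolerance = 5L, min_reads = 2L) {
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      chrom_a = character(), breakpoint_a = integer(),
                      chrom_b = character(), breakpoint_b = integer(),
                      spanning_reads = integer(), reported = logical())
  if (nrow(evidence) == 0L) return(empty)
  has_genes <- all(c("gene_a", "gene_b") %in% names(evidence))
  grp <- .cluster_evidence(evidence, tolerance)
  calls <- lapply(unique(grp), function(g) {
    sub <- evidence[grp == g, , drop = FALSE]
    nreads <- length(unique(sub$read_id))
    data.frame(
      gene_a = if (has_genes) sub$gene_a[1L] else NA_character_,
      gene_b = if (has_genes) sub$gene_b[1L] else NA_character_,
      chrom_a = sub$chrom_a[1L], breakpoint_a = .modal_pos(sub$pos_a),
      chrom_b = sub$chrom_b[1L], breakpoint_b = .modal_pos(sub$pos_b),
      spanning_reads = nreads, reported = nreads >= min_reads,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, calls)
  out[order(-out$spanning_reads, out$chrom_a, out$breakpoint_a), , drop = FALSE]
}

#' Detect gene fusions from breakpoint evidence and the panel
#'
#' Assigns each evidence locus to its panel gene, discards reads with clips
#' shorter than `min_clip`, reads whose loci fall outside panel genes, and
#' intra-gene events (both loci in the same gene), normalizes the gene pair
#' alphabetically so both orientations collapse to one candidate, then
#' clusters breakpoints and applies the >= `min_reads` reporting rule.
#'
#' @param evidence Breakpoint evidence `data.frame`.
#' @param panel Panel `GRanges` with `gene` metadata.
#' @param min_clip Minimum soft-clip length for usable evidence (default 20).
#' @param tolerance,min_reads Passed to [cluster_breakpoints()].
#' @return A `data.frame` of fusion calls with `gene_a < gene_b`
#'   alphabetically; attribute `n_skipped` counts evidence records dropped
#'   for short clips or off-panel loci.
#' @export
detect_fusions <- function(evidence, panel, min_clip = 20L,
                           tolerance = 5L, min_reads = 2L) {
  locate_gene <- function(chrom, pos) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    hits <- GenomicRanges::findOverlaps(gr, panel)
    g <- rep(NA_character_, length(gr))
    g[S4Vectors::queryHits(hits)] <- panel$gene[S4Vectors::subjectHits(hits)]
    g
  }
  if (nrow(evidence) == 0L)
    return(cluster_breakpoints(evidence, tolerance, min_reads))
  ev <- evidence
  usable <- ev$clip_len >= min_clip
  ev$gene_a <- locate_gene(ev$chrom_a, ev$pos_a)
  ev$gene_b <- locate_gene(ev$chrom_b, ev$pos_b)
  usable <- usable & !is.na(ev$gene_a) & !is.na(ev$gene_b)
  n_skipped <- sum(!usable)
  if (n_skipped > 0L)
    warning(n_skipped, " evidence record(s) skipped (short clip or off-panel locus)")
  ev <- ev[usable & ev$gene_a != ev$gene_b, , drop = FALSE]
  # collapse both read orientations onto the alphabetical gene pair
  flip <- ev$gene_a > ev$gene_b
  if (any(flip)) {
    tmp <- ev[flip, c("gene_a", "chrom_a", "pos_a", "strand_a")]
    ev[flip, c("gene_a", "chrom_a", "pos_a", "strand_a")] <-
      ev[flip, c("gene_b", "chrom_b", "pos_b", "strand_b")]
    ev[flip, c("gene_b", "chrom_b", "pos_b", "strand_b")] <- tmp
  }
  if (nrow(ev) == 0L)
    return(cluster_breakpoints(ev[0, , drop = FALSE], tolerance, min_reads))
  parts <- split(ev, paste(ev$gene_a, ev$gene_b, sep = "--"))
  out <- do.call(rbind, lapply(parts, cluster_breakpoints,
                               tolerance = tolerance, min_reads = min_reads))
  rownames(out) <- NULL
  out <- out[order(-out$spanning_reads, out$gene_a, out$gene_b), , drop = FALSE]
  attr(out, "n_skipped") <- n_skipped
  out
}
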