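# Independent brute-force oracles. These deliberately re-derive each quantity
# with the simplest possible algorithm (per-base scans, set enumeration,
# explicit loops) and stay independent of the package's implementation paths.

# per-base scan: count coding panel bases with depth >= min_depth
oracle_panel_size <- function(depth_df, panel_df, min_depth) {
  count <- 0L
  coding <- panel_df[panel_df$is_coding, , drop = FALSE]
  for (i in seq_len(nrow(coding))) {
    for (base in seq(coding$start[i] + 1L, coding$end[i])) {  # 1-based positions
      d <- 0
      for (j in seq_len(nrow(depth_df))) {
        if (depth_df$chrom[j] == coding$chrom[i] &&
            base > depth_df$start[j] && base <= depth_df$end[j]) {
          d <- depth_df$depth[j]
          break
        }
      }
      if (d >= min_depth) count <- count + 1L
    }
  }
  count
}

# explicit re-application of the TMB eligibility filter, one variant at a time
oracle_tmb_count <- function(variants, min_vaf = 0.05, min_alt = 5, min_depth = 15) {
  n <- 0L
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    ok <- v$filter_pass && !v$in_dbsnp && v$is_coding &&
      v$consequence != "synonymous" && v$vaf >= min_vaf &&
      v$alt_depth >= min_alt && v$total_depth >= min_depth
    if (ok) n <- n + 1L
  }
  n
}

# set-based confusion counts (exact string keys, no normalization — callers
# supply already-normalized alleles)
oracle_confusion <- function(truth, calls) {
  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt)
  tk <- key(truth); ck <- unique(key(calls))
  pos <- tk[truth$truth == "positive"]; neg <- tk[truth$truth == "negative"]
  list(tp = length(intersect(pos, ck)), fn = length(setdiff(pos, ck)),
       fp = length(intersect(neg, ck)), tn = length(setdiff(neg, ck)))
}

# per-gene mean of bin ratios by explicit loop
oracle_segment_means <- function(ratio, gene_of_bin) {
  genes <- sort(unique(gene_of_bin[!is.na(gene_of_bin)]))
  out <- numeric(length(genes)); names(out) <- genes
  for (g in genes) {
    vals <- c()
    for (i in seq_along(ratio))
      if (!is.na(gene_of_bin[i]) && gene_of_bin[i] == g && !is.na(ratio[i]))
        vals <- c(vals, ratio[i])
    out[g] <- mean(vals)
  }
  out
}

# breakpoint clustering by BFS over the pairwise both-loci-agree relation
oracle_cluster_sizes <- function(ev, tolerance) {
  n <- nrow(ev)
  linked <- function(i, j)
    ev$chrom_a[i] == ev$chrom_a[j] && ev$chrom_b[i] == ev$chrom_b[j] &&
    abs(ev$pos_a[i] - ev$pos_a[j]) <= tolerance &&
    abs(ev$pos_b[i] - ev$pos_b[j]) <= tolerance
  comp <- rep(NA_integer_, n); cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      i <- queue[1L]; queue <- queue[-1L]
      for (j in seq_len(n)) {
        if (is.na(comp[j]) && linked(i, j)) {
          comp[j] <- cid
          queue <- c(queue, j)
        }
      }
    }
  }
  sort(as.integer(table(comp)))
}

# closed-form OLS via the normal equations
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# small panel used across unit tests: 3 genes, coding + one non-coding interval
tiny_panel <- function() {
  panel_granges(
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    start = c(0L, 5000L, 0L, 2000L),
    end = c(1000L, 6000L, 1500L, 2600L),
    gene = c("GA", "GB", "GC", "GC"),
    is_coding = c(TRUE, TRUE, TRUE, FALSE)
  )
}

# flat depth profile over a panel
flat_profile <- function(panel, depth) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(panel)),
                   start = GenomicRanges::start(panel) - 1L,
                   end = GenomicRanges::end(panel))
  depth_granges(df$chrom, df$start, df$end, rep(depth, nrow(df)))
}

grange_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             depth = if (!is.null(gr$depth)) gr$depth else NA,
             is_coding = if (!is.null(gr$is_coding)) gr$is_coding else NA)
}
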