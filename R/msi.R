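#' Microsatellite instability (MSI)
#'
#' @name msi
#' @keywords internal
NULL

.PCR_MSI_MARKERS <- c("BAT-25", "BAT-26", "MONO-27", "NR-21", "NR-24")

#' Read microsatellite locus repeat-length tables
#'
#' Expects a TSV with columns `locus_id`, `chrom`, `pos`, `repeat_unit`,
#' `sample` (`"tumor"` or `"normal"`), `length` (repeat length in units) and
#' `count` (supporting reads). Tumor and normal rows may live in one file or
#' in two files passed separately.
#'
#' @param tumor_path Path to the tumor (or combined) TSV.
#' @param normal_path Optional path to the normal TSV.
#' @return A `data.frame` in long format with the columns above.
#' @export
read_msi_profiles <- function(tumor_path, normal_path = NULL) {
  dt <- data.table::fread(tumor_path, data.table = FALSE)
  if (!is.null(normal_path))
    dt <- rbind(dt, data.table::fread(normal_path, data.table = FALSE))
  need <- c("locus_id", "sample", "length", "count")
  if (!all(need %in% names(dt)))
    stop("MSI profile needs columns: ", paste(need, collapse = ", "))
  if (!all(dt$sample %in% c("tumor", "normal")))
    stop("sample column must be 'tumor' or 'normal'")
  dt
}

# counts: named numeric vectors (name = repeat length). Returns the 2 x K
# contingency table with adjacent length bins merged until every cell's
# expected count under independence is >= 5.
.msi_contingency <- function(normal_counts, tumor_counts) {
  lens <- sort(unique(as.integer(c(names(normal_counts), names(tumor_counts)))))
  m <- rbind(
    normal = vapply(lens, function(l) sum(normal_counts[names(normal_counts) == l]), 0),
    tumor  = vapply(lens, function(l) sum(tumor_counts[names(tumor_counts) == l]), 0)
  )
  colnames(m) <- lens
  repeat {
    if (ncol(m) <= 1L) break
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    low <- which(apply(e, 2L, min) < 5)
    if (!length(low)) break
    j <- low[1L]
    k <- if (j == ncol(m)) j - 1L else j + 1L  # merge into adjacent bin
    m[, k] <- m[, k] + m[, j]
    m <- m[, -j, drop = FALSE]
  }
  m
}

#' Test one microsatellite locus for instability
#'
#' A locus is unstable when a two-sample chi-squared test comparing the
#' tumor and normal repeat-length distributions (adjacent length bins merged
#' until all expected counts reach 5) rejects at `alpha` AND the tumor modal
#' repeat length differs from the normal modal length. Loci with fewer than
#' `min_reads` reads in either sample are not evaluable and return `NA`.
#'
#' @param normal_counts,tumor_counts Named numeric vectors mapping repeat
#'   length to read count.
#' @param alpha Test level (default 0.05).
#' @param min_reads Minimum reads per sample for the locus to be evaluable
#'   (default 20).
#' @return `TRUE` (unstable), `FALSE` (stable) or `NA` (not evaluable).
#' @export
call_locus_instability <- function(normal_counts, tumor_counts,
                                   alpha = 0.05, min_reads = 20L) {
  if (any(c(normal_counts, tumor_counts) < 0))
    stop("repeat-length counts must be non-negative")
  if (sum(normal_counts) < min_reads || sum(tumor_counts) < min_reads)
    return(NA)
  m <- .msi_contingency(normal_counts, tumor_counts)
  if (ncol(m) <= 1L) return(FALSE)
  p <- suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
  if (is.na(p)) return(FALSE)
  modal <- function(x) as.integer(names(x)[which.max(x)])
  (p < alpha) && modal(tumor_counts) != modal(normal_counts)
}

#' Classify a sample's MSI status from locus profiles
#'
#' Each locus with sufficient reads in both tumor and normal is tested with
#' [call_locus_instability()]; the sample is MSI-High when the percentage of
#' unstable loci among the detected (evaluable) loci reaches the threshold
#' (default 20 percent, inclusive), otherwise microsatellite-stable (MSS).
#' With zero evaluable loci the status is `"uncallable"`, never MSS.
#'
#' @param profiles Long-format locus table (see [read_msi_profiles()]).
#' @param threshold_pct MSI-High threshold in percent (default 20).
#' @param alpha,min_reads Per-locus test parameters.
#' @return An object of class `msi_result`: list with `n_loci_detected`,
#'   `n_unstable`, `proportion` (percent), `status` (`"MSI-H"`, `"MSS"` or
#'   `"uncallable"`), and the per-locus call table.
#' @export
classify_msi <- function(profiles, threshold_pct = 20,
                         alpha = 0.05, min_reads = 20L) {
  loci <- unique(profiles$locus_id)
  if (!length(loci)) stop("no loci in profile table")
  calls <- vapply(loci, function(id) {
    sub <- profiles[profiles$locus_id == id, ]
    nc <- setNames(sub$count[sub$sample == "normal"],
                   sub$length[sub$sample == "normal"])
    tc <- setNames(sub$count[sub$sample == "tumor"],
                   sub$length[sub$sample == "tumor"])
    if (!length(nc) || !length(tc)) return(NA)
    call_locus_instability(nc, tc, alpha = alpha, min_reads = min_reads)
  }, NA)
  detected <- sum(!is.na(calls))
  unstable <- sum(calls, na.rm = TRUE)
  if (detected == 0L) {
    status <- "uncallable"
    prop <- NA_real_
  } else {
    prop <- 100 * unstable / detected
    status <- if (prop >= threshold_pct) "MSI-H" else "MSS"
  }
  structure(
    list(n_loci_detected = detected, n_unstable = unstable,
         proportion = prop, status = status, threshold_pct = threshold_pct,
         locus_calls = data.frame(locus_id = loci, unstable = calls,
                                  row.names = NULL)),
    class = "msi_result"
  )
}

#' @export
print.msi_result <- function(x, ...) {
  if (x$status == "uncallable")
    cat("MSI: no evaluable loci -> uncallable\n")
  else
    cat(sprintf("MSI: %d/%d detected loci unstable (%.1f%%) -> %s (threshold %.0f%%, inclusive)\n",
                x$n_unstable, x$n_loci_detected, x$proportion, x$status,
                x$threshold_pct))
  invisible(x)
}

#' Classify MSI from the 5-marker PCR panel
#'
#' The fluorescent-PCR assay examines five mononucleotide repeat markers
#' (BAT-25, BAT-26, MONO-27, NR-21, NR-24). A sample with at least 2 altered
#' markers is MSI-High; otherwise it is microsatellite-stable.
#'
#' @param altered Logical vector of length 5 (optionally named with the
#'   marker names) indicating which markers are altered.
#' @return An object of class `pcr_msi_result`: list with `markers`,
#'   `altered`, `n_altered`, `status`.
#' @export
classify_msi_pcr <- function(altered) {
  if (length(altered) != 5L)
    stop("exactly 5 marker flags are required (",
         paste(.PCR_MSI_MARKERS, collapse = ", "), ")")
  altered <- as.logical(altered)
  if (anyNA(altered)) stop("marker flags must be TRUE/FALSE")
  nm <- if (!is.null(names(altered)) && all(nzchar(names(altered))))
    names(altered) else .PCR_MSI_MARKERS
  structure(
    list(markers = nm, altered = setNames(altered, nm),
         n_altered = sum(altered),
         status = if (sum(altered) >= 2L) "MSI-H" else "MSS"),
    class = "pcr_msi_result"
  )
}

#' @export
print.pcr_msi_result <- function(x, ...) {
  cat(sprintf("PCR MSI: %d/5 markers altered (%s) -> %s\n", x$n_altered,
              paste(x$markers[x$altered], collapse = ", "), x$status))
  invisible(x)
}
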