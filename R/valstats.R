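#' Analytical-validation statistics
#'
#' @name valstats
#' @keywords internal
NULL

#' Normalize an indel to its parsimonious left-aligned form
#'
#' Trims the common allele suffix, then the common prefix (advancing the
#' position), so equivalent representations of the same indel compare equal.
#'
#' @param pos,ref,alt Vectors of 1-based position and allele strings.
#' @return A `data.frame` with normalized `pos`, `ref`, `alt`.
#' @export
normalize_alleles <- function(pos, ref, alt) {
  n <- length(pos)
  pos <- as.integer(pos); ref <- as.character(ref); alt <- as.character(alt)
  for (i in seq_len(n)) {
    r <- strsplit(ref[i], "")[[1L]]; a <- strsplit(alt[i], "")[[1L]]
    while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]; a <- a[-length(a)]
    }
    while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
      r <- r[-1L]; a <- a[-1L]; pos[i] <- pos[i] + 1L
    }
    ref[i] <- paste(r, collapse = ""); alt[i] <- paste(a, collapse = "")
  }
  data.frame(pos = pos, ref = ref, alt = alt, stringsAsFactors = FALSE)
}

.variant_key <- function(df) {
  norm <- normalize_alleles(df$pos, df$ref, df$alt)
  paste(df$chrom, norm$pos, norm$ref, norm$alt, sep = ":")
}

#' Confusion counts against a truth set with declared negatives
#'
#' Matches calls to truth by exact chromosome/position/ref/alt (indels
#' compared after left-aligned normalization). The truth table declares both
#' positive sites (expected variants) and negative sites (positions verified
#' variant-free in the reference material); calls outside this universe are
#' ignored, so `tp + fp + tn + fn` equals the universe size.
#'
#' @param truth `data.frame` with `chrom`, `pos`, `ref`, `alt` and a `truth`
#'   column of `"positive"`/`"negative"`.
#' @param calls `data.frame` with `chrom`, `pos`, `ref`, `alt`.
#' @return An object of class `confusion_counts`: list with `tp`, `fp`,
#'   `tn`, `fn`, `sensitivity`, `specificity` (NA when a denominator is 0).
#' @export
confusion <- function(truth, calls) {
  if (!all(c("chrom", "pos", "ref", "alt", "truth") %in% names(truth)))
    stop("truth needs columns chrom, pos, ref, alt, truth")
  tk <- .variant_key(truth)
  if (anyDuplicated(tk)) stop("duplicate entries in the truth set")
  ck <- unique(.variant_key(calls))
  pos_keys <- tk[truth$truth == "positive"]
  neg_keys <- tk[truth$truth == "negative"]
  tp <- sum(pos_keys %in% ck)
  fn <- length(pos_keys) - tp
  fp <- sum(neg_keys %in% ck)
  tn <- length(neg_keys) - fp
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("tp=%d fp=%d tn=%d fn=%d | sensitivity %.4f, specificity %.4f\n",
              x$tp, x$fp, x$tn, x$fn, x$sensitivity, x$specificity))
  invisible(x)
}

#' Limit of detection from replicate detections
#'
#' The LOD is the minimum tested VAF level detected in at least 95 percent
#' of technical replicates (inclusive). When no level qualifies the LOD is
#' undefined (`NA`) and the per-level detail is still returned.
#'
#' @param detections `data.frame` with columns `level` (tested VAF) and
#'   `detected` (logical, one row per replicate); at least 3 replicates per
#'   level.
#' @param min_fraction Qualification fraction (default 0.95).
#' @return An object of class `lod_estimate`: list with `levels` (per-level
#'   `level`, `n`, `detected`, `fraction`) and `lod` (numeric or `NA`).
#' @export
estimate_lod <- function(detections, min_fraction = 0.95) {
  if (!all(c("level", "detected") %in% names(detections)))
    stop("detections needs columns level, detected")
  agg <- do.call(rbind, lapply(split(detections, detections$level), function(s)
    data.frame(level = s$level[1L], n = nrow(s), detected = sum(s$detected))))
  if (any(agg$n < 3L)) stop("at least 3 replicates per level are required")
  agg$fraction <- agg$detected / agg$n
  agg <- agg[order(agg$level), ]
  rownames(agg) <- NULL
  qual <- agg$level[agg$fraction >= min_fraction]
  structure(
    list(levels = agg, lod = if (length(qual)) min(qual) else NA_real_,
         min_fraction = min_fraction),
    class = "lod_estimate"
  )
}

#' @export
print.lod_estimate <- function(x, ...) {
  print(x$levels, row.names = FALSE)
  cat("LOD (detected in >= ", 100 * x$min_fraction, "% of replicates): ",
      if (is.na(x$lod)) "undefined" else x$lod, "\n", sep = "")
  invisible(x)
}

#' Concordance between paired categorical calls
#'
#' @param calls_a,calls_b Equal-length vectors of per-sample categorical
#'   calls (e.g. MSI status), paired by position or by names when both are
#'   named.
#' @return Fraction of pairs with identical category.
#' @export
concordance <- function(calls_a, calls_b) {
  if (!is.null(names(calls_a)) && !is.null(names(calls_b))) {
    if (!setequal(names(calls_a), names(calls_b)))
      stop("call sets are not paired: sample names differ")
    calls_b <- calls_b[names(calls_a)]
  } else if (length(calls_a) != length(calls_b)) {
    stop("call sets are not paired: lengths differ")
  }
  if (!length(calls_a)) stop("no paired calls")
  mean(calls_a == calls_b)
}

#' Ordinary least-squares linear fit with R-squared
#'
#' Thin wrapper over [stats::lm()] returning slope, intercept and
#' `R^2 = 1 - SS_res / SS_tot`, as used to report linearity between assay
#' results and reference values.
#'
#' @param x,y Paired numeric observations, `n >= 3`.
#' @return An object of class `linear_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
fit_linear <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("at least 3 paired observations are required")
  if (stats::var(x) == 0) stop("x has zero variance; slope is undefined")
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::var(y) == 0) 0 else suppressWarnings(summary(fit)$r.squared)
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = r2,
         n = length(x)),
    class = "linear_fit"
  )
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("OLS fit (n=%d): y = %.4f x + %.4f, R^2 = %.4f\n",
              x$n, x$slope, x$intercept, x$r_squared))
  invisible(x)
}
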