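#' Personalized ctDNA / minimal-residual-disease tracking
#'
#' @name mrd
#' @keywords internal
NULL

.MRD_WEIGHTS <- c(vaf = 0.30, pathogenicity = 0.25, type = 0.15,
                  dbfreq = 0.20, whitelist = 0.10)

#' Score tumor variants for MRD-tracking suitability
#'
#' Each candidate tumor variant receives a composite score in `[0, 1]`: a
#' weighted sum of five components reflecting the criteria used to pick
#' trackable mutations — tissue VAF, predicted pathogenicity, mutation type,
#' recurrence in large cancer databases, and internal validation as
#' tumor-derived:
#'
#' * `vaf_term = min(vaf / 0.5, 1)` — clonal variants score higher;
#' * `pathogenicity_term` — the supplied score in `[0, 1]`;
#' * `type_term` — 1.0 truncating (nonsense/frameshift/splice), 0.8 missense
#'   at a recurrent hotspot, 0.6 other missense, 0.3 everything else;
#' * `dbfreq_term = min(log10(1 + recurrence) / 3, 1)` — database recurrence
#'   on a log scale, saturating at 999 reports;
#' * `whitelist_term` — 1 when internally validated as tumor-derived, else 0.
#'
#' Missing annotations contribute 0 to their term (with a warning), never an
#' error. Default weights are `c(0.30, 0.25, 0.15, 0.20, 0.10)` in the order
#' above; weights are renormalized to sum to 1.
#'
#' @param variants Variant `data.frame`; optional annotation columns
#'   `pathogenicity` (in `[0, 1]`), `db_recurrence` (count),
#'   `hotspot` (logical), `whitelist` (logical).
#' @param weights Named numeric weights for `vaf`, `pathogenicity`, `type`,
#'   `dbfreq`, `whitelist`.
#' @return The input with columns `vaf_term`, `pathogenicity_term`,
#'   `type_term`, `dbfreq_term`, `whitelist_term`, `score` appended.
#' @export
score_variants <- function(variants, weights = .MRD_WEIGHTS) {
  if (is.null(names(weights)) || !setequal(names(weights), names(.MRD_WEIGHTS)))
    stop("weights must be named: ", paste(names(.MRD_WEIGHTS), collapse = ", "))
  weights <- weights[names(.MRD_WEIGHTS)] / sum(weights)
  n <- nrow(variants)
  grab <- function(col, default) {
    if (!is.null(variants[[col]])) variants[[col]]
    else {
      warning("annotation column '", col, "' missing; its term scores 0")
      rep(default, n)
    }
  }
  v <- variants
  v$vaf_term <- pmin(v$vaf / 0.5, 1)
  patho <- grab("pathogenicity", 0)
  v$pathogenicity_term <- ifelse(is.na(patho), 0, pmin(pmax(patho, 0), 1))
  hotspot <- grab("hotspot", FALSE)
  v$type_term <- ifelse(v$consequence %in% c("nonsense", "frameshift", "splice"), 1.0,
                 ifelse(v$consequence == "missense" & !is.na(hotspot) & hotspot, 0.8,
                 ifelse(v$consequence == "missense", 0.6, 0.3)))
  rec <- grab("db_recurrence", 0)
  v$dbfreq_term <- pmin(log10(1 + ifelse(is.na(rec), 0, rec)) / 3, 1)
  wl <- grab("whitelist", FALSE)
  v$whitelist_term <- as.numeric(!is.na(wl) & wl)
  v$score <- combine_score(
    cbind(vaf = v$vaf_term, pathogenicity = v$pathogenicity_term,
          type = v$type_term, dbfreq = v$dbfreq_term,
          whitelist = v$whitelist_term),
    weights)
  v
}

#' Combine score components into the composite MRD score
#'
#' @param components Numeric vector (one variant) or matrix (rows =
#'   variants) with entries in `[0, 1]`, named/columned `vaf`,
#'   `pathogenicity`, `type`, `dbfreq`, `whitelist`.
#' @param weights Named weights (renormalized to sum to 1).
#' @return Numeric score(s) in `[0, 1]`.
#' @export
combine_score <- function(components, weights = .MRD_WEIGHTS) {
  weights <- weights[names(.MRD_WEIGHTS)] / sum(weights)
  if (is.null(dim(components)))
    components <- matrix(components, nrow = 1L,
                         dimnames = list(NULL, names(components)))
  if (any(components < 0 | components > 1))
    stop("score components must lie in [0, 1]")
  as.numeric(components[, names(.MRD_WEIGHTS), drop = FALSE] %*% weights)
}

#' Rank scored variants and select the tracking set
#'
#' Variants are ordered by score (descending), breaking ties by VAF
#' (descending) then by `(chrom, pos)` ascending, and the top
#' `min(k_max, n)` are returned (default top 2–5 per patient). When fewer
#' than `k_min` candidates exist the selection is still returned but flagged
#' with attribute `insufficient = TRUE`.
#'
#' @param scored Output of [score_variants()].
#' @param k_min,k_max Bounds on the tracking-set size (defaults 2 and 5).
#' @return The selected rows with a `rank` column; attribute `insufficient`.
#' @export
select_tracking_variants <- function(scored, k_min = 2L, k_max = 5L) {
  if (nrow(scored) == 0L) stop("no candidate variants to select from")
  ord <- order(-scored$score, -scored$vaf, scored$chrom, scored$pos)
  ranked <- scored[ord, , drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  sel <- ranked[seq_len(min(k_max, nrow(ranked))), , drop = FALSE]
  attr(sel, "insufficient") <- nrow(sel) < k_min
  sel
}

#' Call ctDNA positivity for one plasma timepoint
#'
#' Each tracked variant is measured by an ultra-deep amplicon (average
#' 100,000X). Amplicons with coverage below `min_coverage` (default 10,000X)
#' are unsuccessful and excluded. The timepoint is ctDNA-positive when at
#' least one evaluable amplicon has VAF strictly above `vaf_threshold_pct`
#' (default 0.05 percent); with no evaluable amplicon the status is
#' `"uncallable"`, never negative.
#'
#' @param measurements `data.frame` with columns `variant_id`, `coverage`,
#'   `alt_reads` (and optionally `timepoint`, `date`).
#' @param vaf_threshold_pct Positivity threshold in percent, strict
#'   (default 0.05).
#' @param min_coverage Amplicon evaluability floor, inclusive
#'   (default 10000).
#' @param label Optional collection label (e.g. "pre-op").
#' @param input_ok Pre-analytic cfDNA input flag (>= 0.15 ng/uL or >= 3 ng
#'   total); recorded, not gating.
#' @return An object of class `plasma_timepoint`: list with `label`,
#'   `measurements` (with `vaf_pct`, `evaluable`), `n_evaluable`,
#'   `max_vaf_pct`, `ctdna_positive` (`TRUE`/`FALSE`/`NA` for uncallable),
#'   `status`, `input_ok`.
#' @export
call_plasma <- function(measurements, vaf_threshold_pct = 0.05,
                        min_coverage = 10000L, label = NA_character_,
                        input_ok = TRUE) {
  if (nrow(measurements) == 0L) stop("at least one amplicon measurement is required")
  if (any(measurements$coverage < 0) || any(measurements$alt_reads < 0))
    stop("read counts must be non-negative")
  if (any(measurements$alt_reads > measurements$coverage))
    stop("alt_reads exceeds coverage")
  m <- measurements
  m$vaf_pct <- ifelse(m$coverage > 0, 100 * m$alt_reads / m$coverage, 0)
  m$evaluable <- m$coverage >= min_coverage
  ev <- m[m$evaluable, , drop = FALSE]
  if (nrow(ev) == 0L) {
    positive <- NA
    status <- "uncallable"
    max_vaf <- NA_real_
  } else {
    positive <- any(ev$vaf_pct > vaf_threshold_pct)
    status <- if (positive) "ctDNA-positive" else "ctDNA-negative"
    max_vaf <- max(ev$vaf_pct)
  }
  structure(
    list(label = label, measurements = m, n_evaluable = nrow(ev),
         max_vaf_pct = max_vaf, ctdna_positive = positive, status = status,
         threshold_pct = vaf_threshold_pct, input_ok = input_ok),
    class = "plasma_timepoint"
  )
}

#' @export
print.plasma_timepoint <- function(x, ...) {
  cat(sprintf("Plasma %s: %d evaluable amplicon(s), max VAF %s%% -> %s\n",
              if (is.na(x$label)) "timepoint" else x$label, x$n_evaluable,
              if (is.na(x$max_vaf_pct)) "NA" else sprintf("%.4f", x$max_vaf_pct),
              x$status))
  invisible(x)
}

#' Longitudinal ctDNA trajectory and MRD events
#'
#' Given plasma timepoints in collection order, reports per-timepoint
#' positivity and maximal VAF and derives the surveillance events:
#' *clearance* (positive at one timepoint, negative at the next) and
#' *molecular relapse* (negative, then positive again). A patient positive
#' throughout is summarized as persistent MRD.
#'
#' @param timepoints List of `plasma_timepoint` objects, ordered by
#'   collection date.
#' @param dates Optional vector (sortable) of collection dates; must be
#'   non-decreasing when given.
#' @return An object of class `mrd_trajectory`: list with `table`
#'   (per-timepoint summary), `events` (`data.frame` of `event`,
#'   `after_label`, `at_label`, `at_index`) and `summary` (one of
#'   `"never-positive"`, `"cleared"`, `"molecular-relapse"`,
#'   `"persistent-MRD"`).
#' @export
track_longitudinal <- function(timepoints, dates = NULL) {
  stopifnot(length(timepoints) >= 1L,
            all(vapply(timepoints, inherits, TRUE, "plasma_timepoint")))
  if (!is.null(dates)) {
    if (length(dates) != length(timepoints)) stop("one date per timepoint required")
    if (is.unsorted(dates)) stop("timepoints must be ordered by collection date")
  }
  tab <- data.frame(
    index = seq_along(timepoints),
    label = vapply(timepoints, function(x) x$label, ""),
    positive = vapply(timepoints, function(x) as.logical(x$ctdna_positive), NA),
    max_vaf_pct = vapply(timepoints, function(x) as.numeric(x$max_vaf_pct), 0)
  )
  events <- data.frame(event = character(), after_label = character(),
                       at_label = character(), at_index = integer())
  st <- tab$positive
  for (i in seq_len(nrow(tab) - 1L)) {
    a <- st[i]; b <- st[i + 1L]
    if (isTRUE(a) && isFALSE(b))
      events <- rbind(events, data.frame(event = "clearance",
                                         after_label = tab$label[i],
                                         at_label = tab$label[i + 1L],
                                         at_index = i + 1L))
    if (isFALSE(a) && isTRUE(b))
      events <- rbind(events, data.frame(event = "molecular_relapse",
                                         after_label = tab$label[i],
                                         at_label = tab$label[i + 1L],
                                         at_index = i + 1L))
  }
  known <- st[!is.na(st)]
  summary <- if (!any(known)) "never-positive"
    else if ("molecular_relapse" %in% events$event) "molecular-relapse"
    else if ("clearance" %in% events$event) "cleared"
    else "persistent-MRD"
  structure(list(table = tab, events = events, summary = summary),
            class = "mrd_trajectory")
}

#' @export
print.mrd_trajectory <- function(x, ...) {
  cat("Longitudinal ctDNA trajectory:\n")
  print(x$table, row.names = FALSE)
  if (nrow(x$events)) {
    cat("Events:\n")
    print(x$events, row.names = FALSE)
  }
  cat("Summary:", x$summary, "\n")
  invisible(x)
}
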