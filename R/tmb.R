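#' Tumor mutational burden (TMB)
#'
#' @name tmb
#' @keywords internal
NULL

#' Eligibility of a somatic variant for TMB counting
#'
#' A somatic variant counts toward TMB when all of the following hold: it
#' passed caller filters, it is not a likely-germline (population-database)
#' hit, it lies in a coding region, it is not synonymous, and it meets the
#' depth criteria VAF >= 5 percent, allele depth >= 5 reads, total depth
#' >= 15 reads (all inclusive).
#'
#' @param variants Variant `data.frame` (see [variant_records()]).
#' @param min_vaf Minimum VAF, inclusive (default 0.05).
#' @param min_alt Minimum alt-supporting reads, inclusive (default 5).
#' @param min_depth Minimum total depth, inclusive (default 15).
#' @return Logical vector, one element per variant.
#' @export
is_tmb_eligible <- function(variants, min_vaf = 0.05, min_alt = 5L,
                            min_depth = 15L) {
  variants$filter_pass &
    !variants$in_dbsnp &
    variants$is_coding &
    variants$consequence != "synonymous" &
    variants$vaf >= min_vaf &
    variants$alt_depth >= min_alt &
    variants$total_depth >= min_depth
}

#' Compute the TMB score and classification
#'
#' TMB is the number of eligible somatic variants divided by the effective
#' panel size in megabases, where the effective size counts coding panel
#' bases with total depth >= 15X. Samples score TMB-High when the score
#' reaches the threshold (default 10 mutations/Mb, inclusive).
#'
#' @param variants Somatic variant `data.frame`.
#' @param depth_profile Depth `GRanges` covering the panel.
#' @param panel Panel `GRanges`.
#' @param threshold TMB-High threshold in mutations/Mb (default 10).
#' @param min_vaf,min_alt,min_depth Eligibility bounds, see
#'   [is_tmb_eligible()]; `min_depth` is also the effective-size depth floor.
#' @return An object of class `tmb_result`: list with `eligible_count`,
#'   `panel_mb`, `score`, `status` (`"TMB-H"` or `"TMB-L"`).
#' @export
compute_tmb <- function(variants, depth_profile, panel, threshold = 10,
                        min_vaf = 0.05, min_alt = 5L, min_depth = 15L) {
  size <- effective_panel_size(depth_profile, panel, min_depth = min_depth)
  if (size <= 0L)
    stop("effective panel size is zero; TMB is not computable")
  n <- sum(is_tmb_eligible(variants, min_vaf = min_vaf, min_alt = min_alt,
                           min_depth = min_depth))
  mb <- size / 1e6
  score <- n * 1e6 / size  # integer-first arithmetic keeps boundaries exact
  structure(
    list(eligible_count = n, panel_mb = mb, score = score,
         status = if (score >= threshold) "TMB-H" else "TMB-L",
         threshold = threshold),
    class = "tmb_result"
  )
}

#' @export
print.tmb_result <- function(x, ...) {
  cat(sprintf("TMB: %d eligible variants / %.4f Mb = %.2f mut/Mb -> %s (threshold %.1f, inclusive)\n",
              x$eligible_count, x$panel_mb, x$score, x$status, x$threshold))
  invisible(x)
}

#' Specification of a tumor/normal in-silico mix
#'
#' Describes one point of the dilution experiment: tumor and normal material
#' mixed at `tumor_parts : normal_parts` (tumor fraction
#' `tumor_parts / (tumor_parts + normal_parts)`), downsampled to a target
#' mean depth.
#'
#' @param tumor_parts Positive integer parts of tumor material.
#' @param normal_parts Non-negative integer parts of normal material.
#' @param target_mean_depth Target mean depth after downsampling (X).
#' @param seed RNG seed for the mix.
#' @return A list of class `mix_spec` with a `tumor_fraction` element.
#' @export
mix_spec <- function(tumor_parts, normal_parts, target_mean_depth, seed = 1L) {
  if (tumor_parts <= 0L || normal_parts < 0L)
    stop("tumor_parts must be positive and normal_parts non-negative")
  structure(
    list(tumor_parts = as.integer(tumor_parts),
         normal_parts = as.integer(normal_parts),
         tumor_fraction = tumor_parts / (tumor_parts + normal_parts),
         target_mean_depth = target_mean_depth,
         seed = as.integer(seed)),
    class = "mix_spec"
  )
}

#' Mix tumor and normal per-site allele counts and downsample
#'
#' Emulates mixing tumor and normal sequencing material at a fixed ratio
#' followed by random downsampling to a target depth, at the level of
#' per-site allele counts. For each site the sampled depth is split between
#' the two source pools binomially at the mix's tumor fraction, and alleles
#' are then drawn without replacement (hypergeometric) from each source's
#' observed alt/ref reads. Planted VAFs therefore scale by the tumor
#' fraction in expectation: `E[vaf] = f * vaf_tumor + (1 - f) * vaf_normal`.
#'
#' @param tumor Variant `data.frame` for the tumor source (per-site
#'   `alt_depth`, `total_depth`).
#' @param normal Optional matching `data.frame` with normal-source
#'   `alt_depth`/`total_depth` per site (same row order). When `NULL`, the
#'   normal pool is taken as alt-free with the tumor's depths.
#' @param spec A [mix_spec()].
#' @param site_depths Optional integer vector of target total depths per
#'   site; defaults to `target_mean_depth` at every site.
#' @return The tumor `data.frame` with `alt_depth`, `total_depth` and `vaf`
#'   replaced by their mixed, downsampled values.
#' @export
mix_allele_counts <- function(tumor, normal = NULL, spec,
                              site_depths = NULL) {
  stopifnot(inherits(spec, "mix_spec"))
  n <- nrow(tumor)
  if (is.null(normal)) {
    normal <- tumor
    normal$alt_depth <- 0L
  }
  if (nrow(normal) != n)
    stop("tumor and normal site tables must align row-for-row")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  d <- if (is.null(site_depths)) rep.int(round(spec$target_mean_depth), n)
       else rep_len(as.integer(site_depths), n)
  f <- spec$tumor_fraction
  from_tumor <- stats::rbinom(n, d, f)
  from_normal <- d - from_tumor
  if (any(from_tumor > tumor$total_depth) || any(from_normal > normal$total_depth))
    stop("target depth exceeds available source material at one or more sites")
  alt_t <- stats::rhyper(n, tumor$alt_depth,
                         tumor$total_depth - tumor$alt_depth, from_tumor)
  alt_n <- stats::rhyper(n, normal$alt_depth,
                         normal$total_depth - normal$alt_depth, from_normal)
  out <- tumor
  out$alt_depth <- as.integer(alt_t + alt_n)
  out$total_depth <- as.integer(d)
  out$vaf <- ifelse(d > 0, out$alt_depth / d, 0)
  out
}

#' In-silico TMB stability experiment over tumor fraction and depth
#'
#' Dilutes a tumor fixture with matched-normal material at a grid of tumor
#' fractions, downsamples to a grid of mean depths, recomputes TMB for each
#' replicate and flags replicates failing the sample QC gate. Reproduces the
#' dilution-series design used to establish the assay's TMB stability
#' envelope (stable for tumor fraction >= 0.30 at mean depth >= 150X).
#'
#' @param tumor Tumor variant `data.frame` carrying tissue-level VAFs and
#'   depths (every row assumed TMB-eligible at full fraction).
#' @param panel Panel `GRanges`.
#' @param fractions Tumor fractions to simulate
#'   (default `c(0.75, 0.5, 0.4, 0.3, 0.2, 0.1)`, i.e. mix ratios 3:1, 1:1,
#'   2:3, 3:7, 1:4, 1:9).
#' @param depths Target mean depths in X (default `c(500, 250, 150, 100)`).
#' @param reps Replicates per grid point (default 20).
#' @param seed Base RNG seed.
#' @param bin_width Width of the simulated coverage bins (default 100).
#' @param dispersion Negative-binomial size parameter for coverage noise
#'   (default 20; larger is closer to Poisson).
#' @return A `data.frame` with one row per replicate: `fraction`,
#'   `target_depth`, `rep`, `mean_depth`, `pct_cov_100x`, `qc_pass`,
#'   `eligible_count`, `tmb`.
#' @export
tmb_stability_experiment <- function(tumor, panel,
                                     fractions = c(0.75, 0.5, 0.4, 0.3, 0.2, 0.1),
                                     depths = c(500, 250, 150, 100),
                                     reps = 20L, seed = 1L,
                                     bin_width = 100L, dispersion = 20) {
  grid <- expand.grid(fraction = fractions, target_depth = depths,
                      rep = seq_len(reps))
  coding <- GenomicRanges::reduce(GenomicRanges::granges(panel[panel$is_coding]))
  bins <- GenomicRanges::slidingWindows(coding, width = bin_width, step = bin_width)
  bins <- unlist(bins)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sd_i <- (seed + i * 1009L) %% .Machine$integer.max
    set.seed(sd_i)
    bin_depth <- stats::rnbinom(length(bins), mu = g$target_depth,
                                size = dispersion)
    profile <- bins
    S4Vectors::mcols(profile)$depth <- as.numeric(bin_depth)
    qc <- profile_qc(profile, panel)
    parts <- round(g$fraction * 100)
    sp <- mix_spec(parts, 100 - parts, g$target_depth, seed = sd_i + 1L)
    site_depths <- pmax(1L, stats::rnbinom(nrow(tumor), mu = g$target_depth,
                                           size = dispersion))
    diluted <- mix_allele_counts(tumor, spec = sp, site_depths = site_depths)
    tm <- compute_tmb(diluted, profile, panel)
    out[[i]] <- data.frame(fraction = g$fraction, target_depth = g$target_depth,
                           rep = g$rep, mean_depth = qc$mean_depth,
                           pct_cov_100x = qc$pct_cov_100x, qc_pass = qc$passed,
                           eligible_count = tm$eligible_count, tmb = tm$score)
  }
  do.call(rbind, out)
}
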