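eligible_template <- function(...) {
  args <- modifyList(list(chrom = "chr1", pos = 10L, ref = "A", alt = "G",
                          alt_depth = 5L, total_depth = 15L,
                          vaf = NA_real_, filter_pass = TRUE,
                          in_dbsnp = FALSE, consequence = "missense"),
                     list(...))
  do.call(variant_records, args)
}

test_that("TMB eligibility applies every criterion with inclusive bounds", {
  expect_true(is_tmb_eligible(eligible_template()))  # exactly 5/15 -> 0.333 vaf
  v <- eligible_template(alt_depth = 5L, total_depth = 100L)  # vaf exactly 0.05
  expect_true(is_tmb_eligible(v))
  expect_false(is_tmb_eligible(eligible_template(consequence = "synonymous")))
  expect_false(is_tmb_eligible(eligible_template(in_dbsnp = TRUE)))
  expect_false(is_tmb_eligible(eligible_template(filter_pass = FALSE)))
  expect_false(is_tmb_eligible(eligible_template(consequence = "noncoding")))
  low_vaf <- eligible_template(alt_depth = 49L, total_depth = 1000L)  # 0.049
  expect_false(is_tmb_eligible(low_vaf))
  expect_false(is_tmb_eligible(eligible_template(alt_depth = 4L, total_depth = 15L)))
  expect_false(is_tmb_eligible(eligible_template(alt_depth = 5L, total_depth = 14L)))
})

test_that("TMB score is eligible count over effective megabases, threshold inclusive", {
  pan <- generate_panel(n_genes = 10L, total_coding_bp = 1.7e5)
  prof <- flat_profile(pan, 500)
  # 17 eligible on 1.7e5 bases -> 100 mut/Mb; scale: plant 17 on 0.17 Mb
  v <- variant_records(rep("chr1", 17), 10000L + (1:17) * 20L,
                       rep("A", 17), rep("G", 17),
                       alt_depth = rep(50L, 17), total_depth = rep(500L, 17))
  tm <- compute_tmb(v, prof, pan)
  expect_equal(tm$eligible_count, 17L)
  expect_equal(tm$panel_mb, 0.17)
  expect_equal(tm$score, 100)
  expect_equal(tm$status, "TMB-H")
  # boundary: score exactly at threshold classifies high
  tm10 <- compute_tmb(v, prof, pan, threshold = 100)
  expect_equal(tm10$status, "TMB-H")
  expect_equal(compute_tmb(v, prof, pan, threshold = 100.0001)$status, "TMB-L")
  # zero eligible variants
  tm0 <- compute_tmb(empty_variants <- v[0, ], prof, pan)
  expect_equal(tm0$score, 0)
  expect_equal(tm0$status, "TMB-L")
})

test_that("TMB with zero effective panel size is an error, not zero", {
  pan <- tiny_panel()
  expect_error(compute_tmb(eligible_template(), flat_profile(pan, 5), pan),
               "not computable")
})

test_that("TMB is permutation-invariant and ignores added ineligible variants", {
  pan <- tiny_panel()
  prof <- flat_profile(pan, 500)
  set.seed(3)
  v <- variant_records("chr1", sample(1:1000, 20), rep("A", 20), rep("G", 20),
                       alt_depth = sample(20:60, 20, TRUE),
                       total_depth = rep(400L, 20))
  base <- compute_tmb(v, prof, pan)$score
  perm <- compute_tmb(v[sample(nrow(v)), ], prof, pan)$score
  expect_equal(perm, base)
  extra <- variant_records("chr2", 1:5, rep("C", 5), rep("T", 5),
                           alt_depth = rep(50L, 5), total_depth = rep(400L, 5),
                           consequence = "synonymous")
  expect_equal(compute_tmb(rbind(v, extra), prof, pan)$score, base)
})

test_that("TMB eligible count matches the brute-force filter on random instances", {
  pan <- tiny_panel()
  prof <- flat_profile(pan, 500)
  set.seed(101)
  for (k in 1:50) {
    n <- sample(5:40, 1)
    depth <- sample(5:400, n, replace = TRUE)
    v <- variant_records(
      "chr1", sample(1e6, n), rep("A", n), rep("G", n),
      alt_depth = pmin(depth, sample(0:40, n, TRUE)), total_depth = depth,
      filter_pass = sample(c(TRUE, FALSE), n, TRUE, prob = c(.8, .2)),
      in_dbsnp = sample(c(TRUE, FALSE), n, TRUE, prob = c(.2, .8)),
      consequence = sample(c("missense", "synonymous", "nonsense", "noncoding"),
                           n, TRUE)
    )
    expect_equal(compute_tmb(v, prof, pan)$eligible_count, oracle_tmb_count(v))
  }
})

test_that("mix specification computes tumor fractions from part ratios", {
  expect_equal(mix_spec(3, 1, 500)$tumor_fraction, 0.75)
  expect_equal(mix_spec(1, 1, 500)$tumor_fraction, 0.5)
  expect_equal(mix_spec(3, 7, 500)$tumor_fraction, 0.3)
  expect_equal(mix_spec(1, 9, 500)$tumor_fraction, 0.1)
  expect_error(mix_spec(0, 1, 500))
})

test_that("mixing scales planted VAFs by the tumor fraction within 3 binomial SDs", {
  pan <- tiny_panel()
  fx <- generate_tmb_stability_fixture(pan, n_eligible = 30L, seed = 5L)
  reps <- 120L
  for (f in c(0.75, 0.3)) {
    parts <- round(f * 100)
    vafs <- matrix(NA_real_, reps, nrow(fx$variants))
    for (r in seq_len(reps)) {
      sp <- mix_spec(parts, 100 - parts, 400, seed = 1000L + r)
      vafs[r, ] <- mix_allele_counts(fx$variants, spec = sp)$vaf
    }
    obs <- colMeans(vafs)
    expected <- f * fx$variants$vaf
    # slope of observed means on tissue VAFs should equal the fraction
    slope <- fit_linear(fx$variants$vaf, obs)$slope
    expect_equal(slope, f, tolerance = 0.05)
    # and the pooled deviation from the binomial expectation stays within
    # 3 SDs of the pooled mean
    dev <- mean(obs - expected)
    pooled_sd <- sqrt(mean(expected * (1 - expected) / 400) / (reps * length(obs)))
    expect_lt(abs(dev), 3 * pooled_sd + 1e-12)
  }
})

test_that("mixing is reproducible under a fixed seed and errors on exhausted material", {
  pan <- tiny_panel()
  fx <- generate_tmb_stability_fixture(pan, n_eligible = 10L, seed = 2L)
  sp <- mix_spec(1, 1, 300, seed = 99L)
  a <- mix_allele_counts(fx$variants, spec = sp)
  b <- mix_allele_counts(fx$variants, spec = sp)
  expect_identical(a, b)
  deep <- mix_spec(1, 0, 1e6, seed = 1L)
  expect_error(mix_allele_counts(fx$variants, spec = deep), "exceeds")
})

test_that("undiluted material at full depth reproduces the fixture's truth TMB", {
  pan <- generate_panel(n_genes = 20L, total_coding_bp = 1.7e5)
  fx <- generate_tmb_stability_fixture(pan, n_eligible = 17L, seed = 9L)
  res <- tmb_stability_experiment(fx$variants, pan, fractions = 1,
                                  depths = 500, reps = 3L, seed = 4L)
  expect_true(all(abs(res$tmb - fx$truth_tmb) / fx$truth_tmb < 0.05))
  expect_true(all(res$qc_pass))
})
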