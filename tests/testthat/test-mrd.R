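mk_candidates <- function(n, seed = 1L) {
  set.seed(seed)
  v <- variant_records("chr1", seq_len(n) * 100L, rep("A", n), rep("G", n),
                       alt_depth = sample(20:200, n, TRUE),
                       total_depth = 400L,
                       consequence = sample(c("missense", "nonsense",
                                              "frameshift", "inframe_indel"),
                                            n, TRUE))
  v$pathogenicity <- runif(n)
  v$db_recurrence <- sample(0:2000, n, TRUE)
  v$hotspot <- sample(c(TRUE, FALSE), n, TRUE)
  v$whitelist <- sample(c(TRUE, FALSE), n, TRUE)
  v
}

test_that("composite score spans [0, 1] and reproduces the hand-computed example", {
  expect_equal(combine_score(c(vaf = 1, pathogenicity = 1, type = 1,
                               dbfreq = 1, whitelist = 1)), 1)
  expect_equal(combine_score(c(vaf = 0, pathogenicity = 0, type = 0,
                               dbfreq = 0, whitelist = 0)), 0)
  # components (1, 0.8, 0.6, 0.5, 1) with default weights
  got <- combine_score(c(vaf = 1, pathogenicity = 0.8, type = 0.6,
                         dbfreq = 0.5, whitelist = 1))
  expect_equal(got, 0.30 + 0.20 + 0.09 + 0.10 + 0.10)
})

test_that("score terms follow their defined transforms", {
  v <- variant_records("chr1", c(1L, 2L, 3L, 4L), rep("A", 4), rep("G", 4),
                       alt_depth = c(100L, 300L, 10L, 50L), total_depth = 400L,
                       consequence = c("nonsense", "missense", "missense",
                                       "inframe_indel"))
  v$pathogenicity <- c(0.5, 1, 0.2, NA)
  v$db_recurrence <- c(0, 999, 10000, 9)
  v$hotspot <- c(FALSE, TRUE, FALSE, FALSE)
  v$whitelist <- c(TRUE, FALSE, TRUE, FALSE)
  s <- score_variants(v)
  expect_equal(s$vaf_term, pmin(v$vaf / 0.5, 1))
  expect_equal(s$type_term, c(1.0, 0.8, 0.6, 0.3))
  expect_equal(s$dbfreq_term[1], 0)
  expect_equal(s$dbfreq_term[2], 1)        # log10(1000)/3 = 1
  expect_equal(s$dbfreq_term[3], 1)        # capped
  expect_equal(s$pathogenicity_term[4], 0) # missing annotation scores 0
  expect_equal(s$whitelist_term, c(1, 0, 1, 0))
  expect_true(all(s$score >= 0 & s$score <= 1))
})

test_that("missing annotation columns warn and score 0, never fail", {
  v <- variant_records("chr1", 1L, "A", "G", 100L, 400L)
  w <- capture_warnings(s <- score_variants(v))
  expect_true(any(grepl("pathogenicity", w)))
  expect_true(any(grepl("whitelist", w)))
  expect_equal(s$pathogenicity_term, 0)
  expect_equal(s$whitelist_term, 0)
})

test_that("score is monotone in each component with the others fixed", {
  base <- c(vaf = 0.4, pathogenicity = 0.5, type = 0.6, dbfreq = 0.3,
            whitelist = 0)
  for (comp in names(base)) {
    lo <- base; hi <- base
    lo[comp] <- 0.1; hi[comp] <- 0.9
    expect_lt(combine_score(lo), combine_score(hi))
  }
})

test_that("tracking-set selection returns the top 2-5 with deterministic ties", {
  sel50 <- select_tracking_variants(score_variants(mk_candidates(50)))
  expect_equal(nrow(sel50), 5L)
  expect_equal(sel50$rank, 1:5)
  expect_false(attr(sel50, "insufficient"))
  expect_true(all(diff(sel50$score) <= 0))
  sel3 <- select_tracking_variants(score_variants(mk_candidates(3)))
  expect_equal(nrow(sel3), 3L)
  expect_false(attr(sel3, "insufficient"))
  sel1 <- select_tracking_variants(score_variants(mk_candidates(1)))
  expect_equal(nrow(sel1), 1L)
  expect_true(attr(sel1, "insufficient"))
  expect_error(select_tracking_variants(score_variants(mk_candidates(2))[0, ]))
  # ties break by VAF then coordinates
  v <- score_variants(mk_candidates(4))
  v$score <- 0.5
  v$vaf <- c(0.2, 0.4, 0.4, 0.1)
  sel <- select_tracking_variants(v)
  expect_equal(sel$pos[1:2], c(200L, 300L))  # highest VAF, coordinate order
})

test_that("plasma positivity applies the strict 0.05% rule and 10,000X evaluability", {
  pos <- call_plasma(data.frame(variant_id = "v1", coverage = 100000L,
                                alt_reads = 60L))
  expect_equal(pos$max_vaf_pct, 0.06)
  expect_true(pos$ctdna_positive)
  at <- call_plasma(data.frame(variant_id = "v1", coverage = 100000L,
                               alt_reads = 50L))
  expect_equal(at$max_vaf_pct, 0.05)
  expect_false(at$ctdna_positive)  # exactly at threshold is negative
  shallow <- call_plasma(data.frame(variant_id = "v1", coverage = 9999L,
                                    alt_reads = 60L))
  expect_equal(shallow$status, "uncallable")
  expect_true(is.na(shallow$ctdna_positive))
  edge <- call_plasma(data.frame(variant_id = "v1", coverage = 10000L,
                                 alt_reads = 6L))
  expect_equal(edge$n_evaluable, 1L)
  expect_error(call_plasma(data.frame(variant_id = "v1", coverage = 100L,
                                      alt_reads = -1L)))
})

test_that("positivity is monotone in any amplicon's alt reads", {
  m <- data.frame(variant_id = c("v1", "v2"), coverage = c(100000L, 100000L),
                  alt_reads = c(10L, 40L))
  for (extra in c(0L, 20L, 60L, 200L)) {
    m2 <- m
    m2$alt_reads[2] <- m$alt_reads[2] + extra
    p1 <- call_plasma(m)$ctdna_positive
    p2 <- call_plasma(m2)$ctdna_positive
    expect_false(isTRUE(p1) && !isTRUE(p2))
  }
})

test_that("planted ctDNA at 0.1% across 5 deep amplicons is essentially always detected", {
  hits <- vapply(1:200, function(i) {
    pu <- generate_plasma_pileup(paste0("v", 1:5), vaf_pct = 0.1,
                                 coverage = 1e5, seed = 4000L + i)
    isTRUE(call_plasma(pu)$ctdna_positive)
  }, TRUE)
  # binomial oracle: per amplicon P(X > 50), X ~ Bin(1e5, 0.0011)
  p_amp <- pbinom(50, 1e5, 0.0011, lower.tail = FALSE)
  p_any <- 1 - (1 - p_amp)^5
  expect_gt(p_any, 0.99)
  expect_gte(mean(hits), 0.99)
})

test_that("ctDNA-free plasma false-positive rate matches the binomial error tail", {
  hits <- vapply(1:200, function(i) {
    pu <- generate_plasma_pileup(paste0("v", 1:5), vaf_pct = 0,
                                 coverage = 1e5, seed = 6000L + i)
    isTRUE(call_plasma(pu)$ctdna_positive)
  }, TRUE)
  p_fp <- 1 - (1 - pbinom(50, 1e5, 1e-4, lower.tail = FALSE))^5
  expect_lt(p_fp, 1e-10)  # with error rate 1e-4, 0.05% sits far in the tail
  expect_equal(mean(hits), 0)
})

test_that("longitudinal tracking derives clearance and molecular relapse", {
  tp <- function(alt, label) call_plasma(
    data.frame(variant_id = "v1", coverage = 100000L, alt_reads = alt),
    label = label)
  traj <- track_longitudinal(list(tp(200L, "pre-op"), tp(10L, "post-op"),
                                  tp(120L, "post-CRT")))
  expect_equal(traj$events$event, c("clearance", "molecular_relapse"))
  expect_equal(traj$summary, "molecular-relapse")
  none <- track_longitudinal(list(tp(10L, "t1"), tp(5L, "t2")))
  expect_equal(nrow(none$events), 0L)
  expect_equal(none$summary, "never-positive")
  persistent <- track_longitudinal(list(tp(900L, "pre-op"), tp(300L, "post-op"),
                                        tp(80L, "post-CRT")))
  expect_equal(nrow(persistent$events), 0L)
  expect_equal(persistent$summary, "persistent-MRD")
  expect_error(track_longitudinal(list(tp(1L, "a"), tp(1L, "b")),
                                  dates = c(2, 1)), "ordered")
})
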