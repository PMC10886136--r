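test_that("VCF records parse with depths, VAF recomputation and decomposition", {
  vcf <- file.path(tempdir(), "mini.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CONSEQ,Number=A,Type=String,Description=\"x\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"x\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"x\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"x\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR",
    "chr1\t100\t.\tA\tG\t.\tPASS\tCONSEQ=missense\tGT:AD:DP\t0/1:95,5:100",
    "chr1\t200\t.\tC\tT,G\t.\tPASS\tCONSEQ=missense,nonsense\tGT:AD:DP\t1/2:80,12,8:100"
  ), vcf)
  v <- read_variants(vcf)
  expect_equal(nrow(v), 3L)  # multi-allelic site decomposed
  expect_equal(v$vaf[1], 0.05)
  expect_equal(v$alt_depth[1], 5L)
  expect_equal(v$total_depth[1], 100L)
  two <- v[v$pos == 200L, ]
  expect_equal(two$alt, c("T", "G"))
  expect_equal(two$alt_depth, c(12L, 8L))
  expect_equal(two$consequence, c("missense", "nonsense"))
})

test_that("header-only VCF yields an empty record table", {
  vcf <- file.path(tempdir(), "empty.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR"
  ), vcf)
  v <- read_variants(vcf)
  expect_equal(nrow(v), 0L)
  expect_true(all(c("chrom", "pos", "vaf", "consequence") %in% names(v)))
})

test_that("missing AD field raises a record-level error", {
  vcf <- file.path(tempdir(), "noad.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:DP\t0/1:100"
  ), vcf)
  expect_error(read_variants(vcf), "AD")
})

test_that("a standard-sized somatic fixture round-trips through VCF exactly", {
  pan <- generate_panel(n_genes = 40L, total_coding_bp = 2e5)
  fx <- generate_somatic_fixture(pan, seed = 11L, n_synonymous = 0L,
                                 n_germline = 0L, n_lowvaf = 0L,
                                 out_dir = file.path(tempdir(), "fx_rt"))
  expect_equal(nrow(fx$variants), 228L)
  expect_equal(sum(fx$variants$variant_class == "SNV"), 211L)
  expect_equal(sum(fx$variants$variant_class == "INDEL"), 17L)
  back <- read_variants(fx$paths$vcf)
  ord <- function(d) d[order(d$chrom, d$pos, d$alt), ]
  a <- ord(fx$variants); b <- ord(back)
  rownames(a) <- rownames(b) <- NULL
  expect_identical(b[names(a)], a)
})

test_that("variant record invariants are enforced", {
  expect_error(variant_records("chr1", 1L, "A", "A", 5L, 10L), "differ")
  expect_error(variant_records("chr1", 1L, "A", "G", 11L, 10L), "exceeds")
  expect_error(variant_records("chr1", 1L, "A", "G", 5L, 10L, vaf = 0.9),
               "inconsistent")
  v <- variant_records("chr1", 1L, "A", "G", 5L, 10L)
  expect_equal(v$vaf, 0.5)  # recomputed from depths
})

test_that("QC gate honors its inclusive boundaries and validates inputs", {
  expect_true(qc_gate(150, 75)$passed)
  expect_false(qc_gate(149.9, 100)$passed)
  expect_false(qc_gate(1000, 74.99)$passed)
  expect_false(qc_gate(0, 0)$passed)
  expect_error(qc_gate(-1, 50))
  expect_error(qc_gate(200, 101))
})

test_that("QC gate is monotone non-decreasing in both arguments", {
  set.seed(42)
  for (i in 1:50) {
    d <- runif(1, 0, 400); p <- runif(1, 0, 100)
    base <- qc_gate(d, p)$passed
    up_d <- qc_gate(d + runif(1, 0, 200), p)$passed
    up_p <- qc_gate(d, min(100, p + runif(1, 0, 40)))$passed
    expect_false(base && !up_d)
    expect_false(base && !up_p)
  }
})

test_that("effective panel size counts only coding bases above the depth floor", {
  pan <- tiny_panel()  # 3500 coding bases, 600 non-coding
  expect_equal(effective_panel_size(flat_profile(pan, 500), pan), 3500L)
  expect_equal(effective_panel_size(flat_profile(pan, 14), pan), 0L)
  expect_equal(effective_panel_size(flat_profile(pan, 15), pan), 3500L)
  # half the coding bases above threshold, verified by per-base scan
  prof <- depth_granges(c("chr1", "chr1", "chr1", "chr2", "chr2"),
                        c(0L, 500L, 5000L, 0L, 2000L),
                        c(500L, 1000L, 6000L, 1500L, 2600L),
                        c(100, 10, 100, 10, 100))
  got <- effective_panel_size(prof, pan, min_depth = 15)
  expect_equal(got, oracle_panel_size(grange_df(prof), grange_df(pan), 15))
  expect_equal(got, 1500L)
})

test_that("effective panel size errors on uncovered panel intervals", {
  pan <- tiny_panel()
  prof <- depth_granges("chr1", 0L, 1000L, 500)  # chr1:5000-6000, chr2 missing
  expect_error(effective_panel_size(prof, pan), "does not cover")
})

test_that("effective panel size is monotone non-increasing in min_depth", {
  pan <- tiny_panel()
  set.seed(7)
  df <- grange_df(pan)
  prof <- depth_granges(df$chrom, df$start, df$end,
                        sample(0:100, nrow(df), replace = TRUE))
  sizes <- vapply(c(0, 10, 15, 50, 90, 101),
                  function(m) effective_panel_size(prof, pan, min_depth = m), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("clustered-event filter removes dense windows and keeps sparse calls", {
  v <- variant_records(rep("chr1", 5), c(100L, 104L, 108L, 500L, 505L),
                       rep("A", 5), rep("G", 5), rep(10L, 5), rep(100L, 5))
  kept <- filter_clustered_events(v)
  expect_equal(kept$pos, c(500L, 505L))  # 3 calls in 10 bp discarded
  expect_equal(nrow(filter_clustered_events(v[4:5, ])), 2L)
})
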