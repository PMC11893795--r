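flat_track <- function(depths, chrom = "chr1") {
  data.frame(chrom = chrom, pos = seq_along(depths), depth = depths)
}

test_that("depth-based VAF follows the deletion and duplication formulas", {
  # region 10000..20000 at half depth, flanks at 40x
  depths <- c(rep(40, 9999), rep(20, 10001), rep(40, 10000))
  del <- sv_records("d", "chr1", 10000, "chr1", 20000, "DEL", svlen = 10000)
  est <- vaf_depth(del, flat_track(depths))
  expect_equal(est$vaf, 0.5)
  expect_equal(est$method, "depth_del")
  # duplication: flank 40, region 60 -> (60 - 40) / 60
  depths <- c(rep(40, 9999), rep(60, 10001), rep(40, 10000))
  dup <- sv_records("u", "chr1", 10000, "chr1", 20000, "DUP", svlen = 10000)
  est <- vaf_depth(dup, flat_track(depths))
  expect_equal(est$vaf, (60 - 40) / 60, tolerance = 1e-12)
  # region at 56% of flank depth gives VAF 0.44
  depths <- c(rep(100, 9999), rep(56, 10001), rep(100, 10000))
  est <- vaf_depth(del, flat_track(depths))
  expect_equal(est$vaf, 0.44, tolerance = 1e-12)
  # deeper region than flank clamps a DEL estimate at 0
  depths <- c(rep(40, 9999), rep(50, 10001), rep(40, 10000))
  expect_equal(vaf_depth(del, flat_track(depths))$vaf, 0)
  # undefined denominators are errors
  expect_error(vaf_depth(del, flat_track(rep(0, 30000))), "zero flank")
  dup0 <- flat_track(c(rep(40, 9999), rep(0, 10001), rep(40, 10000)))
  expect_error(vaf_depth(dup, dup0), "zero region")
})

test_that("breakpoint-read VAF divides altered reads by junction depth", {
  inv <- sv_records("v", "chr1", 5000, "chr1", 9000, "INV", svlen = 4000)
  track <- flat_track(rep(34, 10000))
  ev <- data.frame(discordant_pairs = 9, split_reads = 5)
  est <- vaf_breakpoint(inv, ev, track)
  expect_equal(est$vaf, 14 / 34, tolerance = 1e-12)
  expect_equal(est$altered, 14)
  # zero altered reads and clamping at 1
  expect_equal(vaf_breakpoint(inv, data.frame(discordant_pairs = 0,
                                              split_reads = 0), track)$vaf, 0)
  big <- data.frame(discordant_pairs = 45, split_reads = 5)
  expect_equal(vaf_breakpoint(inv, big, flat_track(rep(40, 10000)))$vaf, 1)
  expect_error(vaf_breakpoint(inv, data.frame(discordant_pairs = -1,
                                              split_reads = 0), track),
               "negative")
  expect_error(vaf_breakpoint(inv, ev, flat_track(rep(0, 10000))),
               "zero depth")
})

test_that("depth VAF recovers heterozygous carriers within sampling error", {
  set.seed(17)
  del <- sv_records("d", "chr1", 11000, "chr1", 14000, "DEL", svlen = 3000)
  hits <- 0
  n_rep <- 150
  for (r in seq_len(n_rep)) {
    pos <- 1000:24000
    lambda <- ifelse(pos >= 11000 & pos <= 14000, 20, 40)
    track <- data.frame(chrom = "chr1", pos = pos,
                        depth = rpois(length(pos), lambda))
    est <- vaf_depth(del, track, flank = 10000)
    hits <- hits + (abs(est$vaf - 0.5) <= 0.08)
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("LOH classification is an exhaustive, exclusive partition", {
  gene <- list(chrom = "chr1", start = 1000, end = 2000)
  seg <- function(major, minor) data.frame(chrom = "chr1", start = 1,
                                           end = 10000, major_cn = major,
                                           minor_cn = minor)
  expect_equal(classify_loh(gene, seg(1, 0)), "LOH_CNL")
  expect_equal(classify_loh(gene, seg(2, 0)), "LOH_CNN")
  expect_equal(classify_loh(gene, seg(3, 0)), "LOH_CNG")
  expect_equal(classify_loh(gene, seg(2, 1)), "LOH_neg")
  # totality over a grid of valid (major, minor) states
  for (major in 0:5) for (minor in 0:major) {
    got <- classify_loh(gene, seg(major, minor))
    expect_true(got %in% c("LOH_neg", "LOH_CNL", "LOH_CNN", "LOH_CNG"))
    expect_equal(got == "LOH_neg", minor > 0)
  }
  expect_warning(got <- classify_loh(list(chrom = "chr9", start = 1,
                                          end = 10), seg(1, 0)),
                 "not covered")
  expect_equal(got, "undetermined")
})

test_that("the majority segment decides gene-level LOH", {
  gene <- list(chrom = "chr1", start = 1000, end = 2000)
  segs <- data.frame(chrom = "chr1", start = c(1, 1801), end = c(1800, 9000),
                     major_cn = c(1, 2), minor_cn = c(0, 1))
  expect_equal(classify_loh(gene, segs), "LOH_CNL")   # 80% of the gene
  # exact tie resolves toward the more altered status
  gene2 <- list(chrom = "chr1", start = 1000, end = 1999)
  segs <- data.frame(chrom = "chr1", start = c(1, 1500), end = c(1499, 9000),
                     major_cn = c(2, 1), minor_cn = c(1, 0))
  expect_equal(classify_loh(gene2, segs), "LOH_CNL")
})

test_that("second-hit labels report somatic events per gene in order", {
  ev <- data.frame(gene_id = c("A", "A", "C"), event = c("CNL", "CNG", "CNG"),
                   stringsAsFactors = FALSE)
  got <- second_hit(c("A", "B", "C"), ev)
  expect_equal(unname(got), c("CNL,CNG", "none", "CNG"))
})
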