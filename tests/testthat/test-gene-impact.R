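# fixture_gene(): exons at tx_start + k*3500 .. +299 (k = 0..5),
# CDS tx_start+100 .. tx_start+17699

test_that("canonical transcript selection follows flag then CDS fallback", {
  g <- rbind(fixture_gene("G1", canonical = 0L, transcript_id = "t.a"),
             fixture_gene("G1", canonical = 1L, transcript_id = "t.b"),
             fixture_gene("G1", canonical = 0L, transcript_id = "t.c"))
  expect_equal(pick_canonical(g)$transcript_id, "t.b")
  g$canonical <- 0L
  g$cds_end <- g$cds_start + c(900L, 1200L, 1200L)
  g$tx_end <- g$tx_start + c(19999L, 19999L, 21999L)
  expect_equal(pick_canonical(g)$transcript_id, "t.c")  # CDS tie, longer tx
  g$tx_end <- g$tx_start + 19999L
  expect_equal(pick_canonical(g)$transcript_id, "t.b")  # full tie, smaller id
  expect_error(pick_canonical(g[0, ]), "no transcripts")
})

test_that("promoter windows sit upstream on the transcribed strand", {
  gp <- fixture_gene("P1", tx_start = 5000L, strand = "+")
  pr <- promoter_regions(gp, window = 1000)
  expect_equal(c(pr$start, pr$end), c(4000L, 4999L))
  gm <- fixture_gene("M1", tx_start = 5000L, strand = "-")
  pr <- promoter_regions(gm, window = 1000)
  # minus-strand TSS is the transcript end
  expect_equal(c(pr$start, pr$end), c(gm$tx_end + 1L, gm$tx_end + 1000L))
  expect_equal(nrow(promoter_regions(gp, window = 0)), 0)
})

test_that("deletion categories depend on exon and CDS overlap", {
  g <- fixture_gene("G1", tx_start = 10000L)
  del <- function(p1, p2) sv_records("d", "chr1", p1, "chr1", p2, "DEL",
                                     svlen = p2 - p1)
  cat_of <- function(sv) annotate_sv(sv, g)$category
  expect_equal(cat_of(del(13300, 14000)), "pLoF")       # spans exon 2
  expect_equal(cat_of(del(13900, 14500)), "intronic")   # intron only
  # exon sequence outside the CDS: first 99 bases of exon 1
  expect_equal(cat_of(del(10000, 10050)), "UTR")
  g2 <- fixture_gene("G2", tx_start = 10000L, cds = FALSE)
  expect_equal(annotate_sv(del(10000, 10050), g2)$category, "pLoF")
})

test_that("duplication categories follow the breakpoint decision table", {
  g <- fixture_gene("G1", tx_start = 10000L)
  dup <- function(p1, p2) sv_records("u", "chr1", p1, "chr1", p2, "DUP",
                                     svlen = p2 - p1)
  cat_of <- function(sv) annotate_sv(sv, g)$category
  expect_equal(cat_of(dup(5000, 40000)), "CG")               # contains gene
  expect_equal(cat_of(dup(13000, 17500)), "IED")             # exon 2 inside
  expect_equal(cat_of(dup(13600, 17100)), "pLoF")            # both bps exonic
  expect_equal(cat_of(dup(13900, 16900)), "partial_exon_DUP")
  expect_equal(cat_of(dup(5000, 14000)), "partial_gene_DUP") # one bp inside
})

test_that("inversion categories distinguish containment from disruption", {
  g <- fixture_gene("G1", tx_start = 10000L)
  inv <- function(p1, p2) sv_records("v", "chr1", p1, "chr1", p2, "INV",
                                     svlen = p2 - p1)
  expect_equal(annotate_sv(inv(5000, 40000), g)$category, "whole_gene_INV")
  expect_equal(annotate_sv(inv(14000, 90000), g)$category, "pLoF")
  # breakpoints both in the same intron: nothing exonic is inverted in-gene
  expect_equal(annotate_sv(inv(13900, 14100), g)$category, "intronic")
})

test_that("translocation breakpoints inside a gene are disruptive", {
  g <- fixture_gene("G1", tx_start = 10000L)
  tra <- sv_records("t", "chr1", 14000, "chr2", 500, "TRA")
  expect_equal(annotate_sv(tra, g)$category, "pLoF")
  # the intronic-breakpoint reading is configurable
  expect_equal(annotate_sv(tra, g, tra_intronic_is_plof = FALSE)$category,
               "intronic")
  away <- sv_records("t2", "chr2", 100, "chr3", 100, "TRA")
  expect_equal(annotate_sv(away, g)$category, "intergenic")
})

test_that("fusion labels join the genes at the two anchors in order", {
  ga <- fixture_gene("GA", chrom = "chr1", tx_start = 10000L)
  gb <- fixture_gene("GB", chrom = "chr2", tx_start = 50000L)
  tra <- sv_records("t", "chr1", 14000, "chr2", 54000, "TRA")
  ann <- annotate_sv(tra, rbind(ga, gb))
  expect_setequal(ann$gene_id, c("GA", "GB"))
  expect_equal(unique(ann$fusion), "GA-GB")
})

test_that("large SVs only annotate genes containing a breakpoint", {
  ga <- fixture_gene("GA", tx_start = 100000L)
  gb <- fixture_gene("GB", tx_start = 800000L)   # fully inside the big DEL
  gc_ <- fixture_gene("GC", tx_start = 1500000L)
  big <- sv_records("big", "chr1", 110000, "chr1", 1510000, "DEL",
                    svlen = 1400000)
  ann <- annotate_sv(big, rbind(ga, gb, gc_))
  expect_setequal(ann$gene_id, c("GA", "GC"))
  small <- sv_records("sm", "chr1", 110000, "chr1", 810000, "DEL",
                      svlen = 700000)
  expect_true("GB" %in% annotate_sv(small, rbind(ga, gb, gc_))$gene_id)
})

test_that("promoter and enhancer annotation use breakpoint placement", {
  g <- fixture_gene("G1", tx_start = 10000L, strand = "+")
  pr <- promoter_regions(g)
  enh <- data.frame(chrom = "chr1", start = 2000L, end = 2500L,
                    linked_gene = "G1", stringsAsFactors = FALSE)
  up <- sv_records("p", "chr1", 9300, "chr1", 9700, "DEL", svlen = 400)
  ann <- annotate_sv(up, g, promoters = pr, enhancers = enh)
  expect_equal(ann$category, "promoter")
  expect_false(ann$enhancer_hit)
  # breakpoint inside the enhancer flags the linked gene
  hit <- sv_records("e", "chr1", 2200, "chr1", 14000, "DEL", svlen = 11800)
  ann <- annotate_sv(hit, g, promoters = pr, enhancers = enh)
  expect_true(ann$enhancer_hit[ann$gene_id == "G1"])
})

test_that("categories are exclusive and match the per-base oracle", {
  set.seed(3)
  genes <- rbind(fixture_gene("G1", tx_start = 10000L),
                 fixture_gene("G2", tx_start = 35000L, strand = "-"),
                 fixture_gene("G3", tx_start = 60000L, cds = FALSE))
  for (rep in 1:120) {
    type <- sample(c("DEL", "DUP", "INV", "TRA"), 1)
    if (type == "TRA") {
      sv <- sv_records("x", "chr1", sample.int(90000, 1), "chr2",
                       sample.int(90000, 1), "TRA")
    } else {
      p <- sort(sample.int(90000, 2))
      sv <- sv_records("x", "chr1", p[1], "chr1", p[2], type,
                       svlen = p[2] - p[1])
    }
    ann <- annotate_sv(sv, genes)
    # exclusivity: one category per (sv, gene)
    expect_false(anyDuplicated(ann$gene_id[!is.na(ann$gene_id)]) > 0)
    for (i in seq_len(nrow(genes))) {
      want <- oracle_impact(sv, genes[i, ])
      got <- ann$category[!is.na(ann$gene_id) & ann$gene_id == genes$gene_id[i]]
      if (is.null(want)) {
        expect_length(got, 0)
      } else {
        expect_equal(got, want,
                     label = sprintf("%s %d-%d vs %s", type, sv$pos1, sv$pos2,
                                     genes$gene_id[i]))
      }
    }
  }
})

test_that("enlarging a deletion never weakens a pLoF call", {
  g <- fixture_gene("G1", tx_start = 10000L)
  base <- sv_records("d", "chr1", 13400, "chr1", 13900, "DEL", svlen = 500)
  expect_equal(annotate_sv(base, g)$category, "pLoF")
  for (grow in c(500L, 3000L, 10000L, 30000L)) {
    big <- sv_records("d", "chr1", 13400 - grow, "chr1", 13900 + grow, "DEL",
                      svlen = 500 + 2 * grow)
    expect_equal(annotate_sv(big, g)$category, "pLoF")
  }
})
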