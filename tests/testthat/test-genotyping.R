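simple_sites <- function(ids, type = "DEL") {
  sv_records(ids, "chr1", 1000L + seq_along(ids) * 10000L,
             "chr1", 2000L + seq_along(ids) * 10000L, type, svlen = 1000L)
}

test_that("site filter applies the passing-genotype-fraction boundary", {
  sites <- simple_sites(c("s1", "s2", "s3", "s4"))
  sites$filter[4] <- "LowQual"
  n <- 10
  ft <- rbind(rep("PASS", n),                      # ratio 1.0
              c(rep("PASS", 5), rep("FAIL", 5)),   # ratio 0.5
              c(rep("PASS", 4), rep("FAIL", 6)),   # ratio 0.4
              rep("PASS", n))                      # site-level non-PASS
  co <- fixture_cohort(sites, rep(list(rep(0L, n)), 4),
                       ft_rows = asplit(ft, 1), n_afr = 5, n_eur = 5)
  expect_equal(co$pass_ratio, c(1, 0.5, 0.4, 1))
  kept <- site_filter(co)
  expect_equal(kept$sites$id, c("s1", "s2"))
})

test_that("genotype masking uses FT for simple types and GQ for breakend-derived", {
  sites <- rbind(simple_sites("del1"),
                 sv_records("tra1", "chr1", 1000, "chr2", 2000, "TRA"))
  co <- fixture_cohort(
    sites, list(c(1L, 1L, 0L, 0L, 1L, 0L, 0L), c(1L, 1L, 0L, 0L, 1L, 0L, 0L)),
    ft_rows = list(c("PASS", "FAIL", "PASS", "PASS", "PASS", "PASS", "PASS"),
                   rep(NA_character_, 7)),
    gq_rows = list(rep(60L, 7), c(60L, 19L, 20L, 60L, 60L, 60L, 60L)))
  m <- mask_genotypes(co)
  expect_equal(unname(m$gt["del1", 2]), NA_integer_)   # FT not PASS
  expect_equal(unname(m$gt["del1", 5]), 1L)            # FT PASS untouched
  expect_equal(unname(m$gt["tra1", 2]), NA_integer_)   # GQ 19 < 20
  expect_equal(unname(m$gt["tra1", 3]), 0L)            # GQ 20 kept
  # identity on an all-PASS site, and masking is idempotent
  expect_equal(mask_genotypes(m)$gt, m$gt)
})

test_that("missingness removal uses per-ancestry 'either' semantics", {
  sites <- simple_sites(c("m1", "m2", "m3"))
  # 5 AFR + 5 EUR samples; NA fractions per ancestry: (0, .4), (.2, .2), (0, 0)
  gt <- list(c(0L, 0L, 0L, 0L, 0L, NA, NA, 0L, 0L, 0L),
             c(NA, 0L, 0L, 0L, 0L, NA, 0L, 0L, 0L, 0L),
             rep(0L, 10))
  co <- fixture_cohort(sites, gt, n_afr = 5, n_eur = 5)
  kept <- missingness_filter(co, max_missing = 0.2)
  expect_equal(kept$sites$id, c("m2", "m3"))  # exactly 20% is retained
  co$samples$ancestry <- NA_character_
  expect_error(missingness_filter(co), "ancestry")
})

test_that("allele frequencies follow carrier arithmetic on clean cohorts", {
  sites <- simple_sites(c("two", "one", "fix"))
  n <- 113
  gt <- list(c(rep(1L, 2), rep(0L, n - 2)),
             c(1L, rep(0L, n - 1)),
             rep(2L, n))
  co <- fixture_cohort(sites, gt, n_afr = n, n_eur = 0)
  fr <- compute_frequencies(co)
  expect_equal(round(fr$maf_afr, 3), c(0.009, 0.004, 0))
  expect_equal(fr$af_afr[1], 2 / 226)
  expect_equal(fr$carriers_afr, c(2L, 1L, n))
  expect_equal(fr$n_alleles_afr, rep(2L * n, 3))
  # fixed-alt site is flagged and dropped by the frequency filter
  expect_true(fr$flag_remove[3])
  expect_equal(frequency_filter(co, fr)$sites$id, c("two", "one"))
})

test_that("frequencies use only non-missing alleles in the denominator", {
  sites <- simple_sites("s")
  gt <- list(c(1L, 1L, 0L, 0L, NA, 0L, NA))
  co <- fixture_cohort(sites, gt, n_afr = 5, n_eur = 2)
  fr <- compute_frequencies(co)
  expect_equal(fr$af_afr, 2 / 8)   # 4 callable AFR samples
  expect_equal(fr$af_eur, 0 / 2)   # 1 callable EUR sample
  expect_equal(fr$maf_max, 0.25)
})

test_that("haploid sex chromosomes contribute one allele per sample", {
  sites <- sv_records("x1", "chrX", 1000, "chrX", 2000, "DEL", svlen = 1000)
  co <- fixture_cohort(sites, list(c(1L, 0L, 0L, 0L, 1L, 0L, 0L)),
                       n_afr = 4, n_eur = 3)
  fr <- compute_frequencies(co)
  expect_equal(fr$af_afr, 1 / 4)
  expect_equal(fr$af_eur, 1 / 3)
  dip <- compute_frequencies(co, ploidy_x = "diploid")
  expect_equal(dip$af_afr, 1 / 8)
})

test_that("rarity classes partition the MAF range", {
  maf <- c(0, 0.004, 0.01, 0.010001, 0.05, 0.050001, 0.3, 0.5)
  cls <- rarity_class(maf)
  expect_equal(cls, c("rare", "rare", "rare", "low_frequency",
                      "low_frequency", "common", "common", "common"))
  # exclusive variant moves the exact 1% boundary
  expect_equal(rarity_class(0.01, exclusive = TRUE), "low_frequency")
  # every MAF on a fine grid maps to exactly one class
  grid <- seq(0, 0.5, by = 0.001)
  expect_false(anyNA(rarity_class(grid)))
})

test_that("QC cascade is idempotent", {
  set.seed(11)
  b <- generate_cohort(sim_config(seed = 11, n_afr = 20, n_eur = 10,
                                  n_background = 20))
  once <- missingness_filter(mask_genotypes(site_filter(b$cohort)))
  twice <- missingness_filter(mask_genotypes(site_filter(once)))
  expect_identical(once$sites$id, twice$sites$id)
  expect_identical(once$gt, twice$gt)
})

test_that("per-genome count comparison matches rank-sum behaviour", {
  expect_error(per_genome_sv_count_test(1L, c(1L, 2L)), "at least 2")
  counts <- rep(c(8900L, 9000L, 9200L, 9500L), 5)
  same <- per_genome_sv_count_test(counts, counts)
  expect_equal(same$median_afr, same$median_eur)
  expect_gt(same$p_value, 0.9)
  # fully separated groups at the study's sample sizes
  set.seed(1)
  sep <- per_genome_sv_count_test(9000L + sample.int(700, 113, TRUE),
                                  7400L + sample.int(600, 57, TRUE))
  expect_gt(sep$median_afr, sep$median_eur)
  expect_lt(sep$p_value, 1e-6)
  # exact agreement with an exhaustive permutation oracle at tiny n
  x <- c(10, 12, 15, 19); y <- c(9, 11, 14)
  got <- per_genome_sv_count_test(x, y)$p_value
  pooled <- c(x, y)
  stat <- function(ix) sum(rank(pooled)[ix])
  obs <- stat(seq_along(x))
  perms <- utils::combn(seq_along(pooled), length(x))
  stats <- apply(perms, 2, stat)
  mu <- length(x) * (length(pooled) + 1) / 2
  p_perm <- mean(abs(stats - mu) >= abs(obs - mu))
  expect_equal(got, p_perm)
})
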