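test_that("generation is a deterministic function of the seed", {
  cfg <- sim_config(seed = 2, n_afr = 15, n_eur = 8, n_background = 15)
  b1 <- generate_cohort(cfg)
  b2 <- generate_cohort(cfg)
  expect_identical(b1$sites, b2$sites)
  expect_identical(b1$cohort$gt, b2$cohort$gt)
  expect_identical(b1$panels, b2$panels)
  expect_identical(b1$caller_a, b2$caller_a)
  b3 <- generate_cohort(sim_config(seed = 3, n_afr = 15, n_eur = 8,
                                   n_background = 15))
  expect_false(identical(b1$cohort$gt, b3$cohort$gt))
  # serialised bundles are byte-identical too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_bundle(b1, d1)
  write_bundle(b2, d2)
  for (f in c("cohort.vcf", "genes.tsv", "known_svs.tsv", "score_panels.tsv",
              "gene_sets.gmt")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("planted carrier counts are engineered exactly", {
  b <- generate_cohort(sim_config(seed = 8))
  gt <- b$truth$genotypes
  anc <- b$cohort$samples$ancestry
  design <- b$truth$design
  for (i in seq_len(nrow(design))) {
    row <- gt[design$id[i], ]
    expect_equal(sum(row[anc == "AFR"] == 1), design$carriers_afr[i],
                 label = design$id[i])
    expect_equal(sum(row[anc == "EUR"] == 1), design$carriers_eur[i])
    expect_true(all(row %in% c(0L, 1L)))
  }
  # the two-carrier deletion lands at the designed MAF after QC
  res <- run_pipeline(b)
  fr <- res$freqs[res$freqs$sv_id == "p1", ]
  expect_equal(fr$carriers_afr, 2L)
  expect_lte(abs(fr$maf_afr - 2 / 226), 0.001)
})

test_that("bundle files round-trip through the package readers", {
  b <- generate_cohort(sim_config(seed = 5, n_afr = 10, n_eur = 6,
                                  n_background = 12))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  co <- read_cohort_vcf(file.path(dir, "cohort.vcf"),
                        utils::read.delim(file.path(dir, "ancestry.tsv")))
  expect_equal(co$sites$id, b$cohort$sites$id)
  expect_equal(unname(co$gt), unname(b$cohort$gt))
  expect_equal(co$pass_ratio, b$cohort$pass_ratio, tolerance = 1e-5)
  genes <- read_gene_models(file.path(dir, "genes.tsv"))
  expect_equal(genes$gene_id, b$genes$gene_id)
  sets <- read_gmt(file.path(dir, "gene_sets.gmt"))
  expect_equal(sets$hallmark, b$sets$hallmark)
  roles <- read_gene_roles(file.path(dir, "gene_roles.tsv"))
  expect_equal(roles, b$roles)
  panels <- read_score_panels(file.path(dir, "score_panels.tsv"))
  expect_equal(panels$phenosv, b$panels$phenosv, tolerance = 1e-6)
  enh <- read_region_bed(file.path(dir, "enhancers.bed"), "enhancers")
  expect_equal(enh$start, b$enhancers$start)
  s1 <- b$cohort$samples$sample_id[1]
  ca <- read_sv_vcf(file.path(dir, "caller_a", paste0(s1, ".vcf")), "callerA")
  expect_equal(nrow(ca), nrow(b$caller_a[[s1]]))
})

test_that("noise-free callers recover every carried SV, jitter breaks it", {
  quiet <- generate_cohort(sim_config(seed = 6, n_afr = 12, n_eur = 6,
                                      n_background = 15, jitter_sd = 0,
                                      drop_rate = 0, nonpass_rate = 0))
  for (s in quiet$cohort$samples$sample_id[1:6]) {
    carried <- sum(quiet$truth$genotypes[, s] > 0)
    m <- match_calls(quiet$caller_a[[s]], quiet$caller_b[[s]])
    expect_equal(nrow(m$concordant), carried)
    expect_equal(nrow(m$only_a), 0)
  }
  # jitter beyond the tolerance loses matches
  noisy <- generate_cohort(sim_config(seed = 6, n_afr = 12, n_eur = 6,
                                      n_background = 15, jitter_sd = 300,
                                      drop_rate = 0, nonpass_rate = 0))
  lost <- 0; total <- 0
  for (s in noisy$cohort$samples$sample_id) {
    carried <- sum(noisy$truth$genotypes[, s] > 0)
    m <- match_calls(noisy$caller_a[[s]], noisy$caller_b[[s]])
    lost <- lost + (carried - nrow(m$concordant))
    total <- total + carried
  }
  expect_gt(lost / total, 0.1)
})

test_that("allele-frequency estimation is unbiased over replicates", {
  est <- numeric(60)
  for (r in seq_len(60)) {
    b <- generate_cohort(sim_config(seed = 100 + r, n_afr = 113, n_eur = 57,
                                    n_background = 0))
    co <- missingness_filter(mask_genotypes(site_filter(b$cohort)))
    fr <- compute_frequencies(co)
    est[r] <- fr$maf_afr[fr$sv_id == "p1"]
  }
  # true AF 2/226; FT masking only shrinks the denominator
  expect_lt(abs(mean(est) - 2 / 226), 0.0015)
})

test_that("truth comparison flags planted recovery and decoy leakage", {
  b <- generate_cohort(sim_config(seed = 9))
  res <- run_pipeline(b)
  tc <- truth_compare(res$calls, b$truth)
  expect_equal(tc$sensitivity[tc$stage == "final"], 1)
  expect_equal(tc$specificity[tc$stage == "final"], 1)
  expect_error(truth_compare(res$calls,
                             list(sites = data.frame(sv_id = "zz",
                                                     expected = "PP_SV"))),
               "ids do not match")
})
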