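panel_row <- function(id, s = NA, c = NA, p = NA, ph = NA) {
  data.frame(sv_id = id, strvctvre = s, cadd_sv = c, postre = p, phenosv = ph,
             stringsAsFactors = FALSE)
}

test_that("consensus counts passing tools against the fixed thresholds", {
  got <- consensus_candidate(panel_row("a", 0.50, 12, 0.1, 0.1))
  expect_equal(got$n_tools_passed, 2L)
  expect_true(got$candidate)
  # every tool just under its threshold
  sub <- consensus_candidate(panel_row("b", 0.36, 9.9, 0.79, 0.49))
  expect_equal(sub$n_tools_passed, 0L)
  expect_false(sub$candidate)
  # at-threshold scores pass
  at <- consensus_candidate(panel_row("c", 0.37, 10, 0.8, 0.5))
  expect_equal(at$n_tools_passed, 4L)
  # a translocation scoreable by two tools only can still be a candidate
  tra <- consensus_candidate(panel_row("t", NA, NA, 0.9, 0.9))
  expect_equal(tra$n_tools_scored, 2L)
  expect_true(tra$candidate)
  # ... but one pass is not enough under absolute counting
  one <- consensus_candidate(panel_row("t", NA, NA, 0.9, 0.2))
  expect_false(one$candidate)
  # relative counting caps the requirement at the scoreable tools
  rel <- consensus_candidate(panel_row("t", NA, NA, 0.9, NA),
                             min_pass_relative = TRUE)
  expect_true(rel$candidate)
  expect_error(consensus_candidate(panel_row("x", -0.1, 5, 0.2, 0.2)),
               "negative")
})

test_that("candidacy is monotone in thresholds and min_pass", {
  set.seed(5)
  panel <- do.call(rbind, lapply(1:200, function(i) {
    panel_row(paste0("s", i),
              ifelse(runif(1) < 0.3, NA, runif(1)),
              ifelse(runif(1) < 0.3, NA, runif(1, 0, 40)),
              ifelse(runif(1) < 0.3, NA, runif(1)),
              runif(1))
  }))
  base <- consensus_candidate(panel)
  for (bump in list(c(strvctvre = 0.6), c(cadd_sv = 20), c(postre = 0.95),
                    c(phenosv = 0.8))) {
    th <- default_score_thresholds()
    th[names(bump)] <- bump
    harder <- consensus_candidate(panel, thresholds = th)
    expect_true(all(harder$candidate <= base$candidate))
  }
  looser <- consensus_candidate(panel, min_pass = 1)
  strictest <- consensus_candidate(panel, min_pass = 4)
  expect_true(all(base$candidate <= looser$candidate))
  expect_true(all(strictest$candidate <= base$candidate))
  # requiring all four tools is drastically stricter
  expect_lt(sum(strictest$candidate), sum(base$candidate) / 4)
})

test_that("cancer relevance supports union and single-gene readings", {
  sets <- list(hallmark = c("TP1", "FUS1"), oncogenic_signatures = "ONC1",
               cancer_census = c("TP1", "ONC1", "FUS2"))
  expect_true(cancer_relevance("TP1", sets))            # two sets, one gene
  expect_false(cancer_relevance("FUS1", sets))          # one set only
  expect_false(cancer_relevance(character(0), sets))
  # fusion partners in different single collections
  expect_true(cancer_relevance(c("FUS1", "FUS2"), sets, union_rule = TRUE))
  expect_false(cancer_relevance(c("FUS1", "FUS2"), sets, union_rule = FALSE))
})

test_that("the gene-role rule engine reproduces the classification rules", {
  roles <- data.frame(
    gene_id = c("TSG1", "TSG2", "ONC1", "CONF1", "UNCL1"),
    role = c("TSG", "TSG", "oncogene", "conflicting", "unclear"),
    stringsAsFactors = FALSE)
  imp <- function(genes, category, svtype = "DEL") {
    data.frame(sv_id = "x", gene_id = genes, category = category,
               breakpoint_gene = TRUE, fusion = NA, stringsAsFactors = FALSE)
  }
  sv <- function(type = "DEL") sv_records("x", "chr1", 1, "chr2", 2, "TRA")
  del <- sv_records("x", "chr1", 100, "chr1", 200, "DEL", svlen = 100)
  no_match <- data.frame(sv_id = "x", status = "unknown",
                         matched_entry = NA, significance = "none",
                         max_reported_af = NA, stringsAsFactors = FALSE)
  cls <- function(impacts, svrec = del, match = no_match) {
    classify_final(svrec, impacts, match, roles)
  }
  # loss of a tumour suppressor
  expect_equal(cls(imp("TSG1", "pLoF"))$final_class, "PP_SV")
  # loss-type fusion of suppressor and oncogene
  tra <- sv_records("x", "chr1", 1, "chr2", 2, "TRA")
  got <- cls(imp(c("TSG1", "ONC1"), "pLoF"), svrec = tra)
  expect_equal(got$final_class, "cautionary")
  expect_equal(got$rule, "R2-tsg-onco-mix")
  # conflicting evidence and unclear partners are cautionary
  expect_equal(cls(imp("CONF1", "pLoF"))$final_class, "cautionary")
  expect_equal(cls(imp(c("TSG1", "UNCL1"), "pLoF"))$final_class, "cautionary")
  # oncogene loss and role-free loss are unlikely
  expect_equal(cls(imp("ONC1", "pLoF"))$final_class, "unlikely")
  expect_equal(cls(imp("UNCL1", "pLoF"))$final_class, "unlikely")
  # dosage gain of an oncogene
  dup <- sv_records("x", "chr1", 100, "chr1", 200, "DUP", svlen = 100)
  expect_equal(cls(imp("ONC1", "CG"), svrec = dup)$final_class, "PP_SV")
  # uncharacterised copy gain whose breakpoints disrupt cancer genes
  mixed <- rbind(imp("UNCL1", "CG"), imp("TSG1", "partial_gene_DUP"))
  expect_equal(cls(mixed, svrec = dup)$final_class, "cautionary")
  plain <- rbind(imp("UNCL1", "CG"))
  expect_equal(cls(plain, svrec = dup)$final_class, "unlikely")
  # known pathogenic entries override with an audit flag
  pmatch <- transform(no_match, significance = "pathogenic", status = "known")
  got <- cls(imp("UNCL1", "pLoF"), match = pmatch)
  expect_equal(got$final_class, "PP_SV")
  expect_true(got$clinvar_override)
  # unknown genes default to role 'none' with a warning
  expect_warning(got <- cls(imp("NEW1", "pLoF")), "no role entry")
  expect_equal(got$final_class, "unlikely")
})
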