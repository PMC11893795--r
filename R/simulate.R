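#' Configuration of the synthetic SV cohort generator
#'
#' The generator emulates the full input bundle of the pipeline on a toy
#' genome with known ground truth: two noisy per-sample caller call sets, a
#' cohort-genotyped site set with GT/FT/GQ, gene models with canonical
#' transcripts, enhancers, a known-SV table with planted clinical
#' significance (3 pathogenic/likely-pathogenic and 10 benign entries by
#' default), per-SV score panels in which planted pathogenic SVs pass at
#' least two tools and benign decoys at most one, cancer gene sets, a gene
#' role table, carrier depth tracks and breakpoint read evidence consistent
#' with heterozygosity, and tumour copy-number segments with planted LOH
#' states.
#'
#' @param seed integer RNG seed; the whole bundle is a deterministic
#'   function of it.
#' @param n_afr,n_eur cohort sizes (defaults 113 and 57).
#' @param chrom_lengths named integer vector of toy chromosome lengths.
#' @param n_genes number of genes laid out on the toy genome.
#' @param n_background number of background (mostly benign) SV sites.
#' @param missing_ft_rate per-genotype probability of a failing FT tag.
#' @param low_gq_rate per-genotype probability of GQ below 20 at
#'   breakend-derived sites.
#' @param jitter_sd caller breakpoint jitter (s.d., bases).
#' @param drop_rate per-caller probability of missing a carried SV.
#' @param nonpass_rate per-caller probability of a non-PASS filter.
#' @param depth_mean haploid-pair mean sequencing depth for depth tracks.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_afr = 113, n_eur = 57,
                       chrom_lengths = c(chr1 = 5e6, chr2 = 5e6, chr3 = 5e6),
                       n_genes = 48, n_background = 60,
                       missing_ft_rate = 0.03, low_gq_rate = 0.03,
                       jitter_sd = 30, drop_rate = 0.03,
                       nonpass_rate = 0.03, depth_mean = 40) {
  stopifnot(n_afr >= 1, n_eur >= 1, jitter_sd >= 0, n_genes >= 24)
  structure(as.list(environment()), class = "sim_config")
}

# deterministic toy gene models: genes on a regular grid, 6 exons each;
# consecutive gene ids interleave chromosomes so engineered fusions can join
# genes on different chromosomes
toy_gene_models <- function(config) {
  n <- config$n_genes
  chroms <- names(config$chrom_lengths)
  i <- seq_len(n) - 1L
  tx_start <- as.integer(150000 + (i %/% length(chroms)) * 300000)
  data.frame(
    gene_id = sprintf("G%02d", i + 1L),
    gene_name = sprintf("GENE%02d", i + 1L),
    transcript_id = sprintf("T%02d.1", i + 1L),
    canonical = 1L,
    chrom = chroms[(i %% length(chroms)) + 1L],
    strand = rep(c("+", "-"), length.out = n),
    tx_start = tx_start,
    tx_end = tx_start + 19999L,
    cds_start = tx_start + 100L,
    cds_end = tx_start + 17699L,
    exon_starts = vapply(tx_start, function(s)
      paste(s + (0:5) * 3500L, collapse = ","), ""),
    exon_ends = vapply(tx_start, function(s)
      paste(s + (0:5) * 3500L + 299L, collapse = ","), ""),
    stringsAsFactors = FALSE
  )
}

# role and gene-set design of the toy genome: the first genes carry the
# curated cancer roles used by the planted variants
toy_roles_and_sets <- function(genes) {
  role <- rep("none", nrow(genes))
  role[1:8] <- "TSG"
  role[9:14] <- "oncogene"
  role[15] <- "conflicting"
  role[16] <- "unclear"
  roles <- data.frame(gene_id = genes$gene_id, role = role,
                      stringsAsFactors = FALSE)
  ids <- genes$gene_id
  sets <- list(
    hallmark = c(ids[1:8], ids[15], ids[16], ids[20]),
    oncogenic_signatures = ids[9:14],
    cancer_census = c(ids[1:16])
  )
  list(roles = roles, sets = sets)
}

exon_of <- function(g, k) {
  ex <- exon_intervals(g)
  ex[k, ]
}

# the planted variant design: each row defines one engineered SV with its
# expected fate in the cascade
planted_design <- function(genes) {
  g <- function(id) genes[genes$gene_id == id, ]
  mk <- function(id, svtype, chrom1, pos1, chrom2, pos2, gene, carriers_afr,
                 carriers_eur, profile, known, known_af, expected) {
    data.frame(id = id, svtype = svtype, chrom1 = chrom1, pos1 = pos1,
               chrom2 = chrom2, pos2 = pos2, gene = gene,
               carriers_afr = carriers_afr, carriers_eur = carriers_eur,
               profile = profile, known = known, known_af = known_af,
               expected = expected, stringsAsFactors = FALSE)
  }
  del_on <- function(gid) {
    gg <- g(gid); e3 <- exon_of(gg, 3)
    c(gg$chrom, e3$start - 200L, e3$end + 200L)
  }
  d <- list()
  # recoverable PP-SVs
  x <- del_on("G01")
  d$p1 <- mk("p1", "DEL", x[1], x[2], x[1], x[3], "G01", 2, 0,
             "pathogenic", "none", NA, "PP_SV")
  gg <- g("G02")
  d$p2 <- mk("p2", "INV", gg$chrom, gg$tx_start + 4000L, gg$chrom,
             gg$tx_end + 50000L, "G02", 1, 0, "pathogenic", "none", NA, "PP_SV")
  ga <- g("G03"); gb <- g("G14")
  d$p3 <- mk("p3", "TRA", ga$chrom, ga$tx_start + 5000L, gb$chrom,
             gb$tx_start + 5000L, "G03", 1, 0, "pathogenic", "none", NA,
             "cautionary")
  gg <- g("G10")
  d$p4 <- mk("p4", "DUP", gg$chrom, gg$tx_start - 5000L, gg$chrom,
             gg$tx_end + 5000L, "G10", 0, 1, "pathogenic", "none", NA, "PP_SV")
  gg <- g("G11")
  d$p5 <- mk("p5", "DUP", gg$chrom, gg$tx_start + 3000L, gg$chrom,
             gg$tx_start + 7500L, "G11", 0, 1, "pathogenic", "none", NA,
             "PP_SV")
  gg <- g("G15")
  d$p6 <- mk("p6", "TRA", gg$chrom, gg$tx_start + 5000L,
             setdiff(unique(genes$chrom), gg$chrom)[1], 40000L, "G15",
             1, 0, "pathogenic", "none", NA, "cautionary")
  # known pathogenic / likely pathogenic controls
  for (k in 1:2) {
    x <- del_on(c("G04", "G05")[k])
    d[[paste0("c", k)]] <- mk(paste0("c", k), "DEL", x[1], x[2], x[1], x[3],
                              c("G04", "G05")[k], 1, 0, "pathogenic",
                              c("pathogenic", "likely_pathogenic")[k], 1e-4,
                              "PP_SV")
  }
  gg <- g("G12")
  d$c3 <- mk("c3", "DUP", gg$chrom, gg$tx_start + 3000L, gg$chrom,
             gg$tx_start + 7500L, "G12", 1, 0, "pathogenic",
             "likely_pathogenic", 1e-4, "PP_SV")
  # decoys: each fails exactly one gate (or the role engine)
  x <- del_on("G06")
  d$d1 <- mk("d1", "DEL", x[1], x[2], x[1], x[3], "G06", 7, 3,
             "pathogenic", "none", NA, "rejected_rarity")
  x <- del_on("G07")
  d$d2 <- mk("d2", "DEL", x[1], x[2], x[1], x[3], "G07", 1, 0,
             "benign", "none", NA, "rejected_scores")
  x <- del_on("G20")
  d$d3 <- mk("d3", "DEL", x[1], x[2], x[1], x[3], "G20", 1, 0,
             "pathogenic", "none", NA, "rejected_noncancer")
  x <- del_on("G08")
  d$d4 <- mk("d4", "DEL", x[1], x[2], x[1], x[3], "G08", 1, 0,
             "pathogenic", "none", 0.03, "rejected_known_af")
  x <- del_on("G13")
  d$d5 <- mk("d5", "DEL", x[1], x[2], x[1], x[3], "G13", 1, 0,
             "pathogenic", "none", NA, "rejected_oncogene_loss")
  # ten known benign controls spread over remaining genes
  for (k in 1:10) {
    gid <- sprintf("G%02d", 20 + k)
    x <- del_on(gid)
    d[[paste0("b", k)]] <- mk(paste0("b", k), "DEL", x[1], x[2], x[1], x[3],
                              gid, 1, 1, "benign", "benign", 1e-3,
                              "rejected_benign")
  }
  out <- do.call(rbind, d)
  rownames(out) <- NULL
  out
}

# score panel row for one SV given its type and planted profile
score_panel_row <- function(sv_id, svtype, profile) {
  can <- list(strvctvre = svtype %in% c("DEL", "DUP"),
              cadd_sv = svtype %in% c("DEL", "DUP", "INS"),
              postre = svtype %in% c("DEL", "DUP", "INV", "TRA"),
              phenosv = TRUE)
  hi <- list(strvctvre = stats::runif(1, 0.5, 0.95),
             cadd_sv = stats::runif(1, 15, 30),
             postre = stats::runif(1, 0.85, 0.99),
             phenosv = stats::runif(1, 0.6, 0.95))
  lo <- list(strvctvre = stats::runif(1, 0.02, 0.3),
             cadd_sv = stats::runif(1, 0.5, 8),
             postre = stats::runif(1, 0.05, 0.6),
             phenosv = stats::runif(1, 0.02, 0.4))
  pick <- if (profile == "pathogenic") hi else lo
  if (profile == "near_miss") {
    # exactly one tool above threshold: not enough for candidacy
    pick <- lo
    pick$phenosv <- stats::runif(1, 0.52, 0.6)
  }
  out <- data.frame(sv_id = sv_id, strvctvre = NA_real_, cadd_sv = NA_real_,
                    postre = NA_real_, phenosv = NA_real_,
                    stringsAsFactors = FALSE)
  for (tool in names(can)) if (can[[tool]]) out[[tool]] <- pick[[tool]]
  out
}

#' Generate a synthetic SV cohort with known ground truth
#'
#' See [sim_config()] for what is emulated.  All outputs are in-memory
#' objects; [write_bundle()] serialises them to the plain-text formats the
#' readers consume.
#'
#' @param config a [sim_config()].
#' @return a list (class `sv_bundle`) with elements `genes`, `enhancers`,
#'   `promoters`, `roles`, `sets`, `sites` (SV record table of all simulated
#'   sites), `cohort` (an [sv_cohort()]), `caller_a`/`caller_b` (named lists
#'   of per-sample SV record tables), `known_table`, `panels`, `patients`,
#'   `depth_tracks`/`evidence` (per planted carrier), `cn_segments`,
#'   `somatic_events`, and `truth` (per-site expected fate, true allele
#'   frequencies and genotypes).
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- toy_gene_models(config)
  rs <- toy_roles_and_sets(genes)
  plant <- planted_design(genes)
  if (any(plant$carriers_afr > config$n_afr) ||
      any(plant$carriers_eur > config$n_eur)) {
    stop("generate_cohort: planted carrier counts exceed the cohort size; ",
         "the configured MAFs are unreachable")
  }
  n <- config$n_afr + config$n_eur
  samples <- data.frame(
    sample_id = c(sprintf("AFR%03d", seq_len(config$n_afr)),
                  sprintf("EUR%03d", seq_len(config$n_eur))),
    ancestry = c(rep("AFR", config$n_afr), rep("EUR", config$n_eur)),
    stringsAsFactors = FALSE
  )

  # ---- background sites: random, mostly low-impact, benign-scored --------
  chroms <- names(config$chrom_lengths)
  nb <- config$n_background
  bg_chrom <- sample(chroms, nb, replace = TRUE)
  bg_pos1 <- as.integer(stats::runif(nb, 1e4, config$chrom_lengths[bg_chrom] - 2e5))
  bg_type <- sample(c("DEL", "DUP", "INS", "INV"), nb, replace = TRUE,
                    prob = c(0.45, 0.2, 0.15, 0.2))
  bg_len <- as.integer(stats::runif(nb, 100, 20000))
  bg_pos2 <- ifelse(bg_type == "INS", bg_pos1, bg_pos1 + bg_len)
  bg_af <- stats::rbeta(nb, 0.4, 6)  # skewed toward rare, some common
  bg <- sv_records(sprintf("bg%03d", seq_len(nb)), bg_chrom, bg_pos1,
                   bg_chrom, bg_pos2, bg_type,
                   svlen = ifelse(bg_type == "INS", bg_len, bg_pos2 - bg_pos1))

  pl <- sv_records(plant$id, plant$chrom1, as.integer(plant$pos1),
                   plant$chrom2, as.integer(plant$pos2), plant$svtype,
                   svlen = ifelse(plant$svtype == "TRA", NA,
                                  as.integer(plant$pos2) - as.integer(plant$pos1)))
  # QC exercise sites: fixed alt, failing site filter, high missingness
  extra <- sv_records(c("fx1", "lp1", "hm1"),
                      c("chr1", "chr2", "chr3"),
                      c(4500000L, 4500000L, 4500000L),
                      c("chr1", "chr2", "chr3"),
                      c(4501000L, 4501000L, 4501000L),
                      c("DEL", "DEL", "DEL"), svlen = 1000L)
  sites <- rbind(pl, bg, extra)

  # ---- true genotypes ----------------------------------------------------
  afr_idx <- which(samples$ancestry == "AFR")
  eur_idx <- which(samples$ancestry == "EUR")
  gt <- matrix(0L, nrow(sites), n,
               dimnames = list(sites$id, samples$sample_id))
  for (i in seq_len(nrow(plant))) {
    if (plant$carriers_afr[i] > 0) {
      gt[plant$id[i], sample(afr_idx, plant$carriers_afr[i])] <- 1L
    }
    if (plant$carriers_eur[i] > 0) {
      gt[plant$id[i], sample(eur_idx, plant$carriers_eur[i])] <- 1L
    }
  }
  for (i in seq_len(nb)) {
    gt[bg$id[i], ] <- stats::rbinom(n, 2, bg_af[i])
  }
  gt["fx1", ] <- 2L
  gt["lp1", ] <- stats::rbinom(n, 2, 0.1)
  gt["hm1", ] <- stats::rbinom(n, 2, 0.1)

  # ---- genotyper noise: FT and GQ ----------------------------------------
  bnd_derived <- sites$svtype %in% c("INV", "TRA")
  ft <- matrix(ifelse(stats::runif(nrow(sites) * n) < config$missing_ft_rate,
                      "FAIL", "PASS"), nrow(sites), n,
               dimnames = dimnames(gt))
  ft["lp1", ] <- ifelse(stats::runif(n) < 0.6, "FAIL", "PASS")
  ft["hm1", afr_idx] <- ifelse(stats::runif(length(afr_idx)) < 0.35,
                               "FAIL", "PASS")
  ft[bnd_derived, ] <- NA_character_
  gq <- matrix(sample(20:99, nrow(sites) * n, replace = TRUE),
               nrow(sites), n, dimnames = dimnames(gt))
  low <- matrix(stats::runif(nrow(sites) * n) < config$low_gq_rate,
                nrow(sites), n)
  gq[low] <- sample(0:19, sum(low), replace = TRUE)
  # planted carriers always genotype cleanly
  for (i in seq_len(nrow(plant))) {
    carry <- gt[plant$id[i], ] > 0
    if (!bnd_derived[match(plant$id[i], sites$id)]) {
      ft[plant$id[i], carry] <- "PASS"
    }
    gq[plant$id[i], carry] <- sample(40:99, sum(carry), replace = TRUE)
  }
  cohort <- sv_cohort(sites, gt, ft, gq, samples)

  # ---- per-sample caller call sets ---------------------------------------
  jitter <- function(pos) as.integer(round(pos + stats::rnorm(length(pos),
                                                              0, config$jitter_sd)))
  caller_sets <- function(label) {
    out <- vector("list", n)
    names(out) <- samples$sample_id
    for (s in seq_len(n)) {
      carried <- which(gt[, s] > 0)
      carried <- carried[stats::runif(length(carried)) >= config$drop_rate]
      if (length(carried) == 0) { out[[s]] <- empty_sv_records(); next }
      sub <- sites[carried, , drop = FALSE]
      p1 <- jitter(sub$pos1); p2 <- jitter(sub$pos2)
      same <- sub$chrom1 == sub$chrom2
      swap <- same & p1 > p2
      tmp <- p1[swap]; p1[swap] <- p2[swap]; p2[swap] <- tmp
      p2[sub$svtype == "INS"] <- p1[sub$svtype == "INS"]
      out[[s]] <- sv_records(
        paste0(sub$id, "_", label), sub$chrom1, p1, sub$chrom2, p2,
        sub$svtype,
        svlen = ifelse(sub$svtype %in% c("DEL", "DUP", "INV"), p2 - p1,
                       ifelse(sub$svtype == "INS", sub$svlen, NA)),
        filter = ifelse(stats::runif(nrow(sub)) < config$nonpass_rate,
                        "LowQual", "PASS"),
        caller = label)
    }
    out
  }
  caller_a <- caller_sets("A")
  caller_b <- caller_sets("B")

  # ---- known-SV table ----------------------------------------------------
  known_rows <- list()
  for (i in seq_len(nrow(plant))) {
    if (plant$known[i] == "none" && is.na(plant$known_af[i])) next
    off <- sample(-80:80, 2, replace = TRUE)
    known_rows[[length(known_rows) + 1]] <- data.frame(
      entry_id = paste0("nsv_", plant$id[i]),
      chrom1 = plant$chrom1[i], pos1 = as.integer(plant$pos1) [i] + off[1],
      chrom2 = plant$chrom2[i], pos2 = as.integer(plant$pos2)[i] + off[2],
      svtype = plant$svtype[i],
      significance = if (plant$known[i] == "none") NA_character_ else plant$known[i],
      af_study = "popA", af_population = "ALL", af = plant$known_af[i],
      stringsAsFactors = FALSE)
  }
  # a slice of background sites is also in the archive, unlabelled
  for (i in seq_len(min(10, nb))) {
    known_rows[[length(known_rows) + 1]] <- data.frame(
      entry_id = paste0("nsv_", bg$id[i]), chrom1 = bg$chrom1[i],
      pos1 = bg$pos1[i] + sample(-80:80, 1), chrom2 = bg$chrom2[i],
      pos2 = bg$pos2[i] + sample(-80:80, 1), svtype = bg$svtype[i],
      significance = NA_character_, af_study = "popA", af_population = "ALL",
      af = signif(bg_af[i] / 2, 3), stringsAsFactors = FALSE)
  }
  known_table <- do.call(rbind, known_rows)

  # ---- score panels ------------------------------------------------------
  profile <- c(plant$profile, rep("benign", nb + 3))
  # half the benign controls pass exactly one tool
  profile[match(sprintf("b%d", 6:10), sites$id)] <- "near_miss"
  panels <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
    score_panel_row(sites$id[i], sites$svtype[i], profile[i])
  }))

  # ---- clinical covariates ------------------------------------------------
  patients <- data.frame(
    patient_id = samples$sample_id, ancestry = samples$ancestry,
    age = round(stats::rnorm(n, ifelse(samples$ancestry == "AFR", 66, 61), 6)),
    psa = round(exp(stats::rnorm(n, ifelse(samples$ancestry == "AFR",
                                           4.5, 2.2), 1)), 1),
    isup_gg = sample(1:5, n, replace = TRUE,
                     prob = c(0.08, 0.1, 0.22, 0.3, 0.3)),
    stringsAsFactors = FALSE
  )

  # ---- depth tracks, breakpoint evidence, CN segments for planted carriers
  depth_tracks <- list()
  evidence <- list()
  cn_segments <- list()
  somatic_events <- list()
  loh_cycle <- c("LOH_neg", "LOH_CNL", "LOH_CNN", "LOH_CNG")
  loh_truth <- list()
  pp_plant <- plant[plant$expected %in% c("PP_SV", "cautionary"), ]
  ci <- 0
  for (i in seq_len(nrow(pp_plant))) {
    sv <- sites[sites$id == pp_plant$id[i], ]
    carriers <- samples$sample_id[gt[sv$id, ] > 0]
    gene <- genes[genes$gene_id == pp_plant$gene[i], ]
    for (s in carriers) {
      key <- paste(sv$id, s, sep = ":")
      if (sv$svtype %in% c("DEL", "DUP")) {
        pos <- (sv$pos1 - 10000):(sv$pos2 + 10000)
        lambda <- rep(config$depth_mean, length(pos))
        inside <- pos >= sv$pos1 & pos <= sv$pos2
        lambda[inside] <- config$depth_mean *
          ifelse(sv$svtype == "DEL", 0.5, 1.5)
        depth_tracks[[key]] <- data.frame(
          chrom = sv$chrom1, pos = pos,
          depth = stats::rpois(length(pos), lambda))
      } else {
        pos1 <- (sv$pos1 - 200):(sv$pos1 + 200)
        pos2 <- (sv$pos2 - 200):(sv$pos2 + 200)
        depth_tracks[[key]] <- data.frame(
          chrom = c(rep(sv$chrom1, length(pos1)), rep(sv$chrom2, length(pos2))),
          pos = c(pos1, pos2),
          depth = stats::rpois(length(pos1) + length(pos2), config$depth_mean))
        alt <- stats::rbinom(1, config$depth_mean, 0.42)
        sp <- stats::rbinom(1, alt, 0.3)
        evidence[[key]] <- data.frame(sv_id = sv$id, sample_id = s,
                                      discordant_pairs = alt - sp,
                                      split_reads = sp)
      }
      # tumour copy-number: chromosome-wide diploid baseline, one altered
      # segment over the candidate gene for a rotating LOH status
      ci <- ci + 1
      status <- loh_cycle[(ci - 1) %% length(loh_cycle) + 1]
      mm <- switch(status, LOH_neg = c(1, 1), LOH_CNL = c(1, 0),
                   LOH_CNN = c(2, 0), LOH_CNG = c(3, 0))
      base <- data.frame(chrom = chroms, start = 1L,
                         end = as.integer(config$chrom_lengths), major_cn = 1L,
                         minor_cn = 1L, stringsAsFactors = FALSE)
      seg <- data.frame(chrom = gene$chrom, start = gene$tx_start - 50000L,
                        end = gene$tx_end + 50000L, major_cn = mm[1],
                        minor_cn = mm[2], stringsAsFactors = FALSE)
      cn_segments[[s]] <- rbind(base, seg)
      loh_truth[[key]] <- status
      if (ci %% 3 == 0) {
        somatic_events[[length(somatic_events) + 1]] <- data.frame(
          patient_id = s, gene_id = gene$gene_id,
          event = sample(c("CNL", "CNG"), 1), stringsAsFactors = FALSE)
      }
    }
  }
  somatic_events <- if (length(somatic_events)) do.call(rbind, somatic_events)
  else data.frame(patient_id = character(0), gene_id = character(0),
                  event = character(0))

  truth_sites <- data.frame(
    sv_id = sites$id,
    planted = c(rep(TRUE, nrow(plant)), rep(FALSE, nb + 3)),
    expected = c(plant$expected, rep("background", nb),
                 "removed_fixed", "removed_site_filter", "removed_missingness"),
    gene = c(plant$gene, rep(NA_character_, nb + 3)),
    af_afr_true = c((plant$carriers_afr / (2 * config$n_afr)), bg_af, 1, 0.1, 0.1),
    af_eur_true = c((plant$carriers_eur / (2 * config$n_eur)), bg_af, 1, 0.1, 0.1),
    stringsAsFactors = FALSE
  )

  structure(list(
    config = config, genes = genes, promoters = promoter_regions(genes),
    enhancers = data.frame(chrom = genes$chrom[1:6],
                           start = genes$tx_start[1:6] - 30000L,
                           end = genes$tx_start[1:6] - 28000L,
                           linked_gene = genes$gene_id[1:6],
                           stringsAsFactors = FALSE),
    roles = rs$roles, sets = rs$sets, sites = sites, cohort = cohort,
    caller_a = caller_a, caller_b = caller_b, known_table = known_table,
    panels = panels, patients = patients, depth_tracks = depth_tracks,
    evidence = evidence, cn_segments = cn_segments,
    somatic_events = somatic_events,
    truth = list(sites = truth_sites, genotypes = gt, design = plant,
                 loh = loh_truth)
  ), class = "sv_bundle")
}

#' Write a synthetic bundle to disk in the pipeline's file formats
#'
#' Emits per-sample caller VCFs (`caller_a/`, `caller_b/`), the cohort VCF,
#' the ancestry map, gene models, enhancer BED, the known-SV table, score
#' panels, gene sets (GMT), the role table, depth tracks, breakpoint
#' evidence, copy-number segments, patient metadata and the ground truth
#' (JSON).
#'
#' @param bundle output of [generate_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "caller_a"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "caller_b"), showWarnings = FALSE)
  dir.create(file.path(dir, "depth"), showWarnings = FALSE)
  dir.create(file.path(dir, "cn"), showWarnings = FALSE)
  for (s in names(bundle$caller_a)) {
    write_sv_vcf(bundle$caller_a[[s]],
                 file.path(dir, "caller_a", paste0(s, ".vcf")))
    write_sv_vcf(bundle$caller_b[[s]],
                 file.path(dir, "caller_b", paste0(s, ".vcf")))
  }
  write_cohort_vcf(bundle$cohort, file.path(dir, "cohort.vcf"))
  write_tsv(bundle$cohort$samples, file.path(dir, "ancestry.tsv"))
  write_gene_models(bundle$genes, file.path(dir, "genes.tsv"))
  write_region_bed(bundle$enhancers, file.path(dir, "enhancers.bed"))
  write_tsv(bundle$known_table, file.path(dir, "known_svs.tsv"))
  write_tsv(bundle$panels, file.path(dir, "score_panels.tsv"))
  write_gmt(bundle$sets, file.path(dir, "gene_sets.gmt"))
  write_tsv(bundle$roles, file.path(dir, "gene_roles.tsv"))
  write_tsv(bundle$patients, file.path(dir, "patients.tsv"))
  for (key in names(bundle$depth_tracks)) {
    utils::write.table(bundle$depth_tracks[[key]],
                       file.path(dir, "depth", paste0(gsub(":", "_", key), ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  if (length(bundle$evidence) > 0) {
    write_tsv(do.call(rbind, bundle$evidence), file.path(dir, "evidence.tsv"))
  }
  for (s in names(bundle$cn_segments)) {
    write_tsv(bundle$cn_segments[[s]],
              file.path(dir, "cn", paste0(s, ".tsv")))
  }
  write_tsv(bundle$somatic_events, file.path(dir, "somatic_events.tsv"))
  jsonlite::write_json(bundle$truth$sites, file.path(dir, "truth.json"))
  invisible(dir)
}

#' Compare pipeline output with the planted ground truth
#'
#' Per-stage confusion counts keyed by site id: sensitivity is the fraction
#' of planted PP-SVs (expected `PP_SV` or `cautionary`) that survive the
#' stage, specificity the fraction of planted decoys and background sites
#' rejected by the final call set.
#'
#' @param calls output of [classify_cohort()] (possibly via
#'   [run_pipeline()]).
#' @param truth the `truth` element of a bundle.
#' @return `data.frame` with one row per stage: `stage`, `tp`, `fn`, `fp`,
#'   `tn`, `sensitivity`, `specificity`.
#' @export
truth_compare <- function(calls, truth) {
  exp_pp <- truth$sites$sv_id[truth$sites$expected %in% c("PP_SV", "cautionary")]
  neg <- truth$sites$sv_id[!(truth$sites$sv_id %in% exp_pp)]
  if (!all(calls$sv_id %in% truth$sites$sv_id)) {
    stop("truth_compare: call and truth site ids do not match")
  }
  stage_flag <- list(
    candidate = calls$sv_id[calls$disruptive & calls$candidate],
    cancer_related = calls$sv_id[calls$disruptive & calls$candidate &
                                   calls$cancer_related],
    final = calls$sv_id[calls$final_class %in% c("PP_SV", "cautionary")]
  )
  out <- do.call(rbind, lapply(names(stage_flag), function(st) {
    pos <- stage_flag[[st]]
    tp <- sum(exp_pp %in% pos); fn <- length(exp_pp) - tp
    fp <- sum(neg %in% pos); tn <- length(neg) - fp
    data.frame(stage = st, tp = tp, fn = fn, fp = fp, tn = tn,
               sensitivity = tp / max(tp + fn, 1),
               specificity = tn / max(tn + fp, 1),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
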