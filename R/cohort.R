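#' Construct a genotyped SV cohort
#'
#' Bundles the site table of a cohort-genotyped multi-sample VCF with its
#' per-sample genotype matrices.  Genotypes are stored as alt-allele dosages
#' (`0`, `1`, `2`, `NA` = missing) alongside per-sample filter tags (`FT`)
#' and genotype qualities (`GQ`).  `INV`/`TRA` sites, which derive from
#' breakend records, carry no `FT`; quality masking for those uses `GQ`.
#'
#' @param sites SV record table, one row per genotyped site.
#' @param gt integer matrix (sites x samples) of alt-allele dosages.
#' @param ft character matrix of per-genotype filter tags (`NA` where the
#'   genotyper emits none, e.g. breakend-derived sites).
#' @param gq integer matrix of genotype qualities (0-99, `NA` allowed).
#' @param samples `data.frame` with columns `sample_id`, `ancestry`
#'   (`"AFR"` or `"EUR"`).
#' @param pass_ratio optional numeric vector: per-site fraction of passing
#'   genotype calls.  Recomputed (over all samples in the denominator) when
#'   absent: `FT == "PASS"` where FT exists, else `GQ >= 20`.
#' @return an object of class `sv_cohort`.
#' @export
sv_cohort <- function(sites, gt, ft, gq, samples, pass_ratio = NULL) {
  stopifnot(nrow(gt) == nrow(sites), ncol(gt) == nrow(samples),
            all(dim(ft) == dim(gt)), all(dim(gq) == dim(gt)))
  if (is.null(pass_ratio) || all(is.na(pass_ratio))) {
    pass_ratio <- recompute_pass_ratio(sites, ft, gq)
  } else if (anyNA(pass_ratio)) {
    fill <- recompute_pass_ratio(sites, ft, gq)
    pass_ratio[is.na(pass_ratio)] <- fill[is.na(pass_ratio)]
  }
  structure(list(sites = sites, gt = gt, ft = ft, gq = gq,
                 samples = samples, pass_ratio = pass_ratio),
            class = "sv_cohort")
}

recompute_pass_ratio <- function(sites, ft, gq, min_bnd_gq = 20) {
  bnd_derived <- sites$svtype %in% c("INV", "TRA")
  ok <- !is.na(ft) & ft == "PASS"
  ok[bnd_derived, ] <- !is.na(gq[bnd_derived, , drop = FALSE]) &
    gq[bnd_derived, , drop = FALSE] >= min_bnd_gq
  unname(rowMeans(ok))
}

#' @export
print.sv_cohort <- function(x, ...) {
  cat(sprintf("sv_cohort: %d sites x %d samples (%s)\n",
              nrow(x$sites), nrow(x$samples),
              paste(sprintf("%s=%d", names(table(x$samples$ancestry)),
                            table(x$samples$ancestry)), collapse = ", ")))
  invisible(x)
}

subset_sites <- function(cohort, keep) {
  cohort$sites <- cohort$sites[keep, , drop = FALSE]
  cohort$gt <- cohort$gt[keep, , drop = FALSE]
  cohort$ft <- cohort$ft[keep, , drop = FALSE]
  cohort$gq <- cohort$gq[keep, , drop = FALSE]
  cohort$pass_ratio <- cohort$pass_ratio[keep]
  cohort
}

#' Site-level genotype quality filter
#'
#' Retains sites whose fraction of passing genotype calls is at least
#' `min_pass_ratio` and whose site-level FILTER is `PASS`.
#'
#' @param cohort an [sv_cohort()].
#' @param min_pass_ratio minimum passing-genotype fraction (default 0.5).
#' @return the filtered `sv_cohort`.
#' @export
site_filter <- function(cohort, min_pass_ratio = 0.5) {
  keep <- cohort$pass_ratio >= min_pass_ratio & cohort$sites$filter == "PASS"
  subset_sites(cohort, keep)
}

#' Mask low-quality individual genotypes as missing
#'
#' For sites with per-genotype filter tags, any genotype whose `FT` is not
#' `PASS` becomes missing.  Breakend-derived sites (`INV`/`TRA`) have no
#' `FT`; there a genotype with `GQ < min_bnd_gq` becomes missing.
#'
#' @param cohort an [sv_cohort()].
#' @param min_bnd_gq GQ threshold for breakend-derived sites (default 20).
#' @return the `sv_cohort` with masked genotypes.
#' @export
mask_genotypes <- function(cohort, min_bnd_gq = 20) {
  bnd_derived <- cohort$sites$svtype %in% c("INV", "TRA")
  drop <- !is.na(cohort$ft) & cohort$ft != "PASS"
  drop[bnd_derived, ] <- is.na(cohort$gq[bnd_derived, , drop = FALSE]) |
    cohort$gq[bnd_derived, , drop = FALSE] < min_bnd_gq
  cohort$gt[drop] <- NA_integer_
  cohort
}

#' Remove sites with excess genotype missingness in either ancestry
#'
#' A site is removed when its missing-genotype fraction exceeds
#' `max_missing` within the AFR subset *or* within the EUR subset.
#'
#' @param cohort an [sv_cohort()] with masked genotypes.
#' @param max_missing maximum tolerated missing fraction (default 0.2).
#' @return the filtered `sv_cohort`.
#' @export
missingness_filter <- function(cohort, max_missing = 0.2) {
  anc <- cohort$samples$ancestry
  if (is.null(anc) || anyNA(anc)) {
    stop("missingness_filter: ancestry labels are required for every sample")
  }
  keep <- rep(TRUE, nrow(cohort$sites))
  for (grp in unique(anc)) {
    cols <- which(anc == grp)
    miss <- rowMeans(is.na(cohort$gt[, cols, drop = FALSE]))
    keep <- keep & miss <= max_missing
  }
  subset_sites(cohort, keep)
}

#' Rarity class of a minor allele frequency
#'
#' `rare` for MAF <= 1%, `low_frequency` for 1-5%, `common` above 5%.
#' With `exclusive = TRUE` the rare boundary becomes MAF < 1%, so a MAF of
#' exactly 0.01 is labelled low-frequency.
#'
#' @param maf numeric vector of minor allele frequencies in `[0, 0.5]`.
#' @param exclusive logical; see above.
#' @return character vector of classes (`NA` for `NA` input).
#' @export
rarity_class <- function(maf, exclusive = FALSE) {
  rare <- if (exclusive) maf < 0.01 else maf <= 0.01
  out <- ifelse(rare, "rare", ifelse(maf <= 0.05, "low_frequency", "common"))
  out[is.na(maf)] <- NA_character_
  out
}

#' Ancestry-stratified allele frequencies of genotyped sites
#'
#' Allele frequencies are computed over non-missing high-quality genotypes
#' only; run [mask_genotypes()] first.  Each sample contributes two alleles
#' (one on haploid chromosomes when `ploidy_x = "haploid"`, the default for
#' an all-male cohort).  The minor allele frequency is `min(af, 1 - af)`;
#' sites fixed for the alternate allele (overall AF of 1, i.e. reference
#' error) and sites with zero non-missing genotypes are flagged for removal.
#'
#' @param cohort an [sv_cohort()].
#' @param rare_boundary_exclusive passed to [rarity_class()].
#' @param ploidy_x `"haploid"` or `"diploid"` treatment of sex chromosomes.
#' @param haploid_chroms chromosome names treated as haploid.
#' @return `data.frame`, one row per site: `sv_id`, `af_overall`, per-ancestry
#'   `af_*`, `maf_*`, `n_alleles_*`, `carriers_*`, `maf_max`, per-ancestry and
#'   combined `rarity_*`, and logical `flag_remove`.
#' @export
compute_frequencies <- function(cohort, rare_boundary_exclusive = FALSE,
                                ploidy_x = c("haploid", "diploid"),
                                haploid_chroms = c("chrX", "chrY", "X", "Y")) {
  ploidy_x <- match.arg(ploidy_x)
  anc <- cohort$samples$ancestry
  gt <- cohort$gt
  haploid <- ploidy_x == "haploid" & cohort$sites$chrom1 %in% haploid_chroms
  alleles_per_sample <- ifelse(haploid, 1L, 2L)
  alt <- gt
  alt[haploid, ] <- (gt[haploid, , drop = FALSE] > 0) * 1L

  freq_block <- function(cols) {
    sub <- alt[, cols, drop = FALSE]
    n_nonmiss <- rowSums(!is.na(sub))
    n_alleles <- n_nonmiss * alleles_per_sample
    alt_count <- rowSums(sub, na.rm = TRUE)
    af <- ifelse(n_alleles > 0, alt_count / n_alleles, NA_real_)
    list(af = af, n_alleles = n_alleles,
         carriers = rowSums(sub > 0, na.rm = TRUE))
  }
  all_b <- freq_block(seq_along(anc))
  afr_b <- freq_block(which(anc == "AFR"))
  eur_b <- freq_block(which(anc == "EUR"))
  maf <- function(af) pmin(af, 1 - af)
  out <- data.frame(
    sv_id = cohort$sites$id,
    af_overall = all_b$af,
    af_afr = afr_b$af, af_eur = eur_b$af,
    maf_afr = maf(afr_b$af), maf_eur = maf(eur_b$af),
    n_alleles_afr = afr_b$n_alleles, n_alleles_eur = eur_b$n_alleles,
    carriers_afr = afr_b$carriers, carriers_eur = eur_b$carriers,
    stringsAsFactors = FALSE
  )
  # rarity for the downstream cascade uses the larger of the two ancestry MAFs
  out$maf_max <- pmax(out$maf_afr, out$maf_eur, na.rm = TRUE)
  out$maf_max[is.na(out$maf_afr) & is.na(out$maf_eur)] <- NA_real_
  out$rarity_afr <- rarity_class(out$maf_afr, rare_boundary_exclusive)
  out$rarity_eur <- rarity_class(out$maf_eur, rare_boundary_exclusive)
  out$rarity <- rarity_class(out$maf_max, rare_boundary_exclusive)
  out$flag_remove <- is.na(out$af_overall) | out$af_overall == 1
  out
}

#' Drop sites flagged by the frequency computation
#'
#' Removes sites fixed for the alternate allele (overall AF of 1) and sites
#' with no callable genotypes.
#'
#' @param cohort an [sv_cohort()].
#' @param freqs output of [compute_frequencies()] for the same cohort.
#' @return the filtered `sv_cohort`.
#' @export
frequency_filter <- function(cohort, freqs) {
  stopifnot(identical(freqs$sv_id, cohort$sites$id))
  subset_sites(cohort, !freqs$flag_remove)
}

#' Compare per-genome SV counts between ancestries
#'
#' Reports group medians and ranges and a two-sided Wilcoxon rank-sum
#' p-value for the difference in per-genome SV counts.
#'
#' @param counts_afr,counts_eur integer vectors of SV counts per genome.
#' @return list with `median_afr`, `range_afr`, `median_eur`, `range_eur`,
#'   `p_value`.
#' @export
per_genome_sv_count_test <- function(counts_afr, counts_eur) {
  if (length(counts_afr) < 2 || length(counts_eur) < 2) {
    stop("per_genome_sv_count_test: each group needs at least 2 genomes")
  }
  w <- suppressWarnings(
    stats::wilcox.test(counts_afr, counts_eur, alternative = "two.sided"))
  list(median_afr = stats::median(counts_afr), range_afr = range(counts_afr),
       median_eur = stats::median(counts_eur), range_eur = range(counts_eur),
       p_value = w$p.value)
}
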