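#' Round half away from zero
#'
#' Reported percentages round half-up (so 12.35 prints as 12.4), unlike
#' base R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Fraction of a cohort carrying at least one SV of given classes
#'
#' Counts distinct patients of an ancestry with one or more SVs in the class
#' set, over the ancestry cohort size; duplicated carrier rows do not
#' inflate the count.
#'
#' @param carriers `data.frame` with at least `patient_id`, `final_class`.
#' @param patients `data.frame` with `patient_id`, `ancestry`.
#' @param ancestry cohort to report (`"AFR"` or `"EUR"`).
#' @param classes final classes to count (default both PP-SV flavours).
#' @return list: `count`, `denominator`, `percent` (1 decimal, half-up).
#' @export
carrier_fraction <- function(carriers, patients, ancestry,
                             classes = c("PP_SV", "cautionary")) {
  denom <- sum(patients$ancestry == ancestry)
  if (denom == 0) stop("carrier_fraction: empty cohort for ", ancestry)
  in_cohort <- patients$patient_id[patients$ancestry == ancestry]
  hit <- unique(carriers$patient_id[carriers$final_class %in% classes &
                                      carriers$patient_id %in% in_cohort])
  list(count = length(hit), denominator = denom,
       percent = round_half_up(100 * length(hit) / denom, 1))
}

#' Fraction of carrier patients with aggressive disease
#'
#' Among distinct patients carrying an SV of the class set, the fraction
#' whose tumour grade group is at least `gg_threshold`.  Carriers of
#' unknown grade are handled by `unknown_policy`: counted as aggressive
#' (default), counted as non-aggressive, or excluded from both counts.
#'
#' @param carriers `data.frame` with `patient_id`, `final_class`.
#' @param patients `data.frame` with `patient_id`, `isup_gg` (integer 1-5 or
#'   `NA`).
#' @param classes final classes defining the carrier set.
#' @param gg_threshold aggressive grade-group cut-off (default 3).
#' @param unknown_policy one of `"count_aggressive"`,
#'   `"count_nonaggressive"`, `"exclude"`.
#' @return list: `count`, `denominator`, `percent`.
#' @export
aggressive_fraction <- function(carriers, patients,
                                classes = c("PP_SV", "cautionary"),
                                gg_threshold = 3,
                                unknown_policy = c("count_aggressive",
                                                   "count_nonaggressive",
                                                   "exclude")) {
  unknown_policy <- match.arg(unknown_policy)
  ids <- unique(carriers$patient_id[carriers$final_class %in% classes])
  gg <- patients$isup_gg[match(ids, patients$patient_id)]
  unk <- is.na(gg)
  if (unknown_policy == "exclude") {
    gg <- gg[!unk]
    aggressive <- sum(gg >= gg_threshold)
    denom <- length(gg)
  } else {
    aggressive <- sum(gg >= gg_threshold, na.rm = TRUE) +
      if (unknown_policy == "count_aggressive") sum(unk) else 0L
    denom <- length(gg)
  }
  list(count = aggressive, denominator = denom,
       percent = if (denom > 0) round_half_up(100 * aggressive / denom, 1)
       else NA_real_)
}

#' Cascade funnel counts
#'
#' Stage-by-stage counts of SVs surviving each gate of the classification
#' cascade, in cascade order; counts are non-increasing by construction.
#'
#' @param calls output of [classify_cohort()].
#' @param n_input,n_site_filtered,n_rare optional upstream counts (total
#'   genotyped sites, sites after site/genotype QC, sites after removing
#'   common SVs); `NA` when not supplied.
#' @return `data.frame` with `stage` and `n`.
#' @export
funnel_counts <- function(calls, n_input = NA, n_site_filtered = NA,
                          n_rare = NA) {
  disruptive <- calls$disruptive
  cand <- disruptive & calls$candidate
  cancer <- cand & calls$cancer_related
  rare <- cancer & calls$rarity_ok
  kept <- rare & calls$known_af_ok
  final <- kept & calls$final_class %in% c("PP_SV", "cautionary")
  data.frame(
    stage = c("input_sites", "site_filtered", "rare_or_low_frequency",
              "gene_disruptive", "score_candidates", "cancer_related",
              "rare_candidates", "after_known_frequency", "final_pp_sv"),
    n = c(n_input, n_site_filtered, n_rare, sum(disruptive), sum(cand),
          sum(cancer), sum(rare), sum(kept), sum(final))
  )
}

#' Write the cohort summary tables
#'
#' Renders three deterministic, sorted tab-separated files: a candidate
#' table (one row per final PP-SV / cautionary SV with coordinates, type,
#' genes and ancestry MAFs), a carrier table (one row per patient-SV pair
#' with clinical columns), and the cascade funnel.  Re-running on identical
#' inputs reproduces the files byte for byte.
#'
#' @param calls output of [classify_cohort()].
#' @param svs SV record table of the classified sites.
#' @param freqs frequency table ([compute_frequencies()]).
#' @param carriers carrier `data.frame` (`patient_id`, `sv_id`, `gene`,
#'   `final_class`, optional `vaf`, `loh`, `second_hit`).
#' @param dir output directory (created if needed).
#' @param funnel optional precomputed [funnel_counts()] table.
#' @return invisible character vector of the files written.
#' @export
summarize_tables <- function(calls, svs, freqs, carriers, dir,
                             funnel = funnel_counts(calls)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  keep <- calls$final_class %in% c("PP_SV", "cautionary")
  tab1 <- merge(calls[keep, c("sv_id", "svtype", "genes", "fusion",
                              "final_class", "rule", "clinvar_override")],
                svs[, c("id", "chrom1", "pos1", "chrom2", "pos2")],
                by.x = "sv_id", by.y = "id")
  tab1 <- merge(tab1, freqs[, c("sv_id", "maf_afr", "maf_eur")], by = "sv_id")
  tab1$maf_afr <- round(tab1$maf_afr, 3)
  tab1$maf_eur <- round(tab1$maf_eur, 3)
  tab1 <- tab1[order(tab1$final_class, tab1$sv_id), ]
  f1 <- file.path(dir, "candidates.tsv")
  write_tsv(tab1, f1)
  carriers <- carriers[order(carriers$patient_id, carriers$sv_id), ,
                       drop = FALSE]
  f2 <- file.path(dir, "carriers.tsv")
  write_tsv(carriers, f2)
  f3 <- file.path(dir, "funnel.tsv")
  write_tsv(funnel, f3)
  invisible(c(f1, f2, f3))
}
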