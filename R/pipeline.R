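#' Run the full prioritization pipeline on an input bundle
#'
#' Executes every stage of the workflow on the in-memory bundle produced by
#' [generate_cohort()] (or assembled from files with the package readers):
#' cohort genotype QC (site filter, genotype masking, missingness filter,
#' removal of alternate-fixed sites), allele-frequency estimation with
#' exclusion of common SVs (MAF > 5% in both-ancestry terms), gene-impact
#' annotation, known-SV matching, the consensus/cancer/rarity/frequency
#' pathogenicity cascade, and — where the bundle carries depth, breakpoint
#' and copy-number evidence — per-carrier VAF, LOH and second-hit calls.
#'
#' @param bundle an `sv_bundle` list (see [generate_cohort()] for the
#'   expected elements).
#' @param min_pass_ratio,max_missing,min_bnd_gq QC thresholds (see
#'   [site_filter()], [missingness_filter()], [mask_genotypes()]).
#' @param max_common_maf MAF above which an SV is common and set aside
#'   before annotation (default 0.05).
#' @param ... further arguments to [classify_cohort()].
#' @return list with `cohort` (QC'ed [sv_cohort()]), `freqs`, `impacts`,
#'   `matches`, `calls`, `carriers`, `funnel`.
#' @export
run_pipeline <- function(bundle, min_pass_ratio = 0.5, max_missing = 0.2,
                         min_bnd_gq = 20, max_common_maf = 0.05, ...) {
  co <- site_filter(bundle$cohort, min_pass_ratio)
  co <- mask_genotypes(co, min_bnd_gq)
  co <- missingness_filter(co, max_missing)
  freqs <- compute_frequencies(co)
  co <- frequency_filter(co, freqs)
  freqs <- freqs[!freqs$flag_remove, , drop = FALSE]
  n_site_filtered <- nrow(co$sites)
  keep <- !is.na(freqs$maf_max) & freqs$maf_max <= max_common_maf
  co <- subset_sites(co, keep)
  freqs <- freqs[keep, , drop = FALSE]

  impacts <- annotate_svs(co$sites, bundle$genes,
                          promoters = bundle$promoters,
                          enhancers = bundle$enhancers)
  matches <- match_known_all(co$sites, bundle$known_table)
  panels <- bundle$panels[match(co$sites$id, bundle$panels$sv_id), ,
                          drop = FALSE]
  calls <- classify_cohort(co$sites, impacts, freqs, matches, panels,
                           bundle$sets, bundle$roles, ...)
  funnel <- funnel_counts(calls, n_input = nrow(bundle$cohort$sites),
                          n_site_filtered = n_site_filtered,
                          n_rare = nrow(co$sites))
  carriers <- carrier_calls(co, calls, bundle)
  list(cohort = co, freqs = freqs, impacts = impacts, matches = matches,
       calls = calls, carriers = carriers, funnel = funnel)
}

# per-patient rows for final PP-SV / cautionary calls, with VAF, LOH and
# second-hit evidence where the bundle provides it
carrier_calls <- function(co, calls, bundle) {
  rows <- list()
  final <- calls[calls$final_class %in% c("PP_SV", "cautionary"), ,
                 drop = FALSE]
  for (i in seq_len(nrow(final))) {
    svid <- final$sv_id[i]
    sv <- co$sites[co$sites$id == svid, , drop = FALSE]
    carriers <- co$samples$sample_id[!is.na(co$gt[svid, ]) & co$gt[svid, ] > 0]
    gene <- strsplit(final$genes[i], ",")[[1]][1]
    for (s in carriers) {
      key <- paste(svid, s, sep = ":")
      vaf <- NA_real_
      if (!is.null(bundle$depth_tracks[[key]])) {
        vaf <- if (sv$svtype %in% c("DEL", "DUP")) {
          vaf_depth(sv, bundle$depth_tracks[[key]])$vaf
        } else {
          vaf_breakpoint(sv, bundle$evidence[[key]],
                         bundle$depth_tracks[[key]])$vaf
        }
      }
      loh <- NA_character_
      if (!is.null(bundle$cn_segments[[s]]) && !is.na(gene) &&
          gene %in% bundle$genes$gene_id) {
        g <- bundle$genes[bundle$genes$gene_id == gene, ]
        loh <- classify_loh(list(chrom = g$chrom, start = g$tx_start,
                                 end = g$tx_end), bundle$cn_segments[[s]])
      }
      hit <- "none"
      if (!is.null(bundle$somatic_events) && nrow(bundle$somatic_events) > 0 &&
          !is.na(gene)) {
        ev <- bundle$somatic_events[bundle$somatic_events$patient_id == s, ,
                                    drop = FALSE]
        hit <- second_hit(gene, ev)
      }
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = s, sv_id = svid, gene = gene,
        final_class = final$final_class[i], vaf = round(vaf, 2),
        loh = loh, second_hit = unname(hit), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(patient_id = character(0), sv_id = character(0),
                      gene = character(0), final_class = character(0),
                      vaf = numeric(0), loh = character(0),
                      second_hit = character(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$patient_id, out$sv_id), , drop = FALSE]
}
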