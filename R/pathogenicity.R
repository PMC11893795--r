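#' Default score thresholds of the four impact-prediction tools
#'
#' A tool votes pathogenic when its score reaches the threshold:
#' StrVCTVRE >= 0.37 (the ClinVar 90%-sensitivity operating point),
#' scaled CADD-SV >= 10 (top decile of the population-SV score
#' distribution), POSTRE >= 0.8 and PhenoSV >= 0.5 (the pathogenicity
#' labelling thresholds those tools define).
#'
#' @return named numeric vector of thresholds.
#' @export
default_score_thresholds <- function() {
  c(strvctvre = 0.37, cadd_sv = 10, postre = 0.8, phenosv = 0.5)
}

#' Multi-tool consensus candidacy of score panels
#'
#' Each SV carries up to four tool scores (`NA` where a tool cannot score
#' that SV type or region).  A tool passes when its score is present and at
#' least its threshold; the SV is a pathogenicity candidate when the number
#' of passing tools reaches `min_pass`.  By default the count is absolute —
#' an SV scoreable by only two tools still needs two passes.  With
#' `min_pass_relative = TRUE` the requirement becomes
#' `min(min_pass, number of tools able to score the SV)`.
#'
#' @param panel `data.frame` with columns `sv_id`, `strvctvre`, `cadd_sv`,
#'   `postre`, `phenosv` (see [read_score_panels()]).
#' @param thresholds named numeric vector ([default_score_thresholds()]).
#' @param min_pass minimum passing tools (default 2).
#' @param min_pass_relative logical; see above.
#' @return `data.frame`: `sv_id`, `n_tools_scored`, `n_tools_passed`,
#'   `candidate`.
#' @export
consensus_candidate <- function(panel, thresholds = default_score_thresholds(),
                                min_pass = 2, min_pass_relative = FALSE) {
  tools <- names(default_score_thresholds())
  stopifnot(all(tools %in% names(panel)), all(tools %in% names(thresholds)))
  scores <- as.matrix(panel[, tools])
  if (any(scores < 0, na.rm = TRUE)) {
    stop("consensus_candidate: negative scores are not valid")
  }
  passed <- sweep(scores, 2, thresholds[tools], ">=")
  n_scored <- rowSums(!is.na(scores))
  n_passed <- rowSums(passed, na.rm = TRUE)
  need <- if (min_pass_relative) pmin(min_pass, pmax(n_scored, 1L)) else min_pass
  data.frame(sv_id = panel$sv_id,
             n_tools_scored = n_scored,
             n_tools_passed = n_passed,
             candidate = n_passed >= need,
             stringsAsFactors = FALSE)
}

#' Cancer-relevance of an SV's disrupted genes
#'
#' Requires representation in at least `min_sets` of the three cancer gene
#' collections (hallmark, oncogenic signature, cancer gene census).  Under
#' the default union reading, the disrupted genes jointly must cover
#' `min_sets` collections — a fusion joining two single-collection genes
#' qualifies.  With `union_rule = FALSE` a single gene must sit in
#' `min_sets` collections by itself.
#'
#' @param genes character vector of the SV's disrupted gene ids.
#' @param sets named list of three character vectors: `hallmark`,
#'   `oncogenic_signatures`, `cancer_census`.
#' @param min_sets minimum collections covered (default 2).
#' @param union_rule logical; see above.
#' @return logical scalar.
#' @export
cancer_relevance <- function(genes, sets, min_sets = 2, union_rule = TRUE) {
  stopifnot(all(c("hallmark", "oncogenic_signatures", "cancer_census") %in%
                  names(sets)))
  if (length(genes) == 0) return(FALSE)
  member <- vapply(sets[c("hallmark", "oncogenic_signatures", "cancer_census")],
                   function(s) genes %in% s, logical(length(genes)))
  member <- matrix(member, nrow = length(genes))
  if (union_rule) {
    sum(apply(member, 2, any)) >= min_sets
  } else {
    any(rowSums(member) >= min_sets)
  }
}

role_of <- function(genes, roles) {
  r <- roles$role[match(genes, roles$gene_id)]
  if (anyNA(r)) {
    warning("classify_final: no role entry for ",
            paste(genes[is.na(r)], collapse = ", "), "; defaulting to 'none'")
    r[is.na(r)] <- "none"
  }
  r
}

# gene-role rule engine for loss-type impact (pLoF by DEL/INV/TRA)
loss_rule <- function(roles_vec) {
  has <- function(x) any(roles_vec == x)
  if (has("conflicting")) return(list(class = "cautionary", rule = "R2-conflicting"))
  if (has("TSG")) {
    if (has("oncogene")) return(list(class = "cautionary", rule = "R2-tsg-onco-mix"))
    if (all(roles_vec == "TSG")) return(list(class = "PP_SV", rule = "R2-all-tsg"))
    return(list(class = "cautionary", rule = "R2-tsg-unclear-partner"))
  }
  if (has("oncogene")) return(list(class = "unlikely", rule = "R2-oncogene-loss"))
  list(class = "unlikely", rule = "R2-no-suppressor-evidence")
}

# rule engine for dosage-type impact (CG / IED)
dosage_rule <- function(dosage_roles, breakpoint_roles) {
  if (any(dosage_roles == "oncogene")) {
    return(list(class = "PP_SV", rule = "R3-oncogene-gain"))
  }
  if (any(breakpoint_roles %in% c("TSG", "oncogene"))) {
    return(list(class = "cautionary", rule = "R3-breakpoint-cancer-gene"))
  }
  list(class = "unlikely", rule = "R3-no-dosage-evidence")
}

#' Final pathogenicity classification of one candidate SV
#'
#' Applies the classification rule engine to an SV that has already passed
#' the consensus-score, cancer-gene-set and rarity gates.  Rules fire in
#' order over the roles of the SV's disrupted genes:
#'
#' * **R1** — matched to a known SV with pathogenic or likely-pathogenic
#'   clinical significance: `PP_SV` with `clinvar_override` set (plausibility
#'   review of non-cancer phenotypes remains a manual step).
#' * **R2** — loss-type impact (`pLoF` by `DEL`/`INV`/`TRA`): all impacted
#'   genes tumour suppressors gives `PP_SV`; any conflicting role, a
#'   TSG/oncogene mixture, or a TSG joined to an unclear partner gives
#'   `cautionary`; oncogene loss or no suppressor evidence gives `unlikely`.
#' * **R3** — dosage-type impact (`CG`/`IED`): an oncogene gaining dosage
#'   gives `PP_SV`; an uncharacterised dosage gene whose breakpoints disrupt
#'   a TSG or oncogene gives `cautionary`; otherwise `unlikely`.
#' * **R4** — anything else is `unlikely`.
#'
#' @param sv one-row SV record table.
#' @param impacts annotation rows of this SV ([annotate_sv()]).
#' @param match one-row result of [match_known()] for this SV.
#' @param roles gene-role table ([read_gene_roles()]).
#' @return list with `final_class`, `rule`, `clinvar_override`.
#' @export
classify_final <- function(sv, impacts, match, roles) {
  if (!is.null(match) && nrow(match) == 1 &&
      match$significance %in% c("pathogenic", "likely_pathogenic")) {
    return(list(final_class = "PP_SV", rule = "R1-clinvar",
                clinvar_override = TRUE))
  }
  loss <- impacts$gene_id[impacts$category == "pLoF" &
                            sv$svtype %in% c("DEL", "INV", "TRA")]
  if (length(loss) > 0) {
    r <- loss_rule(role_of(loss, roles))
    return(list(final_class = r$class, rule = r$rule, clinvar_override = FALSE))
  }
  dosage <- impacts$gene_id[impacts$category %in% c("CG", "IED")]
  if (length(dosage) > 0) {
    bp_genes <- setdiff(impacts$gene_id[impacts$breakpoint_gene &
                                          !is.na(impacts$gene_id)], dosage)
    r <- dosage_rule(role_of(dosage, roles),
                     if (length(bp_genes)) role_of(bp_genes, roles) else character(0))
    return(list(final_class = r$class, rule = r$rule, clinvar_override = FALSE))
  }
  list(final_class = "unlikely", rule = "R4-default", clinvar_override = FALSE)
}

#' Run the full pathogenicity cascade over annotated cohort SVs
#'
#' Combines the per-stage gates into one audit table:
#' gene-disruptive impact -> 2-of-4 score consensus -> 2-of-3 cancer gene
#' sets -> rarity (MAF <= `max_rare_maf` in both ancestries) -> reported
#' population-frequency exclusion -> gene-role rule engine.  SVs failing any
#' gate receive `final_class = "not_candidate"` with the failing gate in the
#' `rule` column.
#'
#' @param svs SV record table of genotyped, frequency-annotated sites.
#' @param impacts annotation table ([annotate_svs()]).
#' @param freqs frequency table ([compute_frequencies()]).
#' @param matches known-SV match table ([match_known_all()]).
#' @param panels score panel table.
#' @param sets cancer gene-set list (see [cancer_relevance()]).
#' @param roles gene-role table.
#' @param max_rare_maf rarity gate (default 0.01, in both ancestries).
#' @param max_known_af reported-frequency exclusion threshold (default 0.01).
#' @param thresholds,min_pass,min_pass_relative passed to
#'   [consensus_candidate()].
#' @param min_sets,union_rule passed to [cancer_relevance()].
#' @return `data.frame`, one row per SV: gate columns (`disruptive`,
#'   `candidate`, `cancer_related`, `rarity_ok`, `known_af_ok`),
#'   `n_tools_scored`, `n_tools_passed`, `final_class`, `rule`,
#'   `clinvar_override`, `genes` (comma-joined disrupted genes), `fusion`.
#' @export
classify_cohort <- function(svs, impacts, freqs, matches, panels, sets, roles,
                            max_rare_maf = 0.01, max_known_af = 0.01,
                            thresholds = default_score_thresholds(),
                            min_pass = 2, min_pass_relative = FALSE,
                            min_sets = 2, union_rule = TRUE) {
  cons <- consensus_candidate(panels, thresholds, min_pass, min_pass_relative)
  out <- lapply(seq_len(nrow(svs)), function(i) {
    sv <- svs[i, ]
    imp <- impacts[impacts$sv_id == sv$id, , drop = FALSE]
    disrupted <- unique(imp$gene_id[imp$category %in% disruptive_categories()])
    # dosage events also implicate genes broken at the duplication breakpoints
    gene_pool <- unique(c(disrupted,
                          imp$gene_id[imp$breakpoint_gene & !is.na(imp$gene_id)]))
    m <- matches[matches$sv_id == sv$id, , drop = FALSE]
    cc <- cons[cons$sv_id == sv$id, , drop = FALSE]
    fr <- freqs[freqs$sv_id == sv$id, , drop = FALSE]
    disruptive <- length(disrupted) > 0
    candidate <- nrow(cc) == 1 && isTRUE(cc$candidate)
    cancer <- disruptive && cancer_relevance(gene_pool, sets, min_sets, union_rule)
    rarity_ok <- nrow(fr) == 1 && !is.na(fr$maf_max) && fr$maf_max <= max_rare_maf
    known_ok <- !(nrow(m) == 1 && !is.na(m$max_reported_af) &&
                    m$max_reported_af >= max_known_af)
    fus <- stats::na.omit(unique(imp$fusion))
    row <- data.frame(
      sv_id = sv$id, svtype = sv$svtype,
      genes = paste(disrupted, collapse = ","),
      fusion = if (length(fus)) fus[1] else NA_character_,
      n_tools_scored = if (nrow(cc)) cc$n_tools_scored else 0L,
      n_tools_passed = if (nrow(cc)) cc$n_tools_passed else 0L,
      disruptive = disruptive, candidate = candidate,
      cancer_related = cancer, rarity_ok = rarity_ok, known_af_ok = known_ok,
      stringsAsFactors = FALSE
    )
    if (!disruptive) {
      row$final_class <- "not_candidate"; row$rule <- "gate-not-disruptive"
      row$clinvar_override <- FALSE
    } else if (!candidate) {
      row$final_class <- "not_candidate"; row$rule <- "gate-score-consensus"
      row$clinvar_override <- FALSE
    } else if (!cancer) {
      row$final_class <- "not_candidate"; row$rule <- "gate-cancer-sets"
      row$clinvar_override <- FALSE
    } else if (!rarity_ok) {
      row$final_class <- "not_candidate"; row$rule <- "gate-rarity"
      row$clinvar_override <- FALSE
    } else if (!known_ok) {
      row$final_class <- "not_candidate"; row$rule <- "gate-known-frequency"
      row$clinvar_override <- FALSE
    } else {
      cl <- classify_final(sv, imp, m, roles)
      row$final_class <- cl$final_class; row$rule <- cl$rule
      row$clinvar_override <- cl$clinvar_override
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
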