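SIGNIFICANCE_LEVELS <- c("pathogenic", "likely_pathogenic", "uncertain",
                         "benign", "none")

#' Consensus clinical significance across study labels
#'
#' An entry reported with conflicting interpretations takes the most
#' pathogenic label only when no benign label exists; a pathogenic (or
#' likely-pathogenic) label alongside a benign one collapses to
#' `"uncertain"`.
#'
#' @param labels character vector of per-study significance labels.
#' @return a single significance label.
#' @export
consensus_significance <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0) return("none")
  bad <- setdiff(unique(labels), SIGNIFICANCE_LEVELS)
  if (length(bad) > 0) stop("unknown significance label(s): ",
                            paste(bad, collapse = ", "))
  path_like <- any(labels %in% c("pathogenic", "likely_pathogenic"))
  if (path_like && any(labels == "benign")) return("uncertain")
  labels[which.min(match(labels, SIGNIFICANCE_LEVELS))]
}

#' Collapse a multi-study known-SV table to one row per entry
#'
#' Aggregates the per-(entry, study) rows of a known-SV table: consensus
#' clinical significance ([consensus_significance()]) and the maximum
#' reported allele frequency across studies and populations.
#'
#' @param table known-SV table ([read_known_sv_table()]).
#' @return `data.frame`, one row per `entry_id`.
#' @export
collapse_known_entries <- function(table) {
  if (nrow(table) == 0) {
    return(data.frame(entry_id = character(0), chrom1 = character(0),
                      pos1 = integer(0), chrom2 = character(0),
                      pos2 = integer(0), svtype = character(0),
                      significance = character(0),
                      max_reported_af = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(split(table, table$entry_id), function(e) {
    data.frame(entry_id = e$entry_id[1], chrom1 = e$chrom1[1],
               pos1 = e$pos1[1], chrom2 = e$chrom2[1], pos2 = e$pos2[1],
               svtype = e$svtype[1],
               significance = consensus_significance(e$significance),
               max_reported_af = if (all(is.na(e$af))) NA_real_ else
                 max(e$af, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Match an SV against a table of known structural variants
#'
#' A cohort SV matches a known entry when the SV types agree, the chromosome
#' anchors agree (orderless for translocations) and both breakpoints lie
#' within `tolerance` bases of the entry's breakpoints.  Among several
#' qualifying entries the minimal summed breakpoint distance wins; ties
#' prefer an entry with a clinical significance other than `none`, then the
#' smallest `entry_id`, making the choice independent of table order.
#'
#' @param sv one-row SV record table.
#' @param table known-SV table ([read_known_sv_table()]); rows sharing an
#'   `entry_id` are collapsed (consensus significance, maximum reported AF).
#' @param tolerance per-breakpoint distance in bases (default 200).
#' @return one-row `data.frame`: `sv_id`, `status` (`known`/`unknown`),
#'   `matched_entry`, `significance`, `max_reported_af`.
#' @export
match_known <- function(sv, table, tolerance = 200) {
  stopifnot(nrow(sv) == 1)
  entries <- collapse_known_entries(table)
  no_match <- data.frame(sv_id = sv$id, status = "unknown",
                         matched_entry = NA_character_,
                         significance = "none",
                         max_reported_af = NA_real_,
                         stringsAsFactors = FALSE)
  if (nrow(entries) == 0) return(no_match)
  hits <- list()
  for (j in seq_len(nrow(entries))) {
    e <- entries[j, ]
    if (e$svtype != sv$svtype) next
    d <- anchor_distances(sv, data.frame(
      chrom1 = e$chrom1, pos1 = e$pos1, chrom2 = e$chrom2, pos2 = e$pos2,
      svtype = e$svtype, stringsAsFactors = FALSE), tolerance)
    if (is.null(d)) next
    hits[[length(hits) + 1]] <- cbind(e, dist_sum = d[1] + d[2])
  }
  if (length(hits) == 0) return(no_match)
  h <- do.call(rbind, hits)
  ord <- order(h$dist_sum, h$significance == "none", h$entry_id)
  best <- h[ord[1], ]
  data.frame(sv_id = sv$id, status = "known", matched_entry = best$entry_id,
             significance = best$significance,
             max_reported_af = best$max_reported_af, stringsAsFactors = FALSE)
}

#' Match a table of SVs against known structural variants
#'
#' @inheritParams match_known
#' @param svs SV record table.
#' @return `data.frame`, one row per SV (see [match_known()]).
#' @export
match_known_all <- function(svs, table, tolerance = 200) {
  out <- do.call(rbind, lapply(seq_len(nrow(svs)), function(i) {
    match_known(svs[i, ], table, tolerance)
  }))
  rownames(out) <- NULL
  out
}

#' Exclude candidates already reported at appreciable population frequency
#'
#' Known SVs whose maximum reported allele frequency reaches
#' `max_known_af` are removed from the candidate list; unknown SVs and known
#' SVs reported only at rarer frequencies are kept.  The threshold is
#' inclusive: an SV reported at exactly the threshold frequency is excluded.
#'
#' @param matches `data.frame` from [match_known_all()].
#' @param max_known_af exclusion threshold (default 0.01).
#' @return list with `kept` and `excluded` subsets of `matches`.
#' @export
frequency_exclusion <- function(matches, max_known_af = 0.01) {
  drop <- !is.na(matches$max_reported_af) &
    matches$max_reported_af >= max_known_af
  list(kept = matches[!drop, , drop = FALSE],
       excluded = matches[drop, , drop = FALSE])
}
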