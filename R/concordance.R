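#' Dual-caller concordance of per-sample SV call sets
#'
#' The high-confidence call set of a sample is the intersection of two
#' independent callers: a call from caller A matches one from caller B when
#' the SV types agree, the chromosome anchors agree, both breakpoint
#' positions lie within `tolerance` bases of each other, and at least one of
#' the two calls carries a `PASS` filter (`require_both_pass = TRUE`
#' tightens this to both).  Matching is one-to-one and greedy by minimal
#' summed breakpoint distance; ties are broken by smaller `pos1`, then by
#' record ids, so results are independent of input order.  Translocation
#' anchors are compared orderlessly.
#'
#' The merged record takes the coordinates of the caller-A member, because
#' downstream graph genotypers consume caller-A-format VCFs with exact
#' breakpoint sequence.
#'
#' @param setA,setB SV record tables from the two callers for one sample.
#' @param tolerance maximum per-breakpoint distance in bases (default 200).
#' @param require_both_pass logical; require `PASS` from both callers.
#' @return list with elements `concordant` (merged records,
#'   `caller = "merged"`), `only_a`, `only_b`, and `match_log`
#'   (`data.frame` with `id_a`, `id_b`, `distance1`, `distance2`).
#' @export
match_calls <- function(setA, setB, tolerance = 200, require_both_pass = FALSE) {
  if (tolerance < 0) stop("match_calls: tolerance must be >= 0")
  cand <- candidate_matches(setA, setB, tolerance, require_both_pass)
  # greedy one-to-one: minimal summed distance, ties by smaller caller-A pos1,
  # then lexicographic ids
  ord <- order(cand$dist_sum, cand$pos1_a, cand$id_a, cand$id_b)
  cand <- cand[ord, , drop = FALSE]
  used_a <- character(0)
  used_b <- character(0)
  take <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$id_a[i] %in% used_a || cand$id_b[i] %in% used_b) next
    take[i] <- TRUE
    used_a <- c(used_a, cand$id_a[i])
    used_b <- c(used_b, cand$id_b[i])
  }
  log <- cand[take, c("id_a", "id_b", "distance1", "distance2"), drop = FALSE]
  rownames(log) <- NULL
  concordant <- setA[match(log$id_a, setA$id), , drop = FALSE]
  if (nrow(concordant) > 0) {
    b_pass <- setB$filter[match(log$id_b, setB$id)] == "PASS"
    concordant$caller <- "merged"
    concordant$filter <- ifelse(concordant$filter == "PASS" | b_pass,
                                "PASS", concordant$filter)
  }
  rownames(concordant) <- NULL
  list(concordant = concordant,
       only_a = setA[!(setA$id %in% log$id_a), , drop = FALSE],
       only_b = setB[!(setB$id %in% log$id_b), , drop = FALSE],
       match_log = log)
}

# all (a, b) pairs satisfying type/anchor/distance/filter constraints
candidate_matches <- function(setA, setB, tolerance, require_both_pass) {
  out <- data.frame(id_a = character(0), id_b = character(0),
                    distance1 = integer(0), distance2 = integer(0),
                    dist_sum = integer(0), pos1_a = integer(0),
                    stringsAsFactors = FALSE)
  if (nrow(setA) == 0 || nrow(setB) == 0) return(out)
  for (i in seq_len(nrow(setA))) {
    a <- setA[i, ]
    for (j in seq_len(nrow(setB))) {
      b <- setB[j, ]
      if (a$svtype != b$svtype) next
      if (require_both_pass) {
        if (a$filter != "PASS" || b$filter != "PASS") next
      } else {
        if (a$filter != "PASS" && b$filter != "PASS") next
      }
      d <- anchor_distances(a, b, tolerance)
      if (is.null(d)) next
      out <- rbind(out, data.frame(
        id_a = a$id, id_b = b$id, distance1 = d[1], distance2 = d[2],
        dist_sum = d[1] + d[2], pos1_a = a$pos1, stringsAsFactors = FALSE))
    }
  }
  out
}

# breakpoint distances between two records under the tolerance, honouring
# orderless anchor comparison for TRA; NULL when no orientation qualifies
anchor_distances <- function(a, b, tolerance) {
  direct <- NULL
  if (a$chrom1 == b$chrom1 && a$chrom2 == b$chrom2) {
    d1 <- abs(a$pos1 - b$pos1); d2 <- abs(a$pos2 - b$pos2)
    if (d1 <= tolerance && d2 <= tolerance) direct <- c(d1, d2)
  }
  if (a$svtype != "TRA") return(direct)
  crossed <- NULL
  if (a$chrom1 == b$chrom2 && a$chrom2 == b$chrom1) {
    d1 <- abs(a$pos1 - b$pos2); d2 <- abs(a$pos2 - b$pos1)
    if (d1 <= tolerance && d2 <= tolerance) crossed <- c(d1, d2)
  }
  if (is.null(direct)) return(crossed)
  if (is.null(crossed)) return(direct)
  if (sum(crossed) < sum(direct)) crossed else direct
}
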