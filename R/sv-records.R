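#' Construct a table of structural variant records
#'
#' The central container of the package is a plain `data.frame` with one row
#' per structural variant (SV).  Coordinates are 1-based inclusive, as in VCF;
#' internal interval arithmetic converts to 0-based half-open only where
#' overlaps are computed, so user-facing positions always match the VCF text.
#'
#' @param id character, record identifiers (unique within a call set).
#' @param chrom1,pos1 chromosome and 1-based position of the first breakpoint.
#' @param chrom2,pos2 chromosome and position of the second breakpoint.  For
#'   intra-chromosomal SVs (`DEL`, `DUP`, `INS`, `INV`) `chrom2 == chrom1`;
#'   inter-chromosomal translocations (`TRA`) carry two independent anchors.
#' @param svtype one of `"DEL"`, `"DUP"`, `"INS"`, `"INV"`, `"TRA"`, `"BND"`.
#' @param svlen SV length in bases, or `NA` (always `NA` for `TRA`).
#' @param strand1,strand2 breakend orientations (`"+"`/`"-"`) or `NA`.
#' @param filter `"PASS"` or any other caller filter string.
#' @param caller provenance label, e.g. `"callerA"`, `"callerB"`, `"merged"`.
#' @param mate_id mate record id for unresolved `BND` records, else `NA`.
#'
#' @return A validated `data.frame` with the columns above.
#' @export
#' @examples
#' sv_records("d1", "chr1", 1000, "chr1", 2000, "DEL", svlen = 1000)
sv_records <- function(id, chrom1, pos1, chrom2 = chrom1, pos2 = pos1,
                       svtype, svlen = NA_integer_,
                       strand1 = NA_character_, strand2 = NA_character_,
                       filter = "PASS", caller = "merged",
                       mate_id = NA_character_) {
  n <- length(id)
  r <- function(x) if (n == 0) x[0] else rep_len(x, n)
  df <- data.frame(
    id = r(as.character(id)),
    chrom1 = r(as.character(chrom1)), pos1 = r(as.integer(pos1)),
    chrom2 = r(as.character(chrom2)), pos2 = r(as.integer(pos2)),
    svtype = r(as.character(svtype)), svlen = r(as.integer(svlen)),
    strand1 = r(as.character(strand1)), strand2 = r(as.character(strand2)),
    filter = r(as.character(filter)), caller = r(as.character(caller)),
    mate_id = r(as.character(mate_id)),
    stringsAsFactors = FALSE
  )
  validate_sv_records(df)
}

SV_TYPES <- c("DEL", "DUP", "INS", "INV", "TRA", "BND")

#' Validate a structural-variant record table
#'
#' Checks the structural invariants of the record model: recognised SV types,
#' same-chromosome anchors for intra-chromosomal types with `pos1 <= pos2`,
#' distinct chromosomes for `TRA`, and `svlen == pos2 - pos1` for
#' `DEL`/`DUP`/`INV` where a length is present.
#'
#' @param df a candidate SV record `data.frame` (see [sv_records()]).
#' @return `df`, invisibly unchanged, if valid; otherwise an error is thrown.
#' @export
validate_sv_records <- function(df) {
  stopifnot(is.data.frame(df))
  needed <- c("id", "chrom1", "pos1", "chrom2", "pos2", "svtype", "svlen",
              "strand1", "strand2", "filter", "caller", "mate_id")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0) {
    stop("sv_records: missing columns: ", paste(miss, collapse = ", "))
  }
  bad <- setdiff(unique(df$svtype), SV_TYPES)
  if (length(bad) > 0) {
    stop("sv_records: unknown svtype(s): ", paste(bad, collapse = ", "))
  }
  intra <- df$svtype %in% c("DEL", "DUP", "INS", "INV")
  if (any(intra & df$chrom1 != df$chrom2)) {
    stop("sv_records: DEL/DUP/INS/INV must have chrom1 == chrom2")
  }
  same <- df$chrom1 == df$chrom2
  if (any(same & df$pos1 > df$pos2)) {
    stop("sv_records: pos1 must be <= pos2 when chrom1 == chrom2")
  }
  if (any(df$svtype == "TRA" & df$chrom1 == df$chrom2)) {
    stop("sv_records: TRA must have chrom1 != chrom2")
  }
  chk <- df$svtype %in% c("DEL", "DUP", "INV") & !is.na(df$svlen)
  if (any(chk & df$svlen != df$pos2 - df$pos1)) {
    stop("sv_records: svlen must equal pos2 - pos1 for DEL/DUP/INV")
  }
  invisible(df)
}

#' An empty SV record table
#' @return A zero-row `data.frame` with the SV record columns.
#' @export
empty_sv_records <- function() {
  sv_records(character(0), character(0), integer(0), character(0),
             integer(0), character(0))
}

#' Span of an SV in bases
#'
#' `pos2 - pos1` for intra-chromosomal records; `NA` for translocations, whose
#' two anchors lie on different chromosomes.
#'
#' @param df SV record table.
#' @return integer vector of spans.
#' @export
sv_span <- function(df) {
  ifelse(df$chrom1 == df$chrom2, df$pos2 - df$pos1, NA_integer_)
}

#' Pair reciprocal breakend records
#'
#' Breakends (`BND`) encode one side of a novel adjacency; a rearrangement is
#' represented by two records referencing each other through `mate_id`.  This
#' pairs every reciprocally-referenced couple exactly once and returns
#' single-sided or asymmetric records as orphans.
#'
#' @param records SV record table; non-BND rows are ignored.
#' @return A list with elements `pairs` (a `data.frame` with columns
#'   `first_id`, `second_id`) and `orphans` (the unpaired BND records).
#' @export
#' @examples
#' b <- rbind(
#'   sv_records("a", "chr1", 100, "chr1", 100, "BND", mate_id = "b"),
#'   sv_records("b", "chr1", 900, "chr1", 900, "BND", mate_id = "a")
#' )
#' pair_breakends(b)$pairs
pair_breakends <- function(records) {
  bnd <- records[records$svtype == "BND", , drop = FALSE]
  if (anyDuplicated(bnd$id)) stop("pair_breakends: duplicated BND ids")
  mate_of <- stats::setNames(bnd$mate_id, bnd$id)
  paired <- character(0)
  first_id <- character(0)
  second_id <- character(0)
  for (i in seq_len(nrow(bnd))) {
    a <- bnd$id[i]
    if (a %in% paired) next
    b <- mate_of[[a]]
    # reciprocal iff the mate exists, points back, and is not already taken
    if (!is.na(b) && b %in% names(mate_of) && !(b %in% paired) &&
        identical(mate_of[[b]], a) && b != a) {
      first_id <- c(first_id, a)
      second_id <- c(second_id, b)
      paired <- c(paired, a, b)
    }
  }
  orphans <- bnd[!(bnd$id %in% paired), , drop = FALSE]
  if (nrow(orphans) > 0) {
    warning(sprintf("pair_breakends: %d orphan breakend(s) without a reciprocal mate",
                    nrow(orphans)))
  }
  list(
    pairs = data.frame(first_id = first_id, second_id = second_id,
                       stringsAsFactors = FALSE),
    orphans = orphans
  )
}

#' Classify a reciprocal breakend pair as an inversion or translocation
#'
#' Junctions joining two loci on different chromosomes are inter-chromosomal
#' translocations (`TRA`).  Same-chromosome junctions are typed from the
#' breakend orientations: `++` or `--` (inverted junction) give `INV`;
#' `+-` is a deletion-type junction and `-+` a tandem-duplication-type
#' junction, following standard breakend orientation semantics.
#'
#' @param first,second one-row SV record tables (`svtype == "BND"`) forming a
#'   reciprocal pair.
#' @return A one-row SV record with `svtype` in `DEL`, `DUP`, `INV`, `TRA`;
#'   the new id is the first record's id with the mate reference dropped.
#' @export
classify_breakend_pair <- function(first, second) {
  stopifnot(nrow(first) == 1, nrow(second) == 1,
            first$svtype == "BND", second$svtype == "BND")
  filt <- if (first$filter == "PASS" && second$filter == "PASS") "PASS" else
    setdiff(unique(c(first$filter, second$filter)), "PASS")[1]
  if (first$chrom1 != second$chrom1) {
    return(sv_records(first$id, first$chrom1, first$pos1,
                      second$chrom1, second$pos1, "TRA",
                      strand1 = first$strand1, strand2 = second$strand1,
                      filter = filt, caller = first$caller))
  }
  p <- sort(c(first$pos1, second$pos1))
  ori <- paste0(first$strand1, second$strand1)
  type <- switch(ori,
                 "++" = "INV", "--" = "INV",
                 "+-" = "DEL", "-+" = "DUP",
                 "INV")  # unknown strands: inverted junction is the common case
  sv_records(first$id, first$chrom1, p[1], first$chrom1, p[2], type,
             svlen = p[2] - p[1],
             strand1 = first$strand1, strand2 = second$strand1,
             filter = filt, caller = first$caller)
}

#' Resolve breakend pairs within a call set
#'
#' Replaces every reciprocal BND pair by a single typed record
#' ([classify_breakend_pair()]) and keeps non-BND records untouched.  Orphan
#' breakends are returned separately, flagged but never typed.
#'
#' @param records SV record table.
#' @return list with `records` (non-BND plus resolved pairs) and `orphans`.
#' @export
resolve_breakends <- function(records) {
  simple <- records[records$svtype != "BND", , drop = FALSE]
  pb <- suppressWarnings(pair_breakends(records))
  resolved <- empty_sv_records()
  for (i in seq_len(nrow(pb$pairs))) {
    a <- records[records$id == pb$pairs$first_id[i], , drop = FALSE]
    b <- records[records$id == pb$pairs$second_id[i], , drop = FALSE]
    resolved <- rbind(resolved, classify_breakend_pair(a, b))
  }
  list(records = rbind(simple, resolved), orphans = pb$orphans)
}
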