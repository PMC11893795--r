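# Interval helpers: 1-based inclusive coordinates throughout this file.
ivl_overlap <- function(a1, a2, b1, b2) a1 <= b2 & b1 <= a2
pt_in <- function(p, b1, b2) b1 <= p & p <= b2

#' Select the canonical transcript of each gene
#'
#' Among a gene's transcripts the flagged canonical one is used; when no flag
#' is present the fallback is the longest CDS, then the longest transcript,
#' then the lexicographically smallest transcript id.
#'
#' @param transcripts gene model `data.frame` (possibly several rows per
#'   `gene_id`, see [read_gene_models()]).
#' @return gene model `data.frame` with exactly one row per gene.
#' @export
pick_canonical <- function(transcripts) {
  if (nrow(transcripts) == 0) stop("pick_canonical: no transcripts given")
  pick_one <- function(tx) {
    flagged <- tx[!is.na(tx$canonical) & tx$canonical == 1, , drop = FALSE]
    if (nrow(flagged) >= 1) return(flagged[1, , drop = FALSE])
    cds_len <- ifelse(is.na(tx$cds_start), 0L, tx$cds_end - tx$cds_start + 1L)
    tx_len <- tx$tx_end - tx$tx_start + 1L
    ord <- order(-cds_len, -tx_len, tx$transcript_id)
    tx[ord[1], , drop = FALSE]
  }
  out <- do.call(rbind, lapply(split(transcripts, transcripts$gene_id), pick_one))
  rownames(out) <- NULL
  out[order(out$chrom, out$tx_start), , drop = FALSE]
}

#' Promoter regions of gene models
#'
#' The promoter is a window of `window` bases immediately upstream of the
#' transcription start site on the transcribed strand: for a `+`-strand gene
#' with TSS `t` it is `[t - window, t - 1]`; for a `-`-strand gene (TSS at
#' `tx_end`) it is `[t + 1, t + window]`.
#'
#' @param genes canonical gene model `data.frame`.
#' @param window promoter width in bases (default 1000); `0` gives an empty
#'   set.
#' @return region `data.frame` (`chrom`, `start`, `end`, `linked_gene`).
#' @export
promoter_regions <- function(genes, window = 1000) {
  if (window <= 0 || nrow(genes) == 0) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), linked_gene = character(0))
    attr(out, "name") <- "promoters"
    return(out)
  }
  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$tx_start, genes$tx_end)
  out <- data.frame(
    chrom = genes$chrom,
    start = as.integer(ifelse(plus, tss - window, tss + 1)),
    end = as.integer(ifelse(plus, tss - 1, tss + window)),
    linked_gene = genes$gene_id,
    stringsAsFactors = FALSE
  )
  attr(out, "name") <- "promoters"
  out
}

# category of one (sv, gene) pair; NULL when the gene body is untouched
impact_category <- function(sv, g, tra_intronic_is_plof = TRUE) {
  ex <- exon_intervals(g)
  has_cds <- !is.na(g$cds_start) && !is.na(g$cds_end)
  if (sv$svtype == "TRA") {
    hits <- c(sv$chrom1 == g$chrom && pt_in(sv$pos1, g$tx_start, g$tx_end),
              sv$chrom2 == g$chrom && pt_in(sv$pos2, g$tx_start, g$tx_end))
    if (!any(hits)) return(NULL)
    pos <- c(sv$pos1, sv$pos2)[hits]
    in_exon <- any(vapply(pos, function(p) any(pt_in(p, ex$start, ex$end)), TRUE))
    if (in_exon || tra_intronic_is_plof) return("pLoF")
    return("intronic")
  }
  if (sv$chrom1 != g$chrom || !ivl_overlap(sv$pos1, sv$pos2, g$tx_start, g$tx_end)) {
    return(NULL)
  }
  s <- sv$pos1; e <- sv$pos2
  bp1_in <- pt_in(s, g$tx_start, g$tx_end)
  bp2_in <- pt_in(e, g$tx_start, g$tx_end)
  contains_gene <- s <= g$tx_start && e >= g$tx_end
  exon_ov <- any(ivl_overlap(s, e, ex$start, ex$end))
  if (sv$svtype == "DEL") {
    if (exon_ov) {
      if (has_cds && !ivl_overlap(s, e, g$cds_start, g$cds_end)) return("UTR")
      return("pLoF")
    }
    return("intronic")
  }
  if (sv$svtype == "DUP") {
    if (contains_gene) return("CG")
    if (bp1_in && bp2_in) {
      if (any(s <= ex$start & ex$end <= e)) return("IED")
      bp_exonic <- any(pt_in(s, ex$start, ex$end)) && any(pt_in(e, ex$start, ex$end))
      if (bp_exonic) return("pLoF")
      return("partial_exon_DUP")
    }
    return("partial_gene_DUP")
  }
  if (sv$svtype == "INV") {
    if (contains_gene && !bp1_in && !bp2_in) return("whole_gene_INV")
    # a breakpoint falls inside the gene: disruptive if the inverted part of
    # the gene carries an exon, otherwise a purely intronic rearrangement
    part_s <- max(s, g$tx_start); part_e <- min(e, g$tx_end)
    if (any(ivl_overlap(part_s, part_e, ex$start, ex$end))) return("pLoF")
    return("intronic")
  }
  if (sv$svtype == "INS") {
    # insertions are tracked through genotyping but assigned no coding
    # impact category; gene containment is reported as intronic
    return("intronic")
  }
  stop("impact_category: unknown svtype ", sv$svtype)
}

# does the SV (interval or anchor pair) overlap a region row?
sv_region_overlap <- function(sv, regions) {
  if (nrow(regions) == 0) return(logical(0))
  if (sv$svtype == "TRA") {
    (regions$chrom == sv$chrom1 & pt_in(sv$pos1, regions$start, regions$end)) |
      (regions$chrom == sv$chrom2 & pt_in(sv$pos2, regions$start, regions$end))
  } else {
    regions$chrom == sv$chrom1 &
      ivl_overlap(sv$pos1, sv$pos2, regions$start, regions$end)
  }
}

# breakpoints of the SV as (chrom, pos) anchor points
sv_anchors <- function(sv) {
  data.frame(chrom = c(sv$chrom1, sv$chrom2), pos = c(sv$pos1, sv$pos2),
             stringsAsFactors = FALSE)
}

#' Annotate one SV with per-gene impact categories
#'
#' Assigns each overlapped gene exactly one impact category by comparing the
#' SV breakpoints with the canonical transcript structure:
#'
#' * `DEL` removing >= 1 exon is `pLoF`; touching only introns, `intronic`;
#'   removing exon sequence outside the CDS only, `UTR`.
#' * `DUP` fully containing the gene is `CG` (copy gain); with both
#'   breakpoints inside the gene it is `IED` when >= 1 exon is fully
#'   duplicated, `pLoF` when both breakpoints land in exons, otherwise
#'   `partial_exon_DUP`; with one breakpoint inside, `partial_gene_DUP`.
#' * `INV` fully containing the gene with both breakpoints outside is
#'   `whole_gene_INV`; a breakpoint inside the gene is `pLoF` when the
#'   inverted portion carries an exon, else `intronic`.
#' * `TRA` with a breakpoint inside the gene body severs the transcript and
#'   is `pLoF` (intronic breakpoints included by default, see
#'   `tra_intronic_is_plof`).
#'
#' SVs spanning more than `max_span` bases only annotate genes that contain a
#' breakpoint, since short-read evidence localises at breakpoints.  An SV
#' overlapping no gene body is checked against promoters (any overlap) and
#' otherwise reported `intergenic`.  `enhancer_hit` is `TRUE` when >= 1
#' breakpoint lies inside an enhancer linked to the annotated gene.  A `TRA`
#' whose two breakpoints fall in two different genes additionally carries a
#' fusion label `GENE1-GENE2` in breakpoint order.
#'
#' @param sv one-row SV record table (typed; no raw `BND`).
#' @param genes canonical gene models ([pick_canonical()]).
#' @param promoters,enhancers region `data.frame`s with `linked_gene`
#'   (`NULL` to skip).
#' @param max_span span above which only breakpoint genes are annotated
#'   (default 1e6 bases).
#' @param tra_intronic_is_plof treat intronic translocation breakpoints as
#'   gene-disrupting (default `TRUE`).
#' @return `data.frame` with columns `sv_id`, `gene_id`, `category`,
#'   `enhancer_hit`, `breakpoint_gene`, `fusion`.
#' @export
annotate_sv <- function(sv, genes, promoters = NULL, enhancers = NULL,
                        max_span = 1e6, tra_intronic_is_plof = TRUE) {
  stopifnot(nrow(sv) == 1)
  if (!(sv$svtype %in% c("DEL", "DUP", "INS", "INV", "TRA"))) {
    stop("annotate_sv: cannot annotate svtype ", sv$svtype)
  }
  anch <- sv_anchors(sv)
  bp_gene <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    any(anch$chrom == g$chrom & pt_in(anch$pos, g$tx_start, g$tx_end))
  }, TRUE)
  span <- sv_span(sv)
  large <- !is.na(span) && span > max_span
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    if (large && !bp_gene[i]) next
    cat_i <- impact_category(sv, genes[i, ], tra_intronic_is_plof)
    if (is.null(cat_i)) next
    rows[[length(rows) + 1]] <- data.frame(
      sv_id = sv$id, gene_id = genes$gene_id[i], category = cat_i,
      breakpoint_gene = bp_gene[i], stringsAsFactors = FALSE)
  }
  ann <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(sv_id = character(0), gene_id = character(0),
               category = character(0), breakpoint_gene = logical(0))
  # promoter annotation for genes untouched in the body
  if (!is.null(promoters) && nrow(promoters) > 0) {
    hit <- sv_region_overlap(sv, promoters)
    for (gid in setdiff(unique(promoters$linked_gene[hit]), ann$gene_id)) {
      ann <- rbind(ann, data.frame(sv_id = sv$id, gene_id = gid,
                                   category = "promoter",
                                   breakpoint_gene = FALSE))
    }
  }
  if (nrow(ann) == 0) {
    ann <- data.frame(sv_id = sv$id, gene_id = NA_character_,
                      category = "intergenic", breakpoint_gene = FALSE,
                      stringsAsFactors = FALSE)
  }
  # enhancer flag: a breakpoint inside an enhancer linked to the gene
  ann$enhancer_hit <- FALSE
  if (!is.null(enhancers) && nrow(enhancers) > 0) {
    bp_hit <- vapply(seq_len(nrow(enhancers)), function(j) {
      any(anch$chrom == enhancers$chrom[j] &
            pt_in(anch$pos, enhancers$start[j], enhancers$end[j]))
    }, TRUE)
    hit_genes <- unique(enhancers$linked_gene[bp_hit])
    ann$enhancer_hit <- !is.na(ann$gene_id) & ann$gene_id %in% hit_genes
  }
  # fusion label for translocations joining two distinct genes
  ann$fusion <- NA_character_
  if (sv$svtype == "TRA") {
    g1 <- genes$gene_id[vapply(seq_len(nrow(genes)), function(i) {
      genes$chrom[i] == sv$chrom1 &&
        pt_in(sv$pos1, genes$tx_start[i], genes$tx_end[i])
    }, TRUE)]
    g2 <- genes$gene_id[vapply(seq_len(nrow(genes)), function(i) {
      genes$chrom[i] == sv$chrom2 &&
        pt_in(sv$pos2, genes$tx_start[i], genes$tx_end[i])
    }, TRUE)]
    if (length(g1) >= 1 && length(g2) >= 1 && !identical(g1[1], g2[1])) {
      n1 <- genes$gene_name[match(g1[1], genes$gene_id)]
      n2 <- genes$gene_name[match(g2[1], genes$gene_id)]
      ann$fusion[ann$gene_id %in% c(g1[1], g2[1])] <- paste0(n1, "-", n2)
    }
  }
  rownames(ann) <- NULL
  ann[, c("sv_id", "gene_id", "category", "enhancer_hit",
          "breakpoint_gene", "fusion")]
}

#' Annotate a table of SVs against gene models
#'
#' Vectorised wrapper around [annotate_sv()].
#'
#' @inheritParams annotate_sv
#' @param svs SV record table.
#' @return row-bound annotation `data.frame`.
#' @export
annotate_svs <- function(svs, genes, promoters = NULL, enhancers = NULL,
                         max_span = 1e6, tra_intronic_is_plof = TRUE) {
  out <- lapply(seq_len(nrow(svs)), function(i) {
    annotate_sv(svs[i, ], genes, promoters, enhancers,
                max_span, tra_intronic_is_plof)
  })
  do.call(rbind, out)
}

#' Gene-disruptive impact categories
#'
#' Only `pLoF`, `CG` and `IED` SVs can directly inactivate a gene or
#' increase its dosage; the remaining categories are annotated for reporting
#' but excluded from pathogenicity classification.
#'
#' @return character vector of the three disruptive categories.
#' @export
disruptive_categories <- function() c("pLoF", "CG", "IED")
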