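mean_depth_in <- function(track, chrom, start, end) {
  sel <- track$chrom == chrom & track$pos >= start & track$pos <= end
  if (!any(sel)) return(NA_real_)
  mean(track$depth[sel])
}

#' Variant allele fraction of a deletion or duplication from read depth
#'
#' A heterozygous deletion halves coverage inside the SV; a heterozygous
#' duplication raises it by half.  The altered read count is the mean-depth
#' difference between the SV region and its flanking regions (`flank` bases
#' either side).  For a `DEL` the denominator is the flank depth
#' (`vaf = (flank - region) / flank`); for a `DUP` it is the region depth
#' (`vaf = (region - flank) / region`).  Estimates are clamped to `[0, 1]`.
#' Depth means are arithmetic means over per-base depth, zero-depth bases
#' included.
#'
#' @param sv one-row SV record (`DEL` or `DUP`).
#' @param track depth track `data.frame` (`chrom`, `pos`, `depth`) covering
#'   the SV region and both flanks.
#' @param flank flank width in bases (default 10000).
#' @return one-row `data.frame`: `sv_id`, `vaf`, `altered`, `total`,
#'   `method`.
#' @export
vaf_depth <- function(sv, track, flank = 10000) {
  stopifnot(nrow(sv) == 1, sv$svtype %in% c("DEL", "DUP"))
  region <- mean_depth_in(track, sv$chrom1, sv$pos1, sv$pos2)
  left <- track$chrom == sv$chrom1 & track$pos >= sv$pos1 - flank &
    track$pos < sv$pos1
  right <- track$chrom == sv$chrom1 & track$pos > sv$pos2 &
    track$pos <= sv$pos2 + flank
  if (!any(left | right) || is.na(region)) {
    stop("vaf_depth: depth track does not cover the SV region and flanks")
  }
  flank_depth <- mean(track$depth[left | right])
  if (sv$svtype == "DEL") {
    if (flank_depth == 0) stop("vaf_depth: zero flank depth, VAF undefined")
    vaf <- (flank_depth - region) / flank_depth
    altered <- flank_depth - region
    total <- flank_depth
    method <- "depth_del"
  } else {
    if (region == 0) stop("vaf_depth: zero region depth, VAF undefined")
    vaf <- (region - flank_depth) / region
    altered <- region - flank_depth
    total <- region
    method <- "depth_dup"
  }
  data.frame(sv_id = sv$id, vaf = min(max(vaf, 0), 1),
             altered = altered, total = total, method = method,
             stringsAsFactors = FALSE)
}

#' Variant allele fraction of an inversion or translocation from breakpoint
#' evidence
#'
#' Altered reads are the deduplicated discordant read pairs plus split reads
#' at the junction (a read showing both signatures counts once).  The total
#' is the mean read depth over windows of `window` bases either side of each
#' breakpoint, pooled across both breakpoints.  The estimate can be
#' conservative: properly-pairing non-reference reads inside the windows
#' inflate the denominator.
#'
#' @param sv one-row SV record (`INV` or `TRA`).
#' @param evidence one-row `data.frame` with `discordant_pairs`,
#'   `split_reads` (deduplicated counts).
#' @param track depth track covering both breakpoint windows.
#' @param window half-window in bases around each breakpoint (default 150).
#' @return one-row `data.frame` as in [vaf_depth()], `method =
#'   "breakpoint_reads"`.
#' @export
vaf_breakpoint <- function(sv, evidence, track, window = 150) {
  stopifnot(nrow(sv) == 1, sv$svtype %in% c("INV", "TRA"))
  if (evidence$discordant_pairs < 0 || evidence$split_reads < 0) {
    stop("vaf_breakpoint: negative evidence counts")
  }
  sel <- (track$chrom == sv$chrom1 & abs(track$pos - sv$pos1) <= window) |
    (track$chrom == sv$chrom2 & abs(track$pos - sv$pos2) <= window)
  if (!any(sel)) stop("vaf_breakpoint: depth track does not cover breakpoints")
  total <- mean(track$depth[sel])
  if (total == 0) stop("vaf_breakpoint: zero depth at breakpoints, VAF undefined")
  altered <- evidence$discordant_pairs + evidence$split_reads
  data.frame(sv_id = sv$id, vaf = min(max(altered / total, 0), 1),
             altered = altered, total = total, method = "breakpoint_reads",
             stringsAsFactors = FALSE)
}

#' Classify tumour loss of heterozygosity over a gene
#'
#' Uses purity/ploidy-adjusted allele-specific copy-number segments.  The
#' segment covering the largest fraction of the gene decides (ties go to the
#' more altered status).  A minor copy number above zero is `LOH_neg`;
#' with the minor allele lost, the major copy number separates hemizygous
#' loss (`LOH_CNL`, major 1), copy-neutral LOH (`LOH_CNN`, major 2) and
#' amplification LOH (`LOH_CNG`, major >= 3).
#'
#' @param gene_region list or one-row `data.frame` with `chrom`, `start`,
#'   `end` of the gene.
#' @param segments copy-number segment `data.frame`
#'   ([read_cn_segments()]).
#' @return character scalar status; `"undetermined"` (with a warning) when
#'   no segment covers the gene.
#' @export
classify_loh <- function(gene_region, segments) {
  cover <- segments$chrom == gene_region$chrom &
    ivl_overlap(segments$start, segments$end, gene_region$start, gene_region$end)
  if (!any(cover)) {
    warning("classify_loh: gene not covered by any segment")
    return("undetermined")
  }
  seg <- segments[cover, , drop = FALSE]
  seg$covered <- pmin(seg$end, gene_region$end) -
    pmax(seg$start, gene_region$start) + 1
  status_of <- function(major, minor) {
    if (minor > 0) return("LOH_neg")
    if (major <= 1) return("LOH_CNL")
    if (major == 2) return("LOH_CNN")
    "LOH_CNG"
  }
  seg$status <- mapply(status_of, seg$major_cn, seg$minor_cn)
  # majority segment; ties resolved toward the more altered status
  severity <- c(LOH_neg = 0, LOH_CNL = 3, LOH_CNN = 2, LOH_CNG = 1)
  ord <- order(-seg$covered, -severity[seg$status])
  seg$status[ord[1]]
}

#' Somatic second-hit labels for germline-variant genes
#'
#' A gene carrying a germline PP-SV receives the somatic copy-number event
#' labels recorded for it in the same patient's tumour (`CNL`, `CNG`);
#' multiple events are reported in input order, comma-joined; genes without
#' an event get `"none"`.
#'
#' @param genes character vector of PP-SV gene ids.
#' @param somatic_events `data.frame` with columns `gene_id`, `event`
#'   (`"CNL"`/`"CNG"`).
#' @return named character vector, one element per gene.
#' @export
second_hit <- function(genes, somatic_events) {
  vapply(genes, function(g) {
    ev <- somatic_events$event[somatic_events$gene_id == g]
    if (length(ev) == 0) "none" else paste(ev, collapse = ",")
  }, "")
}
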