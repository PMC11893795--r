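#' Read gene models from a tab-separated table
#'
#' Gene models are one row per transcript with columns `gene_id`, `gene_name`,
#' `transcript_id`, `canonical` (0/1 flag), `chrom`, `strand`, `tx_start`,
#' `tx_end`, `cds_start`, `cds_end` (may be `NA`), and exon coordinates as
#' comma-separated `exon_starts`/`exon_ends` (1-based inclusive, sorted,
#' non-overlapping), in the style of UCSC flat gene tables.
#'
#' @param path TSV file with a header line.
#' @return gene model `data.frame`.
#' @export
read_gene_models <- function(path) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_gene_models(g)
}

#' Validate a gene model table
#'
#' @param g candidate gene model `data.frame`.
#' @return `g` invisibly if valid.
#' @export
validate_gene_models <- function(g) {
  needed <- c("gene_id", "gene_name", "transcript_id", "canonical", "chrom",
              "strand", "tx_start", "tx_end", "cds_start", "cds_end",
              "exon_starts", "exon_ends")
  miss <- setdiff(needed, names(g))
  if (length(miss) > 0) stop("gene models: missing columns: ",
                             paste(miss, collapse = ", "))
  for (i in seq_len(nrow(g))) {
    ex <- exon_intervals(g[i, ])
    if (nrow(ex) == 0) stop("gene models: transcript without exons: ",
                            g$transcript_id[i])
    if (any(ex$start > ex$end)) stop("gene models: malformed exon in ",
                                     g$transcript_id[i])
    if (is.unsorted(ex$start) ||
        any(ex$start[-1] <= ex$end[-nrow(ex)])) {
      stop("gene models: exons must be sorted and non-overlapping in ",
           g$transcript_id[i])
    }
    if (ex$start[1] < g$tx_start[i] || ex$end[nrow(ex)] > g$tx_end[i]) {
      stop("gene models: exons outside transcript bounds in ",
           g$transcript_id[i])
    }
  }
  invisible(g)
}

#' Exon intervals of one gene-model row
#' @param row one-row gene model `data.frame`.
#' @return `data.frame` with `start`, `end` (1-based inclusive).
#' @export
exon_intervals <- function(row) {
  data.frame(
    start = as.integer(strsplit(as.character(row$exon_starts), ",")[[1]]),
    end = as.integer(strsplit(as.character(row$exon_ends), ",")[[1]])
  )
}

#' Write gene models to TSV
#' @param g gene model `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(g, path) {
  utils::write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a region set from a BED-like file
#'
#' BED intervals are 0-based half-open; they are converted to the package's
#' external 1-based inclusive convention on read.  A fourth column carries the
#' linked gene (required for promoter and enhancer sets).
#'
#' @param path BED file (chrom, start, end, linked_gene; no header).
#' @param name label for the set, e.g. `"enhancers"`.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `linked_gene`
#'   and attribute `name`.
#' @export
read_region_bed <- function(path, name = "regions") {
  b <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(chrom = b[[1]], start = as.integer(b[[2]]) + 1L,
                    end = as.integer(b[[3]]),
                    linked_gene = if (ncol(b) >= 4) as.character(b[[4]]) else NA_character_,
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("read_region_bed: start > end interval")
  attr(out, "name") <- name
  out
}

#' Write a region set as BED
#' @param regions region `data.frame` (1-based inclusive).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(regions, path) {
  utils::write.table(
    data.frame(regions$chrom, regions$start - 1L, regions$end,
               regions$linked_gene),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a known-SV table
#'
#' A tab-separated emulation of a public SV archive: one row per
#' (entry, study) with columns `entry_id`, `chrom1`, `pos1`, `chrom2`, `pos2`,
#' `svtype`, `significance` (pathogenic / likely_pathogenic / uncertain /
#' benign / none), `af_study`, `af_population`, `af`.
#'
#' @param path TSV file with header.
#' @return the table as a `data.frame`.
#' @export
read_known_sv_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read per-SV score panels from four impact-prediction tools
#'
#' @param path TSV with columns `sv_id`, `strvctvre`, `cadd_sv`, `postre`,
#'   `phenosv`; empty cells mean the tool cannot score that SV.
#' @return `data.frame` with numeric score columns (`NA` = absent).
#' @export
read_score_panels <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  for (col in c("strvctvre", "cadd_sv", "postre", "phenosv")) {
    p[[col]] <- as.numeric(p[[col]])
  }
  p
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file: one set per line, `name<TAB>description<TAB>gene...`.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1], "")
  sets
}

#' Write gene sets to GMT
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, ""), path)
  invisible(path)
}

#' Read a curated gene-role table
#'
#' @param path TSV with columns `gene_id`, `role` (one of TSG, oncogene,
#'   conflicting, unclear, none) and optional `evidence`.
#' @return `data.frame`.
#' @export
read_gene_roles <- function(path) {
  r <- utils::read.delim(path, stringsAsFactors = FALSE)
  bad <- setdiff(unique(r$role), c("TSG", "oncogene", "conflicting",
                                   "unclear", "none"))
  if (length(bad) > 0) stop("read_gene_roles: unknown role(s): ",
                            paste(bad, collapse = ", "))
  if (anyDuplicated(r$gene_id)) stop("read_gene_roles: duplicated gene_id")
  r
}

#' Read a per-base depth track
#'
#' Three-column TSV as produced by a depth utility: chromosome, 1-based
#' position, read depth.
#'
#' @param path TSV file without header.
#' @return `data.frame` with columns `chrom`, `pos`, `depth`.
#' @export
read_depth_track <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(d[, 1:3], c("chrom", "pos", "depth"))
}

#' Read allele-specific copy-number segments
#'
#' @param path TSV with header: `chrom`, `start`, `end`, `major_cn`,
#'   `minor_cn` (purity/ploidy-adjusted integer copy numbers).
#' @return `data.frame`; errors if any `minor_cn > major_cn`.
#' @export
read_cn_segments <- function(path) {
  s <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (any(s$minor_cn > s$major_cn)) {
    stop("read_cn_segments: minor_cn must not exceed major_cn")
  }
  s
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
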