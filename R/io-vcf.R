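#' Read a structural-variant VCF into an SV record table
#'
#' Parses a VCF 4.2 file whose records carry `SVTYPE` (and, for non-BND
#' records, `END`/`SVLEN`) in INFO.  BND records are returned unpaired with
#' `mate_id` taken from `MATEID`; use [resolve_breakends()] to type them.
#' Records without a parseable `SVTYPE` are skipped and reported (with their
#' line number in the file) in the `"errors"` attribute of the result.
#'
#' @param path path to a plain-text VCF file.
#' @param caller_label provenance label stored in the `caller` column.
#' @return SV record table (see [sv_records()]) with attribute `errors`, a
#'   character vector of record-level problems (empty when the file is clean).
#' @export
read_sv_vcf <- function(path, caller_label = "callerA") {
  if (!file.exists(path)) stop("read_sv_vcf: cannot read ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  n <- nrow(fix)
  errors <- character(0)
  if (n == 0) {
    out <- empty_sv_records()
    attr(out, "errors") <- errors
    return(out)
  }
  # line numbers of data records in the original file, for error reports
  n_header <- length(v@meta) + 1L
  info1 <- function(key) unname(vcfR::extract.info(v, key))
  svtype <- info1("SVTYPE")
  end <- suppressWarnings(as.integer(info1("END")))
  svlen <- suppressWarnings(as.integer(info1("SVLEN")))
  mateid <- info1("MATEID")
  strands <- info1("STRANDS")
  chr2 <- info1("CHR2")
  pos2i <- suppressWarnings(as.integer(info1("POS2")))

  keep <- !is.na(svtype) & svtype %in% SV_TYPES
  for (i in which(!keep)) {
    errors <- c(errors, sprintf("line %d: missing or unknown SVTYPE", n_header + i))
  }
  idx <- which(keep)
  chrom1 <- fix[idx, "CHROM"]
  pos1 <- as.integer(fix[idx, "POS"])
  st <- svtype[idx]
  chrom2 <- chrom1
  pos2 <- pos1
  # non-BND intra-chromosomal records end at INFO/END; TRA and BND carry a
  # second anchor (CHR2/POS2 for TRA, the mate record for BND)
  simple <- st %in% c("DEL", "DUP", "INS", "INV")
  pos2[simple] <- ifelse(is.na(end[idx][simple]), pos1[simple], end[idx][simple])
  tra <- st == "TRA"
  chrom2[tra] <- chr2[idx][tra]
  pos2[tra] <- pos2i[idx][tra]
  s1 <- rep(NA_character_, length(idx))
  s2 <- rep(NA_character_, length(idx))
  has_str <- !is.na(strands[idx]) & nchar(strands[idx]) >= 2
  s1[has_str] <- substr(strands[idx][has_str], 1, 1)
  s2[has_str] <- substr(strands[idx][has_str], 2, 2)
  len <- abs(svlen[idx])
  len[tra | st == "BND"] <- NA_integer_
  # fall back to coordinates where SVLEN is absent for DEL/DUP/INV
  fb <- st %in% c("DEL", "DUP", "INV") & is.na(len)
  len[fb] <- pos2[fb] - pos1[fb]
  out <- sv_records(
    id = fix[idx, "ID"], chrom1 = chrom1, pos1 = pos1,
    chrom2 = chrom2, pos2 = pos2, svtype = st, svlen = len,
    strand1 = s1, strand2 = s2,
    filter = ifelse(is.na(fix[idx, "FILTER"]), "other", fix[idx, "FILTER"]),
    caller = caller_label, mate_id = mateid[idx]
  )
  attr(out, "errors") <- errors
  if (length(errors) > 0) {
    warning("read_sv_vcf: skipped ", length(errors), " malformed record(s)")
  }
  out
}

vcf_info_string <- function(df) {
  info <- paste0("SVTYPE=", df$svtype)
  simple <- df$svtype %in% c("DEL", "DUP", "INS", "INV")
  info[simple] <- paste0(info[simple], ";END=", df$pos2[simple])
  has_len <- !is.na(df$svlen)
  sgn <- ifelse(df$svtype == "DEL", -1L, 1L)
  info[has_len] <- paste0(info[has_len], ";SVLEN=", sgn[has_len] * df$svlen[has_len])
  tra <- df$svtype == "TRA"
  info[tra] <- paste0(info[tra], ";CHR2=", df$chrom2[tra], ";POS2=", df$pos2[tra])
  bnd <- df$svtype == "BND" & !is.na(df$mate_id)
  info[bnd] <- paste0(info[bnd], ";MATEID=", df$mate_id[bnd])
  has_str <- !is.na(df$strand1) & !is.na(df$strand2)
  info[has_str] <- paste0(info[has_str], ";STRANDS=", df$strand1[has_str],
                          df$strand2[has_str])
  info
}

vcf_header_lines <- function(samples = character(0), extra = character(0)) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate breakend id\">",
    "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"Second anchor chromosome\">",
    "##INFO=<ID=POS2,Number=1,Type=Integer,Description=\"Second anchor position\">",
    "##INFO=<ID=STRANDS,Number=1,Type=String,Description=\"Breakpoint orientations\">",
    extra,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples) > 0) c("FORMAT", samples)), collapse = "\t"))
}

#' Write an SV record table as a plain-text VCF
#'
#' Inverse of [read_sv_vcf()]: coordinates, types and lengths round-trip
#' field-for-field.
#'
#' @param records SV record table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(records, path) {
  body <- paste(records$chrom1, records$pos1, records$id, "N",
                paste0("<", records$svtype, ">"), ".", records$filter,
                vcf_info_string(records), sep = "\t")
  writeLines(c(vcf_header_lines(), body), path)
  invisible(path)
}

#' Read a cohort-genotyped multi-sample SV VCF
#'
#' Builds an [sv_cohort()] from a multi-sample VCF with per-sample
#' `GT`, `FT` and `GQ` FORMAT fields and an optional per-site
#' `PASS_RATIO` INFO key (the fraction of passing genotype calls; recomputed
#' from FT/GQ when absent).
#'
#' @param path VCF file path.
#' @param ancestry named character vector or two-column `data.frame`
#'   (`sample_id`, `ancestry`) assigning each sample an ancestry label.
#' @return an `sv_cohort` object.
#' @export
read_cohort_vcf <- function(path, ancestry) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  recs <- read_sv_vcf(path, caller_label = "merged")
  gt_chr <- vcfR::extract.gt(v, "GT")
  ft <- vcfR::extract.gt(v, "FT")
  gq <- vcfR::extract.gt(v, "GQ", as.numeric = TRUE)
  gt <- matrix(NA_integer_, nrow(gt_chr), ncol(gt_chr),
               dimnames = dimnames(gt_chr))
  gt[gt_chr %in% c("0/0", "0|0")] <- 0L
  gt[gt_chr %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  gt[gt_chr %in% c("1/1", "1|1")] <- 2L
  if (is.data.frame(ancestry)) {
    ancestry <- stats::setNames(ancestry[[2]], ancestry[[1]])
  }
  samples <- colnames(gt_chr)
  pr <- suppressWarnings(as.numeric(vcfR::extract.info(v, "PASS_RATIO")))
  sv_cohort(recs, gt, ft, gq,
            data.frame(sample_id = samples,
                       ancestry = unname(ancestry[samples]),
                       stringsAsFactors = FALSE),
            pass_ratio = pr)
}

#' Write an `sv_cohort` as a multi-sample VCF
#'
#' @param cohort an [sv_cohort()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path) {
  df <- cohort$sites
  gt_str <- matrix("./.", nrow(cohort$gt), ncol(cohort$gt))
  gt_str[cohort$gt == 0L] <- "0/0"
  gt_str[cohort$gt == 1L] <- "0/1"
  gt_str[cohort$gt == 2L] <- "1/1"
  ft <- ifelse(is.na(cohort$ft), ".", cohort$ft)
  gq <- ifelse(is.na(cohort$gq), ".", as.character(cohort$gq))
  cells <- matrix(paste(gt_str, ft, gq, sep = ":"),
                  nrow(cohort$gt), ncol(cohort$gt))
  info <- paste0(vcf_info_string(df), ";PASS_RATIO=",
                 formatC(cohort$pass_ratio, digits = 6, format = "g"))
  body <- paste(df$chrom1, df$pos1, df$id, "N", paste0("<", df$svtype, ">"),
                ".", df$filter, info, "GT:FT:GQ",
                apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  hdr <- vcf_header_lines(
    samples = cohort$samples$sample_id,
    extra = c(
      "##INFO=<ID=PASS_RATIO,Number=1,Type=Float,Description=\"Fraction of passing genotype calls\">",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=FT,Number=1,Type=String,Description=\"Genotype filter\">",
      "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">"))
  writeLines(c(hdr, body), path)
  invisible(path)
}
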