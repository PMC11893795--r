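# Shared fixtures and independent brute-force oracles.

# one-gene model on demand: 6 exons of 300 bases spaced 3.5 kb
fixture_gene <- function(gene_id = "G1", chrom = "chr1", tx_start = 10000L,
                         strand = "+", canonical = 1L, cds = TRUE,
                         transcript_id = paste0(gene_id, ".t1")) {
  data.frame(
    gene_id = gene_id, gene_name = gene_id, transcript_id = transcript_id,
    canonical = canonical, chrom = chrom, strand = strand,
    tx_start = tx_start, tx_end = tx_start + 19999L,
    cds_start = if (cds) tx_start + 100L else NA_integer_,
    cds_end = if (cds) tx_start + 17699L else NA_integer_,
    exon_starts = paste(tx_start + (0:5) * 3500L, collapse = ","),
    exon_ends = paste(tx_start + (0:5) * 3500L + 299L, collapse = ","),
    stringsAsFactors = FALSE
  )
}

# small genotyped cohort built from explicit dosage vectors
fixture_cohort <- function(sites, gt_rows, ft_rows = NULL, gq_rows = NULL,
                           n_afr = 4, n_eur = 3) {
  n <- n_afr + n_eur
  gt <- do.call(rbind, gt_rows)
  dimnames(gt) <- list(sites$id, sprintf("S%02d", seq_len(n)))
  ft <- if (is.null(ft_rows)) matrix("PASS", nrow(gt), n, dimnames = dimnames(gt))
  else {
    m <- do.call(rbind, ft_rows); dimnames(m) <- dimnames(gt); m
  }
  gq <- if (is.null(gq_rows)) matrix(60L, nrow(gt), n, dimnames = dimnames(gt))
  else {
    m <- do.call(rbind, gq_rows); dimnames(m) <- dimnames(gt); m
  }
  sv_cohort(sites, gt, ft, gq,
            data.frame(sample_id = colnames(gt),
                       ancestry = c(rep("AFR", n_afr), rep("EUR", n_eur)),
                       stringsAsFactors = FALSE))
}

# random SV call set on a toy genome (typed records, no BND)
random_call_set <- function(n, prefix = "r", chroms = c("chr1", "chr2"),
                            max_pos = 1e6, types = c("DEL", "DUP", "INV")) {
  chrom <- sample(chroms, n, replace = TRUE)
  pos1 <- as.integer(sample.int(max_pos, n))
  len <- as.integer(sample.int(5000, n))
  sv_records(paste0(prefix, seq_len(n)), chrom, pos1, chrom, pos1 + len,
             sample(types, n, replace = TRUE), svlen = len,
             filter = sample(c("PASS", "LowQual"), n, replace = TRUE,
                             prob = c(0.8, 0.2)))
}

# --- independent oracle: greedy one-to-one matching via a distance matrix --
oracle_match_ids <- function(setA, setB, tolerance = 200,
                             require_both_pass = FALSE) {
  nA <- nrow(setA); nB <- nrow(setB)
  d <- matrix(Inf, nA, nB)
  for (i in seq_len(nA)) for (j in seq_len(nB)) {
    a <- setA[i, ]; b <- setB[j, ]
    if (a$svtype != b$svtype) next
    pass_ok <- if (require_both_pass) {
      a$filter == "PASS" && b$filter == "PASS"
    } else a$filter == "PASS" || b$filter == "PASS"
    if (!pass_ok) next
    if (a$chrom1 == b$chrom1 && a$chrom2 == b$chrom2 &&
        abs(a$pos1 - b$pos1) <= tolerance && abs(a$pos2 - b$pos2) <= tolerance) {
      d[i, j] <- abs(a$pos1 - b$pos1) + abs(a$pos2 - b$pos2)
    }
    if (a$svtype == "TRA" && a$chrom1 == b$chrom2 && a$chrom2 == b$chrom1 &&
        abs(a$pos1 - b$pos2) <= tolerance && abs(a$pos2 - b$pos1) <= tolerance) {
      d[i, j] <- min(d[i, j], abs(a$pos1 - b$pos2) + abs(a$pos2 - b$pos1))
    }
  }
  pairs <- character(0)
  repeat {
    if (all(!is.finite(d))) break
    best <- Inf; bi <- 0; bj <- 0
    for (i in seq_len(nA)) for (j in seq_len(nB)) {
      if (!is.finite(d[i, j])) next
      better <- d[i, j] < best ||
        (d[i, j] == best && bi > 0 &&
           (setA$pos1[i] < setA$pos1[bi] ||
              (setA$pos1[i] == setA$pos1[bi] &&
                 (setA$id[i] < setA$id[bi] ||
                    (setA$id[i] == setA$id[bi] && setB$id[j] < setB$id[bj])))))
      if (better) { best <- d[i, j]; bi <- i; bj <- j }
    }
    pairs <- c(pairs, paste(setA$id[bi], setB$id[bj], sep = "|"))
    d[bi, ] <- Inf; d[, bj] <- Inf
  }
  sort(pairs)
}

# --- independent oracle: best known-SV entry by full scan ------------------
oracle_match_known <- function(sv, entries, tolerance = 200) {
  best <- NULL; best_key <- NULL
  for (j in seq_len(nrow(entries))) {
    e <- entries[j, ]
    if (e$svtype != sv$svtype) next
    ok_direct <- e$chrom1 == sv$chrom1 && e$chrom2 == sv$chrom2 &&
      abs(e$pos1 - sv$pos1) <= tolerance && abs(e$pos2 - sv$pos2) <= tolerance
    ok_cross <- sv$svtype == "TRA" && e$chrom1 == sv$chrom2 &&
      e$chrom2 == sv$chrom1 && abs(e$pos1 - sv$pos2) <= tolerance &&
      abs(e$pos2 - sv$pos1) <= tolerance
    if (!ok_direct && !ok_cross) next
    dd <- Inf
    if (ok_direct) dd <- abs(e$pos1 - sv$pos1) + abs(e$pos2 - sv$pos2)
    if (ok_cross) dd <- min(dd, abs(e$pos1 - sv$pos2) + abs(e$pos2 - sv$pos1))
    key <- c(dd, as.integer(e$significance == "none"), e$entry_id)
    if (is.null(best) || dd < as.numeric(best_key[1]) ||
        (dd == as.numeric(best_key[1]) &&
           (key[2] < best_key[2] ||
              (key[2] == best_key[2] && key[3] < best_key[3])))) {
      best <- e$entry_id; best_key <- key
    }
  }
  best
}

# --- independent oracle: per-base gene-impact category ---------------------
# recomputes the category of one (sv, gene) pair from per-base membership
# vectors instead of interval arithmetic
oracle_impact <- function(sv, g, tra_intronic_is_plof = TRUE) {
  ex <- exon_intervals(g)
  gene_bases <- g$tx_start:g$tx_end
  is_exon <- rep(FALSE, length(gene_bases))
  for (k in seq_len(nrow(ex))) {
    is_exon[gene_bases >= ex$start[k] & gene_bases <= ex$end[k]] <- TRUE
  }
  in_gene <- function(chrom, p) chrom == g$chrom && p >= g$tx_start && p <= g$tx_end
  if (sv$svtype == "TRA") {
    hit <- c(in_gene(sv$chrom1, sv$pos1), in_gene(sv$chrom2, sv$pos2))
    if (!any(hit)) return(NULL)
    pos <- c(sv$pos1, sv$pos2)[hit]
    exonic <- any(is_exon[match(pos, gene_bases)])
    if (exonic || tra_intronic_is_plof) return("pLoF")
    return("intronic")
  }
  sv_bases <- gene_bases >= sv$pos1 & gene_bases <= sv$pos2
  if (sv$chrom1 != g$chrom || !any(sv_bases)) return(NULL)
  exon_touched <- any(sv_bases & is_exon)
  bp_in <- c(in_gene(sv$chrom1, sv$pos1), in_gene(sv$chrom1, sv$pos2))
  contains_gene <- sv$pos1 <= g$tx_start && sv$pos2 >= g$tx_end
  if (sv$svtype == "DEL") {
    if (!exon_touched) return("intronic")
    if (!is.na(g$cds_start)) {
      cds_bases <- gene_bases >= g$cds_start & gene_bases <= g$cds_end
      if (!any(sv_bases & cds_bases)) return("UTR")
    }
    return("pLoF")
  }
  if (sv$svtype == "DUP") {
    if (contains_gene) return("CG")
    if (all(bp_in)) {
      full_exon <- any(vapply(seq_len(nrow(ex)), function(k)
        sv$pos1 <= ex$start[k] && ex$end[k] <= sv$pos2, TRUE))
      if (full_exon) return("IED")
      both_exonic <- is_exon[match(sv$pos1, gene_bases)] &&
        is_exon[match(sv$pos2, gene_bases)]
      if (both_exonic) return("pLoF")
      return("partial_exon_DUP")
    }
    return("partial_gene_DUP")
  }
  if (sv$svtype == "INV") {
    if (contains_gene && !any(bp_in)) return("whole_gene_INV")
    if (any(sv_bases & is_exon)) return("pLoF")
    return("intronic")
  }
  if (sv$svtype == "INS") return("intronic")
  stop("oracle_impact: unknown svtype")
}
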