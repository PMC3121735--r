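# Strand-resolved allele counting and the five locus-selection criteria.

count_cols <- function() as.vector(t(outer(NTS, c("fwd", "rev"), paste,
                                           sep = "_")))

# Strand-summed count matrix (rows x A,C,G,T) from a wide counts data frame.
nt_totals <- function(counts) {
  m <- sapply(NTS, function(nt)
    counts[[paste0(nt, "_fwd")]] + counts[[paste0(nt, "_rev")]])
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(NULL, NTS))
  m
}

# Per-row counts of the annotated alleles, split and summed by strand.
allele_counts_at <- function(counts, loci) {
  idx <- match_loci(counts, loci)
  ref <- loci$ref[idx]; alt <- loci$alt[idx]
  n <- nrow(counts)
  cm <- as.matrix(counts[, count_cols()])
  pick <- function(nt, strand)
    as.integer(cm[cbind(seq_len(n), match(paste0(nt, "_", strand),
                                          colnames(cm)))])
  ref_fwd <- pick(ref, "fwd"); ref_rev <- pick(ref, "rev")
  alt_fwd <- pick(alt, "fwd"); alt_rev <- pick(alt, "rev")
  dup <- as.matrix(counts[, paste0("dup_", NTS)])
  list(idx = idx, ref = ref, alt = alt,
       ref_fwd = ref_fwd, ref_rev = ref_rev,
       alt_fwd = alt_fwd, alt_rev = alt_rev,
       ref_n = ref_fwd + ref_rev, alt_n = alt_fwd + alt_rev,
       dup_ref = dup[cbind(seq_len(n), match(ref, NTS))],
       dup_alt = dup[cbind(seq_len(n), match(alt, NTS))])
}

#' Tally stranded allele counts from per-read observations
#'
#' Aggregates per-read base observations (one row per read covering a SNP)
#' into per-(cell, locus) nucleotide counts split by alignment strand, and
#' computes for each supported nucleotide the modal identical-alignment-
#' position fraction used by the PCR-duplicate filter.
#'
#' @param observations Data frame with columns `cell_id`, `chrom`, `pos`
#'   (1-based SNP position), `nt` (observed base, one of A/C/G/T), `strand`
#'   (`+` or `-`, the alignment strand) and `aln_start` (leftmost alignment
#'   position of the read, for duplicate grouping). See
#'   [read_sam_observations()] for deriving these from SAM records.
#' @param loci SNP annotation (`chrom`, `pos`, `ref`, `alt`, ...).
#'   Observations at positions absent from `loci` are dropped with a message.
#' @return Wide stranded counts, one row per (cell, locus) observed, with
#'   columns `A_fwd` .. `T_rev` and `dup_A` .. `dup_T`.
#' @examples
#' obs <- data.frame(cell_id = "c1", chrom = "chr1", pos = 100,
#'                   nt = c("A", "A", "G"), strand = c("+", "-", "+"),
#'                   aln_start = c(61, 80, 61))
#' loci <- data.frame(chrom = "chr1", pos = 100, ref = "A", alt = "G")
#' count_alleles(obs, loci)
#' @export
count_alleles <- function(observations, loci) {
  assert_df_cols(observations,
                 c("cell_id", "chrom", "pos", "nt", "strand", "aln_start"),
                 "observations")
  assert_df_cols(loci, c("chrom", "pos", "ref", "alt"), "loci")
  bad_nt <- !observations$nt %in% NTS
  if (any(bad_nt))
    stop_(sprintf("observations contain %d non-ACGT nucleotide(s)",
                  sum(bad_nt)))
  if (!all(observations$strand %in% c("+", "-")))
    stop_("observation strand must be '+' or '-'")
  known <- locus_key(observations$chrom, observations$pos) %in%
    locus_key(loci$chrom, loci$pos)
  if (!all(known)) {
    message(sum(!known), " observation(s) at unannotated loci ignored")
    observations <- observations[known, , drop = FALSE]
  }
  if (!nrow(observations)) return(empty_wide_counts(0L))

  grp <- interaction(observations$cell_id, observations$chrom,
                     observations$pos, drop = TRUE, lex.order = TRUE)
  groups <- split(observations, grp)
  out <- empty_wide_counts(length(groups))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    out$cell_id[i] <- g$cell_id[1]
    out$chrom[i] <- g$chrom[1]
    out$pos[i] <- g$pos[1]
    for (nt in NTS) {
      sel <- g$nt == nt
      if (!any(sel)) next
      out[[paste0(nt, "_fwd")]][i] <- sum(sel & g$strand == "+")
      out[[paste0(nt, "_rev")]][i] <- sum(sel & g$strand == "-")
      out[[paste0("dup_", nt)]][i] <-
        max(table(g$aln_start[sel])) / sum(sel)
    }
  }
  rownames(out) <- NULL
  out
}

#' Apply the five locus-selection criteria
#'
#' A locus enters the allelic analysis of a cell only if (1) more than one
#' nucleotide is observed; (2) the observed alleles are the annotated SNP
#' alleles (the two most frequent observed nucleotides are a subset of
#' \{ref, alt\}); (3) it is covered by at least `min_coverage` reads; (4) for
#' every observed nucleotide, no more than `max_dup_frac` of its supporting
#' reads align to one identical position (PCR-duplicate guard; strands
#' pooled); and (5) annotation supports transcription of only one strand.
#'
#' @param counts Wide stranded counts (see [simulate_cells()] or
#'   [count_alleles()]).
#' @param loci SNP annotation with `ref`, `alt` and (for criterion 5)
#'   `tx_strand` in `+`, `-` or `conflict`; a missing `tx_strand` column
#'   passes criterion 5.
#' @param min_coverage Minimum total read coverage (criterion 3).
#' @param max_dup_frac Maximum modal identical-position fraction per
#'   supported nucleotide (criterion 4); the comparison is `<=`, so exactly
#'   half fails nothing. Missing duplicate bookkeeping (`NA`) passes.
#' @return Data frame with `cell_id`, `chrom`, `pos`, logical `crit1` ..
#'   `crit5` and `passed` (the conjunction).
#' @export
select_loci <- function(counts, loci, min_coverage = 25, max_dup_frac = 0.5) {
  min_coverage <- assert_count(min_coverage, "min_coverage", min = 1L)
  max_dup_frac <- assert_prob(max_dup_frac, "max_dup_frac")
  tot <- nt_totals(counts)
  ac <- allele_counts_at(counts, loci)
  crit1 <- rowSums(tot > 0L) >= 2L
  other <- tot
  other[cbind(seq_len(nrow(tot)), match(ac$ref, NTS))] <- 0L
  other[cbind(seq_len(nrow(tot)), match(ac$alt, NTS))] <- 0L
  other_max <- apply(other, 1L, max)
  crit2 <- other_max <= pmin(ac$ref_n, ac$alt_n)
  crit3 <- rowSums(tot) >= min_coverage
  dup <- as.matrix(counts[, paste0("dup_", NTS)])
  dup_ok <- is.na(dup) | dup <= max_dup_frac
  dup_ok[tot == 0L] <- TRUE
  crit4 <- rowSums(dup_ok) == 4L
  crit5 <- if ("tx_strand" %in% names(loci))
    loci$tx_strand[ac$idx] %in% c("+", "-") else rep(TRUE, nrow(counts))
  data.frame(cell_id = counts$cell_id, chrom = counts$chrom,
             pos = counts$pos, crit1 = crit1, crit2 = crit2, crit3 = crit3,
             crit4 = crit4, crit5 = crit5,
             passed = crit1 & crit2 & crit3 & crit4 & crit5,
             stringsAsFactors = FALSE)
}

#' Minor allele frequency at annotated SNP alleles
#'
#' `min(ref, alt) / (ref + alt)` over strand-summed raw counts of the two
#' annotated alleles; no pseudocount. Reads supporting other nucleotides are
#' ignored.
#'
#' @inheritParams select_loci
#' @return Numeric vector in `[0, 0.5]`, one value per row of `counts`.
#' @export
minor_allele_frequency <- function(counts, loci) {
  ac <- allele_counts_at(counts, loci)
  covered <- ac$ref_n + ac$alt_n
  if (any(covered == 0L))
    stop_(sprintf(
      "minor allele frequency undefined at %d locus/loci with zero coverage of the annotated alleles",
      sum(covered == 0L)))
  pmin(ac$ref_n, ac$alt_n) / covered
}

#' Allelic ratio (reference over alternative)
#'
#' The reported ratio adds a pseudocount of 1 to both allele counts to avoid
#' singularities at mono-allelic loci; the raw ratio `ref/alt` is also
#' returned (NA when `alt` is 0).
#'
#' @inheritParams select_loci
#' @param pseudocount Added to both counts for the reported ratio.
#' @return Data frame with `ref_count`, `alt_count`, `ratio`
#'   (pseudocounted), `log2_ratio`, and `raw_ratio`.
#' @export
allelic_ratio <- function(counts, loci, pseudocount = 1) {
  if (!is.numeric(pseudocount) || pseudocount < 0)
    stop_("'pseudocount' must be a non-negative number")
  ac <- allele_counts_at(counts, loci)
  ratio <- (ac$ref_n + pseudocount) / (ac$alt_n + pseudocount)
  data.frame(ref_count = ac$ref_n, alt_count = ac$alt_n, ratio = ratio,
             log2_ratio = log2(ratio),
             raw_ratio = ifelse(ac$alt_n > 0, ac$ref_n / ac$alt_n, NA_real_))
}
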