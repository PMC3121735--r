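# Allele-specific expression via an empirical strand-balance null.
#
# Double-stranded cDNA synthesis means each allele is observed on both
# alignment strands. Writing a1/b1 for reference observations on the +/-
# strand and a2/b2 for alternative observations on the +/- strand, the
# statistic
#
#     B = (a1 + b2 + 1) / (a2 + b1 + 1)
#
# equals 1 in expectation when no library or instrument bias exists,
# irrespective of the locus's true allelic skew: under unbiased strand
# assignment its numerator is a Binomial(coverage, 1/2) draw whatever the
# allele mix. The per-cell distribution D of log2(B) over all heterozygous
# loci therefore approximates the distribution of allelic ratios of balanced
# loci, including library and instrument noise, and serves as the empirical
# null against which observed log2 allelic ratios are tested two-tailed.

#' Strand-balance statistic B
#'
#' @inheritParams select_loci
#' @param pseudocount Added to numerator and denominator to avoid
#'   singularities (mirrors the allelic-ratio convention).
#' @return Numeric vector of B values, one per row of `counts`. A strongly
#'   skewed allele with unbiased strands still gives B near 1; only
#'   strand-asymmetric observation moves B away from 1.
#' @export
strand_balance <- function(counts, loci, pseudocount = 1) {
  ac <- allele_counts_at(counts, loci)
  (ac$ref_fwd + ac$alt_rev + pseudocount) /
    (ac$alt_fwd + ac$ref_rev + pseudocount)
}

#' Build the per-cell empirical null of log2 strand balance
#'
#' Collects log2(B) over a cell's heterozygous loci. The distribution is
#' pooled across coverage levels; its median becomes the centre of the
#' two-tailed test so that residual global reference bias is absorbed.
#'
#' @param counts Wide stranded counts of the heterozygous loci of one cell.
#' @param loci SNP annotation.
#' @param min_loci Minimum number of het loci required for a usable null.
#' @return Object of class `"balance_distribution"`: `cell_id`, `values`
#'   (log2 B per locus), `n`, `center` (median).
#' @export
balance_distribution <- function(counts, loci, min_loci = 50) {
  cell <- unique(counts$cell_id)
  if (length(cell) != 1L)
    stop_("'counts' must contain exactly one cell; got ",
          length(cell), " cell ids")
  if (nrow(counts) < min_loci)
    stop_(sprintf(
      "insufficient heterozygous loci for empirical null: %d, need >= %d",
      nrow(counts), min_loci))
  values <- log2(strand_balance(counts, loci))
  d <- list(cell_id = cell, values = values, n = length(values),
            center = median(values))
  class(d) <- "balance_distribution"
  d
}

#' @export
print.balance_distribution <- function(x, ...) {
  cat(sprintf(
    "Strand-balance null for cell %s: %d het loci, centre %.4f, IQR [%.3f, %.3f]\n",
    x$cell_id, x$n, x$center,
    quantile(x$values, 0.25), quantile(x$values, 0.75)))
  invisible(x)
}

#' Two-tailed empirical p-value against the strand-balance null
#'
#' Rank-based with add-one correction:
#' `p = (1 + #\{v in D : |v - centre| >= |r - centre|\}) / (n + 1)`,
#' so the smallest attainable p is `1/(n+1)` and p is monotonically
#' non-increasing in the ratio's distance from the centre.
#'
#' @param log2_ratio Observed log2 allelic ratio(s) (pseudocounted).
#' @param dist A `"balance_distribution"`.
#' @return p-value(s) in `(0, 1]`.
#' @export
ase_pvalue <- function(log2_ratio, dist) {
  if (!inherits(dist, "balance_distribution"))
    stop_("'dist' must be a balance_distribution object")
  a <- sort(abs(dist$values - dist$center))
  x <- abs(log2_ratio - dist$center)
  n_less <- findInterval(x, a, left.open = TRUE)  # values strictly below x
  (1 + dist$n - n_less) / (dist$n + 1)
}

#' Call allele-specific expression for one cell
#'
#' Computes the pseudocounted log2 allelic ratio of every supplied
#' (heterozygous) locus, its two-tailed empirical p-value against the cell's
#' strand-balance null, and the ASE call `p < alpha`.
#'
#' @param counts Wide stranded counts of the het-called loci of one cell.
#' @param loci SNP annotation.
#' @param dist The cell's [balance_distribution()].
#' @param alpha ASE significance level; calls use the strict inequality
#'   `p < alpha` (with `alpha >= 1` every locus is called, since p never
#'   exceeds 1).
#' @param pseudocount Pseudocount for the allelic ratio.
#' @return Data frame with `cell_id`, `chrom`, `pos`, `ref_count`,
#'   `alt_count`, `log2_ratio`, `p_value`, `is_ase`.
#' @export
call_ase <- function(counts, loci, dist, alpha = 0.01, pseudocount = 1) {
  alpha <- assert_pos(alpha, "alpha")
  ar <- allelic_ratio(counts, loci, pseudocount = pseudocount)
  p <- ase_pvalue(ar$log2_ratio, dist)
  data.frame(cell_id = counts$cell_id, chrom = counts$chrom,
             pos = counts$pos, ref_count = ar$ref_count,
             alt_count = ar$alt_count, log2_ratio = ar$log2_ratio,
             p_value = p, is_ase = (p < alpha) | (alpha >= 1),
             stringsAsFactors = FALSE)
}

#' Per-cell ASE summary counts
#'
#' @param ase_calls Output of [call_ase()] (one or more cells).
#' @param n_selected Named vector: selected loci per cell (criteria 1-5).
#' @param alpha ASE significance level used for the calls.
#' @return Data frame with one row per cell: selected loci, het loci tested,
#'   ASE calls, expected ASE false positives (`n_het * alpha`), and ASE%
#'   (`100 * n_ase / n_het`).
#' @export
ase_cell_summary <- function(ase_calls, n_selected, alpha = 0.01) {
  cells <- unique(ase_calls$cell_id)
  n_het <- sapply(cells, function(cid) sum(ase_calls$cell_id == cid))
  n_ase <- sapply(cells, function(cid)
    sum(ase_calls$is_ase[ase_calls$cell_id == cid]))
  data.frame(cell_id = cells,
             n_selected = as.integer(n_selected[cells]),
             n_het = as.integer(n_het),
             n_ase = as.integer(n_ase),
             expected_ase_fp = n_het * alpha,
             ase_pct = 100 * n_ase / n_het,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Direction concordance of allelic skew across cells
#'
#' A locus is concordant within a group of cells when the sign of its log2
#' allelic ratio is identical in every cell of the group (cells with a ratio
#' of exactly 0 are excluded; at least two signed cells are required).
#' Grouping `"within_embryo"` compares sister blastomeres of each embryo;
#' `"across_embryos"` compares cells of the same stage drawn from at least
#' two different embryos.
#'
#' @param calls Output of [call_ase()] (het loci of several cells).
#' @param cells Cell metadata (`cell_id`, `embryo_id`, `stage`).
#' @param grouping `"within_embryo"` or `"across_embryos"`.
#' @return List with `fraction` (overall concordant fraction), `n_loci`
#'   (qualifying locus-group combinations) and `per_locus` (data frame).
#' @export
direction_concordance <- function(calls, cells,
                                  grouping = c("within_embryo",
                                               "across_embryos")) {
  grouping <- match.arg(grouping)
  assert_df_cols(calls, c("cell_id", "chrom", "pos", "log2_ratio"), "calls")
  x <- merge(calls, cells[, c("cell_id", "embryo_id", "stage")],
             by = "cell_id")
  x <- x[x$log2_ratio != 0, , drop = FALSE]
  group <- if (grouping == "within_embryo") x$embryo_id else x$stage
  key <- paste(group, x$chrom, x$pos, sep = "\r")
  keys <- unique(key)
  conc <- vapply(keys, function(k) {
    sel <- key == k
    if (grouping == "across_embryos" &&
        length(unique(x$embryo_id[sel])) < 2L) return(NA)
    s <- sign(x$log2_ratio[sel])
    if (length(s) < 2L) return(NA)
    all(s == s[1])
  }, logical(1))
  keep <- !is.na(conc)
  if (!any(keep)) {
    warning("no loci shared by >= 2 qualifying cells", call. = FALSE)
    return(list(fraction = NA_real_, n_loci = 0L,
                per_locus = data.frame()))
  }
  parts <- do.call(rbind, strsplit(keys[keep], "\r", fixed = TRUE))
  list(fraction = mean(conc[keep]), n_loci = sum(keep),
       per_locus = data.frame(group = parts[, 1], chrom = parts[, 2],
                              pos = as.integer(parts[, 3]),
                              concordant = unname(conc[keep]),
                              stringsAsFactors = FALSE))
}
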