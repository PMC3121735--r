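# Allelic imbalance (AI) between sister blastomeres of one embryo.
#
# AI is the ratio of (pseudocounted) allelic ratios between the two cells:
# AI = (ref1+1)/(alt1+1) / ((ref2+1)/(alt2+1)). A locus is called imbalanced
# when the Pearson chi-squared test (1 df, no continuity correction) on the
# raw-count 2x2 table is significant at alpha AND the fold change passes
# (AI > fc_hi or AI < fc_lo).

# Vectorised Pearson chi-squared for 2x2 tables [[a, b], [c, d]];
# stats::chisq.test is the per-table reference this is tested against, the
# closed form N(ad - bc)^2 / (product of margins) is used so thousands of
# loci are one vector operation.
pearson_chi2_2x2 <- function(a, b, c, d) {
  # double arithmetic: margin products overflow 32-bit integers
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  ifelse(denom > 0, n * (a * d - b * c)^2 / denom, NA_real_)
}

#' Call allelic imbalance between two sister cells
#'
#' For every locus present in both cells (the caller restricts these to loci
#' het-called in both, each passing the selection criteria), computes the AI
#' value from pseudocounted allelic ratios, the Pearson chi-squared statistic
#' on the raw 2x2 table (ref/alt x cell1/cell2, 1 df, no continuity
#' correction) and its p-value, and calls AI when both the p-value and the
#' fold-change criterion pass. Tables with any expected cell below 5 are
#' still tested but flagged `low_expected`.
#'
#' @param counts1,counts2 Wide stranded counts of the shared het loci in the
#'   two cells (same loci; matched by chrom and pos).
#' @param loci SNP annotation.
#' @param alpha Chi-squared significance level.
#' @param fc_hi,fc_lo Fold-change bounds: pass iff `ai > fc_hi` or
#'   `ai < fc_lo`.
#' @param pseudocount Pseudocount for the allelic ratios (not the test).
#' @return Data frame with one row per shared locus: the 2x2 raw counts,
#'   `ai`, `log2_ai`, `chi2`, `p_value`, `fc_pass`, `low_expected`, `is_ai`.
#' @export
call_ai <- function(counts1, counts2, loci, alpha = 0.05,
                    fc_hi = 2, fc_lo = 0.5, pseudocount = 1) {
  alpha <- assert_prob(alpha, "alpha")
  if (fc_lo >= fc_hi) stop_("'fc_lo' must be below 'fc_hi'")
  cell1 <- unique(counts1$cell_id); cell2 <- unique(counts2$cell_id)
  if (length(cell1) != 1L || length(cell2) != 1L)
    stop_("each counts table must contain exactly one cell")
  k1 <- locus_key(counts1$chrom, counts1$pos)
  k2 <- locus_key(counts2$chrom, counts2$pos)
  shared <- intersect(k1, k2)
  if (!length(shared))
    return(data.frame())
  counts1 <- counts1[match(shared, k1), , drop = FALSE]
  counts2 <- counts2[match(shared, k2), , drop = FALSE]
  a1 <- allele_counts_at(counts1, loci)
  a2 <- allele_counts_at(counts2, loci)
  r1 <- (a1$ref_n + pseudocount) / (a1$alt_n + pseudocount)
  r2 <- (a2$ref_n + pseudocount) / (a2$alt_n + pseudocount)
  ai <- r1 / r2
  chi2 <- pearson_chi2_2x2(a1$ref_n, a1$alt_n, a2$ref_n, a2$alt_n)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  n <- a1$ref_n + a1$alt_n + a2$ref_n + a2$alt_n
  min_expected <- pmin((a1$ref_n + a1$alt_n), (a2$ref_n + a2$alt_n)) *
    pmin((a1$ref_n + a2$ref_n), (a1$alt_n + a2$alt_n)) / n
  fc_pass <- ai > fc_hi | ai < fc_lo
  data.frame(cell_id_1 = cell1, cell_id_2 = cell2,
             chrom = counts1$chrom, pos = counts1$pos,
             ref1 = a1$ref_n, alt1 = a1$alt_n,
             ref2 = a2$ref_n, alt2 = a2$alt_n,
             ai = ai, log2_ai = log2(ai), chi2 = chi2, p_value = p,
             fc_pass = fc_pass,
             low_expected = !is.na(min_expected) & min_expected < 5,
             is_ai = !is.na(p) & p < alpha & fc_pass,
             stringsAsFactors = FALSE)
}

#' Summarise allelic imbalance per embryo
#'
#' Counts AI calls over the shared het loci of a cell pair (a paired
#' statistic: both cells of the pair report the same count) and estimates
#' the expected number of false positives under the no-imbalance null by
#' Monte Carlo: for each locus, tables with the observed margins are drawn
#' from the hypergeometric distribution and passed through the same
#' chi-squared + fold-change rule.
#'
#' @param ai_calls Output of [call_ai()] for one cell pair.
#' @param alpha,fc_hi,fc_lo The thresholds used for the calls.
#' @param n_null_draws Monte Carlo draws for the expected-false-positive
#'   estimate (0 skips it).
#' @param pseudocount Pseudocount used in the fold-change ratios.
#' @return One-row data frame: `n_tested`, `n_ai`, `ai_pct`
#'   (`100 * n_ai / n_tested`, `NA` when nothing was tested) and
#'   `expected_ai_fp`.
#' @export
ai_summary <- function(ai_calls, alpha = 0.05, fc_hi = 2, fc_lo = 0.5,
                       n_null_draws = 20, pseudocount = 1) {
  n_tested <- nrow(ai_calls)
  if (!n_tested)
    return(data.frame(n_tested = 0L, n_ai = 0L, ai_pct = NA_real_,
                      expected_ai_fp = NA_real_))
  n_ai <- sum(ai_calls$is_ai, na.rm = TRUE)
  expected_fp <- NA_real_
  if (n_null_draws > 0) {
    row1 <- ai_calls$ref1 + ai_calls$alt1
    row2 <- ai_calls$ref2 + ai_calls$alt2
    col_ref <- ai_calls$ref1 + ai_calls$ref2
    col_alt <- ai_calls$alt1 + ai_calls$alt2
    hits <- numeric(n_null_draws)
    for (b in seq_len(n_null_draws)) {
      ref1s <- rhyper(n_tested, m = col_ref, n = col_alt, k = row1)
      alt1s <- row1 - ref1s
      ref2s <- col_ref - ref1s
      alt2s <- col_alt - alt1s
      chi2 <- pearson_chi2_2x2(ref1s, alt1s, ref2s, alt2s)
      p <- pchisq(chi2, df = 1, lower.tail = FALSE)
      ai <- ((ref1s + pseudocount) / (alt1s + pseudocount)) /
        ((ref2s + pseudocount) / (alt2s + pseudocount))
      hits[b] <- sum(!is.na(p) & p < alpha & (ai > fc_hi | ai < fc_lo))
    }
    expected_fp <- mean(hits)
  }
  data.frame(n_tested = as.integer(n_tested), n_ai = as.integer(n_ai),
             ai_pct = 100 * n_ai / n_tested,
             expected_ai_fp = expected_fp)
}
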