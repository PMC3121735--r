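# Per-cell expression summaries: RPM, expressed calls, fold-change flags,
# inter-cell correlation.

#' Reads per million (RPM)
#'
#' @param counts Non-negative per-transcript read counts.
#' @param total Total mapped reads of the cell (> 0).
#' @return `counts / total * 1e6`, same length as `counts`.
#' @export
compute_rpm <- function(counts, total) {
  if (!is.numeric(counts) || any(counts < 0, na.rm = TRUE))
    stop_("'counts' must be non-negative")
  total <- assert_pos(total, "total")
  counts / total * 1e6
}

#' Expressed-transcript detection
#'
#' A transcript counts as expressed when its RPM strictly exceeds the
#' threshold.
#'
#' @param rpm RPM vector (optionally named).
#' @param threshold Expression cutoff (strict `>`).
#' @return Logical vector parallel to `rpm`.
#' @export
detect_expressed <- function(rpm, threshold = 0.1) {
  if (!is.numeric(rpm)) stop_("'rpm' must be numeric")
  rpm > assert_pos(threshold, "threshold")
}

#' Fold-change flags between two groups of cells
#'
#' Group means get a small pseudocount so ratios are defined at zero; a
#' transcript is `up` when meanA/meanB exceeds `hi`, `down` when it is below
#' `lo`, otherwise `unchanged`.
#'
#' @param rpm_a,rpm_b Matched RPM vectors (or matrices with transcripts in
#'   rows, whose row means are compared).
#' @param hi,lo Fold-change bounds.
#' @param eps Pseudocount (RPM units).
#' @return Factor with levels `down`, `unchanged`, `up`.
#' @export
fold_change_flags <- function(rpm_a, rpm_b, hi = 2, lo = 0.5, eps = 0.01) {
  if (lo >= hi) stop_("'lo' must be below 'hi'")
  ma <- if (is.matrix(rpm_a)) rowMeans(rpm_a) else rpm_a
  mb <- if (is.matrix(rpm_b)) rowMeans(rpm_b) else rpm_b
  if (length(ma) != length(mb))
    stop_("'rpm_a' and 'rpm_b' must cover the same transcripts")
  fc <- (ma + eps) / (mb + eps)
  factor(ifelse(fc > hi, "up", ifelse(fc < lo, "down", "unchanged")),
         levels = c("down", "unchanged", "up"))
}

#' Correlation between two cells' transcriptomes
#'
#' Pearson correlation of the two cells' RPM profiles after an optional
#' `log2(rpm + 1)` transform.
#'
#' @param rpm1,rpm2 Matched RPM vectors of at least 100 shared transcripts.
#' @param transform `"log2p1"` (default) or `"none"`.
#' @return Pearson correlation coefficient.
#' @export
cell_correlation <- function(rpm1, rpm2, transform = c("log2p1", "none")) {
  transform <- match.arg(transform)
  if (length(rpm1) != length(rpm2))
    stop_("'rpm1' and 'rpm2' must cover the same transcripts")
  if (length(rpm1) < 100)
    stop_("at least 100 shared transcripts are required")
  if (transform == "log2p1") {
    rpm1 <- log2(rpm1 + 1)
    rpm2 <- log2(rpm2 + 1)
  }
  if (stats::sd(rpm1) == 0 || stats::sd(rpm2) == 0)
    stop_("correlation undefined: zero-variance expression vector")
  cor(rpm1, rpm2)
}
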