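# Heterozygosity calling calibrated on near-homozygous control cells.
#
# A homozygous locus can still show a minor allele through RT/PCR/sequencing
# error or mismapping. Control cells from a nearly inbred line measure that
# error empirically: the pooled minor-allele-frequency (MAF) distribution of
# their loci gives, at a chosen percentile p, a threshold such that a
# homozygous locus exceeds it with probability at most 1 - p.

#' Calibrate the heterozygosity threshold from control cells
#'
#' Pools minor allele frequencies over all control-cell loci that meet the
#' coverage, duplicate and single-strand criteria (criteria 3-5 of
#' [select_loci()]; criterion 1 is deliberately not required, since
#' single-nucleotide loci are exactly the calibration substrate), and takes
#' the nearest-rank empirical percentile as the calling threshold: the
#' smallest pooled value whose empirical CDF reaches `percentile`. By
#' construction at least `percentile` of the pooled calibration MAFs lie at
#' or below the threshold.
#'
#' @param counts Wide stranded counts of the control cells (all cells
#'   together; see [simulate_control_cells()]).
#' @param loci SNP annotation.
#' @param percentile Calibration percentile; the expected rate of miscalling
#'   a homozygous locus heterozygous is at most `1 - percentile`.
#' @param min_coverage,max_dup_frac Passed to [select_loci()].
#' @param min_loci Minimum pooled loci for a usable model.
#' @return An object of class `"maf_calibration"`: a list with `threshold`,
#'   `percentile`, `n_loci_pooled`, `pooled_maf`, `min_coverage`,
#'   `max_dup_frac`.
#' @seealso [call_genotype()], [expected_het_fp()], [write_calibration()]
#' @export
calibrate_maf <- function(counts, loci, percentile = 0.95,
                          min_coverage = 25, max_dup_frac = 0.5,
                          min_loci = 100) {
  percentile <- assert_prob(percentile, "percentile")
  if (percentile <= 0 || percentile >= 1)
    stop_("'percentile' must lie strictly between 0 and 1")
  flags <- select_loci(counts, loci, min_coverage = min_coverage,
                       max_dup_frac = max_dup_frac)
  keep <- flags$crit3 & flags$crit4 & flags$crit5
  kept <- counts[keep, , drop = FALSE]
  if (nrow(kept) < min_loci)
    stop_(sprintf(
      "insufficient calibration loci: %d pooled, need at least %d",
      nrow(kept), min_loci))
  maf <- minor_allele_frequency(kept, loci)
  s <- sort(maf)
  k <- ceiling(percentile * length(s))
  model <- list(threshold = s[k], percentile = percentile,
                n_loci_pooled = length(s), pooled_maf = maf,
                min_coverage = as.integer(min_coverage),
                max_dup_frac = max_dup_frac)
  class(model) <- "maf_calibration"
  model
}

#' @export
print.maf_calibration <- function(x, ...) {
  cat("MAF calibration from near-homozygous control cells\n")
  cat(sprintf("  pooled loci: %d (coverage >= %d)\n", x$n_loci_pooled,
              x$min_coverage))
  cat(sprintf("  het threshold: MAF > %.4g (nearest-rank %.0fth percentile)\n",
              x$threshold, 100 * x$percentile))
  cat(sprintf("  expected het false-positive rate <= %.1f%%\n",
              100 * (1 - x$percentile)))
  invisible(x)
}

#' @export
summary.maf_calibration <- function(object, ...) {
  print(object)
  if (!is.null(object$pooled_maf)) {
    cat("  pooled MAF quantiles:\n")
    print(signif(quantile(object$pooled_maf,
                          c(0.5, 0.9, 0.95, 0.99, 1)), 3))
  }
  invisible(object)
}

#' Call genotypes against a calibrated threshold
#'
#' A locus is called heterozygous when its minor allele frequency strictly
#' exceeds the calibrated threshold, and homozygous toward the majority
#' annotated allele otherwise (a MAF exactly at the threshold is homozygous).
#' Rows should already pass criteria 3-5 of [select_loci()].
#'
#' @inheritParams calibrate_maf
#' @param model A `"maf_calibration"` from [calibrate_maf()] or
#'   [read_calibration()].
#' @return Data frame with `cell_id`, `chrom`, `pos`, `maf` and `genotype`
#'   (`hom_ref`, `hom_alt` or `het`).
#' @export
call_genotype <- function(counts, loci, model) {
  if (!inherits(model, "maf_calibration"))
    stop_("'model' must be a maf_calibration object; run calibrate_maf() first")
  ac <- allele_counts_at(counts, loci)
  maf <- minor_allele_frequency(counts, loci)
  genotype <- ifelse(maf > model$threshold, "het",
                     ifelse(ac$ref_n >= ac$alt_n, "hom_ref", "hom_alt"))
  data.frame(cell_id = counts$cell_id, chrom = counts$chrom,
             pos = counts$pos, maf = maf, genotype = genotype,
             stringsAsFactors = FALSE)
}

#' Expected number of false heterozygous calls
#'
#' Under calibration at percentile p, each truly homozygous locus is miscalled
#' heterozygous with probability at most `1 - p`, so among `n_tested` loci the
#' expected count is `n_tested * (1 - p)`.
#'
#' @param model A `"maf_calibration"`.
#' @param n_tested Number of loci tested.
#' @return Expected false-positive count.
#' @export
expected_het_fp <- function(model, n_tested) {
  if (!inherits(model, "maf_calibration"))
    stop_("'model' must be a maf_calibration object")
  n_tested <- assert_count(n_tested, "n_tested", min = 0L)
  n_tested * (1 - model$percentile)
}

#' Flag sister cells with discordant genotype calls
#'
#' Sister blastomeres share their genotype, so per-cell calls that disagree
#' within one embryo indicate a calling error at that locus. Calls are
#' flagged, not corrected.
#'
#' @param genotypes Output of [call_genotype()] for several cells.
#' @param cells Cell metadata with `cell_id` and `embryo_id`.
#' @return Data frame of (embryo_id, chrom, pos) combinations whose cells
#'   disagree, with the calls concatenated.
#' @export
genotype_discordance <- function(genotypes, cells) {
  assert_df_cols(genotypes, c("cell_id", "chrom", "pos", "genotype"),
                 "genotypes")
  assert_df_cols(cells, c("cell_id", "embryo_id"), "cells")
  g <- merge(genotypes, cells[, c("cell_id", "embryo_id")], by = "cell_id")
  key <- interaction(g$embryo_id, g$chrom, g$pos, drop = TRUE)
  disc <- tapply(g$genotype, key, function(v)
    if (length(v) >= 2 && length(unique(v)) > 1) paste(v, collapse = ",")
    else NA_character_)
  disc <- disc[!is.na(disc)]
  if (!length(disc))
    return(data.frame(embryo_id = character(), chrom = character(),
                      pos = integer(), calls = character(),
                      stringsAsFactors = FALSE))
  parts <- do.call(rbind, strsplit(names(disc), ".", fixed = TRUE))
  data.frame(embryo_id = parts[, 1], chrom = parts[, 2],
             pos = as.integer(parts[, 3]), calls = unname(disc),
             stringsAsFactors = FALSE)
}

#' Persist / restore a calibration model
#'
#' The model is stored as readable JSON: threshold, percentile, pooled-locus
#' count, filter settings and a fixed-width histogram of the pooled MAF
#' values (the raw values themselves are not stored).
#'
#' @param model A `"maf_calibration"`.
#' @param path File path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns a `"maf_calibration"` (without `pooled_maf`).
#' @export
write_calibration <- function(model, path) {
  if (!inherits(model, "maf_calibration"))
    stop_("'model' must be a maf_calibration object")
  breaks <- seq(0, 0.5, by = 0.005)
  h <- if (is.null(model$pooled_maf)) NULL else
    as.integer(table(cut(model$pooled_maf, breaks, include.lowest = TRUE)))
  jsonlite::write_json(
    list(threshold = model$threshold, percentile = model$percentile,
         n_loci_pooled = model$n_loci_pooled,
         min_coverage = model$min_coverage,
         max_dup_frac = model$max_dup_frac,
         maf_hist_breaks = breaks, maf_hist_counts = h),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop_("calibration file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(threshold = x$threshold, percentile = x$percentile,
                n_loci_pooled = x$n_loci_pooled,
                pooled_maf = NULL,
                min_coverage = x$min_coverage,
                max_dup_frac = x$max_dup_frac,
                maf_hist_breaks = x$maf_hist_breaks,
                maf_hist_counts = x$maf_hist_counts)
  class(model) <- "maf_calibration"
  model
}
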