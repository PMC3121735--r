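# Proximal/distal 3'UTR isoform inference from 3'-biased coverage.
#
# Poly(T)-primed single-cell libraries cover mRNAs from the 3' end, decaying
# upstream and nearly vanishing ~1.5 kb in. A gene expressing a short and a
# long 3'UTR isoform therefore shows a coverage step at the proximal poly(A)
# site on top of the distal isoform's ramp. Ends are detected as drop points
# where the mean smoothed coverage just upstream exceeds the mean just
# downstream by a configurable ratio; every threshold is a ratio, so
# predictions are invariant to uniform coverage scaling.

#' Predict 3'UTR ends from a coverage track
#'
#' Smooths the track with a running median, scans for drop points where the
#' mean over the `min_segment` nt upstream is at least `min_step_ratio` times
#' the mean over the `min_segment` nt downstream, and keeps at most six drop
#' points, strongest step first. The per-isoform abundance at each end is the
#' upstream-window mean minus the downstream-window mean (for the most distal
#' end the downstream mean is ~0, so its abundance is the terminal segment's
#' mean coverage).
#'
#' @param coverage Non-negative numeric vector of per-base coverage in
#'   transcript orientation (position increases toward the 3' end).
#' @param min_step_ratio Minimum upstream/downstream mean ratio at a drop.
#' @param smooth_window Running-median window (nt).
#' @param min_segment Window (nt) for the upstream/downstream means; also the
#'   minimum distance of a predicted end from the track boundary.
#' @param max_ends Maximum number of predicted ends.
#' @return Data frame with `end` (1-based position) and `abundance`
#'   (mean-coverage units), ends strictly increasing; zero rows (with a
#'   warning) for an all-zero track.
#' @export
predict_utr_ends <- function(coverage, min_step_ratio = 3,
                             smooth_window = 50, min_segment = 100,
                             max_ends = 6L) {
  if (!is.numeric(coverage) || any(coverage < 0, na.rm = TRUE))
    stop_("'coverage' must be a non-negative numeric vector")
  min_step_ratio <- assert_pos(min_step_ratio, "min_step_ratio")
  w <- assert_count(min_segment, "min_segment")
  empty <- data.frame(end = integer(), abundance = numeric())
  if (!length(coverage) || all(coverage == 0)) {
    warning("zero-coverage track: no UTR predictions", call. = FALSE)
    return(empty)
  }
  L <- length(coverage)
  if (L < 2 * w + 1) {
    warning("track shorter than two analysis windows: no UTR predictions",
            call. = FALSE)
    return(empty)
  }
  k <- min(smooth_window, L)
  if (k %% 2 == 0) k <- k + 1
  s <- stats::runmed(coverage, k, endrule = "median")
  # candidate end i: upstream window [i-w, i-1], downstream [i, i+w-1];
  # the ratio scan runs on the median-smoothed track (robust detection),
  # the picked drop is then re-localised on the raw track, whose windowed
  # step height peaks at the true cleavage site without the upstream bias
  # a running median acquires on sparse (mostly 0/1) coverage
  cs_s <- c(0, cumsum(s))
  cs_r <- c(0, cumsum(coverage))
  i <- seq(w + 1L, L - w + 1L)
  up <- (cs_s[i] - cs_s[i - w]) / w
  down <- (cs_s[i + w] - cs_s[i]) / w
  ratio <- ifelse(down > 0, up / down, ifelse(up > 0, Inf, NA_real_))
  cand <- !is.na(ratio) & ratio >= min_step_ratio
  if (!any(cand)) return(empty)
  height_raw <- function(j) (cs_r[j] - cs_r[j - w]) / w -
    (cs_r[j + w] - cs_r[j]) / w
  height <- up - down
  runs <- rle(cand)
  stops <- cumsum(runs$lengths)
  starts <- stops - runs$lengths + 1L
  ends <- numeric(0); heights <- numeric(0)
  for (r in which(runs$values)) {
    span <- starts[r]:stops[r]
    pick <- i[span[which.max(height[span])]]
    j <- max(w + 1L, pick - as.integer(smooth_window)):
      min(L - w + 1L, pick + as.integer(smooth_window))
    h <- height_raw(j)
    best <- j[which.max(h)]
    # `best` indexes the first post-drop base; the cleavage site is the
    # last covered base before it
    ends <- c(ends, best - 1L)
    heights <- c(heights, max(h))
  }
  keep <- !duplicated(ends)
  ends <- ends[keep]; heights <- heights[keep]
  ord <- order(heights, decreasing = TRUE)
  sel <- ord[seq_len(min(length(ord), max_ends))]
  o <- order(ends[sel])
  data.frame(end = as.integer(ends[sel][o]), abundance = heights[sel][o])
}

#' Predict 3'UTR ends for every (cell, transcript) track
#'
#' @param coverage Long coverage data frame (`cell_id`, `transcript_id`,
#'   `pos`, `count`), e.g. from [simulate_utr_coverage()] or
#'   [read_bedgraph()].
#' @inheritParams predict_utr_ends
#' @return Data frame with `cell_id`, `transcript_id`, `end`, `abundance`.
#' @export
predict_utr <- function(coverage, min_step_ratio = 3, smooth_window = 50,
                        min_segment = 100, max_ends = 6L) {
  assert_df_cols(coverage, c("cell_id", "transcript_id", "pos", "count"),
                 "coverage")
  out <- list()
  for (cid in unique(coverage$cell_id)) {
    cc <- coverage[coverage$cell_id == cid, , drop = FALSE]
    for (tx in unique(cc$transcript_id)) {
      tt <- cc[cc$transcript_id == tx, , drop = FALSE]
      y <- numeric(max(tt$pos))
      y[tt$pos] <- tt$count
      pred <- suppressWarnings(
        predict_utr_ends(y, min_step_ratio, smooth_window, min_segment,
                         max_ends))
      if (nrow(pred))
        out[[length(out) + 1L]] <-
          data.frame(cell_id = cid, transcript_id = tx, pred,
                     stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(cell_id = character(), transcript_id = character(),
                      end = integer(), abundance = numeric()))
  do.call(rbind, out)
}

#' Scan for canonical poly(A) signals near a predicted cleavage site
#'
#' Searches the transcript-orientation sequence for the canonical cleavage
#' and polyadenylation specificity factor (CPSF) hexamers within `window` nt
#' of the predicted end and returns the offset of the closest motif start
#' relative to the cleavage position (negative = upstream; biologically the
#' signal sits ~20 nt upstream, offset -20). Ties between an upstream and a
#' downstream motif at equal distance resolve upstream.
#'
#' @param sequence Character scalar, transcript orientation.
#' @param end Predicted cleavage position (1-based) in `sequence`.
#' @param window Scan half-width (nt).
#' @param motifs Poly(A) hexamers to accept.
#' @return Integer offset, or `NA_integer_` if no motif lies in the window.
#' @export
scan_cpsf <- function(sequence, end, window = 50,
                      motifs = c("AATAAA", "ATTAAA")) {
  if (!is.character(sequence) || length(sequence) != 1L)
    stop_("'sequence' must be a single character string")
  end <- assert_count(end, "end")
  from <- max(1L, end - window)
  to <- min(nchar(sequence), end + window + max(nchar(motifs)) - 1L)
  region <- substr(sequence, from, to)
  offsets <- integer(0)
  for (m in motifs) {
    hit <- gregexpr(m, region, fixed = TRUE)[[1]]
    if (hit[1] != -1L) offsets <- c(offsets, hit + from - 1L - end)
  }
  offsets <- offsets[abs(offsets) <= window]
  if (!length(offsets)) return(NA_integer_)
  best <- offsets[order(abs(offsets), offsets)][1]
  as.integer(best)
}

#' Proximal-to-distal abundance ratio of a transcript's isoforms
#'
#' @param prediction Data frame of predicted ends for one transcript
#'   (columns `end`, `abundance`) with at least two rows.
#' @return The abundance of the most proximal end divided by that of the
#'   most distal end; `Inf` when the distal abundance is 0.
#' @export
proximal_distal_ratio <- function(prediction) {
  assert_df_cols(prediction, c("end", "abundance"), "prediction")
  if (nrow(prediction) < 2L)
    stop_("at least two predicted ends are required for a proximal:distal ratio")
  o <- order(prediction$end)
  prox <- prediction$abundance[o[1]]
  dist <- prediction$abundance[o[length(o)]]
  if (dist == 0) return(Inf)
  prox / dist
}

#' Cross-cell consensus of 3'UTR predictions
#'
#' Clusters per-cell predicted ends of each transcript (sorted ends are
#' chained while consecutive ends are within `tolerance` nt) and keeps
#' clusters supported by at least `min_fraction` of all cells. The consensus
#' end is the median end of the cluster and the consensus abundance the
#' median of the supporting cells' abundances.
#'
#' @param predictions Output of [predict_utr()] (several cells).
#' @param n_cells Total number of cells the support fraction refers to
#'   (defaults to the number of distinct cells in `predictions`).
#' @param tolerance Clustering tolerance (nt).
#' @param min_fraction Minimum supporting fraction of cells.
#' @param max_ends Maximum consensus ends per transcript.
#' @return Data frame with `transcript_id`, `end`, `abundance`, `support`
#'   (fraction of cells).
#' @export
consensus_utr <- function(predictions, n_cells = NULL, tolerance = 50,
                          min_fraction = 0.5, max_ends = 6L) {
  assert_df_cols(predictions, c("cell_id", "transcript_id", "end",
                                "abundance"), "predictions")
  if (is.null(n_cells)) n_cells <- length(unique(predictions$cell_id))
  n_cells <- assert_count(n_cells, "n_cells")
  min_fraction <- assert_prob(min_fraction, "min_fraction")
  out <- list()
  for (tx in unique(predictions$transcript_id)) {
    p <- predictions[predictions$transcript_id == tx, , drop = FALSE]
    p <- p[order(p$end), , drop = FALSE]
    cluster <- cumsum(c(1L, diff(p$end) > tolerance))
    for (cl in unique(cluster)) {
      q <- p[cluster == cl, , drop = FALSE]
      support <- length(unique(q$cell_id)) / n_cells
      if (support < min_fraction) next
      per_cell_ab <- tapply(q$abundance, q$cell_id, mean)
      out[[length(out) + 1L]] <- data.frame(
        transcript_id = tx, end = as.integer(round(median(q$end))),
        abundance = median(per_cell_ab), support = support,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(transcript_id = character(), end = integer(),
                      abundance = numeric(), support = numeric()))
  res <- do.call(rbind, out)
  keep <- list()
  for (tx in unique(res$transcript_id)) {
    r <- res[res$transcript_id == tx, , drop = FALSE]
    r <- r[order(-r$support, -r$abundance), , drop = FALSE]
    r <- r[seq_len(min(nrow(r), max_ends)), , drop = FALSE]
    keep[[tx]] <- r[order(r$end), , drop = FALSE]
  }
  res <- do.call(rbind, keep)
  rownames(res) <- NULL
  res
}
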