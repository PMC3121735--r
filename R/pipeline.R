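# End-to-end orchestration: simulate -> count -> calibrate -> genotype ->
# ASE -> AI -> UTR -> expression -> report, with a parameter echo and a
# per-filter audit trail in the run log.

#' Pipeline configuration
#'
#' Collects every stage's parameters. Defaults are the analysis thresholds
#' used throughout the package: minimum coverage 25 reads, duplicate cap
#' 50%, calibration at the 95th percentile, ASE at p < 0.01, AI at
#' chi-squared p < 0.05 with fold change > 2 or < 0.5, expressed transcripts
#' at RPM > 0.1.
#'
#' @param sim A [sim_config()] describing the synthetic dataset.
#' @param n_control_cells Control cells simulated for calibration.
#' @param percentile Calibration percentile.
#' @param min_coverage,max_dup_frac Locus-selection settings.
#' @param alpha_ase,alpha_ai Significance levels.
#' @param fc_hi,fc_lo AI fold-change bounds.
#' @param rpm_threshold Expressed-transcript cutoff.
#' @param min_het_loci Minimum het loci per cell for the strand-balance null.
#' @param utr UTR-stage parameters (`min_step_ratio`, `smooth_window`,
#'   `min_segment`, `tolerance`, `min_fraction`, `max_ends`).
#' @param ai_null_draws Monte Carlo draws for expected AI false positives.
#' @param seed Master seed; all stage seeds derive from it.
#' @param outdir Output directory.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            n_control_cells = 12,
                            percentile = 0.95,
                            min_coverage = 25,
                            max_dup_frac = 0.5,
                            alpha_ase = 0.01,
                            alpha_ai = 0.05,
                            fc_hi = 2, fc_lo = 0.5,
                            rpm_threshold = 0.1,
                            min_het_loci = 50,
                            utr = list(),
                            ai_null_draws = 20,
                            seed = 1L,
                            outdir = tempfile("strandase_run_")) {
  stopifnot(inherits(sim, "sim_config"))
  cfg <- list(
    sim = sim,
    n_control_cells = assert_count(n_control_cells, "n_control_cells"),
    percentile = assert_prob(percentile, "percentile"),
    min_coverage = assert_count(min_coverage, "min_coverage"),
    max_dup_frac = assert_prob(max_dup_frac, "max_dup_frac"),
    alpha_ase = assert_pos(alpha_ase, "alpha_ase"),
    alpha_ai = assert_prob(alpha_ai, "alpha_ai"),
    fc_hi = assert_pos(fc_hi, "fc_hi"),
    fc_lo = assert_pos(fc_lo, "fc_lo"),
    rpm_threshold = assert_pos(rpm_threshold, "rpm_threshold"),
    min_het_loci = assert_count(min_het_loci, "min_het_loci"),
    utr = utils::modifyList(
      list(min_step_ratio = 3, smooth_window = 50, min_segment = 100,
           tolerance = 50, min_fraction = 0.5, max_ends = 6L), utr),
    ai_null_draws = assert_count(ai_null_draws, "ai_null_draws", min = 0L),
    seed = assert_count(seed, "seed", min = 0L),
    outdir = outdir)
  if (cfg$fc_lo >= cfg$fc_hi) stop_("'fc_lo' must be below 'fc_hi'")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Every key of [pipeline_config()] may appear; the `sim` block is passed to
#' [sim_config()]. Missing keys keep their defaults.
#'
#' @param path YAML file.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_("config file not found: ", path)
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$genotype_probs))
    sim_args$genotype_probs <- unlist(sim_args$genotype_probs)
  y$sim <- do.call(sim_config, sim_args)
  do.call(pipeline_config, y)
}

#' Build the per-cell summary table
#'
#' One column per cell; rows: selected loci, heterozygous loci, ASE calls,
#' expected ASE false positives, AI calls, expected AI false positives,
#' ASE%, AI%. Both blastomeres of a pair report the same AI count (a paired
#' statistic).
#'
#' @param ase_summary Output of [ase_cell_summary()].
#' @param ai_by_embryo Data frame `embryo_id`, `n_tested`, `n_ai`,
#'   `expected_ai_fp`.
#' @param cells Cell metadata.
#' @return Data frame whose first column `metric` labels the rows and whose
#'   remaining columns are cells.
#' @export
make_summary_table <- function(ase_summary, ai_by_embryo, cells) {
  metrics <- c("selected loci", "# of Heterozygous", "# of ASE",
               "# Expected False Positive (ASE)", "# Allelic Imbalance (AI)",
               "# Expected False Positive (AI)", "ASE (%)", "AI (%)")
  out <- data.frame(metric = metrics, stringsAsFactors = FALSE)
  for (cid in ase_summary$cell_id) {
    a <- ase_summary[ase_summary$cell_id == cid, ]
    emb <- cells$embryo_id[match(cid, cells$cell_id)]
    b <- ai_by_embryo[match(emb, ai_by_embryo$embryo_id), ]
    n_ai <- if (nrow(b) && !is.na(b$n_ai[1])) b$n_ai[1] else NA_real_
    ai_fp <- if (nrow(b)) b$expected_ai_fp[1] else NA_real_
    ai_pct <- if (nrow(b) && !is.na(b$n_tested[1]) && b$n_tested[1] > 0)
      100 * n_ai / b$n_tested[1] else NA_real_
    out[[cid]] <- round(c(a$n_selected, a$n_het, a$n_ase,
                          a$expected_ase_fp, n_ai, ai_fp,
                          a$ase_pct, ai_pct), 2)
  }
  out
}

log_stage <- function(log_path, lines) {
  cat(paste0(lines, "\n"), file = log_path, sep = "", append = TRUE)
}

run_stage <- function(name, log_path, expr) {
  log_stage(log_path, sprintf("[stage %s] start", name))
  res <- tryCatch(expr, error = function(e)
    stop_(sprintf("stage '%s' failed: %s", name, conditionMessage(e))))
  log_stage(log_path, sprintf("[stage %s] done", name))
  res
}

#' Run the full ASE / AI / UTR / expression pipeline on simulated data
#'
#' Executes all stages in dependency order, writes every input and result
#' table under `config$outdir`, and logs parameter values plus locus counts
#' at every filter. Reruns with the same configuration and seed produce
#' byte-identical files. A failing stage stops the run, names itself, and
#' leaves the outputs of earlier stages intact.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the calibration model, per-cell genotype
#'   and ASE calls, AI calls and summaries, UTR predictions and consensus,
#'   expression summaries, the summary table, and the output paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run_log.txt")
  cat("strandase pipeline run\n----------------------\n", file = log_path)
  log_stage(log_path, c("parameters:",
                        yaml::as.yaml(unclass_config_for_log(config))))
  seeds <- child_seeds(config$seed, 5L)

  sim <- run_stage("simulate", log_path, {
    s <- simulate_cells(config$sim, seed = seeds[1])
    write_allele_counts(s$counts, file.path(outdir, "allele_counts.tsv"))
    write_snp_table(s$loci, file.path(outdir, "snps.vcf"), dialect = "vcf")
    write_cell_meta(s$cells, file.path(outdir, "cells.tsv"))
    write_tsv(s$truth, file.path(outdir, "truth.tsv"))
    s
  })

  model <- run_stage("calibrate", log_path, {
    ctrl <- simulate_control_cells(control_config(config$sim),
                                   n_cells = config$n_control_cells,
                                   seed = seeds[2])
    write_allele_counts(ctrl$counts,
                        file.path(outdir, "control_counts.tsv"))
    m <- calibrate_maf(ctrl$counts, ctrl$loci,
                       percentile = config$percentile,
                       min_coverage = config$min_coverage,
                       max_dup_frac = config$max_dup_frac)
    write_calibration(m, file.path(outdir, "calibration.json"))
    log_stage(log_path, sprintf(
      "  calibration: %d pooled loci, threshold %.4f",
      m$n_loci_pooled, m$threshold))
    m
  })

  ase <- run_stage("ase", log_path, withr::with_seed(seeds[3], {
    calls <- list(); het_counts <- list()
    n_selected <- setNames(integer(nrow(sim$cells)), sim$cells$cell_id)
    for (cid in sim$cells$cell_id) {
      cc <- sim$counts[sim$counts$cell_id == cid, , drop = FALSE]
      flags <- select_loci(cc, sim$loci, config$min_coverage,
                           config$max_dup_frac)
      log_stage(log_path, sprintf(
        "  %s: loci %d | crit1 %d crit2 %d crit3 %d crit4 %d crit5 %d | selected %d",
        cid, nrow(flags), sum(flags$crit1), sum(flags$crit2),
        sum(flags$crit3), sum(flags$crit4), sum(flags$crit5),
        sum(flags$passed)))
      sel <- cc[flags$passed, , drop = FALSE]
      n_selected[cid] <- nrow(sel)
      if (!nrow(sel)) next
      geno <- call_genotype(sel, sim$loci, model)
      het <- sel[geno$genotype == "het", , drop = FALSE]
      log_stage(log_path, sprintf("  %s: heterozygous %d", cid, nrow(het)))
      if (nrow(het) < config$min_het_loci) {
        log_stage(log_path, sprintf(
          "  %s: skipped ASE (fewer than %d het loci)", cid,
          config$min_het_loci))
        next
      }
      d <- balance_distribution(het, sim$loci,
                                min_loci = config$min_het_loci)
      calls[[cid]] <- call_ase(het, sim$loci, d, alpha = config$alpha_ase)
      het_counts[[cid]] <- het
    }
    ase_calls <- do.call(rbind, calls)
    if (is.null(ase_calls)) ase_calls <- data.frame()
    rownames(ase_calls) <- NULL
    write_tsv(ase_calls, file.path(outdir, "ase_calls.tsv"))
    smry <- if (nrow(ase_calls))
      ase_cell_summary(ase_calls, n_selected, alpha = config$alpha_ase)
    else data.frame(cell_id = character(), n_selected = integer(),
                    n_het = integer(), n_ase = integer(),
                    expected_ase_fp = numeric(), ase_pct = numeric())
    list(calls = ase_calls, summary = smry, het_counts = het_counts)
  }))

  ai <- run_stage("ai", log_path, withr::with_seed(seeds[3] + 1L, {
    pair_calls <- list(); embryo_rows <- list()
    for (emb in unique(sim$cells$embryo_id)) {
      members <- intersect(sim$cells$cell_id[sim$cells$embryo_id == emb],
                           names(ase$het_counts))
      if (length(members) < 2L) next
      pairs <- utils::combn(members, 2L, simplify = FALSE)
      emb_ai_keys <- character(0); emb_tested <- character(0); emb_fp <- 0
      for (pr in pairs) {
        calls <- call_ai(ase$het_counts[[pr[1]]], ase$het_counts[[pr[2]]],
                         sim$loci, alpha = config$alpha_ai,
                         fc_hi = config$fc_hi, fc_lo = config$fc_lo)
        if (!nrow(calls)) next
        pair_calls[[paste(pr, collapse = "|")]] <- calls
        smry <- ai_summary(calls, alpha = config$alpha_ai,
                           fc_hi = config$fc_hi, fc_lo = config$fc_lo,
                           n_null_draws = config$ai_null_draws)
        emb_fp <- emb_fp + (smry$expected_ai_fp %||% 0)
        keys <- locus_key(calls$chrom, calls$pos)
        emb_tested <- union(emb_tested, keys)
        emb_ai_keys <- union(emb_ai_keys, keys[calls$is_ai])
        log_stage(log_path, sprintf(
          "  %s ~ %s: tested %d, AI %d", pr[1], pr[2], smry$n_tested,
          smry$n_ai))
      }
      embryo_rows[[emb]] <- data.frame(
        embryo_id = emb, n_tested = length(emb_tested),
        n_ai = length(emb_ai_keys), expected_ai_fp = emb_fp,
        stringsAsFactors = FALSE)
    }
    ai_calls <- do.call(rbind, pair_calls)
    rownames(ai_calls) <- NULL
    by_embryo <- do.call(rbind, embryo_rows)
    rownames(by_embryo) <- NULL
    if (is.null(ai_calls)) ai_calls <- data.frame()
    if (is.null(by_embryo))
      by_embryo <- data.frame(embryo_id = character(), n_tested = integer(),
                              n_ai = integer(), expected_ai_fp = numeric())
    write_tsv(ai_calls, file.path(outdir, "ai_calls.tsv"))
    list(calls = ai_calls, by_embryo = by_embryo)
  }))

  concord <- run_stage("concordance", log_path, {
    if (is.null(ase$calls) || !nrow(ase$calls)) list(within = NULL) else {
      w <- suppressWarnings(direction_concordance(ase$calls, sim$cells,
                                                  "within_embryo"))
      a <- suppressWarnings(direction_concordance(ase$calls, sim$cells,
                                                  "across_embryos"))
      log_stage(log_path, sprintf(
        "  direction concordance: within-embryo %.3f (%d loci), across-embryo %.3f (%d loci)",
        w$fraction, w$n_loci, a$fraction, a$n_loci))
      list(within = w, across = a)
    }
  })

  utr <- run_stage("utr", log_path, {
    u <- simulate_utr_coverage(config$sim, seed = seeds[4],
                               cell_ids = sim$cells$cell_id)
    first <- sim$cells$cell_id[1]
    write_bedgraph(u$coverage[u$coverage$cell_id == first, , drop = FALSE],
                   file.path(outdir, "coverage_cell1.bedgraph"))
    up <- config$utr
    preds <- predict_utr(u$coverage, min_step_ratio = up$min_step_ratio,
                         smooth_window = up$smooth_window,
                         min_segment = up$min_segment,
                         max_ends = up$max_ends)
    cons <- consensus_utr(preds, n_cells = nrow(sim$cells),
                          tolerance = up$tolerance,
                          min_fraction = up$min_fraction,
                          max_ends = up$max_ends)
    if (nrow(cons))
      cons$cpsf_offset <- mapply(function(tx, e)
        scan_cpsf(u$sequences[[tx]], e), cons$transcript_id, cons$end)
    write_tsv(preds, file.path(outdir, "utr_predictions.tsv"))
    write_tsv(cons, file.path(outdir, "utr_consensus.tsv"))
    log_stage(log_path, sprintf(
      "  UTR: %d per-cell predictions, %d consensus ends over %d genes",
      nrow(preds), nrow(cons), length(unique(cons$transcript_id))))
    list(sim = u, predictions = preds, consensus = cons)
  })

  expr <- run_stage("expr", log_path, {
    e <- simulate_expression(config$sim, seed = seeds[5])
    cm <- as.matrix(e$counts[, -1, drop = FALSE])
    rpm <- sweep(cm, 2, colSums(cm), "/") * 1e6
    expressed <- colSums(rpm > config$rpm_threshold)
    rpm_df <- data.frame(transcript_id = e$counts$transcript_id,
                         round(rpm, 4), check.names = FALSE)
    write_tsv(rpm_df, file.path(outdir, "expression_rpm.tsv"))
    cors <- list()
    for (emb in unique(e$cells$embryo_id)) {
      mem <- e$cells$cell_id[e$cells$embryo_id == emb]
      if (length(mem) < 2L) next
      prs <- utils::combn(mem, 2L, simplify = FALSE)
      for (pr in prs)
        cors[[paste(pr, collapse = "|")]] <- data.frame(
          cell_id_1 = pr[1], cell_id_2 = pr[2],
          pearson_r = cell_correlation(rpm[, pr[1]], rpm[, pr[2]]),
          stringsAsFactors = FALSE)
    }
    cors <- do.call(rbind, cors)
    rownames(cors) <- NULL
    smry <- data.frame(cell_id = colnames(rpm),
                       total_reads = colSums(cm),
                       n_expressed = as.integer(expressed),
                       stringsAsFactors = FALSE)
    write_tsv(smry, file.path(outdir, "expr_summary.tsv"))
    write_tsv(cors, file.path(outdir, "expr_correlations.tsv"))
    log_stage(log_path, sprintf(
      "  expression: %d transcripts, %d-%d expressed per cell",
      nrow(rpm), min(expressed), max(expressed)))
    list(rpm = rpm, summary = smry, correlations = cors)
  })

  summary_tab <- run_stage("report", log_path, {
    st <- make_summary_table(ase$summary, ai$by_embryo, sim$cells)
    write_tsv(st, file.path(outdir, "cell_summary.tsv"))
    st
  })

  invisible(list(config = config, sim = sim, model = model,
                 ase_calls = ase$calls, ase_summary = ase$summary,
                 ai_calls = ai$calls, ai_by_embryo = ai$by_embryo,
                 concordance = concord, utr = utr, expr = expr,
                 summary = summary_tab, outdir = outdir,
                 log = log_path))
}

# Config as plain lists for the YAML parameter echo. The output directory
# is omitted: it is where the log lives, and including it would make
# otherwise identical runs compare differently.
unclass_config_for_log <- function(config) {
  x <- unclass(config)
  x$outdir <- NULL
  x$sim <- unclass(x$sim)
  x$sim$genotype_probs <- as.list(x$sim$genotype_probs)
  x
}
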