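# Synthetic single-cell allele-count, coverage and expression generator.
#
# The generator emulates the data structure the ASE pipeline assumes: single
# cells are either homozygous or heterozygous at every SNP, sister cells of one
# embryo share their genotype, double-stranded cDNA spreads observations over
# both alignment strands, RT/PCR/sequencing error puts false minor alleles on
# homozygous loci (with locus-level overdispersion), PCR duplicates stack reads
# at identical alignment positions, and poly(T)-primed libraries give 3'-biased
# transcript coverage with one or two poly(A) sites per gene.

#' Simulation configuration
#'
#' Builds and validates the parameter set consumed by [simulate_cells()],
#' [simulate_control_cells()], [simulate_utr_coverage()] and
#' [simulate_expression()]. Defaults emulate outbred cleavage-stage embryos:
#' a majority of expressed SNPs heterozygous, roughly half of het loci with a
#' skewed allelic ratio, ~6% of het loci re-drawing their skew independently
#' per sister cell (stochastic allelic imbalance), and a mean per-read
#' error/mismap rate of 2% with strong locus-to-locus overdispersion.
#'
#' @param n_embryos Number of embryos.
#' @param cells_per_embryo Sister blastomeres per embryo.
#' @param n_loci Number of annotated SNP loci.
#' @param genotype_probs Named probabilities over `hom_ref`, `hom_alt`, `het`;
#'   must sum to 1.
#' @param coverage Per-locus read-depth law: a list with `mean` and `size`
#'   (negative binomial) and `min` (left truncation, reads).
#' @param error_rate Mean per-read probability that a read at a homozygous
#'   locus reports the other annotated allele.
#' @param error_overdispersion Beta overdispersion rho in `[0, 1)` of the
#'   per-library, per-locus error probability; 0 gives a pure binomial error.
#' @param ase_fraction Fraction of (non-imbalanced) het loci with a truly
#'   skewed allelic ratio.
#' @param ase_log2_skew Law of true log2 allelic ratios for skewed loci: a list
#'   with `law` one of `"normal"` (`mean`, `sd`), `"constant"` (`value`) or
#'   `"uniform"` (`min`, `max`).
#' @param ai_fraction Fraction of het loci whose skew is re-drawn independently
#'   in every sister cell (true allelic imbalance).
#' @param dup_rate Probability that a read is a PCR duplicate of an earlier
#'   read, i.e. shares its exact alignment position.
#' @param strand_bias Probability that a read observation derives from the
#'   first cDNA strand (aligns to `+`); 0.5 is unbiased.
#' @param control_het_residual Residual heterozygosity of the near-homozygous
#'   control line used by [control_config()].
#' @param utr 3'UTR coverage parameters: `n_genes`; `two_isoform_fraction`;
#'   `proximal_range` and `gap_range` (nt windows for the proximal site and the
#'   proximal-to-distal gap); `margin` (nt of track retained past the distal
#'   end); `decay_length` (nt scale of the exponential 3'-bias decay; near zero
#'   by 1.5 kb); `abundance_ratio` (proximal:distal isoform abundance);
#'   `distal_abundance` (distal isoform coverage, reads/nt, at its 3' end);
#'   `cpsf_proximal_prob`, `cpsf_distal_prob` (probability a canonical poly(A)
#'   hexamer is planted 20 nt upstream of each true end).
#' @param expr Expression parameters: `n_transcripts`, `depth` (reads per
#'   cell), `log2_sd` (spread of true abundances), `embryo_log2_sd`
#'   (between-embryo perturbation of true abundances).
#'
#' @return A validated list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_loci = 200)
#' sim <- simulate_cells(cfg, seed = 1)
#' head(sim$counts)
#' @export
sim_config <- function(n_embryos = 2,
                       cells_per_embryo = 2,
                       n_loci = 2000,
                       genotype_probs = c(hom_ref = 0.20, hom_alt = 0.20,
                                          het = 0.60),
                       coverage = list(mean = 60, size = 8, min = 1),
                       error_rate = 0.02,
                       error_overdispersion = 0.1,
                       ase_fraction = 0.45,
                       ase_log2_skew = list(law = "normal", mean = 0, sd = 2.5),
                       ai_fraction = 0.06,
                       dup_rate = 0.1,
                       strand_bias = 0.5,
                       control_het_residual = 0.003,
                       utr = list(),
                       expr = list()) {
  cfg <- list(
    n_embryos = assert_count(n_embryos, "n_embryos"),
    cells_per_embryo = assert_count(cells_per_embryo, "cells_per_embryo"),
    n_loci = assert_count(n_loci, "n_loci"),
    genotype_probs = genotype_probs,
    coverage = utils::modifyList(list(mean = 60, size = 8, min = 1), coverage),
    error_rate = assert_prob(error_rate, "error_rate"),
    error_overdispersion = assert_prob(error_overdispersion,
                                       "error_overdispersion"),
    ase_fraction = assert_prob(ase_fraction, "ase_fraction"),
    ase_log2_skew = ase_log2_skew,
    ai_fraction = assert_prob(ai_fraction, "ai_fraction"),
    dup_rate = assert_prob(dup_rate, "dup_rate"),
    strand_bias = assert_prob(strand_bias, "strand_bias"),
    control_het_residual = assert_prob(control_het_residual,
                                       "control_het_residual"),
    utr = utils::modifyList(
      list(n_genes = 50, two_isoform_fraction = 0.13,
           proximal_range = c(800, 1400), gap_range = c(600, 1200),
           margin = 600, decay_length = 600, abundance_ratio = 5,
           distal_abundance = 1.2, cpsf_proximal_prob = 0.4,
           cpsf_distal_prob = 0.7),
      utr),
    expr = utils::modifyList(
      list(n_transcripts = 2000, depth = 1e6, log2_sd = 2,
           embryo_log2_sd = 0.25),
      expr)
  )
  gp <- cfg$genotype_probs
  if (is.null(names(gp)) || !setequal(names(gp), c("hom_ref", "hom_alt", "het")))
    stop_("'genotype_probs' must be named hom_ref, hom_alt, het")
  if (any(gp < 0 | gp > 1))
    stop_("'genotype_probs' must lie in [0, 1]")
  if (abs(sum(gp) - 1) > 1e-9)
    stop_("'genotype_probs' must sum to 1 (within 1e-9)")
  cfg$genotype_probs <- gp[c("hom_ref", "hom_alt", "het")]
  assert_pos(cfg$coverage$mean, "coverage$mean")
  assert_pos(cfg$coverage$size, "coverage$size")
  assert_count(cfg$coverage$min, "coverage$min", min = 0L)
  if (cfg$error_overdispersion >= 1)
    stop_("'error_overdispersion' must be < 1")
  law <- cfg$ase_log2_skew$law %||% "normal"
  if (!law %in% c("normal", "constant", "uniform"))
    stop_("'ase_log2_skew$law' must be one of normal, constant, uniform")
  if (cfg$utr$gap_range[1] <= 0)
    stop_("'utr$gap_range' must be positive: distal site strictly downstream of proximal")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  %d embryo(s) x %d cell(s), %d loci\n",
              x$n_embryos, x$cells_per_embryo, x$n_loci))
  cat(sprintf("  genotypes: hom_ref %.2f / hom_alt %.2f / het %.2f\n",
              x$genotype_probs[1], x$genotype_probs[2], x$genotype_probs[3]))
  cat(sprintf("  coverage ~ NB(mean %.0f, size %.1f), min %d\n",
              x$coverage$mean, x$coverage$size, x$coverage$min))
  cat(sprintf("  error %.3f (rho %.2f); ASE %.2f, AI %.2f; dup %.2f; strand %.2f\n",
              x$error_rate, x$error_overdispersion, x$ase_fraction,
              x$ai_fraction, x$dup_rate, x$strand_bias))
  invisible(x)
}

draw_skew <- function(n, law) {
  switch(law$law %||% "normal",
         normal   = rnorm(n, law$mean %||% 0, law$sd %||% 2.5),
         constant = rep(as.numeric(law$value %||% 2), n),
         uniform  = runif(n, law$min %||% -3, law$max %||% 3))
}

# Left-truncated negative binomial depths.
rtrunc_nbinom <- function(n, mean, size, min) {
  x <- rnbinom(n, mu = mean, size = size)
  for (i in 1:100) {
    low <- x < min
    if (!any(low)) return(x)
    x[low] <- rnbinom(sum(low), mu = mean, size = size)
  }
  x[x < min] <- min
  x
}

# Modal identical-alignment-position fraction among n supporting reads.
# Each read past the first is a PCR duplicate with probability dup_rate and
# then stacks on the position of a uniformly chosen original read.
sim_dup_modal <- function(n, dup_rate) {
  out <- rep(NA_real_, length(n))
  pos <- n > 0L
  if (dup_rate == 0) {
    out[pos] <- 1 / n[pos]
    return(out)
  }
  k <- integer(length(n))
  k[pos] <- rbinom(sum(pos), pmax(n[pos] - 1L, 0L), dup_rate)
  for (i in which(pos)) {
    if (k[i] == 0L) {
      out[i] <- 1 / n[i]
    } else {
      n_orig <- n[i] - k[i]
      stack <- tabulate(sample.int(n_orig, k[i], replace = TRUE), nbins = n_orig)
      out[i] <- (1 + max(stack)) / n[i]
    }
  }
  out
}

empty_wide_counts <- function(n) {
  df <- data.frame(cell_id = character(n), chrom = character(n),
                   pos = integer(n), stringsAsFactors = FALSE)
  for (nt in NTS) {
    df[[paste0(nt, "_fwd")]] <- integer(n)
    df[[paste0(nt, "_rev")]] <- integer(n)
  }
  for (nt in NTS) df[[paste0("dup_", nt)]] <- rep(NA_real_, n)
  df
}

# Core count sampler over per-(cell, locus) rows. `p_ref` is NA for homozygous
# rows; `genotype` in {hom_ref, hom_alt, het}.
sim_counts_core <- function(cell_id, loci, locus_idx, genotype, p_ref, cfg) {
  n <- length(cell_id)
  cov <- rtrunc_nbinom(n, cfg$coverage$mean, cfg$coverage$size,
                       cfg$coverage$min)
  ref_n <- integer(n)
  hom <- genotype != "het"
  if (any(hom)) {
    e <- if (cfg$error_overdispersion > 0) {
      rho <- cfg$error_overdispersion
      a <- cfg$error_rate * (1 - rho) / rho
      b <- (1 - cfg$error_rate) * (1 - rho) / rho
      rbeta(sum(hom), a, b)
    } else rep(cfg$error_rate, sum(hom))
    wrong <- rbinom(sum(hom), cov[hom], e)
    ref_hom <- ifelse(genotype[hom] == "hom_ref", cov[hom] - wrong, wrong)
    ref_n[hom] <- ref_hom
  }
  if (any(!hom)) ref_n[!hom] <- rbinom(sum(!hom), cov[!hom], p_ref[!hom])
  alt_n <- cov - ref_n
  ref_fwd <- rbinom(n, ref_n, cfg$strand_bias)
  alt_fwd <- rbinom(n, alt_n, cfg$strand_bias)

  df <- empty_wide_counts(n)
  df$cell_id <- cell_id
  df$chrom <- loci$chrom[locus_idx]
  df$pos <- loci$pos[locus_idx]
  cnt <- matrix(0L, n, 8L)  # A_fwd A_rev C_fwd C_rev G_fwd G_rev T_fwd T_rev
  ref_col <- (match(loci$ref[locus_idx], NTS) - 1L) * 2L
  alt_col <- (match(loci$alt[locus_idx], NTS) - 1L) * 2L
  rows <- seq_len(n)
  cnt[cbind(rows, ref_col + 1L)] <- ref_fwd
  cnt[cbind(rows, ref_col + 2L)] <- ref_n - ref_fwd
  cnt[cbind(rows, alt_col + 1L)] <- alt_fwd
  cnt[cbind(rows, alt_col + 2L)] <- alt_n - alt_fwd
  df[, 4:11] <- as.data.frame(cnt)
  dup <- matrix(NA_real_, n, 4L)
  dup[cbind(rows, match(loci$ref[locus_idx], NTS))] <-
    sim_dup_modal(ref_n, cfg$dup_rate)
  dup[cbind(rows, match(loci$alt[locus_idx], NTS))] <-
    sim_dup_modal(alt_n, cfg$dup_rate)
  df[, 12:15] <- as.data.frame(dup)
  df
}

sim_loci <- function(cfg) {
  n <- cfg$n_loci
  pos <- sort(sample.int(5e7, n))
  ref_i <- sample.int(4L, n, replace = TRUE)
  alt_i <- sample.int(3L, n, replace = TRUE)
  alt_i <- ifelse(alt_i >= ref_i, alt_i + 1L, alt_i)
  gene <- ceiling(seq_len(n) / 5)
  gene_strand <- sample(c("+", "-"), max(gene), replace = TRUE)
  data.frame(chrom = "chr1", pos = pos, ref = NTS[ref_i], alt = NTS[alt_i],
             gene_id = sprintf("g%05d", gene),
             tx_strand = gene_strand[gene], stringsAsFactors = FALSE)
}

sim_cell_meta <- function(cfg) {
  stage <- if (cfg$cells_per_embryo == 1L) "oocyte"
           else paste0(cfg$cells_per_embryo, "cell")
  emb <- rep(seq_len(cfg$n_embryos), each = cfg$cells_per_embryo)
  bla <- rep(seq_len(cfg$cells_per_embryo), times = cfg$n_embryos)
  data.frame(cell_id = sprintf("%s_E%d_B%d", stage, emb, bla),
             embryo_id = sprintf("E%d", emb),
             stage = stage, is_control = FALSE, stringsAsFactors = FALSE)
}

#' Simulate stranded allele counts for sister blastomeres
#'
#' Draws genotypes per embryo (sister cells share genotype at every locus),
#' true allelic skews for het loci (shared across sister cells except at
#' allelic-imbalance loci, whose skew is re-drawn independently per cell), and
#' per-cell strand-resolved allele counts with beta-binomial error on
#' homozygous loci, binomial strand assignment, and PCR-duplicate position
#' bookkeeping.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical seed and config give identical output.
#' @return A list with `counts` (wide per-(cell, locus) stranded counts; one
#'   column per nucleotide and strand, plus per-nucleotide modal duplicate
#'   fractions `dup_A` .. `dup_T`), `loci` (SNP annotation), `cells` (cell
#'   metadata), and `truth` (per cell and locus: true genotype, true log2
#'   skew, and whether the locus is imbalanced between sister cells).
#' @export
simulate_cells <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(as.integer(seed), {
    loci <- sim_loci(config)
    cells <- sim_cell_meta(config)
    n_emb <- config$n_embryos
    nl <- config$n_loci
    gp <- config$genotype_probs
    geno <- matrix(sample(names(gp), n_emb * nl, replace = TRUE, prob = gp),
                   nrow = n_emb)
    is_ai <- matrix(FALSE, n_emb, nl)
    shared_skew <- matrix(0, n_emb, nl)
    het <- geno == "het"
    if (any(het)) {
      u <- runif(sum(het))
      ai <- u < config$ai_fraction
      is_ai[het] <- ai
      skew_flag <- !ai & (runif(sum(het)) < config$ase_fraction)
      s <- numeric(sum(het))
      s[skew_flag] <- draw_skew(sum(skew_flag), config$ase_log2_skew)
      shared_skew[het] <- s
    }

    rows_cell <- rep(cells$cell_id, each = nl)
    rows_emb <- rep(match(cells$embryo_id, sprintf("E%d", seq_len(n_emb))),
                    each = nl)
    rows_loc <- rep(seq_len(nl), times = nrow(cells))
    idx <- cbind(rows_emb, rows_loc)
    g <- geno[idx]
    skew <- shared_skew[idx]
    ai_row <- is_ai[idx]
    if (any(ai_row)) skew[ai_row] <- draw_skew(sum(ai_row),
                                               config$ase_log2_skew)
    p_ref <- ifelse(g == "het", 2^skew / (1 + 2^skew), NA_real_)
    counts <- sim_counts_core(rows_cell, loci, rows_loc, g, p_ref, config)
    truth <- data.frame(
      embryo_id = sprintf("E%d", rows_emb), cell_id = rows_cell,
      chrom = loci$chrom[rows_loc], pos = loci$pos[rows_loc],
      genotype = g, log2_skew = ifelse(g == "het", skew, NA_real_),
      is_ai = ai_row, stringsAsFactors = FALSE)
    list(counts = counts, loci = loci, cells = cells, truth = truth,
         config = config)
  })
}

#' Configuration for near-homozygous control cells
#'
#' Rescales the genotype probabilities of a configuration so that all but
#' `het_residual` of the mass sits on the homozygous states, emulating an
#' embryonic-stem-cell line derived from a nearly inbred embryo.
#'
#' @param config A [sim_config()].
#' @param het_residual Residual heterozygous fraction (defaults to the
#'   configuration's `control_het_residual`).
#' @return A `sim_config` suitable for [simulate_control_cells()].
#' @export
control_config <- function(config, het_residual = NULL) {
  stopifnot(inherits(config, "sim_config"))
  het_residual <- assert_prob(het_residual %||% config$control_het_residual,
                              "het_residual")
  hom <- config$genotype_probs[c("hom_ref", "hom_alt")]
  hom <- hom / sum(hom) * (1 - het_residual)
  config$genotype_probs <- c(hom, het = het_residual)
  config
}

#' Simulate near-homozygous control cells for calibration
#'
#' All cells come from one genotype draw (one cell line), so every cell is
#' genotypically identical at every locus; counts are then drawn per cell
#' exactly as in [simulate_cells()]. The pooled minor-allele-frequency
#' distribution of these cells is the calibration substrate for
#' [calibrate_maf()].
#'
#' @param config A [sim_config()] whose `genotype_probs` put at least 0.99 of
#'   their mass on the homozygous states (see [control_config()]); a larger
#'   heterozygous mass triggers a warning because it degrades calibration.
#' @param n_cells Number of control cells.
#' @param seed Integer seed.
#' @return As [simulate_cells()]; `cells$is_control` is `TRUE` and residual
#'   het loci are balanced.
#' @export
simulate_control_cells <- function(config, n_cells = 12L, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  n_cells <- assert_count(n_cells, "n_cells")
  if (config$genotype_probs[["het"]] > 0.01)
    warning("control configuration has heterozygous mass > 0.01; ",
            "calibration from these cells may be invalid", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    loci <- sim_loci(config)
    nl <- config$n_loci
    gp <- config$genotype_probs
    geno <- sample(names(gp), nl, replace = TRUE, prob = gp)  # one line
    cells <- data.frame(cell_id = sprintf("ES_%02d", seq_len(n_cells)),
                        embryo_id = NA_character_, stage = "ES",
                        is_control = TRUE, stringsAsFactors = FALSE)
    rows_cell <- rep(cells$cell_id, each = nl)
    rows_loc <- rep(seq_len(nl), times = n_cells)
    g <- geno[rows_loc]
    p_ref <- ifelse(g == "het", 0.5, NA_real_)  # residual het loci balanced
    counts <- sim_counts_core(rows_cell, loci, rows_loc, g, p_ref, config)
    truth <- data.frame(
      embryo_id = NA_character_, cell_id = rows_cell,
      chrom = loci$chrom[rows_loc], pos = loci$pos[rows_loc],
      genotype = g, log2_skew = ifelse(g == "het", 0, NA_real_),
      is_ai = FALSE, stringsAsFactors = FALSE)
    list(counts = counts, loci = loci, cells = cells, truth = truth,
         config = config)
  })
}

#' Simulate 3'-biased transcript coverage with one or two poly(A) sites
#'
#' Expected coverage at transcript position x (orientation: positions increase
#' toward the 3' end) is the sum over isoforms of
#' `abundance_i * exp(-(end_i - x) / decay_length)` for `x <= end_i`, so reads
#' pile up near each 3' end and nearly vanish ~1.5 kb upstream; per-base
#' Poisson noise is drawn independently per cell. Canonical poly(A) hexamers
#' (AATAAA) are planted 20 nt upstream of true ends with the configured
#' probabilities.
#'
#' @param config A [sim_config()]; see the `utr` block.
#' @param seed Integer seed.
#' @param cell_ids Cells to draw tracks for; defaults to the configuration's
#'   blastomere layout.
#' @return A list with `coverage` (long data frame: `cell_id`,
#'   `transcript_id`, `pos` (1-based, transcript orientation), `count`),
#'   `truth` (per gene: number of isoforms, true end positions, true
#'   abundances, planted motif flags), and `sequences` (named character vector
#'   of transcript-orientation sequences for motif scanning).
#' @export
simulate_utr_coverage <- function(config, seed = 1L, cell_ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  up <- config$utr
  if (is.null(cell_ids)) cell_ids <- sim_cell_meta(config)$cell_id
  withr::with_seed(as.integer(seed), {
    ng <- assert_count(up$n_genes, "utr$n_genes")
    two <- runif(ng) < up$two_isoform_fraction
    prox <- round(runif(ng, up$proximal_range[1], up$proximal_range[2]))
    gap <- round(runif(ng, up$gap_range[1], up$gap_range[2]))
    dist <- prox + gap
    if (any(prox >= dist))
      stop_("proximal site must be strictly upstream of the distal site")
    len <- dist + up$margin
    prox_ab <- up$distal_abundance * up$abundance_ratio
    truth <- data.frame(
      transcript_id = sprintf("tx%04d", seq_len(ng)),
      n_isoforms = ifelse(two, 2L, 1L),
      proximal_end = ifelse(two, prox, NA_integer_),
      distal_end = dist,
      proximal_abundance = ifelse(two, prox_ab, NA_real_),
      distal_abundance = ifelse(two, up$distal_abundance, prox_ab),
      stringsAsFactors = FALSE)
    truth$cpsf_proximal <- two & (runif(ng) < up$cpsf_proximal_prob)
    truth$cpsf_distal <- runif(ng) < up$cpsf_distal_prob

    mu <- vector("list", ng)
    seqs <- character(ng)
    for (g in seq_len(ng)) {
      x <- seq_len(len[g])
      m <- truth$distal_abundance[g] *
        exp(-(truth$distal_end[g] - x) / up$decay_length)
      m[x > truth$distal_end[g]] <- 0
      if (two[g]) {
        mp <- prox_ab * exp(-(prox[g] - x) / up$decay_length)
        mp[x > prox[g]] <- 0
        m <- m + mp
      }
      mu[[g]] <- m
      s <- sample(NTS, len[g], replace = TRUE)
      plant <- function(end) {
        at <- end - 20L  # motif start 20 nt upstream of cleavage
        if (at >= 1 && at + 5L <= len[g])
          s[at:(at + 5L)] <<- c("A", "A", "T", "A", "A", "A")
      }
      if (two[g] && truth$cpsf_proximal[g]) plant(prox[g])
      if (truth$cpsf_distal[g]) plant(truth$distal_end[g])
      seqs[g] <- paste(s, collapse = "")
    }
    names(seqs) <- truth$transcript_id

    cov <- do.call(rbind, lapply(cell_ids, function(cid) {
      do.call(rbind, lapply(seq_len(ng), function(g) {
        data.frame(cell_id = cid, transcript_id = truth$transcript_id[g],
                   pos = seq_len(len[g]),
                   count = rpois(len[g], mu[[g]]),
                   stringsAsFactors = FALSE)
      }))
    }))
    list(coverage = cov, truth = truth, sequences = seqs, config = config)
  })
}

#' Simulate per-cell transcript counts for expression summaries
#'
#' True relative abundances are log-normal per transcript, perturbed slightly
#' per embryo; sister cells of one embryo share their true abundances exactly
#' and differ only by Poisson sampling at the configured depth.
#'
#' @param config A [sim_config()]; see the `expr` block.
#' @param seed Integer seed.
#' @return A list with `counts` (data frame: `transcript_id` plus one integer
#'   column per cell), `cells` (metadata) and `truth` (true per-embryo RPM).
#' @export
simulate_expression <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  ep <- config$expr
  withr::with_seed(as.integer(seed), {
    cells <- sim_cell_meta(config)
    nt <- assert_count(ep$n_transcripts, "expr$n_transcripts")
    base <- 2^rnorm(nt, 0, ep$log2_sd)
    emb <- unique(cells$embryo_id)
    lambda <- sapply(emb, function(e) base * 2^rnorm(nt, 0, ep$embryo_log2_sd))
    lambda <- sweep(lambda, 2, colSums(lambda), "/")
    counts <- data.frame(transcript_id = sprintf("tx%05d", seq_len(nt)),
                         stringsAsFactors = FALSE)
    for (i in seq_len(nrow(cells)))
      counts[[cells$cell_id[i]]] <-
        rpois(nt, ep$depth * lambda[, match(cells$embryo_id[i], emb)])
    truth <- data.frame(transcript_id = counts$transcript_id,
                        lambda[, match(cells$embryo_id, emb), drop = FALSE])
    names(truth)[-1] <- cells$cell_id
    list(counts = counts, cells = cells, truth = truth, config = config)
  })
}
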