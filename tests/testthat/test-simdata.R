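# The generator must honour its degenerate cases exactly, be reproducible
# under a fixed seed, and match brute-force recounts of its own output.

test_that("zero-error homozygous simulation has no minor alleles", {
  cfg <- sim_config(n_loci = 300, n_embryos = 1, cells_per_embryo = 1,
                    genotype_probs = c(hom_ref = 1, hom_alt = 0, het = 0),
                    error_rate = 0, error_overdispersion = 0)
  s <- simulate_cells(cfg, seed = 1)
  ac <- allelic_ratio(s$counts, s$loci)
  expect_true(all(ac$alt_count == 0))
  expect_true(all(minor_allele_frequency(s$counts, s$loci) == 0))
})

test_that("the same seed and config reproduce the count table exactly", {
  cfg <- sim_config(n_loci = 200)
  a <- simulate_cells(cfg, seed = 77)
  b <- simulate_cells(cfg, seed = 77)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  c <- simulate_cells(cfg, seed = 78)
  expect_false(identical(a$counts, c$counts))
})

test_that("constant log2 skew 2 is recovered in the mean at high coverage", {
  cfg <- het_cell_config(2000, ase_fraction = 1,
                         skew_law = list(law = "constant", value = 2),
                         coverage = list(mean = 200, size = 10, min = 100))
  s <- simulate_cells(cfg, seed = 5)
  # brute-force average of observed log2(ref/alt) over all loci
  ac <- allelic_ratio(s$counts, s$loci)
  obs <- log2(ac$ref_count / ac$alt_count)
  expect_true(all(is.finite(obs)))
  expect_lt(abs(mean(obs) - 2), 0.05)
})

test_that("read counts are conserved: all reads carry an annotated allele", {
  cfg <- sim_config(n_loci = 150)
  s <- simulate_cells(cfg, seed = 3)
  nt_cols <- as.vector(outer(c("A", "C", "G", "T"), c("fwd", "rev"),
                             paste, sep = "_"))
  total <- rowSums(s$counts[, nt_cols])
  ac <- allelic_ratio(s$counts, s$loci)
  expect_equal(total, ac$ref_count + ac$alt_count)
})

test_that("sister cells share genotype and non-AI skew in truth", {
  cfg <- sim_config(n_loci = 400, n_embryos = 2, cells_per_embryo = 2)
  s <- simulate_cells(cfg, seed = 9)
  tr <- s$truth
  for (emb in unique(tr$embryo_id)) {
    te <- tr[tr$embryo_id == emb, ]
    g <- tapply(te$genotype, te$pos, function(v) length(unique(v)))
    expect_true(all(g == 1))
    sk <- te[!te$is_ai & te$genotype == "het", ]
    spread <- tapply(sk$log2_skew, sk$pos, function(v) diff(range(v)))
    expect_true(all(spread == 0))
  }
})

test_that("control cells share one genotype draw and obey the error law", {
  cfg0 <- control_config(sim_config(n_loci = 300, error_rate = 0,
                                    error_overdispersion = 0),
                         het_residual = 0)
  s0 <- simulate_control_cells(cfg0, n_cells = 12, seed = 2)
  g <- tapply(s0$truth$genotype, s0$truth$pos,
              function(v) length(unique(v)))
  expect_true(all(g == 1))
  expect_true(all(minor_allele_frequency(s0$counts, s0$loci) == 0))

  # with error: pipeline count of high-MAF loci equals a brute-force recount
  cfg1 <- control_config(sim_config(n_loci = 400), het_residual = 0)
  s1 <- simulate_control_cells(cfg1, n_cells = 12, seed = 4)
  maf <- minor_allele_frequency(s1$counts, s1$loci)
  nt_cols <- as.vector(outer(c("A", "C", "G", "T"), c("fwd", "rev"),
                             paste, sep = "_"))
  cov <- rowSums(s1$counts[, nt_cols])
  # independent recount from the raw wide table
  idx <- match(paste(s1$counts$chrom, s1$counts$pos),
               paste(s1$loci$chrom, s1$loci$pos))
  brute <- mapply(function(i, r) {
    ref <- s1$loci$ref[r]; alt <- s1$loci$alt[r]
    rn <- s1$counts[[paste0(ref, "_fwd")]][i] +
      s1$counts[[paste0(ref, "_rev")]][i]
    an <- s1$counts[[paste0(alt, "_fwd")]][i] +
      s1$counts[[paste0(alt, "_rev")]][i]
    min(rn, an) / (rn + an)
  }, seq_len(nrow(s1$counts)), idx)
  expect_identical(sum(maf[cov >= 25] > 0.066),
                   sum(brute[cov >= 25] > 0.066))
})

test_that("control simulation warns when the config is not near-homozygous", {
  cfg <- sim_config(n_loci = 120)
  expect_warning(simulate_control_cells(cfg, n_cells = 2, seed = 1),
                 "heterozygous mass")
  expect_silent(simulate_control_cells(control_config(cfg), n_cells = 2,
                                       seed = 1))
})

test_that("strand balance concentrates near 1 at high coverage regardless of skew", {
  cfg <- het_cell_config(400, ase_fraction = 1,
                         skew_law = list(law = "constant", value = 3),
                         coverage = list(mean = 700, size = 10, min = 500))
  s <- simulate_cells(cfg, seed = 21)
  b <- strand_balance(s$counts, s$loci)
  expect_lt(median(abs(log2(b))), 0.1)
  expect_gt(mean(abs(log2(b)) < 0.3), 0.99)
})

test_that("invalid configurations are rejected with the parameter named", {
  expect_error(sim_config(genotype_probs = c(hom_ref = 0.5, hom_alt = 0.5,
                                             het = 0.1)),
               "genotype_probs")
  expect_error(sim_config(error_rate = 1.5), "error_rate")
  expect_error(sim_config(dup_rate = -0.1), "dup_rate")
  expect_error(sim_config(ase_log2_skew = list(law = "cauchy")),
               "ase_log2_skew")
  expect_error(sim_config(utr = list(gap_range = c(-5, 10))), "gap_range")
})

test_that("duplicate bookkeeping responds to the duplicate rate", {
  cfg_hi <- sim_config(n_loci = 200, dup_rate = 0.9)
  cfg_lo <- sim_config(n_loci = 200, dup_rate = 0)
  hi <- simulate_cells(cfg_hi, seed = 6)$counts
  lo <- simulate_cells(cfg_lo, seed = 6)$counts
  dup_hi <- unlist(hi[paste0("dup_", c("A", "C", "G", "T"))])
  dup_lo <- unlist(lo[paste0("dup_", c("A", "C", "G", "T"))])
  # more duplication stacks more reads on the modal position
  expect_gt(mean(dup_hi, na.rm = TRUE), 2 * mean(dup_lo, na.rm = TRUE))
  # without duplicates every read has its own position: modal fraction 1/n
  nt_cols <- as.vector(outer(c("A", "C", "G", "T"), c("fwd", "rev"),
                             paste, sep = "_"))
  ref_alt_n <- rowSums(lo[, nt_cols])
  expect_true(all(abs(apply(
    lo[paste0("dup_", c("A", "C", "G", "T"))], 1,
    function(v) max(1 / v, na.rm = TRUE)) <= ref_alt_n + 1e-9)))
})

test_that("two-isoform coverage matches the closed-form decay sum", {
  cfg <- sim_config(utr = list(n_genes = 6, two_isoform_fraction = 1,
                               abundance_ratio = 5, distal_abundance = 1))
  u <- simulate_utr_coverage(cfg, seed = 8, cell_ids = "c1")
  up <- cfg$utr
  for (g in seq_len(3)) {
    t1 <- u$truth[g, ]
    cc <- u$coverage[u$coverage$transcript_id == t1$transcript_id, ]
    mu_at <- function(x) {
      m <- t1$distal_abundance * exp(-(t1$distal_end - x) / up$decay_length)
      m[x > t1$distal_end] <- 0
      mp <- t1$proximal_abundance *
        exp(-(t1$proximal_end - x) / up$decay_length)
      mp[x > t1$proximal_end] <- 0
      m + mp
    }
    # mean observed coverage just upstream of each site vs analytic mean
    for (end in c(t1$proximal_end, t1$distal_end)) {
      win <- (end - 99):end
      analytic <- mean(mu_at(win))
      observed <- mean(cc$count[match(win, cc$pos)])
      tol <- 3 * sqrt(analytic / 100)  # Poisson SE of the window mean
      expect_lt(abs(observed - analytic), tol + 1e-9)
    }
    # nothing beyond the annotated distal end
    expect_true(all(cc$count[cc$pos > t1$distal_end] == 0))
  }
})

test_that("single-isoform genes show one ramp ending at the annotated end", {
  cfg <- sim_config(utr = list(n_genes = 5, two_isoform_fraction = 0))
  u <- simulate_utr_coverage(cfg, seed = 10, cell_ids = "c1")
  expect_true(all(u$truth$n_isoforms == 1L))
  t1 <- u$truth[1, ]
  cc <- u$coverage[u$coverage$transcript_id == t1$transcript_id, ]
  expect_true(all(cc$count[cc$pos > t1$distal_end] == 0))
  expect_gt(mean(cc$count[cc$pos <= t1$distal_end &
                            cc$pos > t1$distal_end - 100]), 1)
  expect_identical(simulate_utr_coverage(cfg, seed = 10, cell_ids = "c1")$coverage,
                   u$coverage)
})
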