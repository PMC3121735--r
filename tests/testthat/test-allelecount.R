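# Counting, the five selection criteria, MAF and allelic-ratio arithmetic.

test_that("count_alleles tallies reads by nucleotide and strand", {
  loci <- one_locus()
  obs <- data.frame(cell_id = "c1", chrom = "chr1", pos = 100L,
                    nt = rep("A", 30), strand = "+",
                    aln_start = 70 + seq_len(30), stringsAsFactors = FALSE)
  w <- count_alleles(obs, loci)
  expect_equal(w$A_fwd, 30L)
  expect_equal(sum(w[, c("A_rev", "C_fwd", "C_rev", "G_fwd", "G_rev",
                         "T_fwd", "T_rev")]), 0)
  expect_equal(w$dup_A, 1 / 30)
})

test_that("reads stacked at one alignment position give dup fraction 1", {
  loci <- one_locus()
  obs <- data.frame(cell_id = "c1", chrom = "chr1", pos = 100L,
                    nt = rep("G", 10), strand = "+", aln_start = 77L,
                    stringsAsFactors = FALSE)
  w <- count_alleles(obs, loci)
  expect_equal(w$dup_G, 1.0)
})

test_that("count_alleles matches an independent brute-force tally", {
  set.seed(11)
  loci <- data.frame(chrom = "chr1", pos = c(100L, 250L, 400L),
                     ref = c("A", "C", "T"), alt = c("G", "T", "A"),
                     stringsAsFactors = FALSE)
  n <- 500
  obs <- data.frame(
    cell_id = sample(c("c1", "c2"), n, TRUE),
    chrom = "chr1", pos = sample(loci$pos, n, TRUE),
    nt = sample(c("A", "C", "G", "T"), n, TRUE),
    strand = sample(c("+", "-"), n, TRUE),
    aln_start = sample(50:120, n, TRUE), stringsAsFactors = FALSE)
  w <- count_alleles(obs, loci)
  for (r in seq_len(nrow(w))) {
    sub <- obs[obs$cell_id == w$cell_id[r] & obs$pos == w$pos[r], ]
    for (nt in c("A", "C", "G", "T")) {
      expect_equal(w[[paste0(nt, "_fwd")]][r],
                   sum(sub$nt == nt & sub$strand == "+"))
      expect_equal(w[[paste0(nt, "_rev")]][r],
                   sum(sub$nt == nt & sub$strand == "-"))
      if (any(sub$nt == nt))
        expect_equal(w[[paste0("dup_", nt)]][r],
                     max(table(sub$aln_start[sub$nt == nt])) /
                       sum(sub$nt == nt))
    }
  }
  # observations at unannotated positions are ignored with a message
  obs2 <- rbind(obs, data.frame(cell_id = "c1", chrom = "chr1", pos = 999L,
                                nt = "A", strand = "+", aln_start = 1L))
  expect_message(w2 <- count_alleles(obs2, loci), "unannotated")
  expect_identical(w2, w)
})

test_that("selection criteria fire individually", {
  loci <- one_locus()
  # criterion 3: 24 reads fail, 25 pass
  expect_false(select_loci(wide_row(ref_fwd = 12, ref_rev = 7, alt_fwd = 5),
                           loci)$crit3)
  expect_true(select_loci(wide_row(ref_fwd = 12, ref_rev = 8, alt_fwd = 5),
                          loci)$crit3)
  # criterion 1: a single observed nucleotide is homozygous-like
  f <- select_loci(wide_row(ref_fwd = 20, ref_rev = 20), loci)
  expect_false(f$crit1)
  expect_false(f$passed)
  # criterion 4: 60% of alt reads at one identical position fails,
  # exactly 50% passes
  expect_false(select_loci(wide_row(ref_fwd = 20, ref_rev = 20,
                                    alt_fwd = 10, dup_alt = 0.6),
                           loci)$crit4)
  expect_true(select_loci(wide_row(ref_fwd = 20, ref_rev = 20,
                                   alt_fwd = 10, dup_alt = 0.5),
                          loci)$crit4)
  # criterion 2: an unannotated nucleotide as second-most frequent fails
  expect_false(select_loci(wide_row(ref_fwd = 30, alt_fwd = 2,
                                    extra = list(C_fwd = 5L)),
                           loci)$crit2)
  expect_true(select_loci(wide_row(ref_fwd = 30, alt_fwd = 6,
                                   extra = list(C_fwd = 5L)),
                          loci)$crit2)
  # criterion 5: both-strand transcription excludes the locus
  expect_false(select_loci(wide_row(ref_fwd = 20, alt_fwd = 20),
                           one_locus(tx_strand = "conflict"))$crit5)
  # all five together
  all_ok <- select_loci(wide_row(ref_fwd = 10, ref_rev = 10, alt_fwd = 5,
                                 alt_rev = 5, dup_ref = 0.2, dup_alt = 0.3),
                        loci)
  expect_true(all(unlist(all_ok[, c("crit1", "crit2", "crit3", "crit4",
                                    "crit5", "passed")])))
})

test_that("coverage criterion is monotone: adding observed-allele reads never unselects", {
  loci <- one_locus()
  set.seed(42)
  for (i in 1:25) {
    rf <- sample(0:30, 1); rr <- sample(0:30, 1)
    af <- sample(0:30, 1); ar <- sample(0:30, 1)
    base <- select_loci(wide_row(ref_fwd = rf, ref_rev = rr,
                                 alt_fwd = af, alt_rev = ar), loci)
    more <- select_loci(wide_row(ref_fwd = rf + sample(1:20, 1),
                                 ref_rev = rr, alt_fwd = af,
                                 alt_rev = ar + sample(1:20, 1)), loci)
    if (base$crit3) expect_true(more$crit3)
  }
})

test_that("minor allele frequency is the spec arithmetic on raw counts", {
  loci <- one_locus()
  expect_equal(minor_allele_frequency(wide_row(ref_fwd = 25), loci), 0)
  expect_equal(minor_allele_frequency(
    wide_row(ref_fwd = 10, ref_rev = 10, alt_fwd = 20), loci), 0.5)
  expect_equal(minor_allele_frequency(
    wide_row(ref_fwd = 47, alt_fwd = 3), loci), 0.06)
  expect_error(minor_allele_frequency(wide_row(), loci), "zero coverage")
  # range property on simulated data
  s <- simulate_cells(sim_config(n_loci = 300), seed = 13)
  maf <- minor_allele_frequency(s$counts, s$loci)
  expect_true(all(maf >= 0 & maf <= 0.5))
})

test_that("allelic ratio applies the pseudocount only to the reported ratio", {
  loci <- one_locus()
  r <- allelic_ratio(wide_row(ref_fwd = 5, ref_rev = 5, alt_fwd = 10), loci)
  expect_equal(r$ratio, 1.0)
  expect_equal(r$raw_ratio, 1.0)
  r <- allelic_ratio(wide_row(ref_fwd = 25), loci)
  expect_equal(r$ratio, 26.0)
  expect_true(is.na(r$raw_ratio))
  r <- allelic_ratio(wide_row(ref_fwd = 30, alt_fwd = 10), loci)
  expect_equal(r$raw_ratio, 3.0)
  expect_equal(r$ratio, 31 / 11)
})
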