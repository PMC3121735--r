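# File formats: allele-count TSV, SNP tables (VCF-like / TSV), BED-lite,
# bedGraph, cell metadata, SAM-derived observations, result bundles.

test_that("allele counts survive a write/read round trip exactly", {
  s <- simulate_cells(sim_config(n_loci = 80), seed = 17)
  path <- tempfile(fileext = ".tsv")
  write_allele_counts(s$counts, path)
  back <- read_allele_counts(path)
  o <- order(s$counts$cell_id, s$counts$chrom, s$counts$pos)
  orig <- s$counts[o, ]
  rownames(orig) <- NULL
  expect_equal(back, orig)
  # gzip-transparent
  gz <- tempfile(fileext = ".tsv.gz")
  write_allele_counts(s$counts, gz)
  expect_equal(read_allele_counts(gz), orig)
})

test_that("malformed allele-count rows are rejected with a line number", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("cell_id\tchrom\tpos\tnt\tstrand\tcount\tmax_dup_frac",
               "c1\tchr1\t100\tA\t+\t10\t0.1",
               "c1\tchr1\t101\tG\t+\t-1\t0.1"), path)
  expect_error(read_allele_counts(path), "line 3")
  writeLines(c("cell_id\tchrom\tpos\tnt\tstrand\tcount\tmax_dup_frac",
               "c1\tchr1\t100\tN\t+\t10\t0.1"), path)
  expect_error(read_allele_counts(path), "nucleotide")
  writeLines(c("cell_id\tchrom\tpos\tnt\tcount", "c1\tchr1\t100\tA\t10"),
             path)
  expect_error(read_allele_counts(path), "lacks column")
  # well-formed three-row file parses to records
  writeLines(c("cell_id\tchrom\tpos\tnt\tstrand\tcount\tmax_dup_frac",
               "c1\tchr1\t100\tA\t+\t10\t0.1",
               "c1\tchr1\t100\tG\t-\t5\t0.2",
               "c1\tchr1\t200\tC\t+\t7\t0.3"), path)
  w <- read_allele_counts(path)
  expect_equal(nrow(w), 2L)      # two (cell, locus) records
  expect_equal(w$A_fwd[1], 10L)
  expect_equal(w$G_rev[1], 5L)
})

test_that("VCF-like and TSV dialects of the same loci parse identically", {
  loci <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                     pos = c(100L, 250L, 40L),
                     ref = c("A", "C", "T"), alt = c("G", "T", "A"),
                     stringsAsFactors = FALSE)
  v <- tempfile(fileext = ".vcf"); t <- tempfile(fileext = ".tsv")
  write_snp_table(loci, v, dialect = "vcf")
  write_snp_table(loci, t, dialect = "tsv")
  from_vcf <- read_snp_table(v)
  from_tsv <- read_snp_table(t)
  expect_equal(from_vcf, from_tsv[, c("chrom", "pos", "ref", "alt")])
})

test_that("invalid SNP tables are rejected", {
  t <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt", "chr1\t100\tA\tG",
               "chr1\t100\tC\tT"), t)
  expect_error(read_snp_table(t), "chr1:100")
  writeLines(c("chrom\tpos\tref\talt", "chr1\t100\tA\tA"), t)
  expect_error(read_snp_table(t), "identical")
  writeLines(c("chrom\tpos\tref\talt", "chr1\t100\tA\tN"), t)
  expect_error(read_snp_table(t), "non-ACGT")
})

test_that("BED-lite gene annotation round-trips through the 0-based boundary", {
  genes <- data.frame(chrom = c("chr1", "chr1"), start = c(1L, 500L),
                      end = c(400L, 900L), gene_id = c("gA", "gB"),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".bed")
  write_gene_bed(genes, path)
  # on disk: 0-based half-open starts
  raw <- read.delim(path, header = FALSE)
  expect_equal(raw$V2, c(0L, 499L))
  expect_equal(raw$V3, c(400L, 900L))
  back <- read_gene_bed(path)
  expect_equal(back, genes)
})

test_that("bedGraph coverage round-trips per base", {
  cov <- data.frame(cell_id = "c1",
                    transcript_id = rep(c("tx1", "tx2"), c(30, 20)),
                    pos = c(1:30, 1:20),
                    count = c(rep(c(4, 0, 2), each = 10), rep(1:2, 10)),
                    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".bedgraph")
  write_bedgraph(cov, path)
  back <- read_bedgraph(path, cell_id = "c1")
  o <- order(cov$transcript_id, cov$pos)
  expect_equal(back$count[order(back$transcript_id, back$pos)],
               as.numeric(cov$count[o]))
})

test_that("cell metadata validation enforces uniqueness and control pairing", {
  cells <- data.frame(cell_id = c("b1", "b2", "es1"),
                      embryo_id = c("E1", "E1", NA),
                      stage = c("2cell", "2cell", "ES"),
                      is_control = c(FALSE, FALSE, TRUE),
                      stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_cell_meta(cells, path)
  expect_equal(read_cell_meta(path), cells)
  bad <- cells; bad$cell_id[2] <- "b1"
  write_cell_meta(bad, path)
  expect_error(read_cell_meta(path), "duplicate")
  bad <- cells; bad$embryo_id[3] <- "E9"
  write_cell_meta(bad, path)
  expect_error(read_cell_meta(path), "control")
})

test_that("gene annotation joins assign transcribed strand and conflicts", {
  loci <- data.frame(chrom = "chr1", pos = c(50L, 150L, 950L),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  genes <- data.frame(chrom = "chr1", start = c(1L, 100L, 100L),
                      end = c(200L, 300L, 250L),
                      gene_id = c("gP", "gM", "gM2"),
                      strand = c("+", "-", "-"), stringsAsFactors = FALSE)
  ann <- annotate_loci(loci, genes)
  expect_equal(ann$tx_strand, c("+", "conflict", NA))
  expect_equal(ann$gene_id[1], "gP")
  expect_true(is.na(ann$gene_id[3]))
})

test_that("SAM records yield per-read observations through the CIGAR walk", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:chr1\tLN:10000",
    # 50M read covering pos 100 with A at offset 21
    paste("r1", 0, "chr1", 80, 60, "50M", "*", 0, 0,
          paste0(strrep("C", 20), "A", strrep("C", 29)),
          strrep("I", 50), sep = "\t"),
    # reverse-strand read, G at pos 100 (offset 11)
    paste("r2", 16, "chr1", 90, 60, "50M", "*", 0, 0,
          paste0(strrep("T", 10), "G", strrep("T", 39)),
          strrep("I", 50), sep = "\t"),
    # soft-clipped: 5S45M starting at 98; pos 100 is query offset 5+3
    paste("r3", 0, "chr1", 98, 60, "5S45M", "*", 0, 0,
          paste0("NNNNN", "CC", "A", strrep("C", 42)),
          strrep("I", 50), sep = "\t"),
    # deletion spanning pos 100: contributes nothing
    paste("r4", 0, "chr1", 95, 60, "4M10D46M", "*", 0, 0,
          strrep("G", 50), strrep("I", 50), sep = "\t"),
    # duplicate of r1 at the same alignment start
    paste("r5", 0, "chr1", 80, 60, "50M", "*", 0, 0,
          paste0(strrep("C", 20), "A", strrep("C", 29)),
          strrep("I", 50), sep = "\t")),
    sam)
  loci <- one_locus(pos = 100L)
  obs <- read_sam_observations(sam, loci, cell_id = "c1")
  expect_equal(nrow(obs), 4L)                    # r4 drops out
  expect_equal(sort(obs$nt), c("A", "A", "A", "G"))
  expect_equal(obs$strand[obs$nt == "G"], "-")
  w <- count_alleles(obs, loci)
  expect_equal(w$A_fwd, 3L)
  expect_equal(w$G_rev, 1L)
  expect_equal(w$dup_A, 2 / 3)                   # r1 and r5 share a start
})

test_that("result bundles refuse to write when a stage is missing", {
  res <- list(ase_calls = data.frame(), ai_calls = data.frame(),
              summary = data.frame())
  expect_error(write_results(res, tempfile()), "utr_consensus")
  res$utr_consensus <- data.frame(transcript_id = character(),
                                  end = integer())
  out <- tempfile()
  paths <- write_results(res, out)
  expect_true(all(file.exists(paths)))
  # header-only file for the empty UTR table
  expect_equal(readLines(paths[["utr_consensus"]]), "transcript_id\tend")
})
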