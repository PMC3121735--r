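# Readers and writers for every external representation the pipeline touches.
#
# Conventions: VCF-like SNP tables and the pileup-style allele-count TSV are
# 1-based; BED-lite gene annotation and bedGraph are 0-based half-open and
# converted at this boundary only. Alleles are always expressed on the
# reference strand; the strand of a read observation is its alignment strand.
# All TSVs are tab-delimited UTF-8 with a header line, and readers are
# gzip-transparent.

open_out <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
}

write_tsv <- function(df, path) {
  con <- open_out(path)
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read / write the stranded allele-count table
#'
#' The on-disk format is long: one row per (cell, locus, nucleotide, strand)
#' with a positive read count, columns `cell_id`, `chrom`, `pos` (1-based),
#' `nt` (A/C/G/T), `strand` (`+`/`-`), `count`, `max_dup_frac` (the modal
#' identical-alignment-position fraction of the reads supporting that
#' nucleotide, strands pooled). In memory the package uses the wide
#' per-(cell, locus) form (`A_fwd` .. `T_rev`, `dup_A` .. `dup_T`).
#'
#' @param path TSV file (optionally gzip-compressed).
#' @return `read_allele_counts()` returns the wide counts data frame, rows
#'   ordered by cell, chrom, pos.
#' @export
read_allele_counts <- function(path) {
  if (!file.exists(path)) stop_("allele-count file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "chrom", "pos", "nt", "strand", "count",
            "max_dup_frac")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_("allele-count file lacks column(s): ", paste(miss, collapse = ", "))
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- which(!df$nt %in% NTS)
  if (length(bad))
    stop_(sprintf("unknown nucleotide '%s' at line %d of %s",
                  df$nt[bad[1]], line[bad[1]], path))
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad))
    stop_(sprintf("invalid strand '%s' at line %d of %s",
                  df$strand[bad[1]], line[bad[1]], path))
  bad <- which(!is.finite(df$count) | df$count < 0 |
                 df$count != floor(df$count))
  if (length(bad))
    stop_(sprintf("count must be a non-negative integer at line %d of %s",
                  line[bad[1]], path))
  bad <- which(!is.na(df$max_dup_frac) &
                 (df$max_dup_frac < 0 | df$max_dup_frac > 1))
  if (length(bad))
    stop_(sprintf("max_dup_frac outside [0, 1] at line %d of %s",
                  line[bad[1]], path))
  counts_long_to_wide(df)
}

#' @rdname read_allele_counts
#' @param counts Wide stranded counts (e.g. from [simulate_cells()]).
#' @export
write_allele_counts <- function(counts, path) {
  write_tsv(counts_wide_to_long(counts), path)
}

#' Convert stranded allele counts between long (file) and wide (working) form
#'
#' @param long,wide The two representations; see [read_allele_counts()].
#' @return The other representation. Only rows with positive counts are kept
#'   in the long form.
#' @export
counts_wide_to_long <- function(wide) {
  rows <- list()
  for (nt in NTS) for (st in c("fwd", "rev")) {
    cnt <- wide[[paste0(nt, "_", st)]]
    keep <- cnt > 0L
    if (!any(keep)) next
    rows[[paste0(nt, st)]] <- data.frame(
      cell_id = wide$cell_id[keep], chrom = wide$chrom[keep],
      pos = wide$pos[keep], nt = nt,
      strand = if (st == "fwd") "+" else "-",
      count = cnt[keep],
      max_dup_frac = wide[[paste0("dup_", nt)]][keep],
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(cell_id = character(), chrom = character(),
                      pos = integer(), nt = character(),
                      strand = character(), count = integer(),
                      max_dup_frac = numeric(), stringsAsFactors = FALSE))
  long <- do.call(rbind, rows)
  long <- long[order(long$cell_id, long$chrom, long$pos, long$nt,
                     long$strand), , drop = FALSE]
  rownames(long) <- NULL
  long
}

#' @rdname counts_wide_to_long
#' @export
counts_long_to_wide <- function(long) {
  key <- paste(long$cell_id, long$chrom, long$pos, sep = "\r")
  first <- !duplicated(key)
  wide <- empty_wide_counts(sum(first))
  wide$cell_id <- long$cell_id[first]
  wide$chrom <- long$chrom[first]
  wide$pos <- as.integer(long$pos[first])
  row <- match(key, key[first])
  col <- match(paste0(long$nt, "_", ifelse(long$strand == "+", "fwd", "rev")),
               names(wide))
  for (j in seq_along(row))
    wide[[col[j]]][row[j]] <- wide[[col[j]]][row[j]] + as.integer(long$count[j])
  dup_col <- match(paste0("dup_", long$nt), names(wide))
  for (j in seq_along(row))
    wide[[dup_col[j]]][row[j]] <- long$max_dup_frac[j]
  o <- order(wide$cell_id, wide$chrom, wide$pos)
  wide <- wide[o, , drop = FALSE]
  rownames(wide) <- NULL
  wide
}

validate_snp_table <- function(loci, origin) {
  if (any(!loci$ref %in% NTS | !loci$alt %in% NTS))
    stop_("non-ACGT allele in SNP table ", origin)
  if (any(loci$ref == loci$alt))
    stop_("ref and alt alleles identical in SNP table ", origin)
  if (any(loci$pos < 1))
    stop_("positions must be 1-based (>= 1) in SNP table ", origin)
  dup <- duplicated(locus_key(loci$chrom, loci$pos))
  if (any(dup))
    stop_("duplicate SNP position(s): ",
          paste(head(locus_key(loci$chrom, loci$pos)[dup], 5),
                collapse = ", "))
  rownames(loci) <- NULL
  loci
}

#' Read / write the SNP annotation table
#'
#' Two dialects describe the same loci: a VCF-like file (parsed with
#' \pkg{vcfR}; CHROM, POS, REF, ALT used, other fields ignored) and a plain
#' TSV with columns `chrom`, `pos`, `ref`, `alt` and optionally `gene_id`,
#' `tx_strand`. Both are 1-based and parse to identical collections.
#'
#' @param path File path.
#' @param dialect `"auto"` (by extension/content), `"vcf"` or `"tsv"`.
#' @return Data frame with `chrom`, `pos`, `ref`, `alt` (+ `gene_id`,
#'   `tx_strand` when present); duplicate positions, identical alleles and
#'   non-ACGT alleles are rejected.
#' @export
read_snp_table <- function(path, dialect = c("auto", "vcf", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_("SNP table not found: ", path)
  if (dialect == "auto") {
    first <- readLines(path, n = 1L)
    dialect <- if (grepl("^##fileformat=VCF", first) ||
                   grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (dialect == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    loci <- data.frame(chrom = fix[, "CHROM"],
                       pos = as.integer(fix[, "POS"]),
                       ref = fix[, "REF"], alt = fix[, "ALT"],
                       stringsAsFactors = FALSE)
  } else {
    loci <- read.delim(path, stringsAsFactors = FALSE)
    assert_df_cols(loci, c("chrom", "pos", "ref", "alt"), basename(path))
    loci$pos <- as.integer(loci$pos)
  }
  validate_snp_table(loci, basename(path))
}

#' @rdname read_snp_table
#' @param loci SNP annotation data frame.
#' @export
write_snp_table <- function(loci, path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  loci <- validate_snp_table(loci, "to be written")
  if (dialect == "tsv") return(write_tsv(loci, path))
  con <- open_out(path)
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", loci$chrom, loci$pos,
                     loci$ref, loci$alt), con)
  invisible(path)
}

#' Read / write BED-lite gene annotation
#'
#' Six-column BED (0-based half-open on disk, via \pkg{rtracklayer});
#' returned 1-based with columns `chrom`, `start`, `end`, `gene_id`,
#' `strand`.
#'
#' @param path BED file.
#' @return Data frame as described.
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) stop_("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             gene_id = gr$name %||% sprintf("gene%05d", seq_along(gr)),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' @rdname read_gene_bed
#' @param genes Data frame with `chrom`, `start`, `end` (1-based closed),
#'   `gene_id`, `strand`.
#' @export
write_gene_bed <- function(genes, path) {
  assert_df_cols(genes, c("chrom", "start", "end", "gene_id", "strand"),
                 "genes")
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand)
  gr$name <- genes$gene_id
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read / write per-base coverage as bedGraph
#'
#' The bedGraph "chromosome" is the transcript id (tracks live in transcript
#' coordinates, 0-based half-open on disk). Runs of equal coverage are
#' compressed on write and expanded to per-base rows on read.
#'
#' @param path bedGraph file.
#' @param cell_id Cell the track belongs to (bedGraph stores one cell).
#' @return `read_bedgraph()` returns a long coverage data frame (`cell_id`,
#'   `transcript_id`, `pos` 1-based, `count`).
#' @export
read_bedgraph <- function(path, cell_id = "cell") {
  if (!file.exists(path)) stop_("bedGraph file not found: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  n <- GenomicRanges::width(gr)
  data.frame(cell_id = cell_id,
             transcript_id = rep(as.character(GenomicRanges::seqnames(gr)), n),
             pos = unlist(lapply(seq_along(gr), function(i)
               seq(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i]))),
             count = rep(gr$score, n),
             stringsAsFactors = FALSE)
}

#' @rdname read_bedgraph
#' @param coverage Long coverage data frame of one cell.
#' @export
write_bedgraph <- function(coverage, path) {
  assert_df_cols(coverage, c("transcript_id", "pos", "count"), "coverage")
  if ("cell_id" %in% names(coverage) &&
      length(unique(coverage$cell_id)) > 1L)
    stop_("a bedGraph stores one cell; subset 'coverage' first")
  o <- order(coverage$transcript_id, coverage$pos)
  tx <- coverage$transcript_id[o]; pos <- coverage$pos[o]
  val <- coverage$count[o]
  new_run <- c(TRUE, tx[-1] != tx[-length(tx)] |
                 pos[-1] != pos[-length(pos)] + 1L |
                 val[-1] != val[-length(val)])
  run_id <- cumsum(new_run)
  start <- tapply(pos, run_id, min); end <- tapply(pos, run_id, max)
  gr <- GenomicRanges::GRanges(tx[new_run],
                               IRanges::IRanges(as.integer(start),
                                                as.integer(end)),
                               score = val[new_run])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read / write cell metadata
#'
#' TSV with columns `cell_id` (unique), `embryo_id` (`NA` for control
#' cells), `stage`, `is_control`.
#'
#' @param path TSV file.
#' @return Data frame as described.
#' @export
read_cell_meta <- function(path) {
  if (!file.exists(path)) stop_("cell metadata file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  assert_df_cols(df, c("cell_id", "embryo_id", "stage", "is_control"),
                 basename(path))
  if (anyDuplicated(df$cell_id))
    stop_("duplicate cell_id in ", basename(path))
  df$is_control <- as.logical(df$is_control)
  if (any(df$is_control & !is.na(df$embryo_id)))
    stop_("control cells must not carry an embryo pairing")
  df
}

#' @rdname read_cell_meta
#' @param cells Cell metadata data frame.
#' @export
write_cell_meta <- function(cells, path) write_tsv(cells, path)

#' Read transcript sequences from FASTA
#'
#' @param path FASTA file (via \pkg{Biostrings}).
#' @return Named character vector of sequences.
#' @export
read_transcript_fasta <- function(path) {
  if (!file.exists(path)) stop_("FASTA file not found: ", path)
  s <- Biostrings::readDNAStringSet(path)
  setNames(as.character(s), names(s))
}

#' Attach gene annotation to SNP loci
#'
#' Assigns each locus the gene(s) overlapping it and the transcribed strand:
#' `+` or `-` when annotation supports transcription of exactly one strand at
#' the position, `"conflict"` when genes on both strands overlap it, `NA`
#' when no gene does.
#'
#' @param loci SNP table (`chrom`, `pos`).
#' @param genes Gene annotation (`chrom`, `start`, `end` 1-based closed,
#'   `gene_id`, `strand`).
#' @return `loci` with `gene_id` and `tx_strand` columns replaced.
#' @export
annotate_loci <- function(loci, genes) {
  assert_df_cols(loci, c("chrom", "pos"), "loci")
  assert_df_cols(genes, c("chrom", "start", "end", "gene_id", "strand"),
                 "genes")
  gl <- GenomicRanges::GRanges(loci$chrom,
                               IRanges::IRanges(loci$pos, loci$pos))
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(gl, gg, ignore.strand = TRUE)
  loci$gene_id <- NA_character_
  loci$tx_strand <- NA_character_
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    for (i in unique(q)) {
      g <- s[q == i]
      strands <- unique(genes$strand[g])
      loci$gene_id[i] <- paste(sort(unique(genes$gene_id[g])),
                               collapse = ",")
      loci$tx_strand[i] <- if (length(strands) > 1L) "conflict" else strands
    }
  }
  loci
}

#' Extract per-read SNP observations from a SAM file
#'
#' Converts the SAM to BAM (\pkg{Rsamtools}), pulls reads overlapping each
#' SNP, and walks each read's CIGAR to find the base covering the SNP
#' position. Unmapped, secondary and supplementary alignments are skipped;
#' reads whose CIGAR places a deletion or skip over the SNP contribute
#' nothing.
#'
#' @param path SAM (or BAM) file.
#' @param loci SNP annotation (`chrom`, `pos`).
#' @param cell_id Cell label attached to the observations.
#' @return Observation data frame for [count_alleles()]: `cell_id`, `chrom`,
#'   `pos`, `nt`, `strand`, `aln_start`.
#' @export
read_sam_observations <- function(path, loci, cell_id = "cell") {
  if (!file.exists(path)) stop_("alignment file not found: ", path)
  bam <- if (grepl("\\.bam$", path)) path else
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = TRUE)
  which <- GenomicRanges::GRanges(loci$chrom,
                                  IRanges::IRanges(loci$pos, loci$pos))
  param <- Rsamtools::ScanBamParam(
    what = c("rname", "strand", "pos", "cigar", "seq"),
    which = which,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  res <- Rsamtools::scanBam(bam, param = param)
  out <- list()
  for (i in seq_along(res)) {
    r <- res[[i]]
    if (!length(r$pos)) next
    target <- loci$pos[i]
    for (j in seq_along(r$pos)) {
      qpos <- cigar_query_offset(r$cigar[j], r$pos[j], target)
      if (is.na(qpos)) next
      nt <- substr(as.character(r$seq[j]), qpos, qpos)
      if (!nt %in% NTS) next
      out[[length(out) + 1L]] <- data.frame(
        cell_id = cell_id, chrom = as.character(loci$chrom[i]),
        pos = target, nt = nt, strand = as.character(r$strand[j]),
        aln_start = r$pos[j], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(cell_id = character(), chrom = character(),
                      pos = integer(), nt = character(),
                      strand = character(), aln_start = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Query-string offset of the base aligned to reference position `target`.
cigar_query_offset <- function(cigar, aln_start, target) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^\\d+", "", ops)
  rpos <- aln_start; qpos <- 1L
  for (k in seq_along(op)) {
    consumes_ref <- op[k] %in% c("M", "=", "X", "D", "N")
    consumes_query <- op[k] %in% c("M", "=", "X", "I", "S")
    if (consumes_ref && target < rpos + len[k]) {
      if (op[k] %in% c("D", "N")) return(NA_integer_)
      return(qpos + (target - rpos))
    }
    if (consumes_ref) rpos <- rpos + len[k]
    if (consumes_query) qpos <- qpos + len[k]
  }
  NA_integer_
}

#' Write the pipeline's result tables
#'
#' Emits the per-locus ASE table (allele counts, log2 allelic ratio, p-value
#' per cell), the AI table (log2 AI and chi-squared p per locus per cell
#' pair), the consensus UTR table (up to six predicted ends per transcript)
#' and the per-cell summary table. Refuses partial result bundles and names
#' the missing stage.
#'
#' @param results Named list with `ase_calls`, `ai_calls`, `utr_consensus`,
#'   `summary` (data frames; empty data frames are written as header-only
#'   files).
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_results <- function(results, outdir) {
  need <- c("ase_calls", "ai_calls", "utr_consensus", "summary")
  miss <- setdiff(need, names(results))
  if (length(miss))
    stop_("incomplete results: missing stage(s) ",
          paste(miss, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ase_calls = file.path(outdir, "ase_calls.tsv"),
             ai_calls = file.path(outdir, "ai_calls.tsv"),
             utr_consensus = file.path(outdir, "utr_consensus.tsv"),
             summary = file.path(outdir, "cell_summary.tsv"))
  for (nm in need) write_tsv(as.data.frame(results[[nm]]), paths[[nm]])
  invisible(paths)
}
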