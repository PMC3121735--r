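# Builders for hand-specified stranded count rows and small configurations.

# One wide counts row with explicit stranded counts of the two annotated
# alleles (other nucleotides via `extra`, a named list like list(C_fwd = 3)).
wide_row <- function(cell_id = "c1", chrom = "chr1", pos = 100L,
                     ref_fwd = 0L, ref_rev = 0L, alt_fwd = 0L, alt_rev = 0L,
                     ref = "A", alt = "G", dup_ref = NA_real_,
                     dup_alt = NA_real_, extra = list()) {
  df <- data.frame(cell_id = cell_id, chrom = chrom, pos = as.integer(pos),
                   stringsAsFactors = FALSE)
  for (nt in c("A", "C", "G", "T")) {
    df[[paste0(nt, "_fwd")]] <- 0L
    df[[paste0(nt, "_rev")]] <- 0L
  }
  for (nt in c("A", "C", "G", "T")) df[[paste0("dup_", nt)]] <- NA_real_
  df[[paste0(ref, "_fwd")]] <- as.integer(ref_fwd)
  df[[paste0(ref, "_rev")]] <- as.integer(ref_rev)
  df[[paste0(alt, "_fwd")]] <- as.integer(alt_fwd)
  df[[paste0(alt, "_rev")]] <- as.integer(alt_rev)
  df[[paste0("dup_", ref)]] <- dup_ref
  df[[paste0("dup_", alt)]] <- dup_alt
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

one_locus <- function(pos = 100L, ref = "A", alt = "G", tx_strand = "+") {
  data.frame(chrom = "chr1", pos = as.integer(pos), ref = ref, alt = alt,
             gene_id = "g1", tx_strand = tx_strand, stringsAsFactors = FALSE)
}

# A minimal balance-distribution object with explicit values.
balance_dist <- function(values, cell_id = "c1") {
  structure(list(cell_id = cell_id, values = values, n = length(values),
                 center = median(values)),
            class = "balance_distribution")
}

# A calibration model with an explicit threshold.
calib_model <- function(threshold, percentile = 0.95) {
  structure(list(threshold = threshold, percentile = percentile,
                 n_loci_pooled = 1000L, pooled_maf = NULL,
                 min_coverage = 25L, max_dup_frac = 0.5),
            class = "maf_calibration")
}

# Configuration for a single cell of pure heterozygous loci.
het_cell_config <- function(n_loci, ase_fraction = 0, ai_fraction = 0,
                            skew_law = list(law = "normal", mean = 0, sd = 2.5),
                            coverage = list(mean = 60, size = 8, min = 25),
                            cells_per_embryo = 1) {
  sim_config(n_loci = n_loci, n_embryos = 1,
             cells_per_embryo = cells_per_embryo,
             genotype_probs = c(hom_ref = 0, hom_alt = 0, het = 1),
             ase_fraction = ase_fraction, ai_fraction = ai_fraction,
             ase_log2_skew = skew_law, coverage = coverage)
}
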