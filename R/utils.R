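# Internal helpers: argument checking, seeded RNG, small table utilities.

NTS <- c("A", "C", "G", "T")

stop_ <- function(...) stop(..., call. = FALSE)

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x))
    stop_(sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1)
    stop_(sprintf("'%s' must be a single probability in [0, 1]", name))
  as.numeric(x)
}

assert_pos <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x <= 0)
    stop_(sprintf("'%s' must be a single positive number", name))
  as.numeric(x)
}

assert_df_cols <- function(df, cols, name) {
  if (!is.data.frame(df))
    stop_(sprintf("'%s' must be a data.frame", name))
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_(sprintf("'%s' is missing column(s): %s", name,
                  paste(miss, collapse = ", ")))
  invisible(df)
}

# Deterministic child seeds spawned from one master seed.
child_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
}

locus_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

# Index of each (chrom, pos) of `df` in the locus table; error on misses.
match_loci <- function(df, loci, what = "counts") {
  idx <- match(locus_key(df$chrom, df$pos), locus_key(loci$chrom, loci$pos))
  if (anyNA(idx))
    stop_(sprintf("%d %s row(s) refer to loci absent from the SNP table",
                  sum(is.na(idx)), what))
  idx
}

`%||%` <- function(a, b) if (is.null(a)) b else a
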