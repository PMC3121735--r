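---
title: "Methods: empirical calibration of single-cell allele-specific expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: empirical calibration of single-cell allele-specific expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandase)
```

# The model

Single-cell RNA-seq libraries have a property bulk libraries lack: every SNP
in a cell is either homozygous or heterozygous, never a population mixture.
Reads over an expressed heterozygous SNP therefore measure the relative
output of the two alleles directly. `strandase` turns that observation into
calibrated per-locus calls in three steps, each of which replaces a
parametric assumption with an empirical distribution measured from the data
itself.

## Locus selection

A (cell, locus) pair enters the analysis only if all five of the following
hold: more than one nucleotide is observed; the observed alleles are the
annotated SNP alleles; coverage is at least `min_coverage` (default 25)
reads; for every observed nucleotide, at most `max_dup_frac` (default 50%)
of its supporting reads share one identical alignment position; and gene
annotation supports transcription of exactly one strand at the position.

The duplicate criterion deserves two remarks. First, we pool strands when
computing the modal identical-position fraction: duplicate stacks are a
property of the library molecule, not of the aligner's strand call. Second,
the criterion is taken literally for singletons — a nucleotide supported by
one read has 100% of its support at one position and fails. This is strict
but symmetric: it is applied identically during calibration and during
analysis, so the calibrated threshold refers to exactly the locus population
that is later genotyped.

Loci where a *non-annotated* nucleotide is among the top two observed are
excluded (criterion 2), but third-nucleotide reads still count toward
coverage; the minor allele frequency and all downstream statistics use only
the two annotated alleles.

## Calibrating heterozygosity

Errors (RT, PCR, sequencing, mismapping) put minor-allele reads on truly
homozygous loci. Control cells from a nearly homozygous line measure that
process: we pool the minor allele frequency
$\mathrm{MAF} = \min(n_\mathrm{ref}, n_\mathrm{alt})/(n_\mathrm{ref}+n_\mathrm{alt})$
over all control-cell loci passing criteria 3–5 (criterion 1 is *not*
required — single-nucleotide loci are precisely the calibration substrate)
and take the nearest-rank percentile as the calling threshold: the smallest
pooled value whose empirical CDF reaches `percentile` (default 0.95). A
locus is then called heterozygous iff its MAF **strictly exceeds** the
threshold; a MAF exactly at the threshold is homozygous. Two properties
follow by construction and are verified in the test suite:

* at least 95% of the calibration pool lies at or below the threshold, and
* freshly drawn homozygous loci from the same error law are miscalled
  heterozygous at a rate of about 5% or less
  (`expected_het_fp(model, n) = n * (1 - percentile)`).

The percentile is distribution-free; nothing is assumed about the error
law's shape, which in our simulations (and plausibly in real libraries) is
strongly overdispersed.

## The strand-balance null for ASE

Double-stranded cDNA synthesis means each allele is observed on both
alignment strands. Let $a_1, b_1$ be reference-allele counts on the plus and
minus strand and $a_2, b_2$ the alternative-allele counts. The statistic

$$B = \frac{a_1 + b_2 + 1}{a_2 + b_1 + 1}$$

mixes the two alleles across strands so that, with unbiased strand
assignment, its numerator is a Binomial(coverage, 1/2) draw *whatever the
true allelic skew*. B ≈ 1 therefore certifies the absence of library and
instrument bias, and — crucially — the per-cell distribution $D$ of
$\log_2 B$ over all heterozygous loci approximates the distribution of
allelic ratios of *balanced* loci, even in a cell where a large fraction of
loci are truly skewed. This is what makes $D$ usable as a null without
knowing which loci are ASE in advance.

Against $D$, a locus with pseudocounted log2 allelic ratio $r$ gets the
two-tailed rank p-value

$$p = \frac{1 + \#\{v \in D : |v - \mathrm{med}(D)| \ge |r - \mathrm{med}(D)|\}}{n + 1},$$

with minimum attainable value $1/(n+1)$; we require at least 50 het loci and
call ASE at $p < 0.01$. Centring on the median of $D$ (rather than on 0)
absorbs any residual global reference bias a re-implementation's aligner may
leave; with an unbiased aligner the median sits at 0 and the choice is
inert. $D$ is pooled across coverage levels, matching the tested loci's own
coverage mixture; a coverage-stratified variant was considered and rejected
as the default because it fragments $D$ below the rank-test's resolution at
realistic locus counts.

## Allelic imbalance between sister cells

Sister blastomeres share their genotype, so comparing the *ratio of allelic
ratios* between them cancels locus-specific technical effects:
$\mathrm{AI} = r_1 / r_2$ with pseudocounted ratios. A shared het locus is
called imbalanced when the Pearson $\chi^2$ test (1 df, no continuity
correction) on the raw-count 2×2 table gives $p < 0.05$ *and* AI > 2 or
< 0.5. Both conditions are required; the fold-change guard suppresses
high-coverage loci whose tiny ratio shifts are statistically but not
biologically meaningful. Tables with any expected cell below 5 are tested
anyway but flagged `low_expected`. For embryos with more than two cells,
every within-embryo pair is tested and a locus counts as imbalanced for the
embryo if any pair calls it — a generalisation beyond the paired design, and
flagged as such.

Expected false-positive counts for AI are estimated by Monte Carlo: for each
observed table, null tables with the same margins are drawn from the
hypergeometric distribution and passed through the same $\chi^2$ +
fold-change rule (default 20 draws per locus). We report this estimate, and
`n_het × alpha` for ASE, as the "expected false positive" columns of the
summary table; they are honest nulls of *our* procedure, not attempts to
reproduce any particular historical bookkeeping.

## 3'UTR isoform inference

Poly(T)-primed libraries cover transcripts from the 3' end with coverage
decaying upstream and effectively vanishing beyond ~1.5 kb. A gene
expressing a short and a long 3'UTR isoform shows a step in coverage at the
proximal poly(A) site. The detector:

1. smooths the track with a running median (`smooth_window`, default 50 nt);
2. scans for positions where the mean over the `min_segment` (default
   100 nt) upstream window is at least `min_step_ratio` (default 3) times
   the downstream-window mean;
3. within each contiguous candidate run, takes the strongest step and
   re-localises it on the **raw** track as the position maximising the
   windowed step height. The running median is robust for *detection* but
   biases *localisation* upstream on sparse coverage (its flip point is
   where half the window is zero, which on Poisson coverage of ~1 read/nt
   happens 10–15 nt before the true end); the raw windowed-mean argmax has
   no such bias because neighbouring candidate positions share almost all
   their noise. The reported end is the last covered base;
4. keeps at most six ends, strongest first, with per-isoform abundance =
   upstream-window mean − downstream-window mean (for the most distal end
   the downstream mean is ~0, so its abundance is the terminal segment
   mean).

All thresholds are ratios, so predictions are invariant to uniform coverage
scaling. Per-cell predictions are merged per transcript by chaining sorted
ends within `tolerance` (50 nt); clusters seen in at least half the cells
survive, with median end and median abundance. The proximal:distal
expression ratio divides the most proximal end's abundance by the most
distal's. Canonical poly(A) hexamers (AATAAA, ATTAAA — the two canonical
CPSF signals; other variants can be supplied) are scanned within ±50 nt of
each predicted end; the offset convention is motif start minus cleavage
position, so a signal 20 nt upstream reports −20. Ties at equal distance
resolve upstream, since poly(A) signals are upstream elements. We report the
full offset distribution rather than asserting fixed fractions of motif-
positive ends.

## Expression summaries

RPM = count/total × 10⁶; a transcript is expressed when RPM strictly
exceeds 0.1. Fold-change flags between cell groups use group means with a
0.01-RPM pseudocount and bounds 2 / 0.5. Inter-cell correlations are Pearson
on log2(RPM + 1) (the transform is configurable); at poly(A)-library depths
(~10⁶ reads) sister cells correlate above 0.99 in simulation, and the same
is expected of technically sound real pairs.

# The synthetic-data generator

The generator is first-class, tested code, and defines the study conditions
the acceptance checks run under.

What it emulates: genotypes drawn per embryo and shared exactly by sister
cells (outbred defaults: 60% of expressed SNPs heterozygous); truncated
negative-binomial coverage (default mean 60, size 8); homozygous error as a
**beta-binomial** — the per-library, per-locus error probability is a Beta
draw with mean `error_rate` (default 0.02) and overdispersion
`error_overdispersion` (default 0.1) — because a pure binomial at a small
per-base rate cannot produce the heavy MAF tail that makes percentile
calibration non-trivial; true allelic skews for a configurable fraction of
het loci (default 45%, log2 skew ~ Normal(0, 2.5), consistent with roughly
half of het loci showing callable skew); stochastic imbalance at 6% of het
loci, whose skew is re-drawn independently per sister cell; binomial strand
assignment (`strand_bias`, default 0.5); PCR duplicates as reads stacking on
an earlier read's alignment position (default rate 0.1), with the modal
stack recorded per nucleotide; control cells as one genotype draw shared by
all cells with 0.3% residual heterozygosity (configurable; residual het loci
are simulated balanced — their ratio structure is irrelevant to calibration,
which excludes or barely registers them); and two-isoform 3'-biased coverage
with exponential decay (length scale 600 nt, near zero by 1.5 kb — the
functional form is our choice; the phenomenon, not the form, is the
constraint), abundance ratio 5:1, and poly(A) hexamers planted 20 nt
upstream of true ends with probabilities 0.4 (proximal) / 0.7 (distal).

What it does not emulate: base-quality structure, mappability and alignment
artefacts correlated along the genome, amplification length bias, bursting
kinetics beyond the per-cell skew re-draw, doublets, or cross-cell
contamination. Passing tests therefore certify the *procedures* —
calibration coverage, test size and power, recovery of planted structure —
not performance on any particular real library.

Seeding: every generator takes one integer seed; a master seed spawns
per-stage child seeds deterministically, and identical seed + configuration
gives byte-identical pipeline outputs (verified by hashing all result files
across independent runs).

# Numerical and boundary conventions

* Nearest-rank percentile: `sort(x)[ceiling(p * n)]` — distribution-free,
  and guarantees ECDF(threshold) ≥ p on the pool itself.
* Strict inequalities throughout: het iff MAF > threshold; ASE iff
  p < alpha; expressed iff RPM > 0.1. One deliberate exception: at
  `alpha >= 1` every het locus is called ASE (the rank p has an atom at
  exactly 1, which a strict comparison would never call).
* Pseudocount +1 enters reported allelic ratios, B, and AI ratios
  (singularity guards); MAF, the $\chi^2$ table and calibration use raw
  counts.
* The $\chi^2$ statistic is computed vectorised in double precision (margin
  products overflow 32-bit integers above coverage ~120 per cell) and is
  tested to 1e-9 against `stats::chisq.test(correct = FALSE)`.
* Genomic coordinates are 1-based internally (the R/Bioconductor
  convention); BED and bedGraph are converted at the I/O boundary only.
* Homozygous calls at MAF exactly 0.5 (possible only when the threshold is
  0.5 or higher, i.e. never with a sane calibration) break toward
  `hom_ref`; documented for completeness.
* UTR candidate runs tie-break by step height, then position; consensus
  clusters by support, then abundance.

# Problem sizes

The test suite and acceptance checks run at desk scale, chosen so every
stochastic bound has comfortable binomial room: calibration from 12 control
cells × 2,500 loci (~26,000 pooled MAFs); false-het measurement on ~4,400
fresh homozygous loci; test size and power on 3,000–5,000 het loci per cell;
AI recovery on 1,500-locus sister pairs; UTR recovery on 100 two-isoform
genes × 2 cells; determinism on a 400-locus end-to-end run. The full suite
completes in well under a minute on one core.

# Known limitations

* Calibration transfers from control cells to embryo cells only insofar as
  their error processes match; a line with atypical mismapping would shift
  the threshold. Using the same platform and pipeline for controls and samples
  mitigates this but cannot remove it.
* The rank p-value's resolution is $1/(n+1)$; cells with few het loci
  (n < 50 refuses outright, n < a few hundred is coarse) cannot support
  calls at small alpha.
* AI testing assumes the two cells' libraries are exchangeable under the
  null; systematic per-cell amplification differences in allele capture
  would inflate calls. The fold-change guard helps; it does not cure.
* The UTR detector finds steps, not poly(A) sites per se: a sharp internal
  coverage cliff (e.g. an unannotated splice into the terminal exon) is
  indistinguishable from a cleavage site without the motif evidence, which
  is why the motif offsets are reported alongside.
* Parent-of-origin assignment is out of scope (it requires informative
  crosses), as are alignment itself and base-quality recalibration.
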