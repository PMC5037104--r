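---
title: "Measuring allele-specific expression in an F1 rice hybrid: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring allele-specific expression in an F1 rice hybrid: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In an F1 hybrid between two inbred rice varieties (here an Apo x IR64
*indica* x *indica* cross), both parental alleles of every gene sit in the
same nucleus and are exposed to the same pool of *trans*-acting factors.
Any systematic difference in the abundance of the two allelic transcripts —
allele-specific expression (ASE) — therefore points at *cis*-regulatory
divergence between the parental genomes, and the way that difference
responds to stress reveals genotype-by-environment interaction at the level
of individual alleles. `asepipe` implements the complete analysis: it
quantifies allelic imbalance (AI) per gene from RNA-seq of the hybrid and
its parents under a control and a water-stress condition, classifies how
the imbalance changes between conditions, and asks whether the imbalanced
genes co-locate with markers for drought-related yield QTL.

Quantifying ASE from short reads has two structural obstacles that shape
the pipeline:

1. **Mapping bias.** Reads are usually mapped against a reference genome
   from a third variety (a *japonica* cultivar, while both parents are
   *indica*). Reads carrying *indica*-specific variants mismatch the
   reference and drop out preferentially, biasing everything downstream.
   The remedy is a **pseudo-reference**: variants carried identically by
   *both* parents (hence uninformative about allelic origin, but divergent
   from the reference) are edited into the reference transcriptome before
   any allele-level quantification.
2. **Allele identity.** Only reads that overlap a SNP *between the two
   parents* can be attributed to one parental allele. These inter-parental
   SNPs are sparse (on the order of 0.7 SNPs per gene between Apo and
   IR64), so only a small percentage of hybrid reads is informative, and
   how those reads are counted matters.

# Pipeline stages and their models

## Quality trimming

For each library, the 75th percentile of the base qualities is computed at
every read position across the whole replicate; positions whose percentile
falls below Q28 are removed from all reads. Removal is positional, not a 3'
truncation: a failing interior position is excised everywhere, keeping the
remaining positions aligned across reads. Trimming is idempotent by
construction.

## Mapping

The internal mapper is a deliberately minimal seed-and-extend aligner:
exact 20-mers at regular offsets along the read (plus one flush seed at the
read end) are looked up in a hash of all reference 20-mers, and each
candidate diagonal is extended ungapped under Hamming distance. The default
mismatch cap is lenient (30 % of the read length), mirroring a permissive
end-to-end alignment policy for cross-subspecies mapping. Ties in the best
score across transcripts of different genes leave the read unmapped; ties
among splice variants of one gene resolve to the lexicographically first
variant, keeping counts reproducible. Gapped alignment is intentionally out
of scope — externally produced alignments can be imported from a minimal
SAM dialect — but short InDels between sample and reference are still
*observed* (next section). This division of labor matters for the
mapping-rate comparison: reads that straddle an InDel in mid-read exceed
the mismatch cap against the original reference and drop out, and are
exactly the reads recovered by the pseudo-reference, so the pseudo-reference
mapping rate is never below the original-reference rate and typically
improves on it.

## Pileups and InDel observation

Pileups tally the observed base of every mapped read at every covered
position. A read whose ungapped placement accumulates four or more
mismatches is compared against the reference for a single 1–3 bp
insertion/deletion breakpoint on either flank of its diagonal; if the
explanation saves more than a three-mismatch penalty, the read's bases are
re-tallied on the corrected diagonals and the event is recorded. Ambiguous
breakpoints in repeat context resolve to the leftmost position (VCF-style
left anchoring). Deleted columns count deletion observations, so column
depth (bases + deletions) is conserved.

## Shared-variant calling and the pseudo-reference

A site becomes a shared SNP when, in each parent independently (all four
libraries of a parent pooled), depth is at least 5x and the *same*
non-reference allele exceeds a 0.8 proportion of the column depth (strictly
greater). Shared InDels require depth 5x and proportion at least 0.5
(inclusive), again identical in both parents. Sites where the parents pass
with different alternative alleles are skipped: a variant is only "shared"
if it is the same event. SNP substitutions and InDel edits are applied
right-to-left per transcript, and every length change is recorded in a
lift-over map with an exact inverse (positions inside spans that do not
exist on the target side map to the span's left edge, flagged). Applying
the recorded provenance to the original reference reproduces the
pseudo-reference byte for byte.

## Inter-parental SNPs and read-wise allele assignment

Against the pseudo-reference, a site is an inter-parental SNP when each
parent shows a single majority allele at depth >= 3x and proportion > 0.8,
and the two majority alleles differ. For each mapped F1 read, every covered
SNP is inspected: the read base votes for the parent whose allele it
matches; a base matching neither allele (a sequencing error) is ignored
rather than vetoing the read. A read voting for exactly one parent counts
**once** toward that parent's gene tally regardless of how many SNPs it
covers — the read-wise principle. The SNP-wise alternative (counting every
read-SNP observation) is implemented for comparison and is provably never
smaller; it overestimates whenever any read covers two or more SNPs. Reads
voting for both parents (conflicts) and reads covering no SNP are
"unspecified". Per-sample assignable percentages are *truncated*, not
rounded, to two decimals, matching the arithmetic of the published
per-sample table.

## Allelic-imbalance testing

Within each condition the four informative-count columns (allele x
replicate) are normalized by median-of-ratios size factors: per gene, the
geometric mean of its counts across columns; per column, the median over
all-positive genes of the count-to-geometric-mean ratio. The median is
taken on the ratio scale; DESeq2's log-scale interpolation agrees to about
five decimals and serves as a cross-check in the test suite. Normalized
replicates are then **summed** per allele, and each gene is tested against
a 1:1 allelic ratio with:

* an exact two-sided binomial test (outcomes no more likely than the
  observed one, capped at 1), on counts rounded to the nearest integer;
* a 1-df chi-square test without continuity correction, reported only for
  genes whose expected count n/2 is at least 5 (the usual validity floor of
  the normal approximation).

Classification gates on the binomial p-value: the binomial test needs no
sample-size filter, so it covers every informative gene, which matches the
larger significant sets the analysis reports; the chi-square p-value and a
Benjamini–Hochberg adjusted column are reported for information only.
Raw p < 0.05 is the significance rule throughout — no multiple-testing
correction gates any class, as the analysis thresholds raw P. A significant
gene with fold magnitude (max/min of the combined allele counts) of at
least 1.25 is asymmetric toward its higher allele — a magnitude of exactly
1.25 is asymmetric ("equal to or more than") — and below that it is
biallelic. A gene whose minor allele contributed zero informative reads is
monoallelic, counted inside its favored side's totals. The 2.0x threshold
is reported alongside as a stricter definition.

## Condition-mediated ASE profiles

Genes are pairwise-compared between conditions over a universe defined by
the *lenient* rule — P < 0.05 in one or both conditions (the stringent
alternative, P < 0.05 in both except for single-condition genes, is
implemented as an option and always selects a subset). Classes:

* **tPAV** (transcript presence/absence variation): informative reads in
  exactly one condition — the detection floor is a single informative read,
  a choice this package makes explicit;
* **bidirectional**: asymmetric in both conditions with opposite favored
  alleles, subtyped by the control-to-stress change of direction;
* **unidirectional**: asymmetric in both conditions with the same favored
  allele;
* **biallelic-unclassified**: below the 1.25x magnitude in either
  condition; such genes cannot be assigned an allele-preference profile.

Percentages are reported over the lenient universe, one decimal.

## QTL association

Co-localization is plain physical distance on user-supplied coordinates:
0 kb when the marker falls inside the gene span, else the bp gap to the
nearer gene end, reported in kb within a configurable window (default
500 kb, spanning the distances such summaries typically print). Selective
genotyping takes the LS means of the two phenotype replicates per line
(equal to the arithmetic mean in this balanced design), selects the top and
bottom `ceiling(n/8)` lines (25 % in total; 20 + 20 of 160), and regresses
line means on an additive genotype score at each polymorphic marker (IR64
homozygote 0, heterozygote 1, Apo homozygote 2; missing codes excluded),
reporting the slope, R² (as a percent, identical to the squared Pearson
correlation for this simple regression) and the F-test p-value on 1 and
n−2 df. Regression uses only the genotyped tails, with no ascertainment
correction, matching the original design. Heterozygote coding is the
package's choice; F3:5 RILs are ~94 % homozygous, so it has little
leverage.

# The synthetic-data generator

All inputs are generated with known truth, so every stage is testable
without external downloads. The generator emulates the study conditions:

* a LOC-style transcriptome (default 200 genes, 500–3000 bp) laid out on
  12 chromosomes with 20–200 kb intergenic gaps;
* two parental haplotypes sharing 0.92 SNPs/kb and 0.07 InDels/kb against
  the reference (the densities the real cross exhibits), with 1–3 bp
  InDels — only counts are documented for the real data, so lengths are a
  generator choice — and inter-parental SNPs at a Poisson mean of 0.72 per
  gene (one parent keeps the reference base);
* single-end 90 bp reads (the real libraries were 38/90 bp paired-end;
  pairing adds no statistical information to any stage here, so single-end
  is the default), Poisson read counts per gene, uniform substitution
  errors at 1e-3 and constant Q35 qualities with an optional low-quality
  tail to exercise trimming — real quality profiles are not available;
* per-gene truth classes (biallelic, favoring either side, monoallelic,
  tPAV, bidirectional, unidirectional) with per-condition Apo fractions.
  The organism's true allelic ratios are unknowable, so the defaults are a
  package choice: 0.5 for biallelic, 0.7/0.75/0.8 grades of asymmetry, 0
  or 1 for monoallelic. The orientation of the direction-free classes is
  randomized per gene, so both alleles are favored equally often
  genome-wide — the published run found near-equal counts on both sides,
  and the balanced-majority assumption of median-of-ratios normalization
  then holds by design (an early imbalanced draft systematically shifted
  biallelic genes off 1:1 after normalization);
* a 160-line F3:5 RIL panel: 153 surveyed SSR markers of which 22 are
  polymorphic, genotype codes 1/2/3/0 with a 1/16 heterozygote fraction
  (the selfing expectation) and 2 % missing calls, and phenotypes as the
  sum of planted additive marker effects plus Gaussian noise scaled to a
  target single-replicate heritability (default 0.6, a moderate value for
  yield under stress), two replicates per line.

What the generator does **not** emulate: GC and positional coverage bias,
fragment-length effects, spliced reads across genomic introns, linkage
between markers (marker genotypes are drawn independently), or genotyping
error beyond missingness. Passing recovery tests therefore demonstrates the
pipeline's correctness under its stated statistical model, not robustness
to every artifact of real libraries.

# Numerical and design choices

* Coordinates are 0-based half-open internally; 1-based only at SAM-like
  boundaries. The SNP proportion thresholds are exclusive (> 0.8), the
  InDel proportion inclusive (>= 0.5), the fold thresholds inclusive —
  each following the wording of its rule.
* Normalized (fractional) combined counts are rounded to the nearest
  integer before the binomial test; fold changes use the unrounded values.
* Genes with zero combined counts are skipped with a notice; a pileup
  column's InDel proportion uses the column depth as denominator.
* Determinism: one master seed drives every stage; derived sub-seeds are
  drawn reproducibly, and re-running a configuration reproduces all output
  files byte for byte (the run manifest deliberately contains no
  timestamps).
* Problem sizes in the test suite and acceptance script — 200 genes at
  ~200 reads/gene/library for the end-to-end recovery run, ~30x pooled
  parental coverage for variant-recall checks, 5000 null genes for test
  calibration, 20 seeded replicates for the QTL scan — were chosen as the
  smallest scales at which the measured quantities are stable, and are
  stated in the code.

# Known limitations

* The mapper is ungapped and transcriptome-only; reads spanning an InDel
  near mid-read against a diverged reference are lost until the
  pseudo-reference incorporates the event (this is also what the
  improvement statistic measures). Splice-aware or genome-level analyses
  need external alignments via SAM import.
* The binomial model treats informative reads as independent Bernoulli
  draws; overdispersion between replicates beyond the size-factor
  normalization is not modeled (the negative-binomial between-treatment
  analysis is a different question and out of scope here).
* Co-localization is physical distance only — no genetic-map
  interpolation — and the selective-genotyping regression reports no
  ascertainment-corrected effect sizes.
* With sparse inter-parental SNPs most hybrid reads are uninformative;
  per-gene power depends on local SNP density, and genes without SNPs are
  invisible to the entire analysis.
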