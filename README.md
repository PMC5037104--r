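# asepipe

Allele-specific expression (ASE) analysis for an F1 hybrid from RNA-seq of
the hybrid and its two inbred parents, built for the Apo x IR64 rice cross
under control and water-stress conditions but applicable to any biparental
design with the same data layout.

## Who it is for and what it does

Quantitative geneticists and transcriptomicists who want to measure, per
gene, how unequally the two parental alleles of a heterozygote are
expressed, how that imbalance responds to a stress treatment, and whether
the imbalanced genes sit near trait-associated markers. The package
implements the full chain:

1. **Pseudo-reference construction** — variants shared by both parents but
   absent from the reference transcriptome (SNPs at depth >= 5x and
   proportion > 0.8 in each parent; 1–3 bp InDels at proportion >= 0.5) are
   edited into the reference, removing cross-subspecies mapping bias; a
   lift-over map tracks every coordinate change.
2. **Read-wise allele assignment** — inter-parental SNPs (depth >= 3x,
   proportion > 0.8, different majority alleles) turn hybrid reads into
   votes; a read counts once toward the parent whose alleles it carries,
   never once per SNP.
3. **Allelic-imbalance (AI) testing** — median-of-ratios size factors over
   the allele x replicate columns, replicates summed, then an exact
   two-sided binomial test of the allele counts against 1:1 (chi-square
   with the expected>=5 filter reported alongside). A significant gene with
   fold magnitude >= 1.25 (or >= 2.0) prefers one allele; one with a
   zero-count allele is monoallelic.
4. **Condition-mediated ASE profiles** — genes significant in at least one
   condition are classified as tPAV (expressed in one condition only),
   bidirectional (allele preference flips between conditions),
   unidirectional (same allele preferred in both) or
   biallelic-unclassified.
5. **QTL association** — physical co-localization of AI genes with SSR
   markers (distance to the nearer gene end, in kb) and selective
   genotyping: LS means over two phenotype replicates, 25 % phenotypic
   tails (20 + 20 of 160 recombinant inbred lines), and single-marker
   regression of line means on an additive genotype score.

A seeded simulator (`simulate_experiment()`) generates every input —
reference, diverged parental haplotypes, all twelve libraries, marker maps
and a RIL panel — with known ground truth, so the whole pipeline is
testable end to end. The statistical heart is the per-gene test of the
combined allele counts \(a\) (Apo) and \(b\) (IR64):

    P = sum over k of C(n,k) (1/2)^n  for all outcomes no more likely
        than the observed a,   n = a + b,
    FC = a / b,   magnitude = max(a,b) / min(a,b)

with classes gated at P < 0.05 and magnitude thresholds 1.25x / 2.0x.

## Worked example

```r
library(asepipe)
cfg <- pipeline_config(
  sim = sim_config(n_genes = 60, gene_length_range = c(500, 1500),
                   depth_per_gene = 150, parental_snp_rate = 4, seed = 101),
  seed = 101)
run <- run_pipeline(cfg)
run
#> ASE pipeline run
#>   48 shared variants edited into the pseudo-reference; 223 inter-parental SNPs
#>   mean mapping-rate improvement on the pseudo-reference: 0.18 %
#>   profile universe: 37 genes; planted-profile recovery 96.2 %
```

The pseudo-reference raised every library's mapping rate (here by 0.18
percentage points on average — reads straddling the shared InDels are
unmappable against the original reference), and 96 % of the profile
classes planted by the simulator were recovered. The per-sample assignment
table mirrors the usual "Table 2" layout; with ~4 inter-parental SNPs per
gene about 31 % of mapped hybrid reads are assignable (with the real
cross's 0.72 SNPs/gene this drops to a few percent):

```r
run$allele_counts
#>   condition replicate  apo ir64 mapped unspecified pct_assignable
#> 1   control      rep1 1394 1266   8698        6038          30.58
#> 2   control      rep2 1452 1223   8706        6031          30.72
#> 3    stress      rep1 1436 1411   8929        6082          31.88
#> 4    stress      rep2 1509 1360   8983        6114          31.93

summary(run$ai$control, threshold = 1.25)
#> AI summary at 1.25x (monoallelic genes inside their favored side)
#>   genes preferring the Apo-specific allele:  19
#>   genes preferring the IR64-specific allele: 13
#>   total genes exhibiting AI:                 32
#>   significant genes (P < 0.05):              32
#>   % AI over significant:                     100

run$profile_summary
#> ASE profile universe: 37 genes (35 common, 0 control-only, 2 stress-only)
#>   tPAV                         2  (5.4 %)
#>   bidirectional                6  (16.2 %)
#>   unidirectional              21  (56.8 %)
#>   biallelic_unclassified       8  (21.6 %)
```

The marker scan on the tail-selected lines puts the two planted QTL first
by a wide margin (slope in phenotype units per allele substitution, R² in
percent):

```r
head(as.data.frame(run$association), 4)
#>   marker  n     slope    r2_pct      p_value monomorphic
#> 1 RM0868 39  5.087481 97.061195 6.056269e-30       FALSE
#> 2 RM0056 40  5.091141 94.192677 4.335702e-25       FALSE
#> 3 RM0784 39 -1.893563 12.791579 2.539162e-02       FALSE
#> 4 RM0686 39 -1.648373  9.474108 5.661896e-02       FALSE
```

`run_pipeline(cfg, outdir = "out")` additionally writes every stage table
(allele counts, AI results and summaries, profiles, variant and SNP
tables, mapping rates, co-localization, association) as TSV plus a JSON
run manifest; re-running the same configuration reproduces the files byte
for byte. A thin command-line wrapper lives at `inst/cli/asepipe.R`
(subcommands `simulate` and `run`).

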