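# varcontact

Most GWAS variants associated with diseases such as breast and prostate
cancer lie in non-coding DNA. `varcontact` links those high-risk SNPs
(association `p <= 5e-8`) to gene-regulatory elements — enhancers and
transcription-factor (TF) binding sites — and to their target genes, either
through the **1D linear genome** (a Hi-C-resolution-sized window centered on
the SNP) or through the **3D genome** (the single most confident significant
chromatin contact of the SNP's fragment), and compares the
disease-association (DA) scores recovered by the two routes. A companion
analysis calls topologically associating domains (TADs) and contrasts
DA scores between SNP-rich and control domains.

## The statistics at the core

**Contact significance.** Binned contact counts are tested against a
distance-dependent null built from equal-occupancy distance strata: a pair
in a stratum with `n_pairs` pairs and `total_count` reads has expected
per-read probability `p_exp = total_count / (N * n_pairs)` (`N` = total
reads), upper-tail binomial p-value `P(X >= k)`, `X ~ Binomial(N, p_exp)`,
and Benjamini–Hochberg q-value computed jointly over all intra- and
inter-chromosomal pairs. Contacts with `q <= 0.05` are significant.

**Fragment selection.** For each SNP, among significant partner fragments
containing at least one element: lowest contact q-value wins; ties go to
the longest-range fragment (inter-chromosomal outranks intra); residual
ties break deterministically.

**Aggregation.** Per-SNP medians of element / target-gene DA scores (or the
fraction of disease-associated TFs where only binary flags exist), then
quartiles and `IQR = Q3 - Q1` across SNPs.

**TADs.** A TopDom-style caller: cross-boundary `w x w` mean signal, local
minima as candidates, one-sided rank-sum filter of cross-boundary versus
within-domain counts, domains labeled `snp_rich` iff they contain a
high-risk SNP.

A seeded synthetic-data module (`sim_config()`, `simulate_study()`) plants
distance decay, TADs, loops, anchor-bound SNPs and class-shifted DA scores
with recorded ground truth, so the whole pipeline is testable offline.

## Worked example

```r
library(varcontact)

cfg <- sim_config(chrom_bins = c(chr1 = 150L), n_tads = 5, n_loops = 5,
                  n_high_risk = 8, n_snps = 40, n_enhancers = 60,
                  n_tfbs = 30, loop_dist_bins = c(8L, 25L))
simulate_study(cfg, seed = 7, "study")

rc <- run_config(contacts = "study/contacts.tsv", gwas = "study/gwas.tsv",
                 elements = "study/elements.bed", genes = "study/genes.tsv",
                 resolution = 10000)
res <- run_pipeline(rc, "study/out")
#> inputs: 10704 contacts, 40 SNPs, 110 elements, 200 genes
#> 379 significant contacts (q <= 0.05); 8 high-risk SNPs (p <= 5e-08)

render_report(res$mapping_summary[res$mapping_summary$measure == "enhancer_da"])
#>    statistic enhancer_da_1D enhancer_da_3D
#> 1:         n       5.000000      8.0000000
#> 2:        q1       2.421928      3.9731648
#> 3:        q2       2.422226      4.2011783
#> 4:        q3       2.692049      4.2464342
#> 5:       iqr       0.270121      0.2732694

res$tads[1:3]
#>           tad_id  chrom  start    end n_snps    label
#> 1: chr1_tad_0001   chr1      0  60000      1 snp_rich
#> 2: chr1_tad_0002   chr1  60000 160000      0  control
#> 3: chr1_tad_0003   chr1 160000 300000      2 snp_rich
```

Reading the report: of the 8 high-risk SNPs, 5 picked up an enhancer within
their linear window (median per-SNP enhancer DA 2.42 — the background
level) while all 8 mapped to an enhancer through a significant chromatin
contact, with a clearly higher median DA of 4.20, reflecting the planted
associated elements at the loop partners. `run_pipeline()` also writes
scored and significant contact tables, per-SNP mapping rows, TAD BED and
summary TSVs, and a YAML manifest; rerunning from the same inputs and
configuration reproduces every output byte for byte.

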