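---
title: "Linking non-coding variants to regulatory elements through the 3D genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking non-coding variants to regulatory elements through the 3D genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varcontact)
```

## The problem

Most disease-associated variants found by genome-wide association studies
(GWAS) fall in non-coding DNA, where their functional interpretation depends
on which regulatory elements — enhancers and transcription-factor (TF)
binding sites — they perturb, and which genes those elements control. Two
competing ways of assigning elements to a variant are compared throughout
this package:

* **1D (linear) mapping** — elements within a window centered on the SNP,
  with total width equal to the Hi-C bin size, i.e. half a bin up- and
  downstream;
* **3D (spatial) mapping** — elements on the chromatin fragment that forms
  the single most confident significant Hi-C contact with the SNP's
  fragment.

Each mapped SNP is then summarized by the median disease-association (DA)
score of its enhancers, TFs and target genes (or, for TF sets annotated
only with a binary flag, the fraction of disease-associated TFs), and the
per-SNP values are aggregated into quartile/IQR tables. A separate analysis
calls topologically associating domains (TADs), splits them into SNP-rich
(holding at least one genome-wide-significant variant) and control domains,
and compares DA distributions between the two groups.

## Contact significance model

Raw binned contact counts are tested against a distance-dependent null.
Intra-chromosomal bin pairs are sorted by genomic distance and split into
`n_strata` (default 100) contiguous strata of near-equal pair counts; all
inter-chromosomal pairs form one additional stratum. Within a stratum
holding `n_pairs` pairs and `total_count` reads, the per-read-pair
probability of landing on one given pair is

```
p_expected = total_count / (N * n_pairs)
```

with `N` the total observed count over all analyzed pairs. A pair with
observed count `k` gets the upper-tail binomial p-value `P(X >= k)` for
`X ~ Binomial(N, p_expected)`, and Benjamini–Hochberg correction is applied
jointly across all intra- and inter-chromosomal records. Contacts with
`q <= 0.05` (inclusive) are significant.

This flat-strata expectation is a deliberate simplification of
spline-smoothed distance models. Its one sharp consequence: inside the
shortest-distance stratum the power-law decay is steep enough that the
smallest distances exceed the stratum mean by themselves. Below roughly
five bins this curvature alone — not any biological enrichment — would make
pairs significant. The workflow configuration therefore excludes
intra-chromosomal pairs closer than `min_dist_bins = 5` bins (50 kbp at
10 kbp resolution) from the significance analysis, analogous to the lower
distance bound used by common contact-calling tools; `score_contacts()`
itself defaults to excluding only the diagonal, and both knobs are exposed.
No matrix balancing (ICE/KR) is applied anywhere: the method consumes raw
counts, and the TAD caller mirrors that choice.

The records handed to `score_contacts()` define the analysis universe.
Zero-count pairs carry no signal individually (their p-value is 1) but they
do calibrate the expected probabilities; the synthetic generator therefore
returns the full intra-chromosomal pair grid. Files written by
`simulate_study()` keep only non-zero rows (the usual sparse contact-file
convention), so a file-based rerun is slightly conservative relative to the
in-memory analysis.

## Mapping rules

High-risk SNPs are those with GWAS `p <= 5e-8`; both this bound and the
contact `q <= 0.05` bound are inclusive. For 3D mapping, every significant
partner fragment of the SNP's bin that contains at least one element is a
candidate, and one fragment is selected: minimal contact q-value first,
then — among ties — the longest-range fragment, where an inter-chromosomal
partner counts as longer-range than any intra-chromosomal one (the linear
distance between chromosomes is undefined, and choosing the spatially
"farthest" reading keeps the tie-break total). Residual ties break by
chromosome name and bin index, making selection a deterministic total
order.

Whether "one fragment per SNP" is selected jointly over all element-bearing
candidates or independently per element class is genuinely open; both are
implemented (`scope = "joint"` / `"per_class"`), and `per_class` is the
default because it guarantees that each element class is represented
whenever any significant element-bearing contact exists, which matches
reporting enhancer-linked and TF-linked SNP counts side by side. An element
overlapping the selected fragment (or the 1D window) by at least one base
pair counts as contained; strand is ignored throughout. A SNP with no
significant contacts yields an empty 3D mapping, never an error, and SNPs
without a value for a measure contribute nothing to the distribution
summaries (they are not zero-filled).

## DA aggregation

Medians use linear interpolation between the central order statistics;
quartiles use the type-7 linear-interpolation estimator (the `quantile()`
default), exposed as `quantile_type` for sensitivity checks since published
tables rarely state their estimator. `IQR = Q3 - Q1` exactly. For
violin-style reporting, outliers are values outside
`[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` and whiskers are computed after removing
them — a convention inferred from standard practice; it affects plots only,
never the tables. Target genes of a mapping are the union of the mapped
elements' targets, de-duplicated by symbol, with the median taken over
their gene-level DA scores.

## TAD calling

A TopDom-style procedure runs per chromosome on raw intra-chromosomal
counts. For the boundary between bins `i` and `i+1`, the signal is the mean
count of the `w x w` submatrix spanning the boundary (`w = 5` bins by
default — the window regime of the original method, whose published
parameterization for any given dataset is typically unstated — truncated at
chromosome edges). Boundary candidates are leftmost window minima of this
signal; a candidate is accepted when a one-sided rank-sum test finds the
cross-boundary counts stochastically smaller than the pooled within-side
counts at `p < 0.05`. The rank-sum p-value is exact (midrank permutation
enumeration) whenever the number of assignments is small, and otherwise
uses the tie-corrected normal approximation with continuity correction;
empty or fully tied samples return `p = 1`. TADs are the inter-boundary
segments; segments shorter than `min_tad_size = 2` bins merge into their
predecessor, runs of at least `w` zero-coverage bins are excluded as gaps,
and a chromosome shorter than `2w` bins yields one whole-chromosome TAD
with a warning. The calls are deterministic and invariant under global
scaling of the matrix.

## What the synthetic generator emulates

`sim_config()` describes a genome with three planted structures:

* **distance decay** — expected pair count `A * d^(-alpha)` with
  `alpha = 1` and base intensity `A = 200`, the near-diagonal depth of a
  deeply sequenced 5–10 kbp map, chosen so that a `lambda = 5` loop at the
  longest planted separation remains detectable against the genome-wide BH
  cutoff;
* **TADs** — boundaries partitioning each chromosome (roughly one per 100
  bins), within-domain counts enriched by `1 + tau` (`tau = 2`);
* **loops** — `n_loops = 40` bin pairs separated by 10–50 bins
  (100–500 kbp, the canonical loop scale) enriched by `1 + lambda`
  (`lambda = 5`), with Poisson noise by default and a negative-binomial
  option for over-dispersion robustness checks.

Sixty high-risk SNPs (log-uniform p-values in `[1e-30, 5e-8]`) are placed
in loop-anchor bins — one designated end per loop, reused when SNPs
outnumber loops, with an error once they outnumber the anchor bins — and
240 background SNPs land elsewhere with `p > 5e-8`. Each SNP-designated
anchor bin receives one background enhancer and one background TF binding
site, representing the variant's linear regulatory neighborhood; each
opposite loop end receives one associated enhancer and TF binding site; 300
enhancers and 200 TF binding sites are scattered uniformly as background.
DA scores are drawn from `N(2.5, 0.5)` (background) and `N(5.0, 0.5)`
(associated), truncated at zero — magnitudes calibrated to the roughly
two-fold orderings seen in published DA tables, a calibration, not a
generative claim. TF disease-associated flags follow Bernoulli(0.33)
(background) and Bernoulli(0.67) (associated), reproducing the
two-thirds-versus-one-third contrast; `tf_score_mode = "score"` switches
TFs to numeric scores instead. Target genes come from class-matched pools
whose gene-level scores follow the element's class.

The TAD-stratification effect is a separate toggle: `tad_da_shift`
(default 0) adds a constant to the numeric scores of elements inside
planted TADs that carry a high-risk SNP. Keeping it off by default keeps
the loop-mapping contrast and the TAD contrast orthogonal, so each analysis
is validated against exactly the structure it claims to detect.

What the generator does **not** emulate: polymer physics, balanced
matrices, linkage disequilibrium among SNPs, sequence content, assay
biases (GC, mappability), or realistic TAD nesting. Passing tests
demonstrate that the pipeline recovers planted structure of the stated kind
and magnitude — they do not certify performance on real Hi-C maps, whose
biases the generator deliberately omits.

## Validation strategy and problem sizes

The test suite checks the statistical primitives against independent
oracles (exact PMF sums for the binomial tail, a hand-written step-up for
BH, brute-force scans for 1D mapping, bitmask enumeration for the rank-sum
tail), property-style invariants (monotonicity, permutation invariance,
shift equivariance, half-open partitioning), and end-to-end recovery on
synthetic genomes: calibration on loop-free null maps (20 seeds of a
400-bin chromosome), the 1D-versus-3D DA ordering (20 seeds of the default
2,000-bin genome), and TAD boundary recovery plus SNP-rich/control
stratification (20 seeds of a 200-bin chromosome with eight planted
domains and a `+1.0` shift). These sizes keep the full suite around two
minutes on one CPU while leaving each Monte-Carlo comparison dozens of
independent replicates. `scripts/acceptance.R` reruns the same analyses
from scratch for a single user-supplied seed and writes the headline
quantities as JSON.

## Known limitations

* The flat-strata expectation under-corrects residual curvature within each
  stratum; with TAD-structured matrices, loops crossing TAD boundaries can
  be partially absorbed into the stratum mean and missed. The stratum count
  and distance bounds are exposed for tuning.
* Only one fragment is selected per SNP (per class); multi-way hubs are
  summarized by their single most confident contact.
* The TAD caller emits contiguous non-overlapping domains; nested or
  hierarchical domain structure is out of scope.
* Inter-chromosomal contacts form a single expectation stratum, which is
  coarse when translocation-like enrichment is present.
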