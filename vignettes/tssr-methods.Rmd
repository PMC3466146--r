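---
title: "Translation stop signal ratios: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translation stop signal ratios: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tssr)
```

## The signal and its model

A protein-coding gene read on its coding strand carries the stop trimers
TAA, TAG and TGA in three contexts.  On the codon frame (frame 1) a stop
trimer is a stop codon — a well-formed CDS has exactly one, at its end.
On the two off-frames (frames 2 and 3) stop-like trimers are "premature"
or "hidden" stop codons: frame-2 signals arise from codon pairs where the
lead codon donates its last two bases (the lead codons are those of the
nonpolar residues L, I, V, M), frame-3 signals from thymine-ending lead
codons donating one base.  `tss_count()` reduces a gene to the 9-vector of
these counts in the fixed order TAA/TAG/TGA within frames 1, 2, 3.

All ratio statistics are plain normalizations of that vector:
`genic_tssr()` (per gene, 9 proportions), `frame_tssr()` (one frame, 3
proportions), and `genomic_tssr()` per genome.  The package's premise,
tested throughout the suite, is that these ratios are a stable, heritable
genome signature: profile distances recover phylogenetic structure without
alignment.

### Counting conventions

* Frame *f* scans trimer windows at 0-based offsets ≡ *f*−1 (mod 3); the
  terminal stop codon is counted on frame 1.
* Sequences are uppercased and RNA U is mapped to T on ingest.  A window
  containing any non-ACGT letter (IUPAC ambiguity codes, gaps) never
  matches: ambiguity is treated conservatively and deterministically.
* Lengths that are not multiples of 3 are accepted — only complete
  windows are scanned — but flagged with a warning, because real
  annotation sets contain imperfect CDSs and silently mangling them would
  hide upstream problems.
* Genes annotated as *authentic frameshift* span two reading frames, so
  no single frame decomposition is correct for them;
  `read_cds_fasta(exclude_frameshift = TRUE)` drops them (by header
  substring) before any counting.
* A documented quirk of the classic worked example: the hypothetical gene
  is described as 15 codons but printed as 12, and the printed sequence
  has no frame-3 signal, while its published 9-scalar summary is
  (1,0,0,2,1,1,1,1,1).  The counter follows the printed sequence (the
  brute-force position scanner in the test suite agrees); the ratio
  examples take the published 9-scalar as their input, as stated.

### Pooled versus mean genome profiles

"Average of the Genic-TSSR over all genes" and "divide each pooled
counter by the grand total" are different statistics: pooling weights
genes by their total signal count (roughly, gene length), the mean gives
each gene equal weight.  The published per-genome arithmetic (the E. coli
K-12 example: nine pooled counts summing to 152100) is the pooled form,
so `mode = "pooled"` is the default and is what reproduces the packaged
61-genome table; `mode = "mean"` is provided because the verbal
definition reads that way and the distinction can matter for genomes with
skewed gene-length distributions.  For a single gene, and for genes of
equal totals, the two coincide (an identity the tests exercise).  Genes
with zero signals have undefined ratios: they are excluded from the mean
(with a warning path for callers) and contribute nothing to the pool.

## Profile trees

`tssr_dist()` computes city-block (L1) distances between raw Genomic-TSSR
vectors — no centering, standardization or correlation transform, since
the ratios are already commensurable proportions on the simplex.
`tssr_cluster()` agglomerates with complete linkage by default (average
and single are available for exploration).

Two numerical choices matter here:

* **Tie-breaking.**  Published profile tables are rounded to 3 decimals,
  which produces *exact* distance ties; off-the-shelf agglomeration
  breaks ties by input order, so reordering rows can change the tree.
  The package's agglomerator is deterministic and order-invariant: among
  minimal-distance pairs it merges the pair whose alphabetically smallest
  member labels sort lowest, with the smaller-keyed cluster as left
  child.  A permutation-invariance test (20 random row orders of the
  61-genome table) locks this in.
* **Display scale.**  Merge heights are reported raw; `to_newick(scale =
  "unit")` divides all heights by the root height so the displayed tree
  runs 0–1, matching the usual dendrogram presentation of these
  profiles.  Newick branch lengths follow the midpoint convention (a
  merge at height *h* puts its children *h*/2 below it).

`smallest_containing_cluster()` and `is_monophyletic()` operationalize
branch-membership claims: the lowest node whose leaf set covers a query
group, and whether that node contains nothing else.  On the packaged
61-genome table the Escherichia+Shigella group (28 genomes) and the
Rickettsia group (11) each form exact clusters and the three subphyla are
monophyletic — the acceptance suite recomputes this from the raw table on
every run.

## Correspondence analysis of per-gene counts

`tssr_ca()` implements classical CA: with `P` the count matrix over its
grand total, row masses `r` and column masses `c`, the standardized
residuals `(P − rcᵀ)/sqrt(rcᵀ)` are SVD-decomposed; principal coordinates
scale the singular vectors by the singular values over the square-root
masses, and total inertia equals the Pearson chi-square over the grand
total (asserted to 1e-9 against an independent chi-square computation).
CA is run on **raw counts**, not ratios: CA's row-profile normalization
makes this equivalent to analyzing Genic-TSSR while keeping
total-count masses, which is the statistically proper weighting.  Axis
signs are fixed by making the largest-magnitude column coordinate
positive on each axis, so results are reproducible across platforms.
All-zero rows carry no profile and are dropped with a message.

Group summaries (`ca_group_summary()`) report mass-weighted centroids on
axes 1–2 and a 95% **data ellipse** — the member-coordinate covariance
scaled by the chi-square(2 df) quantile, 5.991 at 0.95.  Data ellipses
(describing the gene cloud) rather than confidence-of-centroid ellipses
were chosen because the analysis is about whether gene *clouds* of
different species overlap; a Monte-Carlo test checks the 95% coverage on
bivariate normal data.  Groups with fewer than 3 members get a centroid
but no ellipse.

## Positional bias and the permutation KS test

`assign_categories()` reduces each gene to its circular midpoint
(1-based, inclusive coordinates on a circular chromosome; genes may wrap
the origin of the coordinate system) and classifies it three ways:
replichore (the arc from Ori forward to Ter is Right, the complement
Left), orientation (Forward = `+` strand), and proximity (on each side of
Ori the `window_n` nearest midpoints are the Ori window, default 100 per
side, and likewise for Ter; overlapping windows are an error rather than
a silent reassignment).  Nearest-gene ties are broken by gene id.

`tssr_ks_test()` compares two equal-sized gene groups.  The group profile
is, by default, the per-signal mean of the genes' Genic-TSSR vectors
("average percentage of counts"); the statistic is the discrete
two-sided KS distance — the maximum gap between the two 9-bin cumulative
profiles accumulated in canonical signal order.  Calibration repartitions
the pooled genes into two disjoint halves of the original sizes, M = 1000
times by default, and reports p = Σ I(Dₘ ≥ D)/M (a tolerance of 1e-12 on
the comparison keeps relabelings that exactly reproduce the observed
split on the ≥ side).  Choices worth noting:

* Disjoint repartition (not bootstrap) is the default reading of
  "selected twice"; `replace = TRUE` gives the bootstrap variant.
* `profile = "pooled"` weights genes by their totals instead; with equal
  group sizes and equal per-gene totals it coincides with the mean form.
  This is the flagged alternative for the ambiguity between computing D
  on group means versus on pooled group counts.
* The per-group `sd_of_means` — the SD over the nine entries of a group's
  mean profile — is reported as a scalar summary of profile evenness,
  matching how such screens are usually presented.
* With a fixed `seed` the whole result object is bit-reproducible, and
  the caller's RNG state is restored.

The published per-chromosome p-values (p = 1 for replichore and strand
splits, p = 0.2 for Ori vs Ter on E. coli K-12, Ori 3923499, Ter 1588799)
depend on the original per-gene data, which is no longer distributable;
the suite instead checks the test's statistical behavior: null
calibration (same-usage groups give p > 0.05 in at least 90 of 100
replicates at n = 200, M = 1000) and power (a doubled frame-2 TGA
junction effect is detected at p ≤ 0.05 with the same sizes).

## The synthetic generator

`codon_usage()` defines the generative model the test suite runs on: a
gene is n body codons drawn from a sense-codon distribution plus one
terminal stop from a stop-usage distribution.  Defaults, chosen once as
plausible study conditions:

* **Sense usage** from an independent-nucleotide composition model at
  GC = 0.508 (E. coli-like): each codon's probability proportional to the
  product of its base frequencies, stops excluded.  This is the simplest
  null model with a single interpretable knob (GC), and it makes every
  expectation exactly enumerable.
* **Stop usage** (0.631, 0.076, 0.293), the frame-1 ratio implied by the
  published pooled E. coli K-12 stop counts (2707, 326, 1256).
* **Gene length** 300 body codons, a typical bacterial mean.

`expected_tss_counts()` is the analytic oracle: frame-1 expectations are
the stop usage; off-frame signals arise only at codon junctions, so their
expectations are pair-probability sums over the n−1 body junctions,
enumerated exactly over all codon pairs (the body→stop junction is
included for completeness but provably contributes nothing: every stop
starts with T and no stop trimer has T second or third).  `junction_bias`
multiplies the transition weight of signal-forming codon pairs (e.g.
`c("TGA.2" = 2)`), turning the body into a first-order Markov chain;
expectations then propagate the position marginals through the transition
matrix.  Note the realized pair frequency scales by `b/(1 + extra row
mass)`, not exactly `b`, because the biased rows renormalize — the tests
pin this down in closed form at a single junction.

For the separated-gene-cloud experiments the suite uses two deliberately
divergent usages emulating the real extremes seen among proteobacteria:
an AT-rich, TAA-dominated profile (Rickettsia-like; GC 0.32, stop usage
0.8/0.1/0.1, frame-2/3 TAA junctions boosted ×2) and a GC-rich,
TGA-dominated one (Neisseria-like; GC 0.55, stop usage 0.4/0.1/0.5,
frame-2/3 TGA junctions boosted ×3).

What the generator does **not** emulate: realistic gene-length
distributions, amino-acid-preserving constraints, dicodon correlations
beyond the injected bias, horizontal transfer, or any positional
(Ori/Ter) structure unless injected.  Passing tests therefore demonstrate
the estimators' correctness and calibration under a clean codon model,
not that real genomes satisfy that model.

## Problem sizes and determinism

The suite's simulation scales are: 1000 random sequences for the counting
oracle; brute-force linkage checks at up to 7 points; 20000 genes of 100
codons for Monte-Carlo convergence of the expectation oracle; 100
replicates at n = 200 per group and M = 1000 for KS calibration; 500
genes per group for the CA cloud experiments; 3 × 3 simulated genomes of
200 genes for end-to-end cluster recovery.  These sizes give comfortable
statistical margins (3-SE tolerances where a standard error is defined)
while keeping a full run around half a minute.  Every stochastic step
takes an explicit seed; nothing draws from global, time-based randomness.

## Known limitations

* The packaged 61-genome table is rounded to 3 decimals, so recomputed
  trees can differ in their smallest merge heights from trees built on
  full-precision profiles; the published group structure is nevertheless
  reproduced exactly.
* Counting assumes the input is a CDS on its coding strand; the package
  does not extract CDSs from raw genomic DNA or GenBank/GFF annotation.
* The KS permutation test conditions on equal group sizes, as in the
  windowed Ori/Ter design; unequal groups are rejected rather than
  approximated (the whole-chromosome wrapper trims to equal sizes
  deterministically).
* Monophyly queries answer set questions about one tree; no bootstrap or
  other support values are computed.
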