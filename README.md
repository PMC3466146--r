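# tssr — Translation Stop Signal Ratio profiling of bacterial genomes

`tssr` is an alignment-free toolkit for bacterial phylogenetic profiling
built on a simple observation: the stop trimers TAA, TAG and TGA occur not
only as a gene's terminating codon (reading frame 1) but also, abundantly,
off-frame (frames 2 and 3), where they are known as premature or hidden
stop codons.  The quantity and quality of these nine signal classes are
under selection, and phylogenetically related bacteria carry strikingly
similar signal profiles — similar enough to recover a credible phylogeny
from ratios of nine numbers per genome, with no sequence alignment at all.

It is intended for microbial genomics researchers who want a fast,
whole-genome, alignment-free phylogenetic signature, and for anyone
studying hidden-stop-codon biology (off-frame ribosome protection, codon
pair bias, replication-associated mutational/recombinational asymmetry).

## The statistic

For a coding sequence of length *L* (coding strand, stop included), frame
*f* ∈ {1,2,3} consists of the trimer windows at 0-based offsets *p* ≡
*f*−1 (mod 3).  Counting TAA/TAG/TGA occurrences per frame gives a
9-vector of counts

&nbsp;&nbsp;**c** = (TAA₁, TAG₁, TGA₁, TAA₂, TAG₂, TGA₂, TAA₃, TAG₃, TGA₃).

- **Genic-TSSR** = **c** / Σᵢcᵢ — a gene's signal profile on the simplex.
- **TSSR-f** — one frame's 3 counts normalized to proportions.
- **Genomic-TSSR** — genome-level profile: either the *pooled* form
  (sum all genes' counts, then normalize — the convention behind the
  published per-genome tables) or the *mean* of the per-gene Genic-TSSRs.

Downstream analyses:

- **Profile tree** — city-block (L1) distances between Genomic-TSSR
  vectors, complete-linkage agglomeration with a deterministic,
  input-order-invariant tie-break; Newick export; monophyly queries.
- **Correspondence analysis** — per-gene count matrices decomposed into
  principal coordinates, with group centroids and 95% data ellipses.
- **Positional bias** — genes classified by replichore, strand
  orientation, and proximity to the replication origin (Ori) or terminus
  (Ter); group profiles compared with a discrete two-sided
  Kolmogorov–Smirnov statistic *D* over the nine ordered signal classes,
  calibrated by M random repartitions: *p* = Σₘ I(Dₘ ≥ D)/M.
- **Simulation** — genes drawn from explicit codon-usage models with an
  exact (enumerated) expected-count oracle, including frame-specific
  junction biases for power studies.

## Worked example

The classic worked gene — twelve codons, one terminal stop:

```r
library(tssr)
gene <- "ATGGTAAGGGTGAGTATAATGGTAGCCGGTGGTTAA"
tss_count(gene)
#>      TAA.1 TAG.1 TGA.1 TAA.2 TAG.2 TGA.2 TAA.3 TAG.3 TGA.3
#> [1,]     1     0     0     2     1     1     0     0     0
```

One in-frame stop (the terminal TAA), and off-frame signals on frame 2:
two TAA, one TAG, one TGA.  Its Genic-TSSR:

```r
genic_tssr(tss_count(gene))
#>      TAA.1 TAG.1 TGA.1 TAA.2 TAG.2 TGA.2 TAA.3 TAG.3 TGA.3
#> [1,]   0.2     0     0   0.4   0.2   0.2     0     0     0
```

Clustering the packaged table of 61 proteobacterial Genomic-TSSR profiles
(`tssr_table2()`: 61 genomes × 9 ratios, each row summing to ≈1):

```r
tab  <- tssr_table2()
tree <- tssr_cluster(tab)        # city-block + complete linkage
tree
#> TSSR dendrogram: 61 leaves, complete linkage, cityblock distance
#>   merge heights: 0.001 .. 0.839

is_monophyletic(tree, grep("^Rickettsia", tab$genome_id, value = TRUE))
#> [1] TRUE
smallest_containing_cluster(tree,
  grep("^(Escherichia|Shigella)", tab$genome_id, value = TRUE))$size
#> [1] 28
to_newick(tree, scale = "unit", file = "tssr_tree.nwk")
```

The 28 Escherichia and Shigella genomes form one exact cluster, the 11
Rickettsia genomes another, and the three proteobacterial subphyla
(α, β, γ) each come out monophyletic — from nine ratios per genome.

A command-line wrapper covering the same operations
(count / profile / cluster / ca / bias / simulate) is at
`inst/cli/tssr.R`:

```sh
Rscript inst/cli/tssr.R cluster \
  --profiles inst/extdata/table2_genomic_tssr.tsv \
  --newick tree.nwk --scale unit
```

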