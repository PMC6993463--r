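---
title: "Reference-free repeat profiling: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free repeat profiling: models, parameters and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(repeatpop)
```

## The model

Skim sequencing samples a genome so thinly that assembly is impossible,
but repetitive families — present in hundreds to thousands of copies —
are still sampled in proportion to their genomic abundance. `repeatpop`
exploits this: reads from all individuals are pooled, every read pair is
scored for sequence similarity, and the hits define an undirected,
simple, weighted graph `G = (v, e)` whose vertices are reads and whose
edge weights are alignment bit scores. Edges below 100 bits are excluded
(the threshold is inclusive: exactly 100.0 is kept). Densely
interconnected regions of this graph are families of related repeats;
greedy modularity maximization (fast_greedy, i.e. Clauset–Newman–Moore
agglomeration on the edge-weighted graph) recovers them as clusters.
Because each read keeps its individual-of-origin label, counting reads
per individual per cluster yields an abundance matrix: the genome-wide
repeat profile of every individual, obtained without any reference.

Downstream of clustering, three analyses reuse that matrix:

1. **Differential abundance.** Per cluster (and separately per annotation
   class), a pooled-variance two-sided t-test compares the two
   populations; Benjamini–Hochberg correction is applied across all
   clusters as one family and across all classes as another, and units
   are flagged at `q < alpha`. Counts are tested raw because the skim
   design gives every individual the same number of reads; a
   total-count normalization flag exists for unbalanced inputs.
2. **Chromosome painting.** The 100 most abundant canonical 12-mers of a
   cluster are mapped exactly (both strands, overlapping occurrences all
   counted, hit = match start) onto a reference assembly; hits are
   counted in 200 kb windows stepped by 100 kb, min/max scaled per
   cluster across the whole genome, loess smoothed per chromosome for
   display, and the scaled (unsmoothed) track is correlated with the
   fraction of each window covered by merged gene annotations.
3. **Structure contrast.** The same 2-component PCA machinery (column
   centering, SVD, fixed sign convention) runs on the min/max scaled
   abundance matrix and on SNP genotypes encoded 1 = major homozygote,
   0 = minor homozygote, heterozygotes masked and mean-imputed. A mean
   silhouette over the two population labels in each score plane turns
   the visual "separated vs intermixed" judgement into a number.

## The internal aligner

The original analysis used megablast for the all-vs-all comparison. At
desk scale `repeatpop` ships its own seed-and-extend scorer so no
external binary is needed: exact shared 16-mers on either strand anchor
ungapped extensions (match +1, mismatch −2, X-drop 20; N never matches
or seeds), and the best raw score `S` is converted to bits via the
Karlin–Altschul form `(λS − ln K) / ln 2` with megablast-like λ = 1.28,
K = 0.46. Two consequences worth knowing: a perfect 150 bp duplicate
scores ≈ 278 bits, and the 100-bit reporting threshold corresponds to a
raw score of 54, i.e. roughly a 54 bp perfect match — this is the
shortest homology the graph can see. Candidate pairs in `all_vs_all()`
come from a shared canonical-seed index; pairs sharing no seed can never
reach the threshold, so the indexed search provably equals brute-force
scoring of every pair (and is tested for exact equality against it).
Gapped alignment is deliberately omitted: for 150 bp reads at
family-level identity, indels shift the optimum by a few points at most,
and `import_hits()` accepts real BLAST tabular output whenever exact
megablast replication matters.

Word size, E-value cutoff and masking settings of the original run are
not on record; the defaults above are documented stand-ins, not
reconstructions.

## Community detection details

`detect_communities()` delegates the agglomeration to igraph's
`cluster_fast_greedy` (the same function family the original analysis
used) on the weighted graph, then cuts the merge dendrogram itself at
the step whose partition maximizes weighted modularity. The explicit cut
matters in one edge case: igraph's own `membership()` can return the
partition one step before a zero-gain merge (a single-edge graph comes
back as two singletons although the merged partition has Q = 0 versus
−0.5). Clusters are renumbered by descending size — `cluster_0` is the
largest — with ties broken by the smallest member read id, matching the
rank-based naming used downstream. Reads with no retained edge are never
forced into clusters; they are reported as unclustered.

One spec-level expectation was corrected during development: for two
unit-weight triangles joined by a weight-1000 bridge, exhaustive
enumeration of all 203 partitions shows the modularity optimum is two
communities with the bridge endpoints together (Q ≈ 0.0079), not a
single community (Q = 0). The tests assert the exhaustively verified
optimum.

## The synthetic world

The generator emulates the statistical structure the analysis assumes,
with defaults chosen once:

- **Families.** A few large divergent LTR-like families plus tandem
  arrays dominate; each family is one ancestral monomer (uniform random
  composition) and `n` copies mutated by independent per-site
  substitution at the declared divergence. Substitution-only (no indels)
  keeps read lengths and k-mer arithmetic exact; divergence is the one
  knob behind the "tight vs dispersed cluster layout" age signal.
- **Genomes.** Background is uniform random sequence, so low-copy
  background cannot form large clusters — the skim premise. Genes
  (3 kb, count scaled to genome size) are placed along a smooth density
  gradient (default linear, gene-rich at the chromosome start,
  caricaturing the telomere-to-pericentromere gradient). Tandem arrays
  are placed first as one contiguous head-to-tail locus — placing them
  after the genes would leave no free gap of array size on a desk-scale
  chromosome — then genes, then dispersed copies, none overlapping.
  Every insertion lands in the truth table.
- **Insertion bias.** A family's placement weight is log-linear in the
  realized local gene density `g` (1 kb bins, ~50 kb smoothing):
  `w ∝ exp(3 b (2g − 1))` for bias `b ∈ [−1, 1]`. `b = 0` is uniform;
  `|b| = 1` concentrates insertions strongly enough that the painting
  stage recovers the sign from ~100 windows. The form was fixed before
  any acceptance measurement.
- **Populations.** Copy numbers per individual are Poisson around the
  family mean, with population 2's mean multiplied by `repeat_effect`
  (1 = the null). SNPs follow a symmetric Balding–Nichols draw:
  ancestral `p ~ U(0.1, 0.9)`, each population's frequency
  `~ Beta(p(1−F)/F, (1−p)(1−F)/F)` with `F = snp_divergence`; calls are
  homozygous draws at the population frequency with heterozygotes
  injected at a small rate (inbred panels are nearly homozygous).
  Defaults mirror the study design: two labelled populations ("SS",
  "NSS"), 47 individuals each, 1585 markers, 50,000 reads of 150 bp per
  individual.
- **Reads.** Uniform start positions, uniform strand (minus-strand reads
  reverse-complemented), labels carried on every read; optional pairs
  share a fragment id so down-sampling can take one read per pair.

What the generator does **not** emulate: indels and structural variants,
transposition mechanism and nested insertions, sequencing error and
quality scores, GC bias, heterozygous repeat loci, and linkage between
SNPs and repeat copies. A green simulation therefore establishes that
the pipeline's logic recovers planted structure of the stated kind — not
that it is robust to every artifact of real sequencing data.

## Numerical choices

- **Read-origin truth.** A simulated read counts as family-derived when
  it overlaps a truth placement by ≥ 54 bp (the minimal alignable
  homology at the default threshold), taking the largest-overlap family.
  Purity checks use this definition so "background" never absorbs reads
  the graph can legitimately connect.
- **Window geometry in simulations.** Production defaults are 200 kb /
  100 kb, as published. Desk-scale genomes (~1 Mb) are painted with
  20 kb / 10 kb windows, preserving the windows-per-genome count (~100)
  rather than the absolute window size.
- **Loess.** Local linear fits with tricube weights over the
  `ceiling(span · n)` nearest windows, span 0.1 per chromosome by
  default; constant and exactly linear tracks are reproduced exactly.
  Correlations use scaled-but-unsmoothed values pooled genome-wide
  (smoothing is display-only); per-chromosome correlation is available.
- **Scaling degeneracies.** Min/max scaling maps constant tracks and
  constant abundance columns to zeros. Zero-variance tracks make
  correlation undefined and are reported as such, never as NaN.
- **t-test degeneracies.** Zero pooled variance with equal means gives
  t = 0, p = 1; with unequal means it is an error rather than a silent
  infinity.
- **PCA.** Column-mean centering and SVD; within each component the
  largest-magnitude loading is made positive, so score plots reproduce
  run to run. Masked genotypes are mean-imputed by default ("drop"
  behind a flag) — the published analysis says only "masked", and
  imputation keeps all markers while adding no between-population
  signal.
- **Seeds.** Every generator and the layout are pure functions of their
  seed; `derive_seed(run_seed, stage_name)` hashes stage names into
  `[1, 2^31 − 2]` so stages draw from independent streams and a full
  pipeline rerun is byte-identical.
- **Fruchterman–Reingold layout.** Unit-square initialization from the
  seed, 500 linearly cooled iterations, `k = sqrt(1/|V|)`; coordinates
  are for visualization and property tests only and never feed
  downstream computation.

## Known limitations

- The seed-and-extend scorer requires an exact shared 16-mer; families
  more diverged than ~15–20% per site fragment into multiple clusters,
  as do long monomers tiled by short reads (the read-overlap graph of a
  3 kb monomer is segment-like and modularity happily cuts it). That is
  a property of graph-based clustering itself, visible in the original
  728-cluster inventory, not a defect the tests hide: the recovery
  criterion states its world (short monomers, divergence ≤ 0.05).
- All-vs-all scales quadratically in candidate pairs; the desk-scale
  target is ≤ ~10,000 pooled reads. Beyond that, run real megablast and
  feed `import_hits()`.
- Annotation is a best-bit-score vote against a user FASTA; it inherits
  that library's completeness and does not attempt structural TE
  annotation (LTR boundaries, target-site duplications).
- The silhouette contrast quantifies separation of two predefined
  labels in a 2-D score plane; it is not a clustering method and says
  nothing about k > 2 substructure.
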