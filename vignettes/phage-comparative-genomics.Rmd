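---
title: "Methods: pham clustering and phage cohort comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pham clustering and phage cohort comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phamily)
```

## The model

Phage genomes are mosaic: homologous genes travel between otherwise
unrelated genomes, so whole-genome trees mislead and the community instead
organizes cohorts by gene-family membership. This package's core object is
a partition of all encoded proteins into *phamilies* (phams) built from
exact pairwise comparisons:

1. **Score.** Each protein pair gets an exact Smith–Waterman local
   alignment under BLOSUM62 with gap open 11 and gap extend 1 (a gap of
   length $k$ costs $11 + k$). The raw score $S$ is converted to an
   E-value by the Karlin–Altschul formula
   $E = K\,m\,n\,e^{-\lambda S}$ with the published gapped constants
   $\lambda = 0.267$, $K = 0.041$ and $m, n$ the two sequence lengths.
   Comparisons are pairwise, not database searches, so the search space
   defaults to $m \times n$; a `fixed_db` policy exists for users who want
   database-style E-values.
2. **Identity.** Percent identity is measured on a *global* (full-length)
   alignment of the pair, identical columns over alignment length with gap
   columns counted. This is a deliberate design choice: identity over the
   local alignment's columns looks attractive (one aligner, one code path)
   but is unusable with an OR-combined threshold, because two unrelated
   proteins almost always share some short stretch whose local identity
   exceeds any reasonable cutoff. Full-length identity behaves like the
   multiple-aligner identities traditionally used for this purpose.
3. **Linking rule.** A pair is linked iff $E < 10^{-50}$ **or**
   identity $> 32.5\%$ — strict inequalities, so boundary values fail.
   Phams are the connected components of the linked graph (single
   linkage): a protein belongs as soon as it passes the cutoff with *one*
   other member. Size-1 phams are orphams. Identical duplicate sequences
   (tandem in-genome duplicates) remain distinct members of their pham.

Because the aligner is symmetric, each unordered pair is compared once;
the both-directions question that arises with heuristic search tools does
not apply here.

## Derived tables

- `pham_summary()` reports pham/orpham counts with percentages rounded
  half-up to one decimal. Half-up (not R's banker's rounding) is used for
  every reported percentage in the package; `round_half_up()` is exported.
- `shared_pham_table()` classifies each gene of a focal phage into exactly
  one of: shared with a phage outside the focal group, focal-group-only
  (pham size ≥ 2, members all inside), or orpham. The three categories sum
  to the gene count by construction.
- `remove_genome_recount()` answers "which proteins would be orphams had
  genome X never been sequenced" by re-clustering from scratch without X —
  not by patching the old partition, so the answer is exact.

## Core-genome percentages

`core_gene_count()` counts reference proteins whose *best* raw score
against the comparison proteome is at least 75. The floor is interpreted on
the raw-score scale (it is exposed as `core_score_params(score_threshold=)`
since conventions differ between tools); the count is unidirectional and no
reciprocal-best-hit refinement is applied, matching default behaviour of
classic core-genome counters. Percentages (count over the reference's
proteome, two decimals, half-up) populate an asymmetric matrix; the family
grouping rule links two genomes when **either** directed percentage reaches
40% and takes connected components. The symmetric-OR choice reflects how
the rule is applied loosely in practice; with near-equal proteome sizes OR
and AND rarely differ, and the cutoff is a parameter.

## Terminase tree and packaging inference

Distances between large terminase proteins are p-distances,
$d = 1 - \mathrm{identity}/100$, from the same pairwise aligner — not a
substitution-model distance. The tree's job is to display pham-consistent
groupings, not to estimate branch lengths, and keeping one aligner keeps
the whole package deterministic. Neighbor joining follows Saitou–Nei with
two numerical conventions: ties on the Q-matrix break toward the smallest
index pair, and a negative branch-length estimate is clamped to zero with
the deficit moved to its sister branch, preserving the path length through
the joined node. On an additive matrix the tree reproduces all pairwise
distances exactly (this is tested against random trees, with the
independent `ape::nj` implementation as a topology cross-check).

Packaging calls are deliberately conservative: a strategy is assigned only
when a characterized phage shares the terminase pham, an orpham terminase
is `undetermined` with evidence `"orpham"`, and two different characterized
strategies inside one pham abort with an error rather than vote — mixed
strategies in a terminase pham would contradict the premise that terminase
family predicts packaging, so it must surface loudly.

## Whole-genome identity and dotplots

Nucleotide identity uses exact global alignment with match +1, mismatch −1
and −2 per gap position. Quadratic-memory aligners cannot hold the DP
matrix of two ~50-kb genomes, so the package ships a compiled
linear-space divide-and-conquer (Hirschberg-style) implementation that
returns the column statistics of one optimal alignment; traceback ties
prefer diagonal, then the gap consuming the first sequence, and the
divide-and-conquer split takes the smallest crossing column, so results are
deterministic. For equal-length sequences differing only by substitutions
the optimum is gapless and identity reduces to Hamming identity — the
near-twin genome scenario (54,312 bp differing at 80 positions → 99.85%)
is computed through this exact path, not by the shortcut.

Dotplots are exact word matches at a configurable word size; for
nucleotide input, reverse-complement matches are indexed too and tagged
separately. A word size longer than a sequence yields an empty plot with a
warning rather than an error.

## Morphology

Replicate measurements are summarized as mean ± *sample* (n−1) standard
deviation, one decimal, half-up; groups with fewer than two replicates are
an error because the sd is undefined. Morphotype classification is rule
based: a contractile sheath always means myovirus; otherwise the capsid
height/width ratio separates elongated from round siphovirus capsids at a
default cutoff of 1.2, chosen because published elongated capsids sit at
ratios ≥ 1.47 and round ones at ≤ 1.11, leaving the boundary uncontested;
missing measurements give `siphovirus_unclassified`. Co-isolated phages are
matched to genomes by rank: longest tape-measure-protein gene to longest
tail. With all lengths distinct the rank bijection is the unique assignment
with zero rank violations; ties are an error rather than an arbitrary
choice.

## The synthetic cohort generator

`generate_cohort()` emulates a small cohort of related phage genomes with
full ground truth. Defaults describe the study conditions the package
targets: ~50 kb genomes, 80 genes, 90% forward-strand genes, GC ≈ 39%,
log-normal gene lengths (median 600 bp, clipped to 150–4,500 bp so
TMP-scale genes occur), intergenic spacers of 2–150 bp, and one designated
tape-measure-protein gene (2,400 bp ancestrally, resizable per leaf via
`tmp_lengths`).

Evolution runs root-to-leaves down a random genealogy. Per branch:

- **Substitutions** at `substitution_rate` per site (default 0.02),
  applied at the nucleotide level and uniformly — synonymous and
  non-synonymous alike; protein divergence is *measured*, never targeted.
  Two guard rails keep every CDS translatable: the terminal stop codon is
  immutable and a substitution that would create an in-frame stop is
  redirected to another base.
- **Gene loss** and **tandem duplication** per gene (defaults 0.02 each);
  a duplicate is inserted next to its parent, diverged by one extra round
  of substitutions, and keeps its parent's ortholog-group label.
- **Gene gain** per branch (default probability 0.3): a novel random gene
  with a fresh group label. A gain on a pendant branch is a future orpham
  by construction; a gain on an internal branch is inherited and founds its
  own small pham.
- **Horizontal block transfer** per branch (default 0.1): 2–4 consecutive
  genes copied from another already-materialized lineage, labels carried —
  the "shared block between otherwise dissimilar genomes" scenario.

Two composition details matter for realism. Excluding the three stop
codons from coding sequence biases GC upward (stops are AT-rich), so gene
bodies are drawn from the 61 sense codons under a base composition
*calibrated* (by root finding) so the expected GC equals the target. And
the substitution kernel draws replacement bases from the stationary
composition rather than uniformly, so heavy mutation does not drift GC
toward 50%. Emitted genomes land within ±2 percentage points of the GC
target at default sizes.

What the generator does **not** emulate: codon usage bias, recombination
hotspots within genes, overlapping genes, sequencing error, or assembly
artifacts. Passing the recovery tests therefore shows the pipeline is
correct on clean annotated genomes with known homology structure; it does
not certify behaviour on mis-annotated or frame-shifted real data.

Everything is reproducible: one seed in `cohort_params()` fixes the
genealogy, all sequences, all events, and the written GenBank files byte
for byte.

## Problem sizes and test design

The test suite exercises every operation against independent oracles:
exhaustive dynamic-programming reimplementations for the local and global
aligners (50 random pairs each), brute-force reachability for single-linkage
clustering (1,000 random graphs of up to 12 proteins) and for the
core-percentage grouping, exhaustive bijection enumeration for TMP/tail
matching, and random additive trees (up to 8 leaves) for neighbor joining.
Synthetic cohorts used in tests are 2–4 genomes of 6–31 genes — large
enough to contain every event type, small enough that the all-vs-all
alignment stage stays fast; the generator's defaults themselves are larger
(80 genes) and are exercised by the same code paths. Ortholog-group
recovery is asserted to be *exact* at the divergence margins the generator
produces under its defaults (within-group protein identity far above the
32.5% cutoff, between-group identity far below it).

## Known limitations

- The aligner-based E-values share BLASTP's score scale but not its
  composition-based corrections; borderline pham membership can differ
  from heuristic-search pipelines near the $10^{-50}$ cutoff.
- Genomes are treated as linear; genes spanning the origin of a circular
  genome are rejected at construction.
- GenBank I/O is single-record and covers CDS features with
  `join`/`complement` locations; other feature types are ignored.
- `nucleotide_identity()` is one whole-sequence global alignment, not a
  fragment-based average identity; for highly rearranged genome pairs the
  dotplot is the more informative comparison.
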