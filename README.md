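# phamily

Comparative genomics of small bacteriophage cohorts, organized the way the
phage genomics community does it: by clustering every encoded protein into
**phamilies ("phams")** under explicit similarity cutoffs, and reading the
relationships between genomes off the resulting partition.

The package was built for cohorts like the *Paenibacillus larvae*
(American Foulbrood) phages — a handful of newly sequenced, annotated
genomes of 40–60 kb that need to be placed relative to each other and to
previously characterized phages — but nothing in it is host-specific.

## What it computes

**Pham clustering.** Every protein pair `(a, b)` is compared exactly:
a Smith–Waterman local alignment under BLOSUM62 (gap open 11, extend 1)
gives a raw score `S`, converted to an E-value with the Karlin–Altschul
formula

```
E = K · m · n · exp(−λ·S),      λ = 0.267, K = 0.041
```

(`m`, `n` the sequence lengths), and a full-length global alignment gives
percent identity over aligned columns. A pair is *linked* when

```
E < 1e−50   OR   identity > 32.5%        (strict inequalities)
```

and phams are the connected components of the linked graph (single linkage:
membership requires passing the cutoff with at least one other member).
Phams of size 1 are **orphams** — proteins with no detectable relative.
From the partition come the summary fractions, the per-phage shared-pham
table, phamily circles, genome-map data, and "what would be orphams if
genome X had not been sequenced" re-counts.

**Core-genome percentages.** A reference protein is a core gene with
respect to a comparison genome when its best raw alignment score there is
≥ 75. The reference×comparison percentage matrix drives the conventional
grouping rule: genomes are linked when either directed percentage is ≥ 40%,
and groups are the connected components.

**Terminase phylogeny and packaging.** Large terminase proteins get a
p-distance matrix (1 − fractional identity) and a Saitou–Nei
neighbor-joining tree (negative branches clamped, deficits moved to the
sister branch). A phage's DNA packaging strategy (headful/circularly
permuted, 3′ cohesive ends, long direct terminal repeats) is inherited from
experimentally characterized phages sharing its terminase pham; an orpham
terminase stays `undetermined`, and conflicting strategies within one pham
are an error.

**Whole-genome comparison.** Exact global nucleotide identity (match +1,
mismatch −1, gap −2) computed in linear space by a compiled
divide-and-conquer aligner, so 50-kb genome pairs align in seconds; and
exact-word dotplots with reverse-complement hits tagged.

**Morphology.** Electron-micrograph replicate summaries (mean ± sample sd),
morphotype classification (contractile sheath → myovirus; capsid aspect
ratio separates elongated from round siphoviruses), and rank-order matching
of co-isolated phages to genomes via the tape-measure-protein (TMP) gene
length / tail length correlation.

**Synthetic cohorts with truth.** `generate_cohort()` evolves an ancestral
annotated genome down a genealogy with substitutions, gene gain/loss,
tandem duplication and horizontal block transfer, emitting GenBank-writable
genomes plus per-gene ortholog-group labels and an event log — so the whole
pipeline is testable end-to-end with no downloads.

## Worked example

```r
library(phamily)

cohort   <- generate_cohort(cohort_params(n_genomes = 3, genes_per_genome = 12, seed = 7))
cohort_stats(cohort$genomes)
#>   phage     accession length_bp n_genes n_forward n_reverse gc_percent
#> 1 synphage1 <NA>           9727      12        10         2       38.6
#> 2 synphage2 <NA>          10367      13        11         2       38.8
#> 3 synphage3 <NA>          10284      12         9         3       38.9

proteins  <- cohort_proteins(cohort$genomes)
partition <- cluster_phams(build_similarity_graph(proteins), proteins)
glance(partition)
#>   n_proteins n_phams n_multimember_phams n_proteins_in_multimember n_orphams ...
#> 1         37      14                  12                        35         2

shared_pham_table(partition, c("synphage1", "synphage2", "synphage3"))
#>   phage     n_shared_outside n_focal_only n_orphams n_genes
#> 1 synphage1                0           12         0      12
#> 2 synphage2                0           12         1      13
#> 3 synphage3                0           11         1      12

core_percentage_matrix(cohort$genomes)
#> <core_genes_matrix> 3 genomes
#>                   synphage1    synphage2    synphage3
#> synphage1 (12 gp) 12 (100.00%) 12 (100.00%) 11 (91.67%)
#> synphage2 (13 gp) 12 (92.31%)  13 (100.00%) 11 (84.62%)
#> synphage3 (12 gp) 11 (91.67%)  11 (91.67%)  12 (100.00%)
```

The three genomes descend from one 12-gene ancestor: almost every protein
sits in a multi-member pham, the two orphams are lineage-specific gains,
and all core percentages clear 40%, so the cohort groups as one family.
A TMP/tail match on a co-isolated pair looks like:

```r
match_coisolated(
  tibble::tibble(genome = c("Emery", "Abouo"), tmp_bp  = c(3000, 2055)),
  tibble::tibble(image  = c("imgA", "imgB"),   tail_nm = c(162.2, 113.6))
)
#>   genome image tmp_bp tail_nm rank      tmp_ratio 1.46, tail_ratio 1.43
#> 1 Emery  imgA    3000   162.2    1
#> 2 Abouo  imgB    2055   113.6    2
```

The longest TMP gene pairs with the longest tail; the near-equal ratios
(1.46 vs 1.43) are what justify the assignment.

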