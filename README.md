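# plastocmp

Comparative chloroplast-genome (plastome) analysis for closely related
taxa, built around the workflow used to place wild rice relatives among
the A-genome *Oryza*: quadripartite structure detection, inverted-repeat
(IR) reduction, whole-plastome alignment, variant calling and
classification, coding-effect prediction, distance matrices, and
maximum-parsimony phylogenetics — together with a plastome-evolution
simulator that provides ground truth for every stage.

## The problem and the methods

Angiosperm plastomes are circular, ~120–160 kb, and quadripartite: a
large single-copy region (LSC), a small single-copy region (SSC) and two
identical inverted repeats (IR\_A, IR\_B) between them. Between close
relatives the genomes are collinear and nearly identical, so their
relationships can be read from a small number of sequence differences —
provided those differences are counted with care.

`plastocmp` implements each step of that comparative workflow:

* **Structure.** `detect_quadripartite()` finds the maximal pair of
  disjoint segments that are exact reverse complements of each other
  (plastid IRs are perfect repeats) and labels the shorter inter-repeat
  arc SSC and the longer LSC, reporting 1-based intervals on an
  LSC-first linearisation. `reduce_single_ir()` deletes the IR\_B copy
  so repeated sites are not double-weighted downstream.
* **Alignment.** `align_pair()` chains unique shared *k*-mers (longest
  increasing subsequence) and closes the gaps with affine-gap dynamic
  programming (match +1, mismatch −1, gap open −4, gap extend −1, a gap
  of length *L* costing 4 + *L*); small inputs go straight to full
  dynamic programming, and on collinear inputs the anchored score equals
  the full-DP optimum. `project_to_reference()` lifts pairwise
  alignments into a reference-coordinate multiple alignment.
* **Variants.** `call_variants()` emits one event per maximal run of
  alignment columns: SNP (single mismatch), MNV (run of ≥2 adjacent
  mismatches), insertion or deletion — each counted once regardless of
  length. `classify_ts_tv()` separates transitions (A↔G, C↔T) from
  transversions; `distance_matrices()` computes both distances used for
  comparisons: events and non-identical bases (each gap column counting
  one).
* **Effects.** `variant_effect()` rebuilds codons from the
  exon-concatenated, strand-corrected CDS, translates with the
  bacterial/plastid genetic code (table 11), and classifies coding
  changes as synonymous, non-synonymous or frameshift — for frameshifts
  reporting the truncated protein length up to the first in-frame stop.
  `clade_partition()` separates clade-specific from focal-taxon-unique
  positions.
* **Phylogenetics.** `build_character_matrix()` treats gaps and N as
  missing data with all characters unordered and equally weighted;
  `fitch_length()` scores trees by the Fitch pass; `exhaustive_search()`
  evaluates all (2n−5)!! topologies for n ≤ 9; `heuristic_search()` uses
  random stepwise addition with tree-bisection-reconnection (TBR)
  branch swapping; `consistency_indices()` reports
  CI = Σm/Σs and RI = (Σg−Σs)/(Σg−Σm); `bootstrap_support()` resamples
  columns; `neighbor_joining()` and `root_with_outgroup()` provide the
  distance-based cross-check and rooting.
* **Simulation.** `generate_ancestor()` builds an annotated
  quadripartite genome (default: LSC 80,604 + IR 20,803 × 2 + SSC
  12,347 = 134,557 bp, 162 gene entries, ~58% coding, AT 61%) and
  `evolve()` walks a tree applying SNP/MNV/indel events with transition
  bias and region-dependent rates, mirroring every IR event to the other
  copy (concerted evolution) and emitting a replayable truth set.

## Worked example

```r
library(plastocmp)

sim  <- simulate_plastomes(seed = 1)       # 8 taxa, 134,557 bp ancestor
quad <- detect_quadripartite(sim$leaves)
quad[quad$id == "TaxonA", c("lsc_end", "ira_start", "ira_end", "ssc_end", "ir_length")]
#>   lsc_end ira_start ira_end ssc_end ir_length
#> 1   80604     80605  101408  113755     20804

red <- reduce_single_ir(sim$leaves, quad)
variant_summary(call_variants(align_pair(red, "TaxonA", "O_meridionalis")))
#>   ref_id qry_id         n_variants n_deletions n_insertions n_mnv n_snp n_transitions n_transversions
#> 1 TaxonA O_meridionalis         37           6            3     3    25            15              10

aln <- multi_align(red, "TaxonA")
cm  <- build_character_matrix(aln)
glance(cm)
#>   n_taxa n_sites n_patterns n_constant n_variable_uninformative n_parsimony_informative
#> 1      8  114276        208     113308                      889                      79

fit <- heuristic_search(cm, n_additions = 200, seed = 42)
glance(fit)
#>   tree_length    CI    RI CI_excluding_uninformative n_trees method    n_evaluated
#> 1         977 0.997 0.982                      0.964       1 heuristic       39200

ape::write.tree(root_with_outgroup(fit$trees[[1]], "O_australiensis"))
#> (((TaxonA,(TaxonB,O_meridionalis)),((O_nivara,O_sativa_indica),
#>   (O_sativa_japonica,O_rufipogon))),O_australiensis);
```

The tree length (977 steps), the dominance of constant sites, and the
two-clade rooted topology mirror what this kind of analysis shows for
the real A-genome *Oryza* plastomes; per-pair variant counts sit in the
tens for close relatives and in the hundreds against the EE-genome
outgroup. `run_all()` chains every stage and writes the TSV/VCF/newick
report bundle plus a JSON manifest.

To rerun the published comparison on the real genomes, fetch the eight
GenBank accessions with `fetch_accessions()` (network required) and pass
the directory to `reproduce_study()`, which returns the measured values
next to the published ones.

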