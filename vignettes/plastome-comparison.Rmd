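---
title: "Comparative plastome analysis with plastocmp: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plastome analysis with plastocmp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the assumptions behind each stage, the counting conventions, the tunable
parameters and their defaults, what the simulator does and does not
emulate, and the places where the design was genuinely open and a choice
had to be made.

## The analysis model

The package targets complete plastomes of *closely related* taxa — the
setting in which whole-chloroplast comparison is used to resolve
relationships that individual loci cannot. Three assumptions carry the
whole workflow:

1. **Collinearity.** The genomes differ by substitutions and small
   indels, not rearrangements. This is why a reference-pivot projection
   of pairwise alignments is an adequate replacement for a progressive
   locally-collinear-block aligner: with no rearrangements, every
   genome maps monotonically onto the reference coordinate system. The
   aligner makes no attempt to detect inversions or transpositions; on
   rearranged inputs the anchor chain simply drops the displaced
   segment and the dynamic program pays for it as a large indel.
2. **Perfect inverted repeats.** Plastid IR\_A and IR\_B are identical
   (concerted evolution), so structure detection demands *exact*
   reverse-complement identity, and one IR copy is deleted before
   alignment, distance counting and phylogenetics so repeated sites are
   not weighted twice. A mismatch-tolerant detection mode would be a
   different instrument; it is deliberately not the default.
3. **Event-level counting.** A variant is one *event* regardless of
   length: a maximal run of adjacent mismatch columns is one SNP
   (length 1) or one MNV (length ≥ 2); a maximal gap run is one
   insertion or deletion. The complementary metric — nucleotide
   differences — counts non-identical bases, each gap column as one.
   Both are reported because they answer different questions: events
   approximate mutation counts; base differences measure divergence
   including indel extent.

## Conventions the implementation fixes

Several details are undefined in common informal usage and are fixed
here explicitly:

* **MNV definition.** A maximal run of contiguous mismatch columns with
  no gap in either row. An indel abutting a mismatch run is *never*
  merged into it; event classes stay disjoint.
* **Indel polarity and position.** Events are polarised relative to the
  reference (first-named) taxon. Deletions and substitution runs are
  reported at their first reference base; an insertion is reported at
  the reference position of the first base *after* the inserted
  material (equivalently: "insertion before position p").
* **Gap placement.** Gap runs are left-shifted within equal-letter runs
  after alignment, so placement is deterministic and score-preserving.
* **Ambiguity codes.** N never contributes to a variant or to a
  nucleotide difference: a column containing N is treated as carrying
  no evidence of difference.
* **Missing data in parsimony.** Gaps and N map to the full state set
  {A,C,G,T}; all characters are unordered and equally weighted.
* **Coordinates.** 1-based inclusive, on the LSC-first linearisation of
  the circle. Converters to 0-based half-open exist only internally.
* **Genetic code.** Coding effects use NCBI translation table 11
  (bacterial/plastid). The choice is configurable (`code` argument)
  because plastid annotation pipelines vary; table 11 is the standard
  for land-plant chloroplasts.
* **MNVs in codons.** An MNV inside one codon is evaluated as one codon
  change, not as independent SNPs; an MNV spanning codons compares all
  affected codons and reports the first differing residue. In-frame
  coding indels (length divisible by 3) are reported with effect
  `none` and an explanatory note — they are neither frameshifts nor
  point substitutions, and forcing them into either class would
  corrupt the counts.
* **IR-duplicated genes.** Effects are computed once, on the copy the
  variant falls in, with the copy tag carried along; IR-mirrored events
  are single evolutionary events and the distance machinery counts them
  once by operating on IR-reduced sequences.
* **Clade partition labels.** A position where each of the two clades
  is internally uniform with different alleles is *clade-specific*, and
  it is labelled after the clade whose allele the focal taxon does
  **not** share (the focal taxon joins the clade it matches). A
  position where the focal taxon's allele occurs in no other taxon is
  *focal-unique*; when both descriptions apply, focal-unique wins, so
  the sets are disjoint.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `min_ir_length` | 1000 | bp | plastid IRs are 20–26 kb; 1 kb excludes tRNA-scale repeats while catching any genuine IR |
| scoring (`match`, `mismatch`, `gap_open`, `gap_ext`) | +1, −1, −4, −1 | score | near-identical genomes: cheap extension keeps long indels as single events; a gap of length L costs 4 + L |
| anchor `k` | 21 | bp | long enough that random 21-mers are unique in a 134 kb genome, short enough to anchor densely |
| `n_additions` | 200 | replicates | random-addition starts for the TBR search, the standard setting for this analysis scale |
| bootstrap `n_reps` | 2000 | replicates | the study scale for nodal support; per-replicate searches use 1 addition, which is ample for 8 taxa |
| `kappa` | 1.5 | Ts:Tv ratio | between the ~1.0 of the closest pairs and the ~1.8 of the outgroup comparison |
| `mnv_rate`, `indel_rate` | 0.115, 0.315 | events per substitution | reproduces the SNP-dominated (~0.7 SNP fraction) event mix |
| `region_multipliers` | 1 : 1.8 : 5.2 (coding : intron : intergenic) | relative rate | matches the observed intergenic bias (two thirds of variants in one third of the genome) |
| `indel_len_mean` | 4 | bp | geometric; plastome indels are mostly short |

**kappa is defined as the expected transition:transversion event-count
ratio**, i.e. P(transition \| substitution) = kappa/(kappa+1), and
`recover_parameters()` estimates it as Ts/Tv. Under the alternative
rate-matrix convention (transition rate ÷ per-target transversion
rate) the same word would denote twice this quantity; the count-ratio
definition is the one the recovery machinery and the defaults use, and
it is what the package reports.

## The simulator: what it emulates, and what it does not

`generate_ancestor()` reproduces the geometry and composition of an
A-genome rice plastome: 80,604 + 20,803 + 12,347 + 20,803 = 134,557 bp;
162 gene entries (114 protein-coding, 40 tRNA, 8 rRNA, of which 20 + 12
+ 8 entries sit in the IRs and are duplicated by construction); 11
one-intron genes; AT content 0.61; ~58% coding. Protein genes are
generated as genuine open reading frames (ATG start, no internal stop,
stop codon), so translating any reference CDS is a meaningful sanity
gate. The default tree has an Australian clade (TaxonA, (TaxonB,
O_meridionalis)), an Asian clade ((O_sativa_indica, O_nivara),
(O_sativa_japonica, O_rufipogon)) and a distant outgroup
(O_australiensis); branch lengths were calibrated once so that
close-pair comparisons yield tens of events and the outgroup comparison
several hundred, and were not revisited afterwards.

`evolve()` draws per-branch event counts from Poisson distributions
(branch length × genome length × rate), places them with
region-multiplier-weighted sampling, and applies them in descending
coordinate order, lifting the annotation and the structure boundaries
through every indel. Events in either IR are mirrored to the other copy
so each simulated genome keeps perfect repeats. Multiple hits within a
branch are excluded by construction (events are spaced apart), which is
adequate at the divergences emulated (≤ 1% per branch) where multiple
hits are negligible anyway.

Two deliberate generator constraints exist purely to make the emitted
ground truth well-defined:

* events on one branch keep a minimum spacing (`min_event_gap`, default
  2 bp), and indels additionally reserve a halo of their length plus
  the affine-gap penalty span, so no two events can share an
  equally-scoring alternative alignment;
* indels are rejected when their aligned representation could shift
  within a flanking repeat (and, for IR-mirrored events, when the
  mirrored copy could), so the truth position is the same canonical
  left-aligned position the caller reports. Deletions are also kept
  within a single annotation run, which keeps coordinate lift-over
  exact.

What the simulator does **not** emulate — and therefore what passing
tests do not demonstrate about real data: selection (synonymous and
non-synonymous changes accrue at the neutral ratio, so simulated coding
regions are nonsynonymous-heavy compared with real plastomes), rate
heterogeneity beyond the three region classes, context-dependent
mutation, IR boundary expansion/contraction, gene loss or
pseudogenisation, rearrangements, and sequencing or assembly error.
Real-accession behaviour additionally depends on annotation quality,
which the simulator idealises.

## Numerical and algorithmic choices

* The pairwise aligner switches to full dynamic programming whenever the
  problem fits (≤ 4 × 10⁷ cells, about 6 kb × 6 kb), so the stated
  contract — full-DP-optimal scores on small inputs — holds by
  construction there; on plastome-scale inputs the unique-anchor chain
  plus per-gap dynamic programming returns the same score on collinear
  inputs, which the test suite verifies against an independent
  implementation (`Biostrings::pairwiseAlignment`) on random divergent
  pairs.
* Gap-state transitions in the Gotoh recursion are unrestricted (a
  deletion may abut an insertion), matching the reference
  implementation used as the oracle.
* Fitch scoring roots the unrooted tree along a pendant edge, which
  keeps every internal node binary; the kernel is compiled (Rcpp), as
  is the alignment recursion — the two places where R-level loops would
  dominate.
* Tied optimal trees are all retained; reported statistics use the
  first tree under a canonical ordering (sorted newick of tip indices),
  so repeated runs with one seed are bit-identical.
* The heuristic search is steepest-descent TBR from each random-addition
  start; for ≤ 9 taxa the exhaustive enumeration ((2n−5)!! topologies)
  is available as the ground-truth search and as the oracle in tests.
* RI is defined as 1, with a warning, when every site attains its
  star-tree maximum at its minimum (Σg = Σm), where the ratio is 0/0.
* CI excluding uninformative characters restricts both sums to
  parsimony-informative sites.
* Bootstrap resampling is implemented as a multinomial redraw of
  site-pattern weights — identical in distribution to resampling
  columns, and much faster on matrices that are almost entirely
  constant.
* Degenerate inputs error early with typed conditions: no repeat ≥
  `min_ir_length` (`plastocmp_structure_not_found`), equal inter-repeat
  arcs (`plastocmp_structure_ambiguous`), overlapping exon claims
  (`plastocmp_feature_overlap`), fewer than 3 taxa for a character
  matrix, more than 9 taxa for exhaustive search.

## Problem sizes used by the tests

The unit and property tests run on small simulated plastomes (6 kb LSC,
1.5 kb IRs, 0.9 kb SSC, a dozen genes) so the whole suite exercises
every stage — including full-scale generation, an 8-taxon 114 k-column
alignment, the 200-addition search and a 2,000-replicate bootstrap in
the acceptance script — in minutes on one CPU. The search-equality
battery uses 8–9-taxon matrices because that is where exhaustive
enumeration is still the ground truth; the aligner oracle battery uses
200 random pairs of 0.2–2 kb at up to ~5% divergence.

## Relation to the published analysis

`reproduce_study()` reruns the full comparison when given the eight
GenBank accessions (downloadable with `fetch_accessions()`): structural
lengths, IR-reduced lengths, both distance matrices, site
classification, parsimony statistics and bootstrap supports, returned
alongside the published reference values. The package does not bundle
those sequences; everything in the test suite and the acceptance script
runs on simulated data whose generating conditions emulate the study.
Two published quantities are intentionally out of reach of any
reimplementation: the exact multiple-alignment column count of the
original progressive aligner (a different algorithm will place gap
columns differently even when every variant call agrees), and the
likelihood/Bayesian analyses, which are outside this package's scope —
the parsimony and distance machinery reproduces the topology and the MP
statistics, which is the acceptance surface for tree shape.

## Known limitations

* The IR detector assumes at most one IR pair; plastomes with highly
  reduced or lost IRs (some legumes, conifers) will return a
  structure-not-found error, which is the honest answer for a
  quadripartite model.
* The aligner is global: it assumes both sequences are complete genomes
  in the same orientation and linearisation (use
  `detect_quadripartite(..., rotate = TRUE)` first if the start point
  is unknown).
* Effect prediction evaluates one variant at a time; compound effects
  of multiple nearby variants in the same codon across *different*
  events are not combined.
* Variants spanning an exon boundary are flagged composite rather than
  given a protein-level interpretation.
* The clade partition expects exactly two clades plus the focal taxon;
  the outgroup must be excluded by the caller.
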