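---
title: "Reconstructing ancestral genomes from hierarchical orthologous groups"
author: "paleohog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing ancestral genomes from hierarchical orthologous groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleohog)
```

## The model: HOGs as ancestral genes

A hierarchical orthologous group (HOG) collects the genes that descend
from a single ancestral gene at a given taxonomic level; nested
subgroups refine the family into the subfamilies created by gene
duplications. Under this reading, the set of HOGs defined at an internal
node of a rooted species tree is a proxy for the gene content of that
ancestor, and paleohog treats it as such throughout:

* **Ancestral gene content.** `hogs_at_level()` walks each family tree
  and returns the deepest nodes whose own level is ancestral to (or
  equal to) the query level and that retain extant members inside the
  query clade. Duplications at or above the level split a family into
  several ancestral genes; members are restricted to the clade.
* **Completeness score.** Each ancestral gene is scored by the number of
  clade species represented in the HOG divided by the total number of
  species in the clade, a value in (0, 1]. Low-completeness HOGs imply
  many independent losses and are often artefacts of orthology
  inference; the conventional quality filter keeps scores ≥ 0.3 (the
  default of `filter_completeness()` and of the `ancestral-genes`
  subcommand). The denominator counts the species present in the input
  genome set under the level node, not all described species — the
  score is relative to the sampled taxonomy.
* **Branch events.** Against the most recent parental genome (by default
  the parent node of the level), `classify_events()` labels each
  ancestral gene *retained* (single descendant of a parent-level HOG),
  *duplicated* (two or more level HOGs descend from one parent-level
  HOG; all siblings are labelled), or *gained* (no counterpart at the
  parent level: the family's root lies on the branch). Parent-level HOGs
  with no descendant and no extant member in the clade are *lost*. One
  interpretation was genuinely open: a family that duplicated and then
  lost all but one copy before the child level is labelled *retained*
  here, because a single surviving lineage is indistinguishable from
  plain descent at the child level; only ≥ 2 surviving sub-HOGs witness
  a duplication.

## Ancestral gene order

Extant gene orders are projected onto the HOGs of the target level:
every gene is replaced by its level HOG, and unmapped genes
(lineage-specific gains, or families absent at the level) are removed
with the gap closed, so their neighbours become adjacent. Without gap
closing, any lineage-specific insertion would erase all ancestral
adjacencies around it.

Every consecutive pair in a projected contig is a *supporting context*;
the unordered pair of HOGs receives one weight unit per occurrence per
extant contig (a pair present on two contigs of one genome counts
twice — support counts contexts, not genomes). Tandem pairs (the same
HOG twice in a row, the signature of a tandem duplication) are skipped,
so the graph has no self-edges. Gene orientation is recorded from GFF3
input for display but never used: adjacencies are unordered.

The ancestral order is the maximum-weight *linear forest* (every node of
degree ≤ 2, no cycles) of this graph; its connected components are the
ancestral contigs, reported by decreasing length. Exact optimisation is
NP-hard in general, so `linearize()` uses a two-regime strategy:

* components with at most 10 nodes are solved exactly by bitmask dynamic
  programming over vertex subsets (a path-partition DP);
* larger components use a deterministic greedy sweep: edges by
  decreasing weight, ties towards the lexicographically smaller HOG
  pair, an edge accepted iff both endpoints keep degree ≤ 2 and no
  cycle forms.

When the exact optimum does not beat the greedy selection the greedy
solution is kept, so tie-breaking is identical in both regimes. The
exact small-component solver matters: pure greedy is provably
suboptimal already on a triangle with a pendant edge at its heaviest
vertex, a configuration that random small graphs hit regularly. The
test suite checks the linearizer against an independent edge-subset
brute force on graphs of up to 8 nodes.

Circular ancestral chromosomes are not modelled explicitly: a cycle in
the support graph is broken at its lightest adjacency as a consequence
of the maximum-weight path selection.

The local synteny viewer (`synteny_window()`) slices the focal HOG's
contig to the focal gene ± `window` positions (default 5 per side, the
conventional 11-slot view), adds one row per extant member gene with its
genomic neighbourhood, and lets whole clades collapse to the inferred
neighbourhood of their last common ancestral gene. Entries are coloured
by the level HOG their own family maps to; neighbours with no homology
to the reference neighbourhood are classed `unrelated` (grey in the
conventional rendering). When a collapsed node's ancestor lacks the
focal family, that row is simply omitted.

## Ancestral GO annotation

Gene Ontology annotations follow the true-path rule: a term implies all
of its is_a/part_of ancestors, and annotation tables are stored
non-redundantly (most specific terms only). `parse_gaf()` keeps all
evidence codes except `ND` and drops NOT-qualified rows; electronically
inferred (IEA) annotations are kept, because in large orthology corpora
they are the bulk of the signal.

`propagate_to_hogs()` lifts annotations from extant genes to ancestral
genes with a child-fraction parsimony rule, a deliberately simplified
form of belief-propagation schemes for function propagation over HOGs:
a leaf carries the closure of its annotations; an internal node's
support for a term is the fraction of its children whose (already
propagated) term set contains it, and the node keeps the term iff
support ≥ τ. The default τ = 0.5 is a majority-of-children rule:

* a term annotated in every leaf reaches the family root with support 1;
* a term seen in a single leaf dies at the first node with ≥ 2 children
  whenever τ > 1/2, which is what makes the rule robust to spurious
  leaf annotations;
* children count equally regardless of subtree size, so large clades
  cannot outvote small ones (`weight_by_size = TRUE` switches to
  size-weighted voting for study).

Only the most specific terms per node are emitted, with their support.
The exact decay constants of published weighted propagation schemes are
not reproduced; τ is exposed instead, and the choice is documented as a
simplification.

Term statistics over a corpus (`term_stats()`) count, for each term, the
subjects whose closure contains it; p(t) is the count divided by the
namespace root's count and the information content is −ln p(t) (natural
logarithm, as in the semantic-similarity literature the measure feeds).

## Enrichment and semantic maps

`run_enrichment()` is a one-sided over-representation test: for each
term, the p-value is the upper hypergeometric tail
P[X ≥ n_study] with X ~ Hypergeom(N_pop, n_pop, N_study) — Fisher's
exact test for enrichment. Population totals count *all* subjects of the
population (all genes of the genome, or all HOGs at the level),
annotated or not. Both Bonferroni (min(1, p·m)) and Benjamini–Hochberg
(step-up) corrections are reported; the default report filter is
BH ≤ 0.05.

Two conventions were open and are switchable:

* the number of tests m counts the terms with at least one study hit
  (default `test_universe = "study"`); terms absent from the study
  cannot be over-represented one-sidedly, but `"population"` is
  available for a more conservative m;
* only over-representation is tested (no depletion), matching the
  purpose of the table.

Phylostratigraphy study sets (`study_from_events()`) turn branch-event
categories — gained, duplicated, retained, lost — into enrichment
study sets at a level.

Significant terms are summarised per namespace as a 2-D semantic map:
pairwise simRel similarity

$$\mathrm{simRel}(t_1,t_2) \;=\; \max_{a \in \mathrm{anc}(t_1)\cap\mathrm{anc}(t_2)}
\frac{2\ln p(a)}{\ln p(t_1) + \ln p(t_2)}\,\bigl(1-p(a)\bigr)$$

(zero when the only shared ancestor is the namespace root;
1 − p(t) for a term with itself), embedded by classical (Torgerson)
metric MDS of d = 1 − simRel. Classical MDS was chosen over iterative
stress majorisation because it is deterministic — the embedding is
reproducible bit for bit, with the sign of each axis fixed by forcing
its largest-magnitude coordinate positive. Self-similarities are
normalised to 1 before embedding so duplicated terms coincide. Term
probabilities are computed over the enrichment population corpus, not a
global database, keeping the module self-contained.

A caveat the tests make explicit: a 2-D map can only be faithful when
the term set has low intrinsic dimensionality. Enriched GO sets
typically split into a few semantic themes and embed well (rank
correlation of embedded distance with 1 − simRel around 0.9 on
clustered 20-term sets); an arbitrary scattered term set has no
faithful 2-D representation and the map should then be read only
locally.

## The clade simulator

`simulate_clade()` generates internally consistent inputs — Newick tree,
OrthoXML families, per-genome gene orders, OBO ontology, GAF
annotations — with full planted truth (per-node gene content and order,
per-branch events at gene-copy resolution, per-family term sets). A
root genome of single-copy genes on one contig evolves down the tree;
on each branch, in order: duplications (copy inserted adjacent to its
template), gains (uniform position), losses (uniform deletion),
inversions (uniform interval reversal). Event counts are Poisson with
the configured expectations — the simplest exchangeable model; every
draw is fixed by one seed and identical configurations reproduce
byte-identical files.

Defaults (10 species, balanced tree, 100 ancestral genes, 5 gains,
5 losses, 3 duplications and 1 inversion expected per branch, a
150-term ontology, 3 planted terms per family, 5% spurious leaf
annotations) describe a moderately dynamic clade in which roughly a
tenth of the genome turns over per branch — enough churn to exercise
every event class without driving families extinct. Duplicates are
inserted adjacent to their template deliberately: zero-inversion
simulations then stay perfectly collinear, isolating order-reconstruction
error from content error.

What the simulator does *not* emulate: sequence evolution (no alignment
or inference noise — the emitted HOGs are the true families, so tests
of `hogs_at_level()` and friends check the reconstruction logic, not
robustness to orthology errors), chromosome fission/fusion (one root
contig), horizontal transfer, and biased annotation loss. Passing the
planted-truth tests therefore demonstrates correctness of the
reconstruction machinery under the stated model, not performance on
real, noisy orthology databases.

## Numerical and interface choices

* Coordinates are 0-based half-open internally; GFF3 is read as 1-based
  inclusive. The TSV gene-order dialect is already 0-based.
* Unlabelled internal tree nodes are auto-named `N1, N2, ...` in
  preorder so every level is addressable; unary chains are collapsed.
* HOG identifiers follow `HOG:<RootId>(.<subId>)*`: root ids are
  preserved from the input (else assigned by root index), and the
  children of the d-th duplication under a group get suffixes
  `.<d>a`, `.<d>b`, ... in document order. Published identifier
  grammars are not specified beyond examples of this shape, so the
  scheme is a compatible reconstruction and only the root-id part
  should be relied on externally.
* OrthoXML groups without a `TaxRange` property get the LCA of their
  member species as level. Explicit `TaxRange` should be preferred: the
  LCA is a lower bound that cannot see losses.
* `propagate_to_hogs()` compares support with τ − 1e−12 to keep exact
  fractions such as 1/2 stable at τ = 0.5.
* Fisher p-values use the exact hypergeometric tail
  (`phyper(lower.tail = FALSE)`); the test suite compares them against
  an exact big-integer oracle over every table with population ≤ 60
  (agreement to < 1e−12).

## Problem sizes in the test suite

The planted-truth checks run on clades of 6–8 species with 20–40 root
genes; the error-control simulation draws 1000 null study sets of 20
from an annotated population of 200; the linearizer is compared with
brute force on 200 random graphs of ≤ 8 nodes; the exhaustive Fisher
sweep covers all ~6.4 × 10⁵ tables with population ≤ 60. These sizes
give exact, enumerable oracles while keeping the whole suite around
three minutes on one CPU.

## Known limitations

* Reconstruction quality is bounded by the input HOGs: no correction of
  orthology errors is attempted beyond the completeness filter.
* The linearizer's greedy regime on large components is near-optimal,
  not optimal; only components ≤ 10 nodes are solved exactly.
* Propagation is upward only; genes are never annotated from ancestors.
* The enrichment test treats subjects as exchangeable; no gene-length
  or annotation-bias correction is applied.
* Collapsed synteny rows require the focal family to exist at the
  collapsed ancestor; otherwise the row is omitted rather than padded.
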