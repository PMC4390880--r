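---
title: "Weighted phylogenomic affinity analysis over ortholog clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted phylogenomic affinity analysis over ortholog clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcogkit)
```

## The problem

Collections of orthologous gene clusters (COGs, arCOGs) over hundreds of
prokaryotic genomes support two complementary phylogenomic signals for
placing a focal clade: (i) the topological neighbourhood of the clade
across large sets of individual gene trees, and (ii) shared derived
characters — genes exclusively present in a set of clades
(synapomorphies).  Both signals are distorted by taxon-sampling bias:
ten near-identical isolates of one species should not outvote a lone
deep-branching genome.  `arcogkit` implements both analyses on top of a
branch-length-based genome weighting that corrects this bias, and ships
a synthetic-data generator so the whole pipeline is testable without any
external database.

## Genome weights

Given a rooted species tree with branch lengths, each node's weight $W$
is split among its children proportionally to $L_i + T_i$, the child's
incoming branch length plus the sum of all branch lengths in its
subtree:

$$W_i = W\,\frac{L_i + T_i}{\sum_k (L_k + T_k)}, \qquad T_{\text{leaf}} = 0.$$

Subtree sums are accumulated leaf-to-root, weights distributed
root-to-leaf; both passes are linear in tree size.  The root weight
defaults to the number of genomes, so weights read as
genome-equivalents and leaf weights sum exactly to the root weight (a
conservation law tested to $10^{-9}$ relative tolerance).  Degenerate
case: if all of a node's children have $L_i + T_i = 0$, the weight is
split equally — this keeps weights positive in all-zero subtrees while
leaving the formula untouched elsewhere (a zero-length subtree facing a
positive-length sibling genuinely receives weight 0, as the formula
dictates).  Weights are insensitive to inserting degree-2 nodes and to
rearrangements across zero-length branches, and a cherry whose branches
shrink to zero converges to half of the weight a single merged leaf
would get — the properties that make the scheme robust to minor
topological uncertainty.

## Phyletic-pattern statistics

From a membership table (genome, gene, cluster) the package builds a
cluster × genome count matrix (paralogs counted).  Two statistics with
deliberately different currencies are derived:

* **Clade representation** (weight-based): for cluster $c$ and clade
  $K$, the summed weight of $K$'s genomes possessing $c$ divided by
  $K$'s total weight.  Presence is binary — paralog multiplicity does
  not raise representation.  Core genes require representation
  $\ge 0.75$ (non-strict) in every non-excluded clade; gene-tree
  candidates require $> 0.5$ (strict) in at least 4 clades.  The
  strict/non-strict boundaries follow the wording of the respective
  rules and are asserted in tests.
* **Exclusivity index** (count-based):
  $R_E = (\min_i C_i + 10^{-4}) / (\max_j C_j + 10^{-4})$ with the
  minimum over in-set clades and the maximum over out-set clades.
  Clusters with $R_E > 10$ (strict) pass the exclusively-shared screen;
  screened clusters contribute 1–3 units to a shared-gene tally with
  tier boundaries $(10, 100] \to 1$, $(100, 10^4] \to 2$,
  $> 10^4 \to 3$.  The boundaries are a package choice (only "1 to 3
  units" is prescribed): with the $10^{-4}$ pseudocount a strictly
  exclusive single-copy cluster scores at least $\sim 10^4$, so the top
  tier isolates strict exclusivity.  They are configurable.

## Alignment-site filtering

Sites are removed when gap fraction $> 0.5$ **or** homogeneity $< 0.1$.
The OR reading is deliberate: a pure AND would keep wholly gappy but
homogeneous columns, defeating the filter; both thresholds are
parameters, so the AND behaviour is one configuration away.
Homogeneity is the mean pairwise similarity over all unordered non-gap
residue pairs under BLOSUM62 affinely rescaled to $[0,1]$ (maximal
diagonal $\to$ 1, minimum entry $\to$ 0); columns with fewer than two
non-gap residues score 0.  Consequences of this rescale worth knowing:
an all-identical column scores 1.0 only for tryptophan (the rescale
anchor); typical mismatches land around 0.13–0.35, so the default
`min_hom = 0.1` removes only strongly dissimilar columns (mean raw
score below about −2.5).  The exact published homogeneity measure is
not reproduced in the source literature; this stand-in is isolated
behind `column_homogeneity()` so it can be swapped without touching the
pipeline.  Filtering is idempotent and monotone in both thresholds
(property-tested).  After site filtering, rows with more than 2/3 gaps
are dropped (the fraction is a package default — no published value
exists — and is configurable), and clades whose weighted representation
among the surviving rows falls strictly below 0.5 are removed before
re-testing the four-clade condition.

## Clade affinity in gene trees

Externally inferred gene trees are midpoint-rooted (longest leaf-to-leaf
path; deterministic lexicographic tie-break; a midpoint falling exactly
on a node makes that node the root).  For a target clade, the affinity
node(s) are all nodes satisfying:

1. descendant leaves cover $\ge 0.75$ of the target clade's total
   weight (denominator: the full weight table, so poorly sampled trees
   are honestly unclassifiable);
2. at least one other clade is likewise covered at $\ge 0.75$;
3. no strictly descendant node satisfies 1–2 (minimality).

Genomes are counted once per node regardless of paralogous leaves;
this genome-level counting is what allows two deep-paralog subtrees to
each qualify.  At each selected node, every other clade's sister
representation is $W_i^* = \sum_{j \in L_{N^*}} w_j^i / \sum_{k \in L_R}
w_k^i$ — note the denominator counts only genomes present in the tree.
With several selected nodes, $W^*$ is averaged across nodes *before*
normalisation to $R_i^* = W_i^*/\sum_k W_k^*$ (the alternative,
averaging $R^*$, differs only in degenerate cases; the W-then-normalise
order is declared in the result invariants and tested).  $R^*$ sums to
1 whenever any $W^* > 0$.

Topology classification is configuration-driven
(`topology_config(target, sister_set, enclosing)`), since the original
study never published its classifier.  Per node, with $q$ the set of
non-target clades covered at $\ge 0.75$: class **II** if
$q \neq \emptyset$ and $q \subseteq$ sister set; class **I** if
$q$ contains two or more enclosing-group clades, at least one outside
the sister set, and nothing outside the enclosing group (the target
sits basal to the group); **X** otherwise.  Multiple nodes vote, ties
and empty node lists give X.

## The synthetic world

The generator's defaults state the emulated conditions: 13 clades
named after archaeal classes, 168 genomes with realistic sampling skew
(30 Halobacteria down to a single Korarchaeota genome), branch lengths
i.i.d. exponential with mean 0.1 substitutions/site, a gene-tree class
mixture matching the observed core-gene breakdown (p(II) = 69/219,
p(I) = 47/219, remainder perturbed by 3 random SPR moves), per-genome
taxon sampling 0.8, and a phyletic matrix with planted exclusive sets
over 200 background clusters at presence probability 0.1.  Planted
class-II trees regraft the target clade as sister to one randomly
chosen sister-set clade; class-I trees regraft it as sister to the rest
of the enclosing group, which the species-tree generator keeps
monophyletic precisely so that a basal plant is recoverable.

What the generator does *not* emulate: sequence evolution (alignment
fixtures are tiny and hand-written), clock-like branch lengths, and
horizontal transfer beyond whole-subtree SPR.  One consequence is
methodologically important: with i.i.d. exponential branch lengths the
longest leaf-to-leaf path is arbitrary with respect to the true root,
so midpoint rooting scrambles planted signal.  Simulated gene trees are
therefore consumed as rooted (`midpoint = FALSE`); the midpoint default
remains in place for real, approximately clock-like trees.  A green
recovery test therefore establishes that the selection criteria,
affinity algebra and classifier are correct on rooted trees — not that
midpoint rooting is reliable on non-clock data (it is not, and that is
a property of the stated branch-length law, not of the rooting code).

Noise knobs and their effects, as observed in the test suite: taxon
sampling below 1 makes some trees unclassifiable (target coverage falls
below 0.75 of the *full* clade weight), which deflates affinity sums —
the per-tree $R^*$ vector is then all zeros and the tree counts as
class X, matching the treatment of undersampled trees as
"not fully compatible with either topology".

## Numerical choices

* Branch lengths are serialised with 10 significant digits; parse ∘
  write round trips conserve topology, lengths and labels (tested up to
  300 leaves).
* Midpoint tie-break: among all leaf pairs at maximal distance, the
  lexicographically smallest sorted label pair wins; positions within
  $10^{-12}$ of a node snap to the node.
* Conservation and normalisation invariants are asserted at $10^{-9}$.
* All generators are pure functions of (config, seed); the pipeline
  writes no timestamps, so identical inputs give byte-identical
  reports.

## Known limitations

* The exclusivity screen is count-based by design and therefore
  sensitive to paralog inflation in the in-set clades.
* The topology-I rule is an operationalisation; alternative classifiers
  can be supplied via `topology_config` but no formal topology test
  (AU/SH) is performed.
* `requalify_clades` drops rows of unmapped genomes rather than
  carrying them as an "unknown" clade.
* The pipeline is single-threaded; determinism, not throughput, is the
  contract.
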