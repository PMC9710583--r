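---
title: "Biclique extension for compound-protein interaction networks: methods and design"
author: "bicext authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biclique extension for compound-protein interaction networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bicext)
```

## The model

A compound-protein interaction (CPI) network is a bipartite graph: one
partition holds small molecules (metabolites, cofactors, drugs), the other
proteins, and an edge records a known interaction with one or more confidence
scores in $[0, 1]$. Within such a network, a *biclique* is a pair of node sets
$(C, P)$ -- $c$ compounds and $p$ proteins -- whose $c \times p$ cross pairs
are all edges; it is *maximal* when no strict superset on either side stays
complete. A maximal biclique is the densest local structure a bipartite graph
admits, and in CPI networks it collects compounds that bind the same protein
set (and vice versa), which tends to have a structural basis: shared
scaffolds on the compound side, homologous binding sites on the protein side.

*Biclique extension* turns this into a link predictor. If an external
compound $x \notin C$ already interacts with all but one protein of $P$, the
one missing pair $(x, p^\*)$ is proposed as a likely false negative of the
network: postulating it makes $x$ a full member of the biclique. The protein
side is treated symmetrically. Optionally, candidates missing exactly two
edges to a side with at least `two_edge_min_side` members yield both missing
edges. The method uses network topology only -- no binding-mode, energetic or
sequence information -- yet implicitly exploits molecular similarity, which
the characterization module makes measurable (see below).

Because all cross pairs of a maximal biclique must be present, every
biclique member has degree at least 2 once both sides have at least two
members; nodes with a single interaction can therefore be pruned before
enumeration without affecting any prediction made at thresholds of
$(c_{\min}, p_{\min}) \ge (2, 2)$.

## Enumeration and its contract

Maximal bicliques are enumerated exactly by a branch-and-bound consensus
algorithm of the iMBEA family: candidates on one side are added one at a
time, the common neighborhood on the other side is intersected,
fully-connected candidates are absorbed into the current biclique, and a
check against already-processed candidates prunes non-maximal branches.
Two implementation choices matter:

* the candidate side is the smaller partition (fewer, larger neighborhoods
  drive the recursion more efficiently), and candidates are processed in
  order of increasing degree;
* size thresholds prune the search -- the non-candidate side only shrinks
  along a branch -- but *maximality is always judged against the network*,
  never against the thresholded subset. Filtering an enumeration taken at a
  loose threshold therefore yields exactly the enumeration at a tighter one,
  which the validation sweep exploits to enumerate once per hold-out split.

The correctness contract is not the algorithm but an oracle: the test suite
compares the enumeration and the extension against exhaustive brute-force
references (subset closure over all $2^{n}$ compound subsets; the extension
rule applied literally to every non-edge) on hundreds of seeded random
graphs. Any algorithm passing that oracle would be acceptable.

Within one prediction pass, all candidates are evaluated against the
iteration-start network (batch semantics). This makes the output independent
of node and edge ordering, which is also asserted by test.

## Predictions, support, and multiplicity

Several (biclique, candidate) derivations can propose the same edge;
predictions are deduplicated per edge with a `support` count of derivations
(a crude confidence surrogate: the method emits no continuous score) and a
`missing_multiplicity` of 1 or 2, the smallest number of edges any single
derivation had to insert. Predictions never duplicate existing edges, by
construction and by test.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `c_min`, `p_min` | 2, 2 (engine); 5, 2 (CLI `predict`) | minimum biclique side sizes; the CLI default mirrors the mid-size optimum typically found for sparse bacterial-scale networks |
| `max_missing` | 1 | edges a candidate may lack (1 or 2) |
| `two_edge_min_side` | 4 | minimum size of the side a two-edge candidate joins; published descriptions of the rule vary between "more than four" and "at least four" nodes, so the bound is exposed as a flag and interpreted inclusively |
| confidence threshold | 0.4 ("medium") | inclusive lower bound on an edge score channel; boundary behaviour is inclusive so a score of exactly 0.4 is kept |
| `min_heavy_atoms` | 5 | compounds with a *known* heavy-atom count below this are dropped; unparseable or missing SMILES never cause removal (removal requires positive evidence of small size) |
| degree-1 pruning | `single_pass` | simultaneous removal of all degree-1 nodes; `fixpoint` repeats to exhaustion; reported pre-processing descriptions do not indicate cascading removal, so a single pass is the default and both are provided |
| `n_swaps` (rewiring) | $\lceil |E| \ln(1/10^{-3}) \rceil \approx 6.9\,|E|$ | attempted edge switches; the standard switching-chain mixing heuristic, exposed as a flag |
| `stop_new_below` | 1 | strict convergence of iterative extension; looser informal stopping ("fewer than 10 new edges") is available by flag |
| hold-out `fraction` | caller-set (0.1 and 0.05 are conventional) | edges removed as positives; the count is `round(fraction * |E|)` with half-away-from-zero rounding, documented because the rounding rule is otherwise ambiguous |

## Cleanup filters

`cleanup_network()` confines a network to naturally occurring metabolites:
small species (ions) judged by heavy-atom count from SMILES; compounds
flagged as antibiotics (and, in bacterial networks, hormones/transmitters or
steroids); and compounds without a KEGG compound ('C') number -- drugs with
only a 'D' number are removed, compounds carrying both are retained. All
three are independent node predicates, so the filter order is irrelevant and
the operation is idempotent (asserted by test). Whether the
hormone/steroid categories should apply outside bacterial networks is a
caller choice via `drop_categories`.

Isolated nodes are dropped from a stored network after every filter, and all
size/density accounting is over nodes with at least one interaction. The one
exception is the hold-out split, which keeps node records and does not
re-prune: a held-out positive whose endpoint lost its last training edge
simply becomes unpredictable yet still counts in $P$, so reported TPRs are
not inflated by silently shrinking the positive set.

## Validation

`holdout_split()` removes a fixed fraction of edges as positives;
`restrict_to_predictable()` keeps validation pairs whose endpoints both
remain in the training network (only those are reachable by extension);
`score_predictions()` computes

$$\mathrm{TPR} = \frac{TP}{P},\quad \mathrm{FPR} = \frac{FP}{N},\quad
F_1 = \frac{2\,TP}{2\,TP + FP + FN},\quad
\mathrm{PPV} = \frac{TP}{TP + FP},$$

plus the confirmation rate $TP/\mathrm{PI}$ (true positives over all
predicted interactions), the quantity that estimates expected experimental
validation success. Predictions matching neither truth set have unknown
status and count only toward the prediction total. Negatives that appear as
edges of the reference network are excluded from $N$ up front: they are not
non-interactions there, and a held-out edge could otherwise be both a
positive and a negative.

`run_validation()` sweeps thresholds with one split per repeat (reused
across thresholds, so threshold rows differ only by threshold; re-splitting
per threshold would add between-threshold variance without benefit) and
reports means and standard deviations over repeats. The shared-enumeration
shortcut is verified against per-threshold recomputation by test.

## The null model

`edge_switch_randomize()` implements the degree-preserving edge switch: two
edges $(c_1, p_1), (c_2, p_2)$ with distinct endpoints are replaced by
$(c_1, p_2), (c_2, p_1)$ iff neither target exists. Rejected draws count
toward the swap budget, so runtime is bounded; degree sequences, edge count
and bipartiteness are preserved exactly (asserted on every output). A
complete bipartite network admits no swap and is returned unchanged.
Comparing hold-out TPR between a network and its randomization separates
genuine biclique structure from degree effects: the randomized network keeps
every node's degree but destroys the correlated neighborhoods that
extension relies on.

## The synthetic generator

`generate_synthetic()` builds networks with known answers: node-disjoint
planted complete bicliques, background noise edges between non-planted pairs
(uniform, or with per-compound Pareto propensities of shape 2.5 rescaled to
the requested mean -- mimicking the heavy-tailed compound degree
distributions of real CPI networks, where cofactor-like "currency
metabolites" interact with very many proteins), an optional one-edge-per-
biclique hold-out, and a sampled set of true-negative pairs disjoint from
all edges and removed edges. Everything derives from one seed.

With zero background noise and one removed edge per planted biclique,
recovery at thresholds $(c_i - 1, p_i - 1)$ (floored at 2) is *provable*:
the damaged biclique retains a maximal sub-biclique passing the threshold,
the removed edge's endpoints are candidates missing exactly one edge, and no
other candidate exists. This guarantee is what the planted-recovery checks
assert as exact 100% recovery with zero false predictions.

What the generator does *not* emulate: realistic confidence-score
distributions (synthetic scores are fixed at 1), the biological construction
of negative sets (negatives are uniform non-edges), overlapping biclique
structure (unless the stress flag is used), or any chemistry -- synthetic
records carry no SMILES or sequences. Passing synthetic benchmarks therefore
demonstrates the correctness of the machinery, not performance on any real
database.

## Characterization

Compound similarity is the Tanimoto index $|A \cap B| / |A \cup B|$ over
structural feature sets; the packaged feature set is ChemmineR atom pairs
(each feature an atom-type pair with its topological distance). Hashed
circular fingerprints are a common alternative; the similarity operation is
feature-agnostic and accepts any feature sets or bit vectors, and no
cross-fingerprint agreement is asserted. Protein similarity is the best
local alignment score under BLOSUM62 with affine gaps 11/1 (the standard
protein-BLAST parameterization), computed in-library; scores are raw
alignment scores, symmetric by construction.

`within_between_similarity()` samples pairs of biclique members that share
at least one biclique versus pairs that share none -- without replacement
and excluding self-pairs (the sampling convention is this package's choice;
published descriptions leave it open) -- and contrasts them with Cohen's
$d$ (pooled standard deviation) and a two-sided Wilcoxon rank-sum test
(exact below group size 50, normal approximation with tie correction above;
a fully tied degenerate input short-circuits to $p = 1$).

Pathway over-representation uses the hypergeometric upper tail
$P(X \ge k)$ for a query of size $n$ against a universe of $N$ proteins
with $K$ annotated per pathway, Benjamini-Hochberg adjustment across tested
pathways, and reports pathways with adjusted $p$ below `alpha` ordered by
fold enrichment $(k/n)/(K/N)$. The default universe is the annotated set of
the annotation map; callers may restrict it to network proteins.

## Numerical and formatting conventions

* Duplicate edge rows collapse keeping the per-channel maximum score.
* Scores distributed on an integer 0--1000 scale are divided by 1000 on
  ingest; any score column with values above 1 is treated as such.
* Rates with zero denominators are 0 by convention; density of an empty
  network is 0; Tanimoto of two empty feature sets is 0.
* KGML reactions link both substrates and products to the reaction's
  enzymes (direction is discarded -- the CPI network is undirected), and
  duplicate enzyme-compound pairs are collapsed after mapping, which for
  undirected edges is equivalent to collapsing reversible duplicates first.
  Only 'C'-number compound entries enter; glycan and drug entries, groups
  and map links are ignored.
* Identifier merging (isoform/salt variants) is driven by a user-supplied
  id-equivalence table; there is no built-in chemistry-based merging.

## Problem sizes

The shipped checks run on desk-scale instances chosen to make exhaustive
oracles feasible and the whole suite quick: oracle comparisons on 8x8
graphs over three edge densities and hundreds of seeds, planted-recovery on
15x9 networks over 50 seeds, null-model separation on 50x80 networks with
background probability 0.02 over 20 seeds with 10 hold-out repeats each.
The engine itself targets networks up to roughly $10^5$ edges; it makes no
attempt at web-scale enumeration, weighted extension, or ROC areas over a
continuous score (the method does not produce one).

## A worked miniature

```{r worked}
truth <- generate_synthetic(synthetic_spec(
  n_compounds = 15, n_proteins = 9,
  planted = list(c(4, 3), c(5, 2), c(6, 4)),
  holdout_per_biclique = 1, n_negatives = 50, seed = 7))
truth

preds <- predict_interactions(truth$network, c_min = 3, p_min = 2)
preds

score_predictions(preds, truth$removed_edges, truth$negatives)
```

All three removed planted edges are recovered with no false positives (TPR
and precision 1); the edges removed from the 4x3 and 6x4 bicliques are each
implied by two damaged sub-bicliques (support 2), the one from the 5x2 by a
single 4x2 remnant. Tightening or loosening `c_min`/`p_min` trades recall
against the number of bicliques consulted, as `run_validation()` quantifies
over repeated random hold-outs.
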