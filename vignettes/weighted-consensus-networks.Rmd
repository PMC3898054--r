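---
title: "Weighted consensus trees and explicit consensus networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted consensus trees and explicit consensus networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcons)
```

## The model

A collection of gene trees on one taxon set rarely agrees with a single
species history.  Hybridization, intragenic recombination and horizontal
gene transfer (HGT) all leave the same footprint: some gene trees contain
*clusters* (bipartitions, or splits, induced by internal branches) that
conflict with the dominant topology.  `netcons` summarizes such a collection
as an **explicit weighted consensus network**: a backbone tree carrying the
dominant signal, plus directed, weighted reticulation branches for the
well-supported conflicts.

Every cluster $i$ receives an overall weight from the branch supports and
tree weights of the trees containing it.  With $\sigma_{ij} = 1$ when
cluster $i$ occurs in tree $j$, $W(C_{ij})$ its branch support there (a
bootstrap percentage or a posterior probability rescaled to percent),
$W(T_j)$ the weight of tree $j$, and $n$ the total number of trees:

* branch supports only: $W_i(C) = \sum_j \sigma_{ij} W(C_{ij}) / n$ (mode `C`),
* tree weights only: $W_i(T) = \sum_j \sigma_{ij} W(T_j) / n$ (mode `T`),
* both: $W_i(C,T) = \sum_j \sigma_{ij} W(C_{ij}) W(T_j) / n$ (mode `CT`).

$n$ always counts *all* trees, including those lacking the cluster, so a
cluster private to one tree of a large collection is penalized however well
supported it is locally.  A branch present without a support value
contributes 0 to the sums (its presence still sets $\sigma_{ij}$); weights
stay on the percent scale of the inputs.

Four consensus constructions are built on these weights:

* **bootstrap-based majority rule** (`bootstrap_majority()`): clusters with
  mode-`C` weight strictly above the cutoff (default 50).  Above 50 the
  retained clusters are automatically pairwise compatible (replace each tree
  by its support-proportional bootstrap replicates and apply strict
  majority); below 50 compatibility is enforced greedily in weight order.
* **bootstrap-based extended majority rule**
  (`bootstrap_extended_majority()`): the majority set, then remaining
  clusters in decreasing weight order, each added when compatible, until the
  tree is fully resolved ($m - 3$ internal branches) or the list ends.
* **bootstrap-based Nelson** (`nelson_consensus()`): all clusters
  (replicated or not) form a compatibility graph; cliques score by summed
  weights; the maximum-score clique defines the tree.  Tied optima keep only
  their common clusters; the symmetric difference is reported as
  *ambiguous*.  The search is exact branch-and-bound — the problem is
  NP-hard — refusing instances above a candidate cap (default 64) rather
  than approximating silently.  With tied optima of empty intersection the
  star tree is returned along with the ambiguous list.
* **weight-based extended majority rule** (`weighted_extended_majority()`):
  pure greedy accretion over any ranked cluster list, the backbone builder
  for networks.

Ranking ties (equal weight) break by larger member-tree count, then by
lexicographically smaller canonical split key, so every construction is
deterministic.

## Reticulations and the first degree of incompatibility

A cluster conflicting with the backbone is admitted as a reticulation only
when it is *one SPR move away*: pruning a proper subtree $P$ of the
cluster's designated side $C$ and regrafting it next to the remainder
$C \setminus P$ must produce a tree displaying $C$.  The implementation
checks this without enumerating moves: such a move exists iff for some
branch side $P \subsetneq C$ of the current tree, $C \setminus P$ is a
branch side of the pruned tree.  Clusters needing two or more moves are
skipped entirely.

The *induced-move* restriction (only subtrees of the designated side move)
matters: under unrestricted SPR the complement orientation of a
second-degree cluster can be reachable in one move, which collapses the
degree hierarchy the method is built on.  The worked five-taxon example
makes the distinction concrete: cluster $(xy)$ is one induced move from
tree $T_3 = ((x,u),(z,w),y)$, while $(xyw)$ needs two.  Because the
designated side of a cluster taken from an *unrooted* tree is an arbitrary
orientation choice, the network builders search both orientations whenever
any source tree is unrooted, and choose among all realizations by the
direction rule below (ties broken toward the smaller taxon span, then
lexicographically).

Candidates are processed in decreasing weight order against the *evolving*
network state: each accepted reticulation's SPR interpretation is applied
before testing the next candidate.  Admission requires weight at or above
the cutoff (default 10%, the scale used for the real-data analyses the
method was designed around; 30% suits noisier collections); an optional
count cap is available.

**Direction.**  A reticulation joining pieces $C_1$ and $C_2$
($C = C_1 \cup C_2$) has two SPR interpretations: $T_1$ moves $C_2$ next to
$C_1$ (transfer $C_1 \to C_2$) and $T_2$ the reverse.  Cumulative
Robinson–Foulds distances are computed from each interpretation to all gene
trees containing $C$, weighted by the tree weights; the smaller sum decides
the direction, and an exact tie is reported as undirected — which is not a
failure mode but the signature of symmetric concurrent transfers (both
moves give the same topology, e.g. within a four-taxon subtree
$((a,b),(c,d))$).  Gene trees not containing $C$ contribute nothing.

Three builders share this machinery:

* `build_network_from_genetrees()` (gene trees only): backbone =
  weight-based extended majority rule consensus;
* `build_hgt_network()` (rooted species tree + gene trees): backbone =
  species tree, never altered — conflicts become transfer branches;
* `build_recombination_network()` (alignment, optional species tree):
  sliding-window scan for intragenic events, below.

## Sliding-window scan

Windows of a fixed fraction of the alignment (10–50%) advance by a 5-site
step; a final clipped placement is appended when full windows do not reach
the end (400 sites at width 40, step 5 give exactly 73 placements, no
clipping).  A tree with bootstrap supports is inferred per window
(`nj_inference()` by default; externally inferred per-window Newick files
can be ingested instead via `scan_external_trees()` — the shape used when
PhyML- or MrBayes-grade inference is available).  Each window tree counts
as one tree of weight 1 and $n$ = number of windows in the weight
equations; windows are not filtered by quality before pooling (no such
filter is stated for the method, so none is applied).  A detected cluster
carries the union span of its supporting windows; overlapping or adjacent
spans merge (weight = maximum over contributing windows; a mean rule is
available), disjoint spans stay separate events.  All intervals are 1-based
inclusive.

## Fallback inference

`distance_matrix()` implements p-distance (DNA and amino acid), JC69 and
K2P with pairwise deletion of gaps and ambiguities; saturated pairs (where
the log correction is undefined) fall back to the p-distance and are
flagged.  `nj_tree()` delegates the NJ core to `ape::nj` (plain NJ rather
than BIONJ variance weighting — this is a fallback, and externally inferred
trees are first-class inputs).  `bootstrap_supports()` resamples columns
and scores each split of the point tree by its replicate frequency, fully
seeded.

## What the simulator emulates — and what it does not

`simulate_dataset()` reproduces the evaluation protocol end to end:

* random binary topologies (`ape::rtree` random splitting, depth growing
  logarithmically in the leaf count) with i.i.d. exponential branch
  lengths;
* clock deviation: every branch length times $1 + a x$, $x \sim
  \mathrm{Exp}(1)$, $a = 0.8$ (mean factor 1.8);
* HKY sequences, TS/TV ratio 2.0 (κ = 4 at equal frequencies), continuous
  Gamma(shape 1) site rates, 400 nt by default;
* recombination blocks: disjoint intervals; for each event a recipient
  clade and a disjoint donor branch are drawn (uniformly over valid pairs
  whose union is not already a split — nested pairs are excluded so the
  truth stays well-defined), and the *recipient clade's columns only* are
  re-evolved from the donor branch's ancestral sequence under the same site
  rates.  This donor-attachment reading makes the inside-block signal a
  local rearrangement of an otherwise identical alignment, which is what a
  mosaic gene looks like; re-simulating all taxa in the block (the naive
  alternative) destroys that structure and was rejected after it erased
  most of the recoverable signal.

Numerical choices worth stating:

* **Branch-length scale.**  The protocol's exponential rate is not fixed by
  any stated value; the obvious guess (mean 0.1 substitutions/site/branch)
  saturates 16–64-taxon alignments once the 1.8× clock noise is applied
  (root-to-tip paths beyond 1 substitution/site, p-distances near 0.75,
  undefined distance corrections).  The default is rate 40 (mean 0.025),
  giving root-to-tip divergences around 0.2–0.4 — the regime occupied by
  the rRNA/mtDNA alignments this class of method is applied to, and one in
  which distance corrections exist for every pair.  The parameter is
  exposed (`br_rate`).
* **Equal stationary frequencies** by default (configurable); continuous
  Gamma rates rather than discretized categories.
* **Scoring** (`score_detections()`): a detection is a true positive only
  when donor and recipient branches *both* equal a not-yet-matched true
  event's; direction is respected for directed detections, either
  orientation matches for undirected ones; everything else is a false
  positive.  Exact-branch matching presupposes the backbone contains the
  true branches, so the simulation study supplies the generating tree as
  the species-tree input.

A green simulation test therefore establishes that the whole chain —
generator, window inference, weighting, admission, direction, scoring —
recovers planted events under the stated conditions.  It does *not*
establish performance on real data: the simulator has no indels, no
amino-acid mode, no rate variation across lineages beyond the 1 + ax
scaling, and single-method NJ window trees are weaker than the multi-method
collections (distance, parsimony, likelihood, Bayesian) the method is
normally fed.  That last gap is visible in the false-positive behaviour: a
single inference method reproduces its own systematic artifacts in many
overlapping windows, so spurious conflicts clear a 10% cutoff at an
appreciable rate, whereas pooling several methods dilutes them.  The
negative-control bound asserted in the acceptance suite (mean FP < 0.5 per
0-event replicate) is not attainable in this single-method world — the
corresponding test is expected to stay red and is reported as measured, and
the same dilution gap depresses the window-width contrast asserted there.

## Degenerate inputs and edge policies

* Fewer than 3 taxa, duplicate labels, or a taxon-set mismatch with the
  established order are parse errors; star trees are valid and carry no
  clusters.
* Multifurcations are accepted everywhere and contribute no extra splits.
* SPR moves discard branch lengths (no algorithm here consumes them) and
  keep supports only on splits unchanged by the move.
* A cluster already present in, or compatible with, the current network
  state is skipped silently (it is not a conflict); a duplicate of an
  accepted reticulation's split is skipped as well.
* Supports are auto-detected as probabilities when every value is ≤ 1 and
  rescaled to percent; an explicit `support_scale` overrides.

## Reproducibility

Every stochastic entry point takes an integer seed and restores the
caller's RNG state; derived seeds stay within the 32-bit range.  The CLI
(`netcons` executable, or `nc_cli()`) requires explicit seeds for
stochastic subcommands and writes a JSON manifest (inputs, parameters,
seed, package version) next to every result, so each output is reproducible
from its manifest alone.
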