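# netcons

Weighted consensus trees and **explicit weighted consensus phylogenetic
networks** from collections of gene trees.

## The problem

Gene trees inferred for different genes (or different parts of one gene)
routinely disagree with each other and with the species history.  Much of
that disagreement is noise, but some of it is signal: hybridization,
intragenic recombination and horizontal gene transfer (HGT) each leave
well-supported conflicting branches behind.  Classical consensus methods
collapse the conflict; splits-graph methods display it but name no events.
`netcons` takes the middle road for phylogeneticists who have a set of
supported gene trees (or an alignment) and want both a backbone tree *and*
an explicit, weighted, directed list of the conflicts worth believing.

## The statistic at its core

Every cluster (bipartition) *i* of the input trees gets an overall weight
from the branch supports and tree weights of the trees containing it
(σ<sub>ij</sub> = 1 iff cluster *i* occurs in tree *j*, *n* = number of
trees):

* W<sub>i</sub>(C)   = Σ<sub>j</sub> σ<sub>ij</sub> W(C<sub>ij</sub>) / n — branch supports only
* W<sub>i</sub>(T)   = Σ<sub>j</sub> σ<sub>ij</sub> W(T<sub>j</sub>) / n — tree weights only
* W<sub>i</sub>(C,T) = Σ<sub>j</sub> σ<sub>ij</sub> W(C<sub>ij</sub>) W(T<sub>j</sub>) / n — both

Clusters are ranked by weight; a greedy compatible accretion gives the
backbone (weight-based extended majority rule; bootstrap-based majority,
extended majority and Nelson consensus trees are also provided).  Remaining
clusters above a cutoff that are exactly **one SPR move away** from the
current network (the *first degree of incompatibility*) become reticulation
branches; the transfer direction is the orientation whose SPR
interpretation minimizes the support-weighted cumulative Robinson–Foulds
distance to the gene trees containing the cluster.

## Worked example

Three five-taxon gene trees; T1 and T2 group (x,y) with supports 40 and 45,
T3 groups (x,u) with support 90, and all three contain (z,w) at 100:

```r
library(netcons)
dir <- tempfile(); make_fixtures(dir)
coll <- read_gene_trees(file.path(dir, "three_trees.nwk"))
rank_clusters(coll, "C")
#>     key  side size    weight n_member
#> 1 00110 00110    2 100.00000        3
#> 2 01110 10001    3  30.00000        1
#> 3 00111 11000    3  28.33333        2
```

(z,w) scores 100 (in every tree at 100%), (x,u) scores 90/3 = 30, and
(x,y) scores (40+45)/3 = 28.33 — the weight divides by *all* trees, so a
locally strong branch found in one tree of three is penalized.

```r
print(bootstrap_majority(coll))
#> <consensus_result> method bm: 1 clusters
#> ((z,w)100,x,y,u);
print(bootstrap_extended_majority(coll))
#> <consensus_result> method bem: 2 clusters
#> (((z,w)100,y)30,x,u);
build_network_from_genetrees(coll)
#> <consensus_network> backbone 5 taxa, 1 reticulation(s), cutoff 10%
#> (((z,w)100,y)30,x,u);
#>   order donor_taxa recipient_taxa  direction   weight
#> 1     1          x              y undirected 28.33333
```

The majority tree keeps only (z,w); the extended tree adds (x,u) because 30
beats 28.33; the network then represents the displaced (x,y) signal as one
reticulation of weight 28.33 linking the x and y branches — undirected,
because moving y to x and x to y produce the same topology, the signature
of symmetric alternatives.

The same machinery scans alignments for mosaic genes
(`build_recombination_network()`: per-window trees, pooled window clusters,
interval-annotated reticulations), uses a rooted species tree as a fixed
backbone for HGT (`build_hgt_network()`), simulates the whole evaluation
protocol (`simulate_dataset()`, `score_detections()`), and runs from the
shell:

```sh
Rscript -e 'netcons::nc_cli()' network --trees trees.nwk --cutoff 10 --out out/
Rscript -e 'netcons::nc_cli()' scan --msa gene.fasta --window-frac 0.3 --step 5 \
    --cutoff 10 --seed 1 --out out/
```

(An executable wrapper is installed at `exec/netcons` inside the package.)

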