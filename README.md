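# graphMLM

Unsupervised integration of weighted gene networks by masked language
modelling over random walks.

Molecular interaction data come as multiple heterogeneous weighted
networks — protein–protein interaction, co-expression, genetic
interaction — over partially overlapping gene sets. graphMLM learns one
embedding for all of them: each network is converted into "sentences" of
genes by weight-biased random walks (transition probability
`w(u,v) / Σ_v' w(u,v')`; 10 walks of 10 nodes per gene by default), a
`[CLS]` token is prepended, and a small transformer encoder is trained to
recover masked gene tokens from context (20% of tokens per sentence,
cross-entropy over the masked positions). Once per epoch, cycling through
the input networks, the shared embedding table `X` is smoothed by one
random-walk-with-restart step on the network's symmetric-normalised
adjacency:

    X' = (1 − α) W X + α X,   W = D^(−1/2) A D^(−1/2)

This propagation acts as a graph-smoothness regulariser: it raises the
training loss yet makes the embedding substantially more informative for
module-level biology. The trained artifacts are the node embedding (the
table after the final epoch) for clustering and gene-function prediction,
and the `[CLS]` sequence embedding for pathway-level classification of
gene paths. It is written for computational biologists who want a
self-contained, CPU-scale, fully deterministic implementation with
built-in evaluation protocols and synthetic benchmarks.

## Worked example

Three stochastic-block-model networks with 5 planted modules over 200
genes, each network missing a random 20% of the genes:

```r
library(graphMLM)

sbm <- generateSBMCollection(seed = 1)   # collection + planted standard
sbm$collection
#> NetworkCollection of 3 networks over 200 nodes
#> WalkNetwork 'sbm1': 160 present / 200 vocabulary nodes, 953 edges
#> WalkNetwork 'sbm2': 160 present / 200 vocabulary nodes, 976 edges
#> WalkNetwork 'sbm3': 160 present / 200 vocabulary nodes, 974 edges

corp <- generateCorpus(sbm$collection, reps = 10, length = 10, seed = 1)
corp
#> WalkCorpus: 2000 walks of length 10 over 200 nodes

cfg <- transformerConfig(e = 32, nBlocks = 2, nHeads = 4, ffnHidden = 128,
                         epochs = 5, seed = 1)
enc <- trainEncoder(sbm$collection, corp, cfg)
lossTrace(enc)
#> [1] 5.421267 5.319576 5.301230 5.296804 5.276231

md <- moduleDetection(nodeEmbeddings(enc), sbm$standard)
md$bestAMI
#> [1] 0.8862734
```

The loss trace is the mean cross-entropy per masked token per epoch
(chance level here is log(200) ≈ 5.30). Even after five epochs the
propagation-smoothed embedding recovers the planted modules with adjusted
mutual information 0.89 (1 = perfect recovery, 0 = chance); the full
30-epoch runs in the acceptance script (seed 1) reach 0.985 integrated
versus 0.713 for the best single network — the gain from integrating the
three partial networks. `sequenceEmbeddings(enc, paths)` returns `[CLS]`
vectors for gene paths, and `pathwayClassification()` scores labelled
paths by macro one-vs-rest ROC AUC against an averaged-node-feature
baseline.

Real data enter through plain-text edge lists
(`readNetworkCollection()`), two-column or GMT-style gene–label standards
(`readFunctionalStandard()`), and path files (`readLabeledPaths()`). A
thin CLI with `train`, `evaluate` and `make-fixtures` subcommands lives
at `inst/scripts/graphMLM`.

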