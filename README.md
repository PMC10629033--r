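# mlnalign — pairwise global alignment of multilayer networks

Multilayer networks model systems whose interactions live on layers:
intralayer edges connect nodes within a layer (drug–drug interactions,
disease–disease relations), interlayer edges connect nodes across layers
(disease–drug associations). Global network alignment maps the nodes of one
such network one-to-one onto another so that topologically similar regions
correspond — the device used, for example, to transfer knowledge between
biological networks from different sources or species. `mlnalign` is an R
package (with a command-line interface) for exactly this setting; generic
global aligners ignore the layer structure, and that is precisely where
they fail on multilayer data.

## Method

A network is an attributed edge list of tuples *(u, v, l)* — undirected,
one layer identifier per intralayer plus a dedicated identifier for
interlayer edges — and is collapsed losslessly into a flat typed-edge
graph. The pipeline is:

1. **Node embeddings.** Second-order biased random walks over the flat
   graph (all layers traversed uniformly) feed a skip-gram model with
   negative sampling: each node becomes a vector of length *N* reflecting
   its topological context across every layer. Initial vectors are a
   deterministic function of the node identifier and the seed, so two
   networks sharing identifiers are embedded in a common coordinate frame.
2. **Similarity matrix.** S[v, u] = cosine(x_v, y_u) over all
   source–target pairs; an externally supplied similarity matrix (e.g.
   curated biological similarity) can replace the embedding step.
3. **Greedy one-to-one pre-mapping.** Pairs are accepted in descending
   similarity order while both endpoints are free — the mapping
   f(v) = argmax_u φ(v, u) with collisions resolved globally.
4. **Jaccard refinement.** Pairs whose mapped neighborhoods overlap
   perfectly (Jc = |Γ(u) ∩ Γ(v)| / |Γ(u) ∪ Γ(v)| = 1, with source
   neighbors translated through the current mapping) are frozen; the rest
   are revisited in ascending-Jc order and swapped pairwise whenever the
   swap strictly raises the mapping's total Jaccard coefficient, within a
   budget of accepted permutations (default: 50% of the pre-mapping size).

The package also ships the scale-free synthetic benchmark the method is
validated on (extended preferential attachment with duplication/divergence
probabilities *p*, *q*; 20% interlayer edges; noisy counterparts by edge
removal with known ground truth) and the evaluation suite: node
correctness, min–max-normalized alignment score, ROC/AUC, F1 aggregates,
MCC, one-way ANOVA recomputed from group summaries, and McNemar's test with
continuity correction. See `vignettes/multilayer-alignment.Rmd` for the
full methods account.

## Worked example

Generate a two-layer benchmark network, damage a copy by removing 15% of
its edges, and align the two:

```r
library(mlnalign)

gen   <- generateMultilayer(generatorConfig(n = 100, m = 2,
                                            p = 0.5, q = 0.4, seed = 7))
net   <- gen$network
net
#> MultilayerNetwork with 200 nodes, 540 edges
#>   layers: 1, 2 | interlayer id: 3
#>   intralayer: 432 | interlayer: 108

noisy <- perturbEdges(net, 0.15, seed = 7)
aln   <- alignNetworks(net, noisy, embConfig = embeddingConfig(seed = 7))
aln
#> Alignment of 200 node pairs | permutations: 5 | stop: converged
#>   source target     score   jaccard
#> 1   L1_1   L1_1 0.7405077 0.9285714
#> 2  L1_10  L1_10 0.6895501 0.7777778
#> 3 L1_100 L1_100 0.7300527 1.0000000
#> ...

evaluateAlignment(aln, gen$mapping)
#> EvaluationReport
#>   NC: 0.9700 | F1: 0.9700 | AUC: 0.6014 | MCC: -0.0300
#>   tp=194 fp=6 tn=0 fn=6 | TPR=0.9700 FPR=1.0000
```

Despite 81 missing edges, 194 of 200 nodes are mapped back onto their true
counterparts (node correctness 0.97); the `jaccard` column shows how much
of each pair's neighborhood survived the noise. The score and Jaccard
columns feed the ROC sweep; tn = 0 is structural at the full-mapping
operating point (every source node is mapped), so FPR there is 1 and the
informative negatives appear only along the thresholded curve.

The same pipeline is scriptable from a shell:

```sh
inst/cli/mlnalign generate --n 100 --m 2 --p 0.5 --q 0.4 \
    --noise 5,10,15,20,25 --seed 7 -o out/
inst/cli/mlnalign align -s out/base.tsv -t out/noisy_15.tsv \
    --seed 7 -o out/aln.tsv
inst/cli/mlnalign evaluate -a out/aln.tsv --truth out/truth.tsv \
    -o out/report.json
```

Run with no arguments on a terminal for guided (step-by-step) parameter
entry; every run writes a JSON run report capturing config and seed.

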