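---
title: "Aligning multilayer networks by topological embedding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning multilayer networks by topological embedding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlnalign)
```

## The problem

Pairwise global network alignment (PGNA) seeks a one-to-one mapping between
the node sets of two networks that preserves topologically similar regions —
the network analogue of sequence homology transfer: if a drug–disease network
of one data source aligns well onto another, node mappings carry knowledge
across them. Multilayer networks complicate this: edges are split into
*intralayer* interactions (within one layer, e.g. drug–drug or
disease–disease) and *interlayer* interactions (across layers, e.g.
disease–drug associations), and a node's identity is shaped by both kinds.

`mlnalign` aligns two multilayer networks in four steps:

1. **Flatten.** Each network, stored as an attributed edge list
   $(u, v, l)$ with $l$ the layer identifier (one dedicated identifier tags
   interlayer edges), is collapsed to an equivalent *flat* typed-edge graph.
   The typing keeps the representation lossless — `fromFlat(toFlat(x))`
   reconstructs the multilayer object exactly — while letting the walk
   machinery traverse all interactions of a node uniformly.
2. **Embed.** Second-order biased random walks over the flat graph feed a
   skip-gram model with negative sampling, producing one vector of length
   $N$ per node. A node is thus characterized by the whole set of its
   interactions across all layers; interlayer edges are treated as ordinary,
   independent edges during walks.
3. **Match.** The similarity matrix $S_{vu} = \cos(\mathbf{x}_v,
   \mathbf{y}_u)$ over all source–target pairs is scanned in descending
   order; a pair is fixed when both endpoints are still free. This greedy
   rule realizes the global maximization of the mapping objective
   $f(v) = \arg\max_u \phi(v, u)$: a pair is accepted only when no remaining
   candidate scores higher. An externally supplied similarity matrix (e.g.
   curated biological similarity) can replace step 2 entirely.
4. **Refine.** The pre-mapping is improved by successive permutations guided
   by the Jaccard coefficient $Jc = |\Gamma(u) \cap \Gamma(v)| /
   |\Gamma(u) \cup \Gamma(v)|$ of mapped neighborhoods, where the source
   node's neighbors are translated into target space through the current
   mapping. Pairs with $Jc = 1$ are final; the rest are revisited in
   ascending-$Jc$ order and swapped pairwise whenever the swap strictly
   increases the mapping's total Jaccard coefficient.

## Why cross-network cosine similarity works at all

Two skip-gram models trained independently produce embeddings that are only
defined up to rotation, so cosine similarity across two embedding spaces is
in general meaningless. `mlnalign` makes the two spaces comparable the same
way mainstream word2vec implementations do: the initial vector of a node is
a deterministic function of the node identifier's hash and the seed. Two
networks that share node identifiers therefore start from identical points,
and similar training corpora keep them in a common frame. Two identical
networks embed identically (self-alignment is exact by construction); a
noisy counterpart drifts in proportion to the topological damage. This is a
genuine assumption of the method: aligning two networks with completely
disjoint identifier vocabularies through embeddings alone would rest only on
corpus statistics, and an external similarity matrix is the better route
there.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `dimensions` | 128 | skip-gram hidden-layer size $N$ (vector length) |
| `numWalks` | 10 | walks started per node |
| `walkLength` | 80 | nodes per walk |
| `window` | 5 | context radius $w$: positions $c-w \dots c+w$ are predicted |
| `epochs` | 5 | passes over the walk corpus |
| `returnParam`, `inoutParam` | 1, 1 | second-order walk biases; 1/1 is a uniform walk |
| `negative` | 5 | negative samples per context |
| `alpha` | 0.025 | initial learning rate, linearly decayed |
| `maxPermutations` | `ceiling(0.5 * |pre|)` | refinement budget, counted in *accepted* swaps |
| `similarityTolerance` | `Inf` | max. drop in total mapped similarity a swap may cost |

The embedding defaults are the customary node2vec settings; nothing in the
method dictates others, and they are deliberately not tuned per dataset.
Training is single-threaded with a fixed seed: the same corpus and seed give
a bit-identical embedding matrix. That costs the wall-clock benefit of
multithreaded training but makes every run exactly reproducible from its
run report.

Two refinement choices deserve justification:

* **Budget in accepted swaps.** "Permutations" could count attempts or
  accepted moves; we count accepted moves, since attempts are an
  implementation detail of the partner search, and record the count and the
  stop reason (`converged`, `all_overlapped`, `budget_exhausted`) in the
  result.
* **`similarityTolerance = Inf`.** A permutation is meant to trade embedding
  similarity for strictly better global neighborhood overlap — a swap that
  must not lower the mapped similarity at all would almost never fire,
  because the greedy pre-mapping already sits near a similarity optimum.
  The tolerance is exposed for users who want refinement constrained
  (`0` or `1e-9` yields a similarity-conservative refinement).
  Every accepted swap is additionally verified against the *recomputed*
  total Jaccard of the whole mapping, not just the local two-pair delta,
  because swapping also changes the translation of every neighbor that
  points at the swapped pair; this keeps the total monotone, which the test
  suite asserts. Pairwise swaps are a hill climb: local optima exist (a
  crossed pair mirrored by a symmetric decoy can be stable), which is the
  expected behavior of a permutation heuristic, not a defect.

## The synthetic benchmark

`generateMultilayer()` emulates scale-free biological networks: each layer
grows by preferential attachment ($n$ nodes, $m$ edges per new node), and
after each attachment an extra edge is added between random existing nodes
with probability $p$ (duplication) and a removable edge is deleted with
probability $q$ (divergence), where *removable* means neither endpoint
would be isolated. At $p = q = 0$ the layer is exactly a Barabási–Albert
graph with $m(n-m)$ edges. Two layers with disjoint node namespaces are
wired with uniformly sampled interlayer edges until those make up 20% of
the final edge total, i.e. $|E_b| = \mathrm{round}(0.25\,|E_a|)$ — the
fraction is interpreted against the final count including the interlayer
edges themselves, computed after the $q$-removals. The benchmark's two
parameter sets are $(n{=}100, m{=}2, p{=}0.5, q{=}0.4)$ and
$(n{=}100, m{=}2, p{=}0.3, q{=}0.7)$.

Noisy counterparts remove exactly $\lfloor f\,|E|\rfloor$ edges
(`floor`; no rounding rule is canonical) drawn uniformly over intralayer
and interlayer edges together, resampling any candidate whose removal would
isolate an endpoint. The node set is therefore preserved, which is what
lets the identity mapping serve as ground truth. For workflows where the
similarity matrix itself is the input, `perturbSimilarity()` noises a
fraction of its entries instead, by resampling from the empirical
distribution of the untouched entries (range-preserving by construction;
Gaussian jitter is available behind `method = "jitter"`). Each noised entry
is forced to differ from its original value — on a two-valued matrix this
makes noise maximally adversarial, which the tests account for.

What the generator does *not* emulate: heterogeneous node types with
per-layer vocabularies, weighted or directed interactions, correlated
(non-uniform) noise, and the sheer size of real association networks.
Passing benchmarks here demonstrates correct mechanics and noise response
on scale-free topologies, not performance on any particular real dataset.

## Evaluation machinery

Node correctness (NC) is the fraction of aligned pairs agreeing with the
true mapping. The *alignment score* is NC after unity-based (min–max)
feature scaling across all alignments of one benchmark run — the
normalization population is the run, not the noise group, so one score of
1 (best alignment of the run) and one 0 (worst) always exist when values
differ; an all-equal run is left on the raw NC scale. Because every source
node is mapped, the natural operating point has no predicted negatives:
`tp + fp = |V|`, `tn = 0`, and true negatives only arise in the
threshold-sweep ROC construction, where pairs scoring below a threshold and
absent from the truth count as negatives. AUC uses the trapezoid rule over
the sweep and equals the Mann–Whitney statistic, which the tests assert.
F1 is the harmonic mean of precision and recall, aggregated as mean,
maximum, and a noise-normalized mean (min–max within each noise level, then
averaged). The statistical layer recomputes one-way ANOVA *from group
summaries* ($SS_b = \sum n_i(\bar x_i - \bar x)^2$,
$SS_w = \sum (n_i - 1)s_i^2$, sample SDs with the $n-1$ denominator) so
published descriptive tables can be re-analyzed without raw data, and
McNemar's test on the discordant cells uses the classical continuity
correction $\chi^2 = (|b - c| - 1)^2/(b + c)$ — the unclamped form, which
is also what `stats::mcnemar.test` computes and serves as the test-suite
oracle.

## Numerical and degenerate-input choices

* Ties in the greedy scan break lexicographically by (source, target)
  label in C locale, so results are platform-stable.
* Cosine values are clamped to $[-1, 1]$ against floating-point drift.
* `|V| \le |U|` is enforced by swapping the inputs and inverting the output
  mapping; the result always has one row per node of the smaller network.
* Empty networks, zero noise fractions, a zero permutation budget, and
  all-equal score vectors all pass through as identities rather than
  errors; zero embedding vectors, isolated nodes, empty truth mappings and
  `b + c = 0` are hard errors with named nodes where applicable.
* The walk and training RNG is a self-contained 64-bit generator seeded
  from the configuration, independent of R's RNG state; generator functions
  use R's RNG under `set.seed` discipline and restore the caller's stream.

## Problem sizes used by the test and acceptance runs

The packaged acceptance run regenerates the benchmark at one network per
parameter set (two networks, six noise levels each, three seeds — 36
alignments of 200-node networks with default embedding settings); unit
tests use 30–60-node networks with reduced embedding dimensions. These
sizes were chosen as the smallest at which the scale-free degree structure
and the noise response are clearly expressed; the benchmark driver scales
to the full ten-network protocol via `networksPerSet = 5`.

## Known limitations

* Embedding-based similarity requires shared node identifiers (or an
  external similarity matrix) to pin the two embedding spaces to a common
  frame.
* The refinement is a pairwise-swap hill climb; it improves the mapping
  monotonically but is not guaranteed to reach the global Jaccard optimum.
* The greedy pre-mapping is deliberately not the Hungarian optimum; it
  implements the descending-order acceptance rule of the mapping objective.
  On small instances the tests compare it against exhaustive enumeration to
  document (not hide) the distinction.
* Only undirected, unweighted, simple edges are modelled; node attributes
  beyond identity, directed or weighted layers, and many-to-many (local)
  alignment are out of scope.
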