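---
title: "Evaluating protein-complex detection: models, criteria and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating protein-complex detection: models, criteria and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(complexeval)
```

## The evaluation problem

Complex-detection algorithms partition (or cover) a protein-protein
interaction network into candidate complexes. Judging such an algorithm
means comparing its detected clusters $\mathcal{C} = \{C_1,\dots,C_m\}$
with the reference complexes $\mathcal{P} = \{P_1,\dots,P_n\}$ of a
curated catalogue. Both sides are families of protein sets; reference
complexes may legitimately overlap each other, and the relation between
the two families is partial — some complexes match no cluster and vice
versa.

`complexeval` models the relation as a weighted bipartite graph. The
`overlap table` built by `build_overlap()` stores, for every pair
$(P_i, C_j)$,

* the shared-protein count $t_{ij} = |P_i \cap C_j|$,
* the neighborhood affinity $NA(P_i,C_j) = t_{ij}^2 / (n_i m_j)$, where
  $n_i = |P_i|$ and $m_j = |C_j|$, and
* the Jaccard index $JCC(P_i,C_j) = t_{ij} / |P_i \cup C_j|$,

because different criteria consume different scores. Both scores are
symmetric, lie in $[0,1]$, vanish exactly when the sets are disjoint and
reach 1 exactly on equality.

## The criterion family

**Set-overlap criteria.** The clustering-wise sensitivity and positive
predictive value
$$SN = \frac{\sum_i \max_j t_{ij}}{\sum_i n_i}, \qquad
  PPV = \frac{\sum_j \max_i t_{ij}}{\sum_{ij} t_{ij}}, \qquad
  ACC = \sqrt{SN \cdot PPV}$$
are threshold-free but have well-known blind spots, each of which is a
generator preset here (see below): a giant cluster spanning all
reference proteins saturates $SN$; duplicating within-complex clusters
inflates $PPV$; spurious within-complex pairs leave $ACC$ at 1;
overlapping reference complexes cap $PPV$ below 1 even for a perfect
method. When nothing overlaps at all we define $PPV = ACC = 0$ rather
than failing: a method with no overlap earns the worst score, not an
error.

The $N$-subscript variants (`n_metrics()`) replace the plain maxima by
maxima over counterparts whose *Jaccard* index strictly exceeds a
threshold $\theta$: per complex, $K_i = \max\{t_{ij} : JCC(P_i,C_j) >
\theta\}$ (0 when the max is empty), $Precision_N = \sum_i K_i / \sum_i
n_i$, with $Recall_N$ defined per cluster as the mirror image, and
$F_N$ their harmonic mean.

**Matching-based criteria.** `threshold_graph()` keeps the pairs with
$NA \ge \theta$ and $t_{ij} > 0$; the zero-overlap guard prevents the
degenerate inflation of matchings at the low end of threshold sweeps.
On that graph:

* `mmr()` — the maximal matching ratio: the total weight of a
  maximum-weight bipartite matching divided by $n$;
* `pr_metrics()` — Precision $= N_p/n$ counts complexes with at least
  one qualifying cluster, Recall $= N_c/m$ the converse (this
  literature's naming, deliberately kept although it is swapped
  relative to machine-learning convention);
* `plus_metrics()` — the one-to-one refinement: only pairs of a
  maximum-cardinality matching count, so $N_p^+ = N_c^+ =
  |Match(\mathcal{P},\mathcal{C},\theta)|$ and redundant near-copies of
  a cluster cannot all be validated by one complex;
* `composite_mmr_fplus()` — $MMR + F^+ \in [0,2]$, combining matched
  quality (affinity mass) with matched quantity (counts). It reaches 2
  exactly when the detected clusters coincide with a gold standard
  whose complexes all pass the threshold against themselves — for
  disjoint catalogues, at every $\theta \in (0,1]$.

A deliberate asymmetry of the definitions is preserved: affinity-based
criteria use $\ge \theta$, the Jaccard-based $N$-family uses strictly
$> \theta$.

**Threshold-free forms.** Because every threshold-dependent value can
reorder methods as $\theta$ moves, `sweep_criterion()` samples a
criterion over a grid and `curve_auc()` integrates it by the
trapezoidal rule. `aumf()` is the area under the $(MMR + F^+, \theta)$
curve; `aupr()` traces precision against recall as $\theta$ varies
(plain or `+` variant), collapsing equal-recall points to their best
precision and integrating over the observed recall range only, with no
extrapolation toward recall 0 or 1 — a single observed point therefore
has area 0, which is reported as such rather than invented.

## Numerical and convention choices

* **Default threshold** $\theta = 0.25$, the conventional neighborhood
  affinity cutoff in this literature.
* **Default grid** $\theta \in \{0.01, 0.02, \dots, 1.00\}$. Zero is
  excluded: with $\ge$ semantics and the $t_{ij} > 0$ guard it adds
  nothing beyond the smallest positive threshold. 100 points resolve
  the step functions of realistic set sizes.
* **No area normalisation.** Areas are not divided by grid width, so
  they are comparable only across identical grids; reports record the
  grid. With the default grid the composite's ceiling is $2 \times
  0.99 = 1.98$.
* **Harmonic means** return 0 when both components are 0.
* **Matching backend.** Both matchings run through `igraph`'s bipartite
  matcher. For MMR this is the *unrestricted* maximum-weight matching
  (a lighter matching with more edges never wins). For the `+` family,
  maximum cardinality is enforced by offsetting every edge weight by
  $\min(n,m)+1$, which makes one extra edge outweigh any achievable
  affinity difference; among maximum-cardinality matchings the
  maximum-affinity one is therefore selected, making the reported pair
  list reproducible. Correctness of both is pinned in the test suite by
  exhaustive brute-force enumeration on instances with $n, m \le 6$,
  not by trust in the backend.
* **Ties in values** cannot occur: cardinality and optimal weight are
  unique even when the pairing is not, and only those enter the
  reported criteria.

## Cross-method integration and filters

`integrate_methods()` builds a k-partite graph with one part per
method and one node per cluster; nodes of different parts are joined
when their clusters' Jaccard index exceeds $\varphi$ (default 0.5),
with identical clusters always linked so that $\varphi = 1$ selects
exactly the clusters several methods reproduce verbatim — at
$\varphi = 1$ union and intersection consequently coincide. All maximal
cliques strictly larger than $\psi$ (default $k/2$) become consensus
clusters, as the union or the intersection of their members; empty
intersections are dropped and exact duplicates collapsed, since
duplicates would distort every downstream criterion. Clique provenance
(which method contributed which cluster) is kept as an attribute and in
a JSON sidecar by the command-line tool. Jaccard is used as the
overlap measure because it is the only cluster-cluster score defined
in this setting and it makes the $\varphi = 1$ identity hold.

Three filters mirror common server-side options: `filter_size()`
(inclusive size band), `filter_protein()` (exact-ID lookup across
methods), and `filter_reliability()`, which keeps a cluster when at
least $\beta$ methods — the filtered method itself included, so
$\beta = 1$ is the identity — contain a cluster with Jaccard index
above $\varphi$.

## What the synthetic generator emulates — and what it does not

`make_gold()` draws complex sizes uniformly from 3–8 (the typical range
of curated heteromeric complexes) and can let a chosen fraction of
consecutive complex pairs share a fixed number of proteins, emulating
catalogue overlap. `perturb_clusters()` starts from a perfect detection
and applies, in a fixed order so one seed fully determines the output:
cluster dropout (false negatives), per-protein dropout, contamination
from a disjoint `N…` namespace (traceable noise), exact duplication,
spurious within-complex pairs, and the giant union cluster. Each knob
reproduces one known pathology of the criteria, and the tests assert
the corresponding metric signature symbolically (e.g. giant $\Rightarrow
SN = 1$; spurious pairs $\Rightarrow ACC = 1$).

`make_ppin()` plants each complex as a dense subgraph: intra-complex
pairs get edges with probability $p_{in} = 0.85$ and reliability
weights uniform on $(0.6, 1)$, background pairs with $p_{out} = 0.02$
and weights on $(0.05, 0.4)$ — complexes denser and more reliable than
their surroundings, the premise of density-based detection. These
defaults were fixed once as plausible desk-scale values.

The generator intentionally does **not** model scale-free degree
structure, experimentally calibrated reliability weights, or the size
distribution tails of real catalogues. Passing tests therefore certify
the *criteria* — their algebraic limits, monotonicity and oracle
equivalence — not any claim about how detection methods rank on real
interactome data.

## Problem sizes and verification

The test suite works at deliberately small scale so that exhaustive
oracles stay feasible: matching is cross-checked against brute-force
enumeration on 200 random instances with at most 6 complexes and 6
clusters; clique enumeration against subset enumeration on k-partite
graphs of at most 12 nodes; monotonicity of all seven
threshold-dependent components over the full default grid on 50 random
fixtures; and the worked two-complex/three-cluster instance that
threads through the documentation is first re-derived from raw set
arithmetic plus brute-force matching, then frozen as a regression
fixture.

## Known limitations

* Quadratic pair enumeration in `build_kpartite()` and the planted
  network generator: fine for catalogue-scale inputs (thousands of
  clusters), not for millions.
* The $JCC$-vs-$NA$ threshold-convention split ($>$ vs $\ge$) is
  preserved from the criteria's definitions; users switching between
  families should not expect the boundary case to behave identically.
* Area values depend on the grid; compare areas only across identical
  grids (the default grid is recorded in every report).

## A worked example

```{r example}
gold <- make_gold(n_complexes = 6, size_range = c(4, 7), seed = 42)
detected <- perturb_clusters(gold, drop_protein_rate = 0.2,
                             duplicate_clusters = 2, seed = 43)
evaluate_method(gold, detected, theta = 0.25)
```

Dropping 20% of proteins costs affinity mass (MMR < 1) and the two
duplicated clusters dilute Recall⁺ without fooling MMR — the pattern
the one-to-one criteria were designed to expose.
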