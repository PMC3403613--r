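---
title: "Detecting protein complexes through the weak ties effect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting protein complexes through the weak ties effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weakties)
library(igraph)
```

## The problem and the model

Protein complexes are molecular assemblies whose members interact densely
with one another. In a protein–protein interaction (PPI) network the edges
therefore play two distinct roles: *cohesive ties* inside a complex, and
*weak ties* that bridge otherwise dissimilar groups and carry most of the
global connectivity. Methods that look only for dense subgraphs ignore this
distinction; `weakties` builds it into every stage of detection.

The pipeline has five stages.

1. **Bridgeness.** For an edge $(u,v)$, let $C_u$ be the size of the largest
   clique containing $u$, $C_{u,v}$ the largest containing the edge, and
   $C_{u\setminus v}$ the largest containing $u$ once $v$ is deleted. The
   reference measure
   $$B^{(\mathrm{ref})}_{u,v} = \frac{\sqrt{C_u C_v}}{C_{u,v}}$$
   assigns every clique edge the value 1, so it cannot tell a small clique's
   edges from a large one's. The weak-tie measure adds the open-neighbourhood
   Jaccard dissimilarity:
   $$B_{u,v} = \bigl(1 - J(u,v)\bigr)\,
     \frac{\sqrt{C_{u\setminus v}\, C_{v\setminus u}}}{C_{u,v}}.$$
   On an edge of an isolated $m$-clique this equals $2(m-1)/m^2$, decreasing
   with clique size, and it is maximal on bridges between dense groups.
   Both quantities are computed *exactly*: the maximum-clique searches are
   confined to the closed neighbourhood of the query vertex or edge, which
   stays small in sparse interaction networks; a guard
   (`max_neighborhood`, default 200) refuses pathological neighbourhoods
   rather than silently approximating.

2. **Edge weights.** $w_{u,v} = e^{-B_{u,v}}$, so strong bridges contribute
   almost nothing to walk strength while cohesive edges keep weights near 1.

3. **Walk similarity.** With $W$ the weighted adjacency matrix,
   $$S = W + \beta W^2 + \beta^2 W^3 .$$
   A walk's strength is the product of its edge weights, discounted by
   $\beta$ per extra step; the polynomial is truncated at cubic order, so
   vertex pairs at distance greater than 3 always score 0. Note that matrix
   powers count *revisiting* walks ($u \to x \to u \to v$), which matters in
   practice: even a single low-weight bridge acquires similarity of the
   order of $\beta^2 w \sum_x w_{u,x}^2$ from its endpoints' neighbourhoods.

4. **Virtual network and cores.** Thresholding $S$ at $\tau$ gives the
   reliable virtual network $\Phi(G,\tau)$: same vertex set, an edge exactly
   where $S_{u,v} \ge \tau$. Cores are its inclusion-maximal cliques with at
   least `min_core` members, enumerated exactly (any maximal-clique finder
   would serve; exact enumeration gives a testable contract).

5. **Attachments.** Candidates are the vertices outside a core $U$ with at
   least one *original-network* edge into it. The closeness
   $cl(v,U) = \sum_{u \in U} S_{v,u} / (|U|+1)$ is compared with the average
   level $acl = \sum_{w \in CS(U)} cl(w,U) / (|CS(U)| + |U|)$; candidates at
   or above $acl$ join the complex. Both denominators are kept exactly as
   the method defines them ($|U|+1$, and $|CS|+|U|$ with the sum running
   over the candidates only); see "Known limitations" for the consequences.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `beta` | 0.618 | walk discount; values below 1 favour short walks. The default balances match quality against coverage. |
| `tau` | 0.02 | virtual-network similarity threshold. No universal default exists; it controls core size and count directly and **should be swept** (`sweep_parameter()`). Virtual edge count is non-increasing in `tau`. |
| `variant` | `"weakties"` | bridgeness feeding the weights; `"reference"` reproduces the clique-ratio baseline. |
| `min_core` | 3 | smallest admissible core; size-2 cores would make every edge a seed. |
| `t` (evaluation) | 0.2 | neighborhood-affinity threshold $|p\cap b|^2/(|p||b|) \ge t$ for counting a match — the standard choice in this evaluation lineage. |
| enrichment cutoff | 0.01 | per-complex best hypergeometric P-value below which a complex counts as functionally significant; no multiple-testing correction is applied. |

A practical note on `tau`: the similarity of a lone bridge edge between two
dense groups sits around $0.1$–$0.2$ (weight $e^{-B}$ plus revisiting-walk
terms), while intra-core similarities are an order of magnitude larger. At
the default `tau = 0.02` a single bridge therefore still joins two
complexes' virtual components (its endpoints become mutual attachments);
any `tau` in roughly $(0.2, 1.5)$ separates them cleanly. This is why the
package recommends sweeping `tau` rather than trusting any single value.

## The percolation diagnostics

`percolation_experiment()` removes edges in ascending or descending score
order (scores fixed on the intact graph, never refreshed) in batches of
`ceiling(step_fraction * |E|)`, recording the giant-component fraction
$R_{GC}$ and the normalized susceptibility
$\tilde S = \sum_{s < s_{max}} s^2 / N$ (exactly one largest component
excluded, also under ties — the standard convention, which keeps the
statistic finite-sample meaningful at the transition). The weak-ties
signature is that ascending-similarity removal disintegrates the network at
a far smaller removed fraction, with a sharp susceptibility peak, than
descending removal.

Ties are broken lexicographically by default (deterministic). On synthetic
union-of-clique graphs the scores are massively degenerate and the
lexicographic order would strip whole cliques in label order — an artifact
no real network shows — so the experiments on planted graphs use the seeded
random tie-break instead (`tie_break = "random"`).

## What the synthetic generator emulates — and what it does not

`planted_network()` builds the core–attachment anatomy directly: each
complex is a core clique (size drawn from `core_size`, default 4–8) plus
`attachments_per_complex = 2` peripheral vertices each linked to
`ceiling(0.6 * core size)` random core members; `bridge_edge_count` edges
join random core pairs (the weak ties) and background noise edges appear
independently with `background_noise_prob`. The defaults (20 complexes, no
noise, no bridges) are the clean recovery condition under which detection
must achieve F-measure 1; the noisy condition used in the tests adds
noise probability 0.01 and 10 bridges. `test_graph_from_catalog()` and
`alter_graph()` implement the union-of-cliques robustness benchmark with
`AG_{add,del}` alterations, both percentages relative to the *original*
edge count, deletion before addition (an added edge may recreate a deleted
one).

Real PPI networks are *not* homogeneous unions of cliques: they have
heavy-tailed degrees, cores of varying density, overlapping complexes and
experiment-specific noise structure. Passing tests on planted graphs shows
the pipeline implements its definitions correctly and that the weak-ties
signal behaves as designed under controlled conditions; it does not certify
performance on any particular real interactome. One concrete consequence of
the homogeneity: *descending*-order percolation on a planted graph also
undergoes a (much later) sharp transition, because all cliques dissolve at
the same rate; the tests therefore compare the two orders within the first
half of removals, where only the weak-tie-first order transitions.

## Numerical and design choices

* Similarity matrices are sparse (`Matrix`) at every size; powers of a
  DIP-scale adjacency matrix stay comfortably sparse because the polynomial
  is cubic.
* Thresholding at `tau = 0` returns the complete graph (all similarities
  are nonnegative, and the threshold is inclusive).
* Diagonal similarity entries (closed walks) are computed but never
  consulted: the virtual network excludes self-loops and closeness sums
  only over core members distinct from the candidate.
* Identical member sets among predictions are deduplicated (first kept);
  overlapping but distinct complexes are retained — the method is
  overlapping by design.
* All catalog orderings are canonical (sorted members, lexicographic list
  order), making every pipeline stage deterministic; the only randomness in
  the package lives in the generators and the optional percolation
  tie-break, all seeded and restored via a local RNG scope.
* `jaccard_similarity()` uses open neighbourhoods; a closed-neighbourhood
  switch exists for sensitivity analysis.
* If deleting $v$ isolates $u$ entirely, $C_{u\setminus v} = 1$ (the
  trivial clique $\{u\}$).
* The hypergeometric tail is computed on the log scale via `stats::phyper`;
  the test suite cross-checks it against an exact big-integer summation.

## Problem sizes used by the test suite

The suite validates the clique machinery against exhaustive subset
enumeration on 200 random graphs of up to 12 vertices; percolation and
anticorrelation signatures on planted graphs of 20 size-8 cores
(200 vertices, ~790 edges); recovery on the generator defaults
(~120 vertices); metric identities on 100 random catalogs plus exact
hypergeometric checks up to universe size 60; and the robustness harness on
a 20-complex disjoint-clique catalog with additions up to 100% and 40%
deletions, two replicates per grid point. These sizes keep every experiment
deterministic and reproducible while exercising each formula away from its
trivial regime.

## Known limitations

* **Attachment accretion under noise.** The attachment rule is a *relative*
  threshold: when a core's candidate set consists entirely of spurious
  neighbours (as on a union-of-cliques test graph with random added edges),
  about half of them still clear the average-closeness bar, and the
  $|CS|+|U|$ denominator lowers it further. Geometric accuracy of the full
  predictions therefore degrades under heavy random edge addition even
  though the mined cores remain accurate — decompose with
  `geometric_accuracy()` on cores versus full complexes if this matters for
  your data. The rule is kept exactly as the method defines it.
* **Deletion is partially self-repairing.** Because the virtual network
  adds edges wherever enough short walks survive, moderate random deletion
  (tested at 40%) barely hurts accuracy on clique-structured benchmarks;
  deletion damage shows up later and more gradually than addition damage.
* The cubic truncation means complexes whose members sit at distance > 3
  in the weighted graph can never be joined; this is intentional (short
  walks carry the biological signal) but worth remembering for very sparse
  inputs.
* Identifiers are opaque case-sensitive strings; no ORF/gene-name mapping
  is attempted.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
pn <- planted_network(complex_count = 20, core_size = c(4, 8),
                      background_noise_prob = 0.01,
                      bridge_edge_count = 10, seed = 1)
fit <- detect_complexes(pn$network)
fit
evaluate_complexes(predicted_catalog(fit), pn$truth, t = 0.2)

# the weak-ties percolation signature
sim <- score_all_edges(pn$network, "similarity")
asc <- percolation_experiment(pn$network, sim, "ascending", 0.02)
plot(asc$fraction_removed, asc$susceptibility, type = "l",
     xlab = "fraction of edges removed", ylab = "normalized susceptibility")
```
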