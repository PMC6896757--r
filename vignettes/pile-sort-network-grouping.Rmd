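---
title: "Methods: from independent pile sorts to candidate theme groupings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from independent pile sorts to candidate theme groupings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pilesortr)
```

## The procedure and its assumptions

`pilesortr` operationalises the analysis stage of a participatory theme
elicitation exercise. The observed data are pile sorts: each of S
co-researchers partitions (a subset of) N quotes into self-defined piles.
The method's working assumption is that shared perceptions of similarity
leave a quantitative trace — the more sorters who put two quotes in one
pile, the more similar the panel, collectively, finds them. Nothing else
about the piles is used: pile labels are opaque and scoped per sorter, and
no attempt is made to align pile labels across sorters.

From the sorts we build an undirected co-occurrence network: quotes are
nodes, and a pair placed together by `c_ij >= 1` sorters gets an edge
carrying the count `c_ij` and the weight `w_ij = 1/c_ij`. Counts are the
canonical stored quantity and weights are derived on demand, so
`w_ij * c_ij == 1` holds exactly (no float drift) and the diagram's
count-proportional edge thickness needs no back-conversion. Every edge
with `c_ij >= 1` is kept — no thresholding — and quotes never co-piled
with anything remain as isolated nodes.

## Weight semantics

The inverse-count weighting admits two readings, and the package fixes one
deliberately: modularity and the greedy merging treat the *count* `c_ij`
as the similarity strength `A_ij`, while edge-betweenness shortest paths
use the *inverse* `w_ij` as the edge length. Under this reading a pair
co-piled by many sorters is both a strong within-group tie (for Q) and a
short hop (for betweenness), so the two uses agree about what "close"
means. The alternative — feeding inverse weights into Q as strengths —
would make high-agreement pairs the *weakest* ties and invert the stated
goal of maximising within-group connection; we therefore reject it.

## The two algorithms

Both algorithms pursue modularity

$$Q = \frac{1}{2m}\sum_{ij}\left[A_{ij} - \frac{k_i k_j}{2m}\right]\delta(c_i, c_j),$$

which is 0 for the trivial one-group partition and positive when
within-group strength exceeds the degree-preserving random expectation.

* `girvan_newman()` is the exact divisive algorithm: betweenness is fully
  recomputed after every removal (no incremental approximation); at the
  scale this method is used (tens of quotes) this costs well under a
  second. The component partition and its Q are recorded whenever a
  removal splits a component, from the initial components down to all
  singletons.
* `greedy_modularity()` is the standard agglomerative merge: from
  singletons, repeatedly apply the merge with the largest
  $\Delta Q = 2(E_{ab}/2m - k_a k_b/(2m)^2)$, recording every level until
  one group remains. It can merge disconnected groups late in the history
  (with negative $\Delta Q$); such levels never win the max-Q selection.

Neither algorithm takes a target number of groups: the grouping count
emerges from max-Q selection. The exact pair of "well established"
algorithms used by the method's originators is not documented; divisive
edge betweenness and greedy agglomerative modularity are the canonical
deterministic pair matching the description, and the package's contract —
two independent deterministic algorithms plus a visible agreement report —
does not depend on the originators' exact choice.

Determinism is a design requirement, not an accident: candidate edges
(betweenness ties) and candidate merges ($\Delta Q$ ties, compared at
tolerance 1e-12) are ordered by the lexicographic node-id pair and the
first maximum is taken, so identical inputs give byte-identical outputs.
`best_partition()` breaks Q ties (1e-12) toward fewer groups — coarser
answers are easier for a discussion panel to refine than to merge.

Degenerate inputs: Q is undefined on an edgeless network (m = 0) and both
`modularity_q()` and `greedy_modularity()` refuse it; `girvan_newman()` on
an edgeless network returns the singleton partition as its only level.
Isolated nodes are excluded from greedy merging and attached to every
level as singleton groups; they have zero strength and cannot change Q.

## Reconciliation and manual overrides

`select_final()` takes the best partition of whichever algorithm attains
the higher max-Q — Q being the objective both pursue — and always attaches
the runner-up's best partition plus the cross-algorithm ARI/NMI, so the
user sees disagreement rather than having it silently resolved. Equal Q
with identical partitions is reported as `"consensus"`. Panel overrides
(`reassign()`) are append-only provenance: the algorithmic partition is
kept as the base, every move is logged with a note, and the final
partition is exactly the replay of the log over the base — mirroring how
discussion panels in practice move a few quotes between groups without
re-running the analysis.

## The synthetic generator

Because pile-sort datasets of this kind are generally not deposited, the
package validates itself on simulated studies. `synthetic_spec()` states
the world the simulator emulates, and its defaults are fixed once:

| parameter | default | meaning |
|---|---|---|
| `n_quotes` (N) | 49 | quote-set size of the motivating study |
| `n_themes` (K) | 6 | latent themes; the motivating analysis produced six groups |
| `n_sorters` (S) | 9 | panel size of the motivating study |
| `noise` | 0.1 | per-(sorter, quote) misfiling probability; mild idiosyncrasy |
| `p_merge` | 0.2 | per adjacent theme pair, chance a sorter lumps them |
| `p_split` | 0.2 | per theme, chance a sorter splits it in two |

Quotes are assigned round-robin to themes. Each sorter starts from one
pile per theme, merges adjacent theme pairs with probability `p_merge`
(adjacent = consecutive theme indices; a deliberate simplification that
avoids a random-graph merge model), splits themes with probability
`p_split` (each quote of a split theme goes to one of two sub-piles
uniformly), and then misfiles each quote into a uniformly random *other*
pile with probability `noise`. With the default merge/split rates the
realised pile counts per sorter spread over roughly 3–10, within the 3–12
range reported for real panels; counts of 11–12 require nearly every theme
to split at once and are correspondingly rare. One root seed drives
everything, with per-sorter sub-streams derived deterministically so that
adding a sorter never perturbs the existing ones.

Two honest caveats about what a green simulation test establishes. First,
the generator has no quote-difficulty heterogeneity, no correlated sorter
styles, and no partial sorting — real panels have all three — so recovery
results are a statement about the algorithmic pipeline, not about human
sorters. Second, at `noise = 1` the generator is *not* perfectly
structureless: a misfiled quote avoids its own designated pile, so two
same-theme quotes still land together slightly more often
(probability `1/(K-1)`) than cross-theme quotes (`(K-2)/(K-1)^2`). The
residue is far too weak to recover themes from — the acceptance suite
checks |mean ARI| < 0.1 at `noise = 1` at the default scale — but a
sufficiently powered frequency test could detect it, so "full noise"
should be read as "no recoverable signal", not "exact independence".

## Visual conventions

The diagram uses a Kamada–Kawai layout with the inverse weights as target
edge lengths (computed per connected component, components tiled on a
grid, seeded and deterministic), node colours from the fixed palette light
blue, green, pink, red, yellow, orange assigned to groups in size order
(ties by label) and cycled with a warning past six groups, and edge widths
proportional to `c_ij`, capped at 8 times the base width so dense diagrams
stay legible. The group report orders groups by label and quotes by id,
and carries no timestamps, so regeneration is byte-identical.

## Known limitations

* ARI/NMI compare exactly two partitions; there is no multi-algorithm
  consensus matrix.
* The greedy algorithm is a heuristic: on small random networks it attains
  the exhaustively verified optimum in most but not all cases (the test
  suite asserts never-exceeds, and an empirical exact-match rate of at
  least 80% under a fixed seed).
* No statistical significance is attached to a partition; Q is a relative
  score, not a test.
* The command-line config file is JSON (no YAML parser is assumed).
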