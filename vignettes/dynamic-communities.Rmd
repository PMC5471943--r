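---
title: "Detecting, tracking and drawing dynamic communities in electrode networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting, tracking and drawing dynamic communities in electrode networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyncomm)
```

`dyncomm` analyzes temporal weighted networks over a fixed node set — its
motivating case is functional connectivity between electrocorticography
(ECoG) electrodes — in four stages: per-timestep community detection,
cross-timestep tracking, timeline ordering, and deterministic SVG
rendering. This vignette explains the model behind each stage, the
parameters that matter, the numerical conventions, and what the bundled
synthetic generator does and does not emulate.

## The data model

A `dynamic_network` is an ordered sequence of symmetric, non-negative
adjacency matrices with zero diagonal over one electrode set. When built
from raw multichannel signals (`build_correlation_network()`), the weight
between two electrodes is the **absolute Pearson correlation** of their
signals within a half-open analysis window `[start, start + len)`. The
sign is discarded deliberately: community detection uses connectivity
*strength*, and strongly anti-correlated electrodes are functionally
coupled. Channels constant within a window receive weight 0 against all
partners (with a warning) rather than NaN, so degenerate recordings stay
inside the type's invariants.

Glyph opacity in the electrode views is driven by an `activation_series`:
per electrode and timestep a scalar in [0, 1]. Raw recordings do not come
with a canonical "activation" definition, so `compute_activation()`
offers two conventional magnitude statistics — mean absolute amplitude
(default) or RMS — per window, min–max rescaled over the whole recording.
This is an explicit modeling choice, switchable via the `mode` argument;
any externally computed series in [0, 1] can be supplied instead.

## Per-timestep detection: consensus clustering

Each node is embedded as its connectivity profile — its row of the
timestep's adjacency matrix. The structural zero on the diagonal is
replaced by the node's mean connectivity before clustering: the self-edge
carries no information, and this convention makes truly indistinguishable
nodes (as in a uniform complete graph) bit-identical, which the
degenerate rule below relies on.

For each candidate $K$ in `k_min:k_max` (default 2–8), k-means is run on
`n_runs` (default 50) random subsamples of `subsample_fraction` (default
0.8) of the nodes, and the runs are combined into a consensus matrix
$M_K(i,j)$: the fraction of co-sampling runs in which $i$ and $j$ were
co-clustered. Each k-means run uses `n_starts` (default 3) random
restarts; restarts guard the base clusterer against poor local optima so
that ambiguity in $M_K$ reflects the data rather than the
initialization. Pairs never co-sampled (possible only at very low
`n_runs` × `subsample_fraction`) get consensus 0 with a warning.

### Choosing K from the consensus CDF

Let $F_K$ be the empirical CDF of the off-diagonal entries of $M_K$. The
package computes three summaries per candidate:

* the area under the CDF, $A(K) = \int_0^1 F_K(x)\,dx$ (computed exactly
  from the CDF's breakpoints);
* the classical relative change $\Delta(K) = (A(K) - A(K-1))/A(K-1)$,
  with $\Delta(k_{\min}) = A(k_{\min})$;
* the proportion of ambiguous clustering,
  $\mathrm{PAC}(K) = F_K(u_2) - F_K(u_1)$ with $(u_1, u_2) = (0.1, 0.9)$
  by default — the mass of consensus values that are neither
  "practically never" nor "practically always" co-clustered.

The reported **likelihood** per $K$ is $1 - \mathrm{PAC}$, min–max
rescaled to [0, 1] across the candidate range, and the selected $K$ is
its argmax with ties broken toward smaller $K$. This was a genuinely open
design point: $\Delta(K)$ is the textbook consensus criterion, but
because $\Delta(2) = A(2)$, any data with *some* structure gives $K = 2$
a large score regardless of the true community count — on a clean planted
3-block instance $\Delta(2)$ slightly exceeds $\Delta(3)$, so an
argmax-of-$\Delta$ rule would systematically return 2. PAC measures
exactly the property the K-cluster heatmap is meant to display —
confidence that a candidate $K$ is crisp — and has a sharp, correct
minimum on planted structure, so selection is PAC-based while $A$ and
$\Delta$ remain available in the profile for inspection.

**Degenerate rule.** If for every candidate $K$ all consensus entries are
within `identity_epsilon` (default 1e-6) of 1, no candidate separates
anything: the likelihood profile is identically 0 and the selected $K$ is
1 (a single community). This is the "all-ones consensus" situation that
arises, for example, late in a seizure when one community dominates; the
corresponding heatmap column renders fully white.

Final labels for the selected $K$ cut an average-linkage hierarchical
clustering of the distance $1 - M_K$ — the standard companion to
consensus matrices, preferable to re-running k-means because it consumes
the evidence accumulated across all runs. Labels are canonicalized
(communities numbered 0-based by decreasing size, ties by smallest member
index), and the whole stage is bit-reproducible: timestep $t$ is seeded
with `seed + t`, so per-timestep results are independent of which
timesteps are processed together.

## Tracking

Two matchers connect the partitions of consecutive timesteps:

* **Greedy maximum overlap** repeatedly pairs the source and sink
  clusters sharing the most electrodes until no overlapping pair remains.
  Ties break row-major (smaller source index, then smaller sink index).
  No similarity threshold applies — the greedy rule is defined on raw
  overlap counts, and its known failure mode (a late forced pairing with
  tiny overlap) is precisely what the optimal matcher fixes.
* **Globally optimal Jaccard matching** builds the matrix of Jaccard
  similarities, zeroes entries below $\theta$ (default 0.1 — small enough
  to keep genuine continuations, large enough to make a sub-10 % overlap
  a birth; configurable), and finds the injective partial assignment
  maximizing the total similarity. The search is exact: depth-first
  enumeration over sources with an admissible bound (sum of remaining row
  maxima) for pruning. The `"enumerate"` method guards the smaller side
  at 10 clusters and errors beyond, advising `"solver"`, which is the
  same exact bounded search without the guard. Unequal cluster counts are
  handled as partial injective matchings; zero-similarity pairings are
  left unmatched; exact ties prefer the lexicographically smallest pair
  list, which keeps tracking deterministic.

A matched sink inherits its source's persistent id; unmatched sinks are
births and unmatched sources deaths, with ids allocated in order of first
appearance. Colors come from a qualitative ColorBrewer palette (default
`Set1`), one stable color per persistent id, recycling with a warning
beyond the palette size. Transition links record every source–sink pair
sharing at least one electrode, so link counts are conservative: they sum
to the block size on both sides, and across a timestep pair to the total
electrode count.

## Timeline ordering

The alluvial view needs a vertical order of blocks per timestep that
keeps ribbons short. Exact crossing minimization is NP-hard, so the
package uses barycenter sweeps over consecutive blocks of `block_size`
timesteps (default 10, a short final block allowed), `n_sweeps` (default
4) forward-and-backward passes. The objective is the count-weighted
vertical distance between linked block centers (unit height per
electrode, gapless stacking) — a smooth, testable surrogate for crossing
counts, which are still computed and reported. Each visit proposes the
count-weighted barycenter order of one timestep relative to its already
placed neighbor (ties: larger cluster first, then smaller index) plus,
when the timestep has at most five clusters, every permutation of that
single layer; a candidate is accepted only if it strictly reduces that
timestep's contribution. Acceptance-gated local moves make the global
objective provably non-increasing across sweeps while keeping the whole
procedure deterministic. The initial order is descending community size,
placing large, stable communities at the top.

## Rendering

All renderers are pure functions from their inputs to an SVG 1.1
document: coordinates are written at fixed two-decimal precision, element
order is fixed, and no timestamps or random ids are embedded, so
identical inputs yield byte-identical files. Each document also carries a
"scene" — the computed geometry as plain data — which can be dumped to
JSON for downstream testing.

* **Alluvial view:** one rectangle per block (height ∝ size, fill =
  community color) and one ribbon per transition link, drawn as two cubic
  Bezier curves with control points at the horizontal midpoint between
  axes (the midpoint is a fixed convention chosen for determinism).
  Within a block, link slots are ordered by the opposite endpoint's
  vertical position to avoid spurious twists.
* **K-cluster heatmap:** a timestep × K grid, grayscale fill
  $1 - \text{likelihood}$ (black = certain, white = uninformative).
* **Electrode views:** clock glyphs — one slice per aggregated timestep,
  clockwise from 12 o'clock, slice color = community color, slice
  opacity = activation (zero activation leaves a transparent fill with a
  visible outline). Views alternate above (`x1`) and below (`x2`) the
  central evolution band, left-to-right in time order, at cumulative
  horizontal offsets. Per-view width follows
  $w_i = w_{\min} S_f$, $S_f = C\,W_{\max} / (w_{\min}\max(N_{x_1},
  N_{x_2}))$; the width model is stated for equal spans, and a shorter
  final span receives a proportionally smaller share, reconciling the
  uniform-width formula with width ∝ time points. $S_f < 1$ is a layout
  error that names the largest feasible $w_{\min}$; $C$ is passed through
  with no further constraint. Electrode positions are mapped into each
  view by a uniform-scale affine transform (relative distances
  preserved), optionally restricted to a crop region, over an optional
  raster underlay.

The interactive operations of a GUI tool — brushing, focus+context,
tooltips — are out of scope by design; their batch equivalent is
re-rendering with different `granularity` or timestep-interval choices,
which the `inst/cli/dyncomm` front end exposes.

## The synthetic generator

`generate_synthetic()` emulates a controlled evaluation design: 54
electrodes on a 9 × 6 grid, 30 timesteps, three planted communities
(contiguous runs in grid row-major order, split as evenly as possible)
with activation modes 0.9 / 0.6 / 0.3, stable over [0, 10) and [20, 30)
and i.i.d. uniform labels per electrode per timestep over [10, 20). All
interval conventions are half-open over 0-based timesteps. The published
design specifies labels and activations but not how the correlation
network itself was materialized, so the generator uses the minimal
construction that makes those outcomes reproducible: adjacency 0.9 within
/ 0.05 between communities plus symmetric Gaussian noise (sd 0.02)
truncated at zero. Whether the planted communities were spatially
contiguous is implied but not stated by the design; contiguity is the
default and switchable (`contiguous = FALSE`).

What passing tests on this generator show: that detection selects the
planted $K$, recovers planted labels (ARI ≥ 0.9 on stable timesteps),
and that tracking threads exactly three persistent communities through
each stable interval. What they do not show: performance on real ECoG,
where weights are noisy correlation estimates with spatial
autocorrelation, community sizes are unbalanced, transitions are gradual
rather than switched, and the true $K$ is unknown. The seizure-like
variant (`generate_seizure_like()`) is likewise a demo construction — a
deterministic focal overlay with radius `spread_rate · t` and activation
ramping to 1 — not a biophysical model.

## Numerical conventions and scale

* Symmetry tolerance 1e-6 on input (averaged away); stored matrices
  symmetric to machine precision; round-trips through the text formats
  hold to 1e-12.
* Objective comparisons in matching and ordering use a 1e-12 slack so
  float noise cannot flip a tie-break.
* Seeds: every stochastic stage takes an explicit seed
  (`consensus_params(seed=)`, `synthetic_spec(seed=)`); fixed seed means
  bit-identical labels, profiles, generated data and SVG output.
* The test suite exercises desk-scale sizes chosen to keep a full run in
  a few minutes: module tests use 6–54 nodes and 1–7 timesteps, the
  recovery test the full 54 × 30 design, and the scale test one
  256-electrode × 64-timestep pipeline run — the largest configuration
  the rendering layout is designed around.

## Known limitations

* Temporal coupling is ignored at detection time (no evolutionary
  clustering); smoothness comes only from tracking.
* Communities are hard partitions; overlapping or fuzzy membership is not
  modeled.
* The optimal matcher is one-to-one: splits and merges appear as
  transition links, not as multi-assignments.
* Color assignment is per-run; two different datasets get independent
  color maps, so cross-dataset visual comparison needs external
  harmonization.
* High-gamma band extraction, artifact rejection, re-referencing and
  other clinical signal preprocessing are out of scope; the package
  starts from signals or networks the user has already prepared.
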