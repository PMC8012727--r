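---
title: "Scoring cluster-to-cluster transitions from RNA velocity streams"
author: "velocts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring cluster-to-cluster transitions from RNA velocity streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(velocts)
```

## The problem

RNA velocity assigns every cell a displacement vector in a low-dimensional
embedding (typically UMAP) that points where its transcriptome is heading.
Visualized as a stream of arrows, these fields are evocative but hard to
read quantitatively, especially when several clusters exchange cells in
multiple directions — the setting that motivated this package, the dissection
of human peripheral B-cell memory subsets, where naive, IgM-memory,
class-switched-memory and double-negative populations form a multi-way flow.

`velocts` turns the stream into a single directed K × K matrix, the
**composite transition score (CTS)**. Its unit of information is one
grid-aggregated arrow: the embedding plane is tiled with a regular grid, and
each occupied rectangle contributes one arrow whose displacement is the mean
of its member cells' velocity vectors and whose *starting cluster* is the
majority vote of their labels.

## The model

Write $X_i$ and $Y_i$ for the start and end of arrow $A_i$, and $Z_j$ for
the centroid (arithmetic mean of member-cell positions in the view plane) of
a candidate destination cluster $j$. The alignment of the arrow with the
direction towards $Z_j$ is measured by a cosine obtained from the law of
cosines on the triangle $(X_i, Y_i, Z_j)$, and folded into a per-pair score

$$S_{i,j} \;=\; \bigl(1 - \cos\theta_{i,j}\bigr)\,
  \frac{|X_iY_i|}{|X_iZ_j|},$$

where $\theta_{i,j}$ is the angle at the arrow **endpoint** $Y_i$ (between
$Y_i\!\to\!X_i$ and $Y_i\!\to\!Z_j$). A long arrow (strong velocity) raises
the score; a distant centroid lowers it; $S$ is maximal when the arrow
points straight at the centroid and exactly zero when it points straight
away.

Scores are summed over all arrows per (starting cluster $j_1$, destination
$j_2$) pair, and the totals are rescaled by a weight built from the
centroid-to-centroid distances $z$ towards each destination:

$$w \;=\; 1 - \frac{z - \min(z)}{\max(z) - \min(z)},
\qquad
\mathrm{CTS}_{j_1,j_2} \;=\; w \times \sum_{i \in j_1} S_{i,j_2}.$$

For every destination, its nearest other cluster gets weight 1 and its
farthest weight 0, so flow between neighbouring clusters is emphasized. For
3D embeddings, the pipeline runs on two 2D perspectives — by default axes
(1, 3) and (2, 3), i.e. UMAP1 vs UMAP3 and UMAP2 vs UMAP3 — and the final
CTS is the element-wise sum of the per-view matrices. For plotting, the
matrix is shown in log2 scale to dampen extreme entries.

### The two alignment conventions

The law-of-cosines formulation admits two readings, and `velocts` implements
both behind the `convention` argument:

* `"endpoint"` (default): the angle sits at the arrow tip $Y_i$ and the
  score uses $(1 - \cos\theta)$. This is the only reading under which the
  $(1-\cos\theta)$ factor *increases* as the arrow aligns with the
  destination, which is the behaviour the score is designed to have.
* `"origin"`: the angle sits at the arrow start $X_i$ (so perfect alignment
  means $\cos\theta = 1$); to preserve the same monotonicity the score uses
  $(1 + \cos\theta)$.

Both conventions are maximal at perfect alignment, zero at perfect
anti-alignment, and agree on collinear aligned arrows. One behavioural
difference is worth knowing: under the endpoint convention an arrow that
*overshoots* its centroid (centroid strictly between start and end) scores
near zero, because the angle at the tip looks back at both points. With
grid-aggregated arrows that are short relative to cluster spacing this
regime is rarely entered.

## Design choices

Several details are under-determined by the score's definition alone; the
package fixes them as follows.

* **Self-transitions are excluded** from scoring and from each destination's
  distance set. Including the self-distance 0 would pin $\min(z) = 0$ and no
  real source could ever attain weight 1.
* **Degenerate weighting**: when all candidate distances towards a
  destination are equal — inevitably so for K = 2 — every weight is set to 1
  rather than dividing by zero; a single distance defines no relative
  penalty.
* **Degenerate geometry is skipped, never silently**: a zero-length arrow,
  or an arrow endpoint coinciding with a centroid, makes the triangle angle
  undefined. Such (arrow, destination) pairs contribute nothing and are
  counted in a skip log (`skipLog()`, and `skip_log.tsv` in the CLI output),
  so data loss is always visible.
* **Cosine clamping**: near-collinear triangles can push the law-of-cosines
  ratio past ±1 by ~1e−16; results are clamped to [−1, 1].
* **Log2 of zero** is masked as `NA` rather than pseudo-counted: zero flow is
  qualitatively different from small flow, and any pseudo-count would
  fabricate an ordering among zeros.
* **Vote ties** in a grid rectangle go to the lexicographically smallest
  label — deterministic and independent of cell order.
* **Arrow starts** default to the grid-rectangle centre, matching the regular
  lattice of stream-overlay plots; `gridConfig(startAt = "mean")` uses the
  mean member position instead.
* **Per-view weighting, then summation** across perspectives: min–max-scaled
  centroid distances are only meaningful within one view's plane, so each
  view's raw totals are weighted by its own centroid geometry before the
  matrices are added. Summation keeps the final matrix additive over views.
* **Axis indices are 1-based** throughout (views `c(1, 3)` and `c(2, 3)` for
  3D), matching both R convention and the UMAP1/UMAP3 naming of the
  perspectives.

The similarity properties are worth stating: because $S$ depends only on the
ratio $|X_iY_i| / |X_iZ_j|$ and an angle, and the weights on min–max-scaled
distances, the CTS matrix is invariant under any rigid motion and uniform
rescaling of the embedding — a desirable property, since UMAP coordinates
carry no absolute scale.

## Grid parameters

The grid itself is inherited conceptually from stream-overlay visualization,
which does not prescribe a resolution, so the defaults are package choices
(all in `gridConfig()`):

| parameter | default | meaning |
|---|---|---|
| `nGrid` | 30 | grid rectangles per axis; 30² matches typical stream-plot density |
| `minCells` | 2 | rectangles with fewer cells emit no arrow (suppresses single-cell noise) |
| `marginFrac` | 0.02 | fractional bounding-box expansion before tiling |
| `arrowScale` | 1 | multiplier on the mean displacement |

Arrow counts are bounded by `nGrid`² and never increase with `minCells`.
Because raw totals are sums (not means) over arrows, CTS magnitudes scale
with the number of occupied rectangles; comparisons should therefore be made
within one configuration, which is why every CLI run serializes its
effective configuration into `manifest.json`.

## The synthetic generator, and what passing tests mean

`chainScenario()` builds the validation condition used throughout the test
suite: four Gaussian clusters A → B → C → D arranged as a bent chain with
centre spacing of about 7 embedding units, 200 cells per cluster, positional
spread 1.2 (below 0.2 of the minimum centre distance, i.e. visually
separated clusters), drift speed 1 unit per step and displacement noise with
s.d. 0.1 of the speed. Displacements point at the destination's *centre
parameter*, not its empirical centroid, so the ground truth is independent
of sampling noise. The 3D centres are placed so that both default
perspectives separate all four clusters. `evaluateRecovery()` then asks, for
every non-terminal cluster, whether the largest CTS entry in its row points
at the true successor; ties count as failures.

Under these conditions the pipeline recovers the full chain (mean recovery
≥ 0.95 over 20 seeds, in practice 1.0) in both the 2D single-view and the
3D two-view mode, and recovery degrades monotonically as displacement noise
grows. The generator emulates Gaussian clusters with a clean drift field; it
does not emulate what makes real data hard — curved manifolds, unequal and
anisotropic cluster shapes, velocity-estimation artefacts, doublets, or
clusters that overlap in every 2D perspective. Passing recovery therefore
certifies the geometry, aggregation and weighting machinery, not the
biological correctness of velocity estimates fed into it.

Test and simulation problem sizes (200 cells/cluster, 20 seeds, 30 × 30
grids) were chosen as the smallest at which the recovery statistic is stable
across seeds.

## Quality control and gene pruning

The preprocessing companion implements the B-cell selection rules the
embedding/label inputs are assumed to come from:

1. remove cells expressing *any* transcript of a forbidden non-B lineage
   marker (CD3E, GNLY, CD14, FCER1A, FCGR3A, LYZ, PPBP, CD8A);
2. remove cells with fewer than 200 distinct genes;
3. remove cells whose total transcript count exceeds the top-1% nearest-rank
   quantile of the survivors — such cells tend to be clumps sharing a
   barcode.

Two details deserve note. The marker list as often reprinted contains
*GCGR3A*, which is not a standard human symbol; the intended NK/monocyte
marker is almost certainly *FCGR3A* (CD16), which is the default here, with
`strict = TRUE` reproducing the verbatim symbol. And stage 3 is
population-relative: the nearest-rank threshold (the `ceiling(0.99 n)`-th
order statistic, strict removal) is defined on the current survivor
population, so re-applying it to its own survivors shifts the quantile and
may remove further cells. Stages 1–2 are idempotent; stage 3 is applied
once, after them.

Variable-gene pruning removes clonotype- and isotype-driven symbols from any
ordered gene list: prefix-anchored regular expressions `IG[HKL][VDJ]`
(Ig V/D/J segments), `TR[ABGD][CV]` (TCR segments) and `IGLL`, plus the
explicit constant-region list (IGHM, IGHD, IGHE, IGHA1–2, IGHG1–4, IGKC,
IGLC1–7, AC233755.1). Anchoring matters: unanchored matching would also
delete unrelated symbols that merely contain the substring. Variable-feature
*selection* itself (e.g. vst top-2000) belongs to the upstream toolchain;
this module prunes whatever ordered list it is given.

## Worked example

```{r example}
scenario <- chainScenario(D = 3, seed = 1)
scenario

ds <- simulateDataset(scenario)
cts <- multiviewCTS(embeddingCoords(ds), velocityVectors(ds),
                    cellClusters(ds))
cts

evaluateRecovery(cts, scenario)

round(log2Display(cts), 2)
```

Each row of the matrix reads as "flow out of this cluster": in the chain
scenario, row A is dominated by A → B, row B by B → C, row C by C → D, and
the terminal cluster D shows no strong outgoing score —
`evaluateRecovery()` returns 1.

## Known limitations

* CTS values are relative, not probabilities: they depend on grid
  resolution and arrow counts, and no significance test is attached to
  them.
* A 2D perspective can superimpose clusters that are distinct in 3D; the
  default two-perspective scheme mitigates but does not eliminate this, and
  users should pick views in which clusters separate.
* The endpoint convention's overshoot behaviour (above) makes very large
  `arrowScale` values inadvisable.
* Weights depend only on centroid geometry, so an elongated cluster whose
  centroid sits far from its mass can be under-weighted as a neighbour.
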