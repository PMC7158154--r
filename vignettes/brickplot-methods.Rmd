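---
title: "Brick plots: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brick plots: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brickplot)
```

## The problem

High-dimensional cytometry (mass cytometry / CyTOF, spectral flow) measures
tens of protein markers per cell. Upstream clustering algorithms group cells
into phenotypically similar clusters, and the analyst is then left with the
question this package addresses: *what is each cluster, phenotypically?*
Heatmaps answer it one matrix at a time; a Brick plot answers it one cluster
at a time, as a compact two-dimensional "barcode" in which every marker is a
square brick whose **position** encodes dataset-wide co-expression structure
and whose **area** encodes the marker's relative expression in that cluster.
Because the marker map is computed once per dataset and shared by every
cluster's plot, two plots can be compared brick-by-brick at a glance.

## The procedure

The input is a clusters-by-markers table of median marker expression (or a
per-event matrix from which `median_by_cluster()` computes it).

1. **Arcsinh transform.** Raw ion counts `x` become `asinh(x / c)` with
   cofactor `c` (default 5, the usual CyTOF choice; units: ion counts). The
   transform is log-like for large counts and linear near zero; dividing by
   the cofactor de-emphasizes noise around zero. Tables exported already
   transformed can be declared as such and are not re-transformed.
2. **Marker correlation matrix.** Pearson correlation between the
   across-cluster expression vectors of every marker pair, values in
   [−1, 1]. Computed on transformed, *pre-threshold* values: the zeroing
   rule below is a display-noise rule, not part of the co-expression model.
3. **PCA of the correlation matrix.** Markers are the observations and each
   marker's feature vector is its row of correlations to all markers
   (column-centered, unscaled — rows already share the [−1, 1] scale). The
   marker is plotted at its (PC1, PC2) score, with the percent variance of
   each axis annotated. Under this convention, perfectly co-expressed
   markers have identical rows and literally coincide in the plot.
4. **K-means with elbow validation.** Marker groups are found by
   multi-restart K-means on the 2-D coordinates for up to 30 K values from 1
   to the number of markers; the elbow point picks K (below). Groups only
   color the bricks — they do not move them.
5. **Zeroing threshold.** Any transformed value strictly below the cutoff
   (default 1, on the arcsinh scale) is set to exactly zero and draws no
   brick. The default reflects background signal typically topping out
   around one; it is user-adjustable (`threshold_config()`).
6. **Brick sizing.** `area = s × value` with one scale factor `s` for the
   whole dataset, chosen so the single largest brick in the dataset has side
   `max_area_fraction` (default 0.25) of the layout's coordinate span.
7. **Overlap resolution.** Bricks are placed largest-first; an overlapping
   brick is translated along the ray from the overlapped brick's center
   through its own original position until the two are edge-adjacent.
8. **Rendering.** SVG (canonical) or PNG, equal aspect, bricks colored by
   group, axes annotated "PC1 (p% variance)".

## Parameters that matter

| parameter | default | units | notes |
|---|---|---|---|
| `cofactor` | 5 | ion counts | linear range of the arcsinh transform |
| `zero_cutoff` | 1 | arcsinh units | strictly-below values are zeroed; the boundary value survives |
| `k_min`, `k_max`, `n_k` | 1, n markers, 30 | — | K values tested for the elbow |
| `max_area_fraction` | 0.25 | fraction of layout span | side of the largest brick |
| `scale_mode` | `"global"` | — | `"per_marker"` rescales each marker to its dataset maximum first |
| `seed` | 42 | — | fixes the K-means restarts; the layout is a pure function of (table, K range, seed) |

## Numerical and design choices

**Zeroing boundary and granularity.** "Below the cutoff" is read strictly: a
value exactly equal to the cutoff keeps its brick. Zeroing is cell-wise, so
a marker can be absent in one cluster and present in another — which is
exactly what makes the barcode informative.

**Correlation flavor.** Pearson by default (Spearman behind a flag). A
marker with zero variance across clusters has no defined correlation; it is
kept, assigned 0 off-diagonal with a warning, rather than dropped, so the
table and the layout never disagree about the marker set.

**PCA determinism.** Eigenvectors are sign-ambiguous, so each component's
sign is fixed by requiring its largest-magnitude loading to be positive.
With that rule the layout is reproducible bit-for-bit across runs.

**Elbow estimator.** "Elbow point" is formalized as the tested K maximizing
the discrete second difference `wcss[i−1] − 2·wcss[i] + wcss[i+1]` over
interior indices, ties to the smallest K. When fewer than three K values are
tested there is no curvature to measure and the smallest K is kept (e.g.
all markers at one coordinate → K = 1). K-means runs with 10 seeded restarts
per K, plus a warm start that extends the previous K's centers with the
points farthest from them; since K-means iterations never worsen their own
initialization, the reported WCSS curve is non-increasing in K and the
second difference is well behaved.

**K-means feature space.** Groups are clustered on the plotted 2-D
coordinates (so the coloring matches what the eye sees); clustering on full
centered correlation rows is available via `build_layout(kmeans_on =
"rows")`.

**Brick shape and scaling.** Bricks are squares (`side = sqrt(area)`):
area is the only encoded quantity, and squares keep it legible and the
overlap geometry simple. The area scale is global per dataset so a brick
twice the area means twice the expression anywhere in the figure set;
per-marker scaling (each marker relative to its own dataset maximum) is
available when a dataset's dynamic range across markers hides low-range
markers, at the cost of cross-marker comparability.

**Overlap resolution rules.** Placement order is descending area with ties
broken by marker name; the push direction is the ray from the overlapped
brick's center through the moving brick's original center; exactly
coincident centers fall back to the +x direction. If chained pushes exceed a
bounded iteration count, a fully deterministic outward spiral (golden-angle
steps, fixed radial increment) finds the nearest free spot; exhausting the
spiral budget raises an error recommending a smaller `max_area_fraction`.
Bricks that never collide are never moved, displaced bricks are flagged,
and resolution only ever translates — never rescales — so area semantics
survive layout adjustment. Edge and corner contact count as disjoint, with
a 1e-9 numeric slack.

**Labels.** Each label sits centered under its brick; label-label collisions
are not auto-resolved (out of scope — dense panels may need manual label
placement in a vector editor).

## The synthetic-data generator

`generate_table()` emulates the structure the method assumes: groups
(blocks) of markers that are co-expressed across clusters, different
per-block expression magnitudes spanning the zeroing threshold, and
"negative" markers that sit below threshold everywhere. Per block, a
per-cluster latent signal `L ~ N(0, 1)` is drawn and each member marker gets

    value = base_level + sqrt(rho) * L + sqrt(1 − rho) * noise_sd * eps

with independent `eps ~ N(0, 1)`, clipped at zero. With `noise_sd = 1` the
within-block correlation is exactly `rho` in expectation; the degenerate
`rho = 1, noise_sd = 0` case produces identical (but varying) columns with
correlation exactly 1. The latent signals of different blocks are
orthogonalized across clusters (QR with deterministic signs,
re-standardized), so the between-block correlation of the signal part is
exactly zero rather than sampling noise of order `1/sqrt(n_clusters)` — the
generated fixtures actually exhibit the negligible between-block
co-expression they are defined to have. Negative markers are uniform in
`[0, cutoff/2]`.

Defaults (40 clusters; three 5-marker blocks at arcsinh base levels 2.5,
3.5, 4.5; within-block correlation 0.9; noise 0.1) describe a mid-sized
immunophenotyping panel with clearly separated functional marker modules —
the regime the method targets. What the generator does *not* emulate:
instrument effects (spillover, bead drift, debarcoding artifacts), heavy-
tailed or zero-inflated event distributions, and block structure that is
only partially modular. Passing the recovery tests therefore shows the
layout machinery is sound, not that every real panel has a clean elbow.

`generate_events()` adds symmetric Gaussian per-event noise around the
cluster-level values so the median-aggregation path can be tested end to
end; zero noise reproduces the table exactly.

## Problem sizes used by the test suite

The suite works at desk scale: oracle comparisons on 100 random
10-cluster × 12-marker tables, elbow recovery over 50 seeds of the default
three-block fixture, 200 randomized overlap configurations, and one
end-to-end run at 50 clusters × 40 markers — the order of magnitude of a
large cytometry panel. All checks are property-based (oracle equality,
disjointness, proportionality, determinism) rather than golden-file images.

## Known limitations

- The marker map is PCA-only; no t-SNE/UMAP alternative is offered, by
  design, since the map must be stable, deterministic, and shared across
  clusters.
- Overlap resolution is a local adjacency rule, not a global optimization;
  extremely crowded plots can displace bricks far from their nominal
  positions (the `displaced` flag records this).
- Labels may overlap in dense regions.
- Upstream concerns — compensation, gating, event clustering — are out of
  scope; the package starts from a cluster-by-marker table.
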