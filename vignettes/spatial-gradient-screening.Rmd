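---
title: "Spatial gradient screening: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial gradient screening: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the method answers

Spatial transcriptomic platforms measure expression at known tissue
positions. Many biological programs organize around landmarks — necrosis,
vessels, wounds, tumour margins — as gradients: expression that rises or
falls with distance to the landmark, or peaks in a layer at some
characteristic distance. `sgscreen` screens every measured variable for
such gradients relative to a *reference feature* the analyst supplies:
either a **spatial annotation** (a polygon outlining an area, optionally
with holes) or a **spatial trajectory** (a directed segment with a
screening width). The method is supervised (the analyst encodes the
hypothesis in the reference feature) and cluster-free (no segmentation of
spots is needed).

## The model

### From 2-D space to a 1-D axis

For annotations, each spot's distance is the minimum Euclidean distance to
the annotation outline; spots inside the area (outer ring minus holes) get
distance 0 and are by default excluded from fitting — the gradient
describes the environment, not the reference area itself
(`include_inside = TRUE` retains them as a distance-0 bin). With several
annotations the pointwise minimum distance is screened. We measure
distance to the polygon *edges* (point-to-segment minimum) rather than to
the nearest vertex; vertex-only distance is a biased upper bound when
outlines are sparsely sampled, and is kept as `dist_mode = "vertex"` only
for comparability experiments.

For trajectories with vector $T$ and a spot offset $C$ from the origin,
the scalar projection $s = (C \cdot T)/|T|$ is the distance along the
axis. The screening frame is the closed rectangle
$[0, |T|] \times [-w/2, +w/2]$; spots behind the origin, beyond the end,
or farther than half the width are out of scope. The width defaults to
the trajectory length (a square frame).

### Gradient inference

Let `distance` be the total screened length and `resolution` the bin
width. A LOESS curve (tricube weights, degree 2, no robustness
iterations — the classical defaults) of expression on distance is fitted
over the in-scope spots with span

$$\alpha = \frac{\mathrm{resolution}}{\mathrm{distance} \cdot \mathrm{CF}},$$

where the **correction factor** CF is the fraction of the spots a
geometrically complete screening region would contain that actually
exist. The complete region is the band of width `distance` around the
annotation outline (outside the area), or the trajectory rectangle; the
expected count divides the region area by the area per spot of an ideal
hexagonal packing, $\tfrac{\sqrt3}{2}\,\mathrm{ccd}^2$. Tissue edges and
capture-area limits reduce the observed count, CF drops below 1 and the
span grows — more smoothing when data are incomplete, which is what keeps
the fit stable.

The fitted curve is evaluated at the mean observed distance of each
non-empty bin (empty interior bins are skipped, not interpolated; the
evaluation points are means of observed distances, so no extrapolation
occurs) and the estimates are range-standardized to $[0,1]$. A constant
curve is mapped to all-0.5, which keeps the total variation 0 and the
model fits well defined. Degenerate configurations (fewer than 10
in-scope spots, or fewer than 2 occupied bins) raise a typed
`insufficient coverage` error that batch drivers record as a per-variable
flag instead of aborting.

### The test statistic and its null

The total variation of the standardized gradient,
$\mathrm{TV} = \sum_i |y_{i+1} - y_i|$, is small for smooth (non-random)
gradients and large for wiggly ones. The null distribution is built by
assigning i.i.d. uniform values to the in-scope spots and re-running the
*identical* pipeline (default 10,000 replicates); because the null
depends only on the geometry and configuration, one null serves all
variables of a screening run. Null TVs outside
$[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$ are trimmed
(the multiplier is our choice; the trimming rule is stated only
qualitatively in the method's description, and 1.5 mirrors the
zero-inflation filter). Then

$$p = \frac{\sum_i \mathbb{1}(\mathrm{rTV}_i \le \mathrm{oTV})}{n},$$

with ties counting against significance; an optional add-one pseudocount
is off by default to match the plain ratio. p-values are BH-adjusted
across the variables of one run (not across models) and reported as
`fdr`; the recommended significance gate is `fdr < 0.05`.

### Pattern classification

Significant gradients are compared against a model library of canonical
$[0,1]$ shapes: four descending (linear, early, late, sigmoid), their
four ascending mirror images, and six peaking bumps (centered at
25/50/75% of the distance, sharp $\sigma = 0.06$ and broad
$\sigma = 0.18$ Gaussian variants). The shapes are our own
parameterization — the classes are standard, their exact formulas are
not published — stored as 100-point templates and resampled to the
gradient length by linear interpolation. Fits are scored by MAE and RMSE;
the best model is the lowest-RMSE one, accepted when RMSE < 0.25.

### Zero-inflated variables

With `rm_zero_infl = TRUE` each variable is pre-filtered: values outside
1.5 × IQR beyond the quartiles are removed, and if only zeros remain the
variable is flagged zero-inflated and skipped. This removes variables
whose sparse spikes the LOESS step cannot handle meaningfully.

## Tunable parameters

| parameter | default | units | notes |
|---|---|---|---|
| `distance` | — | µm (or "3mm") | total screened length; drives bin count |
| `resolution` | ccd | µm | bin width; warning above the ccd, best between ccd/2 and ccd |
| `loess_degree` | 2 | — | local polynomial degree |
| `n_sim` | 10,000 | — | null replicates |
| `fdr_threshold` | 0.05 | — | significance gate |
| `rmse_threshold` | 0.25 | — | model acceptance gate |
| `eps` (annotation building) | 1.25 × ccd | µm | density radius for outlier removal |
| `min_pts` | 3 | — | density core size |
| `concavity` | 2 | — | outline smoothness; maps to the hull's neighbour count |
| `fp_niche_radius` | 3 × ccd | µm | focal-noise disc radius |

The span is clamped to $[\,4/n,\,1\,]$ with a logged warning: spans that
leave fewer than ~4 points per local window make the local regression
singular, and an explicit clamp replaces a runtime failure.

## The simulation engine

The simulator emulates a Visium-like sample: a hexagonal lattice with
100 µm center-to-center distance, a reference feature, and per-variable
expression painted in three steps — (1) the distance field is computed
exactly as in screening; (2) spots are binned at the screening
resolution and every member of bin $k$ receives the $k$-th value of a
pattern template (identical values within a bin); (3) noise is injected.
Four mechanisms: **ED** mixes pattern and uniform noise convexly per
spot; **EP** replaces a random subset; **FP** replaces spatially
contiguous niches grown around random seeds; **Combined** splits the
budget equally across the three (the published description says only
that the three are amalgamated; the equal split is our choice and is
configurable). Noise is always drawn uniformly over the observed value
range. Simulated variables are named
`SE.<pattern>.<noise type>.<pct>.<iteration>` and the name parses back to
its fields.

The benchmark grid crosses 6 templates (two descending, two ascending,
two peaking, drawn from the model library — the published study shows its
six patterns only graphically) × 4 noise types × noise levels 0–100% in
2% steps × 50 iterations = 61,200 simulations; the per-configuration
iteration count is recoverable from the total and exposed as a parameter.
`estimate_r2()` re-runs a reduced grid on the user's exact geometry and
regresses TV on the noise percentage per stratum: the resulting $R^2$ is
a reliability measure for that setup (it grows with resolution and
coverage). `sensitivity_experiment()` perturbs the reference feature
(smooth radial jitter, rotation, translation for annotations — deviation
scored as $100(1-\mathrm{IoU})$ between the areas; endpoint, angle and
width changes for trajectories) and reports false positive and false
negative rates against ground-truth variable sets built on the original
feature.

### What the simulations do and do not show

The lattice is geometrically ideal (constant spacing, no tissue holes
unless masked), noise is uniform and spatially unstructured except for
the FP niches, and patterns are exact functions of distance. Passing
tests therefore demonstrate the statistical machinery — calibration of
the permutation null, monotone TV–noise response, recovery of planted
patterns, robustness to feature misplacement — not biological validity on
real tissue, where expression ranges, spatial autocorrelation and
platform artefacts are richer. Two knowingly idealized behaviours worth
remembering: a variable that is *constant* across a screened region
yields a constant gradient, TV = 0 and a minimal p-value (the constant
rule makes "perfectly smooth" indistinguishable from "perfectly flat"),
which is why ground-truth positive sets should carry some noise; and
under nearly complete coverage the standardized gradient of a monotone
pattern keeps TV pinned at its baseline until noise is strong enough to
break monotonicity, which makes the TV-vs-noise response convex rather
than linear at low noise levels and caps the linear $R^2$ of peaking
strata on fully covered lattices below what less complete tissue
geometries show.

## Numerical choices

- Point-in-polygon uses the even-odd rule with NA-separated rings
  (`mgcv::in.out`), which handles holes without special casing.
- Polygon overlap (for the deviation score) and the screening-band area
  (for CF) are measured by deterministic grid rasterisation: membership
  evaluated on a regular grid over the joint bounding box (cell size
  bbox/360 for overlap, ccd/2 for areas). Exact cases — identity,
  disjoint shapes, symmetric rotations — are exact on the shared grid;
  elsewhere the error is of the order of one cell.
- Density-based outlier removal is a direct $O(n^2)$ implementation of
  DBSCAN (radius `eps`, core size `min_pts`); the largest cluster is
  outlined. The concave outline is a k-nearest-neighbour hull that
  escalates k until a simple polygon containing all retained points is
  found, degenerating to the convex hull at worst. `concavity` scales the
  starting neighbourhood (larger → smoother).
- The `"dte"` screening-distance option caps the distance at the farthest
  extent of the point cloud from the outline — an interpretation of a
  tissue-edge cap, flagged as such.
- LOESS on regular lattices sees many tied distances; the resulting
  pseudoinverse warnings are muffled (the fit is well defined), and
  numerically constant predictions are detected with a relative
  tolerance of 1e-8.
- All randomness flows from one user seed through a deterministic
  splitter (`derive_seed`), so per-variable and per-simulation streams
  are reproducible regardless of execution order; derived seeds stay
  below $2^{31}$.
- Problem sizes used by the shipped verification runs: reliability
  estimates use a 7 × 7 mm full lattice (disc annotation radius 400 µm,
  distance 3 mm, resolution 100 µm, 26 noise levels × 10 iterations per
  stratum ≈ 1,560 simulations); misplacement experiments use a 5 × 5 mm
  lattice with 200 pure-noise variables and 1,000 null replicates; null
  calibration uses 500 variables and 1,000 replicates. These sizes are
  the package's own choice of a desk-scale reproduction of the original
  61,200-run study.

## Known limitations

- Distances are 2-D Euclidean in the section plane; no 3-D stacks.
- The permutation null assumes exchangeability of spots within the
  screened region; strong spatial autocorrelation of technical origin
  inflates smoothness and is not modelled.
- The CF geometry ("complete" = the full band/rectangle, not clipped to
  tissue) is an interpretation; with `cf_mode = "off"` the span reduces
  to resolution/distance.
- Model classification is nearest-template, not a formal test; RMSE
  thresholds trade sensitivity against interpretability.
- No spatially-variable-gene pre-filter is included; pass an external
  gene list (`variables =` / `--gene-list`) to restrict the screen.
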