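# sgscreen — spatial gradient screening

`sgscreen` finds genes (or any numeric per-spot feature) whose expression
changes systematically with the distance to a spatial reference feature in
spatial transcriptomic data — for example hypoxia signatures rising toward
a necrotic core, or wound-response programs decaying away from a lesion.
It is supervised and cluster-free: instead of segmenting the tissue, you
declare the biology you care about (an annotated area or a directed
trajectory) and the package screens every variable against it.

The method, for a variable with per-spot values `y` and a reference
feature:

1. **Distance field.** Every spot gets a distance to the feature: the
   minimum Euclidean distance to an annotation's polygon outline (0 inside
   the area), or the scalar projection `s = (C·T)/|T|` onto a trajectory
   with vector `T` (spots outside the trajectory frame are dropped).
2. **Gradient inference.** A LOESS curve of `y` on distance is fitted with
   span `α = resolution / (distance · CF)`, where the correction factor
   `CF ∈ (0, 1]` is the fraction of the spots a geometrically complete
   screening region would contain that actually exist (incomplete tissue
   ⇒ larger α ⇒ more smoothing). The curve is evaluated at the mean
   observed distance of each `resolution`-wide bin and range-standardized
   to [0, 1]; with a 3 mm distance and 100 µm resolution this gives 30
   estimates centered near 0.05 … 2.95 mm.
3. **Non-randomness test.** The total variation
   `TV = Σ |y_{i+1} − y_i|` of the standardized gradient measures
   wiggliness. A permutation null is built by re-running the identical
   pipeline on i.i.d. uniform values (default 10,000 draws, IQR-trimmed),
   and `p = #{rTV ≤ oTV}/n`; p-values are Benjamini–Hochberg adjusted
   (`fdr` column, threshold 0.05).
4. **Pattern classification.** Significant gradients are scored by MAE and
   RMSE against a model library — descending (association), ascending
   (recovery) and peaking (layered) shapes — and labelled by the
   best-fitting model (acceptance RMSE < 0.25).

A full simulation engine (hexagonal Visium-like lattices, per-bin pattern
painting, four noise mechanisms, benchmark grid, reliability estimator,
perturbation experiments) makes every statistic testable without external
data.

## Worked example

```r
library(sgscreen)

# synthetic Visium-like sample: 4x4 mm lattice, 100 um spacing,
# a disc annotation, and three variables with known behaviour
coords <- make_lattice("4mm", "4mm", ccd = 100)
ds0    <- lattice_dataset(coords)
core   <- spatial_annotation("core", cbind(2000 + 300 * cos(seq(0, 2 * pi, length.out = 65)[-65]),
                                           2000 + 300 * sin(seq(0, 2 * pi, length.out = 65)[-65])))
cfg    <- gradient_config(distance = "1500um", resolution = "100um")
field  <- annotation_distance(core, ds0, max_distance = cfg$distance)

tm   <- simulation_templates()
expr <- rbind(
  assoc = apply_noise(simulate_pattern(field, tm$desc_linear, 100), "ED", 20, seed = 1),
  layer = apply_noise(simulate_pattern(field, tm$peak_50_broad, 100), "ED", 20, seed = 2),
  noise = apply_noise(simulate_pattern(field, tm$desc_linear, 100), "ED", 100, seed = 3)
)
colnames(expr) <- coords$id
ds <- sgs_dataset(coords, expr, ccd = 100)

res <- spatial_annotation_screening(ds, core, cfg, n_sim = 1000, seed = 7)
print(as.data.frame(tidy(res)), digits = 3)
#>   variable tot_var p_value   fdr    best_model best_class best_mae best_rmse
#> 1    assoc    1.00   0.000 0.000   desc_linear descending   0.0107    0.0157
#> 2    layer    1.98   0.000 0.000 peak_50_broad    peaking   0.0164    0.0214
#> 3    noise    3.62   0.128 0.128    asc_linear  ascending   0.2917    0.3437
#>   significant zero_inflated insufficient_coverage
#> 1        TRUE         FALSE                 FALSE
#> 2        TRUE         FALSE                 FALSE
#> 3       FALSE         FALSE                 FALSE
```

Reading the columns: `tot_var` is the smoothness statistic (the two
patterned variables sit far below the permutation null; the pure-noise
variable does not), `fdr` is the BH-adjusted permutation p-value, and
`best_model`/`best_class` name the library shape with the lowest RMSE —
the linear association and the mid-distance layer are recovered, each
passing both significance gates (`fdr < 0.05`, RMSE < 0.25), while the
noise variable fails both. `autoplot(res)` shows the observed TVs against
the null distribution and
`autoplot(res$gradients$assoc)` draws a single inferred gradient.

The same screening runs from the shell:

```sh
sgs sas --coords coords.csv --expr expr.tsv --annotations ann.geojson \
    --ids core --distance 1500um --resolution 100um --n-sim 1000 --seed 7 \
    --out results.tsv
```

which writes the results TSV plus a `results.tsv.meta.json` with the full
configuration, seed, package version and input checksums.

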