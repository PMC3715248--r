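# vineseg

Pixel-level discrimination of grapevine canopy elements — **fruit, stems,
leaves, branches and background** — from a registered RGB image plus three
narrow-band images (635, 660, 880 nm), for precision-viticulture tasks such
as yield mapping, leaf-area estimation and targeted spraying.

The classifier is a *sequential masking* cascade built entirely on seeded
K-means (no training data): each stage clusters the band in which the
remaining classes contrast most, claims one cluster as a mask, and removes
those pixels from later stages.

| stage | feature | K | claimed cluster | why |
|---|---|---|---|---|
| 1 background | 635 nm | 2 | brighter centroid | chlorophyll absorbs red: canopy dark, soil/sky bright |
| 2 fruit | (a\*, b\*) | 4 | lowest b\* centroid | grapes are the blue-purple extreme |
| 3 stems | 880 nm | 3 | lowest centroid | woody tissue reflects less NIR than foliage |
| 4 leaves/branches | 660 nm | 3 | middle = leaves, highest = branches | masked fill forms the darkest cluster |

Every stage minimises the K-means objective
*J*<sub>K</sub> = Σ<sub>k</sub> Σ<sub>i∈C_k</sub> ‖x<sub>i</sub> − m<sub>k</sub>‖²
through one deterministic, seedable implementation (`kmeans_fit()`). An
RGB-only baseline (single K-means, K = 5, on a\*b\*) quantifies what the
multispectral cascade buys. Evaluation covers the per-class matching
matrix, hit rate, FP rate, precision, accuracy/error rate, ROC points and
cross-scene aggregation. A seeded synthetic vineyard-scene generator with
ground truth makes the whole system testable without field imagery.

## Worked example

```r
library(vineseg)
library(dplyr)

scenes <- generate_scene_set(6, scene_spec(seed = 0), base_seed = 0)
reports <- bind_rows(lapply(scenes, function(sc) {
  evaluate_labels(classify_scene(sc)$labels, sc$truth, sc$scene_id)
}))
baseline <- bind_rows(lapply(scenes, function(sc) {
  evaluate_labels(classify_scene_rgb_only(sc$rgb), sc$truth, sc$scene_id)
}))
aggregate_scenes(reports, baseline)
```

```
<vineseg_summary> over 6 scene(s)
# A tibble: 5 × 6
  class      mean_tp_rate mean_fp_rate mean_precision baseline_mean_precision
  <chr>             <dbl>        <dbl>          <dbl>                   <dbl>
1 FRUIT              99.9          0             98.5                    15.3
2 STEM               99.2          0.4           89.3                     6.2
3 LEAF               82.2          0            100                      99.9
4 BRANCH             70.3          1.9           63.8                     3.9
5 BACKGROUND        100            3.4           99.2                    99.8
# ℹ 1 more variable: improvement_points <dbl>
mean accuracy: 97.1%
baseline mean accuracy: 37.8% (ratio 2.6)
```

Reading: on the default synthetic six-scene set the cascade recovers
background, fruit and stems almost perfectly, leaves and branches are the
contested pair, and overall accuracy (97.1%) is ~2.6× the RGB-only
baseline (37.8%) — the baseline cannot separate stems, branches and soil
in chromaticity alone. `plot_roc(reports)` plots one (FP rate, TP rate)
point per class per scene; `autoplot()` methods exist for label maps,
matching matrices and signature tables.

The published six-scene field tables ship with the package and aggregate
the same way:

```r
m <- reported_scene_metrics()
aggregate_scenes(filter(m, method == "sequential"),
                 filter(m, method == "rgb_baseline"))
#> mean precisions 89.7 / 57.2 / 87.6 / 5.4 / 89.2 (fruit/stems/leaves/
#> branches/background), mean accuracy 75.8% vs baseline 35.1% (ratio 2.2)
```

## Command line

```sh
inst/cli/vineseg generate --out scenes --n 6 --seed 0
inst/cli/vineseg classify --scene scenes/synthetic-0 --out labels.ppm --audit audit.json
inst/cli/vineseg evaluate --pred labels.ppm --truth scenes/synthetic-0/truth.ppm --out report.json
inst/cli/vineseg report --reports report.json --out summary.csv
```

Scenes are stored as plain-text NetPBM rasters (16-bit ASCII PGM/PPM) with
JSON sidecars; label maps use a fixed palette (fruit magenta, stems orange,
leaves green, branches yellow, background white) plus a JSON legend.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the default six-scene synthetic set from the given seed, runs
the sequential pipeline and the RGB baseline on every scene, evaluates both
against ground truth, aggregates across scenes, re-aggregates the published
per-scene tables, prints both summaries, and writes the result object to
`--out`.

See `vignettes/sequential-masking.Rmd` for the model, the synthetic-world
assumptions, parameter defaults and known limitations.
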