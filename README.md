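# organellaR

Automated morphometry and content profiling of secretory organelles in
multi-channel fluorescence microscopy images.

Endothelial cells store Von Willebrand factor (VWF) in elongated secretory
organelles — Weibel-Palade bodies (WPBs) — whose number, size, shape and
intracellular position vary strongly between cells and conditions, so valid
quantification requires scoring thousands of organelles consistently.
`organellaR` implements the full analysis chain for images stained for
nuclei, a cell-membrane marker (e.g. VE-cadherin), an organelle cargo
(e.g. VWF, or EEA1 for endosomes) and optionally a secondary content marker
(e.g. Rab27A):

1. **Nuclei** — Gaussian smoothing, global thresholding (Otsu over 256
   bins), hole filling, optional watershed declumping on the smoothed
   distance transform, size filtering.
2. **Cells** — seeded propagation from the nuclei over the membrane
   channel: each pixel joins the seed with the cheapest path, a step
   between 8-neighbors costing `sqrt(dI^2 + lambda^2 * s^2)` (`dI` =
   guide-intensity difference, `s` = step length). Boundaries follow
   membrane ridges; ties go to the lower label, so results are
   deterministic.
3. **Membrane** — per-cell boundary band (cell minus erosion).
4. **Organelles** — white top-hat enhancement (disk for puncta, pixel-wise
   maximum of multi-angle linear elements for rods), thresholding, size
   filtering.
5. **Measurements** — per organelle: area (µm²), eccentricity
   `e = sqrt(1 − (b/a)²)` of the moment-equivalent ellipse, length as the
   maximum Feret diameter over convex-hull vertices of pixel centers (µm),
   distance of the centroid to the nucleus and to the cell edge, and the
   relative distance `100·d_nuc/(d_nuc + d_mem)` (0% at the nucleus, 100%
   at the cell edge). Organelles are related to parent cells; results are
   reported per organelle, per cell and per image.
6. **Content** (optional) — organelle labels expanded by 2 px; the
   secondary marker's mean intensity inside vs outside the expanded
   organelles per cell, and the cytoplasm-corrected value
   `corrected = mean_in − mean_out` (A.U.).

A synthetic-field generator (`generate_field()`) renders confluent
monolayers — Voronoi cells, elliptical nuclei, membrane ridges,
anti-aliased capsule-shaped organelles, a content channel — with exact
ground truth, so the whole pipeline is testable without external data.

## Worked example

```r
library(organellaR)

# a synthetic confluent field: 12 cells, 6 organelles each, with a
# Rab27A-like content channel (0.08 A.U. on organelles, 0.05 outside)
field <- generate_field(synth_params(rng_seed = 7))
res   <- run_ocp(list(field))

res$per_image
#> # A tibble: 1 x 8
#>   image_id        cell_count organelle_count_total organelle_count_assigned
#>   <chr>                <int>                 <int>                    <int>
#> 1 synthetic_seed7         12                    75                       75
#> # with organelle_count_unassigned 0, mean_cell_area_um2 54.6,
#> #  mean_organelles_per_cell 6.25, nucleus_count 12

dplyr::select(res$per_cell, cell_label, organelle_count,
              mean_length_um, mean_eccentricity, content_corrected)[1:3, ]
#> # A tibble: 3 x 5
#>   cell_label organelle_count mean_length_um mean_eccentricity content_corrected
#>        <int>           <int>          <dbl>             <dbl>             <dbl>
#> 1          1               6           1.32             0.797            0.0266
#> 2          2               6           1.35             0.770            0.0262
#> 3          3               7           1.17             0.768            0.0264
```

All 12 nuclei and cells are found; the per-cell mean organelle length and
eccentricity recover the generator's distribution (length ~ N(1.38, 0.21)
µm, eccentricity ~ N(0.78, 0.04)); `content_corrected` ≈ 0.026 here —
slightly below the rendered 0.03 contrast because the point-spread blur
dilutes mask edges (see the methods vignette; without blur it reads 0.030).

Real images enter through `read_image()` (multi-channel TIFF, explicit
µm/px calibration or TIFF resolution metadata, optional max z-projection)
or the batch runners:

```r
cfg <- op_config(channels = list(nuclei = 1, membrane = 2, organelle = 3),
                 pixel_size_um = 0.104)
res <- run_op(c("img1.tif", "img2.tif"), cfg, out_dir = "results/")
# -> per_image.csv, per_cell.csv, per_organelle.csv, QC overlay PNGs,
#    resolved_config.yaml
```

Two labeled batches compare with `compare_groups()` (Mann-Whitney U or
Welch's t on per-cell values; `tidy()`, `glance()` and `autoplot()`
methods). A thin CLI (`inst/scripts/orgprof`) exposes `run-op`, `run-ocp`,
`synth` and `report` subcommands.

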