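---
title: "Organelle profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organelle profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organellaR)
```

# The measurement problem

Endothelial cells store Von Willebrand factor in elongated ("cigar-shaped")
secretory organelles, Weibel-Palade bodies (WPBs), whose number, length,
shape and intracellular position vary strongly between cells and conditions.
Valid quantification therefore needs thousands of organelles scored
consistently — an automated pipeline, not manual outlines. `organellaR`
implements that pipeline for multi-channel fluorescence images: a nuclear
stain, a cell-membrane stain (e.g. VE-cadherin), an organelle cargo stain
(e.g. VWF or EEA1), and optionally a second marker whose enrichment in or on
the organelle is to be quantified (e.g. Rab27A, with PDI as a negative
control).

The segmentation hierarchy is the classic primary/secondary/tertiary design:

1. **Nuclei (primary).** The nuclear channel is Gaussian-smoothed, rescaled
   and thresholded (Otsu over 256 bins by default); holes are filled;
   touching nuclei can be split by a watershed on the smoothed Euclidean
   distance transform; components outside a diameter range are discarded.
2. **Cells (secondary, seeded propagation).** Every foreground pixel joins
   the nucleus seed with the cheapest path, where a step between
   8-neighbors $p \to q$ costs
   $\sqrt{\Delta I(p,q)^2 + \lambda^2 s^2}$,
   with $\Delta I$ the absolute difference of the smoothed membrane-channel
   intensity and $s$ the Euclidean step length (1 or $\sqrt 2$). Small
   $\lambda$ makes boundaries hug membrane ridges (crossing a ridge costs
   climbing it); large $\lambda$ tends to a Voronoi partition of the seeds.
   The default $\lambda = 0.05$ keeps both terms of comparable scale for
   ridge heights of order 1 on normalized channels. Realized as multi-source
   Dijkstra in compiled code; ties in accumulated cost go to the lower seed
   label, so results are deterministic and match an exhaustive relaxation
   fixpoint exactly (the test suite checks pixel-for-pixel agreement against
   an independent Bellman–Ford oracle).
3. **Membrane (tertiary).** Per cell, the band of cell pixels within
   `width_px` of the cell's boundary (cell minus erosion).
4. **Organelles (primary on the enhanced cargo channel).** The cargo channel
   is rescaled to $[0,1]$, then enhanced with two white top-hats — a disk of
   radius 5 px for compact puncta, and the pixel-wise maximum over linear
   elements (length 11 px, every 15°) for rods — combined by pixel-wise
   maximum so round and elongated organelles survive a single threshold.
   White top-hats subtract the grayscale opening, so output never exceeds
   the input and broad background is removed; this separates organelles
   lying close together before thresholding.

# Measurements

Per organelle: area (pixel count $\times$ pixel size$^2$), **eccentricity**
$e=\sqrt{1-(b/a)^2}$ of the second-moment-equivalent ellipse, and length as
the **maximum Feret diameter** — the largest pairwise distance between
convex-hull vertices of the object's pixel centers. Conventions we fix
because they differ by $\pm 1$ px between tools: pixel centers sit at
integer coordinates, so a $1\times N$ segment has Feret $(N-1)$ px; moments
treat each pixel as a unit square (adding $1/12$ per axis), so a 1-px-wide
line has $e<1$. The synthetic ground truth uses the same conventions.

Position is summarized by the distance of the organelle **centroid** to the
nearest pixel of its cell's nucleus ($d_{nuc}$, zero inside the nucleus) and
to the nearest pixel of the cell's outer boundary ($d_{mem}$), both per cell
in isolation so neighboring nuclei never interfere, and the **relative
distance** $100\, d_{nuc}/(d_{nuc}+d_{mem})$ (0% at the nucleus, 100% at the
cell edge; undefined when both are zero). We use the centroid rather than
the organelle edge so that rod length does not contaminate position; this is
a deliberate reading of "distance of the object" and is flagged for
sensitivity analysis.

Organelles are assigned to the cell under their centroid pixel, falling back
to maximal pixel overlap (ties to the lower label); unassigned organelles
are counted in the QC log, never silently dropped. Reporting is two-level —
per-cell means (the default statistical unit for group comparisons) and the
pooled per-organelle table — because group effects are usually tested on
per-cell values while single-organelle distributions are informative on
their own.

# Content quantification

For a secondary marker, organelle labels are expanded by 2 px (Euclidean,
ties to the lower label) to capture membrane-bound signal hugging the
organelle surface; each cell is split into *inside* (expanded organelles
∩ cell) and *outside* (the rest of the cell), and the marker's mean
intensity is measured over both, with the cytoplasm-corrected value
`corrected = mean_in − mean_out` (never clipped; a marker with no organelle
association reads ≈ 0). Intensities stay in dtype-normalized arbitrary
units; full-range rescaling is used only for QC display, since it would
destroy the A.U. scale the correction is defined on. Three outside-mask
variants exist: whole-cell (default), whole-cell minus nucleus
(`exclude_nucleus`), and a local ring of configurable width around the
organelles, which tracks local background gradients; a `signal_objects`
mode re-thresholds the masked channel before averaging, which makes the
captured signal insensitive to the exact expansion width at the cost of an
extra threshold.

# The synthetic-field generator

No real images ship with the package, so every stage is validated on
generated fields with exact ground truth: a Poisson-disk-seeded Voronoi
tessellation of cells (confluent monolayer), one elliptical nucleus per
cell, a membrane ridge along cell borders, anti-aliased capsule
(rectangle + semicircular caps) organelles, and an optional content channel
at level $\mu_{out}$ inside cells and $\mu_{in}$ on the organelles plus a
2-px halo. All channels are blurred with a Gaussian PSF and corrupted with
additive Gaussian noise (clipped at 0); truth is recorded before blur and
noise, and a seed fully determines the field.

Default conditions (chosen once, as a realistic miniature of a confocal
field at organelle scale): 0.1 µm/px (63× confocal sampling), 256×256 px
with 12 cells, nucleus semi-axes 1.6×1.1 µm, 6 organelles per cell, length
∼ Normal(1.38, 0.21) µm truncated above 0.3 µm, eccentricity
∼ Normal(0.78, 0.04), content levels 0.08/0.05 A.U., PSF σ = 1 px, noise
σ = 0.01. The cells are smaller than real endothelial cells relative to
their nuclei — the geometry is faithful at organelle scale, not cell scale.

Choices worth recording:

* **Per-organelle eccentricity sampling.** Lengths and eccentricities are
  both reported as population distributions in practice, and a single fixed
  capsule width makes the realized mean eccentricity drift far from any
  stated target (short capsules are rounder). Each organelle therefore draws
  its own eccentricity and derives its width from the closed-form capsule
  moments (`capsule_eccentricity()` has an analytic inverse via
  root-finding). A fixed `width_um` remains available.
* **Placement.** Organelles are placed at a uniform radial fraction along a
  ray from the nucleus *edge* to the cell border (0 = at the nucleus, 1 = at
  the border) in a random direction, rejecting placements that leave the
  cell, overlap another organelle (1.5-px clearance, so clean renders can
  never 8-connect two organelles and truth counts stay unambiguous), or
  overlap the nucleus (these organelles are cytoplasmic). Anchoring the ray
  at the nucleus edge rather than the cell center matters: the pipeline's
  relative distance is measured from the nucleus edge, and a center-anchored
  fraction correlates with it only weakly (Spearman ρ ≈ 0.85–0.92 even with
  perfect measurement, vs ≈ 0.91–0.98 edge-anchored). The two quantities are
  still different metrics and exact equality is never asserted.
* **Noise model.** Additive Gaussian only; at these intensity scales Poisson
  shot noise adds little and would complicate exactness of the truth.
* **A "crowded" mode** drops the clearance so under-segmentation behavior
  can be studied deliberately.

# Calibration of pipeline defaults

The segmentation defaults cannot be copied from any published settings (the
original tool's parameter files are not part of this implementation), so
they were validated on synthetic fixtures, as one would tune any such
pipeline on pilot images: nuclei smoothing σ = 2 px, diameter range
10–80 px with shape declumping (watershed `tolerance = 1`,
`ext = max(1, ⌊d_min/2⌋)` — calibrated so two diameter-20 disks overlapping
by 4 px split while a single ellipse stays whole); organelle enhancement as
above with threshold correction **1.2** — at 1.0 blur-bridged organelle
pairs stay merged (per-cell length errors up to ~11%), at 1.4 rods start to
fragment; 1.2 keeps counts near truth with ≤ 5% length error. These are
analysis parameters exposed in `op_config()`, and any real dataset will need
its own fine-tuning of smoothing, thresholds and enhancement sizes.

# Numerical and degenerate-case decisions

* Reflective borders for all filters; Gaussian kernels truncated at 3σ and
  renormalized (an impulse keeps mass to 1e-6).
* Constant images rescale to all zeros; zero nuclei means zero cells and a
  valid empty result; empty masks yield missing means; zero-organelle cells
  keep `NA` means and count 0.
* All tie-breaks (propagation equidistance, expansion nearest-label,
  parent-assignment overlap) go to the lower label: determinism over
  elegance. Re-running a batch reproduces byte-identical CSVs.
* Labels are renumbered 1..N in raster order of each object's first pixel,
  so numbering is stable across runs and platforms.
* Nuclei touching the image border are kept by default (discarding them
  biases per-image counts in tile scans); configurable.
* Iterated label expansion `expand(expand(L, a), b)` equals `expand(L, a+b)`
  in support only for small radii on the integer lattice (a counterexample
  exists already at a = 2, b = 1); the tests assert the unit-step case only.

# What passing tests do and do not show

The generator emulates geometry, PSF blur and additive noise — not uneven
illumination, bleed-through, out-of-focus organelles, clustered/overlapping
organelles (unless `crowded`), or irregular (non-convex) cell shapes. Green
tests therefore certify the measurement machinery and its conventions, not
performance on any particular microscope's data.

Known limitations, measured on the synthetic fields:

* With a realistic PSF (σ = 1 px) the mask-mean content estimator is biased
  low by edge dilution — of order σ·P/A relative to the true contrast
  (~13% under the default geometry). Content-recovery checks are therefore
  run under the additive-noise-only corruption model; on blurred fields the
  `local_ring`/`signal_objects` variants or a deconvolution step upstream
  are the remedies.
* Binary-moment eccentricity of small, nearly round objects is biased high
  (the larger moment eigenvalue is a positively biased statistic); on
  noiseless renders of ~10-px capsules the population bias is ≈ +0.05 near
  e = 0.5 and ≤ 3% at e ≥ 0.63.
* Per-cell mean length is inflated by any residual organelle merging; with
  the default clearance and threshold correction the recovered group means
  stay within 10% of truth in the regimes the tests exercise.

Problem sizes used by the test-suite and the acceptance script (package
choices, balancing statistical resolution against desk-scale runs): single
fields of 256×256 px / 12 cells; two-group experiments of 5 images per
group; shift-detection on 10 replicate pairs of 224×224 px / 8 cells;
propagation oracle trials on ≤ 30×30 grids with ≤ 4 seeds.
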