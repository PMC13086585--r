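---
title: "fascreenkit: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fascreenkit: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fascreenkit)
```

# What this package computes

`fascreenkit` re-implements, as one tested toolkit, the quantitative
image-analysis and screening-statistics procedures used to study focal
adhesions (FAs) in high-content microscopy:

1. **Per-field FA quantification** (`quantify_field()`): segment paxillin
   puncta, count nuclei, apply field-level quality control, and report
   FAs per cell.
2. **Screen statistics** (`zprime()`, `plate_zscores()`, `call_hits()`,
   `secondary_confirm()`, `screen_report()`): plate QC and hit calling
   for an arrayed siRNA screen.
3. **Morphometry** (`spreading_area()`, `protrusive_area()`): cell
   spreading from F-actin masks, and the flat/elevated decomposition of
   the cell footprint via marker-controlled watershed.
4. **FA dynamics** (`correct_drift()`, `autocrop()`, `track_fas()`,
   `fit_rates()`, `count_novel_fas()`): time-lapse tracking and
   assembly/disassembly kinetics.
5. **Synthetic data** (`make_field()`, `make_plate()`, `make_movie()`,
   `simulate_plate_values()`): generators that plant objects, effects
   and event schedules with exactly known ground truth, so that every
   stage above is testable without any external image.

Because the R stack this package targets ships no image-processing
package, the pixel-level primitives (median and Gaussian filters,
rolling-ball background, Otsu/Triangle/Huang thresholds, connected
components, prominence maxima, marker-controlled watershed) are part of
the package (C++ under `src/`). During development the thresholding
functions were cross-checked against scikit-image's implementations on
shared fixtures; the Triangle threshold matches to the histogram bin in
both tail orientations.

# The FA quantification model

The FA channel is processed with a **median filter of radius 2** (the
ImageJ 13-pixel disc, offsets with $dx^2+dy^2 \le r^2+1$) followed by
**rolling-ball background subtraction of radius 1 with the sliding
paraboloid**. The background is the grey-scale opening of the intensity
surface with the structuring function — for the paraboloid,
$z(d) = d^2/(2r)$. The 2-D paraboloid separates into two 1-D parabolas,
so the exact opening is computed in $O(n)$ per scan line with the
lower-envelope algorithm; tests verify bit-equality against a
brute-force oracle that explicitly pushes the element up against the
surface at every placement. Note this is the *exact* 2-D paraboloid
opening, not ImageJ's four-direction (rows/columns/diagonals)
approximation.

Segmentation is a global **Otsu threshold** (256-bin histogram over the
min–max range), 8-connected components, and an **inclusive size window**:

* `screen` mode: 50–5,000 px², no circularity filter;
* `percell` mode: 50–500 px², circularity $4\pi A/P^2 \in [0, 0.95]$,
  with the perimeter from Moore boundary tracing (orthogonal steps 1,
  diagonal steps $\sqrt 2$) and values above 1 from discretisation
  clipped to 1 before filtering.

**Nuclei** are maxima of the channel smoothed with a Gaussian of sigma
20 px (filter "radius" is interpreted as sigma throughout — the Fiji
convention), accepted when their topographic **prominence** is at least
100 (the screen's "noise level" and the macro's "prominence" are the
same criterion here). Prominence is computed by a union-find sweep over
pixels in decreasing intensity (persistence); it is offset-free, so
nuclei counts are invariant under adding a constant to the channel.
With edge exclusion on (`percell` mode), a maximum is rejected when the
connected region at level `peak − 100` containing it touches the image
border.

Field-level QC mirrors the screening rules: fields are excluded when
the raw (pre-filter) structure count exceeds 20,000, when three or fewer
— strictly, "two nuclei or fewer" — nuclei are found, or when the
**local focus score** of the nucleus channel falls below 0.03. The
focus score here is the mean over non-overlapping windows (default
64 px) of the per-window normalised variance
$\mathrm{var}/\mathrm{mean}^2$: zero for constant images and
monotonically degraded by defocus blur. The exact formula of the
original CellProfiler metric is not public in the source method; this is
a documented, monotone proxy that keeps the 0.03 threshold.

# Screen statistics

* $Z' = 1 - 3(\sigma_p + \sigma_n)/|\mu_p - \mu_n|$ with sample (n−1)
  SDs, computed per plate from the positive-control and mock wells'
  FAs-per-cell. Plates below 0.5 are flagged, never dropped.
* Plate-wise Z-scores $(x - \mu_{ref})/\sigma_{ref}$. The reference
  population defaults to **all sample wells of the plate** (robust when
  controls are sparse) and can be switched to the mock wells; the
  choice is recorded in the output attributes because the source method
  does not state which was used.
* Hits: `z_count > 4.2` **or** `z_area > 3.5`, strict inequalities,
  with wells under 50 cells excluded as low-viability (a manual
  staining-artifact exclusion is supported as a pass-through flag).
* Secondary confirmation: per replicate, sample readouts are divided by
  the mock mean; the two replicate folds are averaged, and a mean
  increase of 30% **or higher** (inclusive) in either parameter
  confirms.

Well aggregation: FAs-per-cell is the mean over non-excluded fields,
FA area the mean of per-FA areas pooled over the well's fields, and the
viability count the total nuclei over non-excluded fields.

# Morphometry

**Spreading**: F-actin blurred at sigma 4, **Triangle** threshold,
objects under 500 px² excluded, retained area divided by the nuclei
count. The Triangle threshold sits near the toe of the background peak,
so the mask carries a boundary skirt of roughly
$\sigma \cdot \Phi^{-1}$-scale width (≈ 8 px at sigma 4 on a noiseless
flat-top cell). This is a property of the stated algorithm, not of this
implementation — scikit-image's Triangle lands on the same bin. It
means absolute 5%-accurate area recovery is only attainable for cells
whose radius exceeds ~300 px; the acceptance test therefore measures a
large (430-px radius) planted cell, while small-cell tests assert mask
containment. Relative comparisons between conditions, the screen's
actual use, are unaffected.

**Protrusive area**: the plasma-membrane channel (blur sigma 1, Huang
threshold, holes filled) defines each cell's total footprint; cells are
separated by **Meyer's marker-controlled watershed** flooding the
inverted, unprocessed cytoplasm channel, seeded at prominence-100 maxima
of the cytoplasm blurred at sigma 25, restricted to the membrane mask,
8-connected, ties resolved first-come (deterministic). "Huang2" is
implemented as Huang's fuzzy-entropy threshold; the Fiji dialect
difference is a bin-convention nuance and the method is pluggable
(any method name, or a manual numeric threshold). The elevated mask
(cytoplasm blur sigma 1 + Huang) is clipped to each cell before
subtraction, so `total = elevated + protrusive` holds exactly and
protrusive area is never negative. Elevated pixels outside every
watershed cell are ignored.

# FA dynamics

* **Drift**: consecutive frames are masked to pixels ≥ 120 grey values
  and registered by integer-pixel FFT cross-correlation; each step is
  clamped to ±20 px, steps accumulate into the drift path, and frames
  are translated back to the first frame's reference. The original
  workflow removes the resulting black padding by manual cropping; here
  `correct_drift()` also returns the always-valid region and the
  pipeline crops to it (`crop_movie()`) before anything else.
* **Auto-crop**: maximum projection, blur sigma 15, Triangle threshold,
  fill holes, keep the largest component, crop to its bounding box.
* **Segmentation for tracking**: "segmentation threshold 2" is read as
  2 background SDs above the background level of a high-pass-filtered
  frame. The high-pass is a difference of Gaussians (default sigmas 0
  and 8: the frame minus its large-scale blur, whose response on a
  noiseless image is strictly positive exactly on object footprints —
  which is what lets a planted 8-px speck fall under the 10-px size
  floor, and keeps noiseless segmented areas equal to planted areas);
  background level and SD are the median and MAD of the filtered frame,
  robust against the sparse bright foreground. Components under 10 px
  are dropped.
* **Linking**: maximal pixel overlap between consecutive frames, no gap
  closing. Merges keep the larger predecessor (the smaller track ends
  `into_merge`); with FA splitting off, the parent stays on the largest
  fragment and other fragments start new tracks flagged `from_split`.
  Ties break to the lower label, deterministically.
* **Rates**: peak frame = argmax of mean intensity; assembly is the
  least-squares slope of log mean intensity vs time (min) from start to
  peak, disassembly from peak to end, both reported as magnitudes
  (1/min) and suppressed for phases shorter than 5 frames. Object mean
  intensity is measured on the raw frame minus the frame median (a
  constant camera offset cannot bend the log slope), and for kinetics
  it is re-measured over a fixed per-track reference region — the
  track's largest segmented footprint. A threshold-selected region
  shrinks when the object dims, and a mean taken over a
  intensity-dependent region is biased toward flat slopes; a fixed
  region makes the measured mean exactly proportional to the scheduled
  intensity on planted objects. With that choice the planted-rate
  recovery error at SNR 10 (peak over noise SD, with the camera offset
  at 4 noise SDs so the sensor clip cannot rectify the noise) is 0.1–4%
  across seeds; with per-frame regions it is 5–40%.
* **Novel FAs**: tracks with origin `birth` only — first-frame tracks
  and split products are filtered out, and merge products never start
  new tracks under this linker. Reported as a per-movie total and as
  mean starts per frame.

# The synthetic world

`make_field()` plants Gaussian nuclear blobs (sigma 8 px, peak 5,000
over a 200-count background — a bright DAPI-like stain) and, per cell,
elliptical FA puncta (default 10 per cell; areas from a truncated
normal on [100, 400] px², axis ratios 1.2–2.5, plateau 3,000) in a
peripheral ring 25–80 px from the nucleus centre. Footprints are kept
pairwise disjoint with a 3-px gap (so 8-connected segmentation cannot
fuse neighbours) and 3 px off the border; the integer pixel area of
every planted object is recorded at generation time and never
re-measured from pixels. The FA-area interval [100, 400] lies well
inside the screen size window so that planted objects still pass the
50-px floor after the median filter erodes their boundary; the interval
is a stated-world constant, chosen once from that geometric argument.
Placement prefers the peripheral ring, widens it when crowded, and only
errors ("field too crowded") when the field is truly full. Defaults
render a 256×256 field — a scaled-down stand-in for a full camera frame,
sized so that fifty fields generate and quantify in well under a minute
on one CPU.

Noise is additive Gaussian (optionally Poisson shot noise), and defocus
is simulated by blurring the whole field; a sigma-40 blur drives the
focus score below the 0.03 exclusion threshold. What the generator does
**not** emulate: optics-accurate point-spread functions, intensity
vignetting, uneven illumination, cell-to-cell morphology variation, or
textured cytoplasm. A green recovery test therefore establishes the
correctness of the operators on their stated model, not performance on
real micrographs.

`make_plate()` renders image-backed wells with per-gene multiplicative
effects on FA count and area (controls: mock and negative at 1×, the
positive control at 2× count — the source layout states only that a
boost exists; 3× overcrowds the 256-px field —, death controls at ~2
nuclei per well, far under the 50-cell viability floor).
`simulate_plate_values()` is the value-level counterpart for
statistics-scale experiments: well readouts are Gaussian with a 10%
coefficient of variation around FAs-per-cell 20 and FA area 250 px²,
cell counts Poisson(300), and planted effects are shifts in units of the
well-to-well SD. One hundred replicate screens of 2×352 wells simulate
in under a second, which is what makes the null false-positive
criterion testable at all.

`make_movie()` renders scheduled adhesions whose noiseless mean
intensity follows `peak · exp(rate · (t − t_peak))` exactly within each
phase, plus planted rigid drift, merges (two objects bridge into one)
and splits (a bridge disappears). Ground truth carries the full event
schedule and drift path.

# Design choices where the method left room

* **Two-replicate screens.** The planted-hit acceptance scenario runs
  the same 300 genes on two replicate plates and calls hits on the
  replicate-mean Z-score (the same two replicates the secondary
  confirmation consumes). With 600 *independent* genes, the Gaussian
  tail of the `z_area > 3.5` rule alone would leave a null screen
  hit-free only ~87% of the time ($(1-2.3\times10^{-4})^{600}$), so a
  zero-false-positive expectation is only coherent for replicated
  designs — which is how the original secondary screen was run.
* **Inclusive size bounds** ("50 to 500" keeps 50 and 500) — pinned by
  boundary tests at 49/50/500/5,000/5,001 px.
* **8-connectivity** for foreground components (Analyze Particles
  default); 4-connectivity for background when filling holes.
* **Otsu on 256 bins** of the min–max-rescaled channel; degenerate
  single-value histograms segment to zero objects with a warning.
* **Oversegmentation fixture**: more than 20,000 8-connected objects
  cannot survive a radius-2 median filter in fields of the sizes used
  here, so the QC test plants a 2-px-pitch dot lattice (22,201 raw
  structures) and sets `median_radius = 0` (the ImageJ radius-0 no-op);
  the 20,000 cap itself is the stated default.
* **Seeding**: every generator is a pure function of (spec, seed); the
  global RNG state is saved and restored around each call. Plate wells
  derive child seeds deterministically from the plate seed.

# Known limitations

* The rolling-ball "ball" shape (non-paraboloid) is brute-force and
  intended for small radii only; the paraboloid path is exact and fast.
* The watershed resolves plateau ties by flooding order (first-come);
  label boundaries on exact-tie pixels may differ from other
  implementations — the test oracle exempts tied pixels.
* Tracking has no gap closing and no subpixel drift; both are faithful
  to the stated configuration, not general-purpose defaults.
* The TIFF reader covers uncompressed grayscale baseline TIFF (8/16-bit,
  II/MM, any strip layout) — sufficient for the package's own files and
  plain microscopy exports, not a general TIFF library.
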