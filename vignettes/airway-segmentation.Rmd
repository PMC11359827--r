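---
title: "Quasi-spherical region-constrained wavefront segmentation of the airway tree"
author: "airwayseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-spherical region-constrained wavefront segmentation of the airway tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airwayseg)
```

## The problem

Segmenting the bronchial tree from chest CT is a trade-off between
completeness and leakage. The airway lumen is air (≈ −1000 HU) enclosed by a
thin, brighter wall; the surrounding lung parenchyma is also air-rich
(≈ −900 to −800 HU). Small airways suffer from partial volume effects and
noise, which depress the apparent wall intensity. Wherever a stretch of wall
falls below the acceptance threshold — a *wall gap* — region growing escapes
into the parenchyma and can flood a large part of the lung. A useful
reference is the histogram rule that voxels below −950 HU are certainly
airway, voxels above −775 HU certainly are not, and the band in between is
where all the trouble lives.

`airwayseg` implements a segmentation strategy with three cooperating
mechanisms:

1. **Wavefront propagation.** Segmentation grows one morphological-dilation
   layer per iteration from a seed point set, with a CT-value judgment on
   each candidate layer. No growth directions are ever computed: branching
   topology is handled for free by the omnidirectional front.
2. **Quasi-spherical region constraint.** Each stage of growth is confined
   to the dilation of its seed surface by a Euclidean ball whose radius is
   set from the airway's local width. Leaks are detected *inside* the
   region (they cannot spread beyond it), the threshold decays until the
   leak stops, and the region boundary supplies the seed surfaces for the
   next stage.
3. **Wall gap sealing.** When a region leaks, the gap the leak crossed is
   localized by morphological closing differences and sealed by raising the
   CT value there; segmentation is retried with the threshold stepped up,
   until either no gap remains or the threshold has risen 200 HU above its
   starting point — the typical wall/lumen contrast at small airways, beyond
   which further sealing is pointless.

## The model, stage by stage

### Region initialization

A *seed surface* is a 26-connected set of voxels where the previous stage's
segmentation met its region boundary (the very first surface is the single
user-provided trachea voxel). Because that surface approximates the airway
cross-section, its voxel count stands in for the cross-sectional area and
sets the region radius

$$R = 3\,\lceil \text{area}/100 \rceil + 5,$$

floored at 8 voxels. The acceptance window derives from the surface CT
values: `Seed` is their minimum and `Threshold` their range plus one, so the
initial window exactly covers the surface. The working image is cropped to
the surface bounding box expanded by `R` (clamped to the volume), the
constraint region is `dilate(P0, Sphere(R))` for the seed-surface matrix
`P0`, its boundary shell is that region minus `dilate(P0, Sphere(R-1))`, and
the restricted image equals the cropped CT inside the region and −2048 HU
(the CT floor) outside it.

### Propagation and leak control

Each iteration considers the one-layer dilation of the current result by
`Sphere(1)` (the 6-neighbourhood) and **rejects** a candidate when its
restricted CT value minus `Seed` reaches `Threshold`. The window has no
lower bound — darker than the seed surface means *more* confidently airway —
so out-of-region voxels, blanked to −2048, must be and are excluded by
region membership rather than by the window. Growth ends when a layer adds
nothing.

Two leak rules bound each attempt. The iteration count may not exceed
`2R + 4` (a front advancing one face-step per iteration crosses the region
in at most `2R` steps; the slack absorbs seed-surface thickness), and a
single layer may not accept more than `growth_factor` (default 2.5) times
the seed-surface area — airway width decreases gradually, so a front that
outgrows its cross-section is leaking. When a rule fires the result resets
to the seed surface, the threshold decays by 1, and the attempt repeats; at
threshold 0 the region is abandoned. The state of the *first* leaking
attempt is kept: it is the leaky segmentation that gap localization needs.
Both rules are waived for the single-voxel bootstrap region, whose seed
area carries no width information (a 2.5-voxel-per-layer budget would
forbid any growth at all); its window width is likewise not derivable from
one voxel and comes from `initial_threshold_override` (default 100 HU).

After a successful attempt, interior holes (noise voxels above the window,
enclosed by accepted ones) are filled by border-connectivity flood fill —
background reaching the crop border, such as the open lumen, is never
filled — and the components of the result intersected with the boundary
shell are counted. One component means the airway crossed the boundary
without branching, two a single bifurcation. A count of zero (terminal or
stalled airway) or more than two (multiple bifurcations in one region)
triggers radius adaptation: `R` shrinks by `radius_step` (default 2) and
the region is rebuilt, down to the floor of 8. Components that survive an
area check (at most `area_factor` = 1.5 times the seed-surface area; larger
ones are leak fronts) become the next stage's seed surfaces. A global
forbidden mask of previously segmented voxels blocks regrowth into old
territory, which is also what makes the boundary component count mean
*onward* branches only.

### Gap localization and sealing

When a region shows leak evidence, the combined mask — retained
segmentation, the recorded leaky attempt, previously segmented territory
and the seed surface — contains the lumen and the leak blob with the thin
wall between them appearing as a narrow background slit. Closing the
combined mask with `Sphere(close_radius)` (default radius 2) fills that
slit; the difference `D1` is the wall sheet, pierced exactly where the leak
crossed. The sheet is completed with the *definitely bright* voxels (CT at
least `Seed + Threshold0 + 200`), and a second closing of the sheet fills
the pierced hole: `close(sheet) − sheet` marks the gap. Four filters make
the localization exact on phantoms:

* membership: a passage voxel either stayed in the retained segmentation
  (the leak crossed it) or was never segmented; voxels only in the leak
  blob are its collar, not wall passage;
* wall envelope: a gap voxel lies inside `close(bright)` — the wall with
  bridgeable holes virtually filled; this excludes responses at the gap
  mouth just outside the wall;
* each gap component must touch definitely-bright wall (a gap is a hole in
  an otherwise bright wall);
* each component must bridge: touch the retained segmentation on one side
  and leak (or previously sealed) evidence on the other.

Sealed voxels receive `Seed + Threshold0 + 201` HU, one unit above the
highest window the loop can reach, so they fail every subsequent judgment.
After sealing, the working threshold steps up by 1 and the region is
re-segmented; the loop repeats while gaps keep being found *or* the latest
re-segmentation still shows leak evidence — for gaps too wide to close,
threshold adaptation is the only remaining control — and exits with a
`capped` flag once the working threshold exceeds its starting point by more
than 200 HU. The retained result is the last non-leaking one, and sealed
voxels are removed from it: sealed voxels are wall, never lumen. A closing
with radius 2 can bridge holes up to about 3 voxels across; wider gaps
yield no (or only rim) detections, the leak persists inside the region, and
the cap exit fires. That matches the intended scope: gaps beyond three
voxels are out of reach of sealing and are handled by threshold adaptation
and containment alone.

## The synthetic phantom

`generate_phantom()` rasterizes a binary tree of straight cylindrical
segments (heap-numbered: children of branch $i$ are $2i$ and $2i+1$): lumen
capsule of the branch radius, wall shell of `wall_thickness` on top of it
(capsule end caps close the tube ends), parenchyma elsewhere, then optional
wall gaps, then rounded Gaussian noise, clamped at −2048 HU. Ground truth —
lumen, wall and per-branch centerline masks — is recorded voxel-exactly.

Default conditions (the reference phantom): a 96³ volume, three
generations (7 branches), root radius 7 voxels decaying by 0.75 per
generation, root length 26 decaying by 0.8, branch half-angle 40°, lumen
−1000 HU, parenchyma −880 HU (inside the uncertain band), wall −400 HU,
noise SD 10 HU. Two defaults deserve their rationale:

* **Wall thickness 4 voxels** (≈ 2.4 mm at typical chest-CT resolution).
  Measured on the curved discrete shell, the radius-2 closing blocks
  pierced channels of diameter 1–3 and fails at 4–5 — exactly the sealable
  range the gap generator is meant to cover. With a 2-voxel wall the
  erosion step of the closing is radially marginal and even 2-voxel gaps
  escape localization.
* **Gap CT value −900 HU.** A gap is a *low-brightness wall*, not missing
  tissue; −900 sits inside the uncertain band, above the lumen and far
  below the wall, so a clinically wide window accepts it while narrow
  windows do not.

A gap is a cylindrical channel of diameter `extent` pierced radially
through the wall of one branch at a chosen axial position and azimuth.
Extents 1–3 are the sealable range; wider channels (negative tests) must be
requested explicitly.

What the phantom deliberately does **not** emulate: partial-volume blur
(edges are one voxel sharp), cartilage rings, vessels and lung texture,
curved or tapering airways, anisotropic voxels. Two consequences matter for
interpreting results. First, seed surfaces lie in pure lumen, so the
per-surface windows of the threshold rule are only a few noise standard
deviations wide and *never* reach the parenchyma band: with default
settings the phantom cannot leak at all, which is the regime of the
clean-recovery checks. Second, to study leakage and sealing one must
emulate the wide windows that partial volume produces clinically; the
`leak_stress` configuration preset does exactly that by fixing every
region's `Threshold` at 170 HU (window reaching ≈ −860 HU from a lumen
seed, covering parenchyma and gaps) and disabling wall enhancement (which
would otherwise brighten and thereby remove the synthetic gaps on its own —
enhancement *is* a leak preventer). Both arms of any sealing comparison use
the same preset. Passing these tests shows the machinery behaves as
designed under controlled conditions; it does not certify performance on
clinical CT, where gap geometry, wall contrast and noise are far less
tidy.

## Numerical and implementation choices

* Coordinates are 1-based `(x, y, z)` with inclusive crop boxes, the native
  R convention; all formulas are voxel-based (no spacing correction), and
  physical units enter only in the evaluation metrics via the volume
  spacing.
* `Sphere(R)` is the digital Euclidean ball: offsets with
  $\|v\|_2 \le R$. `Sphere(1)` is the 7-voxel cross, `Sphere(2)` has 33
  voxels. Binary erosion (hence closing) treats out-of-bounds as
  background; working crops keep an `R`-voxel margin so this never touches
  the constraint region.
* Connectivity: 26 for labelling surfaces and boundary components (thin
  diagonal sheets must not fragment), 6 for propagation (dictated by the
  `Sphere(1)` dilation) and for hole filling.
* Surfaces are labelled in column-major scan order and processed LIFO;
  with a deterministic generator, end-to-end runs are bit-identical.
* Wall enhancement marks per-axis brightness maxima with at least one axis
  neighbour more than `min_gradient` (default 100 HU) darker, thins each
  axis run to its first brightest voxel, and raises the union by `strength`
  (default 300 HU). The gradient floor exists because with pure noise,
  difference maxima are dense speckle and raising them would shred the
  lumen; 100 HU is far above noise differences (≈ 14 HU at SD 10) and far
  below tissue interfaces (≥ 480 HU here). Threshold statistics always use
  the unenhanced image.
* The wavefront inner loop, morphology kernels, component labelling and
  border flood fill are small C++ kernels; the front-queue formulation of
  propagation is exactly equivalent to repeated `Sphere(1)` dilation with
  judgment and is tested set-for-set against a plain BFS oracle.
* Problem sizes in the test suite: oracle equivalence on one hundred 24³
  images, morphological algebra on fifty 32³ masks, and whole-tree runs on
  the 96³ reference phantom; these sizes exercise every code path while
  keeping the suite quick.

## Known limitations

* Radial gap channels are axis-snapped; on strongly oblique branches the
  localization filters are less exact than on the (axis-aligned) trachea.
* An oversize gap costs the full 201 sealing rounds before the cap exit;
  the loop is cheap per round but this is the slowest path in the system.
* The boundary-area leak check can let small leak speckles seed further
  (contained) regions; leakage never escapes the visited quasi-spheres,
  but the unsealed leakage volume varies considerably with the noise
  realization.
* Very narrow airways (lumen ≤ 1 voxel) are below the resolution of both
  the propagation and the phantom generator.

## A worked run

```{r, eval = FALSE}
library(airwayseg)

bundle <- generate_phantom(phantom_spec(
  gaps = list(gap_spec(1, 0.45, 1), gap_spec(1, 0.75, 2, azimuth = 180))))

mask <- segment_airway_tree(bundle$volume, phantom_seed(bundle),
                            airway_config("leak_stress"))
evaluate(mask, bundle)
attr(mask, "regions")  # per-region log: R, windows, leaks, sealing rounds
```
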