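---
title: "Measuring flow-imaged fish larvae and eggs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring flow-imaged fish larvae and eggs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ichmorph)
```

## The measurement problem

A flow-through imaging rig draws seawater containing fish eggs or larvae
through a transparent tube mounted in front of a telecentric lens, back-lit
by a strobed LED array. The telecentric optics give an orthographic
projection: an object's size in pixels does not depend on its distance from
the lens within the depth of field, so a single scalar `mm_per_px` converts
every pixel measurement to millimetres. `ichmorph` covers the analysis
chain from the raw frame stream to per-individual morphometrics; capture
hardware and the neural segmenter itself are outside its scope, reached
through file formats and a mask adapter (`labeled_region`).

All coordinates in the package are 1-based `(row, col)` matrix indices with
inclusive bounding boxes — the native convention of R matrices and of
EBImage, which backs the morphological primitives. RGB input collapses to
the equal-weight channel mean on ingest; the analysis is purely
intensity-based.

## Candidate-frame selection

Most frames show only background. A frame's background model is the
per-pixel mean of the `window` frames nearest to it (default 50), excluding
the frame itself so a transient animal does not suppress its own detection.
At the ends of the stream the window shifts inward rather than shrinking,
keeping its size — and hence the noise level of the mean — constant. A pixel
is foreground when it deviates from this mean by more than a fixed
`threshold` (default 25 of 255 counts). Back-lit imaging has high and stable
contrast, which is why a fixed absolute threshold suffices and why the
whole stage is invariant to global intensity offsets. Connected foreground
components (8-connectivity by default, so thin larva tails stay in one
piece) are filtered by area; the minimum area is configured physically
(default 0.2 mm²) and converted through the pixel scale, so the setting
survives resolution changes. Every frame with at least one surviving blob
is selected — any further sub-sampling for annotation is a downstream,
human choice.

Two caveats follow directly from the model. An object present in *every*
window frame is absorbed into the background mean and never detected; the
tests assert this behaviour rather than hide it. And detection degrades as
object contrast approaches `threshold`; the synthetic stream tests use
contrast 80 against threshold 25, mirroring the strong contrast of the
imaging rig.

## Mask validation rules

An external instance segmenter supplies one binary mask per feature
(larva-mode classes `body`, `eye`, `yolk`; egg-mode `egg`, `body`, `yolk`).
Validation applies, in order:

1. **Hole filling** — enclosed background components are added to each
   region. Running this first makes the later containment test meaningful.
   Concavities open to the image border are not holes and stay open.
2. **Edge discard** — bodies with any border pixel are removed (an
   off-frame body cannot be measured); edge-touching eyes/yolks are removed
   individually; *interior* organs are kept even when their body was
   discarded, because those measurements are still sound.
3. **Association and containment** — each part goes to the body whose
   filled mask contains the largest fraction (> 50%) of its pixels; parts
   extending more than `slack` pixels (default 0) outside every body are
   dropped. Orphan parts form a bodiless record only when a body was lost
   to edge discard in that frame.
4. **Cardinality** — at most one body, two eyes, one yolk sac per fish.
   Survivors are ranked by segmenter confidence, ties broken by larger
   area, then upper-left-most centroid, so the result is deterministic even
   for segmenters that emit no confidence.

Exceeding a cardinality limit is itself diagnostic: merged or touching fish
produce one body with too many organs, so the record is kept but flagged
`cardinality_suspect` and reported with `body_valid = FALSE`. Two partly
overlapping eyes segmented as a single two-lobed ("figure-8") region are
not split — that would be a correction the upstream segmenter never made —
but flagged `eye_shape_suspect` when the region's solidity (area over
convex-hull area) falls below 0.85. The whole validation pass is
idempotent, which the tests assert on every fixture.

In egg mode only the shell outline is validated and measured. Embryo-body
and yolk regions inside eggs are deliberately unused: their pose cannot be
recovered from a single projection, so any volume inferred from them would
be noise.

## Morphometrics

**Standard length.** The body mask is thinned to a one-pixel skeleton
(Zhang–Suen, implemented in C++), the skeleton is read as a graph with
orthogonal steps weighing 1 and diagonal steps √2 (diagonal edges that
merely short-cut a staircase corner are omitted, or every corner would look
like a junction), endpoint branches shorter than ~1.5× the local inscribed
radius are pruned as thinning artifacts of blunt ends, and the longest
remaining end-to-end path is the centerline. Its coordinates are smoothed
with a short moving average before the arc length is computed — a raw
digital path over-counts the length of curved bodies by a few percent of
staircase jitter — and both ends are extended along the terminal tangent to
the mask boundary so the length runs snout to tail tip. On synthetic ground
truth this recovers standard length within 2% for straight bodies and 5%
up to semicircular poses (the package's acceptance suite measures 100 of
each).

**Curvature flag.** The spread (max − min) of the unwrapped tangent heading
along the centerline is ~0 for a straight body, exactly π for a semicircle,
and beyond π for curled poses. Records above `max_turn_rad` (default
1.25 π) are flagged `curvature_suspect`: such fish cannot be measured
reliably, and the threshold deliberately leaves the semicircular pose —
which the length recovery handles — unflagged. The spread statistic is used
instead of summed absolute turning because pixel-level heading jitter
cancels in a spread but accumulates in a total-variation sum.

**Facing direction.** Mean inscribed body width (twice the Euclidean
distance transform) over the terminal 20% of arc length at each end; the
wider end is the head. A width ratio under 1.1 flags the heading ambiguous
(a symmetric capsule has no head).

**Axes.** Eye and yolk axes come from the ellipse with the same second
central moments as the pixel set, normalised so a solid ellipse returns its
own axis lengths (`major = 4√λ₁`). Moment axes were chosen over min/max
Feret extents for robustness to boundary noise; the acceptance sweep checks
recovery within 1 px over 200 rasterized ellipses spanning 20–400 px.
Areas are plain pixel counts times `mm_per_px²` — no smoothing is applied
to areas.

**Eye diameter** is reported as the measured width (minor axis) `W_E`, the
quantity comparable across the literature. When two eyes are retained the
record carries their mean and `n_eyes = 2`.

## Volume models

With `A_L` (mm²) and `L_L` (mm) measured, the larva body is modelled as a
cylinder seen side-on, `V_L = (A_L²/L_L)·(π/4)`; yolk sac and eye as
prolate spheroids, `V = (4/3)π(W/2)²(L/2)`; and the structural volume is
`V_S = V_L − V_Y`. A negative `V_S` (yolk model exceeding body model —
a segmentation fault) is retained and flagged rather than clipped, keeping
the fault auditable. The egg is a sphere over the mean of its measured
axes, `D_E = (L_E+W_E)/2`, `V_E = (4/3)π(D_E/2)³`; an axis ratio below 0.95
warns that the sphere assumption is degrading. The sphere formula is coded
as `(R²·R)` so it is bit-identical to the spheroid at equal axes — an
identity the tests assert exactly. An egg-internal yolk spheroid function
exists in the API but is excluded from egg-mode output, consistent with the
unreliability of internal egg segmentations. All three solids agree with
3-D voxel-count oracles at 0.002 mm pitch within 1%.

## The synthetic generator

The generator exists so every stage has exact ground truth. A larva is a
tube swept along a constant-curvature spine with a half-width profile
tapering linearly from the head (default 0.255 mm half-width) to 25% of
that at the tail, closed by circular caps; eyes are near-black ellipses and
the yolk a mid-contrast ellipse placed on the spine inside the envelope.
True standard length is the spine arc plus the two cap radii — exactly the
span the centerline-plus-extension measures — and true area is the analytic
swept strip plus half-disc caps. Defaults mirror the study population the
package targets: standard length ~ Normal(4.48, 0.36) mm, body area
≈ 1.43 mm², yolk sac 0.60 × 0.30 mm (prolate volume ≈ 0.028 mm³), eye
diameter 0.286 mm, egg diameter 1.36 ± 0.02 mm, at the default scale of
0.0036 mm/px (field-of-view width 8.8 mm over 2448 px — a documented
default, not a calibration). Rendering is 2-D orthographic with a bright
(220-count) background, additive clipped Gaussian noise (σ = 5), and for
streams a slow sinusoidal background drift (amplitude 3 counts) plus small
sub-threshold distractor blobs standing in for bubbles and fibres.

`scenario_suite()` adds the documented failure modes: a tail clipped by the
frame edge (body discarded, organs retained), two overlapping and two
touching larvae (merged body, `cardinality_suspect`), an over-curled pose
(1.7 π, `curvature_suspect`), and a top-down view with no visible yolk and
the eye pair merged into a figure-8. Two overlapping convex lobes cannot
fall below solidity ≈ 0.88, so the figure-8 scene joins its lobes with a
thin dark bridge — emulating the single merged region a segmenter produces
— which brings solidity to ≈ 0.7, under the 0.85 flag threshold.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: partial-focus blur and depth-of-field loss, real
sensor noise statistics, pigmentation patterns, refraction at the tube
walls, and genuinely three-dimensional poses (the "imaged from above" scene
is a 2-D stand-in). Results on camera data depend on the upstream
segmenter's quality in ways synthetic scenes cannot probe.

## The bundled null segmenter

`null_segmenter()` classifies pixels by fixed intensity bands below
background (eye < bg−150, yolk in [bg−150, bg−80), body < bg−30) and splits
each class into connected components. It exists to close the end-to-end
loop on synthetic scenes at the segmenter adapter boundary; it is not a
substitute for a learned segmenter on real imagery, where contrast bands
overlap. Components under `min_region_px` (default 30) are dropped as
noise.

## Reproducibility and outputs

Every run is parameterised by a `run_config` that is serialized (with a
content hash) next to the outputs; result CSVs use fixed 6-decimal
formatting so identical runs are byte-identical. Rather than manually
excluding extreme data points, the pipeline keeps every row, ties each
numeric field to a validity flag, and offers a report-only robust outlier
screen (median ± 5 MAD) — automation with an audit trail, no silent drops.
Summaries report mean, SD, quartiles and n per endpoint per group,
restricted to valid rows, with invalid counts alongside.

## Problem sizes and numerical choices

The validation suite runs at the sizes its claims state: 100 straight and
100 curved larvae for length recovery, a 200-case ellipse sweep, a
200-frame stream with 12 injected objects and 20 distractors, and a
scenario suite of 8–10 clean scenes plus the failure scenes, rendered at
the default 0.0036 mm/px in frames of roughly 340–900 × 1500 px. These
sizes keep the full suite in the minutes range on a single core while
leaving the statistical checks (means within two standard errors of
generator truth) well-posed. Degenerate inputs are handled explicitly:
empty masks error, a disc-like body yields a flagged diameter-length
centerline, single-pixel regions are flagged degenerate in axis
measurement, and a zero-perimeter outline cannot be resampled.

## Known limitations

* Curved fish are measured as-is along the centerline; strongly curled
  poses are flagged, not straightened, and lengths of swimming fish may be
  slightly underestimated.
* The isotropic single-scalar pixel scale ignores any per-axis difference
  in optical magnification; with the recommended telecentric optics the
  difference is negligible, but the package offers no anisotropic scaling.
* Eye volume inherits the figure-8 merging problem: flagged, not corrected.
* The per-day/treatment grouping of results comes from experiment metadata
  the images do not carry; grouping keys are user-supplied.
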