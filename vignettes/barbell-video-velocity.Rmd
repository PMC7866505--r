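---
title: "Measuring barbell velocity from monocular video: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring barbell velocity from monocular video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbtrack)
```

## The measurement problem

Velocity-based training (VBT) prescribes loads by the velocity at which an
athlete can move them, so the mean concentric velocity of each repetition
must be measured in real time. On a multipower (Smith) machine the barbell
slides on two parallel vertical guides, so its motion is confined to a
single plane — the *guide* or *barbell plane*. vbtrack implements a
camera-based instrument for this setting: a single smartphone-class camera
on a tripod films the machine, and image processing recovers the metric
barbell trajectory without any manual digitizing.

Two obstacles make this non-trivial. First, a monocular camera loses depth:
a pixel only determines a ray. Because the barbell stays in a known plane,
an invertible plane-to-image map (a homography) restores metric
coordinates — but the guide plane itself cannot carry reference markers,
since the guides must stay clean and lubricated. Second, the reference
markers that *can* be placed (striped warning tape on the front structural
pillars) live in a *different*, parallel plane, offset by a gap `Dg` of
typically 10–20 cm. Mapping barbell pixels through the structural-plane
homography would introduce a systematic parallax error.

## The two-plane calibration

The calibration transfers a homography from the measurable plane to the
plane of interest:

1. Four reference corners `P1..P4` (upper-left corners of the highest and
   lowest tape stripes on each pillar) are located in the image. Their
   *world* coordinates are reconstructed from six tape-measured distances —
   the four sides and both diagonals of the quadrilateral — by the law of
   cosines, with `P1` at the origin and `P2` straight below it (the world
   frame has x rightward, y downward, z away from the camera, matching
   image axes so that ascent decreases y).
2. The direct linear transform with Hartley normalization estimates the
   structural homography `H_s` from the four correspondences.
3. With the camera intrinsics, `H_s` factors as `K [r1 r2 t]`, giving the
   full scene-to-camera pose `T_scene2cam`.
4. Four *virtual* guide-plane points are synthesized directly behind the
   reference corners, `P_ig = (X_is, Y_is, Dg)`, and projected through the
   recovered pose.
5. Those four synthetic correspondences yield the guide homography `H_g`,
   which is computed once per session and then maps every tracked barbell
   pixel to metric plane coordinates.

The sixth measured distance is redundant and serves as a consistency check
on the tape measurements; the default tolerance of 5 mm reflects realistic
tape-measure error (`reconstruct_reference_quad(tolerance_m = )`).

### Intrinsics

The intrinsic model assumes square pixels (`f_x = f_y`), zero skew and the
principal point at the image centre — accurate for modern phone sensors,
whose lens distortion is negligible at these working distances. The focal
length can be supplied (`focal_px`, e.g. from camera metadata) or
self-calibrated from `H_s` via the rotation-orthonormality constraints
`r1·r2 = 0`, `|r1| = |r2|`, combined by least squares. Self-calibration is
mathematically degenerate for an exactly fronto-parallel camera and is
ill-conditioned near it: with corner positions quantized to whole pixels,
tilts below roughly 10 degrees can bias the focal estimate by several
percent, which propagates into the plane transfer. Supplying the focal
length is therefore the recommended mode, and is what the end-to-end
accuracy checks use; self-calibration is verified separately on exact
correspondences, where it recovers the focal within one pixel.

## Automatic detection

Both the tape corners (once per session) and the barbell marks (every
frame) are found by the same color pipeline:

* **Circular hue similarity.** The frame is converted to HSV; the hue
  distance to the target (red 0 for the tape, yellow 1/6 for the mark) is
  measured circularly, `min(|h-t|, 1-|h-t|)`. Pixels with saturation below
  50% are discarded — their hue is meaningless. The binarization threshold
  is half the circular distance from the target hue to the nearest *other*
  primary/secondary hue (1/12 for red or yellow), so the accepted hue band
  scales sensibly for any target color.
* **Top-hat bandpass.** Two white top-hats with linear structuring elements
  of twice and half the expected feature size are subtracted, eliminating
  regions larger than twice or smaller than half the expected extent along
  the element's orientation. The tape uses vertical and 135-degree
  elements; the marks use vertical and horizontal ones. The two
  orientations are intersected (the conservative combination) and the
  result is restored to full stripe shapes by morphological reconstruction
  under the binarized hue image. Structuring-element lengths are rounded up
  to odd values so erode-then-dilate is the exact set-theoretic opening.
* **RANSAC line fit.** The pillar stripes are collinear by construction, so
  a first-degree polynomial `x = a·y + b` is fitted to the candidate
  upper-left corners per image half (threshold 3 px, 200 iterations, seeded
  for reproducibility); outliers — reflections, clothing, gym equipment —
  are discarded, and the highest and lowest inliers give the reference
  corners.

Per-frame mark detection is restricted to two narrow search strips built
from the tape inliers (the fitted tape line shifted by half a stripe width,
out to midway toward the image bisector), which both suppresses false
positives and keeps the per-frame cost low: only the strip columns are
touched, and the homography is applied to at most two points per frame
(the mark corners), never to whole images.

Candidate pairing exploits the rigid bar: among left/right candidates the
pair with the most similar *row* (height) coordinate is chosen. (Pairing on
column proximity would be meaningless for marks ~1.5 m apart; the bar
constrains heights, not columns.) Missing detections — occlusion, glare —
are filled by linear interpolation between neighbouring frames and flagged
`interpolated`; gaps longer than 5 frames are additionally marked
low-confidence.

## Kinematics

The barbell height is `-Y` of the left/right mark midpoint (robust to small
bar tilt). Velocity is the central difference of position at the capture
rate, acceleration the central difference of velocity; both use one-sided
differences at the series ends, with an optional moving-average
pre-smoothing (off by default). Force follows
`F = (m_a + m_l)(a_b + g)` with `g = 9.81` m/s², equating centre-of-mass
displacement with barbell displacement as is standard for guided squats;
power is `F·v`.

Concentric segmentation finds each lift between two rest plateaus:

* the ascent trigger is `v > v_start` (default 0.05 m/s) sustained for 3
  samples; the start index then walks back to the last sample of the
  preceding plateau — the instant before the ascent begins;
* the end trigger is `v` non-positive or `|v| < v_stop` (default
  0.02 m/s) sustained for 3 samples, *confirmed* by a 0.1 s lookahead in
  which the height must not rise by more than `pos_tol_m` (default 3 mm,
  about one pixel); the confirmed end then extends to the first sample of
  the final plateau. The lookahead is essential at 2 mm quantization:
  during slow phases the quantized height staircases produce spurious
  zero-velocity runs that must not terminate the repetition.

Segments with range below 5 cm are discarded. All thresholds live in
`kinematics_config()` with units documented there. Mean velocity, force and
power are means of the instantaneous series over the segment; the range is
the height difference between its endpoints.

## Agreement statistics

Validation against a criterion instrument (e.g. a linear position
transducer) uses the standard method-comparison toolkit, assembled by
`agreement_report()`: ICC(2,1) (two-way random, absolute agreement, single
measures, with the F-based confidence interval and the usual
poor/moderate/good/excellent labels), Cronbach's alpha, paired-t mean
difference, Bland–Altman bias and 95% limits of agreement with a
proportional-bias regression (`r² > 0.1` flags proportional bias), the
smallest worthwhile change (20% of the between-subject SD of subject
means), the typical error SEM, their usefulness ratio (good > 1), and
Pearson r with the standard error of estimate, raw and standardized.

Two SEM conventions exist in the literature: the difference-score typical
error `SD(a-b)/sqrt(2)` and the ANOVA residual `sqrt(MSE)` from the ICC
decomposition. Both are implemented (`sem_method`); the difference-score
form is the default because it is the convention of the SWC/SEM usefulness
framework. No installed package provides ICC(2,1), so the ANOVA
decomposition is implemented directly from sums of squares; the test suite
cross-checks it against mean squares obtained independently from
`anova(lm(...))` to 1e-10.

## The synthetic scene generator

Real validation videos cannot ship with a package, so `render_scene()`
produces fully ground-truthed scenes: striped tape rectangles on the
structural plane, square colored marks on the guide plane at gap `Dg`,
projected through an exact pinhole camera and rasterized without
anti-aliasing, so every ground-truth pixel position is an exact projection.
The default scene mirrors a realistic setup: a 150 cm-wide machine, the
camera 2.2 m away framing 2.1 m horizontally in portrait 1080x1920 — a
pixel pitch just under 2 mm — with stripes sized to the detector's default
expected polygon size (image height / 40). Options add Gaussian pixel
noise, a vertical illumination gradient, occluded frames, off-line
distractor blobs, and the black–yellow tape palette; all randomness is
seeded.

What the generator deliberately does *not* emulate: motion blur, rolling
shutter, lens distortion, compression artifacts, shadows, or a moving
human body. Passing the synthetic end-to-end checks therefore demonstrates
the correctness of the geometry, detection and kinematics chain at the
stated resolutions — not robustness to every nuisance of a real gym.

Motion profiles are rest–lift–rest with closed-form kinematics:
constant-velocity, half-sine (peak = π/2 × mean, matching observed lift
shapes) and minimum-jerk (peak = 1.875 × mean). The end-to-end recovery
sweep (20 sequences, mean velocities 0.4–1.2 m/s, camera tilts 0–20°,
240 fps) uses the constant-velocity family: with position quantized at
~2 mm, the onset of a smoothly starting profile is observable only once
the bar has moved a full pixel, so the measured duration of a half-sine
lift is intrinsically shorter than the prescribed one (by tens of
milliseconds at slow velocities) and the prescribed mean velocity is not
the right yardstick for it. Sharp-onset profiles make the prescribed value
well-defined to within a frame; half-sine profiles are instead checked
against their closed-form *peak* velocity within the measured segment.

### Problem sizes

The test-suite scenes run at half resolution (540x960, ~4 mm/px) to keep
unit tests fast; the end-to-end acceptance sweep and the acceptance script
render the full 1080x1920 default at 240 fps (about 190 frames per
sequence, 20 sequences). Statistical recovery checks use the 20-subject ×
8-repetition design at 100 seeded replicates.

## Known limitations

* Absolute accuracy is bounded by the pixel pitch (~2 mm at the default
  framing); range errors up to one pixel are expected and observed.
* The upper-left corner of a detected polygon is a bounding-box corner; at
  strong camera tilts it can drift a few pixels in x from the projected
  stripe vertex. Heights (y) are much less affected, and the effect on the
  transferred homography is below the quantization error at tilts ≤ 20°.
* Focal self-calibration needs a clearly tilted view (see above).
* Tracking assumes the camera does not move after calibration; there is no
  recalibration during a session.
* Free (unguided) lifts with out-of-plane motion are out of scope: the
  plane constraint is what makes monocular metric measurement possible.
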