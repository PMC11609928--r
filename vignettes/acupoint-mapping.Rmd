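---
title: "Proportional acupoint mapping and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proportional acupoint mapping and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acumap)
```

## The model

Classical acupuncture locates points by proportional measurement: a point is
defined as a fixed fraction of the distance between two palpable anatomical
structures, possibly offset along a second direction. Landmark detection
models emit exactly those structures as indexed keypoints — 21 slots per
hand, 468 per face — so each textbook recipe can be expressed as a short
program over landmark coordinates. `acumap` implements that idea in three
layers:

1. **A declarative rule table.** Every acupoint is one registry entry with a
   code, name, meridian, region and an ordered list of geometric steps
   (`anchor`, `midpoint`, `fraction`, `toward`, `offset`) over landmark
   slots. Rules are data, not code: the whole catalogue lives in one
   versioned JSON file (`inst/extdata/acupoint_rules.json`) that can be
   reviewed, diffed and replaced. Only one recipe — HT-8, computed from the
   slot-5/slot-17 base distance, starting at `midpoint(13, 17)` and
   projecting one fifth of the base toward the wrist — comes from a
   published worked example. The other 37 entries encode textbook anatomical
   descriptions as proportional approximations, and each carries a
   provenance note saying exactly that. Anyone with better constants edits
   the table, not the engine.

2. **View gating.** A palmar point cannot be drawn on an image of the back
   of the hand. Hands are classified into front / back / inside / outside
   from the angle between the palm normal (cross product of the frame
   spanned by slots 0, 5 and 17) and the optical axis; faces into center /
   left / right from a nose-to-contour asymmetry ratio. Each rule lists the
   views under which it fires; under other views the point is reported
   `visible = FALSE` rather than extrapolated.

3. **An evaluation stack** matching standard keypoint-benchmark practice:
   Euclidean pixel errors with normal-approximation 95% confidence
   intervals, physical calibration from a reference object, object keypoint
   similarity `OKS = exp(-d^2 / (2 s^2 k^2))`, greedy confidence-ordered
   matching, 101-point interpolated average precision per acupoint code, and
   per-axis two-sample Kolmogorov–Smirnov comparisons of predicted versus
   annotated coordinate distributions.

## Coordinate conventions

All geometry is double precision in image coordinates: origin top-left, x
rightward, y downward, z increasing away from the viewer (a palm facing the
camera has normal `(0, 0, -1)`). Normalized landmark inputs (x, y in [0, 1])
are scaled by image width/height on ingest; **rule evaluation is 2D in pixel
space** — z participates only in posture classification. This matches how
drawn overlays and annotation-based evaluation work (both are image-space),
and avoids pretending the depth channel of landmark detectors has metric
meaning.

Whether proportional rules should operate in normalized or pixel
coordinates is genuinely open; the package standardizes on pixels because
calibration and all error metrics are pixel-based, and because uniform
scaling cancels in every shipped rule (see the equivariance property below).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `hand_front_max_deg` | 45 | degrees | front band `[0, 45)`; with the 135 back threshold the sphere splits into four equal zones. Package convention — the mechanism (palm-normal angle) is given, numeric cut-offs are not published. |
| `hand_back_min_deg` | 135 | degrees | back band `[135, 180]`; lateral zone resolved by the sign of the normal's x-component (flipped for left hands). Boundary values fall to the band whose closed end they touch. |
| `face_yaw_threshold` | 0.2 | unitless | center when the asymmetry ratio is below 0.2; the ratio is scale- and translation-invariant. |
| `oks_k` | 0.02 | unitless | per-keypoint falloff constant, identical for all acupoints. |
| OKS scale `s` | `sqrt(bbox area)` | pixels | per ground-truth annotation; falls back to the keypoint bounding box when no bbox is annotated. |
| `palm_frame` | slots 0, 5, 17 | — | wrist and the two outer finger MCPs span the palm plane in the 21-slot schema. |

All thresholds are overridable through `acumap_config()` (a JSON file with
typo-safe key checking) or per-call arguments.

## Design choices where the design was open

- **Label semantics for face poses.** The yaw proxy is
  `(d_left - d_right) / (d_left + d_right)` of projected nose-to-contour
  distances; turning the head to the subject's right foreshortens the right
  contour and drives the proxy positive. The label therefore names the
  direction the head is turned.
- **Mirroring swaps slot semantics.** A pure x-reflection is an isometry, so
  it changes no pairwise distance and could never swap left/right pose
  labels. What a landmark detector run on a mirrored image actually reports
  is reflected coordinates *with left/right slot roles exchanged*;
  `mirror_landmarks()` reproduces that by swapping the documented
  left/right slot pairs (`face_mirror_pairs()`) for faces and flipping the
  handedness tag for hands. With that definition, mirroring swaps left and
  right poses, fixes center, and commutes with `map_acupoints()`.
- **One rule per bilateral facial point.** The registry keeps exactly 20
  face entries; bilateral points are authored once on the subject's left
  side and gated visible in the center and right-turned poses (the views in
  which that side faces the camera). In a left-turned pose only the four
  midline points fire. Duplicating the catalogue into left/right variants
  would double the table for no modelling gain; callers who need both sides
  can map the mirrored landmark set.
- **Hand visibility grouping.** Palmar points fire in front (and the
  matching lateral) views, dorsal points in back/outside views; nail-corner
  points at the fingertips (e.g. PC-9, SI-1, HT-9, LU-11) are visible from
  both front and back, which is how such points are conventionally drawn on
  dorsal images.
- **Truncation, not rounding, of the calibration factor** at 4 decimals
  (80 cm / 1488 px reports 0.0537 cm/px); the untruncated ratio is retained
  alongside.
- **KS variant.** The statistic is the exact sup of the ECDF difference
  (verified in tests against a brute-force enumeration for all sample sizes
  up to 8); the p-value uses the asymptotic two-sample Kolmogorov series,
  appropriate for the hundreds-of-points samples it is applied to. No tie
  correction is applied; coordinates are continuous.
- **AP protocol.** Greedy confidence-ordered matching (ties broken by
  ground-truth order), 101-point interpolated precision over recall, OKS
  thresholds 0.50:0.05:0.95 — the de-facto keypoint benchmark protocol.

## The synthetic generators

`gen_hand_landmarks()` and `gen_face_landmarks()` place versioned canonical
templates (a 21-slot right hand with plausible relative proportions; a
468-slot face whose rule-referenced slots are anatomically shaped and whose
remaining slots are deterministic filler) under rigid rotations chosen so
the classifiers recover the requested label at zero jitter, then apply
scale, translation and isotropic Gaussian jitter **in the image plane
only**. The 2D noise model is deliberate: it has a closed-form mean
Euclidean displacement (`sigma * sqrt(pi/2)`, the Rayleigh mean), giving the
test suite an independent oracle for the whole
generate→map→annotate→evaluate loop.

`gen_eval_scene()` draws per-image postures, scales and rotations from a
seeded spec, computes ground-truth acupoints *with the same mapping rules*,
perturbs them by the scene's `jitter_sd`, and emits landmark JSON plus one
COCO keypoint file. Two consequences worth stating plainly:

- At zero jitter the ground truth **is** the mapper's output, so the
  noiseless end-to-end check (mean error 0, mAP@50 = 1, KS statistic 0) is
  a closure property of the software, not evidence of anatomical accuracy.
- A green suite establishes geometric correctness (equivariance, mirror
  consistency, exact proportionality, metric identities) — it cannot
  establish clinical localization accuracy, because the generators emulate
  landmark geometry, not real hands, faces, detector bias or annotator
  disagreement. Validating the 37 approximate rules against expert
  annotations requires real data the package does not ship.

Default scene parameters (scale 0.8–1.2, in-plane rotation ±15°, 640x480
frames, uniform posture mix) describe a plausible tabletop capture; they are
fixed once and not tuned against any test outcome.

## Numerical notes

- `arccos` arguments are clamped to [-1, 1] so parallel/antiparallel vectors
  cannot produce NaN; zero vectors and coincident ray endpoints raise
  classed degenerate-geometry errors rather than returning NaN.
- Absolute tolerance 1e-9 for geometric comparisons; similarity equivariance
  of the full mapper holds to 1e-6 relative.
- JSON writers emit 17 significant digits, so landmark and ground-truth
  files round-trip bit-identically and seeded scene regeneration is
  byte-identical.
- `match_by_oks` ties (one prediction equally similar to two ground truths)
  resolve to the earlier ground-truth row, making matching deterministic.
- The normal-approximation CI is degenerate (equal to the mean) at n = 1;
  empty samples are errors, not NaNs.

## Known limitations

- Forearm points (LI-11, LI-10, TE-5) are out of scope: no reliable
  anatomical landmark for them exists in the 21-slot hand schema.
- The 37 non-HT-8 rules are stated approximations; their constants have not
  been validated against expert annotations.
- Posture thresholds (45°/135°, 0.2) are package conventions; real detector
  output near band boundaries will flicker between adjacent labels, and no
  temporal smoothing is provided.
- Live capture is only an adapter contract (`landmark_provider()`); the
  package neither decodes video nor reads raster image files, and
  `overlay_predictions()` operates on in-memory arrays.
- Left-turned face poses expose only midline points (see above).
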