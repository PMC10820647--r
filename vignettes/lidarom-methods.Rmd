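---
title: "How lidarom estimates joint angles from a swept LiDAR and a camera"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How lidarom estimates joint angles from a swept LiDAR and a camera}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Range-of-motion assessment asks for the angle a joint subtends while a
patient holds or repeats a rehabilitation exercise. The approach
implemented here replaces the goniometer with two uncalibrated sensors: a
sparse 16-beam LiDAR, mounted vertically so its beam fan spreads across the
horizontal direction, and an RGB camera mounted directly on top of it. Both
ride on a robot arm that translates them horizontally through roughly ten
stops per sweep, so consecutive LiDAR measurements see the subject from
slightly shifted vantage points. The LiDAR contributes metric 3D structure;
the camera contributes semantics (where the person and their joints are);
and the robot's reported positions stitch the sweep together.

## The pipeline

Each estimation iteration runs these stages:

1. **Axis correction** (`swap_vertical_axes()`). The sensor is mounted
   rotated by 90 degrees, so the raw vertical-plane axes are exchanged:
   every point $(x, y, z)$ becomes $(x, z, y)$. After the swap, $x$ is the
   sweep direction, $y$ depth, $z$ up.
2. **Sweep fusion** (`merge_sweep()`). With the first measurement of a
   sweep as reference, points of measurement $i$ are shifted along $x$ by
   the rig displacement $x_i - x_0$. A full sweep is 11 measurements; if
   fewer arrive, the last is replicated (replicated points merely overlap),
   and surplus measurements beyond 11 are ignored. Method `S` skips this
   stage and uses a single measurement; method `F` uses the merged sweep.
3. **Flattening and proportional fit** (`project_to_image_plane()`,
   `compute_fit()`, `apply_fit()`). Depth is discarded, and the 2D cloud is
   scaled anisotropically so its width and height match the detected
   person's pixel box, then translated onto it. This deliberately replaces
   extrinsic/intrinsic calibration; its cost is analyzed below.
4. **Keypoint association** (`select_joint_points()`). For each joint of
   the exercise's triple, the $k_{\max} = 10$ fitted points nearest the
   detected keypoint within a 40-pixel radius are selected (all of them if
   fewer qualify; none means the iteration is skipped). Both values are the
   empirical defaults the method was validated with and are exposed in
   `selection_params()`.
5. **Lifting and the angle** (`centroid()`, `joint_angle_deg()`). Selected
   points are lifted back to their original 3D coordinates through their
   stable indices, averaged per joint, and the angle at vertex $B$ is
   $$\theta = \arccos\frac{\vec{BA}\cdot\vec{BC}}
   {\lVert\vec{BA}\rVert\,\lVert\vec{BC}\rVert},$$
   with $A$, $B$, $C$ the three joint centroids.

Exercise triples: shoulder abduction (RA) and shoulder flexion (RF) use
hip–shoulder–wrist with the vertex at the shoulder; elbow flexion (R7) uses
shoulder–elbow–wrist with the vertex at the elbow. The wrist (rather than
the elbow) as the far endpoint for the shoulder exercises follows how the
selected joint points are grouped in practice; the mapping is configurable
through the `triple` argument if a clinic prefers the elbow.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| selection radius | 40 | px | association search radius around a keypoint |
| $k_{\max}$ | 10 | points | centroid support per joint |
| sweep size | 11 | measurements | full robot pass (10 stops, sometimes 11) |
| minimum keypoint confidence | 0.25 | — | below it a joint counts as missing |
| alignment max gap | 0.2 | s | two periods at the ~10 Hz acquisition rate |
| mirroring flag | on | — | sensor $x$ vs image $u$ handedness |

All internal geometry is meters and radians; degrees appear only in
reported angles, which files carry with 3 decimal places.

## What the simulator emulates — and what it does not

`generate_session()` reproduces the acquisition protocol: a subject at 3 or
4 m holding poses while the rig sweeps $-0.3\ldots-0.1$ m at ~10 Hz; a
16-beam, $\pm18^\circ$, 4.8 m-range LiDAR modeled by ray casting (2-degree
beam spacing, 0.2-degree spin steps); a pinhole camera (640x480, 600 px
focal length, principal point at center); and a ground-truth trace playing
the role of the wearable reference sensor. The body is a set of capsules:
torso, head, both arms, plus shoulder-girdle and pelvic-girdle capsules so
that joint keypoints sit on fleshed surface rather than on bare tube ends.
Occlusion falls out of ray casting (each ray stops at its first surface).

Anthropometry defaults are plausible adult values: upper arm 0.30 m,
forearm 0.27 m, shoulder width 0.40 m, limb radius 0.045 m, torso capsule
radius 0.11 m (chest half-depth), hip keypoint spacing 0.22 m. The widths
are distances between *joint centers*, where pose-network keypoints sit —
hip keypoints in particular are medial of the pelvis silhouette. Only
relative geometry matters for recovery tests.

Exercise kinematics are solved so the generated triple subtends exactly the
requested angle (the package's own angle routine applied to the generated
joints returns it to $10^{-9}$ degrees, which the tests assert):

* **RA** rotates the trunk direction outward in the frontal plane — a rigid
  rotation, exact for any angle in $[0, 180]$.
* **RF** moves the straight arm in the sagittal plane through the shoulder
  (constant lateral offset), solving the in-plane elevation $\varphi$ from
  $\cos\theta = b\cos\varphi$, where $b$ is the in-plane component of the
  trunk direction. Angles with $|\cos\theta| > b$ (roughly outside
  $[10.3^\circ, 169.7^\circ]$ at the defaults) would require the arm to
  leave the sagittal plane and are rejected with an informative error.
* **R7** keeps the upper arm at the side and flexes the forearm in the
  subject's frontal plane. This choice keeps the flexion plane visible to
  the frontal camera, as the exercise is presented frontally in the
  protocol; a sagittal forearm would point down the optical axis and hide
  the elbow behind the hand in *any* implementation of this method.

Views are whole-body yaws: frontal $0^\circ$, oblique $45^\circ$ (the
protocol never quantifies "oblique"; this is a configurable midpoint),
lateral $90^\circ$. Sensor height (1.2 m) and camera intrinsics are
configuration values, not claims about the original rig.

The simulated detector replays the *projected true joints*, optionally with
Gaussian pixel noise, and a silhouette-derived box. It therefore does not
reproduce the systematic failure modes of a real pose network (left/right
swaps, missed hands, clothing effects), and passing recovery tests say
nothing about detector robustness on real imagery — a real detector adapter
can be plugged in through `detect_joints()` and its outputs cached as JSON
for replay. Likewise there is no clothing, no robot occlusion, and no
timing jitter beyond the nominal frame spacing.

## Numerical choices and degenerate inputs

* The cosine in the angle formula is clamped to $[-1, 1]$ before `acos`.
* Selection ties at equal pixel distance resolve toward the smaller point
  index, making replays deterministic.
* Empty selections, missing/low-confidence keypoints, and coincident
  centroids abort the iteration with a classed condition and a reason;
  the session estimator records these and continues.
* Degenerate clouds (empty, or spanning zero width/height after
  projection) raise classed errors rather than producing angles.
* On a constant truth series NRMSE and $R^2$ are reported as `NA`;
  zero-truth pairs are excluded from MAPE and counted, since percentage
  error is unstable near 0 degrees.
* NRMSE normalizes by the truth range by default (`"mean"` is available);
  the error sign convention is estimate minus truth.
* All session randomness flows from one integer seed; equal seeds give
  byte-identical session directories and output files.

## Where the method's accuracy genuinely ends

Two error floors are visible in the simulator exactly because they are
properties of the method, not of the implementation:

* **Surface vs bone.** LiDAR returns come from the body surface, so each
  centroid sits a capsule radius in front of its joint center. When the
  offsets are similar across the triple (RA, R7, frontal views) they nearly
  cancel; when they differ — the torso surface is ~0.07–0.09 m proud of the
  hip and shoulder joints while the wrist tip is only ~0.03 m — the angle
  acquires a bias of a few degrees. This is what limits shoulder-flexion
  accuracy at low elevations.
* **Depth-axis degeneracy.** Flattening discards depth, so two joints that
  differ mainly in depth project to nearly the same pixel. At 90 degrees of
  shoulder flexion the wrist and shoulder coincide exactly in the flattened
  cloud, and no nearest-pixel association can separate them; in lateral
  views the same happens to whichever exercise moves in the now-depth-wise
  plane (abduction, frontal-plane elbow flexion). The evaluation suite
  shows this as the lateral-view error exceeding the frontal one, the same
  ordering the underlying study reports.

Merging the 11-measurement sweep densifies the cloud roughly tenfold along
the sweep axis, which stabilizes the 10-point centroids; the suite checks
that full-sweep (F) estimates are never less accurate on average than
single-measurement (S) ones under measurement noise.

## Problem sizes used by the checks

The recovery study runs 30 noiseless frontal conditions (2 distances x 3
exercises x 5 held angles); the stochastic comparisons run 20 seeded trials
per exercise/view cell with LiDAR range noise of 0.02 m (the sensor's
accuracy class) and 2 px keypoint noise, angles cycling over 30–150 degrees
and distances alternating 3/4 m. Each simulated measurement casts about
2,900 rays (16 beams x 181 spin steps), yielding a few hundred returns per
measurement at 3–4 m.
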