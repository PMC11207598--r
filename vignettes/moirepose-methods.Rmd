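---
title: "Moire-marker head-pose tracking: models, conventions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moire-marker head-pose tracking: models, conventions and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(moirepose)
```

# The problem

Head motion during brain MRI corrupts images at the sub-millimetre scale of
the acquisition. Motion correction — prospective or retrospective — needs a
6-DOF head pose stream that is roughly 5–10 times more precise than the
voxel size, i.e. on the order of 0.1 mm and 0.1 degrees. `moirepose`
implements a complete, desk-scale test platform for developing such optical
tracking: a marker-based reference system whose output is accurate enough
to act as ground truth, and a markerless, learning-based prototype trained
against it. Every stage can be exercised on synthetic imagery generated by
the package itself, so the entire chain is testable without cameras,
markers, or a scanner.

# The marker and its moire physics

The fiducial marker (`marker_spec()`) is a flat plate carrying:

* a central checkerboard, used for the in-plane DOF (X, Y, roll) via planar
  PnP and for depth (Z) via stereo triangulation of its corners;
* four ArUco-style binary squares in the corners, used only to localise the
  face and identify its orientation;
* four moire grating pairs — fine and coarse for each of pitch and yaw.

A moire pair is two printed line gratings of slightly different spatial
frequency separated by a transparent substrate of thickness $d$ and
refractive index $n$. A viewing ray refracts at the front surface, so its
crossing point on the depth-separated grating shifts laterally by
$d\tan\beta$ with $\sin\theta = n\sin\beta$. The beat ("moire") pattern
therefore advances in phase under a through-plane rotation $\theta$:

$$\theta = n \, \sin\!\big(\tan^{-1}\!\big(\varphi / (2\pi f_1 d)\big)\big),$$

with $\varphi$ the beat-phase shift and $f_1$ the frequency of the
depth-separated print. `rotation_from_phase()` implements this law and
`phase_from_rotation()` its exact algebraic inverse.

Two modelling choices deserve comment:

* **Which layer is "f1".** Writing the beat of
  $\sin(2\pi f_a c)\cdot\sin(2\pi f_b (c+\delta))$ in the coordinate frame
  of the face (the frame that homography rectification restores exactly,
  because the anchors are printed on it), the phase shift is
  $2\pi f_{\text{displaced}}\,\delta$: the conversion law holds exactly
  with $f_1$ equal to the frequency of the *depth-separated* layer. The
  renderer therefore mounts the higher-frequency print of each pair
  ($f_1$ = 3 or 1.7 lines/mm) as the separated layer. With the opposite
  stacking the sensitivity would be rescaled by $f_2/f_1$ (about 6–7%);
  the stacking is a physical property of the marker, fixed here once.
* **Refractive index.** The substrate material (polycarbonate) fixes
  $n \approx 1.585$, which gives phase-wrap rotations of 3.03° (fine) and
  5.33° (coarse) for the default 10 mm substrate. $n$ is a configurable
  field of `moire_grating_pair()` because fabricated markers may differ;
  all validation uses self-consistent round trips rather than any single
  printed wrap value.

Fine and coarse channels are fused by `through_plane_rotation()`: the
coarse channel (larger wrap) fixes the integer wrap count of the fine
channel, whose angle is returned — high sensitivity over a wide dynamic
range. Channel disagreement beyond half the coarse wrap is an error, not a
guess.

# Frame analysis

`analyze_marker_frame()` runs the per-frame pipeline:

1. **Anchor detection** (`detect_aruco()`): threshold, connected
   components, convex-hull quadrilateral extraction, sub-pixel edge
   refinement (total-least-squares lines through interpolated edge
   crossings, using the per-profile mid-level so the estimate is unbiased
   by the global threshold), then decoding of the interior 4×4 code over
   all four rotations. Fewer than four anchors flags the frame occluded;
   occluded frames contribute nothing downstream.
2. **Rectification** (`rectify_marker()`): a homography from the sixteen
   anchor corners maps the face to a canonical millimetre grid
   (10 px/mm by default).
3. **Profile extraction** (`extract_moire_profile()`): the pixel lines of
   each grating region are averaged along its long edge into one 1-D
   signal, the profile coordinate always increasing along the positive
   marker axis.
4. **Phase fitting** (`fit_moire_phase()`): least squares of
   $A\sin(\omega s - \varphi) + b$ on the mean-centred profile. Numerical
   choices that matter:
   * the two printed carrier frequencies are notched out first with
     zero-phase fractional-width moving averages (the beat, two orders of
     magnitude slower, passes unattenuated) — without this the residual
     carrier leaks into the fit and biases the phase at the
     $10^{-2}$-degree level;
   * $\omega$ starts at the nominal beat frequency and is free (a
     variable-projection line search with the linear parameters solved
     exactly), absorbing print imperfections;
   * because the beat of two square waves is not sinusoidal, the odd beat
     harmonics (3rd, 5th) are included in the linear basis;
   * the phase is referenced to the profile *centre* (`phase_mid`), so
     frame-to-frame jitter of the fitted frequency does not couple into
     the phase difference; the Eq.-style phase at $s = 0$ is also
     reported;
   * a fitted amplitude below the noise floor marks the measurement
     low-confidence; a frequency running into its search bracket is an
     error carrying the residual diagnostics.

# Pose estimation

The division of labour follows the platform design: monocular planar PnP
(`solve_planar_pnp()`, homography initialisation plus Gauss–Newton on the
reprojection error) is trusted only for X, Y and roll; depth comes from
DLT triangulation (`triangulate_points()`) of the checkerboard corners
across the stereo pair (reported as the centroid displacement along the
left camera's optical axis); pitch and yaw come from the moire channels.
`fuse_pose()` assembles the six DOF with per-DOF method tags, and
`track_sequence()` runs the whole chain over paired streams relative to a
reference frame (the first non-occluded frame by convention), with
nearest-timestamp pairing (half-frame tolerance) and an optional
zero-phase frequency-domain low-pass (default cutoff 5 Hz — above the
simulated physiological band of at most 2.3 Hz; the platform's published
description filters "outside the range of measurable physiological
motion" without a number). Invalid frames are flagged, never interpolated.

The monocular through-plane instability that motivates all of this is
reproduced on the synthetic renders: under per-frame pixel noise the PnP
pitch/yaw estimates scatter one to two orders of magnitude more than the
moire estimates on the same frames (only the ordering is asserted in the
tests, since its magnitude is hardware-dependent).

# Calibration

`generate_calibration_protocol()` enumerates the 50-placement board
protocol (nine field-of-view cells × five tilts, four compound-tilt centre
placements, one final forward centre). `estimate_intrinsics()` implements
planar calibration: focal lengths are initialised from the orthonormality
constraints each board homography places on the image of the absolute
conic — with the principal point pinned to the image centre during
initialisation, a stabilising choice at this extremely narrow field of
view (about 1.5°, where the classic closed form is ill-conditioned) — and
everything (fx, fy, cx, cy, k1, k2, all board poses) is then refined by a
block Levenberg–Marquardt on pixel reprojection. Degenerate (e.g. all
fronto-parallel) view sets are refused. `estimate_stereo_extrinsics()`
averages per-view relative poses (rotations projected to SO(3)) and
jointly refines the right-to-left transform with the board poses.
`simulate_calibration_views()` generates the matching synthetic corner
observations; on noiseless data both estimators recover the generating
parameters to numerical precision, and with 0.2 px corner noise the
reprojection RMS equals the injected noise.

# Cross-calibration

`solve_rigid_transform()` is the Kabsch/Umeyama SVD solution (no scale):
centred point sets, SVD of the cross-covariance, determinant-corrected
rotation (a reflection is never returned), centroid translation. The
fiducial registration error is reported as the RMS pair distance — stated
explicitly because a residual metric is otherwise unspecified.
`preprocess_camera_points()` applies the documented gross corrections, in
a fixed order (mirror fold −90° about X, then the 180° X and Z
frame-convention rotations, then the −3000 mm Z offset), each toggleable;
removing these large known discrepancies first leaves only a small
residual transform for the solve. `repeatability()` decomposes repeated
transforms into 6 DOF (package Euler convention, stated because none is
otherwise fixed) and reports per-DOF mean, SD and maximum deviation.

One property worth noting: with three point pairs a rigid fit interpolates
most of the noise, so the *fiducial* residual grows — not shrinks — as
points are added at fixed noise. The test suite asserts this direction
(mean FRE over seeds smaller at N = 3 than N = 15); robustness to losing
redundant points is asserted separately (any non-collinear 3-subset of an
exact 15-point problem reproduces the full solution to $10^{-9}$).

# The synthetic scene

`render_marker_view()` replaces the physical rig. The planar face is
rendered by exact perspective projection (inverse ray mapping per
super-sample); the moire regions are rendered from first principles by
sampling both grating layers along the refracted ray through the
substrate, so agreement with the rotation/phase law is emergent, not
assumed. All pattern edges — gratings, checkerboard (an exact separable
box average of the ±1 square-wave product), anchor cells and the face
outline — are *area-sampled analytically* over each sample's footprint.
This matters: with point-sampled binary patterns the rendered edge
positions quantise at the sub-sample pitch, and a commanded 0.1 mm depth
step (a 0.1 px image shift) can disappear entirely. With analytic area
sampling the default 4× supersampling is only needed for the remaining
shading effects. Optional realism controls (`render_options()`): Gaussian
pixel noise, point-spread blur, illumination gradients, elliptical glare
patches, occlusion masks, background level; outputs are quantised to 8-bit
grey levels like the real cameras. `add_frame_noise()` draws fresh noise
realisations on a rendered scene, which is how 150-frame noisy
observations of a static pose are produced cheaply.

Two camera presets reproduce the platform optics: "external"
(720×480 px, 76×58 mm FOV at 3 m — a 200 mm-equivalent lens) and
"in-bore" (720×480 px, 151×112 mm FOV at about 220 mm — 6 mm lens).
`stereo_rig_preset()` mounts two external cameras 600 mm apart, toed in at
3 m (about 11° relative yaw).

`render_head_proxy()` stands in for the rendered-head environment used to
pre-train the markerless system: a procedural, seeded head — an ellipsoid
with human-plausible axes, a rigid 3-D texture (sums of sinusoids in
head-local coordinates, in two bands: broad shading variation plus
near-pixel-scale detail, because the fine band is what encodes sub-pixel
motion to a learner), compact high-contrast facial landmarks (eyes,
brows, nostrils, mouth, hairline), Lambertian shading — ray-traced
through the in-bore cameras at roughly 4.5–5 px/mm. Feature contrast was
deliberately matched to what face renders provide (a 0.1 mm pose change
moves the image by about 2 grey levels on average); an early, smoother
texture draft produced barely a third of that and made the regression
task unrealistically hard. It is
deliberately synthetic and is labelled as such: it reproduces the *scale*
and *geometry* of the learning problem (sub-pixel texture shifts under
sub-millimetre pose changes, two opposing views), not skin, expression or
shadow realism. Passing tests on it demonstrate that the training
machinery and the pose-to-image chain work; they do not demonstrate
performance on real faces.

# Motion simulation and the learning experiment

`generate_trajectory()` draws one noisy sinusoid per DOF: amplitude
1.5 mm / 1.5°, frequency uniform in [1.7, 2.3] Hz, uniform phase, 30 Hz
sampling, all six DOF varying simultaneously. The noise model is additive
white Gaussian with σ = 5% of the amplitude — a documented choice, since
"noisy" is otherwise unquantified. `make_pose_pairs()` yields consecutive
pose pairs labelled with componentwise deltas (valid in this small-angle
regime; the cumulative sum reconstructs the trace exactly).

The regression network (`hpnet_train()`) is the fixed three-block
architecture: blocks of depth 4, 16 and 64, each with two 3×3 stride-1
pad-1 convolutions with ReLU, one 20% dropout layer, and a 2×2 stride-2
max-pool; the 180×120 input falls to 22×15 after three pools (integer
floor), is flattened (21120 features) into a 128-unit ReLU layer — the
smallest head that passes the capacity (overfit) sanity test — and a
6-unit linear output.

The per-block dropout is implemented *channel-wise* (zeroing whole
feature maps), a deliberate choice among the readings of "a 20% dropout
layer per block", made for a calibration reason specific to regression:
channel masks commute exactly with max-pooling, so training-time and
inference-time activation scales agree. The two unit-wise alternatives
were implemented and measured before being rejected: between ReLU and
max-pool, the maximum of $1/(1-p)$-scaled randomly-zeroed units is biased
upward, which systematically shrinks inference-time outputs relative to
the function fitted in training (directly visible as an eval-mode loss
inflation on the training samples themselves — a regression head, unlike
a classifier, is not scale-tolerant); after the pool, the third block's
mask lands on the fully-connected input and destabilises validation at
this training budget. The engine's backward pass is verified against
finite differences in the test suite. Inputs are the four frames (two cameras × two
timepoints) stacked as channels, scaled to [0, 1] and resized bilinearly;
channel stacking (rather than width concatenation) preserves spatial
alignment between views. Labels are min-max scaled per DOF on the
training + validation sets only; the saved mapping is applied and inverted
at inference, and test isolation is guarded by a test. Training is Adam
(learning rate 1e-4, L2 weight decay 1e-5), MSE loss, Kaiming
initialisation, minibatch 32 (a conventional choice; the protocol does not
state one), fully seeded — identical seeds give bit-identical loss curves.
The engine is single-precision C++ over BLAS, with convolutions as nine
shifted GEMMs on zero-padded activations.

The proof-of-concept experiment (`hp_proof_of_concept()`) simulates a
trajectory of 2001 samples so that exactly 2000 consecutive pose pairs
exist for the 1400/400/200 split (a 2000-sample trajectory would yield
only 1999 pairs; the split sizes are taken as authoritative), renders the
seen head, trains, and evaluates per-DOF RMSE (and their unweighted mean)
on the 200 unshuffled held-out pairs and on 200 fresh pairs of a
different-seed head proxy never seen in training. The full protocol is
100 epochs; the packaged experiment defaults to 30 epochs to keep the
experiment inside a desk-scale compute budget (the problem sizes used
throughout — 150-frame benchtop averages, 2000-pair training sets,
five-trial repeatability — are stated here as the package's chosen study
conditions).

A candid note on what the scaled-down learning analogue achieves: on the
procedural proxy, the dropout-regularised protocol at the reduced epoch
budget converges noticeably more slowly than the published experiment on
realistic rendered heads, and its held-out error remains above the
published figures; the acceptance harness reports whatever the run
produces rather than a curated number. Disabling the regulariser (an
architecture probe, not the protocol) shows the remaining gap is
dominated by the regularisation-versus-budget trade-off rather than by
missing image signal. The proxy's feature statistics — periodic-ish
procedural texture rather than the aperiodic, richly detailed surfaces
of scanned heads — are the other acknowledged fidelity gap.

# Validation design

`benchtop_increment_experiment()` mirrors the physical protocol: render
the reference and the stepped pose once, then observe both under 150
fresh pixel-noise realisations and average the per-frame recovered
increments. Depth uses corner-level jitter (0.5 px) on the detected
stereo corners, matching how that experiment is specified. The published
benchtop means this analogue is compared against are 0.1 deg yaw → 0.1,
0.1 deg pitch → 0.095, 0.1 mm Y → 0.10, 0.1 mm Z → 0.11, 0.5 deg roll
→ 0.49.

`crosscal_repeatability_sim()` repeats the five-trial phantom protocol
with a fixed true residual transform (of the published magnitude), random
phantom placements, and 0.3 mm isotropic point noise on both sides; the
published repeatability bound is under 1 mm / 1 degree per DOF.

# Known limitations

* The head proxy does not model skin deformation, expression, blinking,
  shadows or camera depth-of-field; generalisation numbers on it are
  analogues, not predictions for real faces.
* Componentwise Euler deltas are only valid for small inter-frame motion
  (fine at the simulated 1.5-unit amplitudes).
* PnP through-plane components are returned but flagged unreliable by
  design; no attempt is made to stabilise narrow-FOV monocular PnP.
* The calibration stage's physical placement hardware is out of scope;
  its geometry informs the synthetic placement spread only.
* Glare removal and anti-reflective modelling are not implemented; glare
  is only simulated as an additive nuisance.
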