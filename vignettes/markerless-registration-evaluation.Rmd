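---
title: "Evaluating depth cameras for markerless patient registration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating depth cameras for markerless patient registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depthreg)
```

## The problem

In image-guided neurosurgery the preoperative MR volume must be aligned to
the patient on the table. Markerless registration does this from surface
geometry: a depth camera captures the patient's face, the captured cloud is
registered to the MR-derived face surface, and a tracked rigid body on the
camera carries that alignment into the coordinate frame of an external
optical tracking system. Whether this is accurate enough depends on the
depth camera, so the question becomes an evaluation problem: given a camera
and a registration algorithm, what fiducial registration error (FRE, on the
surface used for alignment) and target registration error (TRE, on the
clinically relevant craniotomy region) does the pipeline achieve?

`depthreg` implements that evaluation framework end to end, together with a
simulator that stands in for all the hardware — phantom head, optical
tracking volume, checkerboard, and depth cameras — so every stage can be
validated against known ground truth on a desk.

## Frame conventions

All transforms are elements of SE(3) stored as a rotation matrix plus a
translation in millimetres, acting on column vectors: `p' = R p + t`. We
write `T_{B<-A}` for the transform that re-expresses frame-A coordinates in
frame B; `compose(a, b)` applies `b` first. The frames are:

* **tracking** (`W`) — the world frame of the optical tracker,
* **camera body** (`CB`) and **board body** (`BB`) — the tracked rigid
  bodies, with poses `m_camera = T_{W<-CB}` and `m_board = T_{W<-BB}`,
* **optical** (`O`) — the camera frame in which the intrinsics define
  projection,
* **board** (`B`) — the checkerboard geometry frame (corners on z = 0),
* **patient** (`P`) — the phantom/MR frame.

The hand-eye chain uses `M = m_board^-1 ∘ m_camera` (camera body expressed
in the board body), `V = T_{O<-B}` (the classic extrinsic board pose from
PnP), and `E = T_{CB<-O}` (the fixed mount between optical centre and the
camera's rigid body). Then `M ∘ E ∘ V` maps board corners into the board
rigid-body frame and is the same transform for every capture; its inverse is
the board mount `G`. These directions are the unique assignment that makes
the chain well-formed under column-vector composition, and the zero-noise
closure test asserts them.

## Hand-eye co-registration

A calibration capture records `m_camera`, `m_board`, and the board pose `V`
estimated from detected corners. For a candidate mount `E`, every corner is
pushed through `M_i ∘ E ∘ V_i`; if `E` is right, each corner lands at the
same physical point for all captures. The objective minimised is the mean
over corners of the per-corner 3-D standard deviation across captures (root
of summed coordinate sample variances) — zero exactly at consistent
noise-free data. We map into the board-body frame rather than the tracking
frame so the objective is invariant to board motion between captures; for a
static board the two differ only by a fixed rigid map and have identical
minima.

Only the 6 degrees of freedom of `E` are searched (axis-angle + translation,
L-BFGS-B with finite differences); `G` is a deterministic function of `E`
per capture and is recovered afterwards as the quaternion-chordal mean of
`(M_i E V_i)^-1`. The objective has local minima far from the solution, so
the optimiser is started from a closed-form estimate: the consistency
condition rearranges to the classic `A X = X B` hand-eye problem
(`A = M_j^-1 M_i`, `B = V_j V_i^-1`), solved linearly in the Tsai–Lenz
fashion over capture pairs. From that start the quasi-Newton refinement
recovers a noise-free `E` to better than 1e-6 mm; from an identity start it
frequently stalls, which is why the closed form is the default.

Calibration quality is validated in the pixel domain: corners of the virtual
board are mapped through the estimated `E`/`G` chain and the tracked poses
into the optical frame, projected, and compared with the observed corners.
With ground truth on clean data this error is identically zero; a session is
conventionally accepted once the mean drops below a quarter pixel.

## Camera model and intrinsics recovery

Projection is the standard pinhole with Brown–Conrady distortion
(`k1, k2, k3, p1, p2`), image origin at the top-left pixel centre, x right,
y down. Intrinsics are recovered from several checkerboard views: per-view
homographies by normalised DLT, the closed-form absolute-conic constraints
for `fx, fy, cx, cy`, then joint Levenberg–Marquardt refinement
(`minpack.lm`) of intrinsics, distortion and all per-view poses against the
total squared reprojection error. Skew is fixed to zero in refinement. The
default simulated protocol mirrors a practical acquisition recipe: eight
views as four tilts at each of two depth planes, placed so the board reaches
toward the sensor edges. Board pose for a single view (`V`) comes from the
undistorted-plane homography decomposition followed by LM refinement of the
6 pose parameters.

With noise-free corners the recovered focal length is exact to well below
0.1 px; with corner noise σ the mean reprojection error settles near
σ·√(π/2) (the mean of a 2-D Gaussian radius), slightly deflated by the
fitted parameters — the tests assert a ±30% envelope around σ = 0.2 px.

## Surface registration

Registration of a captured face cloud to the MR face runs in three stages:

1. **Global initialisation (RANSAC).** Triplets of well-separated source
   points are matched to target triplets by pairwise-distance compatibility
   (a rotation-invariant descriptor) and fitted by the closed-form Kabsch
   solution. Candidates are batch-scored by inlier votes against a single
   kd-tree of the target. Because a smooth, partly symmetric face yields
   many high-vote impostors (including near-180° flips), a diverse set of
   top candidates — always including the four proper principal-axes
   alignments, one of which lies in the true basin by construction — is
   polished with a short coarse ICP and re-scored at a tight tolerance;
   alignment quality, not raw vote count, picks the winner. Deterministic
   per seed.
2. **Coarse ICP** on the voxel-downsampled source (default 5 mm, matching
   the evaluation's working voxel size) against the full-resolution target.
3. **Full-resolution point-to-point ICP**: alternate nearest-neighbour
   correspondence with rejection beyond the current tolerance (10 mm,
   halving every 15 iterations to a 2 mm floor) and closed-form rigid
   refitting. Within each iteration the least-squares step cannot increase
   the RMSE of its own correspondence set — that descent guarantee is
   recorded per iteration and asserted by the tests. Trimmed re-matching
   between iterations can legitimately change the inlier set, so
   convergence is declared when the tolerance has annealed to its floor and
   the RMSE improvement falls below 1e-12 mm.

Nearest-neighbour search is a hand-written 3-d kd-tree in C++ with
lowest-index tie-breaking, verified to agree exactly with an exhaustive
scan.

## Evaluation protocol and metrics

The benchmark reproduces a two-stage clinical protocol. At the
*registration stage*, the camera is placed at 10 positions facing the face
(standoff ≈ 44 cm) and takes 5 captures per position. Each capture is
registered to the MR face and chained into the tracking frame through the
tracked camera pose and the mount `E`; the position's estimate is the
quaternion-chordal mean of its 5 capture transforms. The position FRE is
the surface RMSE between the pooled captures (in the tracking frame) and
the MR face mapped by the position's mean transform, restricted to
overlapping points (nearest-neighbour distance within 5 mm). Positions with
overlap below 95% are excluded; the patient registration carried forward is
the mean transform over surviving positions. At the *testing stage*, 10
further placements face the craniotomy (standoff ≈ 45 cm); captures are
expressed in the registered patient frame, both capture and MR cloud are
cropped by the craniotomy bounding box expanded by a 10 mm margin, and the
TRE is the same overlap-restricted RMSE, with the same gate. An
all-excluded configuration is reported as such ("Overlay < 95%"), not as an
error.

The manual baseline is the fiducial-marker route: 8 markers on the phantom,
half used to fit the rigid alignment (their post-fit RMSE is the FRE), half
held out (their RMSE under that alignment is the TRE). Held-out error
dominates fitted error in expectation, which the tests verify over 500
noisy replicates.

Key tunable parameters, all config-exposed with these defaults: overlap
tolerance 5 mm (equal to the registration voxel size; the source material
for this framework does not state one), overlap threshold 0.95, ROI margin
10 mm, voxel 5 mm, ICP cap 100 iterations, tracking jitter 0.05° / 0.15 mm.
Aggregation is over positions (n = 10 per stage), each via its mean
transform, not over pooled captures.

## The simulator

The simulator provides ground truth for every stage.

* **Phantom head.** A parametric surface: an egg-cross-section cranium
  (flatter face side, rounder occiput) with a vertical width profile tuned
  to a bigonial width of 118 mm, a wedge nose of 50 mm length and 35 mm
  alar base, and facial relief (eye sockets, brow, flattened forehead,
  cheekbones, temple hollows, mouth, chin). Relief matters: a smooth
  quasi-ellipsoidal face is nearly registration-degenerate under
  point-to-point ICP. A circular craniotomy patch (default 70 mm diameter)
  on the parietal surface is recessed by up to 4 mm, labelled, and boxed;
  8 fiducials are spread by farthest-point sampling. The surface is sampled
  by *seeded uniform random draws*, deliberately not on a grid, ring or
  quasi-regular spiral: any (quasi-)lattice aliases under rotations of one
  lattice period, creating spurious ICP minima about 1.5° from truth that
  we observed directly with ring and Fibonacci-spiral sampling. Everything
  is deterministic per seed.
* **Tracking jitter** perturbs a pose by a random-axis rotation with angle
  ~ N(0, σ_rot) and an isotropic N(0, σ_trans) translation.
* **Calibration sessions** place the board with random tilt and the camera
  on a 380–620 mm standoff, rejection-sampling until all corners are inside
  the frustum; exact `M` and `V` follow from the ground-truth `E`, `G`,
  after which tracking jitter and corner noise are applied and `V` is
  re-estimated from the noisy corners exactly as in a real session.
* **Depth captures** cull by working range and outward-normal orientation,
  remove hidden surface via a z-buffer over a virtual 640×480 grid, then
  apply axial (along-ray) noise, lateral jitter, i.i.d. dropout and
  optional depth quantisation.
* **Presets.** Seven named presets mirror the five commercial cameras and
  two feature toggles evaluated by the framework. Their depth ranges follow
  the manufacturers' specifications; the noise magnitudes are this
  package's own estimates of the technology classes (textured stereo,
  untextured stereo, structured light) — no sensor noise figures were
  available to copy. They are data, not code: the registry round-trips
  through YAML. The untextured configurations (`d435f-no-projector`,
  `oak-d`, `zed-m`) carry axial noise of 5–6 mm and heavy dropout, which is
  what makes them fail the 95% overlap gate while their textured or
  refined counterparts pass — the exclusion *pattern* is reproduced in
  kind, not in quantitative error values.

## What the simulator does and does not show

Passing on the simulator demonstrates the mathematics and the pipeline: the
frame chain closes exactly at zero noise (pose recovered to 1e-6 mm, FRE =
TRE = 0), estimators track injected noise levels, the exclusion gate and
protocol counts behave as specified, and TRE degrades monotonically with
axial noise. It does not demonstrate performance on real sensors: real
depth error is structured (textureless patches, edge bleeding, multipath),
corner detectors have biases, phantom surfaces have texture and specularity
the simulator omits, and the published per-camera error values were
measured on physical hardware. Quantitative agreement with those values is
out of reach by design; the framework is judged on its verifiable
properties.

## Numerical choices and degenerate inputs

* Rotations are stored as matrices; unit quaternions are used only for
  averaging (chordal mean via the dominant eigenvector of the sign-aligned
  outer-product sum; for the sub-degree spreads among repeat captures this
  agrees with the iterative Karcher mean far below 0.01°). Antipodal
  rotation sets raise an error rather than returning an arbitrary mean.
* `rigid_fit` rejects reflections by the determinant sign correction and
  refuses collinear sources (second singular value test). Composition
  re-orthonormalises if drift exceeds 1e-12.
* The `acos`-based geodesic rotation distance has a measurement floor near
  zero of about 1e-6 degrees (square-root loss of precision at
  `acos(1 - eps)`); exactness tests therefore also compare rotation
  matrices elementwise.
* LM refinements stop at `ftol` 1e-14/1e-15 or 200 iterations; the hand-eye
  L-BFGS-B at `factr = 10` with parameter scaling (0.02 rad / 5 mm).
* Closed PLY conventions: binary little-endian doubles so write-read cycles
  are bit-exact; big-endian files are refused loudly.
* Problem sizes used by the shipped tests and the acceptance script —
  phantom spacing 2.5 mm (~13k points), 15-capture sessions, 10×5 benchmark
  protocol, 100-trial (tests) / 50-trial (script) jitter replicates,
  12–20-seed noise-monotonicity replicates — were chosen as the smallest
  sizes at which the measured properties are stable.

## Known limitations

* Point-to-point ICP only; point-to-plane and colour/feature-augmented
  variants are out of scope, as is any learned registration backend — the
  `registration_backend()` seam accepts external ones but none is bundled.
* The RANSAC initialiser is tuned for head-scale clouds (its minimum
  triplet separation adapts to cloud extent but its tolerances are in mm).
* The simulator abstracts sensor physics into four noise knobs; it cannot
  rank real cameras, only validate the evaluation machinery.
* Corner *detection* is not implemented: the framework consumes detected
  corner coordinates, as the simulator produces them directly.
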