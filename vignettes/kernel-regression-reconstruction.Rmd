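---
title: "Freehand 3D ultrasound reconstruction by local kernel regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Freehand 3D ultrasound reconstruction by local kernel regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusrecon)
```

## The problem

Freehand 3D ultrasound assembles a volumetric image from ordinary 2D
B-scans acquired with a tracked, freely moved probe. Each frame carries a
rigid pose (rotation + translation) placing its pixels in a common world
frame. Because the sweep is irregular, mapping pixels into a voxel grid
leaves two artifacts: *collisions* (several samples landing in one voxel)
and *holes* (voxels no sample reaches). The package implements the
standard two-stage answer for annular soft-tissue targets such as the
anal sphincter complex, where wall thickness at clock positions is the
clinically reported quantity:

1. **Bin-filling** (`bin_fill()`): each sample is deposited into the
   voxel whose center is nearest; collisions are averaged.
2. **Kernel-regression hole-filling** (`reconstruct_volume()`): each
   remaining empty voxel is estimated by a Gaussian-weighted local
   polynomial fit over the filled voxels of its surrounding cube.

## Observation model and estimator

Binned voxel values are treated as noisy observations of an underlying
intensity field \(f\):

\[ A_l = f(Y_l) + \delta_l, \qquad l = 1, \dots, O, \]

with \(Y_l \in \mathbb{R}^3\) the voxel-center position, and
\(\delta_l\) independent zero-mean noise. Around a query point \(Y\)
(an empty voxel's center) the field is expanded to first order,
\(f(Y_l) \approx g_0 + \sum_{t=1}^3 g_t (Y_{lt} - Y_t)\), and the
coefficients are fitted by weighted least squares:

\[ \min_{g} \sum_l B_l \Big( A_l - g_0 - \sum_{t=1}^3 g_t (Y_{lt} - Y_t) \Big)^2,
   \qquad B_l = \exp\!\Big( -\tfrac{1}{2} \big\| (Y_l - Y)/M \big\|^2 \Big). \]

In matrix form, with design \(E\) (a column of ones plus the three
coordinate differences), diagonal weights \(W\), and neighbour values
\(Z\):

\[ \hat\lambda = (E^\top W E)^{-1} E^\top W Z, \qquad
   \hat V_E = \hat\lambda_0, \]

i.e. the voxel estimate is the *fitted intercept*. The Gaussian kernel's
normalising prefactor is omitted: it multiplies both \(E^\top W E\) and
\(E^\top W Z\) and cancels in the ratio. Order 0 drops the slopes and
reduces to the Gaussian-weighted mean, a convex combination of the
neighbour values.

The local-linear form has one property this package leans on throughout
its tests: it reproduces any affine field *exactly* at the query point
whenever the neighbour geometry identifies all three slopes. This is
what makes correctness checkable to floating-point precision without
any reference dataset.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `ksize` | 3 voxels | side of the cubic search neighbourhood; even sides span `-k/2 .. k/2-1` per axis (floor-centred), odd sides are symmetric |
| `bandwidth` (M) | `ksize * spacing / 4` mm | Gaussian length scale; the default puts ~2 standard deviations at the cube edge; a length-3 vector gives per-axis anisotropy |
| `order` | 1 | polynomial order of the local fit (0 = weighted mean) |
| `min_neighbors` | 8 (order 1), 1 (order 0) | minimum filled neighbours before fitting; order 1 needs at least 4 for identifiability, 8 is a conservative over-determination margin |
| `ridge` | 1e-10 | non-negative term added to the slope block of the normal-matrix diagonal (never the intercept) |
| `fallback` | `"order0"` | handling of unsupported/degenerate voxels; also `"expand_once"` (one retry with the cube grown by a voxel per side) and `"leave_empty"` |

Larger `ksize` fills wider gaps at cubically growing cost and stronger
smoothing; the bandwidth controls how quickly influence decays inside
the cube.

## Numerical choices

* **Voxel assignment** rounds half up per axis
  (`floor((p - origin)/spacing + 0.5)`), fixed so results are bit-exact
  and order-independent. Voxel indices are 0-based: voxel `v`'s center
  is `origin + v * spacing`.
* **Bin averaging** sorts samples by voxel and sums residuals about a
  per-bin reference value, so the mean is independent of sample order to
  the last bit and exactly equals `c` when every contributor has value
  `c`.
* **Degenerate geometry.** An order-1 system whose normal matrix has
  reciprocal condition below `sqrt(.Machine$double.eps)` is treated as
  degenerate and routed to the fallback. This matters for *coplanar*
  neighbour sets (common beside missing-frame slabs and volume faces):
  the out-of-plane slope is then unidentifiable, and any finite answer
  absorbs part of it into the intercept, biasing the estimate by the
  field gradient times the plane offset. A tiny ridge cannot repair
  identifiability — it only hides it — so such voxels are better served
  by the order-0 fallback, which is gradient-blind but unbiased for
  locally symmetric neighbourhoods. In practice the observed condition
  spectrum is sharply bimodal (healthy systems sit orders of magnitude
  above the cut), so the threshold is not delicate.
* **Order-0 clamping.** The weighted mean is mathematically confined to
  `[min(Z), max(Z)]`; the implementation clamps it there so roundoff can
  never leak outside the neighbour range.
* **Single pre-pass read.** All empty voxels are estimated from the
  original filled mask only — no progressive filling — so estimates are
  independent of visit order and any parallel partition over empty
  voxels would produce identical output. The compiled
  (RcppArmadillo) and reference R engines implement the same
  arithmetic and are tested against each other voxel for voxel; the
  reference engine is itself tested against a brute-force
  normal-equations oracle that forms \(E^\top W E\) explicitly.

## The sweep simulator

`simulate_sweep()` emulates a tracked acquisition over a closed-form
phantom: exact per-frame rigid poses along a `linear_z` (parallel
planes) or `fan` (planes rotated about a pivot axis) trajectory, pixel
values equal to the field at the pixel's world position plus i.i.d.
Gaussian noise of standard deviation `noise_sigma`, and a noise-free
ground-truth volume sampled at voxel centers. `drop_frames()` removes a
seeded random subset of frames to create the holes the regression stage
must fill.

The default study phantom is an annular tube with inner radius 5 mm,
outer radius 8 mm (a 3 mm wall), wall intensity 100 over background 0 —
a sphincter-like ring at the mm scale of endoanal ultrasound. Study
conditions used by the test suite and the acceptance script: 64 frames
of 32x32 pixels at 1 mm spacing, 0.5 mm frame step, a 32^3-voxel grid
at 1 mm spacing, 30% frames dropped, and noise levels
\(\sigma \in \{0, 1, 2, 4\}\) with 5 replicate seeds. These sizes keep a
full pipeline run under a second while leaving thousands of holes to
fill; affine-reproduction checks use a voxel-aligned sweep (frame step
equal to the voxel spacing) so that bin averaging is exact and the
residual isolates the regression stage.

What the simulator deliberately does **not** model: speckle and its
Rayleigh statistics, attenuation, shadowing, refraction, tissue
deformation, and tracker pose error. Passing tests therefore certify
the geometry, compounding and estimation machinery — not robustness to
ultrasound physics. On real data, pose jitter and speckle would inflate
errors in ways these phantoms cannot show.

## Clock-position thickness

`clock_thickness()` mirrors the clinical protocol of measuring
sphincter wall thickness at the 12, 3, 6 and 9 o'clock directions on an
axial plane. Convention (the clinical literature rarely states one, so
it is fixed here explicitly): 12 o'clock is the in-plane +y world axis,
3 o'clock +x, 6 o'clock -y, 9 o'clock -x. A ray from the user-supplied
center is sampled by bilinear interpolation at a fixed step (default
0.25 mm); thickness is the length of the first above-threshold run.
Empty voxels read as background so holes never masquerade as wall. The
threshold defaults to the midpoint of the plane's intensity range —
the simplest auditable segmentation rule; plane selection (proximal /
mid / distal) is left to the user.

```{r example, eval = FALSE}
spec <- phantom_spec("annulus_tube", center = c(15.5, 15.5),
                     r1 = 5, r2 = 8, wall = 100, background = 0)
cfg <- sweep_config(n_frames = 64, frame_dims = c(32, 32), step = 0.5,
                    noise_sigma = 1, seed = 17)
sw <- simulate_sweep(spec, cfg)
vol <- bin_fill(frames_to_cloud(drop_frames(sw$frames, 0.3, 17)), sw$grid)
rec <- reconstruct_volume(vol, kernel_params(ksize = 3, order = 1))
compare_volumes(rec, sw$truth)
clock_thickness(rec, plane = 16, center = c(15.5, 15.5),
                threshold = 50, step = 0.25)
```

## Limitations

* Holes wider than the `ksize` cube (after one optional expansion) are
  left to the order-0 fallback or empty; there is no iterative
  multi-pass refilling.
* The estimator smooths: sharp boundaries (the checker phantom is the
  worst case) are blurred over roughly a bandwidth.
* Poses are taken as ground truth; probe calibration and tracking error
  estimation are out of scope.
* No GPU path is provided; the single-pass design keeps the estimates
  partition-independent, so a parallel implementation must be
  bit-compatible with the serial one.
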