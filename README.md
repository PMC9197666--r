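# fusrecon

Freehand 3D ultrasound reconstruction by local kernel regression, with a
synthetic sweep simulator and a clock-position wall-thickness utility
for annular structures such as the anal sphincter complex.

Freehand 3D ultrasound builds a volume from tracked 2D B-scans: every
frame carries a rigid pose placing its pixels in a world frame. Because
the sweep is irregular, depositing pixels into a voxel grid leaves some
voxels with several samples (averaged) and others with none (holes).
`fusrecon` fills the holes by Gaussian-weighted local polynomial
regression: treating binned voxels as observations
`A_l = f(Y_l) + δ_l`, each empty voxel at `Y` is estimated from the
filled voxels of its surrounding `ksize³` cube by weighted least
squares

```
min_g  Σ_l B_l (A_l − g₀ − Σ_t g_t (Y_lt − Y_t))²,
B_l = exp(−‖(Y_l − Y)/M‖² / 2),
```

equivalently `λ̂ = (EᵀWE)⁻¹ EᵀWZ`, and the voxel estimate is the fitted
intercept `V̂ = λ̂₀`. The order-1 fit reproduces affine intensity fields
exactly, which the test suite exploits to verify the whole pipeline to
floating-point precision. A compiled (RcppArmadillo) voxel loop and a
pure-R reference engine implement identical arithmetic and are tested
against each other and against a brute-force normal-equations oracle.

The package is aimed at people prototyping freehand compounding and
hole-filling methods: everything is seeded, single-pass (estimates read
only the pre-pass fill mask, so results are independent of visit
order), and checkable against closed-form phantoms.

## Worked example

Simulate a noisy tracked sweep over a sphincter-like ring (inner radius
5 mm, outer radius 8 mm — a 3 mm wall), drop 30% of the frames, bin,
reconstruct, and measure:

```r
library(fusrecon)

spec <- phantom_spec("annulus_tube", center = c(15.5, 15.5),
                     r1 = 5, r2 = 8, wall = 100, background = 0)
cfg <- sweep_config(n_frames = 64, frame_dims = c(32, 32), step = 0.5,
                    noise_sigma = 1, seed = 17)
sw  <- simulate_sweep(spec, cfg)
vol <- bin_fill(frames_to_cloud(drop_frames(sw$frames, 0.3, 17)), sw$grid)
vol
#> recon_volume: 34 x 34 x 35 voxels, 29696 filled (73.4%)

rec <- reconstruct_volume(vol, kernel_params(ksize = 3, order = 1))
fill_report(rec)[1:3]
#> $filled_by_kr
#> [1] 4096
#> $fallback_filled
#> [1] 6668
#> $left_empty
#> [1] 0

compare_volumes(rec, sw$truth)
#> metrics: rmse 4.04343, mae 1.16712, psnr 27.86 dB (peak 100), fill 100.0%, n = 40460

clock_thickness(rec, plane = 16, center = c(15.5, 15.5),
                threshold = 50, step = 0.25)
#> clock thickness on plane 16 (threshold 50, step 0.25 mm):
#>   direction thickness_mm found
#> 1        12         2.75  TRUE
#> 2         3         2.50  TRUE
#> 3         6         3.00  TRUE
#> 4         9         3.00  TRUE
```

Reading the output: bin-filling reaches 73% of the grid; kernel
regression fills 4096 voxels from well-conditioned local fits, the
order-0 fallback covers the rest (voxels whose neighbours cannot
identify a gradient, e.g. beside missing-frame slabs). Against the
noise-free ground truth the reconstruction has RMSE ≈ 4 intensity units
(on a 0–100 ring), and the measured wall thickness at the four clock
positions brackets the analytic 3 mm within the sampling noise of a
σ = 1 acquisition. At σ = 0 all four directions read exactly 3.0 mm.

A command-line front end over the same functions is installed at
`system.file("cli", "fusrecon", package = "fusrecon")`, with
subcommands `simulate`, `binfill`, `reconstruct`, `evaluate` and
`measure` operating on MetaImage (MHD+RAW) volumes and CSV pose tables.

See the vignette (`vignettes/kernel-regression-reconstruction.Rmd`) for
the model, parameter meanings, numerical choices and limitations.

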