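# topoivim

Voxelwise estimation of intravoxel incoherent motion (IVIM) parameters from
diffusion-weighted MRI, for researchers who need stable perfusion maps —
above all a usable pseudo-diffusion coefficient D*, the parameter that
conventional fitters estimate so erratically that it is often discarded.

## The model and the method

IVIM decomposes the diffusion-weighted signal of a voxel into tissue
diffusion and capillary pseudo-diffusion:

S(b)/S0 = f·exp(−b·D*) + (1−f)·exp(−b·D),

with perfusion fraction f, diffusion coefficient D and pseudo-diffusion
coefficient D* (mm²/s; b in s/mm²). The model is symmetric under swapping
the compartments and nearly flat in D* whenever f is small, so its residual
surface has symmetric basins and long valleys of near-equivalent solutions
— the root cause of unstable D* maps.

The core fitter attacks this in two levels:

1. **Level 1 — variable projection.** The compartment weights are linear
   and are eliminated in closed form under the sum-to-one constraint,
   leaving a better-conditioned *reduced* functional over (D, D*) only.
   This reduced surface is minimized globally by a simplicial-homology
   optimizer: low-discrepancy sampling of the search box, Delaunay
   triangulation of the samples, extraction of the *minimizer pool* (every
   vertex dominating its neighbours marks a locally convex star domain that
   contains a stationary point), bound-constrained derivative-free
   refinement within each star, and sample doubling until the pool
   cardinality is invariant. All minima — not just the best — are retained,
   which is how bimodal voxels are recognized rather than silently
   mis-fitted.
2. **Level 2 — penalized refinement.** The full three-parameter functional
   is refined around the Level-1 solution; voxels classified as
   low-perfusion (f ≤ 0.2) receive the physical penalty λ·(D*)², weighted
   by the Level-1 misfit so it vanishes on clean data and selects the
   minimal physically plausible D* inside a noise-flattened valley.

The package also provides the reference fitters used for comparison
(segmented two-stage fitting, Bayesian random-walk Metropolis with a flat
prior, bounded Levenberg-Marquardt least squares), a Shepp-Logan digital
phantom with six tissue classes, analytic multi-coil sensitivities and
sum-of-squares chi noise at controlled per-slice SNR, an evaluation harness
(range-normalized RMSE, alternating-b-value test-retest with Pearson
reliability), NIfTI/bval I/O and a command-line interface. See the methods
vignette (`vignettes/topoivim-methods.Rmd`) for the algorithmic details and
design rationale.

## Worked example

Fit a single voxel lying in the classic bimodal regime (f = 0.349 with
well-separated rates):

```r
library(topoivim)

scheme <- make_bvalues(54)                       # 0-1000 s/mm2
truth  <- ivim_params(0.349, 0.001, 0.04)
y      <- voxel_signal(ivim_signal(truth, scheme), scheme)

fit <- fit_voxel_topopro(y, topopro_config())
fit
#> voxel fit: f = 0.3490, D = 1.000e-03, D* = 4.000e-02 (residual 4.247e-16)
```

The printed line is the canonical estimate (D* ≥ D): the generating values
are recovered to four digits and the residual is at numerical zero.
On the same voxel a bounded Levenberg-Marquardt fit started on the
symmetry ridge D = D* stalls at a mono-exponential fit with a residual
orders of magnitude larger — the instability the two-level scheme removes.

Simulate a phantom slice and benchmark two fitters against ground truth:

```r
ph  <- make_phantom(phantom_spec(shape = c(32, 32, 1),
                                 bvalues = make_bvalues(27),
                                 snr_per_slice = Inf, seed = 4))
rep <- run_benchmark(ph, methods = c("topopro", "segmented"))
rep[, c("method", "parameter", "nrmse")]
#>      method parameter        nrmse
#> 1   topopro         f 3.426562e-08
#> 2   topopro         D 1.049041e-08
#> 3   topopro     Dstar 4.469551e-08
#> 4 segmented         f 2.483739e-02
#> 5 segmented         D 4.689094e-03
#> 6 segmented     Dstar 1.344389e+00
```

`nrmse` is the RMSE of each fitted map against the simulated truth over the
tissue mask, normalized by the ground-truth range. On this noiseless slice
the topological fitter is exact to optimizer precision for every parameter,
while the segmented baseline already misestimates D* badly (its two-stage
construction pins D* of no-perfusion fluid voxels at the tissue diffusion
rate).

## Command line

```sh
topoivim simulate --nx 64 --ny 64 --slices 1 --bvalues 27 --snr 10 --seed 7 --out phantom/
topoivim fit --dwi phantom/dwi.nii.gz --bvals phantom/dwi.bval \
             --mask phantom/labels.nii.gz --method topopro --out maps/
topoivim evaluate --est maps/ --gt phantom/ --out metrics.csv
topoivim retest --dwi phantom/dwi.nii.gz --bvals phantom/dwi.bval --out retest.csv
```

The shim lives at `inst/cli/topoivim` (installed under
`system.file("cli", "topoivim", package = "topoivim")`).

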