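---
title: "Topological two-level IVIM fitting: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological two-level IVIM fitting: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topoivim)
```

## The model and why it is hard to fit

Intravoxel incoherent motion (IVIM) imaging decomposes the diffusion-weighted
MR signal of a voxel into two Gaussian compartments: tissue water diffusing
with coefficient $D$, and capillary blood whose randomly oriented flow looks
like a fast pseudo-diffusion process with coefficient $D^* \gg D$. With
perfusion volume fraction $f$, the normalized signal at diffusion weighting
$b$ (s/mm$^2$) is

$$\frac{S(b)}{S_0} = f\,e^{-b D^*} + (1-f)\,e^{-b D}.$$

Estimating $(f, D, D^*)$ per voxel is a separable nonlinear least-squares
problem with two well-known pathologies:

* **Swap symmetry.** The model is invariant under
  $(f, D, D^*) \to (1-f, D^*, D)$, so the residual surface always has (at
  least) two symmetric basins. When $D$ and $D^*$ approach each other the
  basins merge into a ridge on which $f$ is unidentifiable.
* **Flat valleys.** When $f$ is small, the perfusion compartment carries a
  few percent of the signal and the residual is almost constant along wide
  ranges of $D^*$: a valley of near-equivalent solutions. Local optimizers
  terminate anywhere in the valley, which is what makes $D^*$ maps
  notoriously unstable.

## Variable projection (Level 1)

For fixed rates $s = (D, D^*)$ the model is linear in the compartment
weights. Writing the two basis columns $\varphi_1 = e^{-b D^*}$,
$\varphi_2 = e^{-b D}$ and enforcing the sum-to-one constraint exactly, the
weight estimation reduces to the scalar least-squares problem
$y - \varphi_2 = (\varphi_1 - \varphi_2) f$, solved in closed form and
clipped to $[0, 1]$ (`project_linear()`). Substituting the solution back
gives the *reduced functional* over only the two rates
(`reduced_residual()`); its minimization is Level 1. The reduced surface is
better conditioned than the full three-parameter surface, and it is what the
global optimizer explores. When the two columns coincide ($D = D^*$, the
symmetry axis), $f$ is unidentifiable; the projection returns $f = 0$ with a
degeneracy flag rather than an error, since the point is merely the
boundary between the two symmetric charts.

## The simplicial-homology global optimizer

The reduced functional is minimized with a derivative-free global method
(`shgo_minimize()`):

1. **Sampling.** The box is covered by its $2^n$ corners plus a
   Cranley-Patterson-shifted Halton sequence (`sample_domain()`). A
   low-discrepancy set needs far fewer points than uniform sampling for the
   same coverage; the shift is the only use of the seed, so runs are exactly
   reproducible, and the sequence is nested so that doubling the sample
   reuses every earlier point. Halton (bases 2, 3, 5) was chosen as the
   package's low-discrepancy generator; corners guarantee that the convex
   hull of the samples is the whole box.
2. **Triangulation.** The samples are Delaunay-triangulated by Bowyer-Watson
   insertion (`build_complex()`), in coordinates normalized to the unit box
   so the complex is invariant to per-axis rescaling. Because the corner
   points are always present, the triangulation is bootstrapped from an
   exact decomposition of the box, which makes the simplices tile the domain
   exactly (their volumes sum to the box volume to floating precision).
   Degenerate configurations are retried with a deterministic jitter.
   The triangulation of a given point pattern is cached, so fitting a whole
   volume triangulates once and only re-evaluates objective values — this,
   not the optimizer mathematics, is what makes whole-volume fits fast. A
   consequence is that the sampling pattern is a property of the
   configuration seed, not of the voxel; every stage downstream is
   deterministic, so per-voxel seeds would have nothing to randomize.
3. **Minimizer pool.** A vertex whose value is $\le$ all of its neighbours'
   values marks a locally convex sub-domain (its *star*: the simplices
   containing it) that contains a stationary point. Equal-valued adjacent
   candidates on plateaus are merged into one representative per connected
   component, so valley-shaped surfaces do not flood the pool.
4. **Refinement.** Each pool vertex is refined by a bound-constrained
   Nelder-Mead descent (`local_refine()`, value tolerance $10^{-8}$, 500
   iterations, candidates clipped into the box) inside the bounding box of
   its star. If the refined point presses against an interior star face —
   the star only grazed a basin — refinement continues under the global
   bounds, so several pool vertices in one basin collapse onto the same
   minimum. Refined minima within $10^{-3}$ of each other (per dimension,
   relative to the bounds width) are merged.
5. **Invariance stopping.** The sample size is doubled and the pipeline
   repeated until the pool cardinality is unchanged across one doubling and
   the best value stops improving ($<10^{-10}$), with a hard cap of 4
   rounds. The incumbent then receives one tight polish (tolerance
   $10^{-14}$): flat valleys need a far smaller value tolerance than the
   pool-stage refinements to localize the argument precisely.

The sanity contract for the optimizer is checked against brute force: on
seeded 2-D reduced functionals its best point matches a $400 \times 400$
dense grid search within one grid cell, and on analytic test surfaces
(double well, convex bowl) the deduplicated pool cardinality plateaus at the
true number of minima.

## Level 2: penalized full-functional refinement

Level 1's rates and projected fraction initialize a second minimization,
now of the full three-parameter residual over a box centred on the
initialization (half-width `level2_box_fraction` = 0.5 of each global
bound's width, intersected with the global bounds). Level 2 runs a single
sampling round of the same optimizer: the sample-doubling invariance rule
earns its keep on the global Level-1 surface, not on a refinement box
seeded at the optimum, and the final polish supplies the precision. In the low-perfusion
regime the objective is augmented with the physical penalty

$$g(x) = \lambda_{\mathrm{eff}}\, (D^*)^2 \quad \text{when } f \le 0.2,$$

which selects the physically minimal pseudo-diffusion rate among the
near-equivalent valley solutions. Four design choices here deserve
explanation, because each one was forced by an identifiable failure mode:

* **Noise-adaptive weight.** The penalty enters with
  $\lambda_{\mathrm{eff}} = \lambda \cdot r_1$, where $r_1$ is the Level-1
  misfit (a proxy for the voxel's noise power). A fixed weight on the
  squared-signal scale cannot work at both ends: it measurably biases $D^*$
  on noiseless or high-SNR voxels (where the valley is shallow but real
  curvature exists), yet is inert against noise-driven valley excursions at
  low SNR. Tying the weight to the misfit makes the penalty vanish exactly
  when the data suffice to determine $D^*$ and act at the scale of the
  noise-equivalence class when they do not. The default $\lambda = 10$
  makes $\lambda_{\mathrm{eff}} (D^*)^2$ at the top of the default $D^*$ box
  comparable to the residual's sampling fluctuations, i.e. decisive within
  the valley, undetectable outside it.
* **Classification is decided per voxel, not per candidate.** If the
  condition $f \le 0.2$ were re-evaluated on every Level-2 candidate, the
  optimizer would park just above the threshold with an arbitrarily large
  $D^*$ and evade the penalty (observed empirically as a cluster of fits at
  $f = 0.2 + \varepsilon$). Instead a voxel is classified low-perfusion
  once, when **either** of two stable estimates says so: the Level-1 VarPro
  fraction (reliable on fast-decaying fluid voxels) or a high-$b$
  log-linear fraction (reliable on tissue voxels, where the fluid estimate
  is reliable and vice versa — the two fail in complementary regimes). If
  an unpenalized fit nevertheless lands at a perfusion fraction within
  0.05 of the threshold, the optimizer is restarted once with the penalty
  active; the margin mirrors the regime in which the penalty is guaranteed
  not to move a well-determined fit.
* **Chart normalization.** The reduced functional is exactly symmetric
  under $(D, D^*) \to (D^*, D)$ with $f \to 1 - f$, so every Level-1
  minimum is first mapped to the physical chart $f \le 0.5$; otherwise a
  low-perfusion voxel could present itself in the swapped chart and dodge
  classification. Outputs are canonicalized to $D^* \ge D$; fits whose
  canonical fraction reaches $f \ge 0.9$ are collapsed to the
  mono-exponential convention $(f, D, D^*) = (0, \hat{D}^*_{\mathrm{dom}}, 0)$
  with a degeneracy flag, because a two-compartment label on a
  one-compartment curve is pure chart arbitrariness (this matches the
  fluid-class convention of the phantom's ground truth).
* **Sub-domain choice.** When Level 1 finds several minima, the one seeding
  Level 2 is the one with the lowest *penalized* value. The unpenalized
  global minimum of a noisy low-perfusion voxel routinely sits at a
  spurious large $D^*$; choosing by penalized value picks the physically
  meaningful basin.

Level 2 accepts its refinement only if it improves the penalized objective
relative to the initialization, and always reports the unpenalized residual.
Note one deliberate asymmetry: with the penalty disabled the Level-2
residual can never exceed the Level-1 residual, but with an active penalty
the refined point trades a (noise-level) residual increase for a large
$D^*$ reduction — that trade is the entire point of the penalty, so a
strict unpenalized-residual monotonicity cannot hold simultaneously.

## Magnitude noise floor

The phantom (and any multi-coil acquisition combined by sum of squares)
produces magnitudes with $\mathbb{E}[M^2] = S^2 + 2 N_c \sigma^2$. At SNR 10
with 8 coils this floor is comparable to the high-$b$ tissue signal, and a
bi-exponential fitted to raw magnitudes converges to a "floor fit" (a
near-zero rate compartment absorbing the offset) for *every* method, the
global optimizer most reliably of all. The volume drivers therefore
estimate the floor per slice from signal-free background voxels — in
expectation the background mean of $M^2$ *is* $2 N_c \sigma^2$, no separate
knowledge of $N_c$ or $\sigma$ needed — and subtract it in the power domain,
$\tilde S = \sqrt{\max(M^2 - \widehat{2 N_c \sigma^2}, 0)}$, identically for
every fitting method (`noise_floor = "auto"`; disable with `"none"`).
Slices without usable background are left untouched.

## The digital phantom

`make_phantom()` emulates a multi-coil IVIM acquisition of the classic
ten-ellipse Shepp-Logan head:

* **Geometry and classes.** The ellipse set is rasterized by analytic
  point-in-ellipse tests and painted in order into six tissue classes
  (normal tissue, infiltrating tumor, low-perfused tumor, high-perfused
  tumor, cavity, CSF); the ellipse-to-class binning is the table
  `.shepp_logan_classes` next to the ellipse definitions.
* **Tissue values.** The default `(f, D, D*)` table
  (`default_tissue_table()`) uses literature-plausible values —
  e.g. normal tissue $(0.10, 8\times10^{-4}, 0.010)$, high-perfused tumor
  $(0.30, 1.2\times10^{-3}, 0.030)$, fluids $f = 0$ with fast diffusion —
  and is fully configurable; every evaluation references the configured
  truth, not these constants.
* **b-values.** The default 54-value scheme spans 0-1000 s/mm$^2$ with a
  repeated $b = 0$, a low-$b$ segment (0-90) for perfusion sensitivity and
  a linear high-$b$ segment (100-1000); the repeated $b = 0$ means an
  alternating test-retest split leaves one $b = 0$ in each half. The count
  scales proportionally for shorter schemes (`make_bvalues(m)`).
* **Noise.** Eight analytic coil maps (Gaussian-profile magnitudes at
  equally spaced angles, linear phases, sum-of-squares-normalized to 1 so
  the zero-noise combination is exact), per-channel complex Gaussian noise,
  sum-of-squares combination. Per slice, $\sigma$ = (mean noiseless
  normal-tissue $b_0$) / SNR, held constant across $b$; the background
  magnitude squared then follows $\sigma^2 \chi^2_{2 N_c}$, which the test
  suite verifies by a Kolmogorov-Smirnov check.

What the phantom does *not* emulate: partial-volume mixing at class
boundaries, spatially varying $T_2$/$T_1$, motion or eddy artifacts,
k-space effects, and anatomical variability. Passing its benchmarks
therefore demonstrates correct estimation under the stated noise model, not
clinical performance.

## Evaluation harness

Accuracy is summarized by range-normalized RMSE over the tissue mask
(`normalized_rmse()`: RMSE divided by the ground-truth range over the mask;
mean-normalization is available by option, and a constant truth falls back
to its magnitude with a flag). Background behaviour is reported separately
as the mean absolute estimate over non-tissue voxels, since folding the
(large, easy) background region into the evaluation mask inflates
between-method contrasts. Stability is measured by the alternating-$b$
test-retest split (`test_retest_split()`: sort, odd ranks vs even ranks,
each half keeping a $b = 0$) and the Pearson correlation of the two halves'
maps. The "SHGO" comparison method is the same global optimizer applied
directly to the full three-parameter functional with neither the VarPro
level nor the penalty.

## Problem sizes and defaults

The package's standard desk-scale benchmark is a $64 \times 64 \times 1$
phantom with 27 b-values at SNR 10 (about 2,000 tissue voxels; a whole-slice
TopoPro fit takes a few minutes), with $32 \times 32$ variants for
trend and retest checks; the full-scale $256 \times 256 \times 5 \times 54$
geometry is the phantom default and is exercised shape-wise in the tests.
Level-1 sampling defaults to 64 points (2-D), Level-2 to 32 points (3-D).
Default search boxes are deliberately wider than classical fitters use
($f \in [0,1]$, $D \in [10^{-5}, 0.02]$, $D^* \in [10^{-5}, 0.2]$ mm$^2$/s):
the global optimizer is the component that tolerates loose bounds. The
baseline fitters use the conventional narrow boxes ($f \in [0, 0.9]$,
$D \in [0, 0.004]$, $D^* \in [0, 0.1]$) with segmentation threshold
$b = 200$ s/mm$^2$, Metropolis with 5,000 samples, burn-in 1,000, proposal
steps of 2% of each bound's width and a flat prior, and the noise scale
profiled out of the Gaussian likelihood (the marginal form
$-(m/2)\log \mathrm{RSS}$), which keeps the chain three-dimensional.

## Known limitations

* The headline contrast between the segmented baseline and TopoPro depends
  strongly on where it is evaluated. Over the tissue mask, both methods'
  $D^*$ errors are bounded — the baseline's by its search box, TopoPro's
  from below by the information actually present at SNR 10 — which caps the
  attainable error ratio at a few fold; the dramatic ratios reported for
  whole-image comparisons are driven by signal-free regions, where a
  stabilized fitter returns zeros and an unstabilized one returns noise.
* The penalty buys $D^*$ stability at the price of a downward $D^*$ bias in
  low-perfusion voxels at low SNR; with the noise-adaptive weight this bias
  vanishes as SNR grows, but at SNR 10 the $D^*$ map should be read as a
  strongly regularized estimate.
* The perfusion fraction of a low-SNR, low-$f$ voxel absorbs part of any
  residual baseline offset once $D^*$ is shrunk; $f$ maps at SNR $\lesssim$ 10
  are noticeably noisier than $D$ maps.
* Bowyer-Watson triangulation is implemented for 1-3 dimensions, which
  covers this model family but not higher-dimensional extensions.
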