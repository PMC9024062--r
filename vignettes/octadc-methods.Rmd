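---
title: "Depth-dependent dispersion compensation for SD-OCT: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-dependent dispersion compensation for SD-OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Spectral-domain OCT reconstructs a depth profile from the Fourier transform
of a spectral interferogram. The detected fringe from a multilayer sample is

$$ S(k) \;=\; I_r(k)\Big(1 + \sum_n r_n\Big)
   \;+\; \sum_n 2\sqrt{r_n}\,I_r(k)\,
   \cos\!\big(k\,\Delta z_n + \phi_n(k)\big), $$

where $I_r(k)$ is the source envelope, $r_n$ and $\Delta z_n$ the
reflectivity and optical pathlength difference of layer $n$, and
$\phi_n(k)$ the residual dispersion phase of the media above that layer.
Expanding $\phi_n$ around the spectral centroid $k_0$, the constant and
linear terms only relocate the peak and are absorbed into $\Delta z_n$;
the quadratic and cubic terms,

$$ \phi_n(k) \;=\; a_2 (k - k_0)^2 + a_3 (k - k_0)^3 + \dots, $$

broaden the axial point-spread function. Numeric compensation multiplies
the (analytic) spectrum by $\exp\{i\bar\phi(k)\}$ with
$\bar\phi(k) = -a_2(k-k_0)^2 - a_3(k-k_0)^3$ before the FFT; a correction
coefficient equal to the residual $a_2$ of a layer cancels its quadratic
phase exactly. Because tissue dispersion varies with depth, **no single
coefficient sharpens every layer**: a reconstruction compensated with one
coefficient is optimal in one depth band only. The package automates the
full workaround: reconstruct the same raw frame with a ladder of
coefficients $C_1 < \dots < C_N$ (equally spaced, $N = 5$ by default),
stitch the all-depth ground truth from the band each channel optimizes, and
train an encoder–decoder network to map the multichannel stack to the fully
compensated B-scan in one pass.

## Coefficient convention

The paper-facing "physical" convention expresses $a_2$ in
$\mathrm{rad}/(\mathrm{rad}\,\mu m^{-1})^2$. The package default is the
instrument-independent *pixel-index* convention: with
$u_j = (j - j_0)/(P/2) \in [-1, 1]$ across the $P$-pixel k-grid, the phase
is $a_2 u^2 + a_3 u^3$, so a coefficient reads directly as "radians of
quadratic phase at the edge of the detector". Sweep ranges such as
$[-40, 40]$ rad therefore transfer between instruments. Both conventions
are supported everywhere via `mode =`.

## The synthetic benchmark

No public raw-fringe retina volumes exist to regress against, so the
package ships a physics-based generator that stands in for a clinical
repeated-frame acquisition:

* **Instrument**: Gaussian source, 840 nm center, 50 nm FWHM, sampled on
  $\pm 2\times$FWHM. The detector defaults to 2048 pixels
  (`make_source_spectrum()`); the desk-scale experiments use 512 pixels and
  128 A-lines per B-scan, which preserves the physics (axial pitch
  ≈ 3.5 µm, transform-limited FWHM ≈ 3.6 pixels) at a fraction of the cost.
* **Sample** (`synth_retina_sample()`): one reflective layer per depth
  band, mimicking the discrete reflective banding of the retina. The depth
  axis is split into $N$ equal bands and the layer in band $i$ carries
  $a_2 = C_i + \mathcal N(0, 2)$ — the synthetic analogue of tissue whose
  dispersion grows smoothly with depth, expressed at the granularity the
  stitching procedure assumes. Layers get uniform reflectivities in
  $[0.3, 1]$, a parabolic lateral sag of 20 µm (retinal curvature), and
  speckle realized as ~8 sub-resolution scatterers per layer per A-line
  with ±10 µm depth jitter.
* **Noise**: additive white Gaussian on the fringe (sd 0.05 of the unit
  envelope peak) plus optional shot noise. Repeated frames (4 per location,
  matching the repeated-frame averaging protocol) share the speckle
  geometry and differ only in detection noise.

What this emulates: depth-varying quadratic dispersion, speckle texture
correlated across repeats, lateral curvature, finite SNR. What it does
not: motion between repeats, vessel shadowing, sensitivity roll-off,
polarization effects, and real anatomical texture. Passing tests therefore
demonstrate that the *pipeline* (coefficient discovery, stitching,
restoration network, metrics) behaves correctly under controlled physics —
not that the trained desk-scale network transfers to clinical data.

## Ground-truth manufacture

`estimate_optimal_coeff()` automates what is otherwise an empirical
per-depth calibration: sweep the coefficient, score a depth band with the
normalized sharpness $\sum I^4 / (\sum I^2)^2$ (1 for an impulse, $1/M$
for a uniform band, scale-invariant), and refine the argmax with a
parabolic fit through the top three scores. A flat landscape (max/min
$< 1 + 10^{-6}$) returns the sweep midpoint with a warning rather than an
arbitrary argmax. `stitch_ground_truth()` copies band $i$ from channel
$i$ (ascending coefficient ↔ increasing depth); stitching is hard by
default — seams are visible in noise-free synthetic images, so an opt-in
linear feather of configurable width exists, but the reference procedure
uses hard stitching and the default follows it.

Band boundaries default to equal-height partitions (the remainder goes to
the last band) because they are reproducible; the anatomically guided
alternative — boundaries at midpoints between detected layer peaks — can be
passed explicitly to `partition_depth_bands()`.

## The restoration network

`build_adcnet()` assembles a compact UNet-style encoder–decoder natively in
R (the heavy lifting is BLAS matrix products; convolutions are expressed
as nine shifted GEMMs, and the backward pass is pinned by a
finite-difference gradient test):

* a stem convolution lifts the 1/3/5/7/9 input channels to a fixed width,
  so the channel count touches only the first layer;
* each encoder stage is a dense block (two 3×3 convolutions whose outputs
  are concatenated back onto the running feature map — intra-block skip
  connections), a 1×1 channel-halving transition, and a 2× max-pool;
* the decoder mirrors it: 2× nearest-neighbour upsampling, concatenation
  with the matching transition output, one 3×3 convolution stage;
* batch norm + ReLU trail every convolution; a terminal 1×1 convolution
  with a sigmoid produces the single-channel output.

The terminal activation deserves a note: the original description uses a
SoftMax, which over a single output channel is the constant 1. The package
defaults to a sigmoid — it preserves the $[0,1]$ image range and trains —
and keeps `softmax` and `linear` selectable for fidelity experiments.

Capacity is configuration, not architecture: the desk-scale experiments use
3 stages / growth 12 / 12 base filters for 64×64 inputs (~30k parameters)
and 2 stages / growth 8 / 8 filters for 32×48 inputs. Encoder weights can
be loaded from a checkpoint (`pretrained_encoder_path`), the hook that
replaces large-scale transfer learning; desk-scale runs use seeded He
initialization instead, since pretraining is not the method's core.

### Loss and optimizer

Training uses Adam; the config default keeps the original learning rate
$10^{-4}$ and dice loss. The desk-scale experiment configs deviate, for
stated reasons:

* **Learning rate $2\times 10^{-3}$**: the desk runs take a few hundred
  optimizer steps on a small from-scratch network; at $10^{-4}$ Adam
  cannot traverse the distance to a useful optimum in that budget. The
  value is the standard Adam regime for small networks.
* **MAE loss**: the soft dice $1 - (2\sum pg + \varepsilon)/(\sum p +
  \sum g + \varepsilon)$ is designed for overlap of near-binary masks. On
  continuous log-scale images its per-pixel gradient is nearly uniform
  (it rewards global overlap, not pixel-wise agreement), so convergence
  per step is slow — immaterial at GPU scale, decisive at desk scale.
  MAE anchors every pixel. Dice remains the default and is exercised by
  the unit tests.

Mini-batches (size 4) are shuffled with a seeded RNG; a 10% validation
holdout selects the best checkpoint; training is deterministic given the
seed (pure-R kernels have no nondeterministic reductions, so the
reproducibility contract — histories within $10^{-4}$ relative — is met
bitwise in practice).

## Evaluation battery

PSNR follows the stated convention that $s$ is the maximum of the
*reconstructed* image (auto mode), which makes it asymmetric; a fixed
dynamic range is available. SSIM uses the conventional 11×11 Gaussian
window ($\sigma = 1.5$); MS-SSIM evaluates contrast/structure on a dyadic
2×2-mean pyramid with luminance at the coarsest scale, canonical 5-scale
exponents, renormalized when image size caps the scale count (64×64 images
support 3 scales; the package warns and reduces). Metrics are computed on
log-compressed, per-image min-max normalized images ($L = 1$) — the display
convention of the figures being emulated; a linear-scale switch exists.
Both metrics are verified against brute-force per-pixel window evaluations
and against an independent reference implementation during development.

Repeated frames at a location are averaged before metrics
(`average_repeats()`), mirroring the repeated-frame protocol;
`axial_profile()` reproduces the profile analysis (6 neighbouring B-scans,
5 adjacent A-lines, linear scale, FWHM by interpolation at half height).

## Numerical choices and degenerate inputs

* Analytic signal by zeroing negative-frequency bins; the complex phase
  correction requires a complex spectrum, so plain real-FFT magnitude is
  not used.
* k-linearization by natural cubic spline (`linearize_fringe()`), linear
  interpolation as fallback. Simulated fringes are generated directly on
  the uniform k-grid; the λ-sampled path exists and is tested against it.
* No apodization beyond the source envelope (the Gaussian source
  self-apodizes).
* $\Delta z$ is the *total* optical pathlength difference — no hidden
  factor of two; the unambiguous depth range is $\pi/\delta k$ and deeper
  layers trigger an aliasing warning but still simulate.
* Sub-pixel FWHM measurements use zero-padded (sinc-interpolated) FFTs
  (`pad_factor`), since the native axial pitch leaves the PSF only ~3.6
  pixels wide.
* All-zero images: `log_display()` and normalization error out;
  `sharpness_score()` returns 0; PSNR of identical images returns the
  `+Inf` sentinel with a warning (the formula is singular there).
* Row 1 is zero delay; depth increases with row index; 1-based row
  intervals are inclusive.

## Problem sizes used by tests and the acceptance script

Simulation and reconstruction run at the full desk instrument (512-pixel
detector). Network experiments use 64×64 inputs (512-pixel frames, axial
4× / lateral 2× block-mean pooling): 200 pairs / 10 epochs for the
5-channel-vs-baseline comparison in the test suite (the acceptance script
uses 120 pairs), and a 32-pair / 32×48 benchmark for the channel-count
trend (1/3/5 channels × 3 seeds). These sizes were chosen as the smallest
at which the compared quantities separate cleanly; they are stated here so
that anyone scaling the experiments up knows the baseline.

## Known limitations

* The simulator's layer dispersion is piecewise-constant per band by
  construction; real tissue varies continuously, so real stitching bands
  would be calibrated anatomically (the configuration surface allows it).
* The desk-scale network is far smaller than a production restoration
  model; its scores quantify the pipeline, not clinical performance, and
  absolute PSNR/MS-SSIM values on synthetic speckle are not comparable to
  values reported on human retina.
* Dice loss underperforms at desk scale (see above); it is retained as the
  default for fidelity, so users reproducing the experiments at larger
  scale can switch back with one argument.
* The `1 - MS-SSIM` training objective is not implemented (its gradient is
  out of scope for the native R engine); `dice` and `mae` are.
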