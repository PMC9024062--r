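# octadc

Automated depth-dependent dispersion compensation for spectral-domain
optical coherence tomography (SD-OCT), end to end in R.

## The problem

Broadband light makes high-resolution OCT possible and chromatic
dispersion is the price: wavelength-dependent pathlength differences add a
spectral phase $\phi(k) \approx a_2(k-k_0)^2 + a_3(k-k_0)^3$ to the
interferogram, broadening the axial point-spread function. Numeric
compensation multiplies the analytic spectrum by
$\exp\{-i[a_2(k-k_0)^2 + a_3(k-k_0)^3]\}$ before the FFT — but in layered
tissue the residual dispersion varies with depth, so one coefficient
sharpens one depth band only. This package implements the automated
workaround for that limit:

1. **Simulate** (`simulate_volume()`, `simulate_benchmark()`) — synthetic
   SD-OCT fringe data: broadband Gaussian source, multilayer retina-like
   samples with per-layer dispersion, speckle, curvature, repeated frames.
2. **Reconstruct** (`reconstruct_bscan()`, `build_compensation_stack()`) —
   background subtraction, k-space linearization, spectral phase
   correction, FFT; a stack of B-scans, each compensated by one
   coefficient of an equally spaced ladder $C_1 \dots C_N$ ($N = 5$).
3. **Build ground truth** (`estimate_optimal_coeff()`,
   `stitch_ground_truth()`) — per-band optimal coefficients found by a
   sharpness sweep ($\sum I^4/(\sum I^2)^2$), and the all-depth
   compensated target stitched band-by-band from the stack.
4. **Restore** (`build_adcnet()`, `adcnet_train()`, `adcnet_predict()`) —
   a compact UNet-style encoder-decoder (dense blocks, channel-halving
   transitions, skip connections; batch norm + ReLU after every
   convolution), taking 1/3/5/7/9-channel stacks to a single fully
   compensated B-scan. Implemented natively in R on BLAS matrix products,
   trained with Adam; gradients are verified against finite differences.
5. **Evaluate** (`psnr()`, `ms_ssim()`, `axial_profile()`,
   `run_channel_experiment()`) — PSNR (with $s$ the maximum of the
   reconstructed image), multi-scale SSIM ($K_1 = 0.01$, $K_2 = 0.03$,
   $C_3 = C_2/2$, 11×11 Gaussian window), differential intensity maps,
   and peak/FWHM profile analysis.

## Worked example

```r
library(octadc)

# a dispersed single reflector: injected a2 = 30 rad (pixel convention)
src  <- make_source_spectrum(840, 50, 512)   # 840 nm / 50 nm FWHM source
grid <- resample_to_k(src)
bg   <- simulate_ascan_spectrum(src, grid, layered_sample(numeric(0), numeric(0)))
fr   <- simulate_ascan_spectrum(src, grid, layered_sample(200, 1, a2 = 30)) - 2 * bg

fwhm <- function(a2) {
  prof <- reconstruct_ascan(fr, grid, a2 = a2, pad_factor = 8)
  octadc:::fwhm_interp(prof) / 8 * depth_pitch_um(grid)
}
round(c(uncorrected = fwhm(0), matched = fwhm(30)), 2)
#> uncorrected     matched
#>       34.93       12.42
```

The uncorrected PSF is 2.8× wider; the matched correction (coefficient
equal to the injected dispersion) restores the 12.4 µm transform-limited
width. On the full benchmark the restoration network learns this per depth
band:

```r
vols <- simulate_benchmark(n_volumes = 4, locations = 4, a_lines = 48,
                           repeats = 2, n_pixels = 256, seed = 31)
ds   <- build_dataset(vols, n_channels = 5, pool_depth = 4)
cfg  <- adcnet_config(n_channels = 5, encoder_stages = 2, growth_per_block = 8,
                      base_filters = 8, batch_size = 4, learning_rate = 2e-3,
                      epochs = 10, loss = "mae")
run_channel_experiment(ds, channel_counts = c(1, 3, 5), seeds = 1:3,
                       config = cfg, ssim_scales = 2)
#> <oct_quality_report>
#>  variant  n psnr_mean psnr_sd ms_ssim_mean ms_ssim_sd
#>       UC  4     16.24  0.5591       0.8809   0.033845
#>       M1 12     15.44  1.6438       0.9092   0.038930
#>       M3 12     21.91  0.5547       0.9648   0.011035
#>       M5 12     22.05  0.5900       0.9651   0.014813
```

`UC` is the uncompensated (midpoint-coefficient) baseline; `M1`–`M5` are
models with 1/3/5 input channels, scored on held-out volumes after
repeated-frame averaging. Quality rises with channel count and saturates
by five channels — more channels mean more depth bands arrive already
optimally compensated in some input channel.

A command-line wrapper covers the same pipeline
(`inst/cli/oct-adc.R`: `simulate`, `reconstruct`, `make-gt`, `train`,
`predict`, `evaluate`, `experiment`), driven by a YAML config such as
`inst/extdata/sim_tiny.yaml`; every run directory records config hash,
seed and versions.

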