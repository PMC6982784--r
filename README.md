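# refdip

Reference-driven Deep Image Prior reconstruction for compressed-sensing MRI,
in R.

## What problem this solves

Compressed-sensing MRI reconstructs an image from a fraction of its k-space
(spatial-frequency) samples, shortening scan time at the price of an
ill-posed inverse problem. Supervised deep-learning reconstructions need
large patient datasets for training, which clinics often cannot assemble.
This package implements a per-image method that needs **no training data at
all**: an untrained convolutional network is optimised, for the one image at
hand, to explain the acquired measurements (the Deep Image Prior idea), and
the network input is a previously acquired high-resolution **reference
image of similar anatomy** — typically an earlier, fully sampled scan of
the same patient — rather than random noise. The structural similarity
between reference and target acts as the prior.

With target $I_t \in \mathbb{C}^{N\times N}$, measurements
$y = F_u I_t$ under the binary sampling mask $U$, and network
$f(\theta \mid \cdot)$:

1. **Reference-driven fit:**
   $\hat\theta = \arg\min_\theta \lVert y - F_u f(\theta \mid I_r)\rVert_2^2$,
   by Adam; $\hat I_{out} = f(\hat\theta \mid I_r)$.
2. **Data correction:**
   $y_{new} = (F\hat I_{out})|_{\bar U} \cup y$, then
   $\hat I_t = F^{-1}(y_{new})$ — the acquired samples are substituted back
   exactly, so the final image is perfectly consistent with everything that
   was measured and the network only fills in the missing k-space.

The package contains everything needed to exercise the method end to end
without scan data: centred orthonormal FFT operators, Cartesian / radial /
variable-density mask generators, the hourglass (encoder–decoder with skip
connections) network — convolution, batch norm, leaky ReLU, bilinear
upsampling and their exact backward passes are implemented in the package,
with the convolution kernels in C++ — relative error / PSNR / SSIM metrics,
a synthetic (reference, target) phantom-pair generator with a complex
Gaussian k-space noise model, classic noise-input DIP and zero-filling
baselines, and a seeded benchmark runner. Users are imaging-methods
researchers who want a dependency-light, fully reproducible testbed for
reference-driven untrained reconstruction.

## Worked example

```r
library(refdip)

# a (reference, target) phantom pair: similar anatomy, not identical
pair <- make_phantom_pair(N = 64, n_structures = 8, jitter_px = 1.5, seed = 0)
print(pair)
#> <phantom_pair> 64 x 64, 8 structures, SSIM(|ref|,|target|) = 0.890

# simulate a 30% Cartesian acquisition of the target
mask <- make_cartesian(64, rate = 0.3, seed = 0)
meas <- simulate_acquisition(pair$target, mask)
print(meas)
#> <kspace_measurement> 64 x 64 grid, 1216 sampled locations (29.7%)

# reconstruct: untrained depth-3 hourglass, reference input, data correction
spec <- network_spec(depth = 3, nd = c(16, 32, 64), ns = 4)
cfg  <- recon_config(iterations = 500, learning_rate = 0.01,
                     input_mode = "reference", seed = 0)
res <- reconstruct(meas, pair$reference, spec, cfg, truth = pair$target)
print(res)
#> <recon_result> 64 x 64, reference input, 500 iterations, loss 2.286e+03 -> 6.670e-01
print(res$metric_trace)
#>   iteration relative_error     psnr
#> 1       100     0.07051367 28.27589
#> 2       200     0.05888376 29.84144
#> 3       300     0.05244989 30.84646
#> 4       400     0.04728802 31.74633
#> 5       500     0.04386979 32.39804

# score against the ground truth, next to the zero-filling baseline
unlist(metrics_report(res$image, pair$target)[1:3])
#> relative_error           psnr           ssim
#>     0.04413477    32.34573813     0.93806655
unlist(metrics_report(zero_fill(meas), pair$target)[1:3])
#> relative_error           psnr           ssim
#>      0.1914683     19.5994163      0.6032700
```

Reading the numbers: the k-space data-fidelity loss falls by more than
three orders of magnitude over the fit, and the relative-error trace keeps
decreasing through iteration 500. The reference-driven reconstruction
reaches 32.3 dB PSNR (4.4% relative error, SSIM 0.94) where zero-filling —
inverse FFT of the measured samples with zeros elsewhere — manages 19.6 dB
(19.1% error, SSIM 0.60) from the same 29.7% of k-space.

`run_benchmark()` repeats this comparison (plus the classic noise-input DIP
arm) over mask families, rates and seeds and writes seed-averaged tables;
the `exec/refdip` script exposes `simulate`, `mask`, `reconstruct`,
`evaluate` and `benchmark` subcommands for shell use. The three published
hyperparameter sets for full-size scans ship as YAML under
`inst/extdata/networks/`.

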