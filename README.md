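# waveden

Two-stage denoising for single-channel medical images, built for imaging
researchers who need a reproducible, parameter-tuned baseline: multilevel
wavelet shrinkage followed by an edge-preserving bilateral filter whose
parameters are tuned automatically by Bayesian optimization.

## The method

**Stage 1 — wavelet shrinkage.** The noisy image is decomposed with an
orthogonal Daubechies `db2` transform at 5 levels (symmetric boundary
extension). The noise level is estimated robustly from the finest diagonal
band, σ̂ₙ = median(|d₁|)/0.6745, and every detail band is soft-thresholded
with its BayesShrink threshold

    T = σ̂ₙ² / σ̂ₓ ,   σ̂ₓ = sqrt(max(mean(w²) − σ̂ₙ², 0)),

(the band is annihilated when it carries no estimated signal; the
approximation band is never touched) before inverse transformation.

**Stage 2 — bilateral post-filter.** The reconstruction is smoothed with
the exact bilateral filter

    I_B(x,y) = (1/W_P) Σ_{x',y'} I(x',y')
               · exp(−((x−x')² + (y−y')²) / 2σ_s²)
               · exp(−(I(x,y) − I(x',y'))² / 2σ_r²),

summed over a d-diameter square window, with W_P the sum of the weights.
Its three parameters — window diameter `d`, range spread `sigma_color`
(grey levels) and spatial spread `sigma_space` (pixels) — are tuned by
Gaussian-process Bayesian optimization with an expected-improvement
acquisition, minimizing −PSNR against a clean reference. For images without
a reference, parameters tuned on one reference image transfer unchanged to
the rest of a dataset (`transfer_parameters()`).

The package also ships an ultrasound-like phantom generator with the two
noise models used throughout (additive Gaussian, σ = 25 grey levels, and
Poisson noise with the pixel intensity as its mean), PSNR/MSE/SSIM quality
metrics on the unit working range, and a small CLI
(`inst/cli/waveden.R`) with verbs `simulate`, `denoise`, `bilateral`,
`optimize`, `evaluate`, `transfer`, `compare`.

## Worked example

```r
library(waveden)
clean <- make_phantom(128, 128, n_lesions = 3, seed = 1)
noisy <- add_gaussian_noise(clean, sd = 25, seed = 2)
fit   <- optimize_bilateral(clean, noisy, iterations = 25, n_initial = 10, seed = 3)
summary(fit)
#> Bayesian optimization of the bilateral post-filter
#>   wavelet stage: db2, 5 level(s), sigma_noise = 0.094969
#>   evaluations: 35 (10 initial + 25 guided), objective calls: 35
#>   PSNR: first incumbent 29.79 dB -> final 30.45 dB
#> <bilateral_params> d = 9, sigma_color = 16.52, sigma_space = 15

tab <- compare_methods(clean, noisy, params = coef(fit), seed = 3)
print(tab, row.names = FALSE, digits = 4)
#>          method psnr_db       mse   ssim
#>           noisy   20.34 0.0092378 0.8623
#>    wavelet_only   28.49 0.0014167 0.9751
#>  bilateral_only   22.90 0.0051309 0.9184
#>        pipeline   30.45 0.0009012 0.9840
```

The noise estimate 0.0949 recovers the injected 25/255 ≈ 0.0980 to within
4%. The wavelet stage alone gains ~8 dB over the noisy input; the tuned
bilateral post-filter adds ~2 dB more, and the full pipeline dominates
either stage alone in PSNR, MSE and SSIM. `plot(fit)` draws the
convergence of the incumbent PSNR over the 35 evaluations, and
`predict(fit, newdata = other_noisy_image)` applies the tuned pipeline to
further images.

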