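# sweshell

Quantitative skin ultrasound for localized scleroderma (LS): an improved
non-local-means (NLM) denoiser for B-mode images, shear-wave elastography
(SWE) "shell" quantification around lesions, dermal thickness measurement,
and the diagnostic statistics that turn per-subject moduli into a
clinical-style table. The package is aimed at researchers who study skin
fibrosis with high-frequency ultrasound + SWE and want a reproducible,
fully synthetic testbed for the image-processing and statistics layers of
that workflow: no patient data are required — layered-skin B-mode phantoms,
elasticity-map phantoms with a stiff lesion and a "hard ring" margin, and
two-group cohorts with known effect sizes are generated in code.

## The methods at the core

**Denoising.** The observed image is `f = y + n` with additive white
Gaussian noise. Classic NLM averages each pixel over its search window with
weights `w(i,j) = exp(-d(i,j)/mu)`, `d` the Gaussian-weighted squared
Euclidean distance between patches. The improved variant multiplies in a
structural factor `((1 + S_c(i,j))/2)^gamma`, `S_c` the cosine similarity of
mean-centered patches, and embeds the filter in a MAP estimate

```
min_u  1/2 ||u - v||^2 + (lambda/2) u'(u - NLM(u)),   lambda = 2 * beta * sigma_hat^2
```

solved by ADMM splitting with per-iteration re-estimated NLM weights and a
per-pixel filter parameter modulated by a Laplacian edge map (less smoothing
at layer interfaces). `beta = 0.02`; `sigma_hat` is a robust (MAD-of-Laplacian)
noise estimate. Denoising quality is scored by MSE, PSNR
(`10 log10(L^2/MSE)`, `L = 255`) and a whole-image SSIM.

**Shell quantification.** Given a modulus map (kPa) and a lesion mask, the
shell of width `w` mm is the set of outside pixels within Euclidean distance
`w/spacing` of the lesion (exact distance transform). The scanner-style ROI
readout `E_max, E_mean, E_min, E_sd` is computed for the lesion and each
shell; ROC/AUC with a Youden cutoff evaluates each statistic as a
case/control discriminator, mirroring the shell-size comparison tables of
SWE studies. Dermal thickness is read from A-line derivative extrema and
`E = S/e`, signed relative modulus differences, and triple-measurement
averaging are provided as the surrounding arithmetic.

## Worked example

```r
library(sweshell)

# B-mode phantom (3 mm dermis), noise, both denoisers
ph       <- make_skin_phantom(skin_phantom_spec(), seed = 1)
noisy    <- add_noise(ph$image, noise_spec(sigma = 20), seed = 2)
classic  <- denoise_nlm(noisy, nlm_config(gamma = 0))
improved <- denoise_nlm_improved(noisy)
mse(noisy, ph$image); mse(classic, ph$image); mse(improved, ph$image)
#> MSE  noisy 403.2 | classic 64.7 | improved 58.6
#> PSNR noisy 22.08 | classic 30.02 | improved 30.45 dB
#> SSIM noisy 0.9441 | classic 0.9905 | improved 0.9913

measure_thickness(noisy, ph$pixel_spacing)
#> [1] 3           # mm, matching the phantom's ground truth

# elasticity phantom: lesion vs 1 mm shell (the "hard ring")
phi  <- make_elasticity_phantom(elasticity_phantom_spec(), seed = 3)
ring <- shell_ring(phi$mask, width_mm = 1, spacing = phi$pixel_spacing)
modulus_stats(phi$map, phi$mask)   # emean 59.8 kPa over 1257 px
modulus_stats(phi$map, ring)       # emean 90.0 kPa over 1548 px

# simulated cohort -> ROC/AUC/Youden cutoff
d <- make_cohort(cohort_spec(n_cases = 50, n_controls = 50, effect_size = 3,
                             base_mean = 60, base_sd = 8, seed = 4))
diagnostic_eval(d, measurement, group)
#> Diagnostic evaluation ( 50 cases, 50 controls )
#>   AUC         0.9924
#>   threshold  >69.07 (Youden)
#>   sensitivity 1.000   specificity 0.900

stage_summary(c(edema = 7, sclerotic = 42, atrophic = 47))
#>   stage     count percent
#> 1 edema         7    7.29
#> 2 sclerotic    42   43.75
#> 3 atrophic     47   48.96
```

The larger MSE drop and higher PSNR/SSIM of the improved denoiser versus the
classic filter is the package's central denoising claim; the shell mean far
above the lesion mean quantifies the hard-ring sign; the AUC/threshold row
is one cell of the Table-1-style output `run_swe_study()` writes for every
statistic × shell width.

Two end-to-end drivers bundle these steps: `run_denoise_benchmark()` (noise
sweep + dominance verdict) and `run_swe_study()` (cohort of elasticity
phantoms → ROC table, stage table, thickness comparison), both writing CSV/
JSON plus a reproducibility manifest. A thin CLI over the same functions
lives at `exec/sweshell`
(`simulate | denoise | metrics | swe | roc | benchmark | study`).

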