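---
title: "Models and methods behind sweshell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sweshell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweshell)
```

`sweshell` implements a quantitative ultrasound workflow for localized
scleroderma (LS): denoising of B-mode skin images with a non-local-means
(NLM) filter and an improved, regularized variant; image-quality scoring of
the denoisers; "shell" quantification of shear-wave elastography (SWE)
modulus maps around a lesion; dermal thickness measurement; and the
diagnostic statistics (ROC/AUC, Youden cutoffs, stage summaries, two-group
tests) that turn per-subject measurements into a clinical-style table. No
patient data ship with the package; everything is exercised on synthetic
phantoms with known ground truth.

## The denoising model

The observed image is modelled as \(f = y + n\) with \(n\) zero-mean
additive white Gaussian noise of standard deviation \(\sigma\). Classic NLM
estimates each pixel as a weighted average over its search window,

\[
\mathrm{NLM}[a](i) = \frac{1}{\sigma(i)} \sum_{j \in W(i)} w(i,j)\, a(j),
\qquad
w(i,j) = \exp\!\left(-\frac{d(i,j)}{\mu}\right),
\]

where \(d(i,j)\) is the Gaussian-kernel-weighted squared Euclidean distance
between the patches around \(i\) and \(j\), \(\sigma(i)\) normalizes the
weights to sum to one, and \(\mu\) sets the smoothing strength.

The improved weight multiplies in a structural factor,

\[
\tilde w(i,j) = \exp\!\left(-\frac{d(i,j)}{\mu}\right)
\left(\frac{1 + S_c(i,j)}{2}\right)^{\gamma},
\]

with \(S_c\) the cosine similarity of the two mean-centered patch vectors.
The Euclidean distance alone cannot distinguish a patch that differs by a
uniform intensity offset (same structure) from one with genuinely different
structure at the same distance; the centered cosine separates the two
cases. Patch pairs that are both constant get \(S_c = 1\); if exactly one
is constant, \(S_c = 0\). At \(\gamma = 0\) the classic weight is recovered
exactly, which the test suite asserts.

### MAP regularization solved by ADMM

The improved denoiser embeds the NLM operator in a maximum-a-posteriori
estimate. With a Gaussian likelihood and an NLM self-similarity prior the
(rescaled) objective is

\[
\min_u \tfrac12 \lVert u - v \rVert^2
+ \tfrac{\lambda}{2}\, u^\top (u - \mathrm{NLM}(u)),
\qquad \lambda = 2\,\beta\,\hat\sigma^2 ,
\]

where \(v\) is the observed image and \(\beta = 0.02\). Two factors scale
\(\beta\) into the working weight \(\lambda\):

* \(\hat\sigma^2\) comes from the Gaussian-likelihood normalization
  \(\lVert u - v\rVert^2 / (2\sigma^2)\): the noisier the data, the more
  the prior should be trusted. Without this scaling a fixed
  \(\beta = 0.02\) would leave the data term dominant at every realistic
  noise level and the regularized estimate indistinguishable from its
  input.
* the fixed factor 2 compensates the single Jacobi sweep used for the
  prior subproblem (below), which under-applies the prior relative to the
  exact linear solve. The factor was calibrated once on paired phantom
  runs and is not exposed as a tunable.

ADMM splits \(u = y\) and iterates, from \(u^0 = y^0 = v\), \(x^0 = 0\):

\[
u^k = \frac{v + \delta (y^{k-1} - x^{k-1})}{1 + \delta}, \qquad
y^k = \frac{t + (\lambda/\delta)\,\mathrm{NLM}(t)}{1 + \lambda/\delta}
\;\; (t = u^k + x^{k-1}), \qquad
x^k = x^{k-1} + u^k - y^k .
\]

The \(y\)-update is one Jacobi step of the exact subproblem
\((I + (\lambda/\delta)(I - W))\,y = t\), with the weight matrix \(W\)
reapplied to the current iterate each outer iteration, so the prior's
weights improve as the iterate cleans up. \(\beta = 0\) makes the scheme
return its input unchanged (asserted in the tests), and the whole map is
shift-equivariant: adding a constant to the input adds the same constant to
the output.

The adaptive component modulates the filter parameter per pixel,
\(\mu_i = \mu\,(1 - \tfrac12 e_i)\), where \(e\) is the absolute 5-point
Laplacian response of the input normalized to \([0,1]\). Edges therefore
receive up to half the smoothing of flat regions, which is what preserves
the layer interfaces the thickness measurement later depends on.

### Numerical choices

* **Noise estimate.** \(\hat\sigma = \mathrm{MAD}(\Delta f)/\sqrt{20}\),
  the median absolute deviation of the 5-point Laplacian response: the
  Laplacian of i.i.d. noise has variance \(20\sigma^2\), and the MAD
  ignores the sparse strong responses of true edges.
* **Defaults.** Patch radius 1, search radius 5, Gaussian patch-kernel SD
  1 px. \(\mu\) defaults to \(1.5\hat\sigma^2\) (chosen once on the
  phantom suite: roughly the noise-only expected patch distance
  \(2\hat\sigma^2\) discounted for texture). \(\delta = \max(0.1,
  \hat\sigma/10)\) ties the ADMM penalty to the noise level. \(\gamma = 1\).
  Stopping: 8 iterations or relative change below \(10^{-4}\).
* **Center weight.** \(w(i,i)\) is set to the maximum of the other weights
  in the window (standard NLM practice; options `one` and `zero` exist).
* **Boundaries.** Mirror (reflect) padding, which keeps patch statistics
  unbiased near borders.
* **Degenerate inputs.** Constant images are exact fixed points of both
  denoisers; a clean (noise-free) input gives \(\hat\sigma \approx 0\), so
  \(\lambda \approx 0\) and the improved denoiser returns its input.

## Quality metrics

MSE uses the \(1/(mn)\) population normalization; PSNR is
\(10\log_{10}(L^2/\mathrm{MSE})\) with \(L = 255\) (8-bit convention) and
an `Inf` sentinel at MSE 0. SSIM is computed with whole-image statistics by
default — means, population variances and covariance over all pixels —
matching the population convention of the MSE; a windowed mean-SSIM mode is
available. Stabilizing constants default to \((0.01L)^2\) and
\((0.03L)^2\), the usual choices when only "a constant" is specified.

## Phantoms: what they emulate, and what they do not

The B-mode phantom is three horizontal layers — near-anechoic coupling gel,
echogenic dermis, intermediate subcutis — with i.i.d. Gaussian within-layer
texture (SD 8 by default) on an 8-bit intensity scale, 0.05 mm/pixel, and
interfaces at rows 40 and 100, i.e. a 3 mm dermis. This captures exactly
the features the downstream operations consume: flat regions for noise
estimation, two axial interfaces for thickness, self-similar texture for
NLM. It deliberately omits beamforming physics: speckle correlation,
attenuation with depth, point-spread anisotropy. Passing tests therefore
demonstrate correctness of the algorithms under the stated noise model, not
clinical image realism; a multiplicative speckle mode exists for
exploration but is off all default paths.

The elasticity phantom is a uniform 30 kPa dermal background with a
stiffer 60 kPa lesion disk and an optional 90 kPa margin band of 1 mm — the
quantitative "hard ring sign" seen at the sclerotic lesion periphery —
plus Gaussian modulus jitter. Values sit where SWE places normal dermis
(tens of kPa) and sclerotic tissue (substantially stiffer).

The cohort generator draws a per-subject measurement from
\(N(\mathrm{base}, s^2)\) for controls and
\(N(\mathrm{base} + d\,s, s^2)\) for cases, so its `effect_size` is
Cohen's d, and the theoretical AUC of a perfect scorer is
\(\Phi(d/\sqrt2)\) — 0.983 at \(d = 3\), which the end-to-end tests check
by simulation together with null (d = 0) calibration.

## Shell quantification and thickness

The shell ring is defined by an exact Euclidean distance transform: pixels
outside the lesion whose distance to the nearest lesion pixel is at most
the shell width, with the mm width converted to a real-valued pixel
threshold (no rounding). This is unambiguous for arbitrary mask shapes and
exactly testable against a brute-force scan, which the suite does on random
masks. ROI statistics report the sample (n − 1) standard deviation; shells
are reported ring-alone (not ring ∪ lesion), with both ROIs exposed so
either convention can be tabulated.

Thickness measurement smooths each A-line with a 5-px moving average,
takes the axial derivative, and reads the two largest-magnitude extrema at
least 0.5 mm apart as the entry echo and the dermis–subcutis interface.
A smoothed step yields a plateau of equal derivative magnitudes; the
detector takes the center of the tied run, which lands exactly on the
interface, making noise-free recovery exact rather than merely close. The
median across columns guards against single-column dropouts. The relative
modulus difference is reported as the signed percent
\(100(E_\mathrm{lesion} - E_\mathrm{control})/E_\mathrm{control}\); the
source convention for this quantity is not printed anywhere we could
follow, so the signed form is a package decision.

## Diagnostics

ROC curves place one operating point per distinct threshold (case when
score > t), ties grouped; with ties credited 1/2, the trapezoidal AUC
equals the Mann–Whitney pairwise statistic exactly, an identity the suite
asserts at 1e-12 on random score sets. Cutoffs maximize Youden's J over
midpoints between adjacent distinct scores, ties broken toward the smaller
threshold — the standard choice where only ">threshold" cutoffs are
reported without a named criterion. The two-group comparison gates on
Shapiro–Wilk normality (alpha 0.05 per group): Welch's t-test when both
groups pass, a Wilcoxon rank-sum test otherwise (our reading of a
"nonparametric" fallback whose printed name matches no standard test).

## Study problem sizes

The denoising benchmark runs the 128×128 phantom at noise SDs
{10, 15, 20, 25} with 10 realizations each; the simulated SWE study uses
50 cases and 50 controls with per-subject 96×96 elasticity maps and shells
at 1 and 2 mm; power and null calibration use 100 and 500 cohort
replicates. These sizes give stable averages (paired same-noise
comparisons for the denoisers) while keeping a full run in minutes on one
core.

## Known limitations

* The phantom noise model is additive Gaussian; real ultrasound speckle is
  correlated and signal-dependent.
* Lesion geometry is restricted to disks and pixel spacing to isotropic —
  enough to exercise every operation, not to represent irregular lesions.
* The windowed SSIM is a plain mean over square windows (no Gaussian
  weighting, no downsampling), kept consistent with the global
  population-statistics convention.
* The improved denoiser's gains over classic NLM are modest at low noise,
  where a single NLM pass is already near the phantom's texture floor.
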