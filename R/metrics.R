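#' Mean squared error between two images
#'
#' `MSE = (1/(m n)) * sum (I - K)^2`. Smaller values mean the denoised image
#' is closer to the clean reference.
#'
#' @param I,K Numeric matrices of identical shape.
#' @return Nonnegative scalar; 0 iff the images are identical.
#' @export
mse <- function(I, K) {
  check_image(I, "I"); check_image(K, "K"); check_same_shape(I, K)
  mean((I - K)^2)
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10(L^2 / MSE)` in dB, with `L` the dynamic range (maximum
#' representable pixel value, default the 8-bit 255). Identical images give
#' the `+Inf` sentinel.
#'
#' @inheritParams mse
#' @param L Positive dynamic range.
#' @return PSNR in dB, or `Inf` when `MSE = 0`.
#' @export
psnr <- function(I, K, L = 255) {
  check_scalar_number(L, "L", min = 0, strict_min = TRUE)
  m <- mse(I, K)
  if (m == 0) Inf else 10 * log10(L^2 / m)
}

#' Structural similarity index
#'
#' `SSIM = ((2 mu_i mu_j + c1)(2 sigma_ij + c2)) /
#' ((mu_i^2 + mu_j^2 + c1)(sigma_i^2 + sigma_j^2 + c2))`, with means,
#' variances and the covariance taken over the whole image (`mode =
#' "global"`, the default) using the population (1/N) convention, matching
#' the 1/(mn) normalization of [mse()]. `mode = "windowed"` averages the
#' same statistic over all fully interior square windows of half-width
#' `window_radius` (mean SSIM).
#'
#' @inheritParams mse
#' @param L Dynamic range used for the default stabilizing constants.
#' @param c1,c2 Stabilizing constants; default `(0.01 L)^2` and `(0.03 L)^2`.
#' @param mode `"global"` or `"windowed"`.
#' @param window_radius Window half-width for windowed mode.
#' @return SSIM in `[-1, 1]`; 1 iff identical (for `c1, c2 > 0`). Symmetric
#'   in its arguments.
#' @export
ssim <- function(I, K, L = 255, c1 = (0.01 * L)^2, c2 = (0.03 * L)^2,
                 mode = c("global", "windowed"), window_radius = 3L) {
  check_image(I, "I"); check_image(K, "K"); check_same_shape(I, K)
  check_scalar_number(c1, "c1", min = 0); check_scalar_number(c2, "c2", min = 0)
  mode <- match.arg(mode)
  if (mode == "global") return(ssim_stat(I, K, c1, c2))
  r <- as.integer(window_radius)
  h <- nrow(I); w <- ncol(I)
  if (h < 2 * r + 1 || w < 2 * r + 1) {
    abort_validation("image smaller than the SSIM window")
  }
  vals <- vapply(seq_len(h - 2 * r), function(i) {
    mean(vapply(seq_len(w - 2 * r), function(j) {
      ssim_stat(I[i:(i + 2 * r), j:(j + 2 * r)],
                K[i:(i + 2 * r), j:(j + 2 * r)], c1, c2)
    }, numeric(1)))
  }, numeric(1))
  mean(vals)
}

ssim_stat <- function(I, K, c1, c2) {
  n <- length(I)
  mi <- mean(I); mk <- mean(K)
  vi <- sum((I - mi)^2) / n
  vk <- sum((K - mk)^2) / n
  cik <- sum((I - mi) * (K - mk)) / n
  ((2 * mi * mk + c1) * (2 * cik + c2)) /
    ((mi^2 + mk^2 + c1) * (vi + vk + c2))
}

#' Sweep noise levels and score both denoisers
#'
#' For each noise standard deviation and each method (`noisy`, `nlm`,
#' `nlm_improved`), adds `n_seeds` independent Gaussian noise realizations
#' to the clean image, denoises, and averages MSE, PSNR and SSIM against the
#' clean reference. Deterministic for a given `seed`.
#'
#' @param clean Clean reference image (numeric matrix).
#' @param sigmas Nonempty vector of noise standard deviations.
#' @param n_seeds Number of noise realizations per sigma.
#' @param seed Integer master seed; per-realization seeds are derived from it.
#' @param cfg_classic [nlm_config()] for classic NLM (`gamma = 0`).
#' @param cfg_improved [nlm_config()] for the improved weights.
#' @param admm [admm_config()] for the improved denoiser.
#' @param L Dynamic range for PSNR/SSIM.
#' @return A tibble of class `noise_sweep` with columns `sigma`, `method`,
#'   `mse`, `psnr`, `ssim`.
#' @export
sweep_noise_levels <- function(clean, sigmas, n_seeds = 10L, seed = 1L,
                               cfg_classic = nlm_config(gamma = 0),
                               cfg_improved = nlm_config(),
                               admm = admm_config(), L = 255) {
  check_image(clean, "clean")
  if (length(sigmas) < 1L || any(!is.finite(sigmas)) || any(sigmas < 0)) {
    abort_validation("`sigmas` must be a nonempty vector of nonnegative numbers",
                     field = "sigmas")
  }
  check_scalar_number(n_seeds, "n_seeds", min = 1, integerish = TRUE)
  rows <- purrr::map_dfr(sigmas, function(sg) {
    per_seed <- purrr::map(seq_len(n_seeds), function(k) {
      s_k <- derive_seed(seed, sprintf("sigma%g_rep%d", sg, k))
      noisy <- add_noise(clean, noise_spec(sigma = sg), s_k)
      list(noisy = noisy,
           nlm = denoise_nlm(noisy, cfg_classic),
           nlm_improved = denoise_nlm_improved(noisy, cfg_improved, admm))
    })
    purrr::map_dfr(c("noisy", "nlm", "nlm_improved"), function(m) {
      tibble::tibble(
        sigma = sg, method = m,
        mse = mean(vapply(per_seed, function(x) mse(x[[m]], clean), numeric(1))),
        psnr = mean(vapply(per_seed, function(x) psnr(x[[m]], clean, L), numeric(1))),
        ssim = mean(vapply(per_seed, function(x) ssim(x[[m]], clean, L), numeric(1))))
    })
  })
  class(rows) <- c("noise_sweep", class(rows))
  rows
}
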