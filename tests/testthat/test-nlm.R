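test_that("patch distance is the Gaussian-weighted squared difference", {
  img <- matrix(c(1, 9, 2, 4), 2, 2)
  cfg0 <- nlm_config(patch_radius = 0, search_radius = 1)
  # degenerate kernel: plain squared difference of the two pixels
  expect_equal(patch_distance(img, c(1, 1), c(2, 1), cfg0), 64)
  expect_equal(patch_distance(img, c(2, 2), c(2, 2), cfg0), 0)

  img8 <- rand_image(8, 8, seed = 21)
  cfg <- nlm_config(patch_radius = 1, search_radius = 2)
  gk <- oracle_gauss_kernel(1, cfg$gaussian_patch_sd)
  for (pair in list(list(c(1, 1), c(8, 8)), list(c(3, 5), c(6, 2)),
                    list(c(4, 4), c(4, 5)))) {
    want <- sum(gk * (oracle_patch(img8, pair[[1]][1], pair[[1]][2], 1) -
                      oracle_patch(img8, pair[[2]][1], pair[[2]][2], 1))^2)
    expect_equal(patch_distance(img8, pair[[1]], pair[[2]], cfg), want,
                 tolerance = 1e-12)
    # symmetry
    expect_equal(patch_distance(img8, pair[[1]], pair[[2]], cfg),
                 patch_distance(img8, pair[[2]], pair[[1]], cfg))
  }
  expect_error(patch_distance(img8, c(0, 1), c(2, 2), cfg),
               class = "sweshell_validation_error")
})

test_that("patch weight reduces to classic NLM at gamma 0 and kills anticorrelated patches", {
  img <- rand_image(8, 8, seed = 3)
  cfg1 <- nlm_config(patch_radius = 1, gamma = 1)
  cfg0 <- nlm_config(patch_radius = 1, gamma = 0)
  # identical patches: d = 0, S_c = 1 -> weight 1 for any gamma
  expect_equal(patch_weight(img, c(4, 4), c(4, 4), cfg1), 1)
  # gamma 0: exp(-d/mu) exactly
  d <- patch_distance(img, c(2, 2), c(6, 5), cfg0)
  expect_equal(patch_weight(img, c(2, 2), c(6, 5), cfg0, mu = 10),
               exp(-d / 10))
  # vertically anticorrelated patches ([1,2,3] vs [3,2,1] profiles):
  # centered cosine -1 -> zero weight at gamma 1
  prof <- matrix(c(1, 2, 3, 5, 3, 2, 1), 7, 3)
  expect_equal(patch_weight(prof, c(2, 2), c(6, 2),
                            nlm_config(patch_radius = 1, gamma = 1), mu = 10),
               0)
})

test_that("classic NLM matches the naive triple-loop reference", {
  cfg <- nlm_config(patch_radius = 1, search_radius = 3, mu = 300, gamma = 0)
  for (seed in 1:3) {
    img <- rand_image(16, 16, seed = 100 + seed)
    expect_equal(denoise_nlm(img, cfg),
                 oracle_nlm(img, p = 1, s = 3, mu = 300, gamma = 0),
                 tolerance = 1e-10)
  }
  # the cosine-weighted variant matches too
  cfgc <- nlm_config(patch_radius = 1, search_radius = 3, mu = 300, gamma = 1)
  img <- rand_image(12, 12, seed = 77)
  expect_equal(denoise_nlm(img, cfgc),
               oracle_nlm(img, p = 1, s = 3, mu = 300, gamma = 1),
               tolerance = 1e-10)
})

test_that("NLM output stays within each search window's input range", {
  img <- rand_image(14, 14, seed = 5)
  cfg <- nlm_config(patch_radius = 1, search_radius = 2, mu = 500, gamma = 0)
  out <- denoise_nlm(img, cfg)
  s <- 2
  for (r in seq_len(14)) for (c in seq_len(14)) {
    win <- img[max(1, r - s):min(14, r + s), max(1, c - s):min(14, c + s)]
    expect_gte(out[r, c], min(win) - 1e-12)
    expect_lte(out[r, c], max(win) + 1e-12)
  }
})

test_that("both denoisers are fixed points on constants and shift-equivariant", {
  const <- matrix(42, 20, 20)
  expect_equal(denoise_nlm(const, nlm_config(mu = 100)), const)
  expect_equal(denoise_nlm_improved(const), const)

  img <- rand_image(16, 16, seed = 8)
  cfg <- nlm_config(patch_radius = 1, search_radius = 3, mu = 200)
  expect_equal(denoise_nlm(img + 17, cfg), denoise_nlm(img, cfg) + 17,
               tolerance = 1e-9)
  adm <- admm_config(delta = 1, max_iter = 4)
  expect_equal(denoise_nlm_improved(img + 17, cfg, adm),
               denoise_nlm_improved(img, cfg, adm) + 17,
               tolerance = 1e-9)
})

test_that("Laplacian edge map flags impulses and ignores affine images", {
  expect_equal(laplacian_edge_map(matrix(7, 6, 6)), matrix(0, 6, 6))
  ramp <- outer(1:8, 1:8, function(a, b) 3 * a + 5 * b)
  expect_equal(laplacian_edge_map(ramp), matrix(0, 8, 8))
  imp <- matrix(0, 7, 7); imp[4, 4] <- 1
  em <- laplacian_edge_map(imp)
  expect_equal(em[4, 4], 1)  # raw response -4 has the max magnitude
  expect_equal(em[4, 5], 0.25)
})

test_that("noise estimate recovers the true sigma on pure-noise images", {
  set.seed(30)
  img <- matrix(rnorm(256 * 256, 100, 15), 256, 256)
  expect_lt(abs(estimate_noise_sd(img) - 15) / 15, 0.05)
})

test_that("improved denoiser honours the beta = 0 identity and reduces noise", {
  img <- rand_image(16, 16, seed = 12)
  expect_identical(denoise_nlm_improved(img, admm = admm_config(beta = 0)), img)

  ph <- make_skin_phantom(skin_phantom_spec(height = 64, width = 64,
                                            entry_depth_px = 20,
                                            dermis_base_depth_px = 50), 1)
  noisy <- add_noise(ph$image, noise_spec(sigma = 20), 2)
  m_classic <- mse(denoise_nlm(noisy, nlm_config(gamma = 0)), ph$image)
  m_improved <- mse(denoise_nlm_improved(noisy), ph$image)
  m_noisy <- mse(noisy, ph$image)
  expect_lt(m_classic, m_noisy)
  expect_lt(m_improved, m_noisy)
})
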