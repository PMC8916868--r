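test_that("skin phantom geometry encodes the ground-truth thickness", {
  spec <- skin_phantom_spec(entry_depth_px = 40, dermis_base_depth_px = 100,
                            pixel_spacing = 0.05, texture_sigma = 0)
  ph <- make_skin_phantom(spec, seed = 1)
  expect_equal(ph$ground_truth$thickness_mm, 3.0)
  # piecewise constant: at most the three layer levels
  expect_lte(length(unique(as.vector(ph$image))), 3L)
  expect_equal(dim(ph$image), c(128L, 128L))
  # layer levels land where the geometry says
  expect_equal(ph$image[40, 1], spec$layer_intensities[["gel"]])
  expect_equal(ph$image[41, 1], spec$layer_intensities[["dermis"]])
  expect_equal(ph$image[101, 1], spec$layer_intensities[["subcutis"]])
})

test_that("phantom generators are pure functions of (spec, seed)", {
  spec <- skin_phantom_spec()
  expect_identical(make_skin_phantom(spec, 42)$image,
                   make_skin_phantom(spec, 42)$image)
  expect_false(identical(make_skin_phantom(spec, 42)$image,
                         make_skin_phantom(spec, 43)$image))
  espec <- elasticity_phantom_spec()
  expect_identical(make_elasticity_phantom(espec, 7)$map,
                   make_elasticity_phantom(espec, 7)$map)
  img <- matrix(100, 32, 32)
  ns <- noise_spec(sigma = 5)
  expect_identical(add_noise(img, ns, 3), add_noise(img, ns, 3))
})

test_that("spec validation names the offending field", {
  expect_error(skin_phantom_spec(entry_depth_px = 100, dermis_base_depth_px = 40),
               class = "sweshell_validation_error")
  expect_error(noise_spec(sigma = -1), class = "sweshell_validation_error")
  expect_error(noise_spec(sigma = 1, clip_range = c(5, 2)),
               class = "sweshell_validation_error")
  expect_error(
    elasticity_phantom_spec(lesion_center = c(5, 5), lesion_radius_px = 20),
    class = "sweshell_validation_error")
})

test_that("additive noise has the stated distribution", {
  img <- matrix(100, 256, 256)
  expect_identical(add_noise(img, noise_spec(sigma = 0), 1), img)
  noisy <- add_noise(img, noise_spec(sigma = 20), seed = 9)
  resid <- as.vector(noisy - img)
  expect_lt(abs(mean(resid)), 0.5)
  expect_lt(abs(sd(resid) - 20) / 20, 0.05)
  # Kolmogorov-Smirnov against Normal(0, sigma)
  expect_gt(ks.test(resid, "pnorm", 0, 20)$p.value, 0.01)
})

test_that("noise clipping and speckle modes honour their contracts", {
  img <- matrix(128, 64, 64)
  clipped <- add_noise(img, noise_spec(sigma = 200, clip_range = c(0, 255)), 4)
  expect_true(all(clipped >= 0 & clipped <= 255))
  spk <- add_noise(img, noise_spec("speckle_multiplicative", sigma = 0.1), 4)
  # multiplicative: sd proportional to the signal level
  expect_lt(abs(sd(as.vector(spk)) - 12.8) / 12.8, 0.1)
})

test_that("elasticity phantom is exact without jitter and ring means order", {
  spec <- elasticity_phantom_spec(jitter_sigma_kpa = 0, ring_width_mm = NULL,
                                  ring_kpa = NULL)
  phi <- make_elasticity_phantom(spec, 1)
  expect_equal(modulus_stats(phi$map, phi$mask)$emean, spec$lesion_kpa)
  expect_equal(modulus_stats(phi$map, phi$mask)$esd, 0)

  spec2 <- elasticity_phantom_spec(jitter_sigma_kpa = 0, ring_width_mm = 1,
                                   ring_kpa = 90)
  phi2 <- make_elasticity_phantom(spec2, 1)
  ring <- shell_ring(phi2$mask, 1, spec2$pixel_spacing)
  m_ring <- modulus_stats(phi2$map, ring)$emean
  m_les <- modulus_stats(phi2$map, phi2$mask)$emean
  m_bg <- modulus_stats(phi2$map, !phi2$mask & !ring)$emean
  expect_gt(m_ring, m_les)
  expect_gt(m_les, m_bg)
})

test_that("cohort generator matches its sampling model", {
  spec <- cohort_spec(n_cases = 1, n_controls = 4, seed = 2)
  expect_equal(nrow(make_cohort(spec)), 5L)
  expect_identical(make_cohort(spec), make_cohort(spec))

  big <- make_cohort(cohort_spec(n_cases = 4000, n_controls = 4000,
                                 effect_size = 2, base_mean = 10,
                                 base_sd = 3, seed = 5))
  mc <- mean(big$measurement[big$group == "case"])
  m0 <- mean(big$measurement[big$group == "control"])
  expect_lt(abs(m0 - 10), 0.2)
  expect_lt(abs((mc - m0) - 6), 0.3)
})
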