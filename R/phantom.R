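#' Specify a layered-skin B-mode phantom
#'
#' Describes a synthetic B-mode image of skin as three horizontal layers:
#' coupling gel above the skin entry echo, dermis between the entry echo and
#' the dermis--subcutis interface, and subcutis below. The dermal thickness
#' implied by the geometry, `(dermis_base_depth_px - entry_depth_px) *
#' pixel_spacing`, is the ground truth recovered by [measure_thickness()].
#'
#' Default geometry (128 rows at 0.05 mm/pixel, interfaces at rows 40 and
#' 100) gives a 3 mm dermis, in the range reported for sclerotic skin imaged
#' with high-frequency probes. Layer intensities are on the 8-bit scale:
#' gel is nearly anechoic, dermis strongly echogenic, subcutis intermediate.
#'
#' @param height,width Image size in pixels.
#' @param pixel_spacing Isotropic pixel size in mm/pixel.
#' @param entry_depth_px Row of the gel--dermis interface (skin entry echo).
#' @param dermis_base_depth_px Row of the dermis--subcutis interface; must
#'   exceed `entry_depth_px`.
#' @param layer_intensities Mean intensity of gel, dermis and subcutis, in
#'   that order, on the intensity scale of the image (default 8-bit).
#' @param texture_sigma Standard deviation of the zero-mean within-layer
#'   intensity texture; 0 gives an exactly piecewise-constant image.
#' @return An object of class `skin_phantom_spec`.
#' @seealso [make_skin_phantom()]
#' @export
skin_phantom_spec <- function(height = 128L, width = 128L, pixel_spacing = 0.05,
                              entry_depth_px = 40L, dermis_base_depth_px = 100L,
                              layer_intensities = c(gel = 30, dermis = 160,
                                                    subcutis = 80),
                              texture_sigma = 8) {
  check_scalar_number(height, "height", min = 1, integerish = TRUE)
  check_scalar_number(width, "width", min = 1, integerish = TRUE)
  check_scalar_number(pixel_spacing, "pixel_spacing", min = 0, strict_min = TRUE)
  check_scalar_number(entry_depth_px, "entry_depth_px", integerish = TRUE)
  check_scalar_number(dermis_base_depth_px, "dermis_base_depth_px", integerish = TRUE)
  check_scalar_number(texture_sigma, "texture_sigma", min = 0)
  if (!(entry_depth_px > 0 && entry_depth_px < dermis_base_depth_px &&
        dermis_base_depth_px < height)) {
    abort_validation(
      "`entry_depth_px` and `dermis_base_depth_px` must satisfy 0 < entry < base < height",
      field = "entry_depth_px")
  }
  if (length(layer_intensities) != 3L || !is.numeric(layer_intensities) ||
      any(!is.finite(layer_intensities))) {
    abort_validation("`layer_intensities` must be three finite numbers",
                     field = "layer_intensities")
  }
  structure(
    list(height = as.integer(height), width = as.integer(width),
         pixel_spacing = pixel_spacing,
         entry_depth_px = as.integer(entry_depth_px),
         dermis_base_depth_px = as.integer(dermis_base_depth_px),
         layer_intensities = layer_intensities,
         texture_sigma = texture_sigma),
    class = "skin_phantom_spec")
}

#' Generate a layered-skin B-mode phantom
#'
#' Renders the piecewise-constant layer structure described by a
#' [skin_phantom_spec()] and adds zero-mean Gaussian within-layer texture.
#' The same `(spec, seed)` pair always yields a bit-identical image.
#'
#' @param spec A [skin_phantom_spec()].
#' @param seed Integer seed for the texture realization.
#' @return A list of class `skin_phantom` with elements `image` (numeric
#'   matrix), `pixel_spacing`, and `ground_truth` (list with
#'   `entry_depth_px`, `dermis_base_depth_px`, `thickness_mm`).
#' @examples
#' ph <- make_skin_phantom(skin_phantom_spec(), seed = 1)
#' ph$ground_truth$thickness_mm
#' @export
make_skin_phantom <- function(spec, seed) {
  if (!inherits(spec, "skin_phantom_spec")) {
    abort_validation("`spec` must be a skin_phantom_spec")
  }
  img <- matrix(spec$layer_intensities[[3L]], spec$height, spec$width)
  img[seq_len(spec$entry_depth_px), ] <- spec$layer_intensities[[1L]]
  img[(spec$entry_depth_px + 1L):spec$dermis_base_depth_px, ] <-
    spec$layer_intensities[[2L]]
  if (spec$texture_sigma > 0) {
    img <- img + with_seed(seed, matrix(
      rnorm(spec$height * spec$width, sd = spec$texture_sigma),
      spec$height, spec$width))
  }
  structure(
    list(image = img,
         pixel_spacing = spec$pixel_spacing,
         ground_truth = list(
           entry_depth_px = spec$entry_depth_px,
           dermis_base_depth_px = spec$dermis_base_depth_px,
           thickness_mm = (spec$dermis_base_depth_px - spec$entry_depth_px) *
             spec$pixel_spacing),
         spec = spec),
    class = "skin_phantom")
}

#' Specify a noise model
#'
#' @param kind `"additive_gaussian"` adds a zero-mean Gaussian field of
#'   standard deviation `sigma` (in intensity units), the noise model of the
#'   denoising benchmark; `"speckle_multiplicative"` multiplies the image by
#'   `1 + sigma * G` (sigma a unitless coefficient of variation), an
#'   ultrasound-flavoured option that is off the default paths.
#' @param sigma Nonnegative noise level.
#' @param clip_range Optional length-2 vector `(lo, hi)`; outputs are clipped
#'   into this intensity range after noising.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("additive_gaussian", "speckle_multiplicative"),
                       sigma, clip_range = NULL) {
  kind <- match.arg(kind)
  check_scalar_number(sigma, "sigma", min = 0)
  if (!is.null(clip_range)) {
    if (length(clip_range) != 2L || !is.numeric(clip_range) ||
        !(clip_range[1L] < clip_range[2L])) {
      abort_validation("`clip_range` must be c(lo, hi) with lo < hi",
                       field = "clip_range")
    }
  }
  structure(list(kind = kind, sigma = sigma, clip_range = clip_range),
            class = "noise_spec")
}

#' Add a reproducible noise realization to an image
#'
#' @param image Numeric matrix of finite intensities.
#' @param noise A [noise_spec()].
#' @param seed Integer seed; the same seed reproduces the same realization.
#' @return Noisy image, same shape as the input.
#' @export
add_noise <- function(image, noise, seed) {
  check_image(image)
  if (!inherits(noise, "noise_spec")) {
    abort_validation("`noise` must be a noise_spec")
  }
  out <- if (noise$sigma == 0) {
    image
  } else {
    g <- with_seed(seed, matrix(rnorm(length(image)), nrow(image), ncol(image)))
    switch(noise$kind,
      additive_gaussian = image + noise$sigma * g,
      speckle_multiplicative = image * (1 + noise$sigma * g))
  }
  if (!is.null(noise$clip_range)) {
    out <- pmin(pmax(out, noise$clip_range[1L]), noise$clip_range[2L])
  }
  out
}

#' Specify an elasticity-map phantom with a stiff lesion and optional hard ring
#'
#' Describes a shear-wave elastography modulus map (kPa) with a uniform soft
#' background, a stiffer circular lesion, and optionally a still stiffer
#' margin band of physical width `ring_width_mm` just outside the lesion
#' boundary -- the quantitative analogue of the "hard ring sign" seen at the
#' periphery of sclerotic lesions.
#'
#' Defaults place a 20-pixel-radius lesion of 60 kPa on a 30 kPa dermal
#' background with a 1 mm, 90 kPa ring at 0.1 mm/pixel; normal dermis sits
#' in the tens of kPa while sclerotic tissue is substantially stiffer.
#'
#' @param height,width Map size in pixels.
#' @param pixel_spacing Isotropic pixel size in mm/pixel.
#' @param background_kpa Background modulus, kPa.
#' @param lesion_center Length-2 `(row, col)` center of the lesion disk.
#' @param lesion_radius_px Lesion disk radius in pixels.
#' @param lesion_kpa Lesion modulus, kPa.
#' @param ring_width_mm,ring_kpa Width (mm) and modulus (kPa) of the stiff
#'   margin band; set `ring_width_mm = NULL` for no ring.
#' @param jitter_sigma_kpa Standard deviation of optional Gaussian modulus
#'   jitter added everywhere (values are kept positive).
#' @return An object of class `elasticity_phantom_spec`.
#' @export
elasticity_phantom_spec <- function(height = 96L, width = 96L,
                                    pixel_spacing = 0.1,
                                    background_kpa = 30,
                                    lesion_center = c(48, 48),
                                    lesion_radius_px = 20,
                                    lesion_kpa = 60,
                                    ring_width_mm = 1, ring_kpa = 90,
                                    jitter_sigma_kpa = 2) {
  check_scalar_number(height, "height", min = 1, integerish = TRUE)
  check_scalar_number(width, "width", min = 1, integerish = TRUE)
  check_scalar_number(pixel_spacing, "pixel_spacing", min = 0, strict_min = TRUE)
  check_scalar_number(background_kpa, "background_kpa", min = 0, strict_min = TRUE)
  check_scalar_number(lesion_radius_px, "lesion_radius_px", min = 0, strict_min = TRUE)
  check_scalar_number(lesion_kpa, "lesion_kpa", min = 0, strict_min = TRUE)
  check_scalar_number(jitter_sigma_kpa, "jitter_sigma_kpa", min = 0)
  if (length(lesion_center) != 2L || !is.numeric(lesion_center)) {
    abort_validation("`lesion_center` must be c(row, col)", field = "lesion_center")
  }
  if (!is.null(ring_width_mm)) {
    check_scalar_number(ring_width_mm, "ring_width_mm", min = 0, strict_min = TRUE)
    check_scalar_number(ring_kpa, "ring_kpa", min = 0, strict_min = TRUE)
  }
  r <- lesion_radius_px
  if (lesion_center[1L] - r < 1 || lesion_center[1L] + r > height ||
      lesion_center[2L] - r < 1 || lesion_center[2L] + r > width) {
    abort_validation("lesion disk must lie fully inside the image",
                     field = "lesion_center")
  }
  structure(
    list(height = as.integer(height), width = as.integer(width),
         pixel_spacing = pixel_spacing, background_kpa = background_kpa,
         lesion_center = lesion_center, lesion_radius_px = lesion_radius_px,
         lesion_kpa = lesion_kpa, ring_width_mm = ring_width_mm,
         ring_kpa = ring_kpa, jitter_sigma_kpa = jitter_sigma_kpa),
    class = "elasticity_phantom_spec")
}

#' Generate an elasticity-map phantom
#'
#' @param spec An [elasticity_phantom_spec()].
#' @param seed Integer seed for the modulus jitter.
#' @return A list of class `elasticity_phantom` with elements `map` (kPa
#'   matrix), `mask` (logical matrix marking the lesion disk only),
#'   and `pixel_spacing`.
#' @export
make_elasticity_phantom <- function(spec, seed) {
  if (!inherits(spec, "elasticity_phantom_spec")) {
    abort_validation("`spec` must be an elasticity_phantom_spec")
  }
  rows <- matrix(seq_len(spec$height), spec$height, spec$width)
  cols <- matrix(seq_len(spec$width), spec$height, spec$width, byrow = TRUE)
  dist_c <- sqrt((rows - spec$lesion_center[1L])^2 +
                 (cols - spec$lesion_center[2L])^2)
  mask <- dist_c <= spec$lesion_radius_px
  map <- matrix(spec$background_kpa, spec$height, spec$width)
  if (!is.null(spec$ring_width_mm)) {
    ring_px <- spec$ring_width_mm / spec$pixel_spacing
    map[!mask & dist_c <= spec$lesion_radius_px + ring_px] <- spec$ring_kpa
  }
  map[mask] <- spec$lesion_kpa
  if (spec$jitter_sigma_kpa > 0) {
    map <- map + with_seed(seed, matrix(
      rnorm(length(map), sd = spec$jitter_sigma_kpa), spec$height, spec$width))
    map <- pmax(map, 0.1)  # modulus maps are strictly positive
  }
  structure(list(map = map, mask = mask, pixel_spacing = spec$pixel_spacing,
                 spec = spec),
            class = "elasticity_phantom")
}

#' Specify a two-group cohort of per-subject measurements
#'
#' Controls are drawn from `Normal(base_mean, base_sd)` and cases from
#' `Normal(base_mean + effect_size * base_sd, base_sd)`, so `effect_size` is
#' the standardized mean difference (Cohen's d) of the simulated measurement
#' (an Emean in kPa, a thickness in mm, ...).
#'
#' @param n_cases,n_controls Group sizes (>= 1).
#' @param effect_size Standardized group difference.
#' @param base_mean,base_sd Control-group mean and common standard deviation.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 50L, n_controls = 50L, effect_size = 1,
                        base_mean = 30, base_sd = 5, seed = 1L) {
  check_scalar_number(n_cases, "n_cases", min = 1, integerish = TRUE)
  check_scalar_number(n_controls, "n_controls", min = 1, integerish = TRUE)
  check_scalar_number(effect_size, "effect_size")
  check_scalar_number(base_mean, "base_mean")
  check_scalar_number(base_sd, "base_sd", min = 0, strict_min = TRUE)
  check_scalar_number(seed, "seed", integerish = TRUE)
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         effect_size = effect_size, base_mean = base_mean, base_sd = base_sd,
         seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Simulate a two-group cohort
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `subject_id`, `group` (`"case"` /
#'   `"control"`) and `measurement`.
#' @examples
#' make_cohort(cohort_spec(n_cases = 3, n_controls = 2, seed = 7))
#' @export
make_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    abort_validation("`spec` must be a cohort_spec")
  }
  with_seed(spec$seed, {
    cases <- rnorm(spec$n_cases,
                   mean = spec$base_mean + spec$effect_size * spec$base_sd,
                   sd = spec$base_sd)
    controls <- rnorm(spec$n_controls, mean = spec$base_mean, sd = spec$base_sd)
    tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(spec$n_cases + spec$n_controls)),
      group = rep(c("case", "control"), c(spec$n_cases, spec$n_controls)),
      measurement = c(cases, controls))
  })
}
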