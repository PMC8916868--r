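#' Shell ring of given physical width around a lesion mask
#'
#' The "shell" of a shear-wave elastogram: the band of pixels outside the
#' outlined lesion whose Euclidean distance to the nearest lesion pixel is
#' at most `width_mm` (e.g. the 1 mm or 2 mm area outside the lesion
#' boundary over which modulus statistics are read). Defined through an
#' exact Euclidean distance transform; the mm width is converted to a
#' real-valued pixel threshold `width_mm / spacing` with no rounding.
#'
#' @param mask Logical matrix marking the lesion (at least one `TRUE`).
#' @param width_mm Shell width in mm (> 0).
#' @param spacing Pixel size in mm/pixel (> 0).
#' @return Logical matrix of the ring, disjoint from `mask`.
#' @export
shell_ring <- function(mask, width_mm, spacing) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    abort_validation("`mask` must be a logical matrix", field = "mask")
  }
  if (!any(mask)) abort_validation("`mask` has no lesion pixels", field = "mask")
  check_scalar_number(width_mm, "width_mm", min = 0, strict_min = TRUE)
  check_scalar_number(spacing, "spacing", min = 0, strict_min = TRUE)
  # distance of every non-lesion pixel to the nearest lesion pixel
  d <- EBImage::distmap(matrix(as.numeric(!mask), nrow(mask), ncol(mask)),
                        metric = "euclidean")
  d <- matrix(as.numeric(d), nrow(mask), ncol(mask))
  !mask & d <= width_mm / spacing
}

#' Elastic-modulus statistics over a region of interest
#'
#' The scanner-style ROI readout: maximum, mean, minimum and standard
#' deviation (sample, n - 1) of the modulus values under the ROI mask.
#'
#' @param map Numeric matrix of elastic moduli in kPa.
#' @param roi Logical matrix, same shape, with at least one `TRUE` pixel.
#' @return One-row tibble with `emax`, `emean`, `emin`, `esd` (kPa) and
#'   `n_pixels`.
#' @export
modulus_stats <- function(map, roi) {
  check_image(map, "map")
  if (!is.matrix(roi) || !is.logical(roi)) {
    abort_validation("`roi` must be a logical matrix", field = "roi")
  }
  check_same_shape(map, roi)
  v <- map[roi]
  if (length(v) == 0L) abort_validation("`roi` is empty", field = "roi")
  tibble::tibble(
    emax = max(v), emean = mean(v), emin = min(v),
    esd = if (length(v) > 1L) sd(v) else 0,
    n_pixels = length(v))
}

#' Elastic modulus from stress and strain
#'
#' `E = S / e`: tissue stiffness as the ratio of applied stress to the
#' resulting strain, in the units of `S`.
#'
#' @param S Stress (pressure units).
#' @param e Strain (dimensionless, nonzero).
#' @return `S / e`.
#' @export
elastic_modulus <- function(S, e) {
  if (any(e == 0)) {
    abort("strain `e` must be nonzero", class = "sweshell_validation_error")
  }
  S / e
}

#' Relative difference of elastic modulus, lesion vs control skin
#'
#' The signed percent difference `100 * (e_lesion - e_control) / e_control`
#' (the M_RD of lesion-versus-normal comparisons).
#'
#' @param e_lesion,e_control Moduli in kPa; `e_control` must be positive.
#' @return Percent difference.
#' @export
relative_difference <- function(e_lesion, e_control) {
  if (any(e_control <= 0)) {
    abort_validation("`e_control` must be positive", field = "e_control")
  }
  100 * (e_lesion - e_control) / e_control
}

#' Measure dermal thickness from a B-mode image
#'
#' Each A-line (image column) is smoothed with a centered moving average,
#' its axial derivative is taken, and the two largest-magnitude derivative
#' extrema separated by at least `min_thickness_mm` are read as the skin
#' entry echo and the dermis--subcutis interface. The reported thickness is
#' the median across columns of the interface separation, in mm. The median
#' makes the estimate robust to local dropouts in single columns.
#'
#' @param bmode Numeric matrix, rows = depth.
#' @param pixel_spacing Pixel size in mm/pixel.
#' @param column_range Optional integer vector of columns to use (default
#'   all).
#' @param smooth_width Moving-average width in pixels (default 5).
#' @param min_thickness_mm Minimum interface separation in mm (default 0.5).
#' @return Thickness in mm.
#' @export
measure_thickness <- function(bmode, pixel_spacing, column_range = NULL,
                              smooth_width = 5L, min_thickness_mm = 0.5) {
  check_image(bmode, "bmode")
  check_scalar_number(pixel_spacing, "pixel_spacing", min = 0, strict_min = TRUE)
  check_scalar_number(smooth_width, "smooth_width", min = 1, integerish = TRUE)
  check_scalar_number(min_thickness_mm, "min_thickness_mm", min = 0)
  cols <- if (is.null(column_range)) seq_len(ncol(bmode)) else column_range
  if (any(cols < 1 | cols > ncol(bmode))) {
    abort_validation("`column_range` outside the image", field = "column_range")
  }
  min_px <- min_thickness_mm / pixel_spacing
  half <- smooth_width %/% 2L
  seps <- vapply(cols, function(cc) {
    a <- bmode[, cc]
    s <- as.numeric(stats::filter(a, rep(1 / smooth_width, smooth_width),
                                  sides = 2))
    valid <- which(!is.na(s))
    if (length(valid) < 2L) return(NA_real_)
    d <- diff(s[valid])
    rows <- valid[-length(valid)]       # derivative between rows[k], rows[k]+1
    mag <- abs(d)
    if (max(mag) == 0) return(NA_real_)
    # a step smoothed over `smooth_width` rows yields a plateau of equal
    # derivative magnitudes; take the center of the tied run so the
    # detected row is the interface itself
    pick_peak <- function(cand) {
      mx <- max(mag[cand])
      if (mx == 0) return(NA_integer_)
      tied <- cand[mag[cand] >= mx - (1e-9 * mx + 1e-12)]
      tied[which.min(abs(tied - mean(tied)))]
    }
    i1 <- pick_peak(seq_along(mag))
    far <- which(abs(rows - rows[i1]) >= min_px)
    if (length(far) == 0L) return(NA_real_)
    i2 <- pick_peak(far)
    if (is.na(i2)) return(NA_real_)
    abs(rows[i2] - rows[i1])
  }, numeric(1))
  seps <- seps[!is.na(seps)]
  if (length(seps) == 0L) {
    abort_detection("no pair of interfaces detected in any column")
  }
  median(seps) * pixel_spacing
}

#' Average of three repeated measurements
#'
#' Scanner practice: the same site is measured three consecutive times and
#' the arithmetic mean is reported.
#'
#' @param values Numeric vector of exactly 3 finite measurements.
#' @return Their mean.
#' @export
average_repeats <- function(values) {
  if (length(values) != 3L || !is.numeric(values) || any(!is.finite(values))) {
    abort_validation("`values` must be exactly 3 finite measurements",
                     field = "values")
  }
  mean(values)
}
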