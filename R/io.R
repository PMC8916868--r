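#' Write an image as a 32-bit TIFF with a range sidecar
#'
#' TIFF storage is unit-range; intensities are affinely rescaled to `[0, 1]`
#' and the original range recorded in a small JSON sidecar at `<path>.json`,
#' so [read_image_tiff()] restores the raw values (kPa, 8-bit intensities,
#' ...) to about nine significant digits.
#'
#' @param image Numeric matrix.
#' @param path Output path.
#' @param sidecar Extra named fields merged into the sidecar JSON.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path, sidecar = list()) {
  check_image(image)
  lo <- min(image); hi <- max(image)
  unit <- if (hi > lo) (image - lo) / (hi - lo) else image * 0
  tiff::writeTIFF(unit, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- c(list(offset = lo, scale = max(hi - lo, 0)), sidecar)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image written by [write_image_tiff()]
#'
#' @param path TIFF path; the `<path>.json` sidecar, if present, restores
#'   the original intensity range.
#' @return Numeric matrix.
#' @export
read_image_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m <- matrix(as.numeric(m), nrow(m), ncol(m))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    m <- m * meta$scale + meta$offset
  }
  m
}

#' Write a binary mask as a 0/255 PNG
#'
#' @param mask Logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    abort_validation("`mask` must be a logical matrix", field = "mask")
  }
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a mask written by [write_mask_png()]
#'
#' @param path PNG path.
#' @return Logical matrix (pixel > 0.5).
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(m > 0.5, nrow(m), ncol(m))
}

#' Write an elasticity map; the sidecar carries the pixel spacing
#'
#' @param map Numeric matrix of moduli in kPa.
#' @param spacing Pixel size in mm/pixel.
#' @param path TIFF path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_elasticity_map <- function(map, spacing, path) {
  write_image_tiff(map, path,
                   sidecar = list(pixel_spacing_mm = spacing, units = "kPa"))
  invisible(path)
}

#' Read an elasticity map and its spacing sidecar
#'
#' @param path TIFF path written by [write_elasticity_map()].
#' @return List with `map` and `pixel_spacing`.
#' @export
read_elasticity_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  list(map = read_image_tiff(path), pixel_spacing = meta$pixel_spacing_mm)
}

#' Write a cohort table as CSV
#'
#' Layout: header `subject_id,group,measurement`.
#'
#' @param cohort Tibble from [make_cohort()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort CSV
#'
#' @param path CSV path with columns `subject_id,group,measurement`.
#' @return Tibble.
#' @export
read_cohort_csv <- function(path) {
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
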