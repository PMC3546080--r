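#' Segmented nerve-plexus image
#'
#' Container for a pre-segmented binary nerve mask together with its pixel
#' calibration. The mask is stored as an integer matrix in row-major raster
#' convention: rows run top to bottom, columns left to right, and each pixel
#' is a unit square. Foreground (`1`) marks nerve-fibre pixels, background
#' (`0`) everything else.
#'
#' The default pixel pitch corresponds to the HRT II / Rostock Cornea Module
#' field used for subbasal nerve plexus imaging: 400 um across 384 px, i.e.
#' 400/384 = 1.0417 um per pixel edge.
#'
#' @param mask integer or logical matrix; any non-zero entry is foreground.
#' @param pixel_pitch_um physical edge length of one pixel in micrometres.
#' @return An object of class `sbp_image` with fields `mask` (0/1 integer
#'   matrix), `width_px`, `height_px` and `pixel_pitch_um`.
#' @examples
#' img <- sbp_image(matrix(0L, 16, 16))
#' image_area_mm2(img)
#' @export
sbp_image <- function(mask, pixel_pitch_um = DEFAULT_PITCH_UM) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix")
  if (nrow(mask) < 3L || ncol(mask) < 3L)
    stop("mask must be at least 3x3 pixels")
  if (!is.numeric(pixel_pitch_um) || length(pixel_pitch_um) != 1L ||
      !is.finite(pixel_pitch_um) || pixel_pitch_um <= 0)
    stop("`pixel_pitch_um` must be a single positive number")
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  structure(
    list(mask = m,
         width_px = ncol(m),
         height_px = nrow(m),
         pixel_pitch_um = pixel_pitch_um),
    class = "sbp_image")
}

#' @rdname sbp_image
#' @export
DEFAULT_PITCH_UM <- 400 / 384

#' @rdname sbp_image
#' @param x an `sbp_image`.
#' @export
image_area_mm2 <- function(x) {
  stopifnot(inherits(x, "sbp_image"))
  x$width_px * x$height_px * x$pixel_pitch_um^2 / 1e6
}

#' @export
print.sbp_image <- function(x, ...) {
  cat(sprintf("<sbp_image> %d x %d px, pitch %.4f um/px (%.4f mm^2), %d foreground px\n",
              x$width_px, x$height_px, x$pixel_pitch_um,
              image_area_mm2(x), sum(x$mask)))
  invisible(x)
}

# Field calibration: pitch plus physical field extent, consistency-checked.
# The imaged field is taken to be 400 x 400 um (pitch * pixels per axis);
# field extents must agree with width_px * pitch to within 0.5 %.
#' Pixel calibration for a segmented image
#'
#' @param pixel_pitch_um micrometres per pixel edge.
#' @param field_width_um,field_height_um physical field extent in um; defaults
#'   are derived from the image dimensions when attached to an image.
#' @return list of class `sbp_calibration`.
#' @export
sbp_calibration <- function(pixel_pitch_um = DEFAULT_PITCH_UM,
                            field_width_um = NULL, field_height_um = NULL) {
  if (pixel_pitch_um <= 0) stop("pixel pitch must be positive")
  structure(list(pixel_pitch_um = pixel_pitch_um,
                 field_width_um = field_width_um,
                 field_height_um = field_height_um),
            class = "sbp_calibration")
}

check_calibration <- function(cal, width_px, height_px) {
  if (!is.null(cal$field_width_um)) {
    expected <- width_px * cal$pixel_pitch_um
    if (abs(cal$field_width_um - expected) / expected > 0.005)
      stop(sprintf("field_width_um (%.2f) inconsistent with %d px at %.4f um/px",
                   cal$field_width_um, width_px, cal$pixel_pitch_um))
  }
  if (!is.null(cal$field_height_um)) {
    expected <- height_px * cal$pixel_pitch_um
    if (abs(cal$field_height_um - expected) / expected > 0.005)
      stop(sprintf("field_height_um (%.2f) inconsistent with %d px at %.4f um/px",
                   cal$field_height_um, height_px, cal$pixel_pitch_um))
  }
  invisible(TRUE)
}

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!file.exists(path)) stop("cannot read mask, file not found: ", path)
  arr <- switch(ext,
    png = tryCatch(png::readPNG(path),
                   error = function(e) stop("failed to decode PNG '", path,
                                            "': ", conditionMessage(e))),
    tif = ,
    tiff = tryCatch(tiff::readTIFF(path),
                    error = function(e) stop("failed to decode TIFF '", path,
                                             "': ", conditionMessage(e))),
    stop("unsupported raster format '", ext, "' for ", path,
         " (PNG or TIFF expected)"))
  if (length(dim(arr)) == 3L) {
    # multi-channel: collapse to luminance (Rec. 601) before thresholding
    nc <- dim(arr)[3]
    if (nc >= 3L) {
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  if (any(dim(arr) == 0L)) stop("empty (0-dimension) image: ", path)
  arr
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Read a binary nerve mask from PNG or TIFF
#'
#' Reads a single-channel (or RGB, collapsed by luminance) raster and
#' thresholds it to a binary mask. Pixel calibration is taken from a JSON
#' sidecar `<image>.json` containing `{"pixel_pitch_um": ...}` when present,
#' otherwise from `pixel_pitch_um`.
#'
#' @param path path to a PNG or TIFF mask.
#' @param binarize_threshold intensity cut in `[0, 255]`; pixels strictly
#'   brighter become foreground.
#' @param invert if `TRUE`, dark pixels are treated as nerve.
#' @param pixel_pitch_um fallback calibration when no sidecar exists.
#' @return an [sbp_image].
#' @export
read_mask <- function(path, binarize_threshold = 127, invert = FALSE,
                      pixel_pitch_um = DEFAULT_PITCH_UM) {
  if (binarize_threshold < 0 || binarize_threshold > 255)
    stop("binarize_threshold must lie in [0, 255]")
  arr <- read_raster(path)
  mask <- (arr * 255) > binarize_threshold
  if (invert) mask <- !mask
  pitch <- pixel_pitch_um
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc)
    if (!is.null(meta$pixel_pitch_um)) pitch <- as.numeric(meta$pixel_pitch_um)
  }
  sbp_image(mask * 1L, pixel_pitch_um = pitch)
}

#' Write a binary nerve mask losslessly
#'
#' Foreground is written as white (255), background as black (0), in a
#' single-channel 8-bit raster, so that `read_mask(write_mask(x))` returns
#' `x` bit-for-bit. A JSON sidecar with the pixel pitch is written alongside
#' unless `sidecar = FALSE`.
#'
#' @param img an [sbp_image].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @param sidecar write the `{"pixel_pitch_um": ...}` sidecar.
#' @export
write_mask <- function(img, path, sidecar = TRUE) {
  stopifnot(inherits(img, "sbp_image"))
  if (!dir.exists(dirname(path)))
    stop("cannot write mask, directory does not exist: ", dirname(path))
  arr <- img$mask * 1.0  # png/tiff expect [0,1] doubles
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(arr, target = path),
    tif = ,
    tiff = tiff::writeTIFF(arr, where = path, bits.per.sample = 8L),
    stop("unsupported output format '", ext, "'"))
  if (sidecar)
    jsonlite::write_json(list(pixel_pitch_um = img$pixel_pitch_um),
                         sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
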