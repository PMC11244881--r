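#' Grayscale image container
#'
#' Lightweight container for a single-channel image with intensities
#' normalized to \[0, 1\]. Pixels are stored as a numeric matrix indexed
#' \[row, col\]; throughout the package x = col and y = row, both 0-based,
#' with y increasing downward (image convention).
#'
#' @param pixels numeric matrix of intensities in \[0, 1\].
#' @param source_path optional path the image was read from.
#' @return an object of class \code{gray_image}.
#' @export
gray_image <- function(pixels, source_path = NA_character_) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one pixel")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop("intensities must lie in [0, 1]")
  structure(list(pixels = pixels, source_path = source_path),
            class = "gray_image")
}

#' Binary (mask) image with calibration
#'
#' @param mask logical matrix; \code{TRUE} marks foreground (nuclear signal).
#' @param pixel_size_um physical side length of one pixel, in micrometers.
#' @param timepoint label such as \code{"Day0"} or \code{"Day2"}.
#' @return an object of class \code{binary_image}.
#' @export
binary_image <- function(mask, pixel_size_um = 1, timepoint = "") {
  if (is.numeric(mask) && is.matrix(mask)) mask <- mask > 0.5
  if (!is.matrix(mask) || !is.logical(mask))
    stop("'mask' must be a logical matrix")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      is.na(pixel_size_um) || pixel_size_um <= 0)
    stop("'pixel_size_um' must be a single positive number")
  structure(list(mask = mask, pixel_size_um = pixel_size_um,
                 timepoint = timepoint),
            class = "binary_image")
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' @export
dim.binary_image <- function(x) dim(x$mask)

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, intensity range [%.3f, %.3f]\n",
              nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("<binary_image%s> %d x %d px, %d foreground px, %.3g um/px\n",
              if (nzchar(x$timepoint)) paste0(" ", x$timepoint) else "",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$pixel_size_um))
  invisible(x)
}

# reduce a H x W x C array to luminance (Rec. 709 weights); pass matrices
# through unchanged
.to_luminance <- function(a) {
  if (is.matrix(a)) return(a)
  if (length(dim(a)) == 3L) {
    if (dim(a)[3L] >= 3L)
      return(0.2126 * a[, , 1L] + 0.7152 * a[, , 2L] + 0.0722 * a[, , 3L])
    return(a[, , 1L])
  }
  stop("unsupported image array layout")
}

#' Read a grayscale image from TIFF or PNG
#'
#' Intensities are rescaled to \[0, 1\] (8- and 16-bit images are divided by
#' the type maximum by the underlying readers); RGB images are converted to
#' luminance. A multi-page TIFF is treated as a z-stack and collapsed by
#' maximum projection.
#'
#' @param path path to a TIFF or PNG file.
#' @return a [gray_image].
#' @seealso [load_gray_stack()] to keep the individual z-slices.
#' @export
load_grayscale <- function(path) {
  slices <- load_gray_stack(path)
  if (length(slices) == 1L) slices[[1L]] else max_z_projection(slices)
}

#' Read a (possibly multi-page) image as a list of grayscale slices
#'
#' @inheritParams load_grayscale
#' @return list of [gray_image] objects, one per page.
#' @export
load_gray_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path, all = TRUE),
    png = png::readPNG(path),
    stop("unsupported image format '.", ext, "' (use TIFF or PNG): ", path))
  if (!is.list(raw)) raw <- list(raw)
  lapply(raw, function(a) {
    m <- .to_luminance(a)
    if (length(m) == 0L) stop("zero-sized image: ", path)
    # clamp reader round-off
    m[m < 0] <- 0; m[m > 1] <- 1
    gray_image(m, source_path = path)
  })
}

#' Maximum z-projection of an image stack
#'
#' Collapses a fluorescence z-stack to a single 2D image by taking the
#' per-pixel maximum across slices.
#'
#' @param slices list of [gray_image] objects (or numeric matrices) of
#'   identical dimensions.
#' @return a [gray_image].
#' @export
max_z_projection <- function(slices) {
  if (length(slices) < 1L) stop("need at least one slice")
  mats <- lapply(slices, function(s) if (inherits(s, "gray_image")) s$pixels else s)
  d <- dim(mats[[1L]])
  for (m in mats) if (!identical(dim(m), d)) stop("slice shape mismatch")
  proj <- Reduce(pmax, mats)
  src <- if (inherits(slices[[1L]], "gray_image")) slices[[1L]]$source_path else NA_character_
  gray_image(proj, source_path = src)
}

# linear stretch of the 1st-99th intensity percentiles to [0, 1], clipped
.stretch_contrast <- function(m, probs = c(0.01, 0.99)) {
  q <- stats::quantile(m, probs = probs, names = FALSE)
  if (q[2L] <= q[1L]) return(m)
  m <- (m - q[1L]) / (q[2L] - q[1L])
  m[m < 0] <- 0; m[m > 1] <- 1
  m
}

#' Binarize a grayscale image with a global threshold
#'
#' A pixel is foreground iff its (optionally corrected) intensity strictly
#' exceeds \code{threshold}. Optional pre-processing, both off by default:
#' background subtraction by morphological white top-hat (removes smooth
#' background larger than the structuring element) and linear contrast
#' stretching of the 1st-99th percentiles. The default threshold of 0.16 on
#' the \[0, 1\] intensity range works well for typical Hoechst-stained
#' maximum projections.
#'
#' @param img a [gray_image].
#' @param threshold global threshold in \[0, 1\].
#' @param subtract_background logical; apply white top-hat first.
#' @param enhance_contrast logical; apply percentile stretch (after
#'   background subtraction, before thresholding).
#' @param bg_radius structuring-element (disc) radius in px for the top-hat.
#' @param pixel_size_um calibration carried into the result.
#' @param timepoint label carried into the result.
#' @return a [binary_image].
#' @export
binarize_global <- function(img, threshold = 0.16,
                            subtract_background = FALSE,
                            enhance_contrast = FALSE,
                            bg_radius = 50,
                            pixel_size_um = 1, timepoint = "") {
  if (!inherits(img, "gray_image")) img <- gray_image(img)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1)
    stop("'threshold' must be a single value in [0, 1]")
  m <- img$pixels
  if (isTRUE(subtract_background)) {
    brush <- EBImage::makeBrush(2L * as.integer(bg_radius) + 1L, shape = "disc")
    m <- as.matrix(EBImage::whiteTopHat(m, brush))
  }
  if (isTRUE(enhance_contrast)) m <- .stretch_contrast(m)
  binary_image(m > threshold, pixel_size_um = pixel_size_um,
               timepoint = timepoint)
}

#' Apply the circular field-of-view mask
#'
#' Sets to background every pixel whose center lies outside the inscribed
#' circle centered at the image center ((H-1)/2, (W-1)/2) with radius
#' min(H, W)/2. This removes the corner/long-axis bias of a rectangular
#' frame: all retained directions see the same maximal extent.
#'
#' @param img a [binary_image].
#' @return a [binary_image] of the same shape.
#' @export
apply_circular_mask <- function(img) {
  stopifnot(inherits(img, "binary_image"))
  h <- nrow(img$mask); w <- ncol(img$mask)
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  r <- min(h, w) / 2
  yy <- matrix(0:(h - 1), h, w)
  xx <- matrix(0:(w - 1), h, w, byrow = TRUE)
  keep <- (xx - cx)^2 + (yy - cy)^2 <= r^2
  binary_image(img$mask & keep, img$pixel_size_um, img$timepoint)
}

#' Apply a correction mask
#'
#' Non-interactive replacement for manual artifact removal: pixels where the
#' correction mask is \code{FALSE} are forced to background (logical AND).
#'
#' @param img a [binary_image].
#' @param correction logical matrix (or [binary_image]) of the same shape;
#'   \code{TRUE} = keep.
#' @return a [binary_image].
#' @export
apply_correction_mask <- function(img, correction) {
  stopifnot(inherits(img, "binary_image"))
  keep <- if (inherits(correction, "binary_image")) correction$mask else correction
  if (is.numeric(keep)) keep <- keep > 0.5
  if (!identical(dim(keep), dim(img$mask)))
    stop("correction mask shape ", paste(dim(keep), collapse = "x"),
         " does not match image shape ", paste(dim(img$mask), collapse = "x"))
  binary_image(img$mask & keep, img$pixel_size_um, img$timepoint)
}

#' Write a binary image to PNG or TIFF
#'
#' Foreground is written as 255, background as 0 (8-bit).
#'
#' @param img a [binary_image].
#' @param path output path ending in .png, .tif or .tiff.
#' @return the path, invisibly.
#' @export
write_binary_image <- function(img, path) {
  stopifnot(inherits(img, "binary_image"))
  m <- ifelse(img$mask, 1, 0)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(m, path),
    tif = ,
    tiff = tiff::writeTIFF(m, path, bits.per.sample = 8L),
    stop("unsupported output format: .", ext))
  invisible(path)
}
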