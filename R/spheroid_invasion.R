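#' Quantify spheroid invasion from an image pair
#'
#' The main entry point: given images of the same spheroid at the initial
#' and final timepoint, runs the full pixel-based quantification pipeline —
#' binarization (if the input is grayscale), optional correction and
#' circular field-of-view masking, initial-boundary segmentation, centroid
#' registration, outer-pixel identification, radial distance/angle
#' measurement, the invasion summary (area change, mean/max distance,
#' radial area moment of inertia) and, when enough outer pixels exist, the
#' PCA directionality analysis.
#'
#' @param day0,day2 the initial and final image. Each may be a file path
#'   (TIFF/PNG), a numeric matrix in \[0, 1\] (grayscale), a logical matrix
#'   (pre-binarized), a [gray_image] or a [binary_image]. Grayscale inputs
#'   are binarized with \code{threshold}; matrices containing only 0/1 (or
#'   logical values) are treated as already binarized.
#' @param pixel_size_um calibration, micrometers per pixel side.
#' @param threshold global binarization threshold in \[0, 1\].
#' @param subtract_background,enhance_contrast passed to
#'   [binarize_global()] for grayscale inputs.
#' @param circular_mask apply the inscribed circular field-of-view mask to
#'   both timepoints (recommended; removes corner bias).
#' @param correction_day0,correction_day2 optional keep-masks (logical
#'   matrix or [binary_image]) for non-interactive artifact removal.
#' @param pca_origin origin for the directionality PCA: \code{"mean"} of
#'   the outer pixels (default) or the spheroid \code{"centroid"}.
#' @param spheroid_id identifier used in printed and exported results.
#' @param min_pixels_pca minimum number of outer pixels required to attempt
#'   the directionality analysis.
#' @return an object of class \code{spheroid_invasion} with components
#'   \code{metrics} (class \code{invasion_metrics}), \code{directionality}
#'   (class \code{directional_metrics} or \code{NULL} when there are too
#'   few outer pixels), \code{cloud}, \code{boundary} (registered),
#'   \code{boundary_day0} (unregistered), \code{day0}, \code{day2} and
#'   \code{call}. Methods: \code{print}, \code{summary}, \code{plot} (polar
#'   plot of the invaded pixels), \code{as.data.frame} (one-row metrics
#'   record).
#' @examples
#' pair <- make_annulus_pair(R0_mm = 0.3, R1_mm = 0.5, pixel_size_um = 20)
#' fit <- spheroid_invasion(pair$day0, pair$day2, pixel_size_um = 20)
#' fit
#' @export
spheroid_invasion <- function(day0, day2, pixel_size_um = 1,
                              threshold = 0.16,
                              subtract_background = FALSE,
                              enhance_contrast = FALSE,
                              circular_mask = TRUE,
                              correction_day0 = NULL,
                              correction_day2 = NULL,
                              pca_origin = c("mean", "centroid"),
                              spheroid_id = "spheroid",
                              min_pixels_pca = 2L) {
  pca_origin <- match.arg(pca_origin)
  b0 <- .as_binary(day0, pixel_size_um, threshold, subtract_background,
                   enhance_contrast, "Day0")
  b2 <- .as_binary(day2, pixel_size_um, threshold, subtract_background,
                   enhance_contrast, "Day2")
  if (!is.null(correction_day0)) b0 <- apply_correction_mask(b0, correction_day0)
  if (!is.null(correction_day2)) b2 <- apply_correction_mask(b2, correction_day2)
  if (isTRUE(circular_mask)) {
    b0 <- apply_circular_mask(b0)
    b2 <- apply_circular_mask(b2)
  }
  boundary0 <- extract_boundary(extract_spheroid_mask(b0))
  boundary <- register_boundary(boundary0, day2_centroid(b2))
  cloud <- find_outer_pixels(b2, boundary)
  metrics <- summarize_invasion(b0, b2, cloud, spheroid_id = spheroid_id)
  direc <- if (nrow(cloud$points) >= min_pixels_pca)
    directionality_summary(cloud, origin = pca_origin) else NULL
  structure(list(metrics = metrics, directionality = direc, cloud = cloud,
                 boundary = boundary, boundary_day0 = boundary0,
                 day0 = b0, day2 = b2, call = match.call()),
            class = "spheroid_invasion")
}

# coerce the flexible day0/day2 inputs to a binary_image
.as_binary <- function(x, pixel_size_um, threshold, subtract_background,
                       enhance_contrast, timepoint) {
  if (inherits(x, "binary_image")) {
    if (!isTRUE(all.equal(x$pixel_size_um, pixel_size_um)) &&
        x$pixel_size_um != 1)
      stop("calibration of supplied binary_image disagrees with 'pixel_size_um'")
    return(binary_image(x$mask, pixel_size_um, timepoint))
  }
  if (is.character(x) && length(x) == 1L) x <- load_grayscale(x)
  if (is.logical(x) && is.matrix(x))
    return(binary_image(x, pixel_size_um, timepoint))
  if (is.numeric(x) && is.matrix(x) && all(x %in% c(0, 1)))
    return(binary_image(x > 0.5, pixel_size_um, timepoint))
  binarize_global(x, threshold = threshold,
                  subtract_background = subtract_background,
                  enhance_contrast = enhance_contrast,
                  pixel_size_um = pixel_size_um, timepoint = timepoint)
}

#' @export
print.spheroid_invasion <- function(x, ...) {
  cat("Pixel-based spheroid invasion quantification\n")
  print(x$metrics)
  if (!is.null(x$directionality)) print(x$directionality)
  else cat("  (directionality not computed: too few outer pixels)\n")
  invisible(x)
}

#' @export
summary.spheroid_invasion <- function(object, ...) {
  df <- as.data.frame(object)
  cat(sprintf("Spheroid '%s': %d x %d px frame, %.3g um/px\n",
              object$metrics$spheroid_id,
              nrow(object$day2$mask), ncol(object$day2$mask),
              object$day2$pixel_size_um))
  cat(sprintf("Initial footprint: %.4g mm^2 enclosed by a %d-vertex boundary\n",
              object$boundary$area_px2 *
                (object$day2$pixel_size_um / 1000)^2,
              nrow(object$boundary$vertices)))
  print(object)
  invisible(df)
}

#' @export
as.data.frame.spheroid_invasion <- function(x, ...) {
  m <- x$metrics
  d <- x$directionality
  data.frame(
    spheroid_id = m$spheroid_id,
    delta_area_mm2 = m$delta_area_mm2,
    mean_distance_mm = m$mean_distance_mm,
    max_distance_mm = m$max_distance_mm,
    radial_moment_mm4 = m$radial_moment_mm4,
    n_outer_pixels = m$n_outer_pixels,
    shrinkage = m$shrinkage,
    angle_max_deg = if (is.null(d)) NA_real_ else d$angle_max_deg,
    angle_min_deg = if (is.null(d)) NA_real_ else d$angle_min_deg,
    I_max_mm4 = if (is.null(d)) NA_real_ else d$I_max_mm4,
    I_min_mm4 = if (is.null(d)) NA_real_ else d$I_min_mm4,
    mean_d_max_mm = if (is.null(d)) NA_real_ else d$mean_d_max_mm,
    mean_d_min_mm = if (is.null(d)) NA_real_ else d$mean_d_min_mm,
    fold_change_moment = if (is.null(d)) NA_real_ else d$fold_change_moment,
    fold_change_distance = if (is.null(d)) NA_real_ else d$fold_change_distance,
    isotropic = if (is.null(d)) NA else d$isotropic,
    stringsAsFactors = FALSE)
}

#' Polar plot of invaded pixels
#'
#' Plots each outer pixel's radial distance from the initial boundary
#' against its angle about the spheroid centroid, with the boundary at the
#' plot center — the standard way to visualize per-spheroid invasion
#' patterns. Principal invasion axes are overlaid when available.
#'
#' @param x a \code{spheroid_invasion} object.
#' @param max_points subsample cap for very dense clouds (plotting only).
#' @param ... passed to [graphics::points()].
#' @return \code{x}, invisibly.
#' @export
plot.spheroid_invasion <- function(x, max_points = 20000L, ...) {
  cl <- x$cloud
  n <- nrow(cl$points)
  if (n == 0L) {
    graphics::plot.new()
    graphics::title(main = sprintf("%s: no invasion past the boundary",
                                   x$metrics$spheroid_id))
    return(invisible(x))
  }
  i <- if (n > max_points) round(seq(1L, n, length.out = max_points)) else seq_len(n)
  th <- cl$angles_deg[i] * pi / 180
  r <- cl$distances_mm[i]
  rmax <- max(r)
  # screen coordinates: angle measured clockwise on screen (y down in data,
  # but plotted y up), so flip the y sign for display
  xs <- r * cos(th); ys <- -r * sin(th)
  graphics::plot(xs, ys, asp = 1, pch = ".", cex = 2,
                 xlab = "distance from boundary (mm)", ylab = "",
                 main = sprintf("%s  (dots: outer pixels; center: Day-0 boundary)",
                                x$metrics$spheroid_id), ...)
  for (rr in pretty(c(0, rmax), 4L)[-1L]) {
    tt <- seq(0, 2 * pi, length.out = 180L)
    graphics::lines(rr * cos(tt), rr * sin(tt), col = "grey80", lty = 3L)
  }
  if (!is.null(x$directionality) && !x$directionality$isotropic) {
    a <- x$directionality$angle_max_deg * pi / 180
    graphics::segments(-rmax * cos(a), rmax * sin(a),
                       rmax * cos(a), -rmax * sin(a),
                       col = "blue", lwd = 2L)
    b <- a + pi / 2
    graphics::segments(-rmax * cos(b), rmax * sin(b),
                       rmax * cos(b), -rmax * sin(b),
                       col = "black", lwd = 1L, lty = 2L)
  }
  invisible(x)
}
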