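# Core invasion metrics: outer-pixel identification, radial distances and
# angles from the registered Day-0 boundary, area change and the radial
# area moment of inertia.

#' Identify outer pixels and measure their radial invasion geometry
#'
#' Finds every foreground pixel of the final-timepoint image whose center
#' lies strictly outside the registered initial boundary (pixels exactly on
#' the polygon count as inside: they belong to the initial footprint). For
#' each outer pixel the boundary crossing along the ray from the spheroid
#' centroid through the pixel is computed by exact segment-segment
#' intersection; where a non-convex boundary gives several crossings, the
#' outermost one not beyond the pixel is used, so distances are always
#' non-negative and measured from the locally outermost spheroid edge.
#'
#' @param day2 final-timepoint [binary_image].
#' @param boundary the Day-0 \code{boundary_polygon}, already registered
#'   onto \code{day2} (see [register_boundary()]).
#' @param check_registration verify that the boundary centroid agrees with
#'   the centroid of the largest Day-2 component.
#' @param registration_tol tolerance (px) for that check.
#' @return an object of class \code{pixel_cloud}: list with \code{points}
#'   (n x 2 matrix, x, y pixel centers), \code{distances_mm} (radial
#'   distance to the boundary), \code{angles_deg} (angle about the centroid
#'   in \[0, 360), clockwise on screen from the +x axis), \code{boundary_pts}
#'   (n x 2 crossings), \code{centroid_distances_mm} (distance to the
#'   centroid, an optional extra column), \code{pixel_area_mm2} (dA) and
#'   \code{boundary}.
#' @export
find_outer_pixels <- function(day2, boundary, check_registration = TRUE,
                              registration_tol = 0.5) {
  stopifnot(inherits(day2, "binary_image"),
            inherits(boundary, "boundary_polygon"))
  if (isTRUE(check_registration)) {
    cc <- day2_centroid(day2)
    if (max(abs(cc - boundary$centroid)) > registration_tol)
      stop(sprintf(
        "boundary is not registered to this image: centroid mismatch (%.2f, %.2f) vs (%.2f, %.2f) px",
        boundary$centroid[1L], boundary$centroid[2L], cc[1L], cc[2L]))
  }
  idx <- which(day2$mask, arr.ind = TRUE)
  px <- idx[, 2L] - 1  # x = col, 0-based
  py <- idx[, 1L] - 1  # y = row
  keep <- !point_in_polygon(px, py, boundary$vertices)
  px <- px[keep]; py <- py[keep]
  mm_per_px <- day2$pixel_size_um / 1000
  cx <- boundary$centroid[1L]; cy <- boundary$centroid[2L]
  cr <- ray_boundary_crossings(px, py, cx, cy, boundary$vertices)
  if (anyNA(cr$t))
    stop("no boundary crossing found for some outer pixels; is the centroid inside the boundary?")
  d_px <- (1 - cr$t) * sqrt((px - cx)^2 + (py - cy)^2)
  structure(list(
    points = cbind(x = px, y = py),
    distances_mm = d_px * mm_per_px,
    angles_deg = if (length(px)) (atan2(py - cy, px - cx) * 180 / pi) %% 360
                 else numeric(0L),
    boundary_pts = cbind(x = cr$xb, y = cr$yb),
    centroid_distances_mm = sqrt((px - cx)^2 + (py - cy)^2) * mm_per_px,
    pixel_area_mm2 = mm_per_px^2,
    pixel_size_um = day2$pixel_size_um,
    boundary = boundary), class = "pixel_cloud")
}

#' @export
print.pixel_cloud <- function(x, ...) {
  cat(sprintf("<pixel_cloud> %d outer pixels, dA = %.3g mm^2\n",
              nrow(x$points), x$pixel_area_mm2))
  if (nrow(x$points) > 0L)
    cat(sprintf("  d: mean %.4g mm, max %.4g mm\n",
                mean(x$distances_mm), max(x$distances_mm)))
  invisible(x)
}

#' Boundary crossing along the centroid-to-pixel ray
#'
#' Intersects the segment from the boundary centroid to \code{pixel} with
#' the polygon edges and returns the crossing at the largest radius not
#' exceeding the pixel's own radius.
#'
#' @param boundary a \code{boundary_polygon} whose centroid lies inside it.
#' @param pixel length-2 (x, y) point outside the polygon, or an n x 2
#'   matrix of such points.
#' @return named numeric (x, y) crossing point, or an n x 2 matrix.
#' @export
boundary_point_on_ray <- function(boundary, pixel) {
  stopifnot(inherits(boundary, "boundary_polygon"))
  p <- if (is.matrix(pixel)) pixel else matrix(pixel, ncol = 2L)
  cr <- ray_boundary_crossings(p[, 1L], p[, 2L],
                               boundary$centroid[1L], boundary$centroid[2L],
                               boundary$vertices)
  if (anyNA(cr$t))
    stop("no ray-boundary crossing: centroid outside polygon or pixel inside")
  if (is.matrix(pixel)) cbind(x = cr$xb, y = cr$yb)
  else c(x = cr$xb, y = cr$yb)
}

#' Radial invasion distance of one pixel
#'
#' Euclidean distance between a pixel center and its boundary crossing,
#' converted to millimeters.
#'
#' @param pixel (x, y) pixel center, px.
#' @param boundary_pt (x, y) boundary crossing from
#'   [boundary_point_on_ray()].
#' @param pixel_size_um calibration, micrometers per pixel.
#' @return distance in mm.
#' @export
radial_distance <- function(pixel, boundary_pt, pixel_size_um = 1) {
  sqrt(sum((as.numeric(pixel) - as.numeric(boundary_pt))^2)) *
    pixel_size_um / 1000
}

#' Angle of a pixel about the spheroid centroid
#'
#' Two-argument arctangent of (y - y0, x - x0) mapped to \[0, 360) degrees.
#' With y increasing downward, increasing angle appears clockwise on screen,
#' as in the polar plots.
#'
#' @param pixel (x, y) point, px.
#' @param centroid (x0, y0) spheroid centroid, px.
#' @return angle in degrees in \[0, 360).
#' @export
pixel_angle <- function(pixel, centroid) {
  dx <- pixel[1L] - centroid[1L]
  dy <- pixel[2L] - centroid[2L]
  if (dx == 0 && dy == 0) stop("angle undefined: pixel equals centroid")
  unname((atan2(dy, dx) * 180 / pi) %% 360)
}

#' Area change between the two timepoints
#'
#' Final foreground area minus initial foreground area, in mm^2: the pixel
#' count difference times dA = (pixel size in mm)^2. A negative value
#' (spheroid compaction) is returned as-is, with a warning and a
#' \code{"shrinkage"} attribute set to \code{TRUE}.
#'
#' @param day0,day2 [binary_image]s with identical calibration.
#' @return area change in mm^2 with attribute \code{shrinkage}.
#' @export
area_change <- function(day0, day2) {
  stopifnot(inherits(day0, "binary_image"), inherits(day2, "binary_image"))
  if (!isTRUE(all.equal(day0$pixel_size_um, day2$pixel_size_um)))
    stop("calibration mismatch between timepoints")
  dA <- (day0$pixel_size_um / 1000)^2
  delta <- (sum(day2$mask) - sum(day0$mask)) * dA
  shrink <- delta < 0
  if (shrink)
    warning("final foreground area is smaller than initial (spheroid shrinkage)")
  structure(delta, shrinkage = shrink)
}

#' Radial area moment of inertia of invasion
#'
#' The integrative invasiveness metric: Ir = sum_i d_i^2 dA over all outer
#' pixels, in mm^4. Area invading farther from the initial boundary is
#' weighted quadratically, by analogy with the second moment of area in
#' mechanics.
#'
#' @param cloud a \code{pixel_cloud} with distances populated.
#' @return Ir in mm^4 (0 for an empty cloud).
#' @export
radial_moment <- function(cloud) {
  stopifnot(inherits(cloud, "pixel_cloud"))
  sum(cloud$distances_mm^2) * cloud$pixel_area_mm2
}

#' Per-spheroid invasion summary
#'
#' @param day0,day2 the [binary_image] pair.
#' @param cloud the \code{pixel_cloud} computed from this pair.
#' @param spheroid_id identifier recorded in the output.
#' @return an object of class \code{invasion_metrics}: list with
#'   \code{delta_area_mm2}, \code{mean_distance_mm}, \code{max_distance_mm},
#'   \code{radial_moment_mm4}, \code{n_outer_pixels}, \code{shrinkage} and
#'   \code{spheroid_id}.
#' @export
summarize_invasion <- function(day0, day2, cloud, spheroid_id = "spheroid") {
  stopifnot(inherits(cloud, "pixel_cloud"))
  delta <- suppressWarnings(area_change(day0, day2))
  n <- nrow(cloud$points)
  structure(list(
    spheroid_id = spheroid_id,
    delta_area_mm2 = as.numeric(delta),
    mean_distance_mm = if (n > 0L) mean(cloud$distances_mm) else 0,
    max_distance_mm = if (n > 0L) max(cloud$distances_mm) else 0,
    radial_moment_mm4 = radial_moment(cloud),
    n_outer_pixels = n,
    shrinkage = isTRUE(attr(delta, "shrinkage"))),
    class = "invasion_metrics")
}

#' @export
print.invasion_metrics <- function(x, ...) {
  cat(sprintf("Invasion metrics for '%s':\n", x$spheroid_id))
  cat(sprintf("  area change        %10.4g mm^2%s\n", x$delta_area_mm2,
              if (x$shrinkage) " (shrinkage)" else ""))
  cat(sprintf("  mean distance      %10.4g mm\n", x$mean_distance_mm))
  cat(sprintf("  max distance       %10.4g mm\n", x$max_distance_mm))
  cat(sprintf("  radial moment Ir   %10.4g mm^4\n", x$radial_moment_mm4))
  cat(sprintf("  outer pixels       %10d\n", x$n_outer_pixels))
  invisible(x)
}

#' Write the per-pixel cloud to CSV
#'
#' One row per outer pixel with columns \code{x_px}, \code{y_px},
#' \code{d_mm}, \code{theta_deg} and \code{d_centroid_mm}, suitable for
#' external polar plotting.
#'
#' @param cloud a \code{pixel_cloud}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_pixel_csv <- function(cloud, path) {
  stopifnot(inherits(cloud, "pixel_cloud"))
  utils::write.csv(data.frame(
    x_px = cloud$points[, 1L], y_px = cloud$points[, 2L],
    d_mm = cloud$distances_mm, theta_deg = cloud$angles_deg,
    d_centroid_mm = cloud$centroid_distances_mm),
    path, row.names = FALSE)
  invisible(path)
}
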