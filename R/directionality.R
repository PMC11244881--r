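# Directional invasion analysis: PCA of the outer-pixel cloud, coordinate
# transformation onto the principal axes, directional area moments and
# fold-change anisotropy metrics.

# outer-pixel coordinates in mm (image frame, y down)
.cloud_mm <- function(cloud) {
  stopifnot(inherits(cloud, "pixel_cloud"))
  cloud$points * (cloud$pixel_size_um / 1000)
}

#' Principal invasion axes of the outer-pixel cloud
#'
#' Eigen-decomposition of the 2x2 second-moment matrix of the outer-pixel
#' coordinates about the chosen origin. Each pixel contributes equally, so
#' this is an area-weighted PCA of the invasion pattern. Axes are
#' undirected: angles are reported modulo 180 degrees in the image frame
#' (y down, angles clockwise on screen from the +x axis).
#'
#' @param cloud a \code{pixel_cloud} with at least 2 points.
#' @param origin \code{"mean"} (default): the mean of the outer-pixel
#'   coordinates; \code{"centroid"}: the spheroid centroid.
#' @param iso_tol relative eigenvalue gap below which the cloud is flagged
#'   isotropic (the direction is then meaningless and the angle is set to 0).
#' @return an object of class \code{principal_axes}: list with \code{origin}
#'   (x, y in mm), \code{angle_max_deg}, \code{angle_min_deg} (in \[0, 180)),
#'   \code{eigenvalues} (variances along max/min axes, mm^2) and
#'   \code{isotropic} flag.
#' @export
principal_axes <- function(cloud, origin = c("mean", "centroid"),
                           iso_tol = 1e-8) {
  origin <- match.arg(origin)
  xy <- .cloud_mm(cloud)
  if (nrow(xy) < 2L)
    stop("insufficient data: need at least 2 outer pixels for PCA")
  o <- switch(origin,
    mean = colMeans(xy),
    centroid = cloud$boundary$centroid * (cloud$pixel_size_um / 1000))
  xc <- xy[, 1L] - o[1L]
  yc <- xy[, 2L] - o[2L]
  S <- matrix(c(mean(xc * xc), mean(xc * yc),
                mean(xc * yc), mean(yc * yc)), 2L, 2L)
  e <- eigen(S, symmetric = TRUE)
  lam <- e$values
  iso <- (lam[1L] - lam[2L]) <= iso_tol * max(lam[1L], .Machine$double.eps)
  ang <- if (iso) 0 else (atan2(e$vectors[2L, 1L], e$vectors[1L, 1L]) *
                            180 / pi) %% 180
  structure(list(origin = c(x = unname(o[1L]), y = unname(o[2L])),
                 angle_max_deg = ang,
                 angle_min_deg = (ang + 90) %% 180,
                 eigenvalues = c(max = lam[1L], min = lam[2L]),
                 isotropic = iso),
            class = "principal_axes")
}

#' @export
print.principal_axes <- function(x, ...) {
  cat(sprintf(
    "<principal_axes> max @ %.1f deg, min @ %.1f deg%s (var %.3g / %.3g mm^2)\n",
    x$angle_max_deg, x$angle_min_deg,
    if (x$isotropic) " [isotropic]" else "",
    x$eigenvalues[1L], x$eigenvalues[2L]))
  invisible(x)
}

#' Transform outer-pixel coordinates onto the principal axes
#'
#' Rigid rotation (plus translation to the PCA origin): x' is the coordinate
#' along the maximum-invasion axis, y' along the minimum axis. Pairwise
#' distances are preserved.
#'
#' @param cloud a \code{pixel_cloud}.
#' @param axes a \code{principal_axes} object, or a numeric angle in degrees
#'   (rotation about the cloud mean).
#' @return n x 2 matrix with columns \code{xp}, \code{yp} in mm.
#' @export
transform_coordinates <- function(cloud, axes) {
  xy <- .cloud_mm(cloud)
  if (inherits(axes, "principal_axes")) {
    o <- axes$origin
    ang <- axes$angle_max_deg
  } else {
    o <- colMeans(xy)
    ang <- as.numeric(axes)
  }
  phi <- ang * pi / 180
  xc <- xy[, 1L] - o[1L]
  yc <- xy[, 2L] - o[2L]
  cbind(xp = cos(phi) * xc + sin(phi) * yc,
        yp = -sin(phi) * xc + cos(phi) * yc)
}

#' Directional area moments of inertia
#'
#' I_xp = sum y'^2 dA is the moment about the maximum-invasion axis
#' (distances are measured perpendicular to it, i.e. along the minimum
#' direction); I_yp = sum x'^2 dA is the moment about the minimum axis and
#' is the larger of the two when x' is the principal direction.
#'
#' @param transformed n x 2 matrix of (x', y') coordinates in mm.
#' @param pixel_area_mm2 dA, the area of one pixel in mm^2.
#' @return named numeric \code{c(I_xp, I_yp)} in mm^4.
#' @export
directional_moments <- function(transformed, pixel_area_mm2) {
  if (NROW(transformed) == 0L) return(c(I_xp = 0, I_yp = 0))
  c(I_xp = sum(transformed[, 2L]^2) * pixel_area_mm2,
    I_yp = sum(transformed[, 1L]^2) * pixel_area_mm2)
}

#' Mean invasion distance along each principal direction
#'
#' Mean absolute transformed coordinate: mean |x'| along the maximum axis
#' and mean |y'| along the minimum axis.
#'
#' @inheritParams directional_moments
#' @return named numeric \code{c(mean_d_max, mean_d_min)} in mm.
#' @export
directional_mean_distances <- function(transformed) {
  if (NROW(transformed) == 0L) return(c(mean_d_max = 0, mean_d_min = 0))
  c(mean_d_max = mean(abs(transformed[, 1L])),
    mean_d_min = mean(abs(transformed[, 2L])))
}

#' Fold change between maximum and minimum directions
#'
#' Ratio of the larger to the smaller of two directional values; always
#' >= 1. A value near 1 indicates isotropic invasion.
#'
#' @param pair numeric length-2 vector of directional values.
#' @return the max/min ratio.
#' @export
fold_change <- function(pair) {
  stopifnot(length(pair) == 2L)
  lo <- min(pair)
  if (lo <= 0) stop("fold change undefined: minimum-direction value is not positive")
  max(pair) / lo
}

#' Full directionality summary of an outer-pixel cloud
#'
#' Runs PCA, transforms coordinates, and assembles directional moments, mean
#' distances and fold changes. Moments about the raw image axes (identity
#' rotation about the same origin) are included as \code{I_x_mm4},
#' \code{I_y_mm4}.
#'
#' @inheritParams principal_axes
#' @return an object of class \code{directional_metrics}: list with the
#'   principal angles (plus their -180 aliases for readability),
#'   \code{I_max_mm4}, \code{I_min_mm4}, \code{mean_d_max_mm},
#'   \code{mean_d_min_mm}, \code{fold_change_moment},
#'   \code{fold_change_distance}, image-axis moments and the
#'   \code{isotropic} flag.
#' @export
directionality_summary <- function(cloud, origin = c("mean", "centroid")) {
  axes <- principal_axes(cloud, origin = origin)
  tr <- transform_coordinates(cloud, axes)
  mom <- directional_moments(tr, cloud$pixel_area_mm2)
  dst <- directional_mean_distances(tr)
  # image-axis moments: identity rotation about the same origin
  axes0 <- axes; axes0$angle_max_deg <- 0
  tr0 <- transform_coordinates(cloud, axes0)
  mom0 <- directional_moments(tr0, cloud$pixel_area_mm2)
  structure(list(
    axes = axes,
    angle_max_deg = axes$angle_max_deg,
    angle_min_deg = axes$angle_min_deg,
    angle_max_alias_deg = axes$angle_max_deg - 180,
    angle_min_alias_deg = axes$angle_min_deg - 180,
    I_max_mm4 = max(mom), I_min_mm4 = min(mom),
    mean_d_max_mm = dst[["mean_d_max"]],
    mean_d_min_mm = dst[["mean_d_min"]],
    fold_change_moment = fold_change(mom),
    fold_change_distance = fold_change(dst),
    I_x_mm4 = mom0[["I_xp"]], I_y_mm4 = mom0[["I_yp"]],
    isotropic = axes$isotropic),
    class = "directional_metrics")
}

#' @export
print.directional_metrics <- function(x, ...) {
  cat("Directional invasion metrics:\n")
  cat(sprintf("  principal angles   %.1f deg (max) / %.1f deg (min)%s\n",
              x$angle_max_deg, x$angle_min_deg,
              if (x$isotropic) " [isotropic]" else ""))
  cat(sprintf("  directional moments  %.4g / %.4g mm^4  (%.2gX)\n",
              x$I_max_mm4, x$I_min_mm4, x$fold_change_moment))
  cat(sprintf("  mean distances       %.4g / %.4g mm  (%.2gX)\n",
              x$mean_d_max_mm, x$mean_d_min_mm, x$fold_change_distance))
  invisible(x)
}
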