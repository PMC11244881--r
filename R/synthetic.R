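# Synthetic image pairs with analytically known invasion metrics. The
# expected values are computed from closed forms (geometry only), entirely
# independent of the measurement pipeline, so they serve as genuine oracles.

# filled disk: pixel centers within radius_px of center (cx, cy), 0-based
.disk_mask <- function(size_px, center, radius_px) {
  h <- size_px[1L]; w <- size_px[2L]
  yy <- matrix(0:(h - 1), h, w)
  xx <- matrix(0:(w - 1), h, w, byrow = TRUE)
  (xx - center[1L])^2 + (yy - center[2L])^2 <= radius_px^2
}

# closed-form annulus truth: Day 0 disk R0, Day 2 disk R1, distances
# measured radially from the R0 circle. W = R1 - R0.
#   delta A = pi (R1^2 - R0^2)
#   mean d  = [2 pi (W^3/3 + R0 W^2/2)] / [pi (R1^2 - R0^2)]
#   Ir      = 2 pi (W^4/4 + R0 W^3/3)
.annulus_truth <- function(R0_mm, R1_mm) {
  W <- R1_mm - R0_mm
  area <- pi * (R1_mm^2 - R0_mm^2)
  list(delta_area_mm2 = area,
       mean_distance_mm = 2 * pi * (W^3 / 3 + R0_mm * W^2 / 2) / area,
       max_distance_mm = W,
       radial_moment_mm4 = 2 * pi * (W^4 / 4 + R0_mm * W^3 / 3))
}

#' Synthetic isotropic invasion: concentric disk pair
#'
#' Day 0 is a filled disk of radius \code{R0_mm} at the image center; Day 2
#' a concentric disk of radius \code{R1_mm}. All invasion metrics have
#' closed forms, returned in \code{truth}; the pattern is isotropic, so
#' directional fold changes are expected near 1.
#'
#' @param R0_mm,R1_mm initial and final spheroid radii in mm, 0 < R0 < R1.
#' @param pixel_size_um resolution, micrometers per pixel.
#' @param image_size_px optional (H, W); default fits R1 plus a margin.
#' @param margin_px margin beyond R1 when sizing the frame automatically.
#' @return list with \code{day0}, \code{day2} ([binary_image]s) and
#'   \code{truth} (class \code{synthetic_truth}).
#' @export
make_annulus_pair <- function(R0_mm = 1, R1_mm = 2, pixel_size_um = 10,
                              image_size_px = NULL, margin_px = 20) {
  if (!(R0_mm > 0 && R1_mm > R0_mm)) stop("need 0 < R0_mm < R1_mm")
  r0 <- R0_mm * 1000 / pixel_size_um
  r1 <- R1_mm * 1000 / pixel_size_um
  if (is.null(image_size_px)) {
    s <- 2L * ceiling(r1 + margin_px) + 1L
    image_size_px <- c(s, s)
  }
  if (min(image_size_px) < 2 * r1 + 2)
    stop("image too small to contain the final disk")
  ctr <- (rev(image_size_px) - 1) / 2  # (x, y)
  day0 <- binary_image(.disk_mask(image_size_px, ctr, r0),
                       pixel_size_um, "Day0")
  day2 <- binary_image(.disk_mask(image_size_px, ctr, r1),
                       pixel_size_um, "Day2")
  truth <- structure(c(
    list(generator = "annulus",
         params = list(R0_mm = R0_mm, R1_mm = R1_mm,
                       pixel_size_um = pixel_size_um,
                       image_size_px = image_size_px)),
    .annulus_truth(R0_mm, R1_mm),
    list(isotropic = TRUE)), class = "synthetic_truth")
  list(day0 = day0, day2 = day2, truth = truth)
}

# run `expr` under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Synthetic directional invasion: disk plus anisotropic nuclear scatter
#'
#' Day 0 is a filled disk of radius \code{R0_mm}; Day 2 adds
#' \code{n_points} synthetic nuclei sampled from a bivariate Gaussian with
#' standard deviations (\code{sigma_major_mm}, \code{sigma_major_mm} /
#' \code{axis_ratio}) rotated to \code{orientation_deg}, rejection-sampled
#' to lie outside the disk (and inside the frame). Nuclei are single pixels
#' by default, which makes the PCA orientation truth exact in expectation;
#' \code{nucleus_radius_px > 0} draws small disk nuclei instead, emulating
#' realistic blob-like clustering.
#'
#' @param R0_mm initial spheroid radius, mm.
#' @param sigma_major_mm Gaussian spread along the major axis, mm.
#' @param axis_ratio major/minor spread ratio, >= 1.
#' @param orientation_deg major-axis orientation in the image frame
#'   (degrees, modulo 180).
#' @param n_points number of distinct nucleus pixels to place.
#' @param pixel_size_um resolution.
#' @param image_size_px optional (H, W) frame size.
#' @param seed RNG seed (the generator is deterministic given the seed).
#' @param nucleus_radius_px 0 for point nuclei; otherwise nucleus disk
#'   radius in px.
#' @return list with \code{day0}, \code{day2}, \code{truth}.
#' @export
make_anisotropic_pair <- function(R0_mm = 0.2, sigma_major_mm = 0.4,
                                  axis_ratio = 3, orientation_deg = 125,
                                  n_points = 5000, pixel_size_um = 10,
                                  image_size_px = NULL, seed = NULL,
                                  nucleus_radius_px = 0) {
  if (axis_ratio < 1) stop("'axis_ratio' must be >= 1")
  if (n_points < 0) stop("'n_points' must be >= 0")
  r0 <- R0_mm * 1000 / pixel_size_um
  smaj <- sigma_major_mm * 1000 / pixel_size_um
  if (is.null(image_size_px)) {
    s <- 2L * ceiling(r0 + 4 * smaj + 10) + 1L
    image_size_px <- c(s, s)
  }
  h <- image_size_px[1L]; w <- image_size_px[2L]
  ctr <- c((w - 1) / 2, (h - 1) / 2)  # (x, y)
  day0_mask <- .disk_mask(image_size_px, ctr, r0)
  day2_mask <- day0_mask
  if (n_points > 0L) {
    pts <- .with_seed(seed, {
      acc <- matrix(numeric(0L), 0L, 2L)
      smin <- smaj / axis_ratio
      phi <- orientation_deg * pi / 180
      guard <- 0L
      while (nrow(acc) < n_points && guard < 1000L) {
        m <- 4L * (n_points - nrow(acc)) + 100L
        u <- stats::rnorm(m, 0, smaj)
        v <- stats::rnorm(m, 0, smin)
        x <- round(ctr[1L] + cos(phi) * u - sin(phi) * v)
        y <- round(ctr[2L] + sin(phi) * u + cos(phi) * v)
        # outside the Day-0 disk with a 1-px guard band (so nuclei fall
        # strictly outside the traced boundary), inside the frame
        ok <- (x - ctr[1L])^2 + (y - ctr[2L])^2 > (r0 + 1 + nucleus_radius_px)^2 &
          x >= 1 & x <= w - 2 & y >= 1 & y <= h - 2
        acc <- unique(rbind(acc, cbind(x[ok], y[ok])))
        guard <- guard + 1L
      }
      if (nrow(acc) < n_points)
        stop("rejection sampling failed to place the requested nuclei")
      acc[seq_len(n_points), , drop = FALSE]
    })
    if (nucleus_radius_px > 0) {
      for (i in seq_len(nrow(pts))) {
        nb <- .disk_mask(image_size_px, pts[i, ], nucleus_radius_px)
        day2_mask <- day2_mask | nb
      }
      # keep nuclei from bleeding back into the Day-0 body's guard band
      day2_mask <- day2_mask | day0_mask
    } else {
      day2_mask[cbind(pts[, 2L] + 1L, pts[, 1L] + 1L)] <- TRUE
    }
  }
  truth <- structure(list(
    generator = "anisotropic",
    params = list(R0_mm = R0_mm, sigma_major_mm = sigma_major_mm,
                  axis_ratio = axis_ratio, orientation_deg = orientation_deg %% 180,
                  n_points = n_points, pixel_size_um = pixel_size_um,
                  seed = seed, nucleus_radius_px = nucleus_radius_px),
    angle_max_deg = orientation_deg %% 180,
    isotropic = axis_ratio == 1,
    fold_changes_above_1 = axis_ratio > 1),
    class = "synthetic_truth")
  list(day0 = binary_image(day0_mask, pixel_size_um, "Day0"),
       day2 = binary_image(day2_mask, pixel_size_um, "Day2"),
       truth = truth)
}

#' Render a binary mask as a noisy grayscale image
#'
#' Foreground pixels get intensity \code{fg_level}, background
#' \code{bg_level}, plus optional additive Gaussian noise clipped to
#' \[0, 1\]. With \code{noise_sd = 0}, thresholding anywhere strictly
#' between the two levels recovers the mask exactly.
#'
#' @param binary a [binary_image].
#' @param fg_level,bg_level intensities with 0 <= bg < fg <= 1.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed RNG seed for the noise.
#' @return a [gray_image].
#' @export
make_grayscale_from_binary <- function(binary, fg_level = 0.8,
                                       bg_level = 0.05, noise_sd = 0,
                                       seed = NULL) {
  stopifnot(inherits(binary, "binary_image"))
  if (!(bg_level >= 0 && bg_level < fg_level && fg_level <= 1))
    stop("need 0 <= bg_level < fg_level <= 1")
  m <- ifelse(binary$mask, fg_level, bg_level)
  if (noise_sd > 0) {
    m <- .with_seed(seed, m + stats::rnorm(length(m), 0, noise_sd))
    m[m < 0] <- 0; m[m > 1] <- 1
  }
  gray_image(m)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> generator '%s'\n", x$generator))
  for (nm in setdiff(names(x), c("generator", "params")))
    cat(sprintf("  %s: %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}
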