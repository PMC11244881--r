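# Fixture builders and independent oracles used across the test files.
# Everything here is deliberately written from first principles (explicit
# loops, closed forms, dense sampling) so it cannot share a defect with the
# package code it checks.

# binary disk image, pixel centers within r of (cx, cy), 0-based coords
fix_disk_image <- function(h, w, cx, cy, r, pixel_size_um = 1,
                           timepoint = "") {
  m <- matrix(FALSE, h, w)
  for (row in seq_len(h)) {
    y <- row - 1
    x <- 0:(w - 1)
    m[row, (x - cx)^2 + (y - cy)^2 <= r^2] <- TRUE
  }
  binary_image(m, pixel_size_um, timepoint)
}

# hand-built boundary_polygon (bypasses segmentation)
fix_polygon <- function(vertices, centroid) {
  structure(list(vertices = vertices,
                 centroid = c(x = centroid[1], y = centroid[2]),
                 area_px2 = fix_shoelace(vertices)),
            class = "boundary_polygon")
}

# independent shoelace area
fix_shoelace <- function(v) {
  n <- nrow(v)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + v[i, 1] * v[j, 2] - v[j, 1] * v[i, 2]
  }
  s / 2
}

# regular polygonization of a circle
fix_circle_polygon <- function(R, n = 720, centre = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  fix_polygon(cbind(centre[1] + R * cos(th), centre[2] + R * sin(th)),
              centre)
}

# non-convex star polygon r(theta) = R0 + amp * cos(k theta)
fix_star_polygon <- function(R0, amp, k, n = 600, centre = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- R0 + amp * cos(k * th)
  fix_polygon(cbind(centre[1] + r * cos(th), centre[2] + r * sin(th)),
              centre)
}

# minimal pixel_cloud for the directionality functions
fix_cloud <- function(points_px, pixel_size_um = 1, boundary = NULL) {
  structure(list(points = points_px,
                 distances_mm = rep(0, nrow(points_px)),
                 angles_deg = rep(0, nrow(points_px)),
                 centroid_distances_mm = rep(0, nrow(points_px)),
                 pixel_area_mm2 = (pixel_size_um / 1000)^2,
                 pixel_size_um = pixel_size_um,
                 boundary = boundary),
            class = "pixel_cloud")
}

# Brute-force ray-crossing oracle: resample the polygon polyline at
# n_samples points and intersect the centroid->pixel segment with every
# tiny segment of the resampled polyline; return the distance from the
# pixel to the outermost admissible crossing, in px.
fix_ray_oracle_d <- function(poly, centroid, pixel, n_samples = 1e4) {
  v <- rbind(poly, poly[1, ])
  seglen <- sqrt(diff(v[, 1])^2 + diff(v[, 2])^2)
  s <- c(0, cumsum(seglen))
  total <- s[length(s)]
  tq <- seq(0, total, length.out = n_samples + 1)
  xs <- approx(s, v[, 1], xout = tq)$y
  ys <- approx(s, v[, 2], xout = tq)$y
  cx <- centroid[1]; cy <- centroid[2]
  dx <- pixel[1] - cx; dy <- pixel[2] - cy
  ax <- xs[-length(xs)] - cx; ay <- ys[-length(ys)] - cy
  ex <- diff(xs); ey <- diff(ys)
  denom <- dx * ey - dy * ex
  tt <- (ax * ey - ay * ex) / denom
  ss <- (ax * dy - ay * dx) / denom
  ok <- is.finite(tt) & ss >= -1e-9 & ss <= 1 + 1e-9 & tt >= 0 & tt <= 1 + 1e-9
  if (!any(ok)) return(NA_real_)
  tbest <- min(max(tt[ok]), 1)
  (1 - tbest) * sqrt(dx^2 + dy^2)
}

# batched version of the ray oracle: resample the polyline once, then
# intersect each centroid->pixel segment against every dense sub-segment
fix_ray_oracle_batch <- function(poly, centroid, pts, n_samples = 1e4) {
  v <- rbind(poly, poly[1, ])
  seglen <- sqrt(diff(v[, 1])^2 + diff(v[, 2])^2)
  s <- c(0, cumsum(seglen))
  tq <- seq(0, s[length(s)], length.out = n_samples + 1)
  xs <- approx(s, v[, 1], xout = tq)$y
  ys <- approx(s, v[, 2], xout = tq)$y
  ax <- xs[-length(xs)] - centroid[1]
  ay <- ys[-length(ys)] - centroid[2]
  ex <- diff(xs); ey <- diff(ys)
  vapply(seq_len(nrow(pts)), function(i) {
    dx <- pts[i, 1] - centroid[1]; dy <- pts[i, 2] - centroid[2]
    denom <- dx * ey - dy * ex
    tt <- (ax * ey - ay * ex) / denom
    ss <- (ax * dy - ay * dx) / denom
    ok <- is.finite(tt) & ss >= -1e-9 & ss <= 1 + 1e-9 & tt >= 0 & tt <= 1 + 1e-9
    if (!any(ok)) return(NA_real_)
    (1 - min(max(tt[ok]), 1)) * sqrt(dx^2 + dy^2)
  }, numeric(1))
}

# graded-intensity grayscale pair for threshold-sweep tests: Day 0 disk at
# constant intensity, Day 2 adds a ring whose intensity decays linearly
# with radius (so the foreground grows as the threshold drops)
fix_graded_pair <- function(R0 = 30, R1 = 60, size = 151, fg = 0.8) {
  c0 <- (size - 1) / 2
  g0 <- matrix(0.02, size, size)
  g2 <- matrix(0.02, size, size)
  for (row in seq_len(size)) {
    y <- row - 1
    x <- 0:(size - 1)
    rr <- sqrt((x - c0)^2 + (y - c0)^2)
    g0[row, rr <= R0] <- fg
    g2[row, rr <= R0] <- fg
    ring <- rr > R0 & rr <= R1
    g2[row, ring] <- fg * (1 - (rr[ring] - R0) / (R1 - R0))
  }
  list(day0 = gray_image(g0), day2 = gray_image(g2))
}
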