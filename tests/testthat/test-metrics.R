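test_that("outer-pixel identification is exact for concentric disk pairs", {
  day0 <- fix_disk_image(121, 121, 60, 60, 30, pixel_size_um = 10, "Day0")
  day2 <- fix_disk_image(121, 121, 60, 60, 50, pixel_size_um = 10, "Day2")
  b <- register_boundary(extract_boundary(extract_spheroid_mask(day0)),
                         day2_centroid(day2))

  # identical pair: nothing outside
  b0 <- register_boundary(extract_boundary(extract_spheroid_mask(day0)),
                          day2_centroid(day0))
  expect_equal(nrow(find_outer_pixels(day0, b0)$points), 0L)

  # the 0.5-level boundary separates exactly the Day-0 pixels from the rest
  cloud <- find_outer_pixels(day2, b)
  expect_equal(nrow(cloud$points), sum(day2$mask) - sum(day0$mask))
  expect_true(all(cloud$distances_mm >= 0))
  expect_equal(nrow(cloud$points), length(cloud$distances_mm))
  expect_equal(nrow(cloud$points), length(cloud$angles_deg))

  # one extra pixel at radius R0 + 10 along +x: exactly that pixel
  one <- day0$mask
  one[61, 101] <- TRUE  # (x, y) = (100, 60), radius 40 from (60, 60)
  c1 <- find_outer_pixels(binary_image(one, 10, "Day2"), b0)
  expect_equal(nrow(c1$points), 1L)
  expect_equal(unname(c1$points[1, ]), c(100, 60))
})

test_that("registration mismatch is rejected", {
  day0 <- fix_disk_image(81, 81, 40, 40, 20)
  day2 <- fix_disk_image(81, 81, 50, 40, 20)
  b <- extract_boundary(extract_spheroid_mask(day0))  # centroid (40, 40)
  expect_error(find_outer_pixels(day2, b), "not registered")
})

test_that("ray crossing picks the outermost admissible boundary point", {
  circ <- fix_circle_polygon(50, n = 2000)
  expect_equal(unname(boundary_point_on_ray(circ, c(80, 0))), c(50, 0),
               tolerance = 1e-3)
  expect_equal(unname(boundary_point_on_ray(circ, c(0, -80))), c(0, -50),
               tolerance = 1e-3)

  # non-convex polygon whose +x ray crosses the boundary at x = 30, 40, 45:
  # a square with one channel cut from the top edge and one from the right
  v <- rbind(c(-50, -50), c(30, -50), c(30, 5), c(40, 5), c(40, -50),
             c(50, -50), c(50, -5), c(45, -5), c(45, 5), c(50, 5),
             c(50, 50), c(-50, 50))
  poly <- fix_polygon(v, c(0, 0))
  bp <- boundary_point_on_ray(poly, c(60, 0))
  expect_equal(unname(bp), c(45, 0), tolerance = 1e-9)
  # matches the dense polyline-sampling oracle
  expect_equal(15, fix_ray_oracle_d(v, c(0, 0), c(60, 0)), tolerance = 0.1)
})

test_that("ray distances agree with the dense-sampling oracle on star shapes", {
  set.seed(13)
  poly <- fix_star_polygon(R0 = 40, amp = 10, k = 5)
  for (i in 1:40) {
    th <- runif(1, 0, 2 * pi)
    r <- runif(1, 55, 70)
    p <- c(r * cos(th), r * sin(th))
    d_pkg <- sqrt(sum((p - boundary_point_on_ray(poly, p))^2))
    d_ora <- fix_ray_oracle_d(poly$vertices, c(0, 0), p)
    expect_lt(abs(d_pkg - d_ora), 0.6)
  }
})

test_that("radial distance and pixel angle follow the stated conventions", {
  expect_equal(radial_distance(c(80, 0), c(50, 0), 1), 0.030)
  expect_equal(radial_distance(c(10, 3), c(10, 3), 1), 0)
  expect_equal(radial_distance(c(53, 54), c(50, 50), 1), 0.005)  # 3-4-5
  expect_equal(radial_distance(c(53, 54), c(50, 50), 10), 0.05)

  c0 <- c(20, 30)
  expect_equal(pixel_angle(c0 + c(10, 0), c0), 0)
  expect_equal(pixel_angle(c0 + c(0, 10), c0), 90)   # +y (down) is 90 deg
  expect_equal(pixel_angle(c0 - c(5, 5), c0), 225)
  expect_error(pixel_angle(c0, c0), "undefined")
})

test_that("area change applies dA and flags shrinkage without clamping", {
  a <- fix_disk_image(30, 30, 15, 15, 5, pixel_size_um = 10)
  expect_equal(as.numeric(area_change(a, a)), 0)

  m0 <- binary_image(matrix(rep(c(TRUE, FALSE), c(100, 300)), 20, 20), 10)
  m2 <- binary_image(matrix(rep(c(TRUE, FALSE), c(250, 150)), 20, 20), 10)
  expect_equal(as.numeric(area_change(m0, m2)), 150 * 0.01^2)

  expect_warning(shr <- area_change(m2, m0), "shrink")
  expect_equal(as.numeric(shr), -150 * 0.01^2)
  expect_true(attr(shr, "shrinkage"))

  b <- fix_disk_image(30, 30, 15, 15, 5, pixel_size_um = 5)
  expect_error(area_change(a, b), "alibration")
})

test_that("radial moment is the d^2-weighted pixel area sum", {
  one <- fix_cloud(matrix(c(5, 5), 1, 2), pixel_size_um = 10)
  one$distances_mm <- 0.1
  expect_equal(radial_moment(one), 0.1^2 * 1e-4)

  day0 <- fix_disk_image(41, 41, 20, 20, 8)
  b <- register_boundary(extract_boundary(extract_spheroid_mask(day0)),
                         day2_centroid(day0))
  empty <- find_outer_pixels(day0, b)
  expect_equal(radial_moment(empty), 0)
  s <- summarize_invasion(day0, day0, empty)
  expect_equal(s$mean_distance_mm, 0)
  expect_equal(s$max_distance_mm, 0)
  expect_equal(s$radial_moment_mm4, 0)
  expect_equal(s$n_outer_pixels, 0L)
})

test_that("annulus metrics match the closed-form truth", {
  # R0 = 0.5 mm, R1 = 1 mm at 10 um/px; truth from independent closed forms
  R0 <- 0.5; R1 <- 1; W <- R1 - R0
  day0 <- fix_disk_image(241, 241, 120, 120, 50, 10, "Day0")
  day2 <- fix_disk_image(241, 241, 120, 120, 100, 10, "Day2")
  fit <- spheroid_invasion(day0, day2, pixel_size_um = 10,
                           circular_mask = FALSE)
  truth_dA <- pi * (R1^2 - R0^2)
  truth_mean <- 2 * pi * (W^3 / 3 + R0 * W^2 / 2) / truth_dA
  truth_Ir <- 2 * pi * (W^4 / 4 + R0 * W^3 / 3)
  expect_lt(abs(fit$metrics$delta_area_mm2 - truth_dA) / truth_dA, 0.01)
  expect_lt(abs(fit$metrics$mean_distance_mm - truth_mean) / truth_mean, 0.02)
  expect_lt(abs(fit$metrics$radial_moment_mm4 - truth_Ir) / truth_Ir, 0.02)
  expect_lt(abs(fit$metrics$max_distance_mm - W), 0.01)  # within 1 px
})

test_that("metrics are invariant under joint translation of the pair", {
  a0 <- fix_disk_image(161, 161, 60, 70, 25, 10, "Day0")
  a2 <- fix_disk_image(161, 161, 60, 70, 45, 10, "Day2")
  b0 <- fix_disk_image(161, 161, 60 + 21, 70 + 13, 25, 10, "Day0")
  b2 <- fix_disk_image(161, 161, 60 + 21, 70 + 13, 45, 10, "Day2")
  fa <- spheroid_invasion(a0, a2, pixel_size_um = 10, circular_mask = FALSE)
  fb <- spheroid_invasion(b0, b2, pixel_size_um = 10, circular_mask = FALSE)
  expect_equal(fa$metrics$delta_area_mm2, fb$metrics$delta_area_mm2)
  expect_equal(fa$metrics$n_outer_pixels, fb$metrics$n_outer_pixels)
  expect_equal(sort(fa$cloud$distances_mm), sort(fb$cloud$distances_mm),
               tolerance = 1e-9)
  expect_equal(fa$metrics$radial_moment_mm4, fb$metrics$radial_moment_mm4,
               tolerance = 1e-9)
})

test_that("scaling law: metrics converge when pixel size halves", {
  truth <- pi * (0.6^2 - 0.3^2)
  vals <- vapply(c(20, 10), function(px) {
    r0 <- 0.3 * 1000 / px; r1 <- 0.6 * 1000 / px
    sz <- 2 * ceiling(r1) + 15
    c0 <- (sz - 1) / 2
    d0 <- fix_disk_image(sz, sz, c0, c0, r0, px, "Day0")
    d2 <- fix_disk_image(sz, sz, c0, c0, r1, px, "Day2")
    fit <- spheroid_invasion(d0, d2, pixel_size_um = px,
                             circular_mask = FALSE)
    c(fit$metrics$delta_area_mm2, fit$metrics$radial_moment_mm4)
  }, numeric(2))
  expect_lt(abs(vals[1, 1] - vals[1, 2]) / vals[1, 2], 0.02)
  expect_lt(abs(vals[2, 1] - vals[2, 2]) / vals[2, 2], 0.02)
})

test_that("per-pixel CSV export carries distances and angles", {
  d <- withr::local_tempdir()
  day0 <- fix_disk_image(81, 81, 40, 40, 15, 10, "Day0")
  day2 <- fix_disk_image(81, 81, 40, 40, 25, 10, "Day2")
  fit <- spheroid_invasion(day0, day2, pixel_size_um = 10)
  p <- file.path(d, "pixels.csv")
  write_pixel_csv(fit$cloud, p)
  tab <- read.csv(p)
  expect_identical(names(tab),
                   c("x_px", "y_px", "d_mm", "theta_deg", "d_centroid_mm"))
  expect_equal(nrow(tab), fit$metrics$n_outer_pixels)
  expect_true(all(tab$theta_deg >= 0 & tab$theta_deg < 360))
})
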