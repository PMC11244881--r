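test_that("principal axes recover cloud orientation, with isotropy flagged", {
  # collinear cloud along y = x (45 degrees on screen, y down)
  line <- fix_cloud(cbind(0:20, 0:20))
  ax <- principal_axes(line)
  expect_equal(ax$angle_max_deg, 45, tolerance = 1e-9)
  expect_equal(ax$angle_min_deg, 135, tolerance = 1e-9)
  expect_false(ax$isotropic)
  expect_gte(ax$eigenvalues[[1]], ax$eigenvalues[[2]])

  # perfect circle: equal eigenvalues, isotropic flag, angle defaults to 0
  th <- seq(0, 2 * pi, length.out = 401)[-401]
  circ <- fix_cloud(cbind(10 * cos(th), 10 * sin(th)))
  axc <- principal_axes(circ)
  expect_true(axc$isotropic)
  expect_equal(axc$angle_max_deg, 0)

  # anisotropic Gaussian cloud: angle recovered within 3 degrees
  set.seed(101)
  n <- 5000
  u <- rnorm(n, 0, 3); v <- rnorm(n, 0, 1)
  phi <- 125 * pi / 180
  g <- fix_cloud(cbind(cos(phi) * u - sin(phi) * v,
                       sin(phi) * u + cos(phi) * v))
  expect_lt(abs(principal_axes(g)$angle_max_deg - 125), 3)

  expect_error(principal_axes(fix_cloud(matrix(0, 1, 2))), "insufficient")
})

test_that("coordinate transformation is the expected rigid rotation", {
  set.seed(5)
  pts <- cbind(rnorm(50, 10), rnorm(50, -4))
  cloud <- fix_cloud(pts, pixel_size_um = 1000)  # 1 px = 1 mm for readability
  ctr <- colMeans(pts)

  t0 <- transform_coordinates(cloud, 0)
  expect_equal(t0[, 1], pts[, 1] - ctr[1], ignore_attr = TRUE)
  expect_equal(t0[, 2], pts[, 2] - ctr[2], ignore_attr = TRUE)

  t90 <- transform_coordinates(cloud, 90)
  expect_equal(t90[, 1], pts[, 2] - ctr[2], ignore_attr = TRUE)
  expect_equal(t90[, 2], -(pts[, 1] - ctr[1]), ignore_attr = TRUE)

  # squared norm about the origin is rotation invariant
  for (ang in c(17, 45, 133)) {
    tr <- transform_coordinates(cloud, ang)
    expect_equal(sum(tr^2), sum(t0^2), tolerance = 1e-12)
  }
  # pairwise distances preserved
  expect_equal(dist(transform_coordinates(cloud, 61))[1:20], dist(t0)[1:20],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("directional moments behave like second moments of area", {
  expect_equal(directional_moments(matrix(numeric(0), 0, 2), 1e-4),
               c(I_xp = 0, I_yp = 0))
  one <- matrix(c(0.1, 0), 1, 2)
  expect_equal(directional_moments(one, 1e-4),
               c(I_xp = 0, I_yp = 1e-6))

  # polar moment I_xp + I_yp is conserved under any rotation angle
  set.seed(21)
  cloud <- fix_cloud(cbind(rnorm(400, 0, 9), rnorm(400, 0, 2)),
                     pixel_size_um = 10)
  base <- sum(directional_moments(transform_coordinates(cloud, 0), 1e-4))
  for (ang in runif(10, 0, 180)) {
    m <- directional_moments(transform_coordinates(cloud, ang), 1e-4)
    expect_equal(sum(m), base, tolerance = 1e-9)
  }
})

test_that("directional mean distances are mean absolute axis coordinates", {
  expect_equal(directional_mean_distances(matrix(numeric(0), 0, 2)),
               c(mean_d_max = 0, mean_d_min = 0))
  pair <- matrix(c(0.1, -0.1, 0, 0), 2, 2)
  expect_equal(directional_mean_distances(pair),
               c(mean_d_max = 0.1, mean_d_min = 0))
  expect_equal(directional_mean_distances(matrix(0, 5, 2)),
               c(mean_d_max = 0, mean_d_min = 0))

  # dense circle of radius r: both means approach (2/pi) r
  th <- seq(0, 2 * pi, length.out = 10001)[-10001]
  ring <- cbind(0.2 * cos(th), 0.2 * sin(th))
  m <- directional_mean_distances(ring)
  expect_equal(unname(m[1]), 2 / pi * 0.2, tolerance = 0.01)
  expect_equal(unname(m[2]), 2 / pi * 0.2, tolerance = 0.01)
})

test_that("fold changes reproduce the reported directional ratios", {
  expect_equal(fold_change(c(2, 2)), 1)
  # moment pair and distance pair as printed for the post-directed spheroid
  expect_equal(round(fold_change(c(0.227e-3, 0.103e-3)), 1), 2.2)
  expect_equal(round(fold_change(c(0.104, 0.071)), 1), 1.5)
  # order-free and scale invariant
  expect_equal(fold_change(c(0.103e-3, 0.227e-3)),
               fold_change(c(0.227e-3, 0.103e-3)))
  expect_equal(fold_change(1e6 * c(0.104, 0.071)),
               fold_change(c(0.104, 0.071)))
  expect_error(fold_change(c(1, 0)), "undefined")
})

test_that("full directionality summary ties the pieces together", {
  set.seed(33)
  n <- 4000
  u <- rnorm(n, 0, 40); v <- rnorm(n, 0, 10)
  phi <- 30 * pi / 180
  pts <- round(cbind(200 + cos(phi) * u - sin(phi) * v,
                     200 + sin(phi) * u + cos(phi) * v))
  cloud <- fix_cloud(unique(pts), pixel_size_um = 10)
  ds <- directionality_summary(cloud)
  expect_lt(abs(ds$angle_max_deg - 30), 3)
  expect_gt(ds$fold_change_moment, ds$fold_change_distance)
  expect_gt(ds$fold_change_distance, 1)
  expect_gte(ds$I_max_mm4, ds$I_min_mm4)
  # aliases are the same undirected axes
  expect_equal(ds$angle_max_alias_deg, ds$angle_max_deg - 180)
  # image-axis moments conserve the polar moment
  expect_equal(ds$I_x_mm4 + ds$I_y_mm4, ds$I_max_mm4 + ds$I_min_mm4,
               tolerance = 1e-9)
})

test_that("orientation is recovered across seeds for modest anisotropy", {
  errs <- vapply(1:8, function(s) {
    set.seed(400 + s)
    n <- 1000
    u <- rnorm(n, 0, 2); v <- rnorm(n, 0, 1)
    phi <- 70 * pi / 180
    cl <- fix_cloud(cbind(cos(phi) * u - sin(phi) * v,
                          sin(phi) * u + cos(phi) * v))
    a <- principal_axes(cl)$angle_max_deg
    min(abs(a - 70), 180 - abs(a - 70))
  }, numeric(1))
  expect_true(all(errs < 5))
})
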