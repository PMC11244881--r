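# Internal 2D geometry kernels.
#
# Coordinate convention (package-wide): 0-based (row, col) pixel indices with
# x = col, y = row; y increases downward (image convention). Polygons are
# n x 2 matrices of (x, y) vertices, stored as an open ring (no repeated
# closing vertex).

# Signed shoelace area of an open ring. Positive sign corresponds to
# counter-clockwise vertex order in the (x, y-down) frame used here.
shoelace_area <- function(xy) {
  x <- xy[, 1L]
  y <- xy[, 2L]
  xn <- c(x[-1L], x[1L])
  yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

# Vectorized point-in-polygon by the crossing-number (even-odd) rule.
# Points lying exactly on an edge (within `tol`, in pixel units) are
# classified as inside. Edges are bucketed by their y-span against the
# sorted point ordinates so each point is only examined by edges that can
# actually cross its horizontal ray.
point_in_polygon <- function(px, py, poly, tol = 1e-9) {
  nv <- nrow(poly)
  n <- length(px)
  if (n == 0L) return(logical(0L))
  ord <- order(py)
  xs <- px[ord]
  ys <- py[ord]
  inside <- logical(n)
  onb <- logical(n)

  xv <- poly[, 1L]
  yv <- poly[, 2L]
  x2 <- c(xv[-1L], xv[1L])
  y2 <- c(yv[-1L], yv[1L])

  for (k in seq_len(nv)) {
    ax <- xv[k]; ay <- yv[k]; bx <- x2[k]; by <- y2[k]
    ymin <- min(ay, by); ymax <- max(ay, by)

    # crossing candidates: ymin <= py < ymax (matches (ay > py) != (by > py))
    if (ay != by) {
      lo <- findInterval(ymin, ys, left.open = TRUE)
      hi <- findInterval(ymax, ys, left.open = TRUE)
      if (hi > lo) {
        idx <- (lo + 1L):hi
        # half-open rule: count edge if py in [ymin, ymax)
        yy <- ys[idx]
        cross <- (ay > yy) != (by > yy)
        xint <- ax + (yy - ay) * (bx - ax) / (by - ay)
        hit <- cross & (xs[idx] < xint)
        inside[idx] <- xor(inside[idx], hit)
        onb[idx] <- onb[idx] | (cross & abs(xs[idx] - xint) <= tol)
      }
    }

    # on-segment candidates (covers horizontal edges and endpoints)
    lo2 <- findInterval(ymin - tol, ys, left.open = TRUE)
    hi2 <- findInterval(ymax + tol, ys)
    if (hi2 > lo2) {
      idx <- (lo2 + 1L):hi2
      ex <- bx - ax; ey <- by - ay
      len2 <- ex * ex + ey * ey
      if (len2 > 0) {
        tproj <- ((xs[idx] - ax) * ex + (ys[idx] - ay) * ey) / len2
        tproj <- pmin(pmax(tproj, 0), 1)
        dx <- xs[idx] - (ax + tproj * ex)
        dy <- ys[idx] - (ay + tproj * ey)
        onb[idx] <- onb[idx] | (dx * dx + dy * dy <= tol * tol)
      }
    }
  }

  res <- logical(n)
  res[ord] <- inside | onb
  res
}

# For each query point (assumed outside the polygon), intersect the segment
# [centre -> point] with every polygon edge and keep the crossing with the
# largest ray parameter t <= 1 (the outermost boundary crossing not beyond
# the point itself). Edges are bucketed by the angular arc they subtend at
# the centre, so each edge only examines rays that can hit it.
#
# Returns list(t, xb, yb): per-point ray parameter and crossing coordinates.
# Points with no valid crossing get NA (the centre is then not inside the
# polygon, or the point is inside).
ray_boundary_crossings <- function(px, py, cx, cy, poly) {
  n <- length(px)
  if (n == 0L) {
    return(list(t = numeric(0L), xb = numeric(0L), yb = numeric(0L)))
  }
  dx <- px - cx
  dy <- py - cy
  phi <- atan2(dy, dx) %% (2 * pi)
  ord <- order(phi)
  phis <- phi[ord]
  dxs <- dx[ord]
  dys <- dy[ord]

  xv <- poly[, 1L]
  yv <- poly[, 2L]
  x2 <- c(xv[-1L], xv[1L])
  y2 <- c(yv[-1L], yv[1L])
  a1 <- atan2(yv - cy, xv - cx) %% (2 * pi)
  a2 <- atan2(y2 - cy, x2 - cx) %% (2 * pi)

  tbest <- rep(-Inf, n)
  eps <- 1e-9

  gather <- function(lo, hi) {
    l <- findInterval(lo, phis, left.open = TRUE)
    h <- findInterval(hi, phis)
    if (h > l) (l + 1L):h else integer(0L)
  }

  for (k in seq_along(xv)) {
    # signed shortest angular difference; an edge not through the centre
    # subtends an arc of width < pi
    w <- atan2(sin(a2[k] - a1[k]), cos(a2[k] - a1[k]))
    lo <- min(a1[k], a1[k] + w) - eps
    hi <- max(a1[k], a1[k] + w) + eps
    idx <- gather(max(lo, 0), min(hi, 2 * pi))
    if (lo < 0) idx <- c(idx, gather(lo + 2 * pi, 2 * pi))
    if (hi > 2 * pi) idx <- c(idx, gather(0, hi - 2 * pi))
    if (length(idx) == 0L) next

    ax <- xv[k] - cx; ay <- yv[k] - cy
    ex <- x2[k] - xv[k]; ey <- y2[k] - yv[k]
    ddx <- dxs[idx]; ddy <- dys[idx]
    denom <- ddx * ey - ddy * ex
    ok <- abs(denom) > 1e-12 * pmax(1, abs(ddx) + abs(ddy))
    tt <- (ax * ey - ay * ex) / denom
    ss <- (ax * ddy - ay * ddx) / denom
    ok <- ok & ss >= -1e-9 & ss <= 1 + 1e-9 & tt >= -1e-12 & tt <= 1 + 1e-9
    if (any(ok)) {
      ii <- idx[ok]
      tbest[ii] <- pmax(tbest[ii], tt[ok])
    }
  }

  t <- rep(NA_real_, n)
  t[ord] <- ifelse(is.finite(tbest), pmin(tbest, 1), NA_real_)
  list(t = t, xb = cx + t * dx, yb = cy + t * dy)
}
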