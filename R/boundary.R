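# Day-0 spheroid segmentation: largest 8-connected component, hole filling,
# sub-pixel outer contour, centroid registration.

# 8-connected labeling built on EBImage::bwlabel (4-connected) plus a
# union-find merge of labels touching diagonally.
.label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  nl <- max(lab)
  if (nl < 2L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  # diagonal neighbor label pairs (down-right and down-left)
  p1 <- cbind(as.vector(lab[-h, -w]), as.vector(lab[-1L, -1L]))
  p2 <- cbind(as.vector(lab[-h, -1L]), as.vector(lab[-1L, -w]))
  pairs <- rbind(p1, p2)
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                 pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  parent <- seq_len(nl)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs) > 0L) {
    pairs <- unique(pairs)
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1L]); b <- find(pairs[r, 2L])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(nl), find, integer(1L))
  relab <- match(root, sort(unique(root)))
  out <- lab
  nz <- lab > 0L
  out[nz] <- relab[lab[nz]]
  out
}

#' Segment the spheroid body from a binary image
#'
#' Keeps the largest 8-connected foreground component (ties broken by the
#' smallest top-left bounding-box corner, row then column), fills its
#' interior holes, and computes its area and area centroid (arithmetic mean
#' of member pixel coordinates, so possibly fractional).
#'
#' @param img a [binary_image] with at least one foreground pixel.
#' @return an object of class \code{spheroid_mask}: list with \code{mask}
#'   (logical matrix, single filled component), \code{area_px},
#'   \code{centroid} (x, y in 0-based pixel coordinates) and
#'   \code{pixel_size_um}.
#' @export
extract_spheroid_mask <- function(img) {
  stopifnot(inherits(img, "binary_image"))
  if (!any(img$mask)) stop("no spheroid found: image has no foreground pixels")
  lab <- .label8(img$mask)
  nl <- max(lab)
  sizes <- tabulate(lab[lab > 0L], nbins = nl)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # deterministic tie-break: smallest bounding-box top-left (row, then col)
    corners <- t(vapply(best, function(l) {
      idx <- which(lab == l, arr.ind = TRUE)
      c(min(idx[, 1L]), min(idx[, 2L]))
    }, numeric(2L)))
    best <- best[order(corners[, 1L], corners[, 2L])][1L]
  }
  comp <- lab == best
  filled <- as.matrix(EBImage::fillHull(comp)) > 0
  idx <- which(filled, arr.ind = TRUE)
  centroid <- c(x = mean(idx[, 2L]) - 1, y = mean(idx[, 1L]) - 1)
  structure(list(mask = filled, area_px = nrow(idx), centroid = centroid,
                 pixel_size_um = img$pixel_size_um),
            class = "spheroid_mask")
}

#' Extract the outer boundary polygon of a spheroid mask
#'
#' Traces the 0.5-level contour of the filled mask (marching squares), which
#' places vertices at sub-pixel positions halfway between foreground and
#' background pixel centers. The mask is padded before tracing so a
#' component touching the frame still yields a closed ring. Vertex order is
#' normalized to positive shoelace area in the (x, y-down) frame.
#'
#' @param smask a \code{spheroid_mask} from [extract_spheroid_mask()], or a
#'   [binary_image] (segmented on the fly).
#' @return an object of class \code{boundary_polygon}: list with
#'   \code{vertices} (n x 2 matrix of x, y; open ring), \code{centroid}
#'   (the spheroid area centroid) and \code{area_px2} (enclosed shoelace
#'   area).
#' @export
extract_boundary <- function(smask) {
  if (inherits(smask, "binary_image")) smask <- extract_spheroid_mask(smask)
  stopifnot(inherits(smask, "spheroid_mask"))
  m <- smask$mask
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0, h + 2L, w + 2L)
  pad[2L:(h + 1L), 2L:(w + 1L)] <- m
  # grid coordinates chosen so pixel [r, c] (1-based) sits at (y, x) = (r-1, c-1)
  cl <- grDevices::contourLines(x = seq(-1, h), y = seq(-1, w), z = pad,
                                levels = 0.5)
  if (length(cl) == 0L) stop("contour extraction failed")
  rings <- lapply(cl, function(g) cbind(x = g$y, y = g$x))
  areas <- vapply(rings, function(r) abs(shoelace_area(.open_ring(r))),
                  numeric(1L))
  ring <- .open_ring(rings[[which.max(areas)]])
  if (nrow(ring) < 3L) stop("degenerate contour")
  if (shoelace_area(ring) < 0) ring <- ring[rev(seq_len(nrow(ring))), ]
  structure(list(vertices = ring, centroid = smask$centroid,
                 area_px2 = shoelace_area(ring)),
            class = "boundary_polygon")
}

# drop a repeated closing vertex if present
.open_ring <- function(r) {
  n <- nrow(r)
  if (n > 1L && all(abs(r[1L, ] - r[n, ]) < 1e-12)) r <- r[-n, , drop = FALSE]
  r
}

#' @export
print.boundary_polygon <- function(x, ...) {
  cat(sprintf(
    "<boundary_polygon> %d vertices, centroid (%.2f, %.2f) px, area %.1f px^2\n",
    nrow(x$vertices), x$centroid[1L], x$centroid[2L], x$area_px2))
  invisible(x)
}

#' Centroid of the final-timepoint spheroid body
#'
#' Centroid of the largest connected foreground component (holes filled) of
#' the final image. Using the spheroid core rather than all foreground
#' pixels keeps the registration unbiased by spatially asymmetric invasion.
#'
#' @param img a [binary_image].
#' @return named numeric (x, y) in 0-based pixel coordinates.
#' @export
day2_centroid <- function(img) {
  extract_spheroid_mask(img)$centroid
}

#' Register a boundary polygon onto another image by centroid translation
#'
#' Rigidly translates every vertex by (target centroid - boundary centroid),
#' so the translated boundary's centroid coincides with the target. This is
#' the only registration step used: no rotation or scaling.
#'
#' @param boundary a \code{boundary_polygon}.
#' @param target_centroid (x, y) centroid to move the boundary onto,
#'   typically from [day2_centroid()].
#' @return the translated \code{boundary_polygon}.
#' @export
register_boundary <- function(boundary, target_centroid) {
  stopifnot(inherits(boundary, "boundary_polygon"))
  shift <- c(target_centroid[1L] - boundary$centroid[1L],
             target_centroid[2L] - boundary$centroid[2L])
  v <- boundary$vertices
  v[, 1L] <- v[, 1L] + shift[1L]
  v[, 2L] <- v[, 2L] + shift[2L]
  structure(list(vertices = v,
                 centroid = c(x = unname(target_centroid[1L]),
                              y = unname(target_centroid[2L])),
                 area_px2 = boundary$area_px2),
            class = "boundary_polygon")
}

#' Write boundary polygon vertices to CSV
#'
#' @param boundary a \code{boundary_polygon}.
#' @param path output CSV path; columns \code{x_px}, \code{y_px}.
#' @return the path, invisibly.
#' @export
write_boundary_csv <- function(boundary, path) {
  stopifnot(inherits(boundary, "boundary_polygon"))
  utils::write.csv(data.frame(x_px = boundary$vertices[, 1L],
                              y_px = boundary$vertices[, 2L]),
                   path, row.names = FALSE)
  invisible(path)
}
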