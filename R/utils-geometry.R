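# Low-level planar geometry shared across modules.
#
# Conventions used package-wide:
#   * label masks are integer matrices m[i, j] where i indexes x (0-based
#     pixel coordinate x = i - 1) and j indexes y; background is 0
#   * physical coordinates are micrometres: um = 0-based pixel * pixel_size
#   * polylines/polygons are n x 2 matrices with columns (x, y) in um

#' Wrap angles to the nematic range (-pi/2, pi/2]
#'
#' Director angles are headless (defined modulo pi); this maps any angle to
#' the canonical half-open interval used throughout the package.
#'
#' @param a numeric vector of angles in radians.
#' @return numeric vector in (-pi/2, pi/2].
#' @export
wrap_nematic <- function(a) {
  a <- (a + pi / 2) %% pi
  a[a <= 0 | abs(a) < 1e-15] <- pi
  a - pi / 2
}

## distance from points (px,py) to segments (ax,ay)-(bx,by); all vectorised
point_seg_dist <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax
  dy <- by - ay
  l2 <- dx * dx + dy * dy
  t <- ((px - ax) * dx + (py - ay) * dy) / (l2 + (l2 == 0)) # 0/1 when degenerate
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

## minimum distance between segment pairs, vectorised over pairs.
## Proper crossings give distance zero.
seg_seg_dist <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  d <- pmin(
    point_seg_dist(ax, ay, cx, cy, dx, dy),
    point_seg_dist(bx, by, cx, cy, dx, dy),
    point_seg_dist(cx, cy, ax, ay, bx, by),
    point_seg_dist(dx, dy, ax, ay, bx, by)
  )
  orient <- function(px, py, qx, qy, rx, ry) {
    sign((qx - px) * (ry - py) - (qy - py) * (rx - px))
  }
  o1 <- orient(ax, ay, bx, by, cx, cy)
  o2 <- orient(ax, ay, bx, by, dx, dy)
  o3 <- orient(cx, cy, dx, dy, ax, ay)
  o4 <- orient(cx, cy, dx, dy, bx, by)
  cross <- (o1 * o2 < 0) & (o3 * o4 < 0)
  d[cross] <- 0
  d
}

## closest points between two segments p = a + t (b - a), q = c + u (d - c).
## Returns list(d, px, py, qx, qy); used by the rod relaxation to get the
## push direction. Vectorised over pairs.
seg_seg_closest <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  cand_ps <- function(px, py, sx1, sy1, sx2, sy2) {
    ddx <- sx2 - sx1
    ddy <- sy2 - sy1
    l2 <- ddx * ddx + ddy * ddy
    t <- ((px - sx1) * ddx + (py - sy1) * ddy) / (l2 + (l2 == 0))
    t <- pmin(pmax(t, 0), 1)
    qx <- sx1 + t * ddx
    qy <- sy1 + t * ddy
    list(d = sqrt((px - qx)^2 + (py - qy)^2), qx = qx, qy = qy)
  }
  c1 <- cand_ps(ax, ay, cx, cy, dx, dy) # a vs cd
  c2 <- cand_ps(bx, by, cx, cy, dx, dy) # b vs cd
  c3 <- cand_ps(cx, cy, ax, ay, bx, by) # c vs ab
  c4 <- cand_ps(dx, dy, ax, ay, bx, by) # d vs ab
  d <- pmin(c1$d, c2$d, c3$d, c4$d)
  n <- length(d)
  px <- py <- qx <- qy <- numeric(n)
  pick <- function(idx, ppx, ppy, qqx, qqy) {
    px[idx] <<- ppx[idx]
    py[idx] <<- ppy[idx]
    qx[idx] <<- qqx[idx]
    qy[idx] <<- qqy[idx]
  }
  i4 <- d == c4$d
  pick(i4, c4$qx, c4$qy, rep(dx, length.out = n), rep(dy, length.out = n))
  i3 <- d == c3$d
  pick(i3, c3$qx, c3$qy, rep(cx, length.out = n), rep(cy, length.out = n))
  i2 <- d == c2$d
  pick(i2, rep(bx, length.out = n), rep(by, length.out = n), c2$qx, c2$qy)
  i1 <- d == c1$d
  pick(i1, rep(ax, length.out = n), rep(ay, length.out = n), c1$qx, c1$qy)
  list(d = d, px = px, py = py, qx = qx, qy = qy)
}

#' Length of a polyline
#' @param pts n x 2 matrix of (x, y) points.
#' @param closed close the curve back to its first point?
#' @return total length in the units of `pts`.
#' @export
polyline_length <- function(pts, closed = FALSE) {
  if (is.null(dim(pts)) || nrow(pts) < 2) return(0)
  if (closed) pts <- rbind(pts, pts[1, , drop = FALSE])
  sum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2))
}

#' Signed area of a simple polygon (shoelace)
#' @param pts n x 2 vertex matrix (implicitly closed).
#' @return area; positive for counter-clockwise orientation.
#' @export
polygon_area <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(0)
  x <- pts[, 1]; y <- pts[, 2]
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' Centroid of a simple polygon
#' @param pts n x 2 vertex matrix (implicitly closed).
#' @return numeric (x, y).
#' @export
polygon_centroid <- function(pts) {
  n <- nrow(pts)
  x <- pts[, 1]; y <- pts[, 2]
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(pts))
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

## circular moving average over a closed polyline; k odd window size.
## Tames the chain-code staircase of rasterised contours so that summed
## segment lengths estimate the true perimeter closely (straight edges are
## fixed points of the filter).
smooth_closed_polyline <- function(pts, k = 7) {
  n <- nrow(pts)
  if (n <= k || k < 3) return(pts)
  h <- (k - 1) / 2
  idx <- c((n - h + 1):n, 1:n, 1:h)
  xs <- stats::filter(pts[idx, 1], rep(1 / k, k), sides = 2)
  ys <- stats::filter(pts[idx, 2], rep(1 / k, k), sides = 2)
  cbind(xs[(h + 1):(h + n)], ys[(h + 1):(h + n)])
}

## moving average for an open polyline (endpoints kept fixed)
smooth_open_polyline <- function(pts, k = 5) {
  n <- nrow(pts)
  if (n <= k || k < 3) return(pts)
  xs <- stats::filter(pts[, 1], rep(1 / k, k), sides = 2)
  ys <- stats::filter(pts[, 2], rep(1 / k, k), sides = 2)
  out <- cbind(as.numeric(xs), as.numeric(ys))
  bad <- is.na(out[, 1])
  out[bad, ] <- pts[bad, ]
  out
}

#' Minimum distance from points to a polyline
#' @param pts n x 2 query points.
#' @param line m x 2 polyline.
#' @return numeric vector of distances.
#' @export
point_polyline_dist <- function(pts, line) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  m <- nrow(line)
  if (m == 1) {
    return(sqrt((pts[, 1] - line[1, 1])^2 + (pts[, 2] - line[1, 2])^2))
  }
  d <- rep(Inf, nrow(pts))
  for (k in seq_len(m - 1)) {
    d <- pmin(d, point_seg_dist(
      pts[, 1], pts[, 2],
      line[k, 1], line[k, 2], line[k + 1, 1], line[k + 1, 2]
    ))
  }
  d
}

## minimum distance between two polygons given as vertex matrices (closed).
## Exact segment-against-segment minimum; zero when they intersect.
polygon_min_dist <- function(p1, p2) {
  a <- p1
  b <- rbind(p1[-1, , drop = FALSE], p1[1, , drop = FALSE])
  c_ <- p2
  d_ <- rbind(p2[-1, , drop = FALSE], p2[1, , drop = FALSE])
  n1 <- nrow(a)
  n2 <- nrow(c_)
  i <- rep(seq_len(n1), times = n2)
  j <- rep(seq_len(n2), each = n1)
  min(seg_seg_dist(
    a[i, 1], a[i, 2], b[i, 1], b[i, 2],
    c_[j, 1], c_[j, 2], d_[j, 1], d_[j, 2]
  ))
}

## extract the contour of each object in a labelled mask as 0-based (x, y)
## pixel coordinates; returns a list indexed by label value.
mask_contours <- function(mask) {
  labs <- sort(unique(as.vector(mask)))
  labs <- labs[labs > 0]
  out <- vector("list", length(labs))
  names(out) <- as.character(labs)
  for (k in seq_along(labs)) {
    oc <- EBImage::ocontour(EBImage::Image(mask == labs[k]))
    if (length(oc) == 0) next
    # keep the longest contour of this object
    lens <- vapply(oc, nrow, integer(1))
    out[[k]] <- oc[[which.max(lens)]]
  }
  out
}

## order the pixels of a thin 8-connected band into a polyline by taking the
## graph-diameter path of the pixel adjacency graph (igraph). xy is an n x 2
## matrix of pixel coordinates.
order_band_pixels <- function(xy) {
  n <- nrow(xy)
  if (n <= 2) return(xy)
  # adjacency: Chebyshev distance 1
  dx <- outer(xy[, 1], xy[, 1], "-")
  dy <- outer(xy[, 2], xy[, 2], "-")
  adj <- (pmax(abs(dx), abs(dy)) == 1)
  ij <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (nrow(ij) == 0) return(xy)
  w <- sqrt((xy[ij[, 1], 1] - xy[ij[, 2], 1])^2 +
              (xy[ij[, 1], 2] - xy[ij[, 2], 2])^2)
  g <- igraph::graph_from_edgelist(ij, directed = FALSE)
  igraph::E(g)$weight <- w
  if (igraph::vcount(g) < n) {
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  }
  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  vmain <- which(comp$membership == main)
  # double BFS approximation of the diameter path
  d1 <- igraph::distances(g, v = vmain[1])[1, vmain]
  e1 <- vmain[which.max(d1)]
  d2 <- igraph::distances(g, v = e1)[1, vmain]
  e2 <- vmain[which.max(d2)]
  path <- igraph::shortest_paths(g, from = e1, to = e2)$vpath[[1]]
  xy[as.integer(path), , drop = FALSE]
}

## largest connected region of a binary matrix (EBImage bwlabel)
largest_component <- function(bin) {
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  lab <- imageData_matrix(lab)
  if (max(lab) <= 1) return(list(mask = lab > 0, n = max(lab)))
  sz <- tabulate(lab[lab > 0])
  list(mask = lab == which.max(sz), n = length(sz))
}

## EBImage images back to plain matrices
imageData_matrix <- function(img) {
  m <- EBImage::imageData(img)
  dim(m) <- dim(m)[1:2]
  m
}

## disc-shaped structuring element of radius r pixels
disc_brush <- function(r) {
  size <- 2 * max(1, round(r)) + 1
  EBImage::makeBrush(size, shape = "disc")
}
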