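# Genealogical-enclave analytics: contact graphs, enclave polygons and the
# interface between them, moving-box Shannon entropy with a permutation
# null, interface curvature, invasion regions, and per-chain phenotype
# statistics.

#' Cell contact graph of one frame
#'
#' Two cells are neighbours when their centroids lie within `radius` and the
#' minimum distance between their boundary polygons is below `tol`. Polygon
#' distances are exact segment-against-segment minima (no boundary point
#' sampling).
#'
#' @param features a `cell_features` object (see [extract_features()]) or a
#'   list with `cells` (data.frame with x, y and optionally chain) and
#'   `contours` (list of n x 2 um polygons).
#' @param chains optional integer vector of chain labels per cell
#'   (overrides a `chain` column).
#' @param radius centroid pre-filter radius (um).
#' @param tol boundary-to-boundary contact tolerance (um).
#' @return a `contact_graph`: edges data.frame (i, j, dist) and per-cell
#'   intra-/inter-chain neighbour counts.
#' @export
contact_graph <- function(features, chains = NULL, radius = 10, tol = 1.2) {
  cells <- features$cells
  contours <- features$contours
  n <- nrow(cells)
  if (is.null(chains)) chains <- cells$chain
  edges <- list()
  if (n >= 2) {
    i <- rep(seq_len(n - 1), times = (n - 1):1)
    j <- sequence((n - 1):1) + i
    cd <- sqrt((cells$x[i] - cells$x[j])^2 + (cells$y[i] - cells$y[j])^2)
    keep <- cd < radius
    i <- i[keep]; j <- j[keep]
    for (k in seq_along(i)) {
      d <- polygon_min_dist(contours[[i[k]]], contours[[j[k]]])
      if (d < tol) edges[[length(edges) + 1]] <- c(i[k], j[k], d)
    }
  }
  edges <- if (length(edges)) {
    as.data.frame(do.call(rbind, edges)) |> stats::setNames(c("i", "j", "dist"))
  } else {
    data.frame(i = integer(0), j = integer(0), dist = numeric(0))
  }
  intra <- inter <- integer(n)
  for (k in seq_len(nrow(edges))) {
    a <- edges$i[k]; b <- edges$j[k]
    same <- !is.null(chains) && !is.na(chains[a]) && !is.na(chains[b]) &&
      chains[a] == chains[b]
    if (same) {
      intra[a] <- intra[a] + 1L
      intra[b] <- intra[b] + 1L
    } else {
      inter[a] <- inter[a] + 1L
      inter[b] <- inter[b] + 1L
    }
  }
  structure(
    list(edges = edges, intra = intra, inter = inter, chains = chains,
         radius = radius, tol = tol, n = n),
    class = "contact_graph"
  )
}

#' Mean interenclave contact fraction
#'
#' Mean over non-isolated cells of (inter-chain neighbours) / (all
#' neighbours). Flags the degenerate all-isolated case.
#'
#' @param graph a [contact_graph()].
#' @return fraction in [0, 1] (NA with a warning if every cell is isolated).
#' @export
interenclave_contact_fraction <- function(graph) {
  tot <- graph$intra + graph$inter
  ok <- tot > 0
  if (!any(ok)) {
    warning("all cells are isolated; contact fraction undefined")
    return(NA_real_)
  }
  mean(graph$inter[ok] / tot[ok])
}

#' Interface length from enclave and colony perimeters
#'
#' Both enclaves lie inside the colony and meet along a single shared
#' interface, so each enclave perimeter decomposes into its exposed share
#' of the colony outline plus the interface, giving
#' L_interface = (Ps1 + Ps2 - Lcolony) / 2.
#'
#' @param ps1,ps2 enclave perimeters (um).
#' @param l_colony colony outline perimeter (um).
#' @return interface length (um).
#' @export
interface_length_formula <- function(ps1, ps2, l_colony) {
  (ps1 + ps2 - l_colony) / 2
}

## chain membership mask: union of pixels of the labels in `labels`
chain_mask <- function(mask, labels) {
  matrix(mask %in% labels, nrow(mask), ncol(mask))
}

#' Partition a frame into its two genealogical enclaves
#'
#' Every pixel of the filled colony region is assigned to the enclave of
#' its nearest cell (two-class distance transform), so the two enclave
#' regions are complementary, absorb the intercellular voids, and meet
#' along a single interface. Reports per-enclave polygon, centroid, area
#' and perimeter Ps, the centroid separation (delta c), the interface
#' length from L_interface = (Ps1 + Ps2 - Lcolony)/2, the directly measured
#' interface polyline, and each enclave's exposed share of the colony
#' outline.
#'
#' @param frame a `colony_frame` whose `cells` table has label and chain.
#' @param chains optional chain label per mask label (defaults to the
#'   frame's cells table).
#' @return an `enclave_partition`.
#' @export
enclave_partition <- function(frame, chains = NULL) {
  mask <- frame$mask
  px <- frame$pixel_size
  cells <- frame$cells
  if (is.null(chains)) chains <- stats::setNames(cells$chain, cells$label)
  labs <- as.integer(names(chains))
  stopifnot(all(chains %in% c(1, 2)))

  colony <- colony_boundary(frame)
  colony_fill <- attr(colony, "filled")

  # nearest-chain assignment of every colony pixel
  dist_to <- function(m) {
    imageData_matrix(EBImage::distmap(EBImage::Image((!m) * 1)))
  }
  m1 <- chain_mask(mask, labs[chains == 1])
  m2 <- chain_mask(mask, labs[chains == 2])
  if (!any(m1) || !any(m2)) stop("each chain needs at least one cell")
  near1 <- dist_to(m1) <= dist_to(m2)
  regions <- list(colony_fill & near1, colony_fill & !near1)

  enclaves <- list()
  flagged <- FALSE
  for (ch in 1:2) {
    lc <- largest_component(regions[[ch]])
    if (lc$n > 1) flagged <- TRUE
    region <- lc$mask
    oc <- mask_contours(matrix(as.integer(region), nrow(region)))[[1]]
    poly <- smooth_closed_polyline(oc, 7) * px
    poly[, 1] <- poly[, 1] + frame$origin[1]
    poly[, 2] <- poly[, 2] + frame$origin[2]
    enclaves[[ch]] <- list(
      region = region, polygon = poly,
      centroid = polygon_centroid(poly),
      area = abs(polygon_area(poly)),
      perimeter = polyline_length(poly, closed = TRUE)
    )
  }

  dc <- sqrt(sum((enclaves[[1]]$centroid - enclaves[[2]]$centroid)^2))
  L_colony <- colony$perimeter
  L_interface <- interface_length_formula(
    enclaves[[1]]$perimeter, enclaves[[2]]$perimeter, L_colony
  )

  # directly measured interface: band where the dilation of enclave 1 meets
  # enclave 2, ordered into a polyline
  dil <- imageData_matrix(EBImage::dilate(
    EBImage::Image(enclaves[[1]]$region * 1), disc_brush(1)
  )) > 0
  band <- which(dil & enclaves[[2]]$region, arr.ind = TRUE)
  interface <- NULL
  interface_length <- 0
  if (nrow(band) > 2) {
    xy <- cbind(band[, 1] - 1, band[, 2] - 1)
    path <- order_band_pixels(xy)
    path <- smooth_open_polyline(path, 7)
    interface <- sweep(path * px, 2, frame$origin, "+")
    interface_length <- polyline_length(interface)
  }

  # exposed colony-outline share: fraction of colony outline vertices lying
  # on each enclave's region
  outline_px <- sweep(colony$polygon, 2, frame$origin, "-") / px
  seglen <- sqrt(diff(colony$polygon[, 1])^2 + diff(colony$polygon[, 2])^2)
  seglen <- c(seglen, sqrt(sum((colony$polygon[1, ] - colony$polygon[nrow(colony$polygon), ])^2)))
  exposed <- numeric(2)
  ii <- pmin(pmax(round(outline_px[, 1]) + 1, 1), nrow(mask))
  jj <- pmin(pmax(round(outline_px[, 2]) + 1, 1), ncol(mask))
  for (ch in 1:2) {
    # nearest-enclave attribution of each outline vertex
    reg <- enclaves[[ch]]$region
    dil2 <- imageData_matrix(EBImage::dilate(
      EBImage::Image(reg * 1), disc_brush(3)
    )) > 0
    on_e <- dil2[cbind(ii, jj)]
    exposed[ch] <- sum(seglen[on_e]) / L_colony
  }

  structure(
    list(
      enclaves = enclaves, delta_c = dc,
      L_colony = L_colony, L_interface = L_interface,
      interface = interface, interface_length = interface_length,
      exposed_fraction = exposed, colony = colony, flagged = flagged
    ),
    class = "enclave_partition"
  )
}

#' @export
print.enclave_partition <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<enclave_partition> areas = (%.1f, %.1f) um^2, delta_c = %.2f um,\n",
      "  L_interface = %.2f um (measured %.2f), exposed = (%.2f, %.2f)%s\n"
    ),
    x$enclaves[[1]]$area, x$enclaves[[2]]$area, x$delta_c,
    x$L_interface, x$interface_length,
    x$exposed_fraction[1], x$exposed_fraction[2],
    if (x$flagged) " [fragmented]" else ""
  ))
  invisible(x)
}

## core moving-box entropy on raw point coordinates; returns boxes table,
## mean SE and the box-membership matrix used by the permutation null.
shannon_entropy_points <- function(x, y, chain, s, stride = s / 2) {
  n <- length(x)
  x0 <- min(x); y0 <- min(y)
  nbx <- max(1, ceiling((max(x) - x0) / stride))
  nby <- max(1, ceiling((max(y) - y0) / stride))
  # box origins on the stride grid; each box covers [o, o + s)
  ox <- x0 + (seq_len(nbx + 1) - 1 - 1) * stride # include one box left of min
  oy <- y0 + (seq_len(nby + 1) - 1 - 1) * stride
  ox <- ox[ox + s > x0]
  oy <- oy[oy + s > y0]
  nb <- length(ox) * length(oy)
  M <- matrix(FALSE, nb, n)
  bi <- rep(seq_along(ox), times = length(oy))
  bj <- rep(seq_along(oy), each = length(ox))
  for (b in seq_len(nb)) {
    inb <- x >= ox[bi[b]] & x < ox[bi[b]] + s &
      y >= oy[bj[b]] & y < oy[bj[b]] + s
    M[b, ] <- inb
  }
  counts <- rowSums(M)
  occ <- counts > 0
  M <- M[occ, , drop = FALSE]
  counts <- counts[occ]
  red <- as.numeric(M %*% (chain == 1))
  pr <- red / counts
  se <- box_se(pr)
  boxes <- data.frame(
    cx = ox[bi[occ]] + s / 2, cy = oy[bj[occ]] + s / 2,
    n = counts, p_r = pr, p_g = 1 - pr, se = se
  )
  list(boxes = boxes, mean_se = mean(se), M = M, counts = counts)
}

## -p log p - q log q with 0 log 0 := 0 (natural log)
box_se <- function(pr) {
  pg <- 1 - pr
  term <- function(p) ifelse(p > 0, -p * log(p), 0)
  term(pr) + term(pg)
}

#' Moving-box Shannon entropy of a two-colour arrangement
#'
#' Square boxes of side `s` tile the bounding box of the cell centroids at
#' stride `s/2`; every box holding at least one centroid contributes
#' SE(B) = -p_r ln p_r - p_g ln p_g, and the colony value is the mean over
#' those boxes. Values range from 0 (every box single-chain) to ln 2
#' (every box balanced).
#'
#' @param frame a `colony_frame` (uses its `cells` x, y, chain) or a
#'   data.frame with columns x, y, chain.
#' @param chains optional chain vector overriding the chain column.
#' @param s box side (um); the default 5.5 um holds a handful of cells.
#' @return an `entropy_result` with `boxes`, `mean_se`.
#' @export
shannon_entropy <- function(frame, chains = NULL, s = 5.5) {
  cells <- if (inherits(frame, "colony_frame")) frame$cells else frame
  if (is.null(chains)) chains <- cells$chain
  ok <- !is.na(chains)
  res <- shannon_entropy_points(cells$x[ok], cells$y[ok], chains[ok], s = s)
  structure(
    list(boxes = res$boxes, mean_se = res$mean_se, s = s,
         membership = res$M, counts = res$counts,
         chains = chains[ok]),
    class = "entropy_result"
  )
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf(
    "<entropy_result> mean SE = %.4f over %d occupied boxes (s = %.2f um)\n",
    x$mean_se, nrow(x$boxes), x$s
  ))
  invisible(x)
}

#' Permutation null for the arrangement entropy
#'
#' Re-assigns the two chain colours at random over the fixed cell positions,
#' preserving the per-chain counts, and records the mean moving-box entropy
#' of each permutation. The observed arrangement is compared against this
#' null (its percentile is reported).
#'
#' @param frame as in [shannon_entropy()].
#' @param chains optional chain vector.
#' @param s box side (um).
#' @param iterations number of label permutations (the full-scale analysis
#'   uses 2e5; reduce for interactive work).
#' @param seed RNG seed.
#' @return list with `null` (vector of mean SEs), `observed`, `null_mean`,
#'   `null_range`, `percentile`.
#' @export
randomized_entropy_null <- function(frame, chains = NULL, s = 5.5,
                                    iterations = 2e5, seed = 1) {
  ent <- shannon_entropy(frame, chains, s)
  set.seed(seed)
  M <- ent$membership * 1
  counts <- ent$counts
  labels <- ent$chains
  n <- length(labels)
  n_red <- sum(labels == 1)
  chunk <- 20000L
  null <- numeric(iterations)
  done <- 0L
  while (done < iterations) {
    k <- min(chunk, iterations - done)
    P <- matrix(0, n, k)
    for (c_ in seq_len(k)) P[sample.int(n, n_red), c_] <- 1
    red <- M %*% P
    pr <- red / counts
    se <- box_se(pr)
    dim(se) <- dim(pr)
    null[(done + 1):(done + k)] <- colMeans(se)
    done <- done + k
  }
  list(
    null = null, observed = ent$mean_se, null_mean = mean(null),
    null_range = range(null),
    percentile = mean(null < ent$mean_se)
  )
}

#' Curvature along an interface polyline
#'
#' Fits smoothing splines x(s), y(s) against arc length and evaluates
#' kappa = |x'y'' - y'x''| / (x'^2 + y'^2)^(3/2) at evenly spaced
#' arc-length samples. The signed curvature uses the traversal orientation;
#' when `orient_point` (e.g. the chain-1 enclave centroid) is supplied the
#' polyline is oriented so that the point lies on its left, making positive
#' curvature bend towards chain 1. High-curvature points are local maxima
#' of |kappa| above `threshold`.
#'
#' @param polyline n x 2 matrix (um), n >= 5. Closed curves (first and last
#'   points coincide within one sample step) are handled periodically.
#' @param threshold high-curvature threshold (1/um); default
#'   `1/(2 * width_hint)`.
#' @param width_hint characteristic cell width (um) used for the default
#'   threshold.
#' @param spar smoothing parameter passed to [stats::smooth.spline()].
#' @param n_samples number of arc-length evaluation points.
#' @param orient_point optional (x, y) defining the chain-1 side.
#' @return an `interface_geometry` with `samples` (s, x, y, kappa,
#'   kappa_signed), `high` (the high-curvature points), `threshold`,
#'   `frequency` (high points per unit length) and `length`.
#' @export
interface_curvature <- function(polyline, threshold = NULL, width_hint = 0.9,
                                spar = 0.7, n_samples = 200,
                                orient_point = NULL) {
  if (nrow(polyline) < 5) stop("polyline too short for spline curvature")
  if (is.null(threshold)) threshold <- 1 / (2 * width_hint)
  pts <- polyline
  step <- polyline_length(pts) / (nrow(pts) - 1)
  closed <- sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2)) <= 2 * step
  if (!is.null(orient_point)) {
    # orient so that orient_point is on the left of the traversal
    mid <- floor(nrow(pts) / 2)
    tangent <- pts[mid + 1, ] - pts[mid, ]
    tomid <- orient_point - pts[mid, ]
    if (tangent[1] * tomid[2] - tangent[2] * tomid[1] < 0) {
      pts <- pts[nrow(pts):1, , drop = FALSE]
    }
  }
  if (closed) {
    # periodic padding by a quarter of the curve on each side
    m <- nrow(pts)
    pad <- max(5, floor(m / 4))
    pts2 <- rbind(pts[(m - pad + 1):m, ], pts, pts[1:pad, ])
    core <- (pad + 1):(pad + m)
  } else {
    pts2 <- pts
    core <- seq_len(nrow(pts))
  }
  ds <- sqrt(diff(pts2[, 1])^2 + diff(pts2[, 2])^2)
  sarc <- c(0, cumsum(ds))
  fit_x <- stats::smooth.spline(sarc, pts2[, 1], spar = spar)
  fit_y <- stats::smooth.spline(sarc, pts2[, 2], spar = spar)
  s_eval <- seq(sarc[core[1]], sarc[core[length(core)]], length.out = n_samples)
  x1 <- stats::predict(fit_x, s_eval, deriv = 1)$y
  x2 <- stats::predict(fit_x, s_eval, deriv = 2)$y
  y1 <- stats::predict(fit_y, s_eval, deriv = 1)$y
  y2 <- stats::predict(fit_y, s_eval, deriv = 2)$y
  cross <- x1 * y2 - y1 * x2
  denom <- (x1^2 + y1^2)^1.5
  kappa_s <- cross / denom
  kappa <- abs(kappa_s)
  xs <- stats::predict(fit_x, s_eval)$y
  ys <- stats::predict(fit_y, s_eval)$y
  samples <- data.frame(
    s = s_eval - s_eval[1], x = xs, y = ys,
    kappa = kappa, kappa_signed = kappa_s
  )
  # local maxima of |kappa| above threshold
  hi <- which(
    kappa > threshold &
      kappa >= c(-Inf, kappa[-length(kappa)]) &
      kappa >= c(kappa[-1], -Inf)
  )
  total_len <- samples$s[nrow(samples)]
  structure(
    list(
      samples = samples, high = samples[hi, , drop = FALSE],
      threshold = threshold, length = total_len,
      frequency = length(hi) / total_len, closed = closed
    ),
    class = "interface_geometry"
  )
}

#' @export
print.interface_geometry <- function(x, ...) {
  cat(sprintf(
    "<interface_geometry> length %.1f um, %d high-curvature points (thr %.2f /um)\n",
    x$length, nrow(x$high), x$threshold
  ))
  invisible(x)
}

## width of a polygon section: at depth v (in the chord frame), sum of the
## u-intervals where the horizontal line crosses the polygon interior
polygon_section_width <- function(uv, v) {
  n <- nrow(uv)
  j <- c(2:n, 1)
  us <- numeric(0)
  for (k in seq_len(n)) {
    v1 <- uv[k, 2]; v2 <- uv[j[k], 2]
    if ((v1 <= v && v2 > v) || (v2 <= v && v1 > v)) {
      t <- (v - v1) / (v2 - v1)
      us <- c(us, uv[k, 1] + t * (uv[j[k], 1] - uv[k, 1]))
    }
  }
  if (length(us) < 2) return(0)
  us <- sort(us)
  sum(us[seq(2, length(us), by = 2)] - us[seq(1, length(us) - 1, by = 2)])
}

#' Invasion regions delimited by high-curvature interface points
#'
#' High-curvature points flag where one enclave's finger enters the other;
#' the chord joining the two points flanking an excursion closes it into a
#' polygon (interface arc + chord). The mean invasion width (IW) is the
#' mean transverse width of that polygon, measured parallel to the chord at
#' equally spaced depth stations.
#'
#' @param geometry an [interface_curvature()] result.
#' @param min_area smallest polygon area (um^2) accepted as an invasion.
#' @param stations number of depth stations for the width average.
#' @return list of regions, each with `polygon`, `area`, `depth`, `iw`,
#'   plus `mean_iw` over regions (empty list when the interface carries no
#'   high-curvature points).
#' @export
invasion_regions <- function(geometry, min_area = 1, stations = 7) {
  high <- geometry$high
  samples <- geometry$samples
  if (nrow(high) < 2) {
    return(list(regions = list(), mean_iw = NA_real_))
  }
  idx <- match(high$s, samples$s)
  # candidate excursions: all pairs of high points; keep maximal disjoint
  # intervals by decreasing enclosed area
  cands <- list()
  for (a in seq_len(length(idx) - 1)) {
    for (b in (a + 1):length(idx)) {
      i1 <- idx[a]; i2 <- idx[b]
      arc <- as.matrix(samples[i1:i2, c("x", "y")])
      if (nrow(arc) < 3) next
      area <- abs(polygon_area(arc))
      if (area < min_area) next
      chord <- arc[nrow(arc), ] - arc[1, ]
      clen <- sqrt(sum(chord^2))
      if (clen < 1e-9) next
      # depth of the arc relative to the chord
      u <- chord / clen
      v <- c(-u[2], u[1])
      rel <- sweep(arc, 2, arc[1, ], "-")
      dep <- rel %*% v
      depth <- max(abs(dep))
      if (depth < clen / 4) next # shallow wiggle, not an excursion
      # a single excursion leaves the chord once and returns once: the
      # samples beyond half depth must form one contiguous run (otherwise
      # the pair spans several separate fingers)
      sgn <- sign(dep[which.max(abs(dep))])
      deep <- which(dep * sgn > depth / 2)
      if (length(deep) && any(diff(deep) > 1)) next
      # the whole arc must stay on one side of its chord
      if (min(dep * sgn) < -0.1 * depth) next
      # a genuine finger has a narrow mouth: its arc is much longer than
      # the chord that closes it
      arclen <- polyline_length(arc)
      if (arclen < 2 * clen) next
      cands[[length(cands) + 1]] <- list(
        a = i1, b = i2, area = area, arc = arc, depth = depth,
        u = u, v = v * sgn, clen = clen, ratio = arclen / clen
      )
    }
  }
  if (!length(cands)) return(list(regions = list(), mean_iw = NA_real_))
  ord <- order(-vapply(cands, function(c_) c_$ratio, numeric(1)))
  taken <- matrix(FALSE, 0, 2)
  regions <- list()
  for (k in ord) {
    c_ <- cands[[k]]
    overlap <- FALSE
    if (nrow(taken)) {
      overlap <- any(c_$a < taken[, 2] & c_$b > taken[, 1])
    }
    if (overlap) next
    taken <- rbind(taken, c(c_$a, c_$b))
    # widths parallel to the chord at equally spaced depths
    rel <- sweep(c_$arc, 2, c_$arc[1, ], "-")
    uv <- cbind(rel %*% c_$u, rel %*% c_$v)
    dmax <- max(uv[, 2])
    vks <- dmax * seq_len(stations) / (stations + 1)
    widths <- vapply(vks, function(vk) polygon_section_width(uv, vk), numeric(1))
    regions[[length(regions) + 1]] <- list(
      polygon = c_$arc, area = c_$area, depth = c_$depth,
      iw = mean(widths[widths > 0])
    )
  }
  iws <- vapply(regions, function(r) r$iw, numeric(1))
  list(regions = regions, mean_iw = mean(iws, na.rm = TRUE))
}

#' Per-chain and colony phenotype statistics
#'
#' Per frame and per chain: mean cell length and area, phenotypic noise of
#' the length (variance / mean^2) and division-event counts; a "colony" row
#' aggregates both chains. Per-cell elongation rates are slopes of
#' log-length against time over each track's life (tracks shorter than 3
#' frames are excluded and counted).
#'
#' @param forest a `lineage_forest` from [build_progeny_chains()].
#' @return list with `per_frame` (frame, chain, n, mean_length, mean_area,
#'   noise, divisions), `rates` (chain, rate per track) and
#'   `excluded_tracks`.
#' @export
phenotype_stats <- function(forest) {
  cells <- forest$cells
  cells <- cells[!is.na(cells$chain), ]
  groups <- expand.grid(
    frame = sort(unique(cells$frame)), chain = c(1, 2, 0) # 0 = colony
  )
  rows <- lapply(seq_len(nrow(groups)), function(r) {
    f <- groups$frame[r]
    ch <- groups$chain[r]
    sub <- cells[cells$frame == f & (ch == 0 | cells$chain == ch), ]
    if (!nrow(sub)) return(NULL)
    ndiv <- if (!is.null(forest$divisions) && nrow(forest$divisions)) {
      dv <- forest$divisions
      sum(dv$frame == f & (ch == 0 | dv$chain == ch))
    } else 0L
    data.frame(
      frame = f, chain = ch, n = nrow(sub),
      mean_length = mean(sub$len), mean_area = mean(sub$area),
      noise = stats::var(sub$len) / mean(sub$len)^2,
      divisions = ndiv
    )
  })
  per_frame <- do.call(rbind, rows)

  # elongation rates per track
  rates <- list()
  excluded <- 0L
  for (tr in unique(cells$track)) {
    sub <- cells[cells$track == tr, ]
    if (nrow(sub) < 3) {
      excluded <- excluded + 1L
      next
    }
    fit <- stats::lm(log(sub$len) ~ sub$time)
    rates[[length(rates) + 1]] <- data.frame(
      track = tr, chain = sub$chain[1], rate = unname(stats::coef(fit)[2])
    )
  }
  list(
    per_frame = per_frame,
    rates = if (length(rates)) do.call(rbind, rates) else NULL,
    excluded_tracks = excluded
  )
}
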