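# Nematic orientation-field analysis and topological-defect detection.
#
# Cell orientations are read off the image structure tensor (gradient outer
# product, Gaussian-averaged at about a quarter cell size); local nematic
# order S_R = sqrt(<cos 2 Phi>^2 + <sin 2 Phi>^2) is evaluated on a moving
# grid; low-order local minima are charged by the winding number of the
# director around a small loop, yielding the +-1/2 defects characteristic
# of rod-shaped cell monolayers.

#' Orientation field container
#'
#' @param phi matrix `[x, y]` of director angles in (-pi/2, pi/2].
#' @param valid logical matrix of pixels carrying a meaningful orientation
#'   (cell pixels with non-zero gradient support).
#' @param pixel_size um per pixel.
#' @return an `orientation_field`.
#' @export
orientation_field <- function(phi, valid = NULL, pixel_size = 1) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(phi), ncol(phi))
  stopifnot(identical(dim(phi), dim(valid)))
  structure(
    list(phi = phi, valid = valid, pixel_size = pixel_size),
    class = "orientation_field"
  )
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf(
    "<orientation_field> %d x %d px, %.1f%% valid, %.3g um/px\n",
    nrow(x$phi), ncol(x$phi), 100 * mean(x$valid), x$pixel_size
  ))
  invisible(x)
}

#' Per-pixel orientation by the structure-tensor method
#'
#' The intensity gradient's outer product is averaged under a Gaussian
#' window of sigma = `cell_size`/4, and the orientation at each pixel is
#' the eigenvector of the smaller eigenvalue (along elongated structures),
#' wrapped to (-pi/2, pi/2]. Only pixels inside `mask` with non-negligible
#' gradient energy are valid.
#'
#' @param image numeric matrix `[x, y]` of intensities.
#' @param mask logical matrix restricting validity to cell pixels
#'   (default: everywhere).
#' @param cell_size typical cell length (um).
#' @param pixel_size um per pixel.
#' @param energy_floor validity threshold as a fraction of the maximum
#'   tensor trace.
#' @return an `orientation_field`.
#' @export
structure_tensor_orientation <- function(image, mask = NULL, cell_size = 3,
                                         pixel_size = 0.1,
                                         energy_floor = 1e-4) {
  nx <- nrow(image)
  ny <- ncol(image)
  if (is.null(mask)) mask <- matrix(TRUE, nx, ny)
  gx <- matrix(0, nx, ny)
  gy <- matrix(0, nx, ny)
  gx[2:(nx - 1), ] <- (image[3:nx, ] - image[1:(nx - 2), ]) / 2
  gy[, 2:(ny - 1)] <- (image[, 3:ny] - image[, 1:(ny - 2)]) / 2
  sigma <- cell_size / 4 / pixel_size
  blur <- function(m) {
    imageData_matrix(EBImage::gblur(EBImage::Image(m), sigma = sigma))
  }
  jxx <- blur(gx * gx)
  jyy <- blur(gy * gy)
  jxy <- blur(gx * gy)
  # dominant gradient direction, rotated 90 degrees to lie along structures
  phi <- wrap_nematic(0.5 * atan2(2 * jxy, jxx - jyy) + pi / 2)
  trace <- jxx + jyy
  valid <- mask & (trace > energy_floor * max(trace))
  orientation_field(phi, valid, pixel_size)
}

#' Moving-grid nematic order parameter
#'
#' S_R = sqrt(<cos 2 Phi>_R^2 + <sin 2 Phi>_R^2) over the valid pixels of
#' each square window R; windows advance by `stride` (at most a third of
#' the window, so each region is sampled repeatedly) and windows with too
#' few valid pixels are skipped.
#'
#' @param field an `orientation_field`.
#' @param window window side (um); should hold roughly 3-4 cells.
#' @param stride window step (um), default `window/3`.
#' @param min_valid_frac minimum fraction of valid pixels for a window to
#'   count.
#' @return an `order_grid`: data.frame `grid` (cx, cy um, S, n_valid) plus
#'   the matrix layout used by [defect_candidates()].
#' @export
order_grid <- function(field, window, stride = window / 3,
                       min_valid_frac = 0.1) {
  px <- field$pixel_size
  wpx <- max(2, round(window / px))
  spx <- max(1, round(stride / px))
  nx <- nrow(field$phi)
  ny <- ncol(field$phi)
  c2 <- cos(2 * field$phi)
  s2 <- sin(2 * field$phi)
  c2[!field$valid] <- 0
  s2[!field$valid] <- 0
  v <- field$valid * 1
  xs <- seq(1, max(1, nx - wpx + 1), by = spx)
  ys <- seq(1, max(1, ny - wpx + 1), by = spx)
  Smat <- matrix(NA_real_, length(xs), length(ys))
  Nmat <- matrix(0, length(xs), length(ys))
  # box sums via padded 2-D cumulative sums
  csum <- function(m) {
    C <- matrix(0, nrow(m) + 1, ncol(m) + 1)
    C[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
    C
  }
  Cc <- csum(c2)
  Cs <- csum(s2)
  Cv <- csum(v)
  boxsum <- function(C, i, j) {
    C[i + wpx, j + wpx] - C[i, j + wpx] - C[i + wpx, j] + C[i, j]
  }
  for (a in seq_along(xs)) {
    for (b in seq_along(ys)) {
      i <- xs[a]; j <- ys[b]
      nv <- boxsum(Cv, i, j)
      Nmat[a, b] <- nv
      if (nv >= min_valid_frac * wpx * wpx) {
        Smat[a, b] <- sqrt(boxsum(Cc, i, j)^2 + boxsum(Cs, i, j)^2) / nv
      }
    }
  }
  centers_x <- (xs - 1 + wpx / 2) * px
  centers_y <- (ys - 1 + wpx / 2) * px
  grid <- expand.grid(ix = seq_along(xs), iy = seq_along(ys))
  grid$cx <- centers_x[grid$ix]
  grid$cy <- centers_y[grid$iy]
  grid$S <- Smat[cbind(grid$ix, grid$iy)]
  grid$n_valid <- Nmat[cbind(grid$ix, grid$iy)]
  structure(
    list(grid = grid, S = Smat, window = window, stride = stride,
         pixel_size = px, centers_x = centers_x, centers_y = centers_y),
    class = "order_grid"
  )
}

#' Candidate defect cores from low-order windows
#'
#' Windows with S_R at or below `threshold` whose S is a local minimum of
#' the 3 x 3 grid neighbourhood become candidates; candidates closer than
#' one window size to a lower-S candidate are suppressed.
#'
#' @param grid an [order_grid()].
#' @param threshold order-parameter ceiling (default 0.3).
#' @return data.frame (x, y um, S).
#' @export
defect_candidates <- function(grid, threshold = 0.3) {
  S <- grid$S
  nx <- nrow(S)
  ny <- ncol(S)
  cand <- list()
  for (a in seq_len(nx)) {
    for (b in seq_len(ny)) {
      s0 <- S[a, b]
      if (is.na(s0) || s0 > threshold) next
      nb <- S[max(1, a - 1):min(nx, a + 1), max(1, b - 1):min(ny, b + 1)]
      if (s0 <= min(nb, na.rm = TRUE)) {
        cand[[length(cand) + 1]] <- c(grid$centers_x[a], grid$centers_y[b], s0)
      }
    }
  }
  if (!length(cand)) {
    return(data.frame(x = numeric(0), y = numeric(0), S = numeric(0)))
  }
  cm <- do.call(rbind, cand)
  cm <- cm[order(cm[, 3]), , drop = FALSE]
  keep <- rep(TRUE, nrow(cm))
  for (k in seq_len(nrow(cm))) {
    if (!keep[k]) next
    if (k < nrow(cm)) {
      d <- sqrt((cm[(k + 1):nrow(cm), 1] - cm[k, 1])^2 +
                  (cm[(k + 1):nrow(cm), 2] - cm[k, 2])^2)
      keep[(k + 1):nrow(cm)][d < grid$window] <- FALSE
    }
  }
  cm <- cm[keep, , drop = FALSE]
  data.frame(x = cm[, 1], y = cm[, 2], S = cm[, 3])
}

## counter-clockwise square loop of Chebyshev radius r around (i, j),
## 1-based matrix indices
square_loop <- function(i, j, r) {
  top <- cbind((i - r):(i + r), j - r)
  right <- cbind(i + r, (j - r + 1):(j + r))
  bottom <- cbind((i + r - 1):(i - r), j + r)
  left <- cbind(i - r, (j + r - 1):(j - r + 1))
  rbind(top, right, bottom, left)
}

#' Winding-number topological charge at a point
#'
#' Accumulates director increments around a counter-clockwise square loop,
#' each increment wrapped to (-pi/2, pi/2] (nematic unwrapping); the charge
#' is the total divided by 2 pi, rounded to the nearest half-integer with
#' the raw residual reported. If the loop crosses invalid pixels a larger
#' radius is attempted (up to 3 x) before failing.
#'
#' @param field an `orientation_field`.
#' @param point (x, y) in um.
#' @param loop_radius loop half-width in pixels.
#' @return list(q, raw, residual, radius) or NULL if no valid loop exists.
#' @export
topological_charge <- function(field, point, loop_radius = 3) {
  px <- field$pixel_size
  i0 <- round(point[1] / px) + 1
  j0 <- round(point[2] / px) + 1
  nx <- nrow(field$phi)
  ny <- ncol(field$phi)
  for (r in loop_radius * (1:3)) {
    if (i0 - r < 1 || i0 + r > nx || j0 - r < 1 || j0 + r > ny) next
    loop <- square_loop(i0, j0, r)
    if (!all(field$valid[loop])) next
    ang <- field$phi[loop]
    d <- diff(c(ang, ang[1]))
    d <- (d + pi / 2) %% pi - pi / 2
    raw <- sum(d) / (2 * pi)
    q <- round(raw * 2) / 2
    return(list(q = q, raw = raw, residual = abs(raw - q), radius = r))
  }
  NULL
}

#' Detect and charge topological defects in an orientation field
#'
#' Convenience wrapper: [order_grid()] + [defect_candidates()] +
#' [topological_charge()]; candidates whose winding charge rounds to 0 are
#' discarded.
#'
#' @param field an `orientation_field`.
#' @param window order-parameter window (um).
#' @param threshold candidate S ceiling.
#' @param loop_radius charge loop radius (px); the default of one window
#'   guarantees the loop encloses a core located at window resolution.
#' @return data.frame (x, y, q, S, residual).
#' @export
detect_defects <- function(field, window, threshold = 0.3,
                           loop_radius = NULL) {
  if (is.null(loop_radius)) {
    loop_radius <- max(3, round(window / field$pixel_size))
  }
  # fine stride so a sharp core cannot slip between window centres
  og <- order_grid(field, window, stride = window / 6)
  cand <- defect_candidates(og, threshold)
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    tc <- topological_charge(field, c(cand$x[k], cand$y[k]), loop_radius)
    if (is.null(tc) || tc$q == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      x = cand$x[k], y = cand$y[k], q = tc$q, S = cand$S[k],
      residual = tc$residual
    )
  }
  if (!length(rows)) {
    return(data.frame(x = numeric(0), y = numeric(0), q = numeric(0),
                      S = numeric(0), residual = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Classify defects by location: interface, boundary or bulk
#'
#' CI when within `d_i` of the enclave interface; otherwise CO when within
#' `boundary_margin` of the colony outline; otherwise CB (bulk).
#'
#' @param defects data.frame with x, y (um).
#' @param interface interface polyline (um) or NULL.
#' @param boundary colony outline polygon (um) or NULL.
#' @param d_i interface vicinity distance (um), ~1.5 um.
#' @param boundary_margin outline vicinity distance (um), default `d_i`.
#' @return `defects` with added `class` column (CI/CO/CB) and distances.
#' @export
classify_defects <- function(defects, interface = NULL, boundary = NULL,
                             d_i = 1.5, boundary_margin = d_i) {
  n <- nrow(defects)
  if (n == 0) {
    defects$class <- character(0)
    return(defects)
  }
  pts <- cbind(defects$x, defects$y)
  di <- if (!is.null(interface)) point_polyline_dist(pts, interface) else
    rep(Inf, n)
  db <- if (!is.null(boundary)) {
    point_polyline_dist(pts, rbind(boundary, boundary[1, ]))
  } else rep(Inf, n)
  defects$dist_interface <- di
  defects$dist_boundary <- db
  defects$class <- ifelse(di <= d_i, "CI",
                          ifelse(db <= boundary_margin, "CO", "CB"))
  defects
}

#' Link defects across frames into tracks
#'
#' Greedy nearest-neighbour linking of same-charge defects between
#' consecutive frames within `max_step`; reports per-track positions and
#' cumulative displacement.
#'
#' @param defect_frames list of per-frame defect data.frames (x, y, q).
#' @param max_step largest allowed frame-to-frame displacement (um).
#' @return data.frame (track, frame, x, y, q, step) plus a `summary`
#'   attribute (track, q, n_frames, total_displacement).
#' @export
track_defects <- function(defect_frames, max_step = 2) {
  stopifnot(length(defect_frames) >= 2)
  next_track <- 1L
  rows <- list()
  prev_tracks <- integer(0)
  prev_df <- NULL
  for (f in seq_along(defect_frames)) {
    df <- defect_frames[[f]]
    tr <- integer(nrow(df))
    if (!is.null(prev_df) && nrow(prev_df) && nrow(df)) {
      D <- sqrt(outer(prev_df$x, df$x, "-")^2 + outer(prev_df$y, df$y, "-")^2)
      D[outer(prev_df$q, df$q, "!=")] <- Inf
      D[D > max_step] <- Inf
      while (any(is.finite(D))) {
        k <- arrayInd(which.min(D), dim(D))
        tr[k[2]] <- prev_tracks[k[1]]
        D[k[1], ] <- Inf
        D[, k[2]] <- Inf
      }
    }
    for (r in seq_len(nrow(df))) {
      if (tr[r] == 0L) {
        tr[r] <- next_track
        next_track <- next_track + 1L
      }
      rows[[length(rows) + 1]] <- data.frame(
        track = tr[r], frame = f, x = df$x[r], y = df$y[r], q = df$q[r]
      )
    }
    prev_df <- df
    prev_tracks <- tr
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$track, out$frame), ]
  out$step <- 0
  for (tr in unique(out$track)) {
    sel <- which(out$track == tr)
    if (length(sel) > 1) {
      out$step[sel[-1]] <- sqrt(diff(out$x[sel])^2 + diff(out$y[sel])^2)
    }
  }
  summ <- do.call(rbind, lapply(unique(out$track), function(tr) {
    sel <- out[out$track == tr, ]
    data.frame(
      track = tr, q = sel$q[1], n_frames = nrow(sel),
      total_displacement = sum(sel$step)
    )
  }))
  attr(out, "summary") <- summ
  out
}
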