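# Label-free lineage tracking of segmented time-lapse masks.
#
# Stage 1 matches cells across consecutive frames when a centroid is the
# mutually unique neighbour within a cutoff (~0.75 um, about one cell
# width). Stage 2 detects divisions: each unmatched mother predicts two
# "dummy" centroids on its axis at +/- l/4 (the daughter centroids of a
# symmetric end-to-end split) and is matched when each dummy claims a
# distinct leftover centroid within the cutoff. Stage 3 rescues fast
# movers (typically boundary cells) whose centroid and both poles moved
# consistently within a larger cutoff. Whatever remains is reported as
# unresolved, never dropped.

#' Tracker configuration
#'
#' @param centroid_cutoff stage-1 matching cutoff d_c (um); ~0.75 um, of
#'   the order of a cell width.
#' @param pole_cutoff stage-3 rescue cutoff (um); default 2 * d_c.
#' @param dummy_offset_fraction dummy centroids sit at +/- this fraction of
#'   the cell length from the centroid (1/4 predicts a symmetric split).
#' @param max_daughter_fraction a candidate daughter must be shorter than
#'   this fraction of the mother's length (division halves the length, so
#'   true daughters sit near 0.5; the ceiling rejects grown neighbours
#'   masquerading as daughters).
#' @return a `tracking_config`.
#' @export
tracking_config <- function(centroid_cutoff = 0.75,
                            pole_cutoff = 2 * centroid_cutoff,
                            dummy_offset_fraction = 0.25,
                            max_daughter_fraction = 0.8) {
  stopifnot(centroid_cutoff > 0, pole_cutoff > 0, dummy_offset_fraction > 0,
            max_daughter_fraction > 0.5)
  structure(
    list(centroid_cutoff = centroid_cutoff, pole_cutoff = pole_cutoff,
         dummy_offset_fraction = dummy_offset_fraction,
         max_daughter_fraction = max_daughter_fraction),
    class = "tracking_config"
  )
}

#' Extract per-cell features from a labelled mask
#'
#' For every label: centroid (arithmetic mean of its pixels), area, the
#' orientation of the pixel-covariance major axis, the two poles (extreme
#' contour points along the major axis), length l_c (pole-to-pole) and
#' width from w_c = 4 a_c / (pi l_c), cross-checked against the
#' moment-equivalent ellipse minor axis. Labels touching the image border
#' are flagged; one-pixel labels are rejected with a warning.
#'
#' @param mask integer label matrix `[x, y]` (background 0) or a
#'   `colony_frame`.
#' @param pixel_size um per pixel (taken from the frame if given one).
#' @return a `cell_features` object: `cells` data.frame (label, x, y, area,
#'   len, width, width_ellipse, angle, border, pole coordinates) and
#'   `contours` (list of n x 2 um polygons).
#' @export
extract_features <- function(mask, pixel_size = NULL) {
  origin <- c(0, 0)
  if (inherits(mask, "colony_frame")) {
    pixel_size <- mask$pixel_size
    origin <- mask$origin
    mask <- mask$mask
  }
  stopifnot(!is.null(pixel_size))
  labs <- sort(unique(as.vector(mask)))
  labs <- labs[labs > 0]
  contours_px <- mask_contours(mask)
  rows <- list()
  contours <- list()
  dropped <- 0L
  for (lab in labs) {
    idx <- which(mask == lab, arr.ind = TRUE)
    if (nrow(idx) <= 1) {
      dropped <- dropped + 1L
      next
    }
    xs <- idx[, 1] - 1
    ys <- idx[, 2] - 1
    cx <- mean(xs)
    cy <- mean(ys)
    border <- any(idx[, 1] == 1 | idx[, 1] == nrow(mask) |
                    idx[, 2] == 1 | idx[, 2] == ncol(mask))
    cxx <- stats::var(xs)
    cyy <- stats::var(ys)
    cxy <- stats::cov(xs, ys)
    angle <- wrap_nematic(0.5 * atan2(2 * cxy, cxx - cyy))
    ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE)$values
    minor <- 4 * sqrt(max(ev[2], 0)) # moment-ellipse minor axis (px)
    oc <- contours_px[[as.character(lab)]]
    if (is.null(oc)) {
      dropped <- dropped + 1L
      next
    }
    proj <- (oc[, 1] - cx) * cos(angle) + (oc[, 2] - cy) * sin(angle)
    p1 <- oc[which.min(proj), ]
    p2 <- oc[which.max(proj), ]
    len <- sqrt(sum((p1 - p2)^2)) * pixel_size
    area <- nrow(idx) * pixel_size^2
    rows[[length(rows) + 1]] <- data.frame(
      label = lab,
      x = cx * pixel_size + origin[1], y = cy * pixel_size + origin[2],
      area = area, len = len, width = 4 * area / (pi * len),
      width_ellipse = minor * pixel_size, angle = angle, border = border,
      pole1_x = p1[1] * pixel_size + origin[1],
      pole1_y = p1[2] * pixel_size + origin[2],
      pole2_x = p2[1] * pixel_size + origin[1],
      pole2_y = p2[2] * pixel_size + origin[2]
    )
    cpoly <- oc * pixel_size
    cpoly[, 1] <- cpoly[, 1] + origin[1]
    cpoly[, 2] <- cpoly[, 2] + origin[2]
    contours[[length(contours) + 1]] <- cpoly
  }
  if (dropped > 0) {
    warning(sprintf("%d label(s) rejected (single-pixel or no contour)", dropped))
  }
  structure(
    list(cells = do.call(rbind, rows), contours = contours,
         pixel_size = pixel_size),
    class = "cell_features"
  )
}

#' Match cells between consecutive frames by mutual centroid uniqueness
#'
#' A pair (i in frame t, j in frame t+1) is assigned iff j is the only
#' next-frame centroid within `centroid_cutoff` of i and i is the only
#' previous-frame centroid within the cutoff of j. Ambiguous or distant
#' cells are left for the later stages.
#'
#' @param prev,nxt `cell_features` of frames t and t+1.
#' @param cfg a [tracking_config()].
#' @return list(assignment = data.frame(prev, nxt), unmatched_prev,
#'   unassigned_next) of row indices.
#' @export
match_frames <- function(prev, nxt, cfg = tracking_config()) {
  p <- prev$cells
  q <- nxt$cells
  D <- sqrt(outer(p$x, q$x, "-")^2 + outer(p$y, q$y, "-")^2)
  within <- D < cfg$centroid_cutoff
  rc <- rowSums(within)
  cc <- colSums(within)
  hits <- which(within, arr.ind = TRUE)
  ok <- rc[hits[, 1]] == 1 & cc[hits[, 2]] == 1
  assignment <- data.frame(prev = hits[ok, 1], nxt = hits[ok, 2])
  list(
    assignment = assignment,
    unmatched_prev = setdiff(seq_len(nrow(p)), assignment$prev),
    unassigned_next = setdiff(seq_len(nrow(q)), assignment$nxt)
  )
}

#' Predicted daughter centroids of a dividing cell
#'
#' Two points on the major axis at +/- `dummy_offset_fraction * l_c` from
#' the centroid -- exactly the daughter centroids of a symmetric
#' end-to-end split.
#'
#' @param cell one row of a `cell_features$cells` table.
#' @param cfg a [tracking_config()].
#' @return 2 x 2 matrix of (x, y) in um.
#' @export
dummy_centroids <- function(cell, cfg = tracking_config()) {
  off <- cfg$dummy_offset_fraction * cell$len
  u <- c(cos(cell$angle), sin(cell$angle))
  rbind(
    c(cell$x, cell$y) - off * u,
    c(cell$x, cell$y) + off * u
  )
}

#' Detect division events via dummy centroids
#'
#' An unmatched mother is recognised as dividing when each of its two dummy
#' centroids has a distinct unassigned next-frame centroid within the
#' cutoff. Competing interpretations are resolved globally by ascending
#' total dummy-to-daughter distance. A mother with only one matching dummy
#' is deferred to the pole-rescue stage.
#'
#' @param prev,nxt `cell_features` of frames t and t+1.
#' @param unmatched_prev,unassigned_next leftover indices from
#'   [match_frames()].
#' @param cfg a [tracking_config()].
#' @return list(events = data.frame(mother, daughter1, daughter2),
#'   unmatched_prev, unassigned_next) after removing resolved cells.
#' @export
detect_divisions <- function(prev, nxt, unmatched_prev, unassigned_next,
                             cfg = tracking_config()) {
  q <- nxt$cells
  cands <- list()
  for (i in unmatched_prev) {
    dum <- dummy_centroids(prev$cells[i, ], cfg)
    short <- q$len[unassigned_next] <
      cfg$max_daughter_fraction * prev$cells$len[i]
    d1 <- sqrt((q$x[unassigned_next] - dum[1, 1])^2 +
                 (q$y[unassigned_next] - dum[1, 2])^2)
    d2 <- sqrt((q$x[unassigned_next] - dum[2, 1])^2 +
                 (q$y[unassigned_next] - dum[2, 2])^2)
    j1s <- unassigned_next[d1 < cfg$centroid_cutoff & short]
    j2s <- unassigned_next[d2 < cfg$centroid_cutoff & short]
    if (!length(j1s) || !length(j2s)) next
    for (j1 in j1s) {
      for (j2 in j2s) {
        if (j1 == j2) next
        cost <- d1[match(j1, unassigned_next)] + d2[match(j2, unassigned_next)]
        cands[[length(cands) + 1]] <- c(i, j1, j2, cost)
      }
    }
  }
  events <- data.frame(mother = integer(0), daughter1 = integer(0),
                       daughter2 = integer(0))
  if (length(cands)) {
    cm <- do.call(rbind, cands)
    cm <- cm[order(cm[, 4]), , drop = FALSE]
    used_m <- integer(0)
    used_d <- integer(0)
    for (r in seq_len(nrow(cm))) {
      i <- cm[r, 1]; j1 <- cm[r, 2]; j2 <- cm[r, 3]
      if (i %in% used_m || j1 %in% used_d || j2 %in% used_d) next
      events <- rbind(events, data.frame(
        mother = i, daughter1 = j1, daughter2 = j2
      ))
      used_m <- c(used_m, i)
      used_d <- c(used_d, j1, j2)
    }
  }
  list(
    events = events,
    unmatched_prev = setdiff(unmatched_prev, events$mother),
    unassigned_next = setdiff(unassigned_next,
                              c(events$daughter1, events$daughter2))
  )
}

#' Rescue moved cells by pole displacement
#'
#' Cells that slid rigidly (often at the colony boundary) are matched when
#' the centroid displacement and both pole displacements (best pole
#' pairing) all fall below `pole_cutoff`. Pairs are accepted greedily by
#' total displacement; leftovers are reported unresolved.
#'
#' @param prev,nxt `cell_features` of frames t and t+1.
#' @param unmatched_prev,unassigned_next leftovers after division
#'   detection.
#' @param cfg a [tracking_config()].
#' @return list(assignment, unmatched_prev, unassigned_next).
#' @export
match_by_poles <- function(prev, nxt, unmatched_prev, unassigned_next,
                           cfg = tracking_config()) {
  p <- prev$cells
  q <- nxt$cells
  cands <- list()
  for (i in unmatched_prev) {
    for (j in unassigned_next) {
      dc <- sqrt((p$x[i] - q$x[j])^2 + (p$y[i] - q$y[j])^2)
      if (dc >= cfg$pole_cutoff) next
      pp <- rbind(c(p$pole1_x[i], p$pole1_y[i]), c(p$pole2_x[i], p$pole2_y[i]))
      qq <- rbind(c(q$pole1_x[j], q$pole1_y[j]), c(q$pole2_x[j], q$pole2_y[j]))
      pair1 <- c(sqrt(sum((pp[1, ] - qq[1, ])^2)), sqrt(sum((pp[2, ] - qq[2, ])^2)))
      pair2 <- c(sqrt(sum((pp[1, ] - qq[2, ])^2)), sqrt(sum((pp[2, ] - qq[1, ])^2)))
      pd <- if (max(pair1) <= max(pair2)) pair1 else pair2
      if (any(pd >= cfg$pole_cutoff)) next
      cands[[length(cands) + 1]] <- c(i, j, dc + sum(pd))
    }
  }
  assignment <- data.frame(prev = integer(0), nxt = integer(0))
  if (length(cands)) {
    cm <- do.call(rbind, cands)
    cm <- cm[order(cm[, 3]), , drop = FALSE]
    for (r in seq_len(nrow(cm))) {
      if (cm[r, 1] %in% assignment$prev || cm[r, 2] %in% assignment$nxt) next
      assignment <- rbind(assignment,
                          data.frame(prev = cm[r, 1], nxt = cm[r, 2]))
    }
  }
  list(
    assignment = assignment,
    unmatched_prev = setdiff(unmatched_prev, assignment$prev),
    unassigned_next = setdiff(unassigned_next, assignment$nxt)
  )
}

## Drift-compensated division rescue (automated "manual correction").
##
## A division missed by the dummy stage leaves a tell-tale pattern: an
## unresolved new cell j plus either a mother that got stage-1 matched to
## the other daughter (false continuation) or a lost mother with both
## daughters unresolved. The whole neighbourhood drifts together near the
## colony rim, so the test removes the common drift first: with candidate
## daughters q1, q2 of mother i, the drift v = (q1 + q2)/2 - centroid(i)
## must stay below the pole cutoff and the drift-corrected daughters must
## each sit within d_c of a distinct dummy centroid of i; both daughters
## must also be substantially shorter than the mother.
rescue_divisions <- function(prev, nxt, assignment, events, unassigned_next,
                             unmatched_prev, cfg) {
  q <- nxt$cells
  cands <- list()
  consider <- function(i, j1, j2, revoked) {
    cell <- prev$cells[i, ]
    if (q$len[j1] > cfg$max_daughter_fraction * cell$len ||
        q$len[j2] > cfg$max_daughter_fraction * cell$len) return()
    vx <- (q$x[j1] + q$x[j2]) / 2 - cell$x
    vy <- (q$y[j1] + q$y[j2]) / 2 - cell$y
    if (sqrt(vx^2 + vy^2) >= cfg$pole_cutoff) return()
    dum <- dummy_centroids(cell, cfg)
    d <- function(j, k) {
      sqrt((q$x[j] - vx - dum[k, 1])^2 + (q$y[j] - vy - dum[k, 2])^2)
    }
    pair1 <- c(d(j1, 1), d(j2, 2))
    pair2 <- c(d(j1, 2), d(j2, 1))
    dd <- if (max(pair1) <= max(pair2)) pair1 else pair2
    if (any(dd >= cfg$centroid_cutoff)) return()
    cands[[length(cands) + 1]] <<- data.frame(
      mother = i, daughter1 = j1, daughter2 = j2, cost = sum(dd),
      revoked = revoked
    )
  }
  for (j in unassigned_next) {
    # false continuation: mother currently matched to the sister
    for (r in seq_len(nrow(assignment))) {
      consider(assignment$prev[r], assignment$nxt[r], j, revoked = r)
    }
    # lost mother: both daughters unresolved
    for (j2 in setdiff(unassigned_next, j)) {
      if (j2 <= j) next
      for (i in unmatched_prev) consider(i, j, j2, revoked = 0L)
    }
  }
  extra <- data.frame(mother = integer(0), daughter1 = integer(0),
                      daughter2 = integer(0))
  revoke <- integer(0)
  if (length(cands)) {
    cm <- do.call(rbind, cands)
    cm <- cm[order(cm$cost), , drop = FALSE]
    used_m <- events$mother
    used_d <- c(events$daughter1, events$daughter2)
    for (r in seq_len(nrow(cm))) {
      i <- cm$mother[r]
      ds <- c(cm$daughter1[r], cm$daughter2[r])
      if (i %in% used_m || any(ds %in% used_d)) next
      if (cm$revoked[r] > 0 && cm$revoked[r] %in% revoke) next
      extra <- rbind(extra, data.frame(
        mother = i, daughter1 = ds[1], daughter2 = ds[2]
      ))
      if (cm$revoked[r] > 0) revoke <- c(revoke, cm$revoked[r])
      used_m <- c(used_m, i)
      used_d <- c(used_d, ds)
    }
  }
  list(events = extra, revoke = revoke)
}

#' Track progeny chains through a colony movie
#'
#' Runs the full pipeline (centroid matching, dummy-centroid division
#' detection, pole rescue) over every consecutive frame pair. Frame 1 must
#' contain exactly the founder's two daughter cells (t = 0 is their
#' birth); they seed chains 1 and 2 and every later cell inherits its
#' chain through the lineage. Unresolved cells start chainless tracks and
#' are listed, never dropped.
#'
#' @param frames list of `colony_frame`s (or of `cell_features`).
#' @param cfg a [tracking_config()].
#' @return a `lineage_forest`: `cells` (frame, label, track, parent,
#'   chain, x, y, len, width, angle, area, time), `divisions` (frame,
#'   mother, daughters, chain), `unresolved`.
#' @export
build_progeny_chains <- function(frames, cfg = tracking_config()) {
  feats <- lapply(frames, function(f) {
    if (inherits(f, "cell_features")) f else extract_features(f)
  })
  times <- vapply(seq_along(frames), function(k) {
    t <- if (inherits(frames[[k]], "colony_frame")) frames[[k]]$time else NA_real_
    if (is.na(t)) (k - 1) else t
  }, numeric(1))
  if (nrow(feats[[1]]$cells) != 2) {
    stop(
      "frame 1 must hold exactly the founder's two daughter cells ",
      "(t = 0 is their birth); got ", nrow(feats[[1]]$cells), " cells"
    )
  }

  n_frames <- length(feats)
  track_of <- vector("list", n_frames) # per frame: track id per cell row
  chain_of_track <- integer(0)
  parent_of_track <- integer(0)
  next_track <- 1L
  new_track <- function(chain, parent) {
    id <- next_track
    next_track <<- next_track + 1L
    chain_of_track[id] <<- chain
    parent_of_track[id] <<- parent
    id
  }
  track_of[[1]] <- c(new_track(1L, 0L), new_track(2L, 0L))

  divisions <- list()
  unresolved <- list()
  for (f in seq_len(n_frames - 1)) {
    prev <- feats[[f]]
    nxt <- feats[[f + 1]]
    m1 <- match_frames(prev, nxt, cfg)
    m2 <- detect_divisions(prev, nxt, m1$unmatched_prev, m1$unassigned_next, cfg)
    m3 <- match_by_poles(prev, nxt, m2$unmatched_prev, m2$unassigned_next, cfg)

    assign_all <- rbind(m1$assignment, m3$assignment)
    events <- m2$events
    lost_prev <- m3$unmatched_prev
    new_next <- m3$unassigned_next
    if (length(new_next)) {
      r4 <- rescue_divisions(prev, nxt, assign_all, events, new_next,
                             lost_prev, cfg)
      if (nrow(r4$events)) {
        if (length(r4$revoke)) {
          assign_all <- assign_all[-r4$revoke, , drop = FALSE]
        }
        events <- rbind(events, r4$events)
        lost_prev <- setdiff(lost_prev, r4$events$mother)
        new_next <- setdiff(new_next,
                            c(r4$events$daughter1, r4$events$daughter2))
      }
    }

    tr_next <- integer(nrow(nxt$cells))
    for (r in seq_len(nrow(assign_all))) {
      tr_next[assign_all$nxt[r]] <- track_of[[f]][assign_all$prev[r]]
    }
    for (r in seq_len(nrow(events))) {
      mother_tr <- track_of[[f]][events$mother[r]]
      ch <- chain_of_track[mother_tr]
      t1 <- new_track(ch, mother_tr)
      t2 <- new_track(ch, mother_tr)
      tr_next[events$daughter1[r]] <- t1
      tr_next[events$daughter2[r]] <- t2
      divisions[[length(divisions) + 1]] <- data.frame(
        frame = f + 1, mother = mother_tr, daughter1 = t1, daughter2 = t2,
        chain = ch
      )
    }
    # leftovers on both sides
    for (i in lost_prev) {
      unresolved[[length(unresolved) + 1]] <- data.frame(
        frame = f, label = prev$cells$label[i], side = "lost"
      )
    }
    for (j in new_next) {
      tr_next[j] <- new_track(NA_integer_, 0L)
      unresolved[[length(unresolved) + 1]] <- data.frame(
        frame = f + 1, label = nxt$cells$label[j], side = "new"
      )
    }
    track_of[[f + 1]] <- tr_next
  }

  cells <- do.call(rbind, lapply(seq_len(n_frames), function(f) {
    cf <- feats[[f]]$cells
    tr <- track_of[[f]]
    data.frame(
      frame = f, label = cf$label, track = tr,
      parent = parent_of_track[tr], chain = chain_of_track[tr],
      x = cf$x, y = cf$y, len = cf$len, width = cf$width,
      angle = cf$angle, area = cf$area, time = times[f]
    )
  }))
  structure(
    list(
      cells = cells,
      divisions = if (length(divisions)) do.call(rbind, divisions) else
        data.frame(frame = integer(0), mother = integer(0),
                   daughter1 = integer(0), daughter2 = integer(0),
                   chain = integer(0)),
      unresolved = if (length(unresolved)) do.call(rbind, unresolved) else
        data.frame(frame = integer(0), label = integer(0),
                   side = character(0)),
      config = cfg, features = feats
    ),
    class = "lineage_forest"
  )
}

#' @export
print.lineage_forest <- function(x, ...) {
  nf <- max(x$cells$frame)
  cat(sprintf(
    "<lineage_forest> %d frames, %d tracks, %d divisions, %d unresolved\n",
    nf, length(unique(x$cells$track)), nrow(x$divisions), nrow(x$unresolved)
  ))
  invisible(x)
}

#' Colony outer boundary from a labelled mask
#'
#' The union of all labels is dilated, hole-filled and eroded back; the
#' contour of each resulting component is returned as a smoothed polygon
#' with perimeter and area (multiple disjoint colonies are flagged).
#'
#' @param frame a `colony_frame` or a label matrix.
#' @param pixel_size um per pixel (from the frame if given one).
#' @param dilation_radius morphological radius in um (default ~half a cell
#'   width).
#' @return list(polygon, perimeter, area, n_components); the filled binary
#'   colony region is attached as attribute "filled".
#' @export
colony_boundary <- function(frame, pixel_size = NULL, dilation_radius = 0.5) {
  origin <- c(0, 0)
  if (inherits(frame, "colony_frame")) {
    pixel_size <- frame$pixel_size
    origin <- frame$origin
    mask <- frame$mask
  } else {
    mask <- frame
  }
  stopifnot(!is.null(pixel_size))
  bin <- mask > 0
  rpx <- max(1, round(dilation_radius / pixel_size))
  brush <- disc_brush(rpx)
  img <- EBImage::Image(bin * 1)
  closed <- EBImage::erode(EBImage::fillHull(EBImage::dilate(img, brush)), brush)
  filled <- imageData_matrix(closed) > 0
  lab <- EBImage::bwlabel(EBImage::Image(filled * 1))
  labm <- imageData_matrix(lab)
  ncomp <- max(labm)
  if (ncomp > 1) {
    warning(sprintf("%d disjoint colonies found; returning the largest", ncomp))
  }
  sz <- tabulate(labm[labm > 0])
  main <- which.max(sz)
  region <- labm == main
  oc <- mask_contours(matrix(as.integer(region), nrow(region)))[[1]]
  poly <- smooth_closed_polyline(oc, 7) * pixel_size
  poly[, 1] <- poly[, 1] + origin[1]
  poly[, 2] <- poly[, 2] + origin[2]
  out <- list(
    polygon = poly,
    perimeter = polyline_length(poly, closed = TRUE),
    area = abs(polygon_area(poly)),
    n_components = ncomp
  )
  attr(out, "filled") <- region
  out
}
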