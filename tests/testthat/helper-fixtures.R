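# Shared fixtures: all built in code at test time.

# binary/labelled disc mask; split = two half-disc labels (chains 1/2)
make_disc_mask <- function(r = 10, px = 0.1, split = FALSE, pad = 10) {
  n <- round(2 * r / px) + 2 * pad + 1
  ctr <- (n - 1) / 2
  xg <- matrix(rep(0:(n - 1), n), n, n)
  yg <- matrix(rep(0:(n - 1), each = n), n, n)
  inside <- (xg - ctr)^2 + (yg - ctr)^2 <= (r / px)^2
  mask <- matrix(0L, n, n)
  if (split) {
    mask[inside & xg < ctr] <- 1L
    mask[inside & xg >= ctr] <- 2L
  } else {
    mask[inside] <- 1L
  }
  mask
}

# filled ellipse mask with semi-axes a, b (um) rotated by ang
make_ellipse_mask <- function(a, b, ang, px = 0.05, pad = 10) {
  n <- round(2 * a / px) + 2 * pad + 1
  ctr <- (n - 1) / 2
  xg <- (matrix(rep(0:(n - 1), n), n, n) - ctr) * px
  yg <- (matrix(rep(0:(n - 1), each = n), n, n) - ctr) * px
  u <- xg * cos(ang) + yg * sin(ang)
  v <- -xg * sin(ang) + yg * cos(ang)
  mask <- matrix(0L, n, n)
  mask[(u / a)^2 + (v / b)^2 <= 1] <- 1L
  mask
}

# spherocylinder outline polygon (um) for contact-graph fixtures
rod_contour <- function(cx, cy, len, w, ang = 0, n_arc = 12) {
  u <- c(cos(ang), sin(ang))
  v <- c(-sin(ang), cos(ang))
  hl <- len / 2 - w / 2
  t1 <- seq(-pi / 2, pi / 2, length.out = n_arc)
  t2 <- seq(pi / 2, 3 * pi / 2, length.out = n_arc)
  local_pts <- rbind(
    cbind(hl + w / 2 * cos(t1), w / 2 * sin(t1)),
    cbind(-hl + w / 2 * cos(t2), w / 2 * sin(t2))
  )
  t(apply(local_pts, 1, function(p) c(cx, cy) + p[1] * u + p[2] * v))
}

# minimal cell_features-like object from rod descriptions
rod_features <- function(df) {
  contours <- lapply(seq_len(nrow(df)), function(k) {
    rod_contour(df$x[k], df$y[k], df$len[k], df$w[k], df$ang[k])
  })
  list(cells = df, contours = contours)
}

# analytic half-disc polygon (left or right), many vertices
half_disc_polygon <- function(r, side = c("left", "right"), n = 720) {
  side <- match.arg(side)
  th <- if (side == "left") seq(pi / 2, 3 * pi / 2, length.out = n) else
    seq(-pi / 2, pi / 2, length.out = n)
  arc <- cbind(r * cos(th), r * sin(th))
  edge_y <- seq(arc[n, 2], arc[1, 2], length.out = n)[-c(1, n)]
  rbind(arc, cbind(0, edge_y))
}

# straight interface with rectangular fingers carved in
finger_interface <- function(widths = 2, depths = 6, step = 0.05,
                             x_start = 9, gap = 4, total = NULL) {
  if (is.null(total)) total <- x_start + sum(widths) +
      gap * length(widths) + 9
  pts <- cbind(seq(0, x_start, by = step), 0)
  x0 <- x_start
  for (k in seq_along(widths)) {
    w <- widths[k]
    d <- depths[k]
    down <- cbind(x0, seq(step, d, by = step))
    across <- cbind(seq(x0 + step, x0 + w - step, by = step), d)
    up <- cbind(x0 + w, seq(d - step, 0, by = -step))
    pts <- rbind(pts, down, across, up)
    x1 <- min(x0 + w + gap, total)
    pts <- rbind(pts, cbind(seq(x0 + w + step, x1, by = step), 0))
    x0 <- x1
  }
  pts
}

# chain accuracy of a lineage forest against generator truth (1 = perfect);
# also returns division/unresolved counts
score_tracking <- function(forest, run) {
  m <- merge(forest$cells, run$truth, by = c("frame", "label"),
             suffixes = c("", ".true"))
  map <- m$chain.true[m$frame == 1][order(m$chain[m$frame == 1])]
  acc <- mean(m$chain == ifelse(m$chain.true == map[1], 1, 2), na.rm = TRUE)
  key <- paste(forest$cells$frame, forest$cells$label)
  truth_track <- m$track[match(key, paste(m$frame, m$label))]
  pure <- all(tapply(truth_track, forest$cells$track,
                     function(v) length(unique(v))) == 1)
  list(
    chain_accuracy = acc,
    n_chain_na = sum(is.na(m$chain)),
    track_pure = pure,
    detected = nrow(forest$divisions),
    true_divisions = nrow(run$divisions),
    unresolved = nrow(forest$unresolved)
  )
}
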