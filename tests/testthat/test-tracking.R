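# Label-free tracker: feature extraction, the three matching stages, the
# colony boundary, and the end-to-end lineage oracle on generator output.

test_that("features of a rasterised ellipse recover axes and orientation", {
  ang <- 30 * pi / 180
  px <- 0.05
  mask <- make_ellipse_mask(2, 0.5, ang, px = px)
  ft <- extract_features(mask, px)
  expect_equal(nrow(ft$cells), 1)
  expect_equal(ft$cells$len, 4, tolerance = 0.05)
  expect_equal(ft$cells$width, 1, tolerance = 0.05)
  expect_equal(ft$cells$angle, ang, tolerance = 0.05)
  expect_equal(ft$cells$width, ft$cells$width_ellipse, tolerance = 0.1)
  # circle: the width formula degenerates to the diameter
  circ <- make_disc_mask(r = 1, px = px)
  fc <- extract_features(circ, px)
  expect_equal(fc$cells$len, 2, tolerance = 0.06)
  expect_equal(fc$cells$width, 2, tolerance = 0.06)
  # rotating the mask by 90 degrees shifts the orientation by pi/2 mod pi
  rot <- t(mask)[ncol(mask):1, ] # (x, y) -> (y, -x)
  fr <- extract_features(rot, px)
  shift <- wrap_nematic(fr$cells$angle - ft$cells$angle)
  expect_equal(abs(shift), pi / 2, tolerance = 0.05)
})

test_that("centroid matching is mutually unique within the cutoff", {
  mk <- function(dx = 0, dy = 0, drop_shift = NULL) {
    df <- data.frame(
      x = c(0, 3, 6) + dx, y = c(0, 0.5, 0.2) + dy,
      len = 3, label = 1:3
    )
    if (!is.null(drop_shift)) df$x[3] <- df$x[3] + drop_shift
    list(cells = df)
  }
  # identical frames: identity assignment
  m <- match_frames(mk(), mk())
  expect_equal(m$assignment$prev, m$assignment$nxt)
  expect_length(m$unmatched_prev, 0)
  # rigid 0.5 um translation stays under the 0.75 um cutoff
  m2 <- match_frames(mk(), mk(dx = 0.3, dy = 0.4))
  expect_equal(nrow(m2$assignment), 3)
  # a single 1.2 um mover is left unassigned, the rest still match
  m3 <- match_frames(mk(), mk(drop_shift = 1.2))
  expect_equal(nrow(m3$assignment), 2)
  expect_equal(m3$unmatched_prev, 3)
  expect_equal(m3$unassigned_next, 3)
})

test_that("dummy centroids sit at a quarter length along the axis", {
  cell <- data.frame(x = 0, y = 0, len = 4, angle = 0)
  dum <- dummy_centroids(cell)
  expect_equal(dum, rbind(c(-1, 0), c(1, 0)))
  # degenerate length collapses both dummies onto the centroid
  tiny <- dummy_centroids(data.frame(x = 2, y = 3, len = 1e-12, angle = 1))
  expect_equal(tiny[1, ], c(2, 3), tolerance = 1e-9)
  expect_equal(tiny[2, ], c(2, 3), tolerance = 1e-9)
})

test_that("division detection pairs distinct daughters to the two dummies", {
  prev <- list(cells = data.frame(
    x = 0, y = 0, len = 4, angle = 0, label = 1
  ))
  nxt <- list(cells = data.frame(
    x = c(-1.02, 1.03), y = c(0.05, -0.04), len = c(2, 2),
    angle = c(0, 0), label = 1:2
  ))
  d <- detect_divisions(prev, nxt, 1, 1:2)
  expect_equal(nrow(d$events), 1)
  expect_setequal(c(d$events$daughter1, d$events$daughter2), 1:2)
  expect_length(d$unassigned_next, 0)
  # nothing unmatched -> no events
  d0 <- detect_divisions(prev, nxt, integer(0), 1:2)
  expect_equal(nrow(d0$events), 0)
  # daughters as long as the mother are not a plausible division
  grown <- list(cells = data.frame(
    x = c(-1.02, 1.03), y = c(0.05, -0.04), len = c(4, 4),
    angle = c(0, 0), label = 1:2
  ))
  d1 <- detect_divisions(prev, grown, 1, 1:2)
  expect_equal(nrow(d1$events), 0)
})

test_that("pole rescue accepts rigid slides and rejects rotations", {
  rod <- function(x, y, ang, len = 3) {
    u <- c(cos(ang), sin(ang))
    data.frame(
      x = x, y = y, len = len, angle = ang, label = 1,
      pole1_x = x - len / 2 * u[1], pole1_y = y - len / 2 * u[2],
      pole2_x = x + len / 2 * u[1], pole2_y = y + len / 2 * u[2]
    )
  }
  prev <- list(cells = rod(0, 0, 0))
  slid <- list(cells = rod(1.2, 0, 0))
  m <- match_by_poles(prev, slid, 1, 1)
  expect_equal(nrow(m$assignment), 1)
  # rotation in place: centroid fine, poles move ~2.1 um -> unresolved
  spun <- list(cells = rod(0, 0, pi / 2))
  m2 <- match_by_poles(prev, spun, 1, 1)
  expect_equal(nrow(m2$assignment), 0)
  expect_equal(m2$unmatched_prev, 1)
  # empty inputs
  m3 <- match_by_poles(prev, slid, integer(0), integer(0))
  expect_equal(nrow(m3$assignment), 0)
})

test_that("colony boundary recovers disc geometry and merges touching discs", {
  px <- 0.1
  r <- 10
  mask <- make_disc_mask(r = r, px = px)
  cb <- colony_boundary(mask, px)
  expect_equal(cb$perimeter, 2 * pi * r, tolerance = 0.03)
  expect_equal(cb$area, pi * r^2, tolerance = 0.02)
  expect_equal(cb$n_components, 1)
  # two overlapping discs merge into one outline
  shift <- round(1.2 * r / px)
  two <- matrix(0L, nrow(mask) + shift, ncol(mask))
  idx <- which(mask > 0, arr.ind = TRUE)
  two[idx] <- 1L
  two[cbind(idx[, 1] + shift, idx[, 2])] <- 1L
  cb2 <- colony_boundary(two, px)
  expect_equal(cb2$n_components, 1)
  expect_gt(cb2$area, 1.5 * pi * r^2)
  # far-apart discs are flagged as disjoint colonies
  three <- matrix(0L, 600, 300)
  three[20:80, 100:160] <- 1L
  three[500:560, 100:160] <- 1L
  expect_warning(cb3 <- colony_boundary(three, px), "disjoint")
  expect_equal(cb3$n_components, 2)
})

test_that("progeny chains start from exactly two founder daughters", {
  cfg <- generator_config(n_target = 8, seed = 2)
  run <- grow_rod_colony(cfg)
  # frame 1 alone: two single-cell chains
  forest1 <- build_progeny_chains(run$frames[1])
  expect_setequal(forest1$cells$chain, c(1, 2))
  # a movie starting mid-way (more than 2 cells) is rejected by convention
  expect_error(build_progeny_chains(run$frames[length(run$frames)]),
               "two daughter cells")
})

test_that("tracker reproduces the generator lineage exactly at 3-min frames", {
  run <- grow_rod_colony(generator_config(n_target = 48, seed = 19))
  forest <- build_progeny_chains(run$frames)
  sc <- score_tracking(forest, run)
  expect_equal(sc$chain_accuracy, 1)
  expect_equal(sc$n_chain_na, 0)
  expect_true(sc$track_pure)
  expect_equal(sc$detected, sc$true_divisions)
  expect_equal(sc$unresolved, 0)
  # chain-label conservation: per-chain counts only grow at divisions
  cells <- forest$cells
  for (ch in 1:2) {
    cnt <- vapply(seq_len(max(cells$frame)), function(f) {
      sum(cells$chain[cells$frame == f] == ch)
    }, numeric(1))
    dv <- vapply(seq_len(max(cells$frame)), function(f) {
      sum(forest$divisions$frame == f & forest$divisions$chain == ch)
    }, numeric(1))
    expect_equal(diff(cnt), dv[-1])
  }
})

test_that("two merging founder colonies map onto the two chains", {
  run <- grow_rod_colony(generator_config(n_target = 24, seed = 6, n_seeds = 2))
  forest <- build_progeny_chains(run$frames)
  sc <- score_tracking(forest, run)
  expect_equal(sc$chain_accuracy, 1)
  expect_equal(sc$n_chain_na, 0)
})

test_that("tracking degrades gracefully, not fatally, at tripled frame spacing", {
  run <- grow_rod_colony(generator_config(
    n_target = 32, seed = 4, frame_interval = 9,
    mean_division = 21, sd_division = 6
  ))
  expect_no_error(forest <- build_progeny_chains(run$frames))
  # unresolved cells are reported rather than silently dropped
  expect_true(is.data.frame(forest$unresolved))
})
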