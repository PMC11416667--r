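# Enclave analytics: contact rules, the interface-length identity, entropy
# with its permutation null, curvature, invasion regions and phenotypes.

test_that("contact decisions follow the 1.2 um boundary tolerance", {
  mk <- function(gap, chains = c(1, 2)) {
    rod_features(data.frame(
      x = c(0, 0), y = c(0, 1 + gap), len = 4, w = 1, ang = 0,
      chain = chains
    ))
  }
  g1 <- contact_graph(mk(1.0))
  expect_equal(nrow(g1$edges), 1)
  expect_equal(g1$edges$dist, 1.0, tolerance = 0.02)
  expect_equal(interenclave_contact_fraction(g1), 1)
  g2 <- contact_graph(mk(2.0))
  expect_equal(nrow(g2$edges), 0)
  expect_warning(f2 <- interenclave_contact_fraction(g2), "isolated")
  expect_true(is.na(f2))
  # same-chain pair: fraction 0
  g3 <- contact_graph(mk(1.0, chains = c(1, 1)))
  expect_equal(interenclave_contact_fraction(g3), 0)
  # single cell: degree zero
  g4 <- contact_graph(rod_features(data.frame(
    x = 0, y = 0, len = 4, w = 1, ang = 0, chain = 1
  )))
  expect_equal(g4$intra + g4$inter, 0L)
})

test_that("interface length of a diameter-split disc matches the chord", {
  r <- 10
  left <- half_disc_polygon(r, "left")
  right <- half_disc_polygon(r, "right")
  circle <- cbind(r * cos(seq(0, 2 * pi, length.out = 1440)[-1440]),
                  r * sin(seq(0, 2 * pi, length.out = 1440)[-1440]))
  ps1 <- polyline_length(left, closed = TRUE)
  ps2 <- polyline_length(right, closed = TRUE)
  l_col <- polyline_length(circle, closed = TRUE)
  l_int <- interface_length_formula(ps1, ps2, l_col)
  chord <- 2 * r
  expect_lt(abs(l_int - chord) / chord, 0.01)
  expect_equal(l_int, 2 * r, tolerance = 0.01)
  # analytic centroid separation of the two half-discs: 8r/(3 pi)
  dc <- sqrt(sum((polygon_centroid(left) - polygon_centroid(right))^2))
  expect_equal(dc, 8 * r / (3 * pi), tolerance = 0.01)
})

test_that("raster partition of a split disc recovers the analytic geometry", {
  px <- 0.1
  r <- 10
  mask <- make_disc_mask(r = r, px = px, split = TRUE)
  fr <- colony_frame(mask, px, cells = data.frame(label = 1:2, chain = 1:2))
  part <- enclave_partition(fr)
  expect_equal(part$L_interface, 2 * r, tolerance = 0.05)
  expect_equal(part$interface_length, 2 * r, tolerance = 0.05)
  expect_equal(part$delta_c, 8 * r / (3 * pi), tolerance = 0.02)
  expect_equal(part$enclaves[[1]]$area, pi * r^2 / 2, tolerance = 0.03)
  expect_equal(part$exposed_fraction, c(0.5, 0.5), tolerance = 0.06)
  expect_false(part$flagged)
})

test_that("partition invariants hold on a generated colony", {
  run <- grow_rod_colony(generator_config(n_target = 96, seed = 7))
  last <- run$frames[[length(run$frames)]]
  part <- enclave_partition(last)
  ca <- part$colony$area
  for (ch in 1:2) {
    expect_gt(part$enclaves[[ch]]$area / ca, 0.3)
    expect_lt(part$enclaves[[ch]]$area / ca, 0.7)
  }
  expect_gte(part$L_interface, 0)
  # the perimeter identity tracks the directly measured interface
  expect_lt(
    abs(part$L_interface - part$interface_length) / part$interface_length,
    0.05
  )
  # both enclaves keep a substantial exposed share of the outline
  expect_gt(min(part$exposed_fraction), 0.25)
})

test_that("centroid separation grows as a demixed colony expands", {
  run <- grow_rod_colony(generator_config(n_target = 96, seed = 11))
  nfr <- length(run$frames)
  pick <- unique(round(seq(nfr / 3, nfr, length.out = 8)))
  dcs <- vapply(pick, function(f) {
    enclave_partition(run$frames[[f]])$delta_c
  }, numeric(1))
  ns <- vapply(pick, function(f) nrow(run$frames[[f]]$cells), numeric(1))
  ct <- suppressWarnings(cor.test(ns, dcs, method = "spearman"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.05)
})

test_that("moving-box entropy respects its bounds and orderings", {
  # all boxes balanced: checkerboard point pattern -> ln 2 everywhere
  n <- 16
  pts <- expand.grid(x = seq_len(n), y = seq_len(n))
  pts$chain <- 1L + (pts$x + pts$y) %% 2L
  ent <- shannon_entropy(pts, s = 4)
  expect_true(all(ent$boxes$se >= 0 & ent$boxes$se <= log(2) + 1e-12))
  expect_equal(ent$mean_se, log(2), tolerance = 1e-6)
  # single chain: exactly zero
  pts$chain <- 1L
  expect_equal(shannon_entropy(pts, s = 4)$mean_se, 0)
  # demixed below random at fixed positions
  pat <- make_two_color_pattern(300, "demixed", seed = 3)
  pat_r <- pat
  set.seed(1)
  pat_r$cells$chain <- sample(pat$cells$chain)
  expect_lt(shannon_entropy(pat)$mean_se, shannon_entropy(pat_r)$mean_se)
})

test_that("the permutation null preserves counts and dominates demixed colonies", {
  pat <- make_two_color_pattern(200, "demixed", seed = 8)
  ent <- shannon_entropy(pat)
  null <- randomized_entropy_null(pat, iterations = 500, seed = 4)
  expect_lt(null$percentile, 0.01)
  expect_lt(ent$mean_se, null$null_mean)
  # label counts conserved by construction: the null of a 60/140 split
  pat2 <- pat
  pat2$cells$chain <- rep(c(1L, 2L), c(60, 140))
  n2 <- randomized_entropy_null(pat2, iterations = 50, seed = 5)
  expect_length(n2$null, 50)
  expect_true(all(is.finite(n2$null)))
  # small iteration counts already reproduce the null mean closely
  nA <- randomized_entropy_null(pat, iterations = 1e3, seed = 6)
  nB <- randomized_entropy_null(pat, iterations = 2e4, seed = 7)
  expect_lt(abs(nA$null_mean - nB$null_mean) / nB$null_mean, 0.02)
})

test_that("spline curvature matches circles, lines and sine crests", {
  # analytic circle: pointwise
  th <- seq(0, 2 * pi, length.out = 400)[-400]
  g <- interface_curvature(cbind(5 * cos(th), 5 * sin(th)), threshold = 10)
  expect_lt(max(abs(g$samples$kappa - 0.2)) / 0.2, 0.02)
  # rasterised circle: curve-level estimate within 2%
  px <- 0.05
  oc <- enclavekit:::mask_contours(make_disc_mask(r = 5, px = px))[[1]] * px
  g2 <- interface_curvature(oc, threshold = 10)
  expect_lt(abs(mean(g2$samples$kappa) - 0.2) / 0.2, 0.02)
  # straight segment: numerically flat
  g3 <- interface_curvature(cbind(seq(0, 20, by = 0.1), 0), threshold = 1)
  expect_lt(max(g3$samples$kappa), 0.01)
  expect_equal(nrow(g3$high), 0)
  # sine crests: kappa = A k^2 within 5%
  A <- 2
  k <- 0.5
  xx <- seq(0, 4 * pi / k, by = 0.05)
  # smoothing matched to the ~12 um feature wavelength via the exposed spar
  g4 <- interface_curvature(cbind(xx, A * sin(k * xx)), threshold = 0.2,
                            spar = 0.55)
  expect_equal(nrow(g4$high), 4)
  expect_lt(max(abs(g4$high$kappa - A * k^2)) / (A * k^2), 0.05)
  expect_error(interface_curvature(cbind(1:3, 1:3)), "too short")
})

test_that("invasion regions recover carved finger geometry", {
  g <- interface_curvature(finger_interface(2, 6), threshold = 1)
  inv <- invasion_regions(g)
  expect_length(inv$regions, 1)
  expect_equal(inv$regions[[1]]$iw, 2, tolerance = 0.1)
  expect_equal(inv$regions[[1]]$area, 12, tolerance = 0.1)
  # two fingers -> two disjoint regions with their own widths (smoothing
  # matched to the 2-3 um feature scale via the exposed spar)
  g2 <- interface_curvature(finger_interface(c(2, 3), c(6, 5)), threshold = 1,
                            spar = 0.5)
  inv2 <- invasion_regions(g2)
  expect_length(inv2$regions, 2)
  areas <- sort(vapply(inv2$regions, function(r) r$area, numeric(1)))
  expect_equal(areas, c(12, 15), tolerance = 0.1)
  # straight interface: no high-curvature points, no regions
  g3 <- interface_curvature(cbind(seq(0, 20, 0.1), 0), threshold = 1)
  expect_length(invasion_regions(g3)$regions, 0)
})

test_that("phenotype statistics recover rates and flag degenerate noise", {
  g0 <- log(2) / 48
  run <- grow_rod_colony(generator_config(
    n_target = 32, seed = 13, elongation = g0
  ))
  forest <- build_progeny_chains(run$frames)
  ph <- phenotype_stats(forest)
  expect_lt(abs(mean(ph$rates$rate) - g0) / g0, 0.05)
  for (ch in 1:2) {
    rch <- ph$rates$rate[ph$rates$chain == ch]
    expect_lt(abs(mean(rch) - g0) / g0, 0.05)
  }
  # the colony row aggregates both chains (count-weighted mean length)
  last <- max(ph$per_frame$frame)
  row <- function(ch) ph$per_frame[ph$per_frame$frame == last &
                                     ph$per_frame$chain == ch, ]
  w <- row(1)$n * row(1)$mean_length + row(2)$n * row(2)$mean_length
  expect_equal(row(0)$mean_length, w / (row(1)$n + row(2)$n), tolerance = 1e-9)
  # equal lengths -> zero phenotypic noise
  fake <- forest
  fake$cells$len <- 3
  ph0 <- phenotype_stats(fake)
  expect_true(all(ph0$per_frame$noise[ph0$per_frame$n > 1] == 0))
  # the two chains are statistically indistinguishable in cell length
  last_cells <- forest$cells[forest$cells$frame == max(forest$cells$frame), ]
  tt <- t.test(len ~ chain, data = last_cells)
  expect_gt(tt$p.value, 0.01)
})
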