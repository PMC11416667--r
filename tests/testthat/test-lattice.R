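# Lattice colony model: initial configuration, division queue, placement,
# shoving, conservation laws and the on-lattice demixing metrics.

test_that("initial colony is two sister cells in Moore contact", {
  m <- division_time_model(48, 13)
  col <- init_colony(m, seed = 11)
  expect_equal(nrow(col$cells), 2)
  expect_equal(sum(col$grid > 0), 2)
  expect_setequal(col$cells$chain, c(1, 2))
  cheb <- max(abs(diff(col$cells$i)), abs(diff(col$cells$j)))
  expect_equal(cheb, 1)
  expect_true(all(col$cells$next_div > 0))
  # seeded: same green-cell site
  col2 <- init_colony(m, seed = 11)
  expect_identical(col$cells, col2$cells)
})

test_that("division clock sampler matches the parameterised log-normal", {
  m <- division_time_model(48, 13)
  set.seed(1)
  x <- sample_division_time(m, 1e5)
  expect_lt(abs(mean(x) - 48), 3 * 13 / sqrt(1e5))
  expect_lt(abs(sd(x) / mean(x) - 13 / 48), 0.005)
  m2 <- division_time_model(21, 6)
  set.seed(1)
  y <- sample_division_time(m2, 1e5)
  expect_lt(abs(sd(y) / mean(y) - 6 / 21), 0.005)
  # degenerate clock
  expect_equal(sample_division_time(division_time_model(30, 0), 5),
               rep(30, 5))
})

test_that("next divider takes the earliest timestamp, ties to the lowest id", {
  m <- division_time_model(48, 13)
  col <- init_colony(m, seed = 2)
  col$cells$next_div <- c(30, 40)
  expect_equal(next_divider(col), col$cells$id[1])
  col$cells$next_div <- c(30, 30)
  expect_equal(next_divider(col), min(col$cells$id))
  # after a division both daughters join the queue
  col$cells$next_div <- c(10, 40)
  col2 <- enclavekit:::step_division(col)
  expect_equal(nrow(col2$cells), 3)
  expect_equal(sum(col2$grid > 0), 3)
  expect_false(col$cells$id[1] %in% col2$cells$id)
})

test_that("daughter placement uses free sites in range, shoving otherwise", {
  m <- division_time_model(48, 13)
  col <- init_colony(m, seed = 4)
  ctr <- which(col$grid == 1L, arr.ind = TRUE)[1, ]
  # isolated mother: daughter lands in the Moore ring
  set.seed(5)
  for (rep in 1:20) {
    ps <- place_daughter(col, ctr)
    expect_equal(max(abs(ps$site - ctr)), 1)
    expect_equal(ps$colony$grid[ps$site[1], ps$site[2]], 0L)
  }
  # Moore ring full, range 1 -> shove frees an adjacent site, count kept
  col_full <- col
  nid <- 10L
  for (di in -1:1) for (dj in -1:1) {
    if (col_full$grid[ctr[1] + di, ctr[2] + dj] == 0L) {
      col_full$grid[ctr[1] + di, ctr[2] + dj] <- nid
      col_full$cells <- rbind(col_full$cells, data.frame(
        id = nid, chain = 1L, i = ctr[1] + di, j = ctr[2] + dj,
        birth = 0, next_div = 1e9
      ))
      nid <- nid + 1L
    }
  }
  n_before <- nrow(col_full$cells)
  set.seed(6)
  ps <- place_daughter(col_full, ctr)
  expect_equal(max(abs(ps$site - ctr)), 1)
  expect_equal(ps$colony$grid[ps$site[1], ps$site[2]], 0L)
  expect_equal(sum(ps$colony$grid > 0), n_before)
  expect_setequal(ps$colony$cells$chain, col_full$cells$chain)
  # range 2 with Moore full but ring-2 open: daughter two steps away
  set.seed(7)
  ps2 <- place_daughter(col_full, ctr, sim_variant(placement_range = 2))
  expect_equal(max(abs(ps2$site - ctr)), 2)
})

test_that("shove direction frequencies follow the 1/run-length weights", {
  m <- division_time_model(48, 13)
  col <- init_colony(m, seed = 1, grid_size = 15)
  ctr <- 8
  g <- matrix(0L, 15, 15)
  g[ctr, ctr] <- 1L
  cells <- list(data.frame(id = 1L, chain = 1L, i = ctr, j = ctr,
                           birth = 0, next_div = 1e9))
  nid <- 1L
  addc <- function(i, j) {
    nid <<- nid + 1L
    g[i, j] <<- nid
    cells[[length(cells) + 1]] <<- data.frame(
      id = nid, chain = 1L, i = i, j = j, birth = 0, next_div = 1e9
    )
  }
  for (di in -1:1) for (dj in -1:1) if (di || dj) addc(ctr + di, ctr + dj)
  addc(ctr, ctr + 2) # north run extended ...
  addc(ctr, ctr + 3) # ... to length 3
  for (d in list(c(-1, 0), c(0, -1), c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
    addc(ctr + 2 * d[1], ctr + 2 * d[2]) # all other runs have length 2
  }
  col$grid <- g
  col$cells <- do.call(rbind, cells)
  # runs: east 1, north 3, the rest 2 -> weights 1, 1/3, 1/2 each
  probs <- c(1, rep(1 / 2, 6), 1 / 3)
  probs <- probs / sum(probs)
  set.seed(42)
  n_tr <- 4000
  dirs <- integer(8)
  for (t in seq_len(n_tr)) {
    res <- shove(col, c(ctr, ctr))
    expect_equal(sum(res$colony$grid > 0), nrow(col$cells))
    d <- res$site - c(ctr, ctr)
    k <- which(enclavekit:::.moore[, 1] == d[1] &
                 enclavekit:::.moore[, 2] == d[2])
    dirs[k] <- dirs[k] + 1L
  }
  east <- which(enclavekit:::.moore[, 1] == 1 & enclavekit:::.moore[, 2] == 0)
  north <- which(enclavekit:::.moore[, 1] == 0 & enclavekit:::.moore[, 2] == 1)
  p_east <- 1 / (1 + 1 / 3 + 6 / 2)
  p_north <- (1 / 3) / (1 + 1 / 3 + 6 / 2)
  expect_lt(abs(dirs[east] - n_tr * p_east),
            3 * sqrt(n_tr * p_east * (1 - p_east)) + 1)
  expect_lt(abs(dirs[north] - n_tr * p_north),
            3 * sqrt(n_tr * p_north * (1 - p_north)) + 1)
  expect_gt(dirs[east] / dirs[north], 2.4) # target ratio 3
  expect_lt(dirs[east] / dirs[north], 3.75)
  # uniform variant: all eight directions near-equiprobable
  set.seed(43)
  dirs_u <- integer(8)
  for (t in seq_len(n_tr)) {
    res <- shove(col, c(ctr, ctr), sim_variant(shove_weighting = "uniform"))
    d <- res$site - c(ctr, ctr)
    k <- which(enclavekit:::.moore[, 1] == d[1] &
                 enclavekit:::.moore[, 2] == d[2])
    dirs_u[k] <- dirs_u[k] + 1L
  }
  expect_true(all(abs(dirs_u - n_tr / 8) < 3 * sqrt(n_tr * (1 / 8) * (7 / 8)) + 1))
})

test_that("run_lattice reaches the target conservatively and deterministically", {
  m <- division_time_model(48, 13)
  res <- run_lattice(init_colony(m, seed = 8), 128)
  col <- res$colony
  expect_equal(nrow(col$cells), 128)
  expect_equal(sum(col$grid > 0), 128)
  # one cell per site: ids on the grid are exactly the cell ids
  expect_setequal(col$grid[col$grid > 0], col$cells$id)
  expect_true(all(col$cells$chain %in% 1:2))
  expect_true(all(col$cells$next_div > col$cells$birth))
  # seeded determinism
  res2 <- run_lattice(init_colony(m, seed = 8), 128)
  expect_identical(res2$colony$cells, col$cells)
  # both chains survive across seeds at equal rates (19 of 20 or better)
  alive <- vapply(1:20, function(s) {
    cc <- run_lattice(init_colony(m, seed = 100 + s), 64)$colony$cells
    all(c(1, 2) %in% cc$chain)
  }, logical(1))
  expect_gte(sum(alive), 19)
})

test_that("strong rate imbalance shrinks the slow chain into a minority", {
  m <- division_time_model(48, 13)
  frac <- vapply(1:10, function(s) {
    col <- run_lattice(
      init_colony(m, sim_variant(chain_rate_factor = 3), seed = 200 + s), 128
    )$colony
    sum(col$cells$chain == 2) / 128
  }, numeric(1))
  expect_gt(mean(frac < 0.25), 0.5)
})

test_that("on-lattice contacts and entropy behave on constructed colonies", {
  m <- division_time_model(48, 13)
  base <- init_colony(m, seed = 1, grid_size = 12)
  mk <- function(chain_fun) {
    g <- matrix(0L, 12, 12)
    cells <- list()
    id <- 0L
    for (i in 1:12) for (j in 1:12) {
      id <- id + 1L
      g[i, j] <- id
      cells[[id]] <- data.frame(
        id = id, chain = chain_fun(i, j), i = i, j = j,
        birth = 0, next_div = 1e9
      )
    }
    col <- base
    col$grid <- g
    col$cells <- do.call(rbind, cells)
    col
  }
  # parity checkerboard: interior cells see 4 orthogonal opposite-chain and
  # 4 diagonal same-chain Moore neighbours (1/2); corner cells 2/3, edge
  # cells 3/5 -- the exact mean over the 12 x 12 grid follows by counting
  checker <- mk(function(i, j) 1L + (i + j) %% 2L)
  exact <- (4 * (2 / 3) + 40 * (3 / 5) + 100 * (1 / 2)) / 144
  expect_equal(lattice_interenclave_contacts(checker), exact, tolerance = 1e-9)
  expect_equal(lattice_entropy(checker), log(2), tolerance = 1e-9)
  mono <- mk(function(i, j) 1L)
  expect_equal(lattice_interenclave_contacts(mono), 0)
  expect_equal(lattice_entropy(mono), 0)
  halves <- mk(function(i, j) if (i <= 6) 1L else 2L)
  expect_lt(lattice_interenclave_contacts(halves), 0.25)
})
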