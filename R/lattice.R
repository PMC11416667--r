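# Coarse-grained stochastic lattice model of enclave formation.
#
# Cells occupy single sites of a square lattice (one cell per site). Each
# cell carries an absolute division timestamp drawn at birth from a
# log-normal clock; the earliest timestamp divides next. One daughter stays
# on the mother's site, the other takes a random unoccupied site within the
# placement range (Moore neighbourhood by default), or, if none is free, a
# contiguous run of cells is shoved outward by one site along a direction
# weighted inversely by the run length.

#' Log-normal division-time model
#'
#' Parameterised by the arithmetic mean and SD of the duration distribution:
#' sigma^2 = log(1 + sd^2/mean^2), mu = log(mean) - sigma^2/2, so that
#' samples have exactly the requested mean and SD. `sd = 0` degenerates to a
#' deterministic clock.
#'
#' @param mean mean division duration (min).
#' @param sd SD of division durations (min).
#' @return a `division_time_model`.
#' @export
division_time_model <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  sigma2 <- if (sd > 0) log(1 + sd^2 / mean^2) else 0
  structure(
    list(mean = mean, sd = sd, mu = log(mean) - sigma2 / 2,
         sigma = sqrt(sigma2)),
    class = "division_time_model"
  )
}

#' Draw division durations
#' @param model a [division_time_model()].
#' @param n number of samples.
#' @return positive durations (min).
#' @export
sample_division_time <- function(model, n = 1) {
  stopifnot(inherits(model, "division_time_model"))
  if (model$sd == 0) return(rep(model$mean, n))
  stats::rlnorm(n, meanlog = model$mu, sdlog = model$sigma)
}

#' Simulation variant switches
#'
#' @param placement_range 1 places daughters in the Moore neighbourhood;
#'   2 additionally allows sites two steps away (weakened sister adhesion).
#' @param shove_weighting "inverse_run" weights shove directions by 1/run
#'   length; "uniform" picks among the 8 directions equiprobably.
#' @param chain_rate_factor multiplier >= 1 applied to chain 2's mean
#'   division time (chain 2 divides slower when > 1).
#' @return a `sim_variant`.
#' @export
sim_variant <- function(placement_range = 1,
                        shove_weighting = c("inverse_run", "uniform"),
                        chain_rate_factor = 1) {
  stopifnot(placement_range %in% c(1, 2), chain_rate_factor >= 1)
  structure(
    list(placement_range = placement_range,
         shove_weighting = match.arg(shove_weighting),
         chain_rate_factor = chain_rate_factor),
    class = "sim_variant"
  )
}

## the 8 Moore directions
.moore <- cbind(
  di = c(1, 1, 0, -1, -1, -1, 0, 1),
  dj = c(0, 1, 1, 1, 0, -1, -1, -1)
)

#' Initialise a two-cell lattice colony
#'
#' A chain-1 cell is placed at the centre of a 25 x 25 grid and its sister
#' (chain 2) on a uniformly random site of its Moore neighbourhood; both get
#' division timestamps sampled from the model.
#'
#' @param model a [division_time_model()].
#' @param variant a [sim_variant()].
#' @param seed optional RNG seed.
#' @param grid_size initial grid side length (auto-expands when shoves
#'   reach the border).
#' @return a `lattice_colony`.
#' @export
init_colony <- function(model, variant = sim_variant(), seed = NULL,
                        grid_size = 25) {
  if (!is.null(seed)) set.seed(seed)
  grid <- matrix(0L, grid_size, grid_size)
  ctr <- ceiling(grid_size / 2)
  k <- sample.int(8, 1)
  sis <- c(ctr + .moore[k, 1], ctr + .moore[k, 2])
  grid[ctr, ctr] <- 1L
  grid[sis[1], sis[2]] <- 2L
  cells <- data.frame(
    id = 1:2, chain = 1:2, i = c(ctr, sis[1]), j = c(ctr, sis[2]),
    birth = 0, next_div = c(
      sample_division_time(model),
      sample_division_time(model) * variant$chain_rate_factor
    )
  )
  structure(
    list(grid = grid, cells = cells, time = 0, model = model,
         variant = variant, next_id = 3L),
    class = "lattice_colony"
  )
}

#' @export
print.lattice_colony <- function(x, ...) {
  cat(sprintf(
    "<lattice_colony> %d cells (chain 1: %d, chain 2: %d), t = %.1f min, grid %d x %d\n",
    nrow(x$cells), sum(x$cells$chain == 1), sum(x$cells$chain == 2),
    x$time, nrow(x$grid), ncol(x$grid)
  ))
  invisible(x)
}

#' Cell due to divide next
#'
#' The cell with the minimum absolute division timestamp; exact ties go to
#' the lowest cell id (equivalent to picking the top of the ascending list).
#'
#' @param colony a `lattice_colony`.
#' @return cell id.
#' @export
next_divider <- function(colony) {
  cells <- colony$cells
  cand <- which(cells$next_div == min(cells$next_div))
  cells$id[cand[which.min(cells$id[cand])]]
}

## grow the grid by pad sites on every side, shifting stored coordinates
expand_grid <- function(colony, pad = 8L) {
  g <- colony$grid
  ng <- matrix(0L, nrow(g) + 2 * pad, ncol(g) + 2 * pad)
  ng[(pad + 1):(pad + nrow(g)), (pad + 1):(pad + ncol(g))] <- g
  colony$grid <- ng
  colony$cells$i <- colony$cells$i + pad
  colony$cells$j <- colony$cells$j + pad
  colony
}

## run length from `site` along Moore direction k: number of contiguous
## occupied sites before the first empty one (diagonals count Chebyshev
## steps). Expands the grid if the run reaches the border.
run_length <- function(colony, site, k) {
  repeat {
    g <- colony$grid
    d <- .moore[k, ]
    r <- 0L
    i <- site[1]; j <- site[2]
    hit_border <- FALSE
    repeat {
      i <- i + d[1]; j <- j + d[2]
      if (i < 1 || i > nrow(g) || j < 1 || j > ncol(g)) {
        hit_border <- TRUE
        break
      }
      if (g[i, j] == 0L) break
      r <- r + 1L
    }
    if (!hit_border) return(list(colony = colony, r = r))
    colony <- expand_grid(colony)
    site <- site + 8L
  }
}

#' Shove a run of cells outward to free a site next to the mother
#'
#' Among the 8 lattice directions, the run length r_k counts the contiguous
#' occupied sites outward from the mother up to the first empty site. A
#' direction is sampled with weight proportional to 1/r_k (or uniformly for
#' the `uniform` variant), the whole run is translated outward by one site,
#' and the now-empty site adjacent to the mother is returned. Cell count
#' and chain labels are preserved; the grid auto-expands at its border.
#'
#' @param colony a `lattice_colony`.
#' @param site mother's (i, j).
#' @param variant a [sim_variant()] (defaults to the colony's).
#' @return list(colony, site) with the freed adjacent site.
#' @export
shove <- function(colony, site, variant = colony$variant) {
  runs <- integer(8)
  for (k in 1:8) {
    rl <- run_length(colony, site, k)
    if (!identical(dim(rl$colony$grid), dim(colony$grid))) {
      # grid expanded: restart with shifted coordinates
      off <- (nrow(rl$colony$grid) - nrow(colony$grid)) / 2
      colony <- rl$colony
      site <- site + off
      return(shove(colony, site, variant))
    }
    runs[k] <- rl$r
  }
  w <- if (variant$shove_weighting == "inverse_run") {
    ifelse(runs > 0, 1 / runs, 0)
  } else {
    rep(1, 8)
  }
  if (all(w == 0)) stop("no occupied direction to shove") # cannot happen post-check
  k <- sample.int(8, 1, prob = w)
  d <- .moore[k, ]
  r <- runs[k]
  if (r == 0) {
    # uniform variant may pick an already-free direction
    return(list(colony = colony, site = c(site[1] + d[1], site[2] + d[2])))
  }
  # translate cells at steps r..1 outward by one site (farthest first)
  for (s in r:1) {
    from <- c(site[1] + s * d[1], site[2] + s * d[2])
    to <- c(from[1] + d[1], from[2] + d[2])
    id <- colony$grid[from[1], from[2]]
    colony$grid[to[1], to[2]] <- id
    colony$grid[from[1], from[2]] <- 0L
    row <- match(id, colony$cells$id)
    colony$cells$i[row] <- to[1]
    colony$cells$j[row] <- to[2]
  }
  list(colony = colony, site = c(site[1] + d[1], site[2] + d[2]))
}

#' Choose the site for a newborn daughter
#'
#' Picks uniformly among unoccupied sites within Chebyshev distance
#' `placement_range` of the mother; when none is free, [shove()] first
#' frees a site adjacent to the mother.
#'
#' @param colony a `lattice_colony`.
#' @param site mother's (i, j).
#' @param variant a [sim_variant()].
#' @return list(colony, site).
#' @export
place_daughter <- function(colony, site, variant = colony$variant) {
  g <- colony$grid
  rng <- variant$placement_range
  # border guard so the neighbourhood window exists
  if (site[1] - rng < 1 || site[1] + rng > nrow(g) ||
      site[2] - rng < 1 || site[2] + rng > ncol(g)) {
    off <- 8L
    colony <- expand_grid(colony)
    site <- site + off
    g <- colony$grid
  }
  ii <- (site[1] - rng):(site[1] + rng)
  jj <- (site[2] - rng):(site[2] + rng)
  win <- g[ii, jj]
  win[rng + 1, rng + 1] <- 1L # mother's own site is not available
  free <- which(win == 0L, arr.ind = TRUE)
  if (nrow(free) > 0) {
    pick <- free[sample.int(nrow(free), 1), ]
    return(list(
      colony = colony,
      site = c(ii[pick[1]], jj[pick[2]])
    ))
  }
  shove(colony, site, variant)
}

## one division event: advance the clock, split the due cell
step_division <- function(colony) {
  id <- next_divider(colony)
  row <- match(id, colony$cells$id)
  mom <- colony$cells[row, ]
  colony$time <- mom$next_div
  ps <- place_daughter(colony, c(mom$i, mom$j), colony$variant)
  colony <- ps$colony
  row <- match(id, colony$cells$id) # coordinates may have shifted
  mom <- colony$cells[row, ]
  rate <- function(chain) {
    if (chain == 2) colony$variant$chain_rate_factor else 1
  }
  d1 <- data.frame(
    id = colony$next_id, chain = mom$chain, i = mom$i, j = mom$j,
    birth = colony$time,
    next_div = colony$time + sample_division_time(colony$model) * rate(mom$chain)
  )
  d2 <- data.frame(
    id = colony$next_id + 1L, chain = mom$chain,
    i = ps$site[1], j = ps$site[2], birth = colony$time,
    next_div = colony$time + sample_division_time(colony$model) * rate(mom$chain)
  )
  colony$grid[mom$i, mom$j] <- d1$id
  colony$grid[ps$site[1], ps$site[2]] <- d2$id
  colony$cells <- rbind(colony$cells[-row, ], d1, d2)
  colony$next_id <- colony$next_id + 2L
  colony
}

#' Run the lattice simulation to a target cell count
#'
#' @param colony a `lattice_colony` from [init_colony()].
#' @param n_target final number of cells (>= 2).
#' @param snapshots record a compact occupancy snapshot after every
#'   division?
#' @return list(colony, snapshots) where each snapshot is a data.frame
#'   (i, j, chain, time).
#' @export
run_lattice <- function(colony, n_target, snapshots = FALSE) {
  stopifnot(n_target >= 2)
  snaps <- if (snapshots) list() else NULL
  while (nrow(colony$cells) < n_target) {
    colony <- step_division(colony)
    if (snapshots) {
      snaps[[length(snaps) + 1]] <- data.frame(
        i = colony$cells$i, j = colony$cells$j,
        chain = colony$cells$chain, time = colony$time
      )
    }
  }
  list(colony = colony, snapshots = snaps)
}

#' Interenclave contact fraction on the lattice
#'
#' For every cell with at least one occupied Moore neighbour, the fraction
#' of those neighbours belonging to the opposite chain; averaged over cells.
#'
#' @param colony a `lattice_colony`.
#' @return fraction in [0, 1].
#' @export
lattice_interenclave_contacts <- function(colony) {
  cells <- colony$cells
  stopifnot(nrow(cells) >= 2)
  g <- colony$grid
  chain_at <- matrix(0L, nrow(g), ncol(g))
  chain_at[cbind(cells$i, cells$j)] <- cells$chain
  fr <- numeric(nrow(cells))
  keep <- logical(nrow(cells))
  for (r in seq_len(nrow(cells))) {
    ii <- cells$i[r] + .moore[, 1]
    jj <- cells$j[r] + .moore[, 2]
    ok <- ii >= 1 & ii <= nrow(g) & jj >= 1 & jj <= ncol(g)
    nb <- chain_at[cbind(ii[ok], jj[ok])]
    nb <- nb[nb > 0]
    if (length(nb)) {
      keep[r] <- TRUE
      fr[r] <- mean(nb != cells$chain[r])
    }
  }
  if (!any(keep)) return(0)
  mean(fr[keep])
}

#' Moving-box Shannon entropy of a lattice colony
#'
#' The same two-colour entropy as [shannon_entropy()], applied to site
#' occupants: square boxes of `box_cells` sites tile the occupied bounding
#' box at half-box stride; boxes holding at least one cell contribute
#' -p_r log p_r - p_g log p_g (natural log) and the colony value is their
#' mean.
#'
#' @param colony a `lattice_colony`.
#' @param box_cells box side length in sites (default 4, roughly matching
#'   the ~5.5 um boxes used off-lattice).
#' @return mean Shannon entropy in [0, log(2)].
#' @export
lattice_entropy <- function(colony, box_cells = 4) {
  cells <- colony$cells
  stopifnot(nrow(cells) >= 2)
  shannon_entropy_points(
    cells$i, cells$j, cells$chain,
    s = box_cells, stride = box_cells / 2
  )$mean_se
}
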