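# Ground-truthed synthetic colony generator.
#
# Off-lattice rod-shaped cells elongate exponentially, divide with
# log-normally distributed division times into two half-length daughters
# placed end-to-end (sisters stay in contact), and are kept from overlapping
# by an iterative pairwise repulsion. Frames are rasterised to labelled
# masks on a common pixel grid so the label-free tracker can be exercised
# against a known lineage.

#' Configuration for the synthetic rod-colony generator
#'
#' Defaults emulate the 25 C growth conditions of slow-growing *E. coli*
#' monolayers: division durations log-normal with mean 48 min and SD 13 min,
#' frames every 3 min, and colonies grown to the ~100-cell monolayer regime.
#' Use `mean_division = 21, sd_division = 6` for the 37 C parameterisation.
#'
#' @param mean_division mean division duration (min).
#' @param sd_division SD of division durations (min); 0 gives a
#'   deterministic clock.
#' @param elongation exponential elongation rate (1/min). The default `NULL`
#'   gives each cell the rate `log(2) / (its own division duration)`, so
#'   every cell doubles its birth length by the time it divides and the
#'   division length stays near-constant across generations, as observed
#'   for rod-shaped cells. A numeric value imposes that fixed rate on all
#'   cells instead (lengths then fluctuate with the stochastic clock).
#' @param frame_interval time between rendered frames (min).
#' @param pixel_size rendering resolution (um/px).
#' @param relaxation_iters cap on overlap-relaxation sweeps per step.
#' @param overlap_tolerance maximum tolerated rod-rod overlap (um).
#' @param n_target cell count at which the run stops.
#' @param seed RNG seed.
#' @param n_seeds 1 starts from a founder's two daughters; 2 starts two
#'   separate founder cells whose colonies eventually merge.
#' @param birth_length cell length at birth (um).
#' @param width rod width (um).
#' @param division_angle_sd SD of the angular noise given to each daughter
#'   at division (rad).
#' @return a `generator_config` list.
#' @export
generator_config <- function(mean_division = 48, sd_division = 13,
                             elongation = NULL,
                             frame_interval = 3, pixel_size = 0.1,
                             relaxation_iters = 200, overlap_tolerance = 0.05,
                             n_target = 64, seed = 1, n_seeds = 1,
                             birth_length = 2.2, width = 0.9,
                             division_angle_sd = 0.05) {
  stopifnot(
    mean_division > 0, sd_division >= 0,
    is.null(elongation) || elongation >= 0,
    frame_interval > 0, pixel_size > 0, relaxation_iters > 0,
    overlap_tolerance > 0, n_target >= 2, n_seeds %in% c(1, 2),
    birth_length > width, width > 0
  )
  structure(as.list(environment()), class = "generator_config")
}

## log-normal parameterised by arithmetic mean/sd (shared with the lattice
## model); returns function(n) drawing durations
duration_sampler <- function(mean, sd) {
  if (sd == 0) return(function(n) rep(mean, n))
  sigma2 <- log(1 + sd^2 / mean^2)
  mu <- log(mean) - sigma2 / 2
  function(n) stats::rlnorm(n, meanlog = mu, sdlog = sqrt(sigma2))
}

## rod core segment endpoints from centre/angle/length/width
rod_segments <- function(cells) {
  half <- pmax(cells$len - cells$width, 0) / 2
  ux <- cos(cells$phi)
  uy <- sin(cells$phi)
  list(
    ax = cells$x - half * ux, ay = cells$y - half * uy,
    bx = cells$x + half * ux, by = cells$y + half * uy
  )
}

## iterative pairwise repulsion until max spherocylinder overlap < tol.
## Synchronous displacement updates, capped iteration count; returns cells
## with a "converged" attribute.
relax_rods <- function(cells, tol, max_iters, step = 0.6) {
  n <- nrow(cells)
  if (n < 2) {
    attr(cells, "converged") <- TRUE
    return(cells)
  }
  converged <- FALSE
  for (it in seq_len(max_iters)) {
    seg <- rod_segments(cells)
    # candidate pairs by centre distance
    i <- rep(seq_len(n - 1), times = (n - 1):1)
    j <- sequence((n - 1):1) + i
    cd <- sqrt((cells$x[i] - cells$x[j])^2 + (cells$y[i] - cells$y[j])^2)
    keep <- cd < (cells$len[i] + cells$len[j]) / 2 + 0.5
    i <- i[keep]; j <- j[keep]
    if (!length(i)) {
      converged <- TRUE
      break
    }
    cp <- seg_seg_closest(
      seg$ax[i], seg$ay[i], seg$bx[i], seg$by[i],
      seg$ax[j], seg$ay[j], seg$bx[j], seg$by[j]
    )
    ov <- (cells$width[i] + cells$width[j]) / 2 - cp$d
    hit <- ov > tol
    if (!any(hit)) {
      converged <- TRUE
      break
    }
    i <- i[hit]; j <- j[hit]
    ov <- ov[hit]
    dirx <- cp$qx[hit] - cp$px[hit]
    diry <- cp$qy[hit] - cp$py[hit]
    dd <- sqrt(dirx^2 + diry^2)
    deg <- dd < 1e-9
    if (any(deg)) { # coincident closest points: push apart along centres
      dirx[deg] <- cells$x[j][deg] - cells$x[i][deg]
      diry[deg] <- cells$y[j][deg] - cells$y[i][deg]
      dd[deg] <- sqrt(dirx[deg]^2 + diry[deg]^2)
      still <- deg & dd < 1e-9
      if (any(still)) {
        th <- stats::runif(sum(still), 0, 2 * pi)
        dirx[still] <- cos(th); diry[still] <- sin(th)
        dd[still] <- 1
      }
    }
    dirx <- dirx / dd
    diry <- diry / dd
    push <- step * ov / 2
    dx <- dy <- numeric(n)
    for (k in seq_along(i)) {
      dx[i[k]] <- dx[i[k]] - dirx[k] * push[k]
      dy[i[k]] <- dy[i[k]] - diry[k] * push[k]
      dx[j[k]] <- dx[j[k]] + dirx[k] * push[k]
      dy[j[k]] <- dy[j[k]] + diry[k] * push[k]
    }
    cells$x <- cells$x + dx
    cells$y <- cells$y + dy
  }
  attr(cells, "converged") <- converged
  cells
}

## rasterise rods to a labelled mask on a fixed grid. origin = physical um
## coordinate of pixel (0, 0); contested pixels go to the deepest rod.
render_rod_mask <- function(cells, pixel_size, origin, dims) {
  mask <- matrix(0L, dims[1], dims[2])
  depth <- matrix(Inf, dims[1], dims[2])
  seg <- rod_segments(cells)
  for (k in seq_len(nrow(cells))) {
    r <- cells$width[k] / 2
    x0 <- floor((min(seg$ax[k], seg$bx[k]) - r - origin[1]) / pixel_size)
    x1 <- ceiling((max(seg$ax[k], seg$bx[k]) + r - origin[1]) / pixel_size)
    y0 <- floor((min(seg$ay[k], seg$by[k]) - r - origin[2]) / pixel_size)
    y1 <- ceiling((max(seg$ay[k], seg$by[k]) + r - origin[2]) / pixel_size)
    xs <- max(0, x0):min(dims[1] - 1, x1)
    ys <- max(0, y0):min(dims[2] - 1, y1)
    if (!length(xs) || !length(ys)) next
    px <- rep(xs, times = length(ys)) * pixel_size + origin[1]
    py <- rep(ys, each = length(xs)) * pixel_size + origin[2]
    d <- point_seg_dist(px, py, seg$ax[k], seg$ay[k], seg$bx[k], seg$by[k]) - r
    inside <- d <= 0
    if (!any(inside)) next
    ii <- rep(xs + 1L, times = length(ys))[inside]
    jj <- rep(ys + 1L, each = length(xs))[inside]
    dv <- d[inside]
    lin <- ii + (jj - 1L) * dims[1]
    take <- dv < depth[lin]
    mask[lin[take]] <- k
    depth[lin[take]] <- dv[take]
  }
  mask
}

#' Grow a synthetic rod colony with known lineage
#'
#' Simulates an off-lattice monolayer colony from the founder's two daughter
#' cells (t = 0 is their birth): cells elongate exponentially, divide at
#' their absolute division times into two half-length daughters placed
#' end-to-end along the mother axis with small angular noise, and pairwise
#' overlaps are relaxed below `overlap_tolerance` by iterative repulsion.
#' Frames are rendered every `frame_interval` minutes on a common pixel
#' grid; the final frame is rendered at the instant the colony reaches
#' `n_target` cells.
#'
#' @param config a [generator_config()].
#' @return list with `frames` (list of `colony_frame`: labelled `mask`,
#'   `cells` table, `time`, `pixel_size`, `origin`), `truth` (per-frame
#'   label -> track/parent/chain map), `divisions` (event table) and
#'   `cells_all` (full per-frame off-lattice state).
#' @export
grow_rod_colony <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  sampler <- duration_sampler(config$mean_division, config$sd_division)

  new_cell <- function(id, parent, chain, x, y, phi, len, birth) {
    dur <- sampler(1)
    g <- if (is.null(config$elongation)) log(2) / dur else config$elongation
    data.frame(
      id = id, parent = parent, chain = chain, x = x, y = y,
      phi = phi, len = len, width = config$width,
      birth = birth, div_time = birth + dur, g = g
    )
  }

  if (config$n_seeds == 1) {
    # founder of length 2 * birth_length divides at t = 0
    phi0 <- stats::runif(1, -pi / 2, pi / 2)
    off <- config$birth_length / 2
    cells <- rbind(
      new_cell(1L, 0L, 1L, -off * cos(phi0), -off * sin(phi0), phi0,
               config$birth_length, 0),
      new_cell(2L, 0L, 2L, off * cos(phi0), off * sin(phi0), phi0,
               config$birth_length, 0)
    )
  } else {
    sep <- 6 # um between the two founder cells (merging-colonies scenario)
    cells <- rbind(
      new_cell(1L, 0L, 1L, -sep / 2, 0, stats::runif(1, -pi / 2, pi / 2),
               config$birth_length, 0),
      new_cell(2L, 0L, 2L, sep / 2, 0, stats::runif(1, -pi / 2, pi / 2),
               config$birth_length, 0)
    )
  }
  next_id <- 3L

  grow_to <- function(cells, from, to) {
    if (to > from) cells$len <- cells$len * exp(cells$g * (to - from))
    cells
  }

  snapshots <- list()
  snap_times <- numeric()
  snap_flags <- logical()
  divisions <- list()
  t_now <- 0
  cells <- relax_rods(cells, config$overlap_tolerance, config$relaxation_iters)
  take_snap <- function(cells, t) {
    snapshots[[length(snapshots) + 1]] <<- cells
    snap_times[length(snap_times) + 1] <<- t
    snap_flags[length(snap_flags) + 1] <<- !isTRUE(attr(cells, "converged"))
  }
  take_snap(cells, 0)
  next_frame <- config$frame_interval

  while (nrow(cells) < config$n_target) {
    td <- min(cells$div_time)
    while (next_frame < td && nrow(cells) < config$n_target) {
      cells <- grow_to(cells, t_now, next_frame)
      t_now <- next_frame
      cells <- relax_rods(cells, config$overlap_tolerance,
                          config$relaxation_iters)
      take_snap(cells, t_now)
      next_frame <- next_frame + config$frame_interval
    }
    # advance to the division event
    cells <- grow_to(cells, t_now, td)
    t_now <- td
    m <- which(cells$div_time <= td)[1]
    mom <- cells[m, ]
    half <- mom$len / 4
    d1 <- new_cell(next_id, mom$id, mom$chain,
                   mom$x - half * cos(mom$phi), mom$y - half * sin(mom$phi),
                   wrap_nematic(mom$phi + stats::rnorm(1, 0, config$division_angle_sd)),
                   mom$len / 2, t_now)
    d2 <- new_cell(next_id + 1L, mom$id, mom$chain,
                   mom$x + half * cos(mom$phi), mom$y + half * sin(mom$phi),
                   wrap_nematic(mom$phi + stats::rnorm(1, 0, config$division_angle_sd)),
                   mom$len / 2, t_now)
    divisions[[length(divisions) + 1]] <- data.frame(
      time = t_now, mother = mom$id, daughter1 = d1$id, daughter2 = d2$id,
      chain = mom$chain
    )
    cells <- rbind(cells[-m, ], d1, d2)
    next_id <- next_id + 2L
    cells <- relax_rods(cells, config$overlap_tolerance,
                        config$relaxation_iters)
    if (nrow(cells) >= config$n_target) take_snap(cells, t_now)
  }
  divisions <- do.call(rbind, divisions)

  # common raster grid over all snapshots
  pad <- max(vapply(snapshots, function(s) max(s$len), numeric(1))) / 2 + 1
  xr <- range(unlist(lapply(snapshots, function(s) s$x)))
  yr <- range(unlist(lapply(snapshots, function(s) s$y)))
  origin <- c(xr[1] - pad, yr[1] - pad)
  dims <- c(
    ceiling((xr[2] + pad - origin[1]) / config$pixel_size) + 1,
    ceiling((yr[2] + pad - origin[2]) / config$pixel_size) + 1
  )

  frames <- vector("list", length(snapshots))
  truth <- vector("list", length(snapshots))
  div_frame <- integer(0)
  for (f in seq_along(snapshots)) {
    s <- snapshots[[f]]
    mask <- render_rod_mask(s, config$pixel_size, origin, dims)
    frames[[f]] <- colony_frame(
      mask = mask, pixel_size = config$pixel_size, time = snap_times[f],
      origin = origin,
      cells = data.frame(
        label = seq_len(nrow(s)), id = s$id, parent = s$parent,
        chain = s$chain, x = s$x, y = s$y, phi = s$phi, len = s$len,
        width = s$width
      ),
      flagged = snap_flags[f]
    )
    truth[[f]] <- data.frame(
      frame = f, label = seq_len(nrow(s)), track = s$id,
      parent = s$parent, chain = s$chain
    )
  }
  truth <- do.call(rbind, truth)
  if (any(snap_flags)) {
    warning(sprintf(
      "overlap relaxation did not converge in %d frame(s); frames flagged",
      sum(snap_flags)
    ))
  }
  list(
    frames = frames, truth = truth, divisions = divisions,
    config = config, times = snap_times
  )
}

#' Construct a colony frame
#'
#' One time point of a colony movie: a labelled mask in a fixed pixel grid
#' plus (optionally) per-cell records in physical units.
#'
#' @param mask integer matrix indexed `[x, y]`, background 0.
#' @param pixel_size um per pixel.
#' @param time acquisition time (min).
#' @param origin physical (x, y) of pixel (0, 0), um.
#' @param cells optional per-cell table.
#' @param flagged logical, relaxation/quality flag.
#' @return a `colony_frame` object.
#' @export
colony_frame <- function(mask, pixel_size, time = NA_real_,
                         origin = c(0, 0), cells = NULL, flagged = FALSE) {
  structure(
    list(mask = mask, pixel_size = pixel_size, time = time,
         origin = origin, cells = cells, flagged = flagged),
    class = "colony_frame"
  )
}

#' @export
print.colony_frame <- function(x, ...) {
  cat(sprintf(
    "<colony_frame> t = %s min, %d cells, %d x %d px @ %.3g um/px%s\n",
    format(x$time), length(setdiff(unique(as.vector(x$mask)), 0)),
    nrow(x$mask), ncol(x$mask), x$pixel_size,
    if (isTRUE(x$flagged)) " [flagged]" else ""
  ))
  invisible(x)
}

#' Analytic director field with a planted topological defect
#'
#' Builds the orientation field Phi(x, y) = q * atan2(y - y0, x - x0) +
#' phase, wrapped to the nematic range. Serves as ground truth for the
#' winding-number charge detector.
#'
#' @param charge half-integer defect charge (0 gives a uniform field).
#' @param core (x, y) core position in 0-based pixels.
#' @param phase constant phase offset (rad).
#' @param shape field dimensions in pixels, `c(nx, ny)`.
#' @param pixel_size um per pixel for the resulting field.
#' @return an `orientation_field` (core pixel masked invalid).
#' @export
make_defect_field <- function(charge, core, phase = 0, shape = c(128, 128),
                              pixel_size = 0.1) {
  if (abs(charge * 2 - round(charge * 2)) > 1e-9) {
    stop("charge must be a half-integer")
  }
  if (core[1] < 0 || core[1] > shape[1] - 1 ||
      core[2] < 0 || core[2] > shape[2] - 1) {
    stop("defect core lies outside the field")
  }
  x <- matrix(rep(0:(shape[1] - 1), shape[2]), shape[1], shape[2])
  y <- matrix(rep(0:(shape[2] - 1), each = shape[1]), shape[1], shape[2])
  phi <- wrap_nematic(charge * atan2(y - core[2], x - core[1]) + phase)
  valid <- matrix(TRUE, shape[1], shape[2])
  ci <- round(core[1]) + 1
  cj <- round(core[2]) + 1
  valid[ci, cj] <- FALSE
  orientation_field(phi, valid, pixel_size)
}

#' Two-colour point patterns for entropy fixtures
#'
#' Places `n` points uniformly in a disc and assigns chain labels 1/2 as a
#' half-plane split (`demixed`), a random balanced permutation (`random`)
#' or alternating vertical stripes (`striped`). Positions are identical
#' across layouts for a given seed, so entropy differences reflect labels
#' only.
#'
#' @param n number of points (>= 2).
#' @param layout one of "demixed", "random", "striped".
#' @param seed RNG seed.
#' @param radius disc radius (um); default packs ~2 um^2 per cell.
#' @param stripe_width stripe period control for `striped` (um).
#' @return a `colony_frame` without a mask (`cells` has x, y, chain).
#' @export
make_two_color_pattern <- function(n, layout = c("demixed", "random", "striped"),
                                   seed = 1, radius = sqrt(2 * n / pi),
                                   stripe_width = radius / 3) {
  stopifnot(n >= 2)
  layout <- match.arg(layout)
  set.seed(seed)
  r <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  x <- r * cos(th)
  y <- r * sin(th)
  chain <- integer(n)
  half <- rep(1:2, length.out = n)
  if (layout == "demixed") {
    chain[order(x)] <- sort(half)
  } else if (layout == "random") {
    chain <- sample(half)
  } else {
    chain <- 1L + (floor((x + radius) / stripe_width) %% 2L)
  }
  colony_frame(
    mask = matrix(0L, 1, 1), pixel_size = 1, time = NA_real_,
    cells = data.frame(label = seq_len(n), x = x, y = y, chain = chain)
  )
}
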