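#' Draw photobleaching-limited track lengths
#'
#' Observed track durations are modelled as geometric: an active emitter
#' survives to the next frame with probability `survival_prob`, so
#' `P(L = k) = (1 - q) q^(k-1)` for `k >= 1` and `E[L] = 1/(1 - q)`. The
#' default acquisition value `q = 0.6` gives a mean duration of 2.5 frames
#' and a `>= 5`-frame tail of `q^4 = 0.1296`.
#'
#' @param n Number of lengths to draw.
#' @param survival_prob Per-frame survival probability `q` in `[0, 1)`.
#' @return Integer vector of track lengths in frames, each `>= 1`.
#' @export
#' @examples
#' set.seed(1)
#' mean(sample_track_length(1e4, 0.6)) # close to 2.5
sample_track_length <- function(n, survival_prob) {
  if (!is.numeric(survival_prob) || length(survival_prob) != 1L ||
      is.na(survival_prob) || survival_prob < 0 || survival_prob >= 1) {
    stop("`survival_prob` must be a single value in [0, 1)", call. = FALSE)
  }
  rgeom(n, prob = 1 - survival_prob) + 1L
}

#' Test whether points lie inside the cell outline
#'
#' The cell outline is a 2-D spherocylinder centred at the origin with its
#' long axis along x: all points within `radius` of the axis segment
#' `[-length/2, length/2] x {0}`.
#'
#' @param xy Two-column matrix of points (um, cell-local coordinates).
#' @param geometry A [cell_geometry()].
#' @param tol Numerical slack on the boundary, um.
#' @return Logical vector.
#' @export
in_spherocylinder <- function(xy, geometry, tol = 1e-12) {
  xy <- as_xy_matrix(xy)
  hl <- geometry$length / 2
  cx <- pmin(pmax(xy[, 1L], -hl), hl)
  sqrt((xy[, 1L] - cx)^2 + xy[, 2L]^2) <= geometry$radius + tol
}

#' Reflect points at the cell boundary
#'
#' Points outside the spherocylinder are mirrored across the nearest boundary
#' (the flat wall in the cylindrical section, the cap circle at the poles),
#' iterating until they fall inside. Points already inside are returned
#' unchanged. A point slightly outside the side wall at distance `d` from the
#' axis comes back at distance `2 * radius - d`.
#'
#' @param xy Two-column matrix (or length-2 vector) of points, cell-local um.
#' @param geometry A [cell_geometry()].
#' @return Matrix of the same shape with every point inside the geometry.
#' @export
reflect_at_boundary <- function(xy, geometry) {
  xy <- as_xy_matrix(xy)
  x <- xy[, 1L]
  y <- xy[, 2L]
  hl <- geometry$length / 2
  r <- geometry$radius
  for (iter in 1:100) {
    cx <- pmin(pmax(x, -hl), hl)
    dx <- x - cx
    d <- sqrt(dx^2 + y^2)
    out <- which(d > r)
    if (length(out) == 0L) break
    sc <- (2 * r - d[out]) / d[out]
    x[out] <- cx[out] + dx[out] * sc
    y[out] <- y[out] * sc
  }
  if (length(out) > 0L) {
    # pathological leftovers (step >> cell size): clamp onto the boundary
    cx <- pmin(pmax(x, -hl), hl)
    dx <- x - cx
    d <- pmax(sqrt(dx^2 + y^2), .Machine$double.eps)
    bad <- which(d > r)
    x[bad] <- cx[bad] + dx[bad] * (r / d[bad])
    y[bad] <- y[bad] * (r / d[bad])
  }
  cbind(x_um = x, y_um = y)
}

#' Simulate a PALM single-molecule-tracking movie
#'
#' Generates a synthetic localization table with the statistical structure of
#' a sparse photoactivation experiment, together with the ground truth needed
#' to validate downstream linking and mixture fitting. Each emitter is
#' assigned a cell, a diffusive species (by occupancy), a uniformly random
#' activation frame, and a geometric lifetime ([sample_track_length()]). Its
#' true position starts uniformly inside the cell and evolves by 2-D Brownian
#' steps with per-axis standard deviation `sqrt(2 * D * frame_interval)`,
#' reflected at the cell boundary ([reflect_at_boundary()]). Reported
#' positions add isotropic Gaussian localization noise.
#'
#' Cells are laid out along x with a pitch wide enough that localizations
#' from different cells can never be confused by the linker.
#'
#' @param acq An [acquisition_config()].
#' @param species A [species_set()].
#' @param geometry A [cell_geometry()].
#' @param seed Integer seed; defaults to `acq$rng_seed`. The same seed and
#'   configuration reproduce the output exactly.
#'
#' @return An object of class `spt_simulation`: a list with
#' \describe{
#'   \item{localizations}{`data.frame` with `frame` (0-based), `cell_id`,
#'     `x_um`, `y_um`, `sigma_um` and the ground-truth `emitter_id`, sorted
#'     by frame then cell.}
#'   \item{truth}{per-emitter `data.frame`: `emitter_id`, `species_index`,
#'     `cell_id`, `activation_frame`, `bleach_frame` (last visible frame).}
#'   \item{truth_positions}{true (noise-free) positions per emitter and
#'     frame.}
#' }
#' @export
#' @examples
#' sim <- simulate_movie(
#'   acquisition_config(n_frames = 200, rng_seed = 1),
#'   species_set(c(0.11, 0.41, 1.24), c(0.16, 0.42, 0.42)),
#'   cell_geometry(n_cells = 5)
#' )
#' head(sim$localizations)
simulate_movie <- function(acq, species, geometry, seed = acq$rng_seed) {
  stopifnot(inherits(acq, "acquisition_config"),
            inherits(geometry, "cell_geometry"))
  if (!inherits(species, "species_set")) {
    stop("`species` must be a species_set()", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  n_cells <- geometry$n_cells
  pitch <- cell_pitch(geometry)
  n_per_cell <- rpois(n_cells, acq$activations_per_cell_per_frame * acq$n_frames)
  n_emit <- sum(n_per_cell)
  if (n_emit == 0L) {
    stop("no emitters activated; increase `activations_per_cell_per_frame`, ",
         "`n_frames` or `n_cells`", call. = FALSE)
  }

  cell <- rep.int(seq_len(n_cells), n_per_cell)
  sp <- sample.int(nrow(species), n_emit, replace = TRUE, prob = species$occupancy)
  activation <- sample.int(acq$n_frames, n_emit, replace = TRUE) - 1L
  lifetime <- sample_track_length(n_emit, acq$survival_prob)
  obs_len <- pmin(lifetime, acq$n_frames - activation)

  # initial positions: uniform inside the spherocylinder (rejection sampling)
  hl <- geometry$length / 2
  r <- geometry$radius
  x0 <- numeric(n_emit)
  y0 <- numeric(n_emit)
  need <- seq_len(n_emit)
  while (length(need) > 0L) {
    px <- runif(length(need), -hl - r, hl + r)
    py <- runif(length(need), -r, r)
    ok <- in_spherocylinder(cbind(px, py), geometry)
    x0[need[ok]] <- px[ok]
    y0[need[ok]] <- py[ok]
    need <- need[!ok]
  }

  step_sd <- sqrt(2 * species$d[sp] * acq$frame_interval)
  max_len <- max(obs_len)
  X <- matrix(NA_real_, n_emit, max_len)
  Y <- matrix(NA_real_, n_emit, max_len)
  X[, 1L] <- x0
  Y[, 1L] <- y0
  if (max_len > 1L) {
    for (t in 2:max_len) {
      alive <- which(obs_len >= t)
      if (length(alive) == 0L) break
      p <- reflect_at_boundary(
        cbind(X[alive, t - 1L] + rnorm(length(alive), 0, step_sd[alive]),
              Y[alive, t - 1L] + rnorm(length(alive), 0, step_sd[alive])),
        geometry
      )
      X[alive, t] <- p[, 1L]
      Y[alive, t] <- p[, 2L]
    }
  }

  i <- rep.int(seq_len(n_emit), obs_len)
  j <- sequence(obs_len)
  frame <- activation[i] + j - 1L
  tx <- X[cbind(i, j)] + (cell[i] - 1L) * pitch
  ty <- Y[cbind(i, j)]
  n_loc <- length(i)
  obs_x <- tx + rnorm(n_loc, 0, acq$localization_sigma)
  obs_y <- ty + rnorm(n_loc, 0, acq$localization_sigma)

  ord <- order(frame, cell[i], i)
  locs <- data.frame(
    frame = frame[ord],
    cell_id = cell[i][ord],
    x_um = obs_x[ord],
    y_um = obs_y[ord],
    sigma_um = acq$localization_sigma,
    emitter_id = i[ord]
  )
  truth <- data.frame(
    emitter_id = seq_len(n_emit),
    species_index = sp,
    cell_id = cell,
    activation_frame = activation,
    bleach_frame = activation + obs_len - 1L
  )
  truth_positions <- data.frame(
    emitter_id = i, frame = frame, x_um = tx, y_um = ty
  )

  structure(
    list(localizations = locs, truth = truth,
         truth_positions = truth_positions,
         acquisition = acq, species = species, geometry = geometry),
    class = "spt_simulation"
  )
}

#' Simulate tracks directly (no movie, no linking)
#'
#' Convenience generator for distributional work: draws `n_tracks` tracks of
#' exactly `n_steps` steps, each from a species chosen by occupancy, with
#' free 2-D Brownian motion (or confined motion when a `geometry` is given)
#' and optional localization noise. With `localization_sigma = 0` and no
#' geometry, the resulting per-track `D*` values follow the closed-form gamma
#' law of [dstar_density()] exactly, which makes this the generator of choice
#' for mixture-fit calibration.
#'
#' @param n_tracks Number of tracks.
#' @param species A [species_set()].
#' @param n_steps Steps per track (each track has `n_steps + 1` positions).
#' @param frame_interval Frame interval, seconds.
#' @param localization_sigma Localization noise sd, um (default 0).
#' @param geometry Optional [cell_geometry()]; `NULL` (default) means
#'   unconfined motion started at the origin.
#' @param seed Optional integer seed.
#'
#' @return A track table (`track_id`, `cell_id`, `frame`, `x_um`, `y_um`)
#'   with the ground-truth species of each track in
#'   `attr(, "species_index")`.
#' @export
simulate_tracks <- function(n_tracks, species, n_steps = 4L,
                            frame_interval = 0.015,
                            localization_sigma = 0,
                            geometry = NULL, seed = NULL) {
  if (!inherits(species, "species_set")) {
    stop("`species` must be a species_set()", call. = FALSE)
  }
  stopifnot(n_tracks >= 1, n_steps >= 1, frame_interval > 0,
            localization_sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  n_tracks <- as.integer(n_tracks)
  n_steps <- as.integer(n_steps)
  n_pos <- n_steps + 1L

  sp <- sample.int(nrow(species), n_tracks, replace = TRUE,
                   prob = species$occupancy)
  step_sd <- sqrt(2 * species$d[sp] * frame_interval)

  if (is.null(geometry)) {
    dx <- matrix(rnorm(n_tracks * n_steps, 0, step_sd), n_tracks, n_steps)
    dy <- matrix(rnorm(n_tracks * n_steps, 0, step_sd), n_tracks, n_steps)
    X <- matrix(0, n_tracks, n_pos)
    Y <- matrix(0, n_tracks, n_pos)
    for (t in 2:n_pos) {
      X[, t] <- X[, t - 1L] + dx[, t - 1L]
      Y[, t] <- Y[, t - 1L] + dy[, t - 1L]
    }
  } else {
    stopifnot(inherits(geometry, "cell_geometry"))
    X <- matrix(NA_real_, n_tracks, n_pos)
    Y <- matrix(NA_real_, n_tracks, n_pos)
    hl <- geometry$length / 2
    r <- geometry$radius
    need <- seq_len(n_tracks)
    while (length(need) > 0L) {
      px <- runif(length(need), -hl - r, hl + r)
      py <- runif(length(need), -r, r)
      ok <- in_spherocylinder(cbind(px, py), geometry)
      X[need[ok], 1L] <- px[ok]
      Y[need[ok], 1L] <- py[ok]
      need <- need[!ok]
    }
    for (t in 2:n_pos) {
      p <- reflect_at_boundary(
        cbind(X[, t - 1L] + rnorm(n_tracks, 0, step_sd),
              Y[, t - 1L] + rnorm(n_tracks, 0, step_sd)),
        geometry
      )
      X[, t] <- p[, 1L]
      Y[, t] <- p[, 2L]
    }
  }

  if (localization_sigma > 0) {
    X <- X + rnorm(length(X), 0, localization_sigma)
    Y <- Y + rnorm(length(Y), 0, localization_sigma)
  }

  tracks <- data.frame(
    track_id = rep(seq_len(n_tracks), each = n_pos),
    cell_id = 1L,
    frame = rep.int(0:n_steps, n_tracks),
    x_um = as.vector(t(X)),
    y_um = as.vector(t(Y))
  )
  attr(tracks, "species_index") <- sp
  tracks
}

# cell centres are spaced along x by this pitch (um); generous so that
# linking can never jump between cells even without the cell-id restriction
cell_pitch <- function(geometry) {
  geometry$length + 2 * geometry$radius + 2
}

as_xy_matrix <- function(xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2L)
  if (ncol(xy) != 2L) stop("`xy` must have two columns", call. = FALSE)
  xy
}
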