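#' Apparent diffusion coefficient of a single track
#'
#' Computes `D* = MSD / (4 * frame_interval)` where MSD is the mean of the
#' squared displacements over exactly the first `n_steps` consecutive-frame
#' steps of the track, regardless of how long the track is. Using a fixed
#' step count keeps the sampling distribution of `D*` identical across
#' tracks, which is what the gamma mixture model assumes.
#'
#' @param track A single track: `data.frame` with columns `frame`, `x_um`,
#'   `y_um` ordered by frame.
#' @param frame_interval Frame interval `dt`, seconds.
#' @param n_steps Number of steps used (default 4).
#'
#' @return A one-row `data.frame` with `track_id` (if present in the input),
#'   `d_star_um2_s` and `n_steps`.
#' @export
#' @examples
#' trk <- data.frame(
#'   frame = 0:4,
#'   x_um = c(0, 0.1, 0.1, 0, 0),
#'   y_um = c(0, 0, 0.1, 0.1, 0)
#' )
#' compute_dstar(trk, frame_interval = 0.015) # D* = 0.01 / (4 * 0.015)
compute_dstar <- function(track, frame_interval, n_steps = 4L) {
  stopifnot(frame_interval > 0, n_steps >= 1)
  if (nrow(track) < n_steps + 1L) {
    stop("track has ", nrow(track), " localizations; need at least ",
         n_steps + 1L, call. = FALSE)
  }
  f <- track$frame[seq_len(n_steps + 1L)]
  if (any(diff(f) != 1L)) {
    stop("the first ", n_steps, " steps must span consecutive frames",
         call. = FALSE)
  }
  dx <- diff(track$x_um[seq_len(n_steps + 1L)])
  dy <- diff(track$y_um[seq_len(n_steps + 1L)])
  msd <- mean(dx^2 + dy^2)
  data.frame(
    track_id = if ("track_id" %in% names(track)) track$track_id[1L] else NA_integer_,
    d_star_um2_s = msd / (4 * frame_interval),
    n_steps = as.integer(n_steps)
  )
}

#' Apparent diffusion coefficients for a track table
#'
#' Vectorized version of [compute_dstar()] for a whole track table. All
#' tracks must have at least `n_steps + 1` localizations (apply
#' [filter_tracks_min_steps()] first) and consecutive frames over the steps
#' used.
#'
#' @param tracks Track table (`track_id`, `frame`, `x_um`, `y_um`, grouped by
#'   track, frames increasing within track).
#' @param frame_interval Frame interval, seconds.
#' @param n_steps Steps used per track (default 4).
#'
#' @return `data.frame` with one row per track: `track_id`, `d_star_um2_s`,
#'   `n_steps`.
#' @export
compute_dstars <- function(tracks, frame_interval, n_steps = 4L) {
  stopifnot(frame_interval > 0, n_steps >= 1)
  n_steps <- as.integer(n_steps)
  if (nrow(tracks) == 0L) {
    return(data.frame(track_id = integer(0), d_star_um2_s = numeric(0),
                      n_steps = integer(0)))
  }
  id <- tracks$track_id
  first <- !duplicated(id)
  sizes <- rle(cumsum(first))$lengths # run lengths per track, input order
  if (any(sizes < n_steps + 1L)) {
    stop(sum(sizes < n_steps + 1L), " track(s) have fewer than ",
         n_steps + 1L, " localizations; run filter_tracks_min_steps() first",
         call. = FALSE)
  }
  pos_in_track <- sequence(sizes)
  use <- pos_in_track <= n_steps + 1L
  f <- tracks$frame[use]
  xx <- tracks$x_um[use]
  yy <- tracks$y_um[use]
  uid <- id[use]
  step_row <- which(pos_in_track[use] > 1L)
  if (any(f[step_row] - f[step_row - 1L] != 1L)) {
    stop("tracks must have consecutive frames over the first ", n_steps,
         " steps", call. = FALSE)
  }
  sq <- (xx[step_row] - xx[step_row - 1L])^2 + (yy[step_row] - yy[step_row - 1L])^2
  msd <- as.vector(rowsum(sq, group = uid[step_row], reorder = FALSE)) / n_steps
  data.frame(
    track_id = id[first],
    d_star_um2_s = msd / (4 * frame_interval),
    n_steps = n_steps
  )
}

#' Sampling density of the apparent diffusion coefficient
#'
#' For a single species with true (apparent) mobility `d`, each squared
#' single-frame displacement divided by `4 dt` is exponential with mean `d`,
#' so the mean over `n_steps` steps follows a gamma law with shape `n_steps`
#' and scale `d / n_steps`:
#' \deqn{f(x) = \frac{(n/d)^n x^{n-1} e^{-n x / d}}{(n-1)!}.}
#' The density integrates to 1 and has mean `d` and variance `d^2 / n`.
#'
#' @param x Evaluation points, um^2/s (`>= 0`).
#' @param d Species mobility, um^2/s (`> 0`).
#' @param n_steps Number of steps `n` used in each `D*`.
#' @return Density values at `x`.
#' @export
#' @examples
#' integrate(dstar_density, 0, Inf, d = 0.41, n_steps = 4)
dstar_density <- function(x, d, n_steps = 4L) {
  if (!(is.numeric(d) && length(d) == 1L && d > 0)) {
    stop("`d` must be a single value > 0", call. = FALSE)
  }
  if (!(n_steps >= 1)) stop("`n_steps` must be >= 1", call. = FALSE)
  if (any(x < 0)) stop("`x` must be >= 0", call. = FALSE)
  dgamma(x, shape = n_steps, scale = d / n_steps)
}

#' Classify apparent diffusion coefficients into mobility classes
#'
#' Strictly below `immobile_max` is `"immobile"`, strictly above `fast_min`
#' is `"fast"`, everything else (boundary values included) is `"slow"`.
#'
#' @param d_star Numeric vector of apparent diffusion coefficients, um^2/s.
#' @param thresholds A [classification_thresholds()].
#' @return Factor with levels `immobile`, `slow`, `fast`.
#' @export
#' @examples
#' classify_dstar(c(0.11, 0.2, 2.0), classification_thresholds())
classify_dstar <- function(d_star, thresholds = classification_thresholds()) {
  stopifnot(inherits(thresholds, "classification_thresholds"))
  out <- rep("slow", length(d_star))
  out[d_star < thresholds$immobile_max] <- "immobile"
  out[d_star > thresholds$fast_min] <- "fast"
  factor(out, levels = c("immobile", "slow", "fast"))
}
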