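#' Link localizations into tracks
#'
#' Conservative frame-to-frame linking for sparse PALM data: for each pair of
#' (gap-adjacent) frames, a localization is linked to a candidate only if the
#' two are mutual nearest neighbours and closer than the displacement gate
#' (`max_displacement` per frame of separation). Each localization joins at
#' most one track; localizations that never link are discarded, so every
#' returned track has at least two localizations. With
#' `restrict_to_cell = TRUE`, links never cross cell boundaries. Ties at
#' identical distance are broken towards the lower input row, making the
#' procedure deterministic.
#'
#' @param locs Localization table with columns `frame`, `cell_id`, `x_um`,
#'   `y_um`, sorted by frame (non-decreasing); extra columns are ignored.
#' @param cfg A [linking_config()].
#'
#' @return Track table: `data.frame` with `track_id` (1..n, in order of
#'   first appearance), `cell_id`, `frame`, `x_um`, `y_um`, grouped by track
#'   and ordered by frame within each track.
#' @seealso [filter_tracks_min_steps()], [compute_dstars()]
#' @export
link_localizations <- function(locs, cfg = linking_config()) {
  stopifnot(inherits(cfg, "linking_config"))
  need <- c("frame", "cell_id", "x_um", "y_um")
  missing_cols <- setdiff(need, names(locs))
  if (length(missing_cols) > 0L) {
    stop("localization table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(locs)
  if (n == 0L) {
    return(empty_track_table())
  }
  frame <- as.integer(locs$frame)
  if (is.unsorted(frame)) {
    stop("localizations must be sorted by frame", call. = FALSE)
  }
  x <- locs$x_um
  y <- locs$y_um
  cell <- locs$cell_id
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("localization coordinates must be finite", call. = FALSE)
  }

  track_of <- integer(n) # 0 = unassigned
  n_tracks <- 0L

  frames <- sort(unique(frame))
  rows_by_frame <- split(seq_len(n), factor(frame, levels = frames))

  # open tails: row index and frame of the last localization of each
  # growing (or not-yet-started) chain
  tail_row <- integer(0)
  tail_frame <- integer(0)

  for (fi in seq_along(frames)) {
    f <- frames[fi]
    cur <- rows_by_frame[[fi]]

    keep <- tail_frame >= f - 1L - cfg$max_gap & tail_frame < f
    cand <- tail_row[keep]
    cand_frame <- tail_frame[keep]
    matched_tail <- logical(length(cand))
    matched_cur <- logical(length(cur))

    if (length(cand) > 0L && length(cur) > 0L) {
      d2 <- outer(x[cand], x[cur], "-")^2 + outer(y[cand], y[cur], "-")^2
      gate <- cfg$max_displacement * (f - cand_frame) # per-row gate, um
      d2[d2 > gate^2] <- Inf
      if (cfg$restrict_to_cell) {
        same <- outer(cell[cand], cell[cur], "==")
        d2[!same] <- Inf
      }
      if (any(is.finite(d2))) {
        # mutual nearest neighbours; which.min / max.col(first) break ties
        # towards the lower row index because rows are in input order
        nn_of_tail <- apply(d2, 1L, which.min)
        nn_of_cur <- apply(d2, 2L, which.min)
        for (a in seq_along(cand)) {
          b <- nn_of_tail[a]
          if (is.finite(d2[a, b]) && nn_of_cur[b] == a) {
            ta <- cand[a]
            if (track_of[ta] == 0L) {
              n_tracks <- n_tracks + 1L
              track_of[ta] <- n_tracks
            }
            track_of[cur[b]] <- track_of[ta]
            matched_tail[a] <- TRUE
            matched_cur[b] <- TRUE
          }
        }
      }
    }

    # tails that matched are replaced by their continuation; unmatched tails
    # survive only while a gap link is still possible
    drop <- keep
    drop[keep] <- matched_tail | (cand_frame < f - cfg$max_gap)
    stale <- !keep & tail_frame < f - cfg$max_gap & tail_frame < f
    retain <- !(drop | stale)
    tail_row <- c(tail_row[retain], cur)
    tail_frame <- c(tail_frame[retain], rep.int(f, length(cur)))
  }

  assigned <- which(track_of > 0L)
  if (length(assigned) == 0L) {
    return(empty_track_table())
  }
  ord <- assigned[order(track_of[assigned], frame[assigned])]
  ids <- track_of[ord]
  data.frame(
    track_id = match(ids, unique(ids)),
    cell_id = cell[ord],
    frame = frame[ord],
    x_um = x[ord],
    y_um = y[ord]
  )
}

#' Keep tracks with a minimum number of steps
#'
#' A track with `m` localizations has `m - 1` steps; only tracks with at
#' least `min_steps` steps (the conventional cut is 4, i.e. at least 5
#' localizations) enter the diffusion analysis. Order is preserved.
#'
#' @param tracks Track table (see [link_localizations()]).
#' @param min_steps Minimum step count, `>= 1`.
#' @return The filtered track table.
#' @export
filter_tracks_min_steps <- function(tracks, min_steps = 4L) {
  if (!(min_steps >= 1)) stop("`min_steps` must be >= 1", call. = FALSE)
  if (nrow(tracks) == 0L) return(tracks)
  sizes <- table(tracks$track_id)
  keep_ids <- names(sizes)[sizes - 1L >= min_steps]
  out <- tracks[as.character(tracks$track_id) %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_track_table <- function() {
  data.frame(
    track_id = integer(0), cell_id = integer(0), frame = integer(0),
    x_um = numeric(0), y_um = numeric(0)
  )
}
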