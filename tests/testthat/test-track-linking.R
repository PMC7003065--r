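test_that("a lone emitter yields exactly one track with all its localizations", {
  locs <- data.frame(
    frame = 0:5, cell_id = 1L,
    x_um = c(0, 0.05, 0.1, 0.12, 0.2, 0.25),
    y_um = c(0, 0.02, 0.05, 0.01, 0.0, -0.04),
    sigma_um = 0.035
  )
  tr <- link_localizations(locs)
  expect_equal(length(unique(tr$track_id)), 1L)
  expect_equal(nrow(tr), 6L)
  expect_equal(tr$frame, 0:5)
})

test_that("well-separated emitters never cross-link", {
  # two emitters in one cell, always > 2 * max_displacement apart
  locs <- data.frame(
    frame = rep(0:4, each = 2),
    cell_id = 1L,
    x_um = rep(c(0, 5), 5) + rnorm(10, 0, 0.05),
    y_um = rep(c(0, 0), 5),
    sigma_um = 0.035
  )
  locs <- locs[order(locs$frame), ]
  tr <- link_localizations(locs, linking_config(max_displacement = 0.9))
  expect_equal(length(unique(tr$track_id)), 2L)
  by_track <- split(tr$x_um, tr$track_id)
  expect_true(all(vapply(by_track, function(x) diff(range(x)) < 1, logical(1))))
})

test_that("linking recovers ground-truth tracks in the sparse regime", {
  # truly sparse activation: chance handovers (one emitter bleaching while
  # another activates nearby a frame later) are negligible and essentially
  # every recovered track is one complete emitter track
  acq <- acquisition_config(n_frames = 3000,
                            activations_per_cell_per_frame = 0.002,
                            rng_seed = 13)
  sim <- simulate_movie(acq, uvrb_species(0.16), cell_geometry(n_cells = 200))
  tr <- link_localizations(sim$localizations)
  ok <- match_tracks_to_truth(tr, sim)
  expect_gt(length(ok), 300) # enough tracks for the rate to mean something
  expect_gte(mean(ok), 0.99)

  # at the default density, indistinguishable bleach/activation handovers
  # chain about 1.5% of tracks (activation rate x gate area, both track
  # ends); recovery stays above 97%
  acq2 <- acquisition_config(n_frames = 3000, rng_seed = 13)
  sim2 <- simulate_movie(acq2, uvrb_species(0.16), cell_geometry(n_cells = 40))
  ok2 <- match_tracks_to_truth(link_localizations(sim2$localizations), sim2)
  expect_gte(mean(ok2), 0.97)
})

test_that("linking partitions localizations and respects the gate", {
  acq <- acquisition_config(n_frames = 1000, rng_seed = 17)
  sim <- simulate_movie(acq, uvrb_species(0.35), cell_geometry(n_cells = 20))
  cfg <- linking_config(max_displacement = 0.5)
  tr <- link_localizations(sim$localizations, cfg)

  # each localization used at most once, never more output than input
  expect_lte(nrow(tr), nrow(sim$localizations))
  key <- paste(tr$frame, tr$x_um, tr$y_um)
  expect_false(any(duplicated(key)))

  # every track has >= 2 localizations, strictly increasing frames
  sizes <- table(tr$track_id)
  expect_true(all(sizes >= 2L))
  incr <- tapply(tr$frame, tr$track_id, function(f) all(diff(f) > 0))
  expect_true(all(incr))

  # no linked step exceeds the displacement gate
  within <- diff(tr$track_id) == 0L
  step <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)[within]
  expect_true(all(step <= cfg$max_displacement))

  # links never join different cells
  expect_true(all(tapply(tr$cell_id, tr$track_id,
                         function(cc) length(unique(cc)) == 1L)))
})

test_that("mutual-nearest-neighbour linking matches exhaustive assignment on sparse frames", {
  set.seed(29)
  gate <- 0.9
  for (case in 1:40) {
    n_pts <- sample(2:6, 1)
    # emitters separated by at least 2 * gate, plus small per-frame motion:
    # the sparse regime the linker is designed for
    base <- cbind(runif(n_pts, 0, 40), runif(n_pts, 0, 40))
    while (n_pts > 1 && min(dist(base)) < 2 * gate) {
      base <- cbind(runif(n_pts, 0, 40), runif(n_pts, 0, 40))
    }
    a <- base + matrix(rnorm(2 * n_pts, 0, 0.15), n_pts, 2)
    b <- base + matrix(rnorm(2 * n_pts, 0, 0.15), n_pts, 2)
    locs <- data.frame(
      frame = rep(0:1, each = n_pts),
      cell_id = 1L,
      x_um = c(a[, 1], b[, 1]),
      y_um = c(a[, 2], b[, 2])
    )
    tr <- link_localizations(locs, linking_config(max_displacement = gate,
                                                  restrict_to_cell = FALSE))
    got <- if (nrow(tr) > 0) {
      cbind(match(tr$x_um[tr$frame == 0], a[, 1]),
            match(tr$x_um[tr$frame == 1], b[, 1]))
    } else {
      matrix(integer(0), ncol = 2)
    }
    want <- brute_assignment(a, b, gate)
    expect_equal(got[order(got[, 1]), , drop = FALSE],
                 want[order(want[, 1]), , drop = FALSE],
                 ignore_attr = TRUE)
  }
})

test_that("unsorted or malformed localization input is rejected", {
  locs <- data.frame(frame = c(2, 0, 1), cell_id = 1L,
                     x_um = c(0, 0, 0), y_um = c(0, 0, 0))
  expect_error(link_localizations(locs), "sorted")
  expect_error(
    link_localizations(data.frame(frame = 0, x_um = 0, y_um = 0)),
    "cell_id"
  )
  locs2 <- data.frame(frame = c(0, 1), cell_id = 1L,
                      x_um = c(0, NaN), y_um = c(0, 0))
  expect_error(link_localizations(locs2), "finite")
})

test_that("minimum-step filter keeps exactly the tracks with enough steps", {
  tracks <- data.frame(
    track_id = rep(c(1L, 2L, 3L), times = c(5L, 2L, 6L)),
    cell_id = 1L,
    frame = c(0:4, 0:1, 0:5),
    x_um = 0, y_um = 0
  )
  kept <- filter_tracks_min_steps(tracks, min_steps = 4)
  expect_setequal(unique(kept$track_id), c(1L, 3L))
  expect_equal(kept$track_id, c(rep(1L, 5), rep(3L, 6))) # order preserved

  expect_equal(nrow(filter_tracks_min_steps(tracks, min_steps = 6)), 0L)
  expect_error(filter_tracks_min_steps(tracks, min_steps = 0), "min_steps")
})

test_that("the kept fraction after the 4-step filter matches the geometric tail", {
  set.seed(37)
  L <- sample_track_length(1e5, 0.6)
  tracks <- data.frame(
    track_id = rep(seq_along(L), L),
    cell_id = 1L,
    frame = sequence(L) - 1L,
    x_um = 0, y_um = 0
  )
  kept <- filter_tracks_min_steps(tracks, 4)
  frac <- length(unique(kept$track_id)) / length(L)
  # P(L >= 5) for the geometric law with q = 0.6
  p_true <- 0.6^4
  se <- sqrt(p_true * (1 - p_true) / length(L))
  expect_lt(abs(frac - p_true), 3 * se)
})
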