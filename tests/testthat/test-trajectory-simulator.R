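test_that("track lengths follow the geometric bleaching law", {
  set.seed(11)
  L <- sample_track_length(1e5, 0.6)
  expect_true(all(L >= 1))

  # mean within 3 standard errors of 1/(1 - q)
  se <- sd(L) / sqrt(length(L))
  expect_lt(abs(mean(L) - 1 / (1 - 0.6)), 3 * se)

  # >= 5 frame tail matches the closed-form geometric tail q^4
  tail_hat <- mean(L >= 5)
  tail_true <- 0.6^4
  se_tail <- sqrt(tail_true * (1 - tail_true) / length(L))
  expect_lt(abs(tail_hat - tail_true), 3 * se_tail)

  # no survival: every track is a single frame
  expect_true(all(sample_track_length(1000, 0) == 1L))

  expect_error(sample_track_length(10, 1), "survival_prob")
  expect_error(sample_track_length(10, -0.1), "survival_prob")
})

test_that("boundary reflection is mirror-like and keeps walkers inside", {
  geo <- cell_geometry(length = 2, radius = 0.45)

  # interior points are untouched
  pts <- cbind(c(0, 0.9, -1.2), c(0, 0.3, 0.1))
  expect_equal(unname(reflect_at_boundary(pts, geo)), unname(pts))

  # just outside the side wall: comes back at 2 r - d from the axis
  p <- reflect_at_boundary(c(0.3, 0.47), geo)
  expect_equal(unname(p[1, 2]), 2 * 0.45 - 0.47, tolerance = 1e-12)
  expect_equal(unname(p[1, 1]), 0.3)

  # just outside a cap: reflected radially about the cap centre
  d0 <- 0.46
  p <- reflect_at_boundary(c(1 + d0, 0), geo)
  expect_equal(unname(p[1, 1]), 1 + (2 * 0.45 - d0), tolerance = 1e-12)

  # 1e5 random-walk steps all end up inside (checked with an independent
  # point-in-shape formula)
  set.seed(21)
  n <- 1e5
  xy <- matrix(0, n, 2)
  cur <- c(0, 0)
  steps <- matrix(rnorm(2 * n, 0, 0.25), n, 2)
  for (i in seq_len(n)) {
    cur <- reflect_at_boundary(cur + steps[i, ], geo)[1, ]
    xy[i, ] <- cur
  }
  expect_true(all(brute_inside(xy[, 1], xy[, 2], geo$length, geo$radius)))
  expect_true(all(in_spherocylinder(xy, geo)))
})

test_that("unconfined noise-free steps reproduce the 4 D dt law", {
  sp <- species_set(1.24, 1)
  tr <- simulate_tracks(1e4, sp, n_steps = 4, frame_interval = 0.015,
                        seed = 31)
  dx <- diff(tr$x_um)
  dy <- diff(tr$y_um)
  within <- diff(tr$track_id) == 0L
  sq <- (dx^2 + dy^2)[within]
  se <- sd(sq) / sqrt(length(sq))
  expect_lt(abs(mean(sq) - 4 * 1.24 * 0.015), 3 * se)
})

test_that("confinement can only shrink the mean squared step", {
  sp <- species_set(1.24, 1)
  geo <- cell_geometry(length = 2, radius = 0.45)
  tr <- simulate_tracks(5e3, sp, geometry = geo, seed = 32)
  dx <- diff(tr$x_um)
  dy <- diff(tr$y_um)
  within <- diff(tr$track_id) == 0L
  expect_lte(mean((dx^2 + dy^2)[within]), 4 * 1.24 * 0.015)
})

test_that("immobile noise-free emitters report constant positions", {
  acq <- acquisition_config(n_frames = 300, localization_sigma = 0,
                            rng_seed = 41)
  sim <- simulate_movie(acq, species_set(0, 1), cell_geometry(n_cells = 5))
  spread <- tapply(sim$localizations$x_um, sim$localizations$emitter_id,
                   function(v) diff(range(v)))
  expect_true(all(spread == 0))
})

test_that("the movie simulator is deterministic and keeps molecules in cells", {
  acq <- acquisition_config(n_frames = 500, rng_seed = 7)
  sp <- uvrb_species(0.16)
  geo <- cell_geometry(n_cells = 10)

  sim1 <- simulate_movie(acq, sp, geo)
  sim2 <- simulate_movie(acq, sp, geo)
  expect_identical(sim1$localizations, sim2$localizations)
  expect_identical(sim1$truth, sim2$truth)

  # true (noise-free) positions always inside their cell
  pitch <- geo$length + 2 * geo$radius + 2
  tp <- sim1$truth_positions
  cell <- sim1$truth$cell_id[match(tp$emitter_id, sim1$truth$emitter_id)]
  local_x <- tp$x_um - (cell - 1) * pitch
  expect_true(all(brute_inside(local_x, tp$y_um, geo$length, geo$radius)))

  # ground-truth bookkeeping invariants
  expect_true(all(sim1$truth$bleach_frame >= sim1$truth$activation_frame))
  expect_true(all(sim1$truth$species_index %in% seq_len(nrow(sp))))
  expect_true(all(sim1$localizations$frame >= 0 &
                    sim1$localizations$frame < acq$n_frames))
})

test_that("simulator rejects invalid parameters", {
  expect_error(acquisition_config(frame_interval = 0), "frame_interval")
  expect_error(acquisition_config(survival_prob = 1), "survival_prob")
  expect_error(species_set(c(0.1, 0.4), c(0.5, 0.6)), "sum to 1")
  expect_error(species_set(-0.1, 1), ">= 0")
  expect_error(cell_geometry(radius = 0), "radius")
  expect_error(
    simulate_movie(acquisition_config(), data.frame(d = 1, occupancy = 1),
                   cell_geometry()),
    "species_set"
  )
})
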