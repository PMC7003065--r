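test_that("a single-species fit recovers the true mobility within 5%", {
  tr <- simulate_tracks(1e4, species_set(0.41, 1), seed = 61)
  ds <- compute_dstars(tr, 0.015)
  fit <- fit_dstar_mixture(ds, k = 1, seed = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$species$d - 0.41) / 0.41, 0.05)
  expect_equal(fit$species$occupancy, 1)
})

test_that("the occupancy-only (fixed mobility) fit recovers occupancies within 0.02", {
  sp <- uvrb_species(0.35)
  tr <- simulate_tracks(2e4, sp, seed = 63)
  ds <- compute_dstars(tr, 0.015)
  fit <- fit_dstar_mixture(ds, k = 3, fixed_d = sp$d, seed = 2)
  expect_true(fit$converged)
  expect_equal(fit$species$d, sp$d) # mobilities untouched
  expect_true(all(abs(fit$species$occupancy - sp$occupancy) < 0.02))
})

test_that("EM log-likelihood is non-decreasing and the fit is well-formed", {
  tr <- simulate_tracks(5e3, uvrb_species(0.16), seed = 65)
  ds <- compute_dstars(tr, 0.015)
  fit <- fit_dstar_mixture(ds, k = 3, seed = 3)
  expect_true(fit$converged)
  expect_gte(min(diff(fit$ll_trace)), -1e-8 * (1 + abs(fit$log_likelihood)))
  expect_equal(sum(fit$species$occupancy), 1, tolerance = 1e-6)
  expect_true(all(diff(fit$species$d) > 0))
  expect_true(is.finite(fit$log_likelihood))
  expect_equal(fit$n_tracks, 5e3)
})

test_that("fits are stable under relabeling: different seeds agree on sorted parameters", {
  tr <- simulate_tracks(1e4, uvrb_species(0.16), seed = 67)
  ds <- compute_dstars(tr, 0.015)
  fits <- lapply(c(1, 7, 42), function(s) fit_dstar_mixture(ds, seed = s))
  for (f in fits[-1]) {
    expect_equal(f$species$d, fits[[1]]$species$d, tolerance = 1e-3)
    expect_equal(f$species$occupancy, fits[[1]]$species$occupancy,
                 tolerance = 1e-3)
  }
})

test_that("EM beats a coarse grid search on small two-species instances", {
  sp <- species_set(c(0.1, 1.0), c(0.4, 0.6))
  tr <- simulate_tracks(400, sp, seed = 69)
  x <- compute_dstars(tr, 0.015)$d_star_um2_s
  fit <- fit_dstar_mixture(x, k = 2, seed = 4)

  grid_d <- exp(seq(log(0.02), log(3), length.out = 15))
  grid_f <- seq(0.05, 0.95, by = 0.1)
  best_grid <- -Inf
  for (d1 in grid_d) for (d2 in grid_d) {
    if (d2 <= d1) next
    for (f1 in grid_f) {
      ll <- brute_mixture_loglik(x, c(d1, d2), c(f1, 1 - f1), 4)
      if (ll > best_grid) best_grid <- ll
    }
  }
  expect_gte(fit$log_likelihood, best_grid)
})

test_that("with localization noise the immobile mobility sits at the noise floor", {
  # truly bound molecules (D = 0) observed with 35 nm precision: the apparent
  # mobility approaches sigma^2 / dt
  tr <- simulate_tracks(5e3, species_set(0, 1), localization_sigma = 0.035,
                        seed = 71)
  ds <- compute_dstars(tr, 0.015)
  fit <- fit_dstar_mixture(ds, k = 1, seed = 5)
  floor <- 0.035^2 / 0.015
  expect_gt(fit$species$d, 0)
  expect_equal(fit$species$d, floor, tolerance = 0.05)
})

test_that("mixture input validation works", {
  expect_error(fit_dstar_mixture(runif(20), k = 3), "at least 30")
  expect_error(fit_dstar_mixture(c(-1, runif(50)), k = 1), "finite and >= 0")
  expect_error(fit_dstar_mixture(runif(50), k = 2, fixed_d = 1), "length k")
  expect_error(fit_dstar_mixture(data.frame(x = 1)), "d_star_um2_s")
})

test_that("immobile fraction: mixture occupancy and threshold counting", {
  # all-immobile population: both estimators say 100%
  tr <- simulate_tracks(600, species_set(0, 1), localization_sigma = 0.02,
                        seed = 73)
  ds <- compute_dstars(tr, 0.015)
  fit <- fit_dstar_mixture(ds, k = 1, seed = 6)
  expect_equal(immobile_fraction(fit), 100)
  expect_equal(immobile_fraction(ds, method = "threshold"), 100)

  expect_equal(immobile_fraction(c(0.05, 0.1, 0.5, 2), method = "threshold"), 50)

  # unconverged fits must not silently feed the mixture estimator
  bad <- fit
  bad$converged <- FALSE
  expect_error(immobile_fraction(bad), "threshold")
  expect_error(immobile_fraction(ds, method = "mixture"), "fit_dstar_mixture")
})

test_that("mixture and threshold estimators agree with ground truth on synthetic data", {
  sp <- uvrb_species(0.35)
  tr <- simulate_tracks(2e4, sp, seed = 75)
  ds <- compute_dstars(tr, 0.015)
  fit <- fit_dstar_mixture(ds, seed = 7)
  mix <- immobile_fraction(fit)
  thr <- immobile_fraction(ds, method = "threshold")
  expect_lt(abs(mix - 35), 3)
  expect_lt(abs(thr - 35), 6) # threshold counting is biased by species overlap
})
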