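# Shared fixtures and independent oracles used across the suite.

# The three UvrB-PAmCherry mobility states (um^2/s) with a chosen immobile
# occupancy; the remaining occupancy is split evenly between slow and fast.
uvrb_species <- function(immobile = 0.16) {
  rest <- (1 - immobile) / 2
  species_set(d = c(0.11, 0.41, 1.24), occupancy = c(immobile, rest, rest))
}

# Brute-force point-in-spherocylinder test, written independently of the
# package's clamp-based formula: inside the central rectangle, or inside one
# of the two cap disks.
brute_inside <- function(x, y, len, radius, tol = 1e-9) {
  hl <- len / 2
  in_rect <- abs(x) <= hl & abs(y) <= radius + tol
  in_cap1 <- (x - hl)^2 + y^2 <= (radius + tol)^2
  in_cap2 <- (x + hl)^2 + y^2 <= (radius + tol)^2
  in_rect | in_cap1 | in_cap2
}

# Exhaustive minimum-total-distance assignment between two point sets,
# links allowed only within `gate`. Returns a 2-column matrix of index pairs
# maximizing the number of links, breaking ties by total distance.
brute_assignment <- function(a, b, gate) {
  na <- nrow(a)
  nb <- nrow(b)
  d <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  feasible <- d <= gate
  best <- NULL
  best_links <- -1L
  best_cost <- Inf
  # enumerate all injective partial assignments of a -> b via recursion
  rec <- function(i, used, pairs, cost) {
    if (i > na) {
      nl <- if (is.null(pairs)) 0L else nrow(pairs)
      if (nl > best_links || (nl == best_links && cost < best_cost)) {
        best <<- pairs
        best_links <<- nl
        best_cost <<- cost
      }
      return(invisible())
    }
    rec(i + 1L, used, pairs, cost) # leave a_i unlinked
    for (j in seq_len(nb)) {
      if (!used[j] && feasible[i, j]) {
        used[j] <- TRUE
        rec(i + 1L, used, rbind(pairs, c(i, j)), cost + d[i, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1L, logical(nb), NULL, 0)
  if (is.null(best)) matrix(integer(0), ncol = 2L) else best
}

# Pooled two-sample t statistic and p value, written out longhand.
brute_pooled_t <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  t_stat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t_stat, df = na + nb - 2,
       p = 2 * stats::pt(-abs(t_stat), df = na + nb - 2))
}

# Kolmogorov-Smirnov distance between a sample and the gamma(shape n,
# scale d/n) law.
ks_distance_gamma <- function(x, d, n_steps) {
  x <- sort(x)
  n <- length(x)
  Fx <- stats::pgamma(x, shape = n_steps, scale = d / n_steps)
  max(pmax(abs(seq_len(n) / n - Fx), abs((seq_len(n) - 1) / n - Fx)))
}

# Log-likelihood of a gamma mixture, written out longhand (independent of
# the fitter's vectorized form).
brute_mixture_loglik <- function(x, d, f, n_steps) {
  dens <- vapply(x, function(xi) {
    sum(f * (n_steps / d)^n_steps * xi^(n_steps - 1) *
          exp(-n_steps * xi / d) / factorial(n_steps - 1))
  }, numeric(1))
  sum(log(dens))
}

# Map each recovered track to ground-truth emitters by exact coordinates;
# returns per-track logical "identical to one full emitter track".
match_tracks_to_truth <- function(tracks, sim) {
  locs <- sim$localizations
  key <- paste(locs$frame, locs$x_um, locs$y_um)
  emitter <- locs$emitter_id[match(paste(tracks$frame, tracks$x_um, tracks$y_um), key)]
  n_locs_per_emitter <- table(locs$emitter_id)
  vapply(split(emitter, tracks$track_id), function(e) {
    length(unique(e)) == 1L &&
      length(e) == n_locs_per_emitter[as.character(e[1L])]
  }, logical(1))
}
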