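#' Fit a gamma mixture of diffusive species to apparent diffusion coefficients
#'
#' Maximum-likelihood decomposition of a `D*` distribution into `k` discrete
#' diffusive species. Each species contributes a gamma density with shape
#' `n_steps` and scale `d_i / n_steps` (see [dstar_density()]); the model is
#' \deqn{p(x) = \sum_{i=1}^{k} f_i \, \mathrm{Gamma}(x;\, n, d_i/n),}
#' fitted by expectation-maximization. Both M-step updates are closed form:
#' occupancies are mean responsibilities and each mobility is the
#' responsibility-weighted mean of the data. When `fixed_d` is supplied the
#' mobilities are held at those values and only the occupancies are fitted
#' (the "constrained" fit used to compare a perturbed condition against
#' reference mobilities).
#'
#' The fit is multi-start: the first start places mobilities at evenly spaced
#' quantiles of the data with equal occupancies; the remaining starts draw
#' mobilities log-uniformly from `[0.01, 5]` um^2/s and occupancies from a
#' flat Dirichlet. The start with the best log-likelihood wins (ties by first
#' found). The run converges when the log-likelihood improvement stays below
#' `tol * (1 + |loglik|)` for 3 consecutive iterations; otherwise it stops at
#' `max_iter` with `converged = FALSE`.
#'
#' @param d_star Numeric vector of apparent diffusion coefficients (um^2/s),
#'   or the `data.frame` returned by [compute_dstars()]. Values must be
#'   `>= 0`; exact zeros are nudged to machine epsilon so the gamma density
#'   stays finite.
#' @param k Number of species (default 3).
#' @param n_steps Gamma shape: the number of steps each `D*` was computed
#'   from (default 4).
#' @param fixed_d Optional numeric vector of `k` mobilities to hold fixed.
#' @param n_starts Number of EM starts (default 10).
#' @param max_iter Maximum EM iterations per start.
#' @param tol Relative log-likelihood tolerance.
#' @param seed Optional integer seed for the randomized starts.
#'
#' @return An object of class `dstar_mixture_fit`: list with `species` (a
#'   `data.frame` of `d` and `occupancy`, ascending in `d`), `n_steps`,
#'   `log_likelihood`, `n_tracks`, `converged`, `fixed_d`, `n_iter`, and
#'   `ll_trace` (log-likelihood per iteration of the winning start).
#' @seealso [immobile_fraction()], [dstar_density()]
#' @export
#' @examples
#' trk <- simulate_tracks(2000, species_set(c(0.11, 1.24), c(0.5, 0.5)),
#'                        seed = 1)
#' ds <- compute_dstars(trk, frame_interval = 0.015)
#' fit_dstar_mixture(ds, k = 2, seed = 1)
fit_dstar_mixture <- function(d_star, k = 3L, n_steps = 4L, fixed_d = NULL,
                              n_starts = 10L, max_iter = 1000L, tol = 1e-8,
                              seed = NULL) {
  if (is.data.frame(d_star)) {
    if (!"d_star_um2_s" %in% names(d_star)) {
      stop("data.frame input must have a `d_star_um2_s` column", call. = FALSE)
    }
    d_star <- d_star$d_star_um2_s
  }
  stopifnot(k >= 1, n_steps >= 1, n_starts >= 1, max_iter >= 1, tol > 0)
  if (any(!is.finite(d_star)) || any(d_star < 0)) {
    stop("`d_star` values must be finite and >= 0", call. = FALSE)
  }
  n <- length(d_star)
  if (n < 10L * k) {
    stop("need at least ", 10L * k, " observations to fit ", k,
         " species; got ", n, call. = FALSE)
  }
  if (!is.null(fixed_d)) {
    if (length(fixed_d) != k) {
      stop("`fixed_d` must have length k = ", k, call. = FALSE)
    }
    if (any(fixed_d <= 0)) stop("`fixed_d` values must be > 0", call. = FALSE)
    fixed_d <- sort(as.numeric(fixed_d))
  }
  if (!is.null(seed)) set.seed(seed)

  x <- pmax(d_star, .Machine$double.eps)
  shape <- as.integer(n_steps)
  # per-observation part of the gamma log-density that does not depend on d
  lx_const <- (shape - 1) * log(x) - lgamma(shape) + shape * log(shape)

  best <- NULL
  for (s in seq_len(n_starts)) {
    if (!is.null(fixed_d)) {
      d <- fixed_d
      f <- if (s == 1L) rep(1 / k, k) else stats::runif(k)
    } else if (s == 1L) {
      d <- as.numeric(quantile(x, probs = (2 * seq_len(k) - 1) / (2 * k)))
      f <- rep(1 / k, k)
    } else {
      d <- sort(exp(runif(k, log(0.01), log(5))))
      f <- stats::rexp(k)
    }
    f <- f / sum(f)
    d <- pmax(d, 1e-12)

    ll_prev <- -Inf
    stable <- 0L
    ll_trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      # E step: log f_i + log gamma density, n x k
      ld <- outer(x, -shape / d) +
        rep(lx_const, times = k) +
        rep(log(f) - shape * log(d), each = n)
      m <- ld[, 1L]
      if (k > 1L) for (j in 2:k) m <- pmax(m, ld[, j])
      lse <- m + log(rowSums(exp(ld - m)))
      ll <- sum(lse)
      resp <- exp(ld - lse)
      # M step
      cs <- colSums(resp)
      f <- cs / n
      if (is.null(fixed_d)) {
        d <- pmax(colSums(resp * x) / pmax(cs, 1e-300), 1e-12)
      }
      ll_trace <- c(ll_trace, ll)
      if (ll - ll_prev < tol * (1 + abs(ll))) stable <- stable + 1L else stable <- 0L
      if (stable >= 3L) {
        converged <- TRUE
        break
      }
      ll_prev <- ll
    }
    if (is.null(best) || ll > best$log_likelihood) {
      best <- list(d = d, f = f, log_likelihood = ll, converged = converged,
                   n_iter = length(ll_trace), ll_trace = ll_trace)
    }
  }

  if (is.null(fixed_d)) {
    o <- order(best$d)
    best$d <- best$d[o]
    best$f <- best$f[o]
  }
  structure(
    list(
      species = data.frame(d = best$d, occupancy = best$f),
      n_steps = shape,
      log_likelihood = best$log_likelihood,
      n_tracks = n,
      converged = best$converged,
      fixed_d = fixed_d,
      n_iter = best$n_iter,
      ll_trace = best$ll_trace
    ),
    class = "dstar_mixture_fit"
  )
}

#' @export
print.dstar_mixture_fit <- function(x, ...) {
  kind <- if (is.null(x$fixed_d)) "free mobilities" else "fixed mobilities"
  cat(sprintf("Gamma mixture of %d diffusive species (%s)\n",
              nrow(x$species), kind))
  cat(sprintf("  %d tracks, %d steps per D*, log-likelihood %.3f%s\n",
              x$n_tracks, x$n_steps, x$log_likelihood,
              if (x$converged) "" else " (NOT converged)"))
  for (i in seq_len(nrow(x$species))) {
    cat(sprintf("  species %d: D = %.4f um^2/s, occupancy %.3f\n",
                i, x$species$d[i], x$species$occupancy[i]))
  }
  invisible(x)
}

#' @export
logLik.dstar_mixture_fit <- function(object, ...) {
  val <- object$log_likelihood
  attr(val, "df") <- if (is.null(object$fixed_d)) {
    2L * nrow(object$species) - 1L
  } else {
    nrow(object$species) - 1L
  }
  attr(val, "nobs") <- object$n_tracks
  class(val) <- "logLik"
  val
}

#' Immobile fraction of a tracked population
#'
#' The fraction of molecules in the lowest-mobility state, the readout used
#' to quantify recruitment of repair proteins to DNA. Two estimators are
#' available: `"mixture"` (default) returns 100 times the fitted occupancy of
#' the lowest-mobility species of a [fit_dstar_mixture()] result;
#' `"threshold"` returns 100 times the fraction of tracks with
#' `D* < immobile_max`, the per-track counting that underlies mobility-map
#' coloring. The threshold estimator is biased when species distributions
#' overlap the cut-off; the mixture estimator is preferred.
#'
#' @param x A `dstar_mixture_fit` (for `method = "mixture"`), or a numeric
#'   vector / [compute_dstars()] table (for `method = "threshold"`).
#' @param method `"mixture"` or `"threshold"`; defaults to whichever matches
#'   the type of `x`.
#' @param thresholds A [classification_thresholds()] (threshold method only).
#' @return Immobile fraction as a percentage in `[0, 100]`.
#' @export
#' @examples
#' immobile_fraction(c(0.05, 0.1, 0.5, 2.0), method = "threshold") # 50
immobile_fraction <- function(x,
                              method = c("mixture", "threshold"),
                              thresholds = classification_thresholds()) {
  if (missing(method)) {
    method <- if (inherits(x, "dstar_mixture_fit")) "mixture" else "threshold"
  } else {
    method <- match.arg(method)
  }
  if (method == "mixture") {
    if (!inherits(x, "dstar_mixture_fit")) {
      stop("method = \"mixture\" needs a fit from fit_dstar_mixture()",
           call. = FALSE)
    }
    if (!isTRUE(x$converged)) {
      stop("mixture fit did not converge; refit with more iterations/starts ",
           "or use method = \"threshold\"", call. = FALSE)
    }
    i <- which.min(x$species$d)
    return(100 * x$species$occupancy[i])
  }
  if (is.data.frame(x)) x <- x$d_star_um2_s
  if (!is.numeric(x) || length(x) == 0L) {
    stop("method = \"threshold\" needs a non-empty numeric vector or a ",
         "compute_dstars() table", call. = FALSE)
  }
  100 * mean(x < thresholds$immobile_max)
}
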