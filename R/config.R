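#' Acquisition settings for a simulated PALM movie
#'
#' Bundles the camera/photophysics parameters of a simulated
#' single-molecule-tracking acquisition. Defaults correspond to a typical
#' bacterial PALM experiment: 10,000 frames at a 15 ms interval, 35 nm
#' localization precision, sparse photoactivation (on average 0.01 new
#' emitters per cell per frame) and a per-frame fluorophore survival
#' probability of 0.6, which gives a mean observed track length of
#' 1/(1 - 0.6) = 2.5 frames.
#'
#' @param frame_interval Time between frames, seconds.
#' @param n_frames Number of frames in the movie.
#' @param localization_sigma Standard deviation of the isotropic Gaussian
#'   localization error, micrometres. With `n_steps = 4` an immobile molecule
#'   then shows an apparent mobility floor of about
#'   `localization_sigma^2 / frame_interval` (0.082 um^2/s at the defaults).
#' @param activations_per_cell_per_frame Expected number of newly activated
#'   emitters per cell per frame. The default keeps at most about one active
#'   emitter per cell at any time, so nearest-neighbour linking is
#'   unambiguous.
#' @param survival_prob Per-frame probability that an active emitter remains
#'   visible in the next frame; track lengths are geometric with mean
#'   `1/(1 - survival_prob)`.
#' @param rng_seed Optional integer seed used by [simulate_movie()] when no
#'   explicit seed is passed.
#'
#' @return An object of class `acquisition_config`.
#' @seealso [simulate_movie()], [sample_track_length()]
#' @export
#' @examples
#' acq <- acquisition_config()
#' 1 / (1 - acq$survival_prob) # mean track length in frames
acquisition_config <- function(frame_interval = 0.015,
                               n_frames = 10000L,
                               localization_sigma = 0.035,
                               activations_per_cell_per_frame = 0.01,
                               survival_prob = 0.6,
                               rng_seed = NULL) {
  stopifnot(is.numeric(frame_interval), length(frame_interval) == 1L)
  if (!(frame_interval > 0)) stop("`frame_interval` must be > 0", call. = FALSE)
  if (!(n_frames >= 2)) stop("`n_frames` must be >= 2", call. = FALSE)
  if (!(localization_sigma >= 0)) stop("`localization_sigma` must be >= 0", call. = FALSE)
  if (!(activations_per_cell_per_frame > 0)) {
    stop("`activations_per_cell_per_frame` must be > 0", call. = FALSE)
  }
  if (!(survival_prob >= 0 && survival_prob < 1)) {
    stop("`survival_prob` must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(
      frame_interval = frame_interval,
      n_frames = as.integer(n_frames),
      localization_sigma = localization_sigma,
      activations_per_cell_per_frame = activations_per_cell_per_frame,
      survival_prob = survival_prob,
      rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
    ),
    class = "acquisition_config"
  )
}

#' Define a set of diffusive species
#'
#' A species set describes the ground-truth mixture the simulator draws from:
#' each species has a diffusion coefficient (um^2/s) and an occupancy, the
#' fraction of molecules in that state. Occupancies must sum to one.
#'
#' @param d Numeric vector of diffusion coefficients, um^2/s (each >= 0).
#' @param occupancy Numeric vector of the same length; fractions in `[0, 1]`
#'   summing to 1 (within 1e-9).
#'
#' @return A `data.frame` of class `species_set` with columns `d` and
#'   `occupancy`.
#' @export
#' @examples
#' # the three UvrB mobility states: immobile, slow, fast
#' species_set(d = c(0.11, 0.41, 1.24), occupancy = c(0.16, 0.42, 0.42))
species_set <- function(d, occupancy) {
  stopifnot(is.numeric(d), is.numeric(occupancy))
  if (length(d) == 0L) stop("species set must contain at least one species", call. = FALSE)
  if (length(d) != length(occupancy)) {
    stop("`d` and `occupancy` must have the same length", call. = FALSE)
  }
  if (any(d < 0)) stop("diffusion coefficients must be >= 0", call. = FALSE)
  if (any(occupancy < 0 | occupancy > 1)) {
    stop("occupancies must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(occupancy) - 1) > 1e-9) {
    stop("occupancies must sum to 1 (within 1e-9), got ", sum(occupancy), call. = FALSE)
  }
  structure(
    data.frame(d = as.numeric(d), occupancy = as.numeric(occupancy)),
    class = c("species_set", "data.frame")
  )
}

#' Rod-shaped cell geometry (2-D spherocylinder projection)
#'
#' Cells are modelled as the 2-D projection of a spherocylinder: a rectangle
#' of the given length capped by two semicircles of the given radius. The
#' default dimensions (cylinder 2.0 um, radius 0.45 um) are typical for
#' *E. coli*. Molecule positions are confined to this shape by mirror
#' reflection at the boundary.
#'
#' @param length Cylinder (straight-section) length, um; `>= 0` (0 gives a
#'   disk).
#' @param radius Cap/half-width radius, um; `> 0`.
#' @param n_cells Number of cells in the simulated field of view.
#'
#' @return An object of class `cell_geometry`.
#' @export
cell_geometry <- function(length = 2.0, radius = 0.45, n_cells = 1L) {
  if (!(length >= 0)) stop("`length` must be >= 0", call. = FALSE)
  if (!(radius > 0)) stop("`radius` must be > 0", call. = FALSE)
  if (!(n_cells >= 1)) stop("`n_cells` must be >= 1", call. = FALSE)
  structure(
    list(length = length, radius = radius, n_cells = as.integer(n_cells)),
    class = "cell_geometry"
  )
}

#' Track-linking settings
#'
#' @param max_displacement Maximum allowed displacement between linked
#'   localizations, um per frame. The default 0.9 um is about three standard
#'   deviations of a single-frame step of the fastest species
#'   (`3 * sqrt(4 * 1.24 * 0.015)` = 0.82 um).
#' @param max_gap Maximum number of missed frames bridged by a link; 0
#'   (default) links consecutive frames only. For a gap of `g` frames the
#'   displacement gate scales to `max_displacement * (g + 1)`.
#' @param restrict_to_cell If `TRUE` (default), localizations are only linked
#'   within the same cell.
#'
#' @return An object of class `linking_config`.
#' @seealso [link_localizations()]
#' @export
linking_config <- function(max_displacement = 0.9, max_gap = 0L,
                           restrict_to_cell = TRUE) {
  if (!(max_displacement > 0)) stop("`max_displacement` must be > 0", call. = FALSE)
  if (!(max_gap >= 0)) stop("`max_gap` must be >= 0", call. = FALSE)
  structure(
    list(
      max_displacement = max_displacement,
      max_gap = as.integer(max_gap),
      restrict_to_cell = isTRUE(restrict_to_cell)
    ),
    class = "linking_config"
  )
}

#' Mobility-class thresholds for apparent diffusion coefficients
#'
#' Tracks are classed as immobile (`d_star < immobile_max`), fast
#' (`d_star > fast_min`) or slow (everything in between, boundaries
#' included). The defaults, 0.2 and 1.5 um^2/s, are the conventional cut-offs
#' for UvrB-PAmCherry mobility maps.
#'
#' @param immobile_max Upper bound of the immobile class, um^2/s.
#' @param fast_min Lower bound of the fast class, um^2/s.
#'
#' @return An object of class `classification_thresholds`.
#' @export
classification_thresholds <- function(immobile_max = 0.2, fast_min = 1.5) {
  if (!(immobile_max > 0 && immobile_max < fast_min)) {
    stop("need 0 < `immobile_max` < `fast_min`", call. = FALSE)
  }
  structure(
    list(immobile_max = immobile_max, fast_min = fast_min),
    class = "classification_thresholds"
  )
}

#' Full pipeline configuration
#'
#' Collects every setting the end-to-end pipeline needs; see [run_pipeline()].
#'
#' @param acquisition An [acquisition_config()].
#' @param geometry A [cell_geometry()].
#' @param linking A [linking_config()].
#' @param thresholds A [classification_thresholds()].
#' @param min_steps Minimum number of steps a track must have to enter the
#'   diffusion analysis; also the number of steps used for each `D*` (default
#'   4).
#' @param k_species Number of species in the mixture fit (default 3).
#' @param seed Integer master seed; replicate seeds are derived from it.
#' @param output_dir Optional directory for intermediate and report files;
#'   `NULL` keeps everything in memory.
#'
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(acquisition = acquisition_config(),
                            geometry = cell_geometry(n_cells = 50L),
                            linking = linking_config(),
                            thresholds = classification_thresholds(),
                            min_steps = 4L,
                            k_species = 3L,
                            seed = 1L,
                            output_dir = NULL) {
  stopifnot(
    inherits(acquisition, "acquisition_config"),
    inherits(geometry, "cell_geometry"),
    inherits(linking, "linking_config"),
    inherits(thresholds, "classification_thresholds")
  )
  if (!(min_steps >= 1)) stop("`min_steps` must be >= 1", call. = FALSE)
  if (!(k_species >= 1)) stop("`k_species` must be >= 1", call. = FALSE)
  structure(
    list(
      acquisition = acquisition, geometry = geometry, linking = linking,
      thresholds = thresholds, min_steps = as.integer(min_steps),
      k_species = as.integer(k_species), seed = as.integer(seed),
      output_dir = output_dir
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' The file mirrors the structure of [pipeline_config()]: top-level keys
#' `acquisition`, `geometry`, `linking`, `thresholds`, `min_steps`,
#' `k_species`, `seed`, `output_dir`, plus an optional `species` section
#' (`d`, `occupancy`) returned as attribute `"species"`. Missing sections fall
#' back to the package defaults.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`; if the file defines species, they are attached
#'   as a [species_set()] in `attr(, "species")`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  grab <- function(section, ctor) {
    if (is.null(y[[section]])) ctor() else do.call(ctor, y[[section]])
  }
  cfg <- pipeline_config(
    acquisition = grab("acquisition", acquisition_config),
    geometry = grab("geometry", cell_geometry),
    linking = grab("linking", linking_config),
    thresholds = grab("thresholds", classification_thresholds),
    min_steps = if (is.null(y$min_steps)) 4L else y$min_steps,
    k_species = if (is.null(y$k_species)) 3L else y$k_species,
    seed = if (is.null(y$seed)) 1L else y$seed,
    output_dir = y$output_dir
  )
  if (!is.null(y$species)) {
    attr(cfg, "species") <- species_set(
      d = as.numeric(unlist(y$species$d)),
      occupancy = as.numeric(unlist(y$species$occupancy))
    )
  }
  cfg
}
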