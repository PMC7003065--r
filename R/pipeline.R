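#' Run the full mobility-analysis pipeline on simulated conditions
#'
#' For every condition and biological replicate: simulate a movie, link the
#' localizations into tracks, keep tracks with at least `min_steps` steps,
#' compute per-track apparent diffusion coefficients, fit the species
#' mixture, and take the immobile fraction. Replicates are then summarized
#' per condition and every pair of conditions is compared with the unpaired
#' two-tailed t-test. A replicate is an independently simulated movie (cells
#' and emitters resampled), the in-silico analogue of a biological
#' replicate.
#'
#' One master seed drives everything: per-replicate child seeds are drawn
#' once from the master seed, so the full report is reproducible and
#' replicates stay independent.
#'
#' @param config A [pipeline_config()].
#' @param conditions Named list of [species_set()]s, one per condition.
#' @param n_replicates Biological replicates per condition (default 4).
#' @param fraction_method `"mixture"` (default) or `"threshold"`; see
#'   [immobile_fraction()].
#' @param n_starts EM starts passed to [fit_dstar_mixture()].
#'
#' @return An object of class `spt_report`: list with `conditions` (named
#'   list of [summarize_replicates()] results), `comparisons` (list of
#'   [compare_groups()] results for every condition pair), `fits` (per
#'   condition, per replicate), `seeds`, and the `config`. When
#'   `config$output_dir` is set, intermediate tables, per-replicate fits, the
#'   report and a run manifest are written under it.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(
#'   acquisition = acquisition_config(n_frames = 1000),
#'   geometry = cell_geometry(n_cells = 40),
#'   seed = 1
#' )
#' conds <- list(
#'   control = species_set(c(0.11, 0.41, 1.24), c(0.16, 0.42, 0.42)),
#'   darT = species_set(c(0.11, 0.41, 1.24), c(0.35, 0.325, 0.325))
#' )
#' run_pipeline(cfg, conds, n_replicates = 2)
#' }
run_pipeline <- function(config, conditions, n_replicates = 4L,
                         fraction_method = c("mixture", "threshold"),
                         n_starts = 10L) {
  stopifnot(inherits(config, "pipeline_config"))
  fraction_method <- match.arg(fraction_method)
  if (length(conditions) == 0L || !all(vapply(conditions, inherits, logical(1), "species_set"))) {
    stop("`conditions` must be a non-empty named list of species_set()s",
         call. = FALSE)
  }
  if (is.null(names(conditions)) || any(!nzchar(names(conditions)))) {
    names(conditions) <- paste0("condition_", seq_along(conditions))
  }
  if (!(n_replicates >= 1)) stop("`n_replicates` must be >= 1", call. = FALSE)

  set.seed(config$seed)
  seeds <- matrix(
    sample.int(.Machine$integer.max - 1L, length(conditions) * n_replicates),
    nrow = n_replicates,
    dimnames = list(NULL, names(conditions))
  )

  out_dir <- config$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  summaries <- list()
  all_fits <- list()
  for (cond in names(conditions)) {
    fracs <- numeric(n_replicates)
    n_cells_total <- 0L
    n_tracks_total <- 0L
    fits <- vector("list", n_replicates)
    for (rep_i in seq_len(n_replicates)) {
      stage <- function(name, expr) {
        tryCatch(expr, error = function(e) {
          stop(sprintf("stage '%s', condition '%s', replicate %d: %s",
                       name, cond, rep_i, conditionMessage(e)), call. = FALSE)
        })
      }
      sim <- stage("simulate", simulate_movie(
        config$acquisition, conditions[[cond]], config$geometry,
        seed = seeds[rep_i, cond]
      ))
      tracks <- stage("link", link_localizations(sim$localizations, config$linking))
      kept <- stage("filter", filter_tracks_min_steps(tracks, config$min_steps))
      dstars <- stage("dstar", compute_dstars(
        kept, config$acquisition$frame_interval, config$min_steps
      ))
      fit <- stage("fit", fit_dstar_mixture(
        dstars, k = config$k_species, n_steps = config$min_steps,
        n_starts = n_starts, seed = seeds[rep_i, cond]
      ))
      fracs[rep_i] <- stage("fraction", if (fraction_method == "mixture") {
        immobile_fraction(fit)
      } else {
        immobile_fraction(dstars, method = "threshold",
                          thresholds = config$thresholds)
      })
      n_cells_total <- n_cells_total + config$geometry$n_cells
      n_tracks_total <- n_tracks_total + fit$n_tracks
      fits[[rep_i]] <- fit

      if (!is.null(out_dir)) {
        rep_dir <- file.path(out_dir, cond, sprintf("rep%02d", rep_i))
        dir.create(rep_dir, recursive = TRUE, showWarnings = FALSE)
        write_localizations(sim$localizations, file.path(rep_dir, "localizations.csv"))
        write_tracks(kept, file.path(rep_dir, "tracks.tsv"))
        write_text_table(dstars, file.path(rep_dir, "dstar.csv"), sep = ",")
        write_fit(fit, file.path(rep_dir, "fit.json"))
      }
    }
    summaries[[cond]] <- summarize_replicates(
      fracs, condition = cond,
      n_cells = n_cells_total, n_tracks = n_tracks_total
    )
    all_fits[[cond]] <- fits
  }

  comparisons <- list()
  cond_names <- names(conditions)
  if (length(cond_names) >= 2L) {
    pairs <- utils::combn(cond_names, 2L, simplify = FALSE)
    comparisons <- lapply(pairs, function(p) {
      compare_groups(summaries[[p[1L]]]$replicate_fractions,
                     summaries[[p[2L]]]$replicate_fractions,
                     labels = p)
    })
  }

  report <- structure(
    list(conditions = summaries, comparisons = comparisons, fits = all_fits,
         seeds = seeds, fraction_method = fraction_method, config = config),
    class = "spt_report"
  )

  if (!is.null(out_dir)) {
    write_report(report, file.path(out_dir, "report.json"))
    manifest <- list(
      package = "sptmix",
      version = as.character(packageVersion("sptmix")),
      r_version = as.character(getRversion()),
      master_seed = config$seed,
      replicate_seeds = as.data.frame(seeds),
      n_replicates = n_replicates,
      fraction_method = fraction_method,
      conditions = lapply(conditions, function(s) {
        list(d = s$d, occupancy = s$occupancy)
      }),
      config = list(
        acquisition = unclass(config$acquisition),
        geometry = unclass(config$geometry),
        linking = unclass(config$linking),
        thresholds = unclass(config$thresholds),
        min_steps = config$min_steps,
        k_species = config$k_species
      )
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  report
}

#' @export
print.spt_report <- function(x, ...) {
  cat("Single-molecule mobility report\n")
  for (s in x$conditions) print(s)
  for (cmp in x$comparisons) print(cmp)
  invisible(x)
}
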