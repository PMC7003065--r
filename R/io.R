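# Readers and writers for the plain-text interchange formats:
#   localizations  CSV  frame,cell_id,x_um,y_um,sigma_um
#   tracks         TSV  track_id,cell_id,frame,x_um,y_um
#   mixture fit    JSON {species:[{d,occupancy}], n_steps, ...}
# Numeric columns are written with 17 significant digits so write -> read
# round-trips to full double precision.

#' Write a localization table to CSV
#'
#' @param locs Localization table (`frame`, `cell_id`, `x_um`, `y_um`,
#'   `sigma_um`); extra columns (e.g. the simulator's `emitter_id`) are not
#'   written.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(locs, path) {
  cols <- c("frame", "cell_id", "x_um", "y_um", "sigma_um")
  miss <- setdiff(cols, names(locs))
  if (length(miss) > 0L) {
    stop("localization table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  write_text_table(locs[cols], path, sep = ",")
}

#' Read a localization table from CSV
#'
#' Expects the header `frame,cell_id,x_um,y_um,sigma_um` (`sigma_um`
#' optional). Malformed rows and unsorted frames are rejected with the
#' offending column or line.
#'
#' @param path CSV file.
#' @return Localization `data.frame` sorted by frame.
#' @export
read_localizations <- function(path) {
  df <- read_text_table(path, sep = ",",
                        required = c("frame", "cell_id", "x_um", "y_um"),
                        numeric_cols = c("frame", "x_um", "y_um", "sigma_um"),
                        id_cols = "cell_id")
  if (is.unsorted(df$frame)) {
    stop("localizations in ", path, " are not sorted by frame", call. = FALSE)
  }
  df
}

#' Write a track table to TSV
#' @param tracks Track table from [link_localizations()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  cols <- c("track_id", "cell_id", "frame", "x_um", "y_um")
  miss <- setdiff(cols, names(tracks))
  if (length(miss) > 0L) {
    stop("track table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  write_text_table(tracks[cols], path, sep = "\t")
}

#' Read a track table from TSV
#' @param path TSV file with header `track_id,cell_id,frame,x_um,y_um`.
#' @return Track `data.frame`.
#' @export
read_tracks <- function(path) {
  read_text_table(path, sep = "\t",
                  required = c("track_id", "cell_id", "frame", "x_um", "y_um"),
                  numeric_cols = c("frame", "x_um", "y_um"),
                  id_cols = c("track_id", "cell_id"))
}

#' Write a mixture fit to JSON
#' @param fit A `dstar_mixture_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "dstar_mixture_fit"))
  obj <- list(
    species = lapply(seq_len(nrow(fit$species)), function(i) {
      list(d = fit$species$d[i], occupancy = fit$species$occupancy[i])
    }),
    n_steps = fit$n_steps,
    log_likelihood = fit$log_likelihood,
    n_tracks = fit$n_tracks,
    converged = fit$converged,
    fixed_d = fit$fixed_d
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a mixture fit from JSON
#' @param path JSON file written by [write_fit()].
#' @return A `dstar_mixture_fit` (without the iteration trace).
#' @export
read_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (field in c("species", "n_steps", "log_likelihood", "n_tracks", "converged")) {
    if (is.null(obj[[field]])) {
      stop("fit file ", path, " is missing field `", field, "`", call. = FALSE)
    }
  }
  structure(
    list(
      species = data.frame(
        d = vapply(obj$species, function(s) as.numeric(s$d), numeric(1)),
        occupancy = vapply(obj$species, function(s) as.numeric(s$occupancy), numeric(1))
      ),
      n_steps = as.integer(obj$n_steps),
      log_likelihood = as.numeric(obj$log_likelihood),
      n_tracks = as.integer(obj$n_tracks),
      converged = isTRUE(obj$converged),
      fixed_d = if (is.null(obj$fixed_d)) NULL else as.numeric(unlist(obj$fixed_d)),
      n_iter = NA_integer_,
      ll_trace = numeric(0)
    ),
    class = "dstar_mixture_fit"
  )
}

#' Write a pipeline report to JSON
#' @param report An `spt_report` from [run_pipeline()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "spt_report"))
  obj <- list(
    conditions = lapply(report$conditions, unclass),
    comparisons = lapply(report$comparisons, unclass)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# ---- internal helpers -------------------------------------------------------

write_text_table <- function(df, path, sep) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- formatC(out[[nm]], digits = 17, format = "g")
  }
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_text_table <- function(path, sep, required, numeric_cols, id_cols = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = sep, header = TRUE, colClasses = "character",
                   check.names = TRUE, strip.white = TRUE)
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) {
    stop("file ", path, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (nm in intersect(numeric_cols, names(df))) {
    vals <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- which(is.na(vals) & !is.na(df[[nm]]))
    if (length(bad) > 0L) {
      stop("file ", path, ": non-numeric value in column `", nm,
           "` at line ", bad[1L] + 1L, " (\"", df[[nm]][bad[1L]], "\")",
           call. = FALSE)
    }
    df[[nm]] <- vals
  }
  if ("frame" %in% names(df)) df$frame <- as.integer(df$frame)
  # id columns stay free-text unless they are plainly integer
  for (nm in intersect(id_cols, names(df))) {
    if (all(grepl("^-?[0-9]+$", df[[nm]]))) df[[nm]] <- as.integer(df[[nm]])
  }
  df
}
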