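#' Read a track table from CSV
#'
#' Required columns: `track_id`, `frame` (0-based), `t_s`, `x_um`, `y_um`,
#' optionally `ratio`. Column aliases support manual-tracker exports via
#' `col_map`; pixel-coordinate exports are converted to micrometres with
#' `pixel_size_um`.
#'
#' @param path CSV file.
#' @param col_map optional named character vector mapping required names to
#'   the file's column names, e.g.
#'   `c(track_id = "TID", frame = "PID", t_s = "t [sec]",
#'      x_um = "x [pixel]", y_um = "y [pixel]")`.
#' @param pixel_size_um when given, `x_um`/`y_um` in the file are taken as
#'   pixel coordinates and multiplied by this calibration.
#' @return track data frame.
#' @export
read_tracks <- function(path, col_map = NULL, pixel_size_um = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      src <- col_map[[std]]
      if (!src %in% names(df)) stop("track table missing column: ", src)
      names(df)[names(df) == src] <- std
    }
  }
  req <- c("track_id", "frame", "t_s", "x_um", "y_um")
  for (column in req) {
    if (!column %in% names(df)) stop("track table missing column: ", column)
  }
  if (!is.null(pixel_size_um)) {
    df$x_um <- df$x_um * pixel_size_um
    df$y_um <- df$y_um * pixel_size_um
  }
  df[order(df$track_id, df$frame), , drop = FALSE]
}

#' Write a track (or any numeric) table to CSV at full precision
#'
#' Numeric columns are written with 17 significant digits so that writing
#' and re-reading reproduces the doubles exactly.
#'
#' @param x data frame.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(x, path) {
  y <- x
  for (j in seq_along(y)) {
    if (is.double(y[[j]])) y[[j]] <- formatC(y[[j]], digits = 17, format = "g")
  }
  utils::write.csv(y, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write conjugate annotations as JSON
#'
#' @param path JSON file.
#' @return a [conjugate_annotation()].
#' @export
read_annotation <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_poly <- function(p) if (is.null(p)) NULL else matrix(unlist(p), ncol = 2, byrow = FALSE)
  conjugate_annotation(
    interface = as_poly(j$interface), rest = as_poly(j$rest),
    width_px = j$width_px %||% 10,
    center = j$center, direction = j$direction,
    roi_size_px = j$roi_size_px %||% 50,
    roi_offset_px = j$roi_offset_px %||% (j$roi_size_px %||% 50),
    pixel_size_um = j$pixel_size_um %||% (3.37 / 50)
  )
}

#' @rdname read_annotation
#' @param annotation a [conjugate_annotation()].
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "conjugate_annotation"))
  jsonlite::write_json(unclass(annotation), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a per-cell calcium measures table
#'
#' Loads an externally produced 13-measure table (for example the published
#' per-cell measures workbook exported to CSV) into the feature-matrix
#' layout used by [run_lda()], applying a user-declared column mapping.
#'
#' @param path CSV file.
#' @param col_map named character vector mapping this package's measure
#'   names (see [compute_features()]) and `label` to the file's columns.
#' @return list with `features` (numeric matrix, 13 columns) and `labels`
#'   (factor or `NULL` when no label column is mapped).
#' @export
read_calcium_measures <- function(path, col_map = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      src <- col_map[[std]]
      if (!src %in% names(df)) stop("measures table missing column: ", src)
      names(df)[names(df) == src] <- std
    }
  }
  need <- feature_measure_names()
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("measures table missing column(s): ",
                         paste(miss, collapse = ", "))
  labels <- if ("label" %in% names(df)) {
    factor(as.character(df$label), levels = signature_levels())
  }
  list(features = as.matrix(df[, need]), labels = labels)
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected so typos fail loudly; known keys override the
#' [sim_config()] / parameter defaults.
#'
#' @param path YAML file with optional blocks `sim` (fields of
#'   [sim_config()]), `classifier` (fields of [classifier_params()]),
#'   `thresholds` (fields of [flow_thresholds()]), and top-level `seed`,
#'   `out_dir`, `input_tracks`, `input_ch340`, `input_ch380`,
#'   `roi_diameter_px`, `render`.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config_from_list(y)
}

run_config_from_list <- function(y) {
  y <- y %||% list()
  known <- c("sim", "classifier", "thresholds", "seed", "out_dir",
             "input_tracks", "input_ch340", "input_ch380",
             "roi_diameter_px", "render")
  unknown <- setdiff(names(y), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  sim_args <- y$sim %||% list()
  if (!is.null(y$seed)) sim_args$seed <- y$seed
  if (!is.null(sim_args$mixture)) sim_args$mixture <- unlist(sim_args$mixture)
  if (!is.null(sim_args$field_size_um)) sim_args$field_size_um <- unlist(sim_args$field_size_um)
  if (!is.null(sim_args$onset_range_s)) sim_args$onset_range_s <- unlist(sim_args$onset_range_s)
  structure(list(
    sim = do.call(sim_config, sim_args),
    classifier = do.call(classifier_params, y$classifier %||% list()),
    thresholds = do.call(flow_thresholds, y$thresholds %||% list()),
    seed = as.integer(y$seed %||% (y$sim$seed %||% 1L)),
    out_dir = y$out_dir %||% ".",
    input_tracks = y$input_tracks,
    input_ch340 = y$input_ch340, input_ch380 = y$input_ch380,
    roi_diameter_px = y$roi_diameter_px %||% 20,
    render = isTRUE(y$render %||% TRUE)
  ), class = "run_config")
}
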