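#' Read a cell-track table into a cohort
#'
#' Reads a per-cell, per-frame position table (comma- or tab-delimited,
#' auto-detected, UTF-8) and builds one [track()] per distinct track id.
#' Two dialects are supported: `"manual_tracking_csv"`, the Fiji/ImageJ
#' Manual Tracking export (columns `Track n°`, `Slice n°`, `X`, `Y`, slices
#' numbered from 1), and `"generic_csv"` (columns `track_id`, `frame`, `x`,
#' `y`, frames numbered from 0). Header names vary across exporter
#' versions, so they can be overridden via `columns`. Positions are
#' multiplied by `scale` to convert pixels to micrometres; internal units
#' are always micrometres and minutes, and frame indices are converted to
#' 0-based on read.
#'
#' Rows are sorted by frame within each track; a duplicated (track, frame)
#' pair is an error naming the offending row, and tracks with fewer than
#' two frames are dropped with a warning. A z column, if present, is
#' ignored with a warning (tracks are 2D maximum-projection positions).
#'
#' @param path Path to the table.
#' @param dialect `"manual_tracking_csv"` or `"generic_csv"`.
#' @param scale Micrometres per coordinate unit (> 0); e.g. the pixel size.
#' @param frame_interval Minutes per frame (default 1).
#' @param cell_type,group Labels applied to all tracks in the file.
#' @param columns Optional named character vector overriding the header
#'   names, with names `track`, `frame`, `x`, `y`.
#' @param t_start Minutes post wounding at frame 0 (default 60).
#' @return A [cohort()]; tracks are ordered by id (numerically when all ids
#'   are numeric, lexicographically otherwise).
#' @export
read_tracks <- function(path,
                        dialect = c("manual_tracking_csv", "generic_csv"),
                        scale = 1, frame_interval = 1,
                        cell_type = "neutrophil", group = "",
                        columns = NULL, t_start = 60) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path), scale > 0)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, fileEncoding = "UTF-8",
                           stringsAsFactors = FALSE)
  cols <- switch(dialect,
    manual_tracking_csv = c(track = "Track n°", frame = "Slice n°",
                            x = "X", y = "Y"),
    generic_csv = c(track = "track_id", frame = "frame", x = "x", y = "y"))
  frame_base <- if (dialect == "manual_tracking_csv") 1L else 0L
  if (!is.null(columns)) cols[names(columns)] <- columns
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         "; use `columns` to map your header names", call. = FALSE)
  zcol <- intersect(c("z", "Z"), names(raw))
  if (length(zcol))
    warning("ignoring z column '", zcol[1L],
            "': tracks are 2D projections", call. = FALSE)
  id <- as.character(raw[[cols["track"]]])
  frame <- as.integer(raw[[cols["frame"]]]) - frame_base
  dup <- duplicated(cbind(id, frame))
  if (any(dup)) {
    r <- which(dup)[1L]
    stop("duplicate (track, frame) at data row ", r, ": track '", id[r],
         "', frame ", frame[r] + frame_base, call. = FALSE)
  }
  ids <- unique(id)
  num <- suppressWarnings(as.numeric(ids))
  ids <- if (!anyNA(num)) ids[order(num)] else sort(ids)
  tracks <- list()
  dropped <- 0L
  for (ii in ids) {
    sel <- which(id == ii)
    sel <- sel[order(frame[sel])]
    if (length(sel) < 2L) { dropped <- dropped + 1L; next }
    tracks[[length(tracks) + 1L]] <- track(
      ii, frame[sel],
      cbind(raw[[cols["x"]]][sel], raw[[cols["y"]]][sel]) * scale,
      cell_type = cell_type, group = group,
      frame_interval = frame_interval)
  }
  if (dropped > 0L)
    warning(dropped, " track(s) with < 2 frames dropped", call. = FALSE)
  if (length(tracks) == 0L)
    stop("no usable tracks (>= 2 frames) in ", path, call. = FALSE)
  cohort(tracks, t_start = t_start)
}

#' Write a cohort as a track table
#'
#' Writes the `generic_csv` dialect ([read_tracks()] reads it back):
#' columns `track_id`, `frame` (0-based), `x`, `y` in micrometres, one row
#' per tracked position.
#'
#' @param cohort A [cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- do.call(rbind, lapply(cohort$tracks, function(tr)
    data.frame(track_id = tr$track_id, frame = tr$frames,
               x = tr$positions[, 1], y = tr$positions[, 2])))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and re-read per-track summary tables
#'
#' `write_summary()` writes a per-track metric table (as produced by
#' [summarize_tracks()]) as CSV with a stable column order and full double
#' precision; `read_summary()` reads it back. Numeric fields round-trip
#' within 1e-9 relative tolerance. An empty table writes a header-only
#' file.
#'
#' @param summaries A `data.frame` of per-track metrics.
#' @param path Output path.
#' @return `write_summary()` returns `path` invisibly; `read_summary()`
#'   returns the `data.frame`.
#' @export
write_summary <- function(summaries, path) {
  stopifnot(is.data.frame(summaries))
  tryCatch(
    utils::write.csv(summaries, path, row.names = FALSE, na = "NA"),
    error = function(e) stop("cannot write '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  stopifnot(file.exists(path))
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read an experiment configuration file
#'
#' A single JSON or YAML file (chosen by extension) describing the wound
#' geometry and analysis constants: `wound_edge` (list of \[x, y\] vertices,
#' um), `ap_axis` (\[x, y\], positive toward the wound), optional `origin`,
#' `scale` (um per coordinate unit), `frame_interval` (min),
#' `classify_threshold` (um, default 200), `arrival_radius` (um, default
#' 20), `recruit_band` (um, default 200) and `t_start` (min post wounding,
#' default 60).
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A list with element `wound` (a [wound_frame()]) plus the scalar
#'   settings, defaults filled in.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("config must be .json, .yaml or .yml, got .", ext, call. = FALSE))
  if (is.null(cfg$wound_edge) || is.null(cfg$ap_axis))
    stop("config must provide wound_edge and ap_axis", call. = FALSE)
  edge <- cfg$wound_edge
  if (is.list(edge)) edge <- do.call(rbind, lapply(edge, as.numeric))
  edge <- as.matrix(edge)
  defaults <- list(scale = 1, frame_interval = 1, classify_threshold = 200,
                   arrival_radius = 20, recruit_band = 200, t_start = 60)
  out <- list(wound = wound_frame(edge, as.numeric(cfg$ap_axis),
                                  origin = as.numeric(cfg$origin %||% c(0, 0))))
  for (nm in names(defaults))
    out[[nm]] <- as.numeric(cfg[[nm]] %||% defaults[[nm]])
  out
}
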