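#' Construct a cell track
#'
#' A track is one cell's time-ordered sequence of 2D positions. Positions are
#' stored in micrometres and frame indices are 0-based; `frame_interval` (in
#' minutes per frame) converts frame indices to experiment time.
#'
#' @param track_id Identifier for the cell (coerced to character).
#' @param frames Integer vector of 0-based frame indices, strictly increasing.
#' @param positions Numeric matrix with one row per frame and two columns
#'   (x, y), in micrometres.
#' @param cell_type `"neutrophil"` or `"macrophage"`.
#' @param group Free-text group/genotype label (e.g. `"wt"`, `"mutant"`).
#' @param frame_interval Minutes per frame (default 1).
#' @return An object of class `track`.
#' @examples
#' tr <- track("c1", 0:2, cbind(0:2, 0), cell_type = "neutrophil")
#' net_displacement(tr)
#' @export
track <- function(track_id, frames, positions,
                  cell_type = c("neutrophil", "macrophage"),
                  group = "", frame_interval = 1) {
  cell_type <- match.arg(cell_type)
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  frames <- as.integer(frames)
  x <- structure(
    list(track_id = as.character(track_id)[1L],
         frames = frames,
         positions = positions,
         cell_type = cell_type,
         group = as.character(group)[1L],
         frame_interval = as.numeric(frame_interval)[1L]),
    class = "track")
  validate_track(x)
}

validate_track <- function(x) {
  stopifnot(inherits(x, "track"))
  if (length(x$frames) < 2L)
    stop("track '", x$track_id, "' must have at least 2 frames", call. = FALSE)
  if (any(diff(x$frames) <= 0L))
    stop("track '", x$track_id, "' frames must be strictly increasing",
         call. = FALSE)
  if (ncol(x$positions) != 2L || nrow(x$positions) != length(x$frames))
    stop("positions must be an n x 2 matrix matching frames", call. = FALSE)
  if (!all(is.finite(x$positions)))
    stop("track '", x$track_id, "' has non-finite positions", call. = FALSE)
  if (!is.finite(x$frame_interval) || x$frame_interval <= 0)
    stop("frame_interval must be > 0", call. = FALSE)
  x
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("<track %s> %s, group '%s': %d frames (%d..%d), dt = %g min\n",
              x$track_id, x$cell_type, x$group, length(x$frames),
              min(x$frames), max(x$frames), x$frame_interval))
  invisible(x)
}

#' Times (minutes) at which a track was observed
#' @param track A [track()].
#' @return Numeric vector, `frames * frame_interval`.
#' @export
track_times <- function(track) track$frames * track$frame_interval

#' Construct a wound reference frame
#'
#' The wound frame carries the wound-edge geometry and the anteroposterior
#' (AP) body axis in one micrometre coordinate system. Distances to the wound
#' are shortest Euclidean distances to the edge polyline; the AP axis defines
#' the sign of the axial velocity projection, oriented so that positive
#' points toward the wound.
#'
#' @param wound_edge Numeric matrix of polyline vertices (>= 2 rows, columns
#'   x, y in micrometres); consecutive vertices must be distinct.
#' @param ap_axis Length-2 direction of the anteroposterior axis, positive
#'   toward the wound; normalised to unit length.
#' @param origin Reference point on the spine (default `c(0, 0)`).
#' @return An object of class `wound_frame`.
#' @examples
#' wf <- wound_frame(rbind(c(0, -200), c(0, 200)), ap_axis = c(-1, 0))
#' distance_to_wound(c(150, 0), wf)
#' @export
wound_frame <- function(wound_edge, ap_axis, origin = c(0, 0)) {
  wound_edge <- as.matrix(wound_edge)
  storage.mode(wound_edge) <- "double"
  if (nrow(wound_edge) < 2L || ncol(wound_edge) != 2L)
    stop("wound_edge must be a polyline of >= 2 vertices (m x 2 matrix)",
         call. = FALSE)
  seg <- diff(wound_edge)
  if (any(rowSums(seg^2) == 0))
    stop("wound_edge has a zero-length segment", call. = FALSE)
  ap_axis <- as.numeric(ap_axis)
  nrm <- sqrt(sum(ap_axis^2))
  if (!is.finite(nrm) || nrm == 0)
    stop("ap_axis must be a non-zero 2D vector", call. = FALSE)
  structure(list(wound_edge = wound_edge,
                 ap_axis = ap_axis / nrm,
                 origin = as.numeric(origin)),
            class = "wound_frame")
}

#' @export
print.wound_frame <- function(x, ...) {
  cat(sprintf("<wound_frame> %d-vertex edge, ap_axis (%.3f, %.3f)\n",
              nrow(x$wound_edge), x$ap_axis[1], x$ap_axis[2]))
  invisible(x)
}

#' Construct a cohort of tracks
#'
#' A cohort is a non-empty collection of tracks sharing one frame interval
#' and (typically) one group label, imaged in one wound frame. `t_start`
#' records the experiment start in minutes post wounding (default 60, i.e.
#' 1 hpw) and is metadata only: all lags are measured from each track's own
#' first frame.
#'
#' @param tracks List of [track()] objects.
#' @param t_start Minutes post wounding at frame 0 (default 60).
#' @return An object of class `cohort`.
#' @export
cohort <- function(tracks, t_start = 60) {
  if (length(tracks) == 0L) stop("cohort must contain >= 1 track", call. = FALSE)
  if (!all(vapply(tracks, inherits, logical(1), "track")))
    stop("all elements must be track objects", call. = FALSE)
  dts <- vapply(tracks, `[[`, numeric(1), "frame_interval")
  if (length(unique(dts)) != 1L)
    stop("all tracks in a cohort must share frame_interval", call. = FALSE)
  structure(list(tracks = tracks, t_start = as.numeric(t_start)[1L]),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d tracks, dt = %g min, t_start = %g min post wound\n",
              length(x$tracks), x$tracks[[1]]$frame_interval, x$t_start))
  invisible(x)
}

#' @export
length.cohort <- function(x) length(x$tracks)
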