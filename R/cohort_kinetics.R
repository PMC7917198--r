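#' Distance-to-wound time series of a single track
#'
#' @param track A [track()].
#' @param wound A [wound_frame()].
#' @return A `data.frame` with `time` (minutes from the track's first frame)
#'   and `distance` (um to the wound edge) at every tracked frame.
#' @export
distance_series <- function(track, wound) {
  stopifnot(inherits(track, "track"))
  data.frame(
    time = (track$frames - track$frames[1L]) * track$frame_interval,
    distance = distance_to_wound(track$positions, wound))
}

#' Anteroposterior velocity projection of a track
#'
#' Rotates the coordinate system so that the anteroposterior (AP) body axis
#' of the larva is aligned across experiments, then projects each
#' frame-to-frame velocity onto that axis. The AP axis in the wound frame is
#' oriented so that positive velocity means movement toward the wound.
#'
#' @param track A [track()].
#' @param wound A [wound_frame()] with `ap_axis` set.
#' @return An object of class `ap_projection`: a list with `time` (minutes,
#'   the start time of each step relative to the track's first frame),
#'   `step_frame` (0-based start frame of each step), `v_ap` (um/min per
#'   step) and `mean_v_ap` (average over steps).
#' @examples
#' wf <- wound_frame(rbind(c(0, -50), c(0, 50)), ap_axis = c(-1, 0))
#' tr <- track("a", 0:2, rbind(c(100, 0), c(95, 0), c(90, 0)))
#' v_ap(tr, wf)$mean_v_ap  # +5 um/min toward the wound
#' @export
v_ap <- function(track, wound) {
  stopifnot(inherits(track, "track"), inherits(wound, "wound_frame"))
  dp <- diff(track$positions)
  dtm <- diff(track$frames) * track$frame_interval
  vap <- (dp[, 1] * wound$ap_axis[1] + dp[, 2] * wound$ap_axis[2]) / dtm
  n <- length(track$frames)
  structure(list(
    time = (track$frames[-n] - track$frames[1L]) * track$frame_interval,
    step_frame = track$frames[-n],
    v_ap = as.numeric(vap),
    mean_v_ap = mean(vap)),
    class = "ap_projection")
}

#' @export
print.ap_projection <- function(x, ...) {
  cat(sprintf("<ap_projection> %d steps, mean V_AP = %.3g um/min\n",
              length(x$v_ap), x$mean_v_ap))
  invisible(x)
}

#' Cohort anteroposterior velocity over time
#'
#' Pools the per-step AP-projected velocities of all cells in the cohort by
#' frame, then averages over windows of `window` consecutive time frames
#' (non-overlapping by default). Each cell-step is weighted equally within a
#' window. Windows containing no observation are omitted (a gap, not zero).
#'
#' @param cohort A [cohort()].
#' @param wound A [wound_frame()].
#' @param window Number of consecutive frames per averaging window
#'   (default 3).
#' @param sliding If `TRUE`, use a sliding (overlapping) window centred on
#'   each frame instead of non-overlapping bins. Off by default.
#' @return A `data.frame` with `time` (window centre, minutes), `mean`
#'   (um/min), `sem` and `n` (number of pooled cell-steps).
#' @export
vap_over_time <- function(cohort, wound, window = 3, sliding = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  dt <- cohort$tracks[[1L]]$frame_interval
  steps <- do.call(rbind, lapply(cohort$tracks, function(tr) {
    ap <- v_ap(tr, wound)
    data.frame(frame = ap$step_frame, v_ap = ap$v_ap)
  }))
  bin <- if (sliding) steps$frame else steps$frame %/% window
  agg <- function(idx) {
    v <- steps$v_ap[idx]
    c(mean = mean(v),
      sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
      n = length(v))
  }
  if (sliding) {
    frames <- sort(unique(steps$frame))
    half <- (window - 1) %/% 2
    rows <- lapply(frames, function(f) {
      idx <- which(abs(steps$frame - f) <= half)
      c(time = f * dt, agg(idx))
    })
  } else {
    bins <- sort(unique(bin))
    rows <- lapply(bins, function(b) {
      idx <- which(bin == b)
      c(time = (b * window + (window - 1) / 2) * dt, agg(idx))
    })
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("time", "mean", "sem", "n")
  out$n <- as.integer(out$n)
  out
}
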