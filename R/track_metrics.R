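#' Per-track migration statistics
#'
#' Classical measures of single-cell motility computed from a 2D track:
#' net displacement (straight-line distance between first and last
#' position), total displacement (path length as the sum of successive
#' frame-to-frame step lengths), meandering index (their ratio, 1 for a
#' perfectly straight path, towards 0 for confined or random motion) and
#' mean speed (path length divided by elapsed tracking time).
#'
#' If a cell is undetected for intermediate frames, the step spans the gap
#' (no interpolation) and the elapsed time in [mean_speed()] counts the true
#' number of frames, so path length can underestimate the distance actually
#' travelled; the measures remain comparable across cohorts recorded at the
#' same frame rate.
#'
#' @param track A [track()].
#' @return A length-1 numeric: micrometres for displacements, a ratio in
#'   \[0, 1\] for [meandering_index()] (`NA` for a stationary cell, with a
#'   message), micrometres per minute for [mean_speed()].
#' @name track_statistics
#' @examples
#' tr <- track("a", 0:2, rbind(c(0, 0), c(1, 0), c(1, 1)))
#' net_displacement(tr)   # sqrt(2)
#' total_displacement(tr) # 2
#' meandering_index(tr)   # sqrt(2)/2
#' mean_speed(tr)         # 1 um/min
NULL

#' @rdname track_statistics
#' @export
net_displacement <- function(track) {
  stopifnot(inherits(track, "track"))
  p <- track$positions
  sqrt(sum((p[nrow(p), ] - p[1L, ])^2))
}

#' @rdname track_statistics
#' @export
total_displacement <- function(track) {
  stopifnot(inherits(track, "track"))
  sum(step_lengths(track))
}

#' @rdname track_statistics
#' @export
meandering_index <- function(track) {
  dtot <- total_displacement(track)
  if (dtot == 0) {
    message("meandering index undefined for stationary track '",
            track$track_id, "'; returning NA")
    return(NA_real_)
  }
  net_displacement(track) / dtot
}

#' @rdname track_statistics
#' @export
mean_speed <- function(track) {
  stopifnot(inherits(track, "track"))
  elapsed <- (track$frames[length(track$frames)] - track$frames[1L]) *
    track$frame_interval
  total_displacement(track) / elapsed
}

step_lengths <- function(track) {
  d <- diff(track$positions)
  sqrt(rowSums(d^2))
}

#' Classify a track as distant or local resident
#'
#' Classification uses only the starting location in the first frame of the
#' time lapse: cells starting further than `threshold` micrometres from the
#' wound edge are distant; cells starting within a distance of up to
#' `threshold` (inclusive) are local residents.
#'
#' @param track A [track()].
#' @param wound A [wound_frame()].
#' @param threshold Classification distance in micrometres (default 200).
#' @return `"distant"` or `"local_resident"`.
#' @export
classify_track <- function(track, wound, threshold = 200) {
  d0 <- distance_to_wound(track$positions[1L, ], wound)
  if (d0 > threshold) "distant" else "local_resident"
}

#' Arrival at and retention near the wound
#'
#' A cell has arrived once any tracked position lies within `radius`
#' micrometres (inclusive) of the wound edge; it stayed if every frame from
#' first arrival onward remains within that radius.
#'
#' @inheritParams classify_track
#' @param radius Capture radius in micrometres (default 20).
#' @return A list with `arrived` (logical), `first_arrival_time` (minutes
#'   from the track's first frame, `NA` if never arrived) and `stayed`
#'   (logical, `NA` if never arrived).
#' @export
arrival_status <- function(track, wound, radius = 20) {
  d <- distance_to_wound(track$positions, wound)
  within <- d <= radius
  if (!any(within))
    return(list(arrived = FALSE, first_arrival_time = NA_real_, stayed = NA))
  first <- which(within)[1L]
  list(arrived = TRUE,
       first_arrival_time =
         (track$frames[first] - track$frames[1L]) * track$frame_interval,
       stayed = all(within[first:length(within)]))
}

#' Count recruited cells near the wound
#'
#' Counts the positions lying within a band of `band` micrometres
#' (inclusive) from the wound edge toward the body trunk, the operational
#' definition of a recruited cell in fixed-timepoint counting.
#'
#' @param points An n x 2 matrix of cell positions (um); may have 0 rows.
#' @param wound A [wound_frame()].
#' @param band Band width in micrometres (default 200).
#' @return Integer count.
#' @export
count_recruited <- function(points, wound, band = 200) {
  p <- if (is.null(dim(points))) matrix(as.numeric(points), ncol = 2L)
       else as.matrix(points)
  if (nrow(p) == 0L) return(0L)
  sum(distance_to_wound(p, wound) <= band)
}

#' Summarise every track in a cohort
#'
#' Computes the full per-track metric set: displacements, meandering index,
#' mean speed, mean anteroposterior velocity, distant/local classification
#' and arrival/retention status.
#'
#' Because cell behaviour changes once a cell reaches the wound (arrested
#' cells stop moving), `until_arrival = TRUE` computes the displacement,
#' meandering, speed and axial-velocity statistics on the pre-arrival
#' segment of each track only (up to and including the first frame within
#' `radius` of the wound edge); classification and arrival columns always
#' use the full track.
#'
#' @param cohort A [cohort()].
#' @param wound A [wound_frame()].
#' @param threshold Distant/local classification distance, um (default 200).
#' @param radius Arrival capture radius, um (default 20).
#' @param until_arrival Restrict motility metrics to the pre-arrival part
#'   of each track (default `FALSE`).
#' @return A `data.frame` with one row per track and columns `track_id`,
#'   `cell_type`, `group`, `d_net`, `d_tot`, `meandering_index`,
#'   `mean_speed`, `mean_v_ap`, `category`, `arrived`, `first_arrival_time`,
#'   `stayed_at_wound`.
#' @export
summarize_tracks <- function(cohort, wound, threshold = 200, radius = 20,
                             until_arrival = FALSE) {
  stopifnot(inherits(cohort, "cohort"), inherits(wound, "wound_frame"))
  rows <- lapply(cohort$tracks, function(tr) {
    arr <- arrival_status(tr, wound, radius)
    mt <- tr
    if (until_arrival && arr$arrived) {
      cut <- max(2L, which(distance_to_wound(tr$positions, wound) <=
                             radius)[1L])
      mt <- track(tr$track_id, tr$frames[seq_len(cut)],
                  tr$positions[seq_len(cut), , drop = FALSE],
                  cell_type = tr$cell_type, group = tr$group,
                  frame_interval = tr$frame_interval)
    }
    data.frame(
      track_id = tr$track_id,
      cell_type = tr$cell_type,
      group = tr$group,
      d_net = net_displacement(mt),
      d_tot = total_displacement(mt),
      meandering_index = suppressMessages(meandering_index(mt)),
      mean_speed = mean_speed(mt),
      mean_v_ap = v_ap(mt, wound)$mean_v_ap,
      category = classify_track(tr, wound, threshold),
      arrived = arr$arrived,
      first_arrival_time = arr$first_arrival_time,
      stayed_at_wound = arr$stayed,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
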