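#' Default wound geometry for simulations
#'
#' A single near-vertical wound edge at x = 0 (a tail-fin cut), spanning
#' `c(-half_length, half_length)` in y, with the anteroposterior axis along
#' -x so that cells placed at x > 0 move toward the wound when their AP
#' velocity is positive.
#'
#' @param half_length Half-extent of the wound edge in y, um (default 200).
#' @return A [wound_frame()].
#' @export
default_wound <- function(half_length = 200) {
  wound_frame(rbind(c(0, -half_length), c(0, half_length)),
              ap_axis = c(-1, 0), origin = c(0, 0))
}

#' Configuration of a synthetic leukocyte cohort
#'
#' Parameters of a discrete correlated random walk emulating leukocyte
#' migration in a 2 h time-lapse at 1 min frame interval. Each walker moves
#' with constant step length `v_true * dt`; its heading carries over from
#' step to step with directional correlation `exp(-dt/tau_true)`
#' (wrapped-normal turning noise), which makes the cohort's MSD converge to
#' the persistent-random-walk closed form with intrinsic speed `v_true` and
#' persistence time `tau_true`. With `bias > 0` the heading relaxes toward
#' the wound-ward direction with weight `bias` (1 = fully wound-directed),
#' and cells entering `arrest_radius` of the wound edge stop; arrest is
#' absorbing unless `depart_prob > 0`, in which case an arrested cell
#' resumes walking with that per-frame probability.
#'
#' @param n_cells Number of cells (default 50).
#' @param duration Movie duration in minutes (default 120, i.e. 2 h).
#' @param dt Frame interval in minutes (default 1).
#' @param v_true Intrinsic speed, um/min (default 6, a typical zebrafish
#'   neutrophil interstitial speed).
#' @param tau_true Persistence time, min (default 10).
#' @param bias Chemotactic bias in \[0, 1\]; 0 = unbiased PRW (default 0).
#' @param arrest_radius Arrest distance from the wound edge, um (default 20).
#' @param depart_prob Per-frame probability that an arrested cell resumes
#'   migration (default 0 = absorbing arrest). A departing cell is
#'   desensitised: it walks on unbiased and does not re-arrest, emulating
#'   resident cells that leave the wound again.
#' @param start_band Range of initial distances from the wound edge, um
#'   (default `c(50, 350)`, spanning local-resident and distant cells).
#' @param seed Integer RNG seed; same seed, same cohort.
#' @param wound A [wound_frame()] (default [default_wound()]).
#' @param cell_type,group Labels attached to the generated tracks.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_cells = 50, duration = 120, dt = 1,
                              v_true = 6, tau_true = 10, bias = 0,
                              arrest_radius = 20, depart_prob = 0,
                              start_band = c(50, 350), seed = 1,
                              wound = default_wound(),
                              cell_type = "neutrophil", group = "sim") {
  stopifnot(n_cells >= 1, dt > 0, duration / dt >= 2,
            v_true >= 0, tau_true > 0, bias >= 0, bias <= 1,
            arrest_radius >= 0, depart_prob >= 0, depart_prob <= 1,
            length(start_band) == 2L, start_band[1] <= start_band[2],
            inherits(wound, "wound_frame"))
  structure(list(n_cells = as.integer(n_cells), duration = duration, dt = dt,
                 v_true = v_true, tau_true = tau_true, bias = bias,
                 arrest_radius = arrest_radius, depart_prob = depart_prob,
                 start_band = as.numeric(start_band),
                 seed = as.integer(seed), wound = wound,
                 cell_type = cell_type, group = group),
            class = "simulation_config")
}

#' Simulate a cohort of persistent random walkers
#'
#' Generates `n_cells` correlated-random-walk tracks under a
#' [simulation_config()]. Walkers start uniformly within `start_band` of the
#' wound edge (uniform in y over the edge extent), with uniform initial
#' headings. At each step the heading direction is mixed with the
#' wound-ward direction with weight `bias`, perturbed by wrapped-normal
#' turning noise of variance `2*dt/tau_true` (so the per-step directional
#' correlation is `exp(-dt/tau_true)`), and the cell advances `v_true * dt`.
#' With `bias > 0`, cells reaching `arrest_radius` of the wound arrest.
#'
#' @param config A [simulation_config()].
#' @return A [cohort()] of `n_cells` tracks with frames `0:(duration/dt)`.
#' @examples
#' co <- simulate_cohort(simulation_config(n_cells = 3, seed = 7))
#' co
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_steps <- floor(config$duration / config$dt)
  sigma_turn <- sqrt(2 * config$dt / config$tau_true)
  ylim <- range(config$wound$wound_edge[, 2])
  tracks <- vector("list", config$n_cells)
  for (i in seq_len(config$n_cells)) {
    pos <- matrix(NA_real_, n_steps + 1L, 2L)
    # wound edge is at x = 0; start_band is distance toward the trunk (+x)
    pos[1L, ] <- c(stats::runif(1, config$start_band[1], config$start_band[2]),
                   stats::runif(1, ylim[1], ylim[2]))
    theta <- stats::runif(1, -pi, pi)
    arrested <- FALSE
    departed <- FALSE   # a departed cell walks on unbiased, no re-arrest
    for (s in seq_len(n_steps)) {
      if (arrested && config$depart_prob > 0 &&
          stats::runif(1) < config$depart_prob) {
        arrested <- FALSE
        departed <- TRUE
        theta <- stats::runif(1, -pi, pi)
      }
      if (arrested) {
        pos[s + 1L, ] <- pos[s, ]
        next
      }
      heading <- c(cos(theta), sin(theta))
      if (config$bias > 0 && !departed) {
        wdir <- wound_direction(pos[s, ], config$wound)[1L, ]
        target <- (1 - config$bias) * heading + config$bias * wdir
        if (sum(target^2) < 1e-12) target <- wdir
        theta <- atan2(target[2], target[1])
      }
      theta <- theta + stats::rnorm(1, 0, sigma_turn)
      pos[s + 1L, ] <- pos[s, ] +
        config$v_true * config$dt * c(cos(theta), sin(theta))
      if (config$bias > 0 && !departed &&
          distance_to_wound(pos[s + 1L, ], config$wound) <=
            config$arrest_radius)
        arrested <- TRUE
    }
    tracks[[i]] <- track(sprintf("sim%03d", i), 0:n_steps, pos,
                         cell_type = config$cell_type, group = config$group,
                         frame_interval = config$dt)
  }
  cohort(tracks)
}

#' Simulate per-frame detections with dropouts
#'
#' Runs [simulate_cohort()] and converts the tracks into per-frame
#' detection point sets, dropping each detection independently with
#' probability `miss_rate` (Bernoulli per cell per frame). The ground-truth
#' cell identity of every surviving detection is retained for scoring a
#' tracker's link accuracy.
#'
#' @param config A [simulation_config()].
#' @param miss_rate Per-frame detection miss probability in \[0, 0.3\].
#' @return An object of class `detection_movie`: a list with `frames` (a
#'   list, one n_i x 2 position matrix per frame), `truth` (parallel list of
#'   integer cell ids), `dt` (frame interval) and `cohort` (the underlying
#'   ground-truth [cohort()]).
#' @export
simulate_detection_movie <- function(config, miss_rate = 0) {
  stopifnot(miss_rate >= 0, miss_rate <= 0.3)
  co <- simulate_cohort(config)
  n_frames <- length(co$tracks[[1L]]$frames)
  # dropout draws follow the cohort draws under the same seed stream
  keep <- matrix(stats::runif(length(co$tracks) * n_frames) >= miss_rate,
                 nrow = length(co$tracks))
  frames <- truth <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    ids <- which(keep[, f])
    frames[[f]] <- do.call(rbind, c(lapply(ids, function(i)
      co$tracks[[i]]$positions[f, , drop = FALSE]), list(matrix(0, 0, 2))))
    truth[[f]] <- as.integer(ids)
  }
  structure(list(frames = frames, truth = truth, dt = co$tracks[[1L]]$frame_interval,
                 cohort = co),
            class = "detection_movie")
}

#' @export
print.detection_movie <- function(x, ...) {
  cat(sprintf("<detection_movie> %d frames, %d detections total\n",
              length(x$frames), sum(vapply(x$frames, nrow, integer(1)))))
  invisible(x)
}
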