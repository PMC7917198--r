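# shared fixtures and independent oracles

make_track <- function(xy, id = "t1", frames = NULL, dt = 1, ...) {
  xy <- as.matrix(xy)
  if (is.null(frames)) frames <- seq_len(nrow(xy)) - 1L
  track(id, frames, xy, frame_interval = dt, ...)
}

vertical_wound <- function(x = 0, half = 200, toward = c(-1, 0)) {
  wound_frame(rbind(c(x, -half), c(x, half)), ap_axis = toward)
}

random_track <- function(n = 10, id = "r", dt = 1, spread = 5) {
  make_track(apply(matrix(stats::rnorm(2 * n, sd = spread), ncol = 2), 2,
                   cumsum), id = id, dt = dt)
}

# brute-force anchored cohort MSD: explicit double loop over cells and lags
oracle_msd_anchored <- function(cohort, kmax) {
  dt <- cohort$tracks[[1]]$frame_interval
  out <- data.frame(lag = numeric(), msd = numeric(), sem = numeric(),
                    n_cells = integer())
  for (k in seq_len(kmax)) {
    vals <- c()
    for (tr in cohort$tracks) {
      rel <- tr$frames - tr$frames[1]
      j <- which(rel == k)
      if (length(j) == 1)
        vals <- c(vals, sum((tr$positions[j, ] - tr$positions[1, ])^2))
    }
    if (length(vals) == 0) next
    out <- rbind(out, data.frame(
      lag = k * dt, msd = mean(vals),
      sem = if (length(vals) > 1) sd(vals) / sqrt(length(vals)) else 0,
      n_cells = length(vals)))
  }
  out
}

# dense-sampling oracle for point-to-polyline distance
oracle_polyline_distance <- function(p, vertices, n_samples = 1e4) {
  best <- Inf
  for (s in seq_len(nrow(vertices) - 1)) {
    t <- seq(0, 1, length.out = n_samples)
    qx <- vertices[s, 1] + t * (vertices[s + 1, 1] - vertices[s, 1])
    qy <- vertices[s, 2] + t * (vertices[s + 1, 2] - vertices[s, 2])
    best <- min(best, sqrt((p[1] - qx)^2 + (p[2] - qy)^2))
  }
  best
}

# exhaustive-enumeration optimum of the linking objective: maximize, over
# all successor assignments (each detection has at most one successor and
# one predecessor, frames increasing, gaps within the model), the summed
# score of the resulting chains of length >= 2; unlinked detections are
# cost-free clutter
oracle_best_link_score <- function(det, model) {
  n <- nrow(det)
  if (n == 0) return(0)
  succ_cand <- lapply(seq_len(n), function(i) {
    span <- det$frame - det$frame[i]
    which(span >= 1 & span <= model$max_gap + 1)
  })
  best <- 0
  succ <- rep(NA_integer_, n)
  has_pred <- rep(FALSE, n)
  score_assignment <- function() {
    starts <- which(!has_pred & !is.na(succ))
    total <- 0
    all_chained <- which(!has_pred)
    for (s in all_chained) {
      path <- s
      while (!is.na(succ[path[length(path)]]))
        path <- c(path, succ[path[length(path)]])
      if (length(path) >= 2)
        total <- total + woundtrack:::path_score(path, det, model)
    }
    total
  }
  rec <- function(i) {
    if (i > n) {
      best <<- max(best, score_assignment())
      return(invisible())
    }
    rec(i + 1)                       # no successor
    for (j in succ_cand[[i]]) {
      if (has_pred[j]) next
      succ[i] <<- j; has_pred[j] <<- TRUE
      rec(i + 1)
      succ[i] <<- NA_integer_; has_pred[j] <<- FALSE
    }
  }
  rec(1)
  best
}

# random small linking instance: n cells drifting smoothly, optional drops
random_link_instance <- function(n_cells, n_frames, sigma = 3,
                                 box = 60, drop = 0) {
  pos <- matrix(stats::runif(2 * n_cells, 0, box), ncol = 2)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    keep <- stats::runif(n_cells) >= drop
    frames[[f]] <- pos[keep, , drop = FALSE]
    pos <- pos + matrix(stats::rnorm(2 * n_cells, sd = sigma), ncol = 2)
  }
  frames
}

rigid_transform <- function(xy, angle, shift) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(xy %*% t(R), 2, shift, "+")
}
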