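#' Scoring model for global track linking
#'
#' Log-likelihood-style scores used by the global linker. A candidate track
#' scores `appear_logp` for entering the field, `disappear_logp` for
#' leaving, `det_logp` for each detection it claims (the log likelihood
#' ratio of a true detection versus clutter; must be > 0 for any track to be
#' worth creating) and, for each link spanning `k` frames over displacement
#' `d`, a motion score `-d^2 / (2 sigma^2 k) + (k - 1) * gap_logp`. Links
#' may skip up to `max_gap` missed frames. Unclaimed detections are treated
#' as cost-free clutter, so a track is kept only while its total score is
#' positive, which subsumes the appear-plus-disappear floor.
#'
#' @param sigma Expected frame-to-frame displacement scale, um.
#' @param appear_logp,disappear_logp Log-probabilities (<= 0) of a track
#'   entering or leaving the imaged field.
#' @param det_logp Per-detection log likelihood ratio (> 0).
#' @param gap_logp Log-probability (<= 0) of a missed detection, paid per
#'   skipped frame.
#' @param max_gap Maximum number of consecutive missed frames a link may
#'   span (default 1).
#' @return An object of class `link_score_model`.
#' @export
link_score_model <- function(sigma, appear_logp = -5, disappear_logp = -5,
                             det_logp = 5, gap_logp = log(0.1), max_gap = 1) {
  stopifnot(sigma > 0, appear_logp <= 0, disappear_logp <= 0,
            det_logp > 0, gap_logp <= 0, max_gap >= 0)
  structure(list(sigma = sigma, appear_logp = appear_logp,
                 disappear_logp = disappear_logp, det_logp = det_logp,
                 gap_logp = gap_logp, max_gap = as.integer(max_gap)),
            class = "link_score_model")
}

motion_score <- function(a, b, k, model) {
  -sum((b - a)^2) / (2 * model$sigma^2 * k) + (k - 1) * model$gap_logp
}

# score of one path (vector of row indices into det), including
# appearance/disappearance and per-detection terms
path_score <- function(path, det, model) {
  s <- model$appear_logp + model$disappear_logp +
    length(path) * model$det_logp
  if (length(path) > 1L) {
    for (i in seq_len(length(path) - 1L)) {
      a <- path[i]; b <- path[i + 1L]
      s <- s + motion_score(c(det$x[a], det$y[a]), c(det$x[b], det$y[b]),
                            det$frame[b] - det$frame[a], model)
    }
  }
  s
}

as_detection_table <- function(detections) {
  frames <- if (inherits(detections, "detection_movie")) detections$frames
            else detections
  rows <- lapply(seq_along(frames), function(f) {
    m <- frames[[f]]
    if (is.null(m) || nrow(m) == 0L)
      return(data.frame(frame = integer(), x = numeric(), y = numeric()))
    data.frame(frame = f - 1L, x = m[, 1], y = m[, 2])
  })
  det <- do.call(rbind, rows)
  rownames(det) <- NULL
  det
}

#' Link per-frame detections into tracks (sequential Viterbi with swaps)
#'
#' Global-linking tracker: tracks are created one at a time, each as the
#' highest-scoring path through the detection graph (states are the
#' detections plus a birth and a death state; links may span up to
#' `max_gap` missed frames). While a new track is created, swap operations
#' may modify links in the pre-existing tracks: the search runs on the
#' residual graph in which every link already claimed by a track can be
#' traversed in reverse at negated score, so a new path can re-route
#' earlier tracks wherever that raises the total score. Each accepted path
#' therefore increases the total score by the largest possible amount, and
#' iteration stops when the best candidate is no longer worth a track (its
#' score, including the appearance and disappearance penalties, is not
#' positive) - at which point the linking is the global optimum of the
#' scoring model. Cell division and death are not modelled: tracks neither
#' split nor merge.
#'
#' @param detections A `detection_movie` from [simulate_detection_movie()],
#'   or a list with one n_i x 2 position matrix per frame (possibly empty).
#' @param model A [link_score_model()].
#' @param frame_interval Minutes per frame for the output tracks (taken
#'   from a `detection_movie`, default 1 otherwise).
#' @param swap If `TRUE` (default) allow swap operations during the path
#'   search; `FALSE` restricts each new track to unclaimed detections
#'   (plain greedy sequential linking, not guaranteed optimal).
#' @return An object of class `linked_tracks`: a list with `tracks` (a list
#'   of [track()] objects), `paths` (detection-index paths), `det` (the
#'   detection table), `model` and `score` (total model score).
#' @export
link_detections <- function(detections, model, frame_interval = NULL,
                            swap = TRUE) {
  stopifnot(inherits(model, "link_score_model"))
  if (is.null(frame_interval))
    frame_interval <- if (inherits(detections, "detection_movie"))
      detections$dt else 1
  det <- as_detection_table(detections)
  n <- nrow(det)
  if (n == 0L) return(build_linked(list(), det, model, frame_interval))
  # unit-capacity score network: S -> in(d) -> out(d) -> {in(e), T}
  S <- 1L; T <- 2L
  node_in <- function(d) 2L + d
  node_out <- function(d) 2L + n + d
  span <- outer(det$frame, det$frame, function(b, a) b - a)
  ok <- which(span >= 1L & span <= model$max_gap + 1L, arr.ind = TRUE)
  a <- ok[, 2L]; b <- ok[, 1L]          # link a -> b, frame[b] > frame[a]
  k <- det$frame[b] - det$frame[a]
  m_score <- -((det$x[b] - det$x[a])^2 + (det$y[b] - det$y[a])^2) /
    (2 * model$sigma^2 * k) + (k - 1L) * model$gap_logp
  arc_from <- c(rep(S, n), node_in(seq_len(n)), node_out(seq_len(n)),
                node_out(a))
  arc_to <- c(node_in(seq_len(n)), node_out(seq_len(n)), rep(T, n),
              node_in(b))
  arc_score <- c(rep(model$appear_logp, n), rep(model$det_logp, n),
                 rep(model$disappear_logp, n), m_score)
  flow <- rep(FALSE, length(arc_from))
  n_nodes <- 2L + 2L * n
  repeat {
    # residual graph: unused arcs forward, claimed arcs reversed (swaps)
    if (swap) {
      rf <- c(arc_from[!flow], arc_to[flow])
      rt <- c(arc_to[!flow], arc_from[flow])
      rs <- c(arc_score[!flow], -arc_score[flow])
      rid <- c(which(!flow), which(flow))
    } else {
      taken <- which(flow[(n + 1L):(2L * n)])   # already-claimed detections
      blk <- c(node_in(taken), node_out(taken))
      keep <- !flow & !(arc_from %in% blk) & !(arc_to %in% blk)
      rf <- arc_from[keep]; rt <- arc_to[keep]
      rs <- arc_score[keep]; rid <- which(keep)
    }
    # Bellman-Ford sweeps for the maximum-score augmenting path
    dist <- rep(-Inf, n_nodes); dist[S] <- 0
    pred <- rep(NA_integer_, n_nodes)
    for (pass in seq_len(n_nodes)) {
      cand <- dist[rf] + rs
      ord <- order(rt, cand, decreasing = TRUE)
      sel <- ord[!duplicated(rt[ord])]
      upd <- sel[cand[sel] > dist[rt[sel]] + 1e-12]
      if (!length(upd)) break
      dist[rt[upd]] <- cand[upd]
      pred[rt[upd]] <- upd
    }
    if (!is.finite(dist[T]) || dist[T] <= 1e-12) break
    node <- T
    steps <- 0L
    while (node != S) {
      r <- pred[node]
      flow[rid[r]] <- !flow[rid[r]]
      node <- rf[r]
      steps <- steps + 1L
      if (steps > 2L * n_nodes)
        stop("internal error: augmenting path reconstruction cycled")
    }
  }
  # read tracks off the flow: claimed motion arcs define successors
  succ <- rep(NA_integer_, n)
  on_link <- which(flow)
  on_link <- on_link[on_link > 3L * n]
  succ[a[on_link - 3L * n]] <- b[on_link - 3L * n]
  has_pred <- rep(FALSE, n)
  has_pred[succ[!is.na(succ)]] <- TRUE
  claimed <- flow[(n + 1L):(2L * n)]
  paths <- lapply(which(claimed & !has_pred), function(s) {
    p <- s
    while (!is.na(succ[p[length(p)]])) p <- c(p, succ[p[length(p)]])
    p
  })
  paths <- paths[vapply(paths, length, integer(1)) >= 2L]
  build_linked(paths, det, model, frame_interval)
}

build_linked <- function(paths, det, model, frame_interval) {
  tracks <- lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    track(sprintf("link%03d", i), det$frame[p],
          cbind(det$x[p], det$y[p]), frame_interval = frame_interval)
  })
  structure(list(tracks = tracks, paths = paths, det = det, model = model,
                 score = sum(vapply(paths, path_score, numeric(1),
                                    det = det, model = model))),
            class = "linked_tracks")
}

#' @export
print.linked_tracks <- function(x, ...) {
  cat(sprintf("<linked_tracks> %d tracks over %d detections, score %.3f\n",
              length(x$paths), nrow(x$det), x$score))
  invisible(x)
}

#' Swap pass: exchange links between tracks to raise the total score
#'
#' For every pair of tracks and every pair of link positions, considers
#' exchanging the two tails (including moving a whole tail from one track
#' to the end of another) and applies the exchange whenever it raises the
#' total model score, repeating until a fixed point. Tracks whose total
#' score is no longer positive after swapping are dissolved and their
#' detections returned to the unclaimed pool. The total score never
#' decreases.
#'
#' @param linked A `linked_tracks` object from [link_detections()].
#' @param model A [link_score_model()]; defaults to the model stored in
#'   `linked`.
#' @return A `linked_tracks` object with the improved linking.
#' @export
swap_pass <- function(linked, model = linked$model) {
  stopifnot(inherits(linked, "linked_tracks"))
  sw <- run_swaps(linked$paths, linked$det, model)
  build_linked(sw$paths, linked$det, model,
               linked$tracks[[1L]]$frame_interval %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_swaps <- function(paths, det, model, max_iter = 10000L) {
  if (length(paths) == 0L) return(list(paths = paths))
  valid_link <- function(a, b) {
    k <- det$frame[b] - det$frame[a]
    k >= 1L && k <= model$max_gap + 1L
  }
  # a track's contribution to the objective: dissolving it back into
  # clutter (score 0) is always available, so never below zero
  contrib <- function(p) {
    if (length(p) == 0L) return(0)
    max(path_score(p, det, model), 0)
  }
  # first improving move, or NULL at the fixed point; moves are tail
  # exchanges between two tracks (empty prefixes allowed, which subsumes
  # merging one track onto another) and single-track splits
  find_move <- function(paths) {
    for (ai in seq_along(paths)) {
      A <- paths[[ai]]
      # split A at any link
      for (i in seq_len(length(A) - 1L)) {
        p1 <- A[seq_len(i)]; p2 <- A[(i + 1L):length(A)]
        if (contrib(p1) + contrib(p2) > contrib(A) + 1e-12)
          return(list(idx = ai, new = list(p1, p2)))
      }
      for (bi in seq_along(paths)) {
        if (ai >= bi) next
        B <- paths[[bi]]
        for (i in 0:length(A)) for (j in 0:length(B)) {
          if (i == 0L && j == 0L) next
          if (i == length(A) && j == length(B)) next
          tailA <- if (i < length(A)) A[(i + 1L):length(A)] else integer()
          tailB <- if (j < length(B)) B[(j + 1L):length(B)] else integer()
          ok <- (i == 0L || !length(tailB) || valid_link(A[i], tailB[1L])) &&
                (j == 0L || !length(tailA) || valid_link(B[j], tailA[1L]))
          if (!ok) next
          nA <- c(A[seq_len(i)], tailB)
          nB <- c(B[seq_len(j)], tailA)
          if (contrib(nA) + contrib(nB) >
                contrib(A) + contrib(B) + 1e-12)
            return(list(idx = c(ai, bi), new = list(nA, nB)))
        }
      }
    }
    NULL
  }
  for (iter in seq_len(max_iter)) {
    mv <- find_move(paths)
    if (is.null(mv)) break
    for (k in seq_along(mv$idx)) paths[[mv$idx[k]]] <- mv$new[[k]]
    if (length(mv$new) > length(mv$idx))
      paths <- c(paths, mv$new[-seq_along(mv$idx)])
    paths <- paths[vapply(paths, length, integer(1)) > 0L]
  }
  # dissolve tracks that moves have made worthless (e.g. singletons)
  scores <- vapply(paths, path_score, numeric(1), det = det, model = model)
  list(paths = paths[scores > 0])
}

#' Fraction of ground-truth links recovered by a tracker
#'
#' A ground-truth link is a pair of consecutive detections of the same
#' simulated cell; it counts as recovered when the two detections are
#' adjacent in the same linked track. Truth links spanning more frames than
#' the model's `max_gap` allows are excluded from the denominator.
#'
#' @param linked A `linked_tracks` from [link_detections()].
#' @param movie The `detection_movie` the detections came from.
#' @return Fraction in \[0, 1\] (1 when every recoverable link is found).
#' @export
link_accuracy <- function(linked, movie) {
  stopifnot(inherits(linked, "linked_tracks"),
            inherits(movie, "detection_movie"))
  det <- linked$det
  # map detection rows back to (frame, cell): rows of as_detection_table
  # enumerate frames in order, cells in truth order
  cell <- unlist(movie$truth)
  stopifnot(length(cell) == nrow(det))
  link_of <- rep(NA_integer_, nrow(det))   # successor within a linked path
  for (p in linked$paths)
    if (length(p) > 1L)
      link_of[p[-length(p)]] <- p[-1L]
  total <- 0L; correct <- 0L
  for (cl in unique(cell)) {
    rows <- which(cell == cl)
    rows <- rows[order(det$frame[rows])]
    if (length(rows) < 2L) next
    for (i in seq_len(length(rows) - 1L)) {
      span <- det$frame[rows[i + 1L]] - det$frame[rows[i]]
      if (span > linked$model$max_gap + 1L) next
      total <- total + 1L
      if (!is.na(link_of[rows[i]]) && link_of[rows[i]] == rows[i + 1L])
        correct <- correct + 1L
    }
  }
  if (total == 0L) return(NA_real_)
  correct / total
}
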