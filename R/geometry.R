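#' Shortest Euclidean distance from points to the wound edge
#'
#' The wound edge is a polyline; the distance from a point is the minimum
#' over its segments of the point-to-segment distance (orthogonal projection
#' onto the segment, clamped to the endpoints).
#'
#' @param points A length-2 numeric vector, or an n x 2 matrix of points (um).
#' @param wound A [wound_frame()].
#' @return Numeric vector of distances in micrometres, one per point.
#' @export
distance_to_wound <- function(points, wound) {
  stopifnot(inherits(wound, "wound_frame"))
  p <- if (is.null(dim(points))) matrix(as.numeric(points), ncol = 2L)
       else as.matrix(points)
  if (ncol(p) != 2L) stop("points must be 2D", call. = FALSE)
  v <- wound$wound_edge
  d2 <- rep(Inf, nrow(p))
  for (s in seq_len(nrow(v) - 1L)) {
    a <- v[s, ]; b <- v[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    # parameter of orthogonal projection, clamped to [0, 1]
    t <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(1, pmax(0, t))
    dx <- p[, 1] - (a[1] + t * ab[1])
    dy <- p[, 2] - (a[2] + t * ab[2])
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

# unit vector(s) from points toward the nearest point on the wound edge;
# zero vector for points lying on the edge
wound_direction <- function(points, wound) {
  p <- if (is.null(dim(points))) matrix(as.numeric(points), ncol = 2L)
       else as.matrix(points)
  v <- wound$wound_edge
  best <- rep(Inf, nrow(p))
  cx <- cy <- numeric(nrow(p))
  for (s in seq_len(nrow(v) - 1L)) {
    a <- v[s, ]; b <- v[s + 1L, ]
    ab <- b - a
    t <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2]) / sum(ab^2)
    t <- pmin(1, pmax(0, t))
    qx <- a[1] + t * ab[1]; qy <- a[2] + t * ab[2]
    d2 <- (p[, 1] - qx)^2 + (p[, 2] - qy)^2
    upd <- d2 < best
    best[upd] <- d2[upd]; cx[upd] <- qx[upd]; cy[upd] <- qy[upd]
  }
  dir <- cbind(cx - p[, 1], cy - p[, 2])
  nrm <- sqrt(rowSums(dir^2))
  pos <- nrm > 0
  dir[pos, ] <- dir[pos, , drop = FALSE] / nrm[pos]
  dir[!pos, ] <- 0
  dir
}
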