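#' Cohort mean squared displacement
#'
#' Computes the cohort-level MSD curve by averaging, at each time lag t, the
#' squared displacement of each cell from its own first tracked frame to the
#' frame at lag t (anchored MSD). This is not the time-averaged MSD common
#' in single-particle tracking: every cell contributes one squared
#' displacement per lag, anchored at its start. Cells that lack the frame at
#' a given lag are excluded from that lag and `n_cells` records the
#' inclusion count; `sem` is the sample standard deviation across cells
#' divided by `sqrt(n_cells)`.
#'
#' A conventional time-averaged variant (averaging over all start points
#' within each track before averaging over cells) is available with
#' `anchored = FALSE` for comparison.
#'
#' @param cohort A [cohort()].
#' @param max_lag Largest lag in minutes (default: longest track span).
#'   Lags with no contributing cell are dropped from the end of the curve,
#'   with a message.
#' @param anchored If `TRUE` (default) anchor at each track's first frame;
#'   if `FALSE` compute the time-averaged MSD.
#' @return An object of classes `msd_curve` and `data.frame` with columns
#'   `lag` (minutes, starting at 0), `msd` (um^2), `sem` (um^2), `n_cells`.
#' @examples
#' co <- simulate_cohort(simulation_config(n_cells = 5, seed = 1))
#' head(compute_msd(co))
#' @export
compute_msd <- function(cohort, max_lag = NULL, anchored = TRUE) {
  stopifnot(inherits(cohort, "cohort"))
  dt <- cohort$tracks[[1L]]$frame_interval
  spans <- vapply(cohort$tracks, function(tr)
    tr$frames[length(tr$frames)] - tr$frames[1L], integer(1))
  kmax <- if (is.null(max_lag)) max(spans) else floor(max_lag / dt)
  kmax <- max(1L, as.integer(kmax))
  sq <- matrix(NA_real_, nrow = length(cohort$tracks), ncol = kmax)
  for (i in seq_along(cohort$tracks)) {
    tr <- cohort$tracks[[i]]
    rel <- tr$frames - tr$frames[1L]   # frames relative to track start
    if (anchored) {
      idx <- match(seq_len(kmax), rel)
      have <- !is.na(idx)
      if (any(have)) {
        dxy <- tr$positions[idx[have], , drop = FALSE] -
          matrix(tr$positions[1L, ], sum(have), 2L, byrow = TRUE)
        sq[i, have] <- rowSums(dxy^2)
      }
    } else {
      for (k in seq_len(min(kmax, max(rel)))) {
        j <- match(rel + k, rel)   # pair each start frame with frame + k
        ok <- !is.na(j)
        if (any(ok)) {
          dxy <- tr$positions[j[ok], , drop = FALSE] -
            tr$positions[ok, , drop = FALSE]
          sq[i, k] <- mean(rowSums(dxy^2))
        }
      }
    }
  }
  n <- colSums(!is.na(sq))
  msd <- colMeans(sq, na.rm = TRUE)
  sdv <- apply(sq, 2L, stats::sd, na.rm = TRUE)
  sem <- ifelse(n > 1L, sdv / sqrt(n), 0)
  keep <- n > 0L
  if (!all(keep)) {
    last <- if (any(keep)) max(which(keep)) else 0L
    message("MSD truncated at lag ", last * dt,
            " min: no cells populate later lags")
    keep <- seq_len(kmax) <= last
  }
  out <- data.frame(lag = c(0, seq_len(kmax)[keep] * dt),
                    msd = c(0, msd[keep]),
                    sem = c(0, sem[keep]),
                    n_cells = c(length(cohort$tracks), n[keep]))
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Fit the persistent-random-walk (Fuerth) model to an MSD curve
#'
#' Fits the 2D persistent-random-walk closed form
#' \deqn{MSD(t) = 2 v^2 \tau t - 2 (v\tau)^2 (1 - e^{-t/\tau})}
#' to a cohort MSD curve by unweighted nonlinear least squares
#' (Levenberg-Marquardt), giving the intrinsic cell speed v (um/min), the
#' persistence time tau (min) and, via the long-time diffusion limit in two
#' dimensions, the cell diffusivity D = v^2 tau / 2 (um^2/min).
#'
#' The fit window restricts which lags enter the fit; shorter windows avoid
#' the poorly populated, high-variance tail of the curve (for fast cells a
#' window of 80 min over a 2 h movie is typical; for slower cells the full
#' span can be used). The fit is deterministic: starting values are
#' `v0` (default: the ballistic-limit estimate `sqrt(msd[1])/lag[1]` from
#' the first populated lag) and `tau0`, with bounds v in (0, 100] um/min and
#' tau in (0, 1000] min.
#'
#' @param curve An `msd_curve` from [compute_msd()], or a data frame with
#'   columns `lag` and `msd`.
#' @param fit_window Largest lag (minutes) included in the fit; `NULL`
#'   (default) uses the whole curve.
#' @param v0,tau0 Starting values for speed (um/min) and persistence (min).
#' @return An object of class `prw_fit`: a list with `v`, `tau`, `D`,
#'   `fit_window`, `residual_norm` (sum of squared residuals, um^4),
#'   `n_lags`, and `tau_at_bound` (TRUE when tau pinned at a box bound).
#' @examples
#' lag <- 1:80
#' curve <- data.frame(lag = lag, msd = prw_msd(lag, v = 10, tau = 5))
#' fit_prw(curve)
#' @export
fit_prw <- function(curve, fit_window = NULL, v0 = NULL, tau0 = 10) {
  stopifnot(is.data.frame(curve), all(c("lag", "msd") %in% names(curve)))
  d <- curve[is.finite(curve$msd) & curve$lag > 0, c("lag", "msd")]
  if (!is.null(fit_window)) d <- d[d$lag <= fit_window, ]
  if (nrow(d) < 5L)
    stop("need >= 5 positive lags within the fit window, got ", nrow(d),
         call. = FALSE)
  if (is.null(v0)) v0 <- sqrt(max(d$msd[1L], .Machine$double.eps)) / d$lag[1L]
  v0 <- min(max(v0, 1e-3), 100)
  tau0 <- min(max(tau0, 1e-3), 1000)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      msd ~ 2 * v^2 * tau * lag - 2 * (v * tau)^2 * (1 - exp(-lag / tau)),
      data = d, start = list(v = v0, tau = tau0),
      lower = c(v = 1e-6, tau = 1e-6), upper = c(v = 100, tau = 1000),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12)),
    error = function(e)
      stop("PRW fit did not converge: ", conditionMessage(e), call. = FALSE))
  est <- stats::coef(fit)
  v <- unname(est["v"]); tau <- unname(est["tau"])
  structure(list(
    v = v, tau = tau, D = diffusivity(v, tau),
    fit_window = if (is.null(fit_window)) max(d$lag) else fit_window,
    residual_norm = sum(stats::resid(fit)^2),
    n_lags = nrow(d),
    tau_at_bound = tau <= 1e-6 * (1 + 1e-6) || tau >= 1000 * (1 - 1e-9)),
    class = "prw_fit")
}

#' @export
print.prw_fit <- function(x, ...) {
  cat(sprintf(
    "<prw_fit> v = %.4g um/min, tau = %.4g min, D = %.4g um^2/min (window %g min, %d lags)\n",
    x$v, x$tau, x$D, x$fit_window, x$n_lags))
  if (x$tau_at_bound) cat("  note: tau pinned at a box bound\n")
  invisible(x)
}

#' Persistent-random-walk MSD closed form
#'
#' Evaluates the 2D Fuerth formula
#' `2 v^2 tau t - 2 (v tau)^2 (1 - exp(-t/tau))`: ballistic (`v^2 t^2`) for
#' t much smaller than tau, diffusive with slope `2 v^2 tau` for t much
#' larger than tau.
#'
#' @param t Lag times, minutes.
#' @param v Intrinsic cell speed, um/min.
#' @param tau Persistence time, min.
#' @return MSD values in um^2.
#' @export
prw_msd <- function(t, v, tau) {
  2 * v^2 * tau * t - 2 * (v * tau)^2 * (1 - exp(-t / tau))
}

#' Cell diffusivity of a persistent random walk
#'
#' Long-time diffusion coefficient in two dimensions,
#' `D = (1/(2n)) * dMSD/dt` with n = 2 and large-t slope `2 v^2 tau`,
#' hence `D = v^2 tau / 2`.
#'
#' @param v Intrinsic cell speed, um/min (>= 0).
#' @param tau Persistence time, min (> 0).
#' @return Diffusivity in um^2/min.
#' @examples
#' diffusivity(10, 2)  # 100
#' @export
diffusivity <- function(v, tau) {
  stopifnot(v >= 0, tau > 0)
  v^2 * tau / 2
}
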