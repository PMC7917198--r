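#' Unpaired two-sample comparison of a track metric
#'
#' Classical unpaired, two-tailed two-sample t-test with pooled variance
#' (Student's test; Welch's unequal-variance form available with
#' `welch = TRUE`). Scalar summaries report mean and SD per group.
#' Significance stars follow the conventional thresholds: `*` p < 0.05,
#' `**` p < 0.01, `***` p < 0.001, `****` p < 0.0001, `ns` otherwise.
#' No multiple-testing correction is applied; p-values are raw.
#'
#' When both groups have zero variance and equal means the statistic is
#' degenerate; by convention t = 0 and p = 1 are returned, with a message.
#'
#' @param a,b Numeric vectors of per-track metric values (n >= 2 each;
#'   non-finite values are dropped).
#' @param metric Name of the compared metric (bookkeeping).
#' @param group_a,group_b Group labels (bookkeeping).
#' @param welch Use Welch's unequal-variance t-test instead of the pooled
#'   form (default `FALSE`).
#' @return A one-row `data.frame` of class `group_comparison` with columns
#'   `metric`, `group_a`, `group_b`, `mean_a`, `sd_a`, `n_a`, `mean_b`,
#'   `sd_b`, `n_b`, `t`, `df`, `p`, `stars`.
#' @examples
#' compare_groups(c(1, 2, 3), c(11, 12, 13), metric = "mean_speed")
#' @export
compare_groups <- function(a, b, metric = "metric",
                           group_a = "A", group_b = "B", welch = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs >= 2 finite values", call. = FALSE)
  degenerate <- function() {
    message("zero variance in both groups with equal means; p = 1 by convention")
    list(statistic = c(t = 0),
         parameter = c(df = length(a) + length(b) - 2), p.value = 1)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    tt <- degenerate()
  } else {
    tt <- tryCatch(
      stats::t.test(a, b, var.equal = !welch, alternative = "two.sided"),
      error = function(e) {
        # t.test refuses numerically constant data; apply the convention
        # when the means agree at that same precision, else re-raise
        if (grepl("constant", conditionMessage(e)) &&
            isTRUE(all.equal(mean(a), mean(b)))) degenerate()
        else stop(e)
      })
  }
  out <- data.frame(
    metric = metric, group_a = group_a, group_b = group_b,
    mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
    mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, stars = significance_stars(tt$p.value),
    stringsAsFactors = FALSE)
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Significance stars for a p-value
#'
#' @param p P-value(s) in \[0, 1\].
#' @return `"****"`, `"***"`, `"**"`, `"*"` or `"ns"`.
#' @export
significance_stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' Write a deterministic analysis report
#'
#' Writes the computed tables of an analysis to `dir`: group comparisons
#' (mean +/- SD per group with t and raw p), per-track summaries, and any
#' cohort curves (MSD or axial-velocity time courses) as CSV with columns
#' `lag_or_time`, `mean`, `sem`, `n`. Optionally renders each curve as a
#' PDF line plot with an SEM-shaded band. Tables are byte-identical across
#' re-runs on the same input.
#'
#' @param comparisons A `data.frame` of stacked [compare_groups()] rows
#'   (may have 0 rows).
#' @param curves Named list of curve data frames; each needs a lag/time
#'   column plus `mean`/`msd`, `sem` and `n`/`n_cells`.
#' @param summaries Optional per-track summary `data.frame`.
#' @param dir Output directory (created if needed).
#' @param plots Also write `<curve>.pdf` plots (default `FALSE`).
#' @return Invisibly, the vector of files written.
#' @export
render_report <- function(comparisons, curves = list(), summaries = NULL,
                          dir = ".", plots = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  path <- file.path(dir, "comparisons.csv")
  utils::write.csv(comparisons, path, row.names = FALSE, na = "NA")
  written <- c(written, path)
  if (!is.null(summaries)) {
    path <- file.path(dir, "track_summaries.csv")
    write_summary(summaries, path)
    written <- c(written, path)
  }
  for (nm in names(curves)) {
    cv <- standardize_curve(curves[[nm]])
    path <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(cv, path, row.names = FALSE, na = "NA")
    written <- c(written, path)
    if (plots) {
      pdf_path <- file.path(dir, paste0(nm, ".pdf"))
      grDevices::pdf(pdf_path, width = 5, height = 4)
      plot_curve(cv, main = nm)
      grDevices::dev.off()
      written <- c(written, pdf_path)
    }
  }
  invisible(written)
}

standardize_curve <- function(cv) {
  stopifnot(is.data.frame(cv))
  tcol <- intersect(c("lag", "time", "lag_or_time"), names(cv))[1L]
  mcol <- intersect(c("mean", "msd"), names(cv))[1L]
  ncol_ <- intersect(c("n", "n_cells"), names(cv))[1L]
  if (anyNA(c(tcol, mcol, ncol_)) || !"sem" %in% names(cv))
    stop("curve needs lag/time, mean/msd, sem and n/n_cells columns",
         call. = FALSE)
  data.frame(lag_or_time = cv[[tcol]], mean = cv[[mcol]],
             sem = cv$sem, n = cv[[ncol_]])
}

# mean line with an SEM-shaded band, base graphics
plot_curve <- function(cv, main = "") {
  ok <- is.finite(cv$mean)
  lo <- cv$mean - ifelse(is.finite(cv$sem), cv$sem, 0)
  hi <- cv$mean + ifelse(is.finite(cv$sem), cv$sem, 0)
  plot(cv$lag_or_time[ok], cv$mean[ok], type = "n",
       ylim = range(lo[ok], hi[ok]),
       xlab = "time (min)", ylab = "mean +/- SEM", main = main)
  graphics::polygon(c(cv$lag_or_time[ok], rev(cv$lag_or_time[ok])),
                    c(lo[ok], rev(hi[ok])),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(cv$lag_or_time[ok], cv$mean[ok], col = "steelblue4")
}
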