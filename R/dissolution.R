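#' Ionic and particulate fractions from a digestion experiment
#'
#' After centrifugation, the top half (500 uL) of a 1 mL sample carries
#' only dissolved analyte while the bottom half carries the pellet plus
#' its share of the dissolved pool. Assuming dissolved ions are
#' homogeneous across both equal-volume halves at sampling, the ionic
#' share of the total content is twice the supernatant concentration over
#' the summed concentrations, clipped to [0, 1].
#'
#' @param supernatant_ionic Measured supernatant concentration (ug/L).
#' @param pellet_total Measured concentration of the redispersed bottom
#'   half (ug/L).
#' @return A list of class \code{spiq_fractions}: the two inputs plus
#'   \code{ionic_fraction} and \code{particulate_fraction} (they sum to 1).
#' @export
digestion_fractions <- function(supernatant_ionic, pellet_total) {
  if (supernatant_ionic < 0 || pellet_total < 0)
    stop("concentrations must be non-negative")
  total <- supernatant_ionic + pellet_total
  if (total == 0) stop("both halves are zero: fractions undefined")
  ionic <- min(1, max(0, 2 * supernatant_ionic / total))
  structure(list(supernatant_ionic = supernatant_ionic,
                 pellet_total = pellet_total,
                 ionic_fraction = ionic,
                 particulate_fraction = 1 - ionic),
            class = "spiq_fractions")
}

#' Assemble a time-resolved dissolution series
#'
#' Sorts per-timepoint metrics by time and summarizes the start and end of
#' the experiment as mean and sample SD over the first and last
#' \code{n_summary} points (the "first three measurements" vs "after a
#' week" comparison).
#'
#' @param points A data.frame with a \code{time_h} column and numeric
#'   metric columns (e.g. \code{ionic_background}, \code{particulate_content},
#'   \code{particles_per_minute}, \code{median_diameter}); an optional
#'   \code{replicate} column is carried through.
#' @param medium Matrix label.
#' @param n_summary Number of points in each of the start/end summaries
#'   (default 3; truncated to the number of available points).
#' @return An object of class \code{spiq_series}: sorted \code{points} and
#'   \code{start_summary} / \code{end_summary} data.frames (metric, mean, sd).
#' @export
assemble_series <- function(points, medium = "H2O", n_summary = 3L) {
  stopifnot(is.data.frame(points), "time_h" %in% names(points), nrow(points) >= 1L)
  if (any(points$time_h < 0)) stop("time_h must be non-negative")
  points <- points[order(points$time_h), , drop = FALSE]
  rownames(points) <- NULL
  metrics <- setdiff(names(points)[vapply(points, is.numeric, logical(1))],
                     c("time_h", "replicate"))
  n <- nrow(points)
  k <- min(as.integer(n_summary), n)
  summarize <- function(rows) {
    data.frame(metric = metrics,
               mean = vapply(metrics, function(m) mean(points[[m]][rows], na.rm = TRUE),
                             numeric(1)),
               sd = vapply(metrics, function(m) {
                 v <- points[[m]][rows]
                 v <- v[!is.na(v)]
                 if (length(v) >= 2L) stats::sd(v) else 0
               }, numeric(1)),
               row.names = NULL)
  }
  structure(list(medium = as.character(medium), points = points,
                 start_summary = summarize(seq_len(k)),
                 end_summary = summarize((n - k + 1L):n)),
            class = "spiq_series")
}

#' @export
print.spiq_series <- function(x, ...) {
  cat(sprintf("Dissolution series [%s]: %d points, %.1f-%.1f h\n", x$medium,
              nrow(x$points), min(x$points$time_h), max(x$points$time_h)))
  cat("start summary:\n"); print(x$start_summary)
  cat("end summary:\n"); print(x$end_summary)
  invisible(x)
}

#' Fit a first-order loss rate to a dissolution series
#'
#' Convenience summary of the kinetics: least-squares line through
#' log(observable) versus time; the loss rate is minus the slope, in 1/h.
#' This is a descriptive single-rate summary, not a mechanistic
#' dissolution model.
#'
#' @param series A [assemble_series()] result, or a data.frame with
#'   \code{time_h} and the observable column.
#' @param observable Column name to fit, e.g. \code{"particles_per_minute"}
#'   or \code{"particulate_content"}.
#' @return A list of class \code{spiq_loss_fit}: \code{rate} (1/h),
#'   \code{se}, \code{r_squared}, \code{n}.
#' @export
fit_first_order_loss <- function(series, observable) {
  pts <- if (inherits(series, "spiq_series")) series$points else series
  stopifnot(is.data.frame(pts), observable %in% names(pts))
  y <- pts[[observable]]
  t <- pts$time_h
  keep <- !is.na(y) & y > 0
  if (sum(keep) < 4L) stop("need at least 4 points with positive '", observable, "'")
  fit <- stats::lm(log(y[keep]) ~ t[keep])
  sm <- summary(fit)
  structure(list(rate = -unname(stats::coef(fit)[2L]),
                 se = sm$coefficients[2L, "Std. Error"],
                 r_squared = sm$r.squared,
                 n = sum(keep)),
            class = "spiq_loss_fit")
}

#' @export
print.spiq_loss_fit <- function(x, ...) {
  cat(sprintf("First-order loss rate: %.4g +/- %.2g per h (r^2 = %.3f, n = %d)\n",
              x$rate, x$se, x$r_squared, x$n))
  invisible(x)
}
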