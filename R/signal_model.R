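#' Acquisition settings for a time-resolved spICP-MS run
#'
#' Bundles the instrument settings that every downstream calculation needs:
#' the dwell time (integration interval of one data point), the total
#' acquisition time, the carrier flow rate, the injection-loop volume, the
#' monitored isotope and a label for the sample matrix.
#'
#' @param dwell_time Dwell time in seconds (default 0.003 s, i.e. 3 ms).
#' @param acquisition_time Total acquisition time in seconds (default 70 s).
#' @param flow_rate Carrier flow rate in uL/min (default 500).
#' @param loop_volume Injection-loop volume in uL (default 300).
#' @param isotope Isotope label, e.g. \code{"65Cu"} or \code{"197Au"}.
#' @param medium Matrix label, e.g. \code{"H2O"}, \code{"BSA"},
#'   \code{"NaHCO3"}, \code{"ALF"}, \code{"GS"}, \code{"EGS"}, \code{"RPMI"}
#'   or any user-defined name.
#' @return An object of class \code{spiq_settings}.
#' @export
acquisition_settings <- function(dwell_time = 0.003, acquisition_time = 70,
                                 flow_rate = 500, loop_volume = 300,
                                 isotope = "65Cu", medium = "H2O") {
  stopifnot(is.numeric(dwell_time), length(dwell_time) == 1L, dwell_time > 0)
  if (!is.numeric(acquisition_time) || acquisition_time < dwell_time)
    stop("'acquisition_time' must be numeric and >= dwell_time")
  stopifnot(is.numeric(flow_rate), flow_rate > 0,
            is.numeric(loop_volume), loop_volume > 0)
  structure(list(dwell_time = dwell_time,
                 acquisition_time = acquisition_time,
                 flow_rate = flow_rate,
                 loop_volume = loop_volume,
                 isotope = as.character(isotope),
                 medium = as.character(medium)),
            class = "spiq_settings")
}

#' A time-resolved intensity scan
#'
#' @param intensities Numeric vector of non-negative intensities, one value
#'   per dwell interval, in counts per dwell.
#' @param settings An [acquisition_settings()] object.
#' @return An object of class \code{spiq_scan} with elements
#'   \code{intensities}, \code{settings} and \code{n_points}.
#' @export
time_scan <- function(intensities, settings) {
  stopifnot(inherits(settings, "spiq_settings"))
  intensities <- as.numeric(intensities)
  if (length(intensities) == 0L) stop("scan must contain at least one dwell")
  if (anyNA(intensities)) stop("scan intensities contain NA")
  if (any(intensities < 0)) stop("scan intensities must be non-negative")
  structure(list(intensities = intensities,
                 settings = settings,
                 n_points = length(intensities)),
            class = "spiq_scan")
}

#' @export
print.spiq_scan <- function(x, ...) {
  cat(sprintf("spICP-MS time scan: %d dwells of %g s (%s, %s), mean %.2f counts/dwell\n",
              x$n_points, x$settings$dwell_time, x$settings$isotope,
              x$settings$medium, mean(x$intensities)))
  invisible(x)
}

#' Read a time scan from CSV
#'
#' Accepts one-column (intensity) or two-column (time, intensity) comma
#' separated files; an optional header row is detected by a non-numeric
#' first line. A time column, if present, must be monotone increasing.
#'
#' @param path Path to the CSV file.
#' @param settings An [acquisition_settings()] object attached to the scan.
#' @return A [time_scan()] object.
#' @export
read_time_scan <- function(path, settings) {
  stopifnot(inherits(settings, "spiq_settings"))
  if (!file.exists(path)) stop("scan file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty scan file: ", path)
  first <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  has_header <- anyNA(suppressWarnings(as.numeric(trimws(first))))
  offset <- if (has_header) 1L else 0L
  body <- lines[(offset + 1L):length(lines)]
  if (length(body) == 0L) stop("scan file has a header but no data: ", path)
  parts <- strsplit(body, ",", fixed = TRUE)
  ncol <- lengths(parts)
  if (any(ncol < 1L | ncol > 2L)) {
    bad <- which(ncol < 1L | ncol > 2L)[1L]
    stop(sprintf("malformed row at line %d of %s", bad + offset, path))
  }
  if (length(unique(ncol)) != 1L) {
    bad <- which(ncol != ncol[1L])[1L]
    stop(sprintf("inconsistent column count at line %d of %s", bad + offset, path))
  }
  mat <- matrix(suppressWarnings(as.numeric(trimws(unlist(parts)))),
                ncol = ncol[1L], byrow = TRUE)
  if (anyNA(mat)) {
    bad <- which(apply(is.na(mat), 1L, any))[1L]
    stop(sprintf("non-numeric value at line %d of %s", bad + offset, path))
  }
  intensity <- mat[, ncol(mat)]
  if (any(intensity < 0)) {
    bad <- which(intensity < 0)[1L]
    stop(sprintf("negative intensity at line %d of %s", bad + offset, path))
  }
  if (ncol(mat) == 2L) {
    tcol <- mat[, 1L]
    if (any(diff(tcol) <= 0))
      stop("time column is not monotone increasing in ", path)
  }
  time_scan(intensity, settings)
}

#' Write a time scan to CSV
#'
#' Writes \code{time,intensity} rows (time derived from the dwell time) or a
#' single intensity column. Values are serialized at full double precision
#' so that a read/write/read round trip is bit-exact.
#'
#' @param scan A [time_scan()] object.
#' @param path Output path.
#' @param time_column Include the derived time column? Default \code{TRUE}.
#' @param header Write a header row? Default \code{TRUE}.
#' @return \code{path}, invisibly.
#' @export
write_time_scan <- function(scan, path, time_column = TRUE, header = TRUE) {
  stopifnot(inherits(scan, "spiq_scan"))
  y <- sprintf("%.17g", scan$intensities)
  if (time_column) {
    t <- sprintf("%.17g", (seq_len(scan$n_points) - 1L) * scan$settings$dwell_time)
    rows <- paste(t, y, sep = ",")
    if (header) rows <- c("time_s,intensity", rows)
  } else {
    rows <- y
    if (header) rows <- c("intensity", rows)
  }
  writeLines(rows, path)
  invisible(path)
}

#' A transient evaluation window
#'
#' Dwell indices are 1-based and the interval is closed: the window covers
#' dwells \code{start} through \code{end} inclusive.
#'
#' @param start,end First and last dwell index of the window.
#' @param settings The [acquisition_settings()] the window refers to.
#' @return An object of class \code{spiq_window} with a \code{duration}
#'   element in seconds.
#' @export
transient_window <- function(start, end, settings) {
  stopifnot(inherits(settings, "spiq_settings"))
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1L || end < start) stop("invalid window [", start, ", ", end, "]")
  structure(list(start = start, end = end,
                 n_dwells = end - start + 1L,
                 duration = (end - start + 1L) * settings$dwell_time,
                 settings = settings),
            class = "spiq_window")
}

# centered moving mean with shrinking (partial) windows at the edges, so the
# smoothed series is defined at every dwell
moving_mean <- function(x, width) {
  n <- length(x)
  half <- width %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (width - half - 1L), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Locate the transient injection window in a scan
#'
#' Direct injection of a fixed loop volume produces a transient plateau
#' rather than a steady-state signal; evaluation should be confined to that
#' plateau. The scan is smoothed with a centered moving mean of width
#' \code{min_run}; the baseline is the median of the first and last 5\% of
#' dwells and the plateau level is the median of the top decile of the
#' smoothed series. The longest contiguous run of at least \code{min_run}
#' dwells whose smoothed intensity exceeds
#' \code{baseline + baseline_fraction * (plateau - baseline)} is returned;
#' if no run qualifies (e.g. a flat scan with no injection) the full scan is
#' returned.
#'
#' @param scan A [time_scan()] object.
#' @param baseline_fraction Fraction of the baseline-to-plateau rise that
#'   the smoothed signal must exceed (default 0.1).
#' @param min_run Minimum window length in dwells and smoothing width
#'   (default 50).
#' @return A [transient_window()].
#' @export
detect_transient_window <- function(scan, baseline_fraction = 0.1, min_run = 50L) {
  stopifnot(inherits(scan, "spiq_scan"))
  if (baseline_fraction <= 0 || baseline_fraction >= 1)
    stop("'baseline_fraction' must be in (0, 1)")
  n <- scan$n_points
  min_run <- as.integer(min_run)
  if (n < min_run) stop("scan shorter than 'min_run' (", min_run, " dwells)")
  x <- scan$intensities
  sm <- moving_mean(x, min_run)
  edge <- max(1L, floor(0.05 * n))
  baseline <- stats::median(c(x[seq_len(edge)], x[(n - edge + 1L):n]))
  n_top <- max(1L, ceiling(0.1 * n))
  plateau <- stats::median(sort(sm, decreasing = TRUE)[seq_len(n_top)])
  thr <- baseline + baseline_fraction * (plateau - baseline)
  above <- sm > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= min_run
  if (!any(ok)) return(transient_window(1L, n, scan$settings))
  best <- which(ok)[which.max(r$lengths[ok])]
  transient_window(starts[best], ends[best], scan$settings)
}

#' Summarize a transient signal
#'
#' Used to characterize the injection profile at different flow rates: the
#' transient duration, its mean intensity and the relative standard
#' deviation (sample SD / mean) of the in-window intensities.
#'
#' @param scan A [time_scan()] object.
#' @param window A [transient_window()] valid for the scan.
#' @return A list of class \code{spiq_transient_summary} with elements
#'   \code{duration} (s), \code{mean_intensity} (counts/dwell) and
#'   \code{rsd} (fraction; \code{NA} when the mean is zero).
#' @export
characterize_transient <- function(scan, window) {
  stopifnot(inherits(scan, "spiq_scan"), inherits(window, "spiq_window"))
  if (window$end > scan$n_points) stop("window extends past the end of the scan")
  v <- scan$intensities[window$start:window$end]
  m <- mean(v)
  s <- if (length(v) >= 2L) stats::sd(v) else 0
  structure(list(duration = window$duration,
                 mean_intensity = m,
                 rsd = if (m == 0) NA_real_ else s / m),
            class = "spiq_transient_summary")
}
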