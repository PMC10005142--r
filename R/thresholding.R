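#' Thresholding configuration
#'
#' Parameters of the automated background/particle discrimination: the scan
#' window is divided into \code{n_pieces} consecutive pieces (to absorb
#' drift within a measurement), and within each piece the detection limit
#' \code{mean + k_sigma * sd} is refined by repeatedly removing the points
#' above it, \code{n_iterations} times.
#'
#' @param n_pieces Number of consecutive pieces (default 10).
#' @param k_sigma Sigma multiplier, typically 3 or 5.
#' @param n_iterations Number of trim-and-recompute passes (default 5).
#' @param gap_tolerance Background dwells tolerated inside one particle
#'   event before it is split in two (default 0: only consecutive
#'   above-threshold dwells merge).
#' @return An object of class \code{spiq_threshold_config}.
#' @export
threshold_config <- function(n_pieces = 10L, k_sigma = 3, n_iterations = 5L,
                             gap_tolerance = 0L) {
  stopifnot(n_pieces >= 1L, k_sigma > 0, n_iterations >= 1L, gap_tolerance >= 0L)
  structure(list(n_pieces = as.integer(n_pieces), k_sigma = k_sigma,
                 n_iterations = as.integer(n_iterations),
                 gap_tolerance = as.integer(gap_tolerance)),
            class = "spiq_threshold_config")
}

#' Split a window into consecutive pieces
#'
#' Pieces are contiguous, 1-based closed index ranges whose lengths differ
#' by at most one; remainder dwells go to the last pieces.
#'
#' @param n_points Number of dwells in the window.
#' @param n_pieces Number of pieces.
#' @return A data.frame with columns \code{piece}, \code{start}, \code{end}.
#' @export
split_into_pieces <- function(n_points, n_pieces) {
  n_points <- as.integer(n_points); n_pieces <- as.integer(n_pieces)
  if (n_points < n_pieces)
    stop("cannot split ", n_points, " dwells into ", n_pieces, " pieces")
  base <- n_points %/% n_pieces
  rem <- n_points %% n_pieces
  len <- rep(base, n_pieces)
  if (rem > 0L) len[(n_pieces - rem + 1L):n_pieces] <- base + 1L
  end <- cumsum(len)
  data.frame(piece = seq_len(n_pieces), start = end - len + 1L, end = end)
}

#' Iterative piecewise background thresholding
#'
#' For each piece independently: start with all its dwells retained; for
#' each of \code{n_iterations} passes compute the mean and sample standard
#' deviation of the retained dwells, set the limit to
#' \code{mean + k_sigma * sd}, and remove the dwells strictly above the
#' limit (points exactly at the limit stay background). The limit of the
#' final pass is the piece's detection threshold. A piece whose retained
#' set shrinks below two dwells, or becomes constant, has SD 0 and
#' threshold equal to its mean; such pieces are flagged.
#'
#' @param intensities Numeric vector of window intensities.
#' @param config A [threshold_config()].
#' @return A data.frame of class \code{spiq_pieces} with one row per piece:
#'   \code{piece}, \code{start}, \code{end}, \code{background_mean},
#'   \code{background_sd}, \code{threshold}, \code{n_retained},
#'   \code{low_retained} flag. The per-iteration limits are attached as the
#'   \code{"iteration_thresholds"} attribute (iterations x pieces matrix).
#' @export
iterative_threshold <- function(intensities, config = threshold_config()) {
  stopifnot(inherits(config, "spiq_threshold_config"))
  x <- as.numeric(intensities)
  if (length(x) == 0L) stop("empty window")
  ranges <- split_into_pieces(length(x), config$n_pieces)
  np <- config$n_pieces
  out <- data.frame(piece = ranges$piece, start = ranges$start, end = ranges$end,
                    background_mean = NA_real_, background_sd = NA_real_,
                    threshold = NA_real_, n_retained = NA_integer_,
                    low_retained = FALSE)
  iter_thr <- matrix(NA_real_, nrow = config$n_iterations, ncol = np)
  for (p in seq_len(np)) {
    v <- x[ranges$start[p]:ranges$end[p]]
    keep <- rep(TRUE, length(v))
    m <- s <- thr <- NA_real_
    for (it in seq_len(config$n_iterations)) {
      r <- v[keep]
      m <- mean(r)
      s <- if (length(r) >= 2L) stats::sd(r) else 0
      thr <- m + config$k_sigma * s
      iter_thr[it, p] <- thr
      keep <- keep & (v <= thr)
    }
    out$background_mean[p] <- m
    out$background_sd[p] <- s
    out$threshold[p] <- thr
    out$n_retained[p] <- sum(keep)
    out$low_retained[p] <- sum(keep) < 2L
  }
  if (any(out$low_retained))
    warning("piece(s) ", paste(which(out$low_retained), collapse = ", "),
            " retained fewer than 2 background dwells; SD set to 0")
  attr(out, "iteration_thresholds") <- iter_thr
  class(out) <- c("spiq_pieces", "data.frame")
  out
}

#' Detect particle events above the piecewise thresholds
#'
#' Dwells strictly above their piece's final threshold are particle dwells;
#' maximal runs of particle dwells separated by at most
#' \code{gap_tolerance} background dwells are merged into single events.
#' The net intensity of an event is the sum over its particle dwells of the
#' intensity minus the local piece background mean (floored at zero).
#'
#' @param intensities Numeric vector of window intensities (same window the
#'   pieces were computed on).
#' @param pieces Result of [iterative_threshold()].
#' @param gap_tolerance Background dwells tolerated inside one event.
#' @return A data.frame of class \code{spiq_events}: \code{start_index},
#'   \code{n_dwells}, \code{piece_index}, \code{raw_intensity},
#'   \code{net_intensity}. Events are disjoint and ordered by start index.
#' @export
detect_events <- function(intensities, pieces, gap_tolerance = 0L) {
  stopifnot(inherits(pieces, "spiq_pieces"))
  x <- as.numeric(intensities)
  if (pieces$end[nrow(pieces)] != length(x))
    stop("pieces do not cover the window (", length(x), " dwells)")
  piece_of <- rep(pieces$piece, pieces$end - pieces$start + 1L)
  thr_of <- pieces$threshold[piece_of]
  bg_of <- pieces$background_mean[piece_of]
  above <- which(x > thr_of)
  empty <- data.frame(start_index = integer(), n_dwells = integer(),
                      piece_index = integer(), raw_intensity = numeric(),
                      net_intensity = numeric())
  class(empty) <- c("spiq_events", "data.frame")
  if (length(above) == 0L) return(empty)
  grp <- cumsum(c(1L, diff(above) > gap_tolerance + 1L))
  raw <- as.numeric(tapply(x[above], grp, sum))
  net <- pmax(0, as.numeric(tapply(x[above] - bg_of[above], grp, sum)))
  start <- as.integer(tapply(above, grp, min))
  out <- data.frame(start_index = start,
                    n_dwells = as.integer(tabulate(grp)),
                    piece_index = piece_of[start],
                    raw_intensity = raw,
                    net_intensity = net)
  class(out) <- c("spiq_events", "data.frame")
  out
}

#' Particle count rate
#'
#' @param events An event table from [detect_events()].
#' @param window The [transient_window()] the events were detected in.
#' @return Events per minute.
#' @export
count_rate <- function(events, window) {
  stopifnot(inherits(window, "spiq_window"))
  if (window$duration <= 0) stop("window duration must be positive")
  nrow(events) / (window$duration / 60)
}

#' Run the full thresholding procedure on a scan window
#'
#' Convenience wrapper: extracts the window intensities, runs
#' [iterative_threshold()] and [detect_events()], and assembles the
#' summary quantities (whole-window untrimmed mean, event rate, and the
#' above-threshold dwell count, which is the naive per-dwell particle
#' number).
#'
#' @param scan A [time_scan()].
#' @param window A [transient_window()]; default: [detect_transient_window()].
#' @param config A [threshold_config()].
#' @param noise_floor Background means below this level (counts/dwell) set
#'   the \code{low_background} flag: thresholds computed on backgrounds at
#'   or below the electrical noise are known to overestimate event numbers.
#' @return A list of class \code{spiq_threshold_result}: \code{pieces},
#'   \code{events}, \code{total_mean}, \code{particles_per_minute},
#'   \code{n_events}, \code{n_above_dwells}, \code{window}, \code{config},
#'   \code{flags}.
#' @export
threshold_scan <- function(scan, window = NULL, config = threshold_config(),
                           noise_floor = 0.1) {
  stopifnot(inherits(scan, "spiq_scan"))
  if (is.null(window)) window <- detect_transient_window(scan)
  x <- scan$intensities[window$start:window$end]
  pieces <- iterative_threshold(x, config)
  events <- detect_events(x, pieces, config$gap_tolerance)
  # report event positions on the scan's own dwell axis
  if (nrow(events)) events$start_index <- events$start_index + window$start - 1L
  piece_of <- rep(pieces$piece, pieces$end - pieces$start + 1L)
  n_above <- sum(x > pieces$threshold[piece_of])
  flags <- character()
  if (any(pieces$low_retained)) flags <- c(flags, "low_retained_piece")
  if (any(pieces$background_mean < noise_floor)) flags <- c(flags, "low_background")
  structure(list(pieces = pieces, events = events,
                 total_mean = mean(x),
                 particles_per_minute = count_rate(events, window),
                 n_events = nrow(events),
                 n_above_dwells = n_above,
                 window = window, config = config, flags = flags),
            class = "spiq_threshold_result")
}

#' @export
print.spiq_threshold_result <- function(x, ...) {
  cat(sprintf(paste0("spICP-MS thresholding (%d pieces, k = %g, %d iterations):\n",
                     "  %d events (%.0f per minute), %d above-threshold dwells\n",
                     "  window [%d, %d] (%.2f s), whole-window mean %.2f counts/dwell\n"),
              x$config$n_pieces, x$config$k_sigma, x$config$n_iterations,
              x$n_events, x$particles_per_minute, x$n_above_dwells,
              x$window$start, x$window$end, x$window$duration, x$total_mean))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
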