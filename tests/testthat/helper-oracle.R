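# Independent naive reference implementations, written as direct loop
# transcriptions of the evaluation rules. They exist to cross-check the
# package's vectorized code and must stay structurally separate from it.

# piece boundaries: lengths differ by at most 1, remainder to last pieces
ref_split <- function(n, np) {
  base <- n %/% np
  rem <- n - base * np
  lens <- c(rep(base, np - rem), rep(base + 1, rem))
  ends <- cumsum(lens)
  cbind(start = ends - lens + 1, end = ends)
}

# one piece of the iterative trim: returns the retained index set of the
# original piece vector plus the last-iteration mean/sd/limit
ref_trim_piece <- function(v, k, n_iter) {
  idx <- seq_along(v)
  m <- s <- lim <- NA_real_
  lims <- numeric(n_iter)
  for (it in 1:n_iter) {
    r <- v[idx]
    m <- sum(r) / length(r)
    s <- if (length(r) >= 2) sqrt(sum((r - m)^2) / (length(r) - 1)) else 0
    lim <- m + k * s
    lims[it] <- lim
    idx <- idx[v[idx] <= lim]
  }
  list(mean = m, sd = s, limit = lim, retained = idx, limits = lims)
}

ref_threshold <- function(x, n_pieces, k, n_iter) {
  b <- ref_split(length(x), n_pieces)
  lapply(seq_len(n_pieces), function(p) {
    res <- ref_trim_piece(x[b[p, "start"]:b[p, "end"]], k, n_iter)
    res$start <- b[p, "start"]; res$end <- b[p, "end"]
    res
  })
}

# event detection by explicit left-to-right scan with gap tolerance
ref_events <- function(x, thr_per_dwell, bg_per_dwell, gap) {
  events <- list()
  current <- integer()
  gap_run <- 0
  for (i in seq_along(x)) {
    if (x[i] > thr_per_dwell[i]) {
      current <- c(current, i)
      gap_run <- 0
    } else if (length(current)) {
      gap_run <- gap_run + 1
      if (gap_run > gap) {
        events[[length(events) + 1]] <- current
        current <- integer()
        gap_run <- 0
      }
    }
  }
  if (length(current)) events[[length(events) + 1]] <- current
  do.call(rbind, lapply(events, function(dw) {
    data.frame(start_index = dw[1], n_dwells = length(dw),
               raw_intensity = sum(x[dw]),
               net_intensity = max(0, sum(x[dw] - bg_per_dwell[dw])))
  }))
}

# full reference pipeline on a window: thresholds then events
ref_full <- function(x, n_pieces, k, n_iter, gap = 0) {
  pieces <- ref_threshold(x, n_pieces, k, n_iter)
  thr <- bg <- numeric(length(x))
  for (p in pieces) {
    thr[p$start:p$end] <- p$limit
    bg[p$start:p$end] <- p$mean
  }
  list(pieces = pieces, events = ref_events(x, thr, bg, gap))
}

# transient-window rule, transcribed independently: smooth with a centered
# partial-window moving mean, baseline from the scan edges, plateau from
# the top decile, longest qualifying run
ref_window <- function(x, frac, min_run) {
  n <- length(x)
  sm <- numeric(n)
  half <- min_run %/% 2
  for (i in 1:n) {
    lo <- max(1, i - half)
    hi <- min(n, i + (min_run - half - 1))
    sm[i] <- mean(x[lo:hi])
  }
  edge <- max(1, floor(0.05 * n))
  baseline <- median(c(x[1:edge], x[(n - edge + 1):n]))
  top <- sort(sm, decreasing = TRUE)[1:max(1, ceiling(0.1 * n))]
  plateau <- median(top)
  thr <- baseline + frac * (plateau - baseline)
  best <- c(NA, NA); best_len <- 0
  i <- 1
  while (i <= n) {
    if (sm[i] > thr) {
      j <- i
      while (j < n && sm[j + 1] > thr) j <- j + 1
      if (j - i + 1 >= min_run && j - i + 1 > best_len) {
        best <- c(i, j); best_len <- j - i + 1
      }
      i <- j + 1
    } else i <- i + 1
  }
  if (best_len == 0) c(1, n) else best
}

# random scan generator for oracle-equivalence checks: Poisson background
# (possibly piecewise-shifted) with planted spikes
random_spiked_vector <- function(n = NULL) {
  if (is.null(n)) n <- sample(200:2000, 1)
  lambda <- sample(c(2, 5, 10, 50), 1)
  x <- rpois(n, lambda)
  n_spikes <- rpois(1, n / 100)
  if (n_spikes > 0) {
    at <- sample(n, min(n_spikes, n))
    x[at] <- x[at] + rpois(length(at), lambda * sample(5:50, 1))
  }
  as.numeric(x)
}

# simple trapezoid profile over dwell indices (50-dwell linear edges)
envelope_ramp <- function(n, from, to, edge = 50) {
  i <- seq_len(n)
  pmin(1, pmax(0, pmin((i - from) / edge, (to - i) / edge)))
}

default_sim_settings <- function(acquisition_time = 70) {
  acquisition_settings(dwell_time = 0.003, acquisition_time = acquisition_time,
                       flow_rate = 500, loop_volume = 300,
                       isotope = "65Cu", medium = "H2O")
}

# a calibration object with known slope/intercept, without fitting
direct_calibration <- function(slope, intercept = 0, medium = "H2O") {
  structure(list(medium = medium, slope = slope, intercept = intercept,
                 r_squared = 1, points = NULL),
            class = "spiq_calibration")
}
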