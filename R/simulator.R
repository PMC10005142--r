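#' Simulation configuration
#'
#' Defines a synthetic direct-injection spICP-MS acquisition with known
#' ground truth: Poisson counting background (optionally drifting), an
#' injection transient envelope, a dissolved-analyte contribution through
#' the calibration slope, and particle spikes arriving as a Poisson
#' process with log-normal sizes.
#'
#' @param settings An [acquisition_settings()] object.
#' @param background_mean Mean instrument background in counts per dwell.
#' @param background_drift Fractional linear drift of the background across
#'   the scan (0.1 = +/-5\% from start to end).
#' @param envelope Numeric triple \code{c(rise, plateau, fall)} in seconds:
#'   linear rise, flat plateau, exponential fall (time constant
#'   \code{fall / 3}). Use \code{c(0, Inf, 0)} for a flat, window-free scan.
#'   The default \code{c(2, 33, 6)} integrates to 36 s of effective sample
#'   time, i.e. exactly one 300 uL loop at 500 uL/min.
#' @param envelope_delay Dead time in seconds before the sample plug
#'   arrives at the detector (default 5 s; 0 starts the rise at t = 0).
#' @param true_eta True transport efficiency.
#' @param ionic_concentration Dissolved analyte concentration in ug/L.
#' @param cal_slope Sensitivity in counts/dwell per ug/L.
#' @param particle_number_concentration Particle number concentration in
#'   particles per L.
#' @param size_median,size_gsd Median (nm) and geometric SD (>= 1) of the
#'   log-normal particle size distribution; \code{size_gsd = 1} is
#'   monodisperse.
#' @param size_pool Optional numeric vector of diameters (nm) to sample
#'   events from instead of the log-normal (used by the dissolution
#'   simulator to carry an evolved population).
#' @param analyte An [analyte_spec()].
#' @param split_events Split each event's counts over two adjacent dwells
#'   (default \code{FALSE}: single-dwell events).
#' @param seed Optional integer seed; a fixed seed gives bit-identical scans.
#' @return An object of class \code{spiq_sim_config}.
#' @export
simulation_config <- function(settings = acquisition_settings(),
                              background_mean = 10, background_drift = 0,
                              envelope = c(2, 33, 6), envelope_delay = 5,
                              true_eta = 0.03, ionic_concentration = 0,
                              cal_slope = 100,
                              particle_number_concentration = 0,
                              size_median = 50, size_gsd = 1.4,
                              size_pool = NULL,
                              analyte = analyte_cuo(),
                              split_events = FALSE, seed = NULL) {
  stopifnot(inherits(settings, "spiq_settings"), inherits(analyte, "spiq_analyte"),
            background_mean >= 0, length(envelope) == 3L, all(envelope >= 0),
            envelope_delay >= 0,
            true_eta > 0, true_eta <= 1, ionic_concentration >= 0,
            cal_slope > 0, particle_number_concentration >= 0,
            size_median > 0, size_gsd >= 1)
  structure(list(settings = settings, background_mean = background_mean,
                 background_drift = background_drift,
                 envelope = envelope, envelope_delay = envelope_delay,
                 true_eta = true_eta,
                 ionic_concentration = ionic_concentration,
                 cal_slope = cal_slope,
                 particle_number_concentration = particle_number_concentration,
                 size_median = size_median, size_gsd = size_gsd,
                 size_pool = size_pool,
                 analyte = analyte, split_events = split_events,
                 seed = seed),
            class = "spiq_sim_config")
}

# trapezoid-with-exponential-tail injection envelope, in [0, 1]
envelope_profile <- function(t, envelope, delay = 0) {
  rise <- envelope[1L]; plateau <- envelope[2L]; fall <- envelope[3L]
  t <- t - delay
  g <- numeric(length(t))
  in_rise <- t >= 0 & t < rise
  g[in_rise] <- if (rise > 0) t[in_rise] / rise else 1
  on_plateau <- t >= rise & t < rise + plateau
  g[on_plateau] <- 1
  after <- t >= rise + plateau
  if (any(after)) {
    # fall = 0 is an instant plug end; otherwise exponential tail
    g[after] <- if (fall > 0) exp(-(t[after] - rise - plateau) / (fall / 3)) else 0
  }
  g
}

#' Simulate one direct-injection time scan
#'
#' Per dwell at envelope level \eqn{g(t)}: background counts are
#' Poisson-distributed around
#' \eqn{\lambda_b (1 + \mathrm{drift}) + R \cdot C_\mathrm{ion} \cdot g(t)};
#' particle arrivals are Poisson with per-dwell rate
#' \eqn{C_p \cdot \eta \cdot Q \cdot t_d \cdot g(t)}; each arrival draws a
#' diameter from the size distribution, and its ideal event intensity
#' \eqn{m R / (\eta Q t_d)} (the inverse of the sizing formula) is Poisson
#' sampled (detector counting statistics) and added to its dwell.
#'
#' @param config A [simulation_config()].
#' @return A list of class \code{spiq_sim}: \code{scan} (a [time_scan()])
#'   and \code{truth} with the planted-event table (\code{dwell},
#'   \code{diameter} nm, \code{analyte_mass} g, \code{ideal_counts},
#'   \code{counts}), the per-dwell expected background, and the generating
#'   parameters.
#' @export
simulate_scan <- function(config) {
  stopifnot(inherits(config, "spiq_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  st <- config$settings
  n <- round(st$acquisition_time / st$dwell_time)
  t_mid <- (seq_len(n) - 0.5) * st$dwell_time
  g <- envelope_profile(t_mid, config$envelope, config$envelope_delay)
  # linear gain of `background_drift` (fractional) from scan start to end
  drift <- 1 + config$background_drift * (seq_len(n) - 0.5) / n
  lambda_bg <- config$background_mean * drift +
    config$cal_slope * config$ionic_concentration * g
  if (any(lambda_bg > 1e9)) stop("expected background counts exceed 1e9 per dwell")
  counts <- stats::rpois(n, lambda_bg)

  q_ls <- ul_per_min_to_L_per_s(st$flow_rate)
  nu <- config$particle_number_concentration * config$true_eta * q_ls *
    st$dwell_time * g
  arrivals <- if (any(nu > 0)) stats::rpois(n, nu) else integer(n)
  k <- sum(arrivals)
  if (k > 0) {
    dwell <- rep.int(which(arrivals > 0), arrivals[arrivals > 0])
    d <- if (!is.null(config$size_pool)) {
      sample(config$size_pool, k, replace = TRUE)
    } else if (config$size_gsd == 1) {
      rep(config$size_median, k)
    } else {
      stats::rlnorm(k, meanlog = log(config$size_median),
                    sdlog = log(config$size_gsd))
    }
    mass_elem <- config$analyte$mass_fraction *
      diameter_to_mass(d, config$analyte$density)        # g element
    ideal <- mass_elem * 1e6 * config$cal_slope /
      (config$true_eta * q_ls * st$dwell_time)
    if (any(ideal > 1e9)) stop("expected event counts exceed 1e9 per dwell")
    ev_counts <- stats::rpois(k, ideal)
    if (config$split_events) {
      frac <- stats::runif(k)
      c1 <- stats::rbinom(k, ev_counts, frac)
      c2 <- ev_counts - c1
      add1 <- tapply(c1, dwell, sum)
      counts[as.integer(names(add1))] <- counts[as.integer(names(add1))] + add1
      nxt <- pmin(dwell + 1L, n)
      add2 <- tapply(c2, nxt, sum)
      counts[as.integer(names(add2))] <- counts[as.integer(names(add2))] + add2
    } else {
      add <- tapply(ev_counts, dwell, sum)
      counts[as.integer(names(add))] <- counts[as.integer(names(add))] + add
    }
    events <- data.frame(dwell = dwell, diameter = d,
                         analyte_mass = mass_elem,
                         ideal_counts = ideal, counts = ev_counts)
    events <- events[order(events$dwell), , drop = FALSE]
    rownames(events) <- NULL
  } else {
    events <- data.frame(dwell = integer(), diameter = numeric(),
                         analyte_mass = numeric(), ideal_counts = numeric(),
                         counts = integer())
  }
  structure(list(scan = time_scan(counts, st),
                 truth = list(events = events,
                              expected_background = lambda_bg,
                              envelope = g,
                              true_eta = config$true_eta,
                              ionic_concentration = config$ionic_concentration,
                              particle_number_concentration =
                                config$particle_number_concentration,
                              config = config)),
            class = "spiq_sim")
}

#' Media presets for the simulator
#'
#' Illustrative parameter bundles for the matrices commonly used in
#' dissolution studies (pure water, BSA solution, hydrocarbonate buffer,
#' artificial lysosomal fluid, Gamble's solution and its lipid-enhanced
#' variant, RPMI cell culture medium). Each preset carries a relative
#' sensitivity factor (matrix suppression of the calibration slope), a
#' background level, a starting dissolved-analyte concentration (RPMI
#' itself contributes dissolved copper) and a shrinking-sphere dissolution
#' rate consistent with the qualitative matrix ranking (fastest in the
#' acidic lysosomal fluid, slowest in buffer). These are defaults for
#' synthetic experiments, not fitted constants.
#'
#' @return A named list of preset lists with elements \code{sensitivity},
#'   \code{background_mean}, \code{ionic0}, \code{shrink_rate} (nm/h).
#' @export
media_presets <- function() {
  list(
    H2O    = list(sensitivity = 1.00, background_mean = 10,  ionic0 = 0.02, shrink_rate = 0.05),
    BSA    = list(sensitivity = 0.90, background_mean = 15,  ionic0 = 0.02, shrink_rate = 0.15),
    NaHCO3 = list(sensitivity = 0.95, background_mean = 12,  ionic0 = 0.02, shrink_rate = 0.02),
    ALF    = list(sensitivity = 0.50, background_mean = 20,  ionic0 = 0.05, shrink_rate = 0.50),
    GS     = list(sensitivity = 0.60, background_mean = 25,  ionic0 = 0.05, shrink_rate = 0.20),
    EGS    = list(sensitivity = 0.55, background_mean = 30,  ionic0 = 0.05, shrink_rate = 0.10),
    RPMI   = list(sensitivity = 0.40, background_mean = 60,  ionic0 = 10,   shrink_rate = 0.05)
  )
}

#' Simulate a time-resolved dissolution experiment
#'
#' Shrinking-sphere kinetics on a finite particle population: every
#' particle's diameter decreases linearly at \code{shrink_rate}; the
#' element mass lost moves to the dissolved (ionic) pool; particles below
#' \code{size_cutoff} are removed and their residual mass dissolved, so
#' total element mass is conserved between the two pools by construction.
#' One scan is generated per timepoint and replicate from the evolved
#' population.
#'
#' @param config A [simulation_config()] describing the t = 0 state
#'   (its \code{particle_number_concentration}, \code{size_median},
#'   \code{size_gsd} and \code{ionic_concentration} define the initial
#'   pools).
#' @param shrink_rate Diameter loss rate in nm/h (>= 0).
#' @param timepoints Sampling times in hours (default the 9-point schedule
#'   0, 1, 2, 4, 6, 8, 24, 48, 168 h).
#' @param replicates Independent replicate scans per timepoint (default 3).
#' @param size_cutoff Diameter (nm) below which particles count as fully
#'   dissolved (default 10).
#' @param n_population Size of the simulated particle population
#'   (default 5000); the represented volume is
#'   \code{n_population / particle_number_concentration}.
#' @return A list of class \code{spiq_sim_series}: \code{truth} (data.frame
#'   per timepoint: \code{time_h}, \code{ionic}, \code{particulate},
#'   \code{total} in ug/L, \code{number_concentration}, \code{n_alive}) and
#'   \code{scans}, a data.frame manifest (\code{time_h}, \code{replicate})
#'   with the matching list of \code{spiq_sim} objects in
#'   \code{scans$sim}.
#' @export
simulate_dissolution_experiment <- function(config, shrink_rate,
                                            timepoints = c(0, 1, 2, 4, 6, 8, 24, 48, 168),
                                            replicates = 3L,
                                            size_cutoff = 10,
                                            n_population = 5000L) {
  stopifnot(inherits(config, "spiq_sim_config"), shrink_rate >= 0,
            length(timepoints) >= 1L, all(timepoints >= 0), replicates >= 1L,
            config$particle_number_concentration > 0)
  if (!is.null(config$seed)) set.seed(config$seed)
  timepoints <- sort(timepoints)
  v_rep <- n_population / config$particle_number_concentration   # L
  d0 <- if (config$size_gsd == 1) rep(config$size_median, n_population)
        else stats::rlnorm(n_population, log(config$size_median), log(config$size_gsd))
  m0 <- config$analyte$mass_fraction * diameter_to_mass(d0, config$analyte$density)
  truth <- data.frame(time_h = timepoints, ionic = NA_real_,
                      particulate = NA_real_, total = NA_real_,
                      number_concentration = NA_real_, n_alive = NA_integer_)
  sims <- vector("list", length(timepoints) * replicates)
  manifest <- data.frame(time_h = rep(timepoints, each = replicates),
                         replicate = rep(seq_len(replicates), length(timepoints)))
  for (i in seq_along(timepoints)) {
    t <- timepoints[i]
    d_t <- pmax(d0 - shrink_rate * t, 0)
    alive <- d_t > size_cutoff
    m_t <- config$analyte$mass_fraction *
      diameter_to_mass(d_t, config$analyte$density)
    m_t[!alive] <- 0                       # fully dissolved below the cutoff
    dissolved <- sum(m0 - m_t)             # g element moved to the ionic pool
    ionic_t <- config$ionic_concentration + dissolved / v_rep * 1e6
    part_t <- sum(m_t) / v_rep * 1e6
    truth$ionic[i] <- ionic_t
    truth$particulate[i] <- part_t
    truth$total[i] <- ionic_t + part_t
    truth$n_alive[i] <- sum(alive)
    truth$number_concentration[i] <- sum(alive) / v_rep
    for (r in seq_len(replicates)) {
      cfg_t <- config
      cfg_t$seed <- NULL                   # inherit the running RNG stream
      cfg_t$ionic_concentration <- ionic_t
      cfg_t$particle_number_concentration <- sum(alive) / v_rep
      cfg_t$size_pool <- if (any(alive)) d_t[alive] else NULL
      if (!any(alive)) cfg_t$particle_number_concentration <- 0
      sims[[(i - 1L) * replicates + r]] <- simulate_scan(cfg_t)
    }
  }
  manifest$sim <- sims
  structure(list(truth = truth, scans = manifest,
                 shrink_rate = shrink_rate, size_cutoff = size_cutoff,
                 represented_volume_L = v_rep, config = config),
            class = "spiq_sim_series")
}
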