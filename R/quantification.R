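#' Analyte specification
#'
#' Links the measured element to the particle compound it sits in, so that
#' event masses (element) can be converted to particle masses (compound)
#' and spherical-equivalent diameters.
#'
#' @param element Element label, e.g. \code{"Cu"}.
#' @param compound Particle compound label, e.g. \code{"CuO"}.
#' @param density Compound density in g/cm^3.
#' @param mass_fraction Element mass / compound mass (Cu in CuO:
#'   63.546 / 79.545).
#' @return An object of class \code{spiq_analyte}.
#' @export
analyte_spec <- function(element, compound, density, mass_fraction) {
  stopifnot(density > 0, mass_fraction > 0, mass_fraction <= 1)
  structure(list(element = as.character(element),
                 compound = as.character(compound),
                 density = density, mass_fraction = mass_fraction),
            class = "spiq_analyte")
}

#' @rdname analyte_spec
#' @export
analyte_cuo <- function() analyte_spec("Cu", "CuO", 6.31, 63.546 / 79.545)

#' @rdname analyte_spec
#' @export
analyte_au <- function() analyte_spec("Au", "Au", 19.3, 1)

#' Spherical-equivalent diameter from particle mass, and back
#'
#' \eqn{d = (6 m / (\pi \rho))^{1/3}} with the result converted from cm to
#' nm; \code{diameter_to_mass} is the exact inverse.
#'
#' @param mass Particle (compound) mass in g.
#' @param diameter Particle diameter in nm.
#' @param density Compound density in g/cm^3.
#' @return Diameter in nm, or mass in g.
#' @export
mass_to_diameter <- function(mass, density) {
  (6 * mass / (pi * density))^(1 / 3) * 1e7
}

#' @rdname mass_to_diameter
#' @export
diameter_to_mass <- function(diameter, density) {
  (pi / 6) * (diameter * 1e-7)^3 * density
}

#' Convert detected events to per-particle masses and diameters
#'
#' The element mass of one event follows from the ionic calibration: a net
#' event intensity of \eqn{I} counts corresponds to the element mass that,
#' dissolved in the effective sample volume of one dwell
#' (\eqn{\eta \cdot Q \cdot t_d}), would produce that intensity, i.e.
#' \eqn{m = I \cdot \eta Q t_d / R} with \eqn{R} the calibration slope.
#' The compound mass is the element mass over the analyte mass fraction and
#' the diameter follows from the spherical model.
#'
#' @param events An event table from [detect_events()] / [threshold_scan()].
#' @param cal A [fit_ionic_calibration()] result.
#' @param te A transport-efficiency result ([transport_efficiency()] or
#'   [known_transport_efficiency()]).
#' @param settings The [acquisition_settings()] of the measurement.
#' @param analyte An [analyte_spec()].
#' @return A data.frame of class \code{spiq_records}: the event columns
#'   plus \code{analyte_mass} (g element), \code{particle_mass} (g
#'   compound) and \code{diameter} (nm). Events with non-positive net
#'   intensity are dropped; the number dropped is attached as attribute
#'   \code{"n_dropped"}.
#' @export
events_to_records <- function(events, cal, te, settings, analyte) {
  stopifnot(inherits(cal, "spiq_calibration"), inherits(te, "spiq_te"),
            inherits(settings, "spiq_settings"), inherits(analyte, "spiq_analyte"))
  if (cal$slope <= 0) stop("calibration slope must be positive")
  keep <- events$net_intensity > 0
  n_dropped <- sum(!keep)
  ev <- events[keep, , drop = FALSE]
  q_ls <- ul_per_min_to_L_per_s(settings$flow_rate)
  mass_ug <- ev$net_intensity * te$efficiency * q_ls * settings$dwell_time / cal$slope
  analyte_mass <- mass_ug * 1e-6                      # g element
  particle_mass <- analyte_mass / analyte$mass_fraction
  out <- cbind(ev,
               data.frame(analyte_mass = analyte_mass,
                          particle_mass = particle_mass,
                          diameter = mass_to_diameter(particle_mass, analyte$density)))
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("spiq_records", "data.frame")
  out
}

#' Ionic background concentration
#'
#' The mean trimmed background level over the pieces, converted to a
#' dissolved-analyte concentration through the ionic calibration. Negative
#' results (blank-level backgrounds below the calibration intercept) are
#' floored at zero and flagged.
#'
#' @param pieces Piece table from [iterative_threshold()].
#' @param cal A [fit_ionic_calibration()] result.
#' @return Concentration in ug/L, with attribute \code{"floored"} set to
#'   \code{TRUE} when a negative value was clipped to zero.
#' @export
ionic_background_concentration <- function(pieces, cal) {
  stopifnot(inherits(cal, "spiq_calibration"))
  conc <- (mean(pieces$background_mean) - cal$intercept) / cal$slope
  floored <- conc < 0
  structure(max(0, conc), floored = floored)
}

# analyzed sample volume in L: flow x evaluated duration, capped at the
# loop volume for direct-injection runs (the loop bounds what was injected)
analyzed_volume_L <- function(flow_rate, duration_s, loop_volume = NULL) {
  v_ul <- flow_rate / 60 * duration_s
  if (!is.null(loop_volume)) v_ul <- min(v_ul, loop_volume)
  v_ul * 1e-6
}

#' Particle number concentration
#'
#' Detected events corrected for the transport efficiency, over the
#' analyzed sample volume.
#'
#' @param n_events Number of detected events.
#' @param te Transport-efficiency result.
#' @param flow_rate Sample flow rate in uL/min.
#' @param duration_s Evaluated (transient) duration in seconds.
#' @param loop_volume Optional injection-loop cap on the analyzed volume,
#'   in uL.
#' @return Particles per L.
#' @export
number_concentration <- function(n_events, te, flow_rate, duration_s,
                                 loop_volume = NULL) {
  stopifnot(inherits(te, "spiq_te"), te$efficiency > 0)
  v <- analyzed_volume_L(flow_rate, duration_s, loop_volume)
  if (v <= 0) stop("analyzed volume must be positive")
  n_events / (te$efficiency * v)
}

#' Particulate element content
#'
#' Sum of per-event element masses corrected for transport efficiency,
#' over the analyzed volume.
#'
#' @param records A [events_to_records()] table.
#' @inheritParams number_concentration
#' @return Concentration in ug/L.
#' @export
particulate_content <- function(records, te, flow_rate, duration_s,
                                loop_volume = NULL) {
  stopifnot(inherits(te, "spiq_te"), te$efficiency > 0)
  v <- analyzed_volume_L(flow_rate, duration_s, loop_volume)
  if (v <= 0) stop("analyzed volume must be positive")
  sum(records$analyte_mass) / (te$efficiency * v) * 1e6
}

#' Quantify a thresholded scan
#'
#' Assembles the per-measurement outputs: event rate, number
#' concentration, median spherical-equivalent diameter, ionic background
#' concentration, particulate content and their sum (the total element
#' content). A measurement whose event count falls below
#' \code{low_count_threshold} is flagged rather than suppressed, following
#' the practice of reporting low-count results in parentheses.
#'
#' @param scan A [time_scan()].
#' @param thr A [threshold_scan()] result for that scan.
#' @param cal Ionic calibration for the scan's medium.
#' @param te Transport efficiency for the scan's medium.
#' @param analyte An [analyte_spec()].
#' @param low_count_threshold Events per measurement below which the
#'   \code{low_event_count} flag is set (default 100).
#' @param cap_at_loop Cap the analyzed volume at the loop volume (default
#'   \code{TRUE}, appropriate for direct injection).
#' @return An object of class \code{spiq_quantification}.
#' @export
quantify_scan <- function(scan, thr, cal, te, analyte,
                          low_count_threshold = 100L, cap_at_loop = TRUE) {
  stopifnot(inherits(scan, "spiq_scan"), inherits(thr, "spiq_threshold_result"),
            inherits(cal, "spiq_calibration"), inherits(te, "spiq_te"),
            inherits(analyte, "spiq_analyte"))
  if (!identical(cal$medium, te$medium))
    stop("medium mismatch: calibration is '", cal$medium,
         "', transport efficiency is '", te$medium, "'")
  st <- scan$settings
  records <- events_to_records(thr$events, cal, te, st, analyte)
  loop <- if (cap_at_loop) st$loop_volume else NULL
  dur <- thr$window$duration
  ionic <- ionic_background_concentration(thr$pieces, cal)
  part <- particulate_content(records, te, st$flow_rate, dur, loop)
  flags <- thr$flags
  if (nrow(records) < low_count_threshold) flags <- c(flags, "low_event_count")
  if (isTRUE(attr(ionic, "floored"))) flags <- c(flags, "negative_ionic_floored")
  structure(list(medium = st$medium,
                 particles_per_minute = thr$particles_per_minute,
                 number_concentration = number_concentration(
                   nrow(records), te, st$flow_rate, dur, loop),
                 median_diameter = if (nrow(records)) stats::median(records$diameter)
                                   else NA_real_,
                 ionic_background = as.numeric(ionic),
                 particulate_content = part,
                 total_content = as.numeric(ionic) + part,
                 n_events = nrow(records),
                 n_dropped = attr(records, "n_dropped"),
                 records = records,
                 analyzed_volume_L = analyzed_volume_L(st$flow_rate, dur, loop),
                 flags = unique(flags)),
            class = "spiq_quantification")
}

#' @export
print.spiq_quantification <- function(x, ...) {
  cat(sprintf(paste0("spICP-MS quantification [%s]:\n",
                     "  particles: %d events, %.0f per minute, %.3g per L\n",
                     "  median diameter: %s nm\n",
                     "  ionic background: %.3g ug/L; particulate: %.3g ug/L; total: %.3g ug/L\n"),
              x$medium, x$n_events, x$particles_per_minute,
              x$number_concentration,
              if (is.na(x$median_diameter)) "NA" else sprintf("%.1f", x$median_diameter),
              x$ionic_background, x$particulate_content, x$total_content))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a quantification to a plain list (for JSON output)
#' @param x A \code{spiq_quantification}.
#' @return A named list of scalar fields (the per-event table excluded).
#' @export
as_list_quantification <- function(x) {
  stopifnot(inherits(x, "spiq_quantification"))
  list(medium = x$medium,
       particles_per_minute = x$particles_per_minute,
       number_concentration_per_L = x$number_concentration,
       median_diameter_nm = x$median_diameter,
       ionic_background_ug_per_L = x$ionic_background,
       particulate_content_ug_per_L = x$particulate_content,
       total_content_ug_per_L = x$total_content,
       n_events = x$n_events,
       n_dropped = x$n_dropped,
       analyzed_volume_L = x$analyzed_volume_L,
       flags = as.list(x$flags))
}
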