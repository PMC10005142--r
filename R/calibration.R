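# unit boundary conversions (internal SI: g, L, s)
ul_per_min_to_L_per_s <- function(q) q * 1e-6 / 60
ul_per_min_to_L_per_min <- function(q) q * 1e-6
nm_to_cm <- function(d) d * 1e-7

#' Fit an ionic response calibration
#'
#' Ordinary least squares of mean intensity (counts per dwell) on dissolved
#' analyte concentration (ug/L), per matrix. The intercept is free by
#' default: matrix blanks (e.g. the dissolved copper content of RPMI
#' medium) produce genuine nonzero intercepts. Set \code{force_origin} to
#' clamp the intercept at zero.
#'
#' @param concentration Standard concentrations in ug/L (the study design
#'   uses 1, 2, 5 and 10 ug/L; a 0 ug/L blank is optional).
#' @param intensity Mean intensities in counts per dwell.
#' @param medium Matrix label.
#' @param force_origin Force the intercept to zero? Default \code{FALSE}.
#' @return An object of class \code{spiq_calibration}: \code{medium},
#'   \code{slope} (counts/dwell per ug/L), \code{intercept} (counts/dwell),
#'   \code{r_squared}, \code{points}.
#' @export
fit_ionic_calibration <- function(concentration, intensity, medium = "H2O",
                                  force_origin = FALSE) {
  concentration <- as.numeric(concentration)
  intensity <- as.numeric(intensity)
  if (length(concentration) != length(intensity))
    stop("concentration and intensity lengths differ")
  if (length(unique(concentration)) < 2L)
    stop("need at least 2 distinct concentrations")
  fit <- if (force_origin) stats::lm(intensity ~ 0 + concentration)
         else stats::lm(intensity ~ concentration)
  co <- stats::coef(fit)
  slope <- unname(co[["concentration"]])
  intercept <- if (force_origin) 0 else unname(co[["(Intercept)"]])
  if (!is.finite(slope) || slope <= 0)
    stop("non-positive calibration slope for medium '", medium, "'")
  pred <- intercept + slope * concentration
  ss_res <- sum((intensity - pred)^2)
  ss_tot <- sum((intensity - mean(intensity))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(medium = as.character(medium), slope = slope,
                 intercept = intercept, r_squared = r2,
                 points = data.frame(concentration = concentration,
                                     intensity = intensity)),
            class = "spiq_calibration")
}

#' @export
print.spiq_calibration <- function(x, ...) {
  cat(sprintf("Ionic calibration [%s]: intensity = %.4g + %.4g * C (r^2 = %.4f, %d points)\n",
              x$medium, x$intercept, x$slope, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' Reference nanoparticle standard
#'
#' A particle standard of certified size and mass concentration used to
#' calibrate the transport efficiency by the particle-frequency method.
#' The default is the NIST 8012 gold standard: nominally "30 nm", with a
#' certified electron-microscopy mean diameter of 27.6 nm, which is the
#' default here; pass \code{diameter = 30} for the nominal value.
#'
#' @param label Standard name.
#' @param diameter Reference diameter in nm.
#' @param density Particle density in g/cm^3 (Au: 19.3).
#' @param mass_concentration Diluted mass concentration in ng/L (the study
#'   uses dilutions down to 50 ng/L).
#' @param mass_fraction Element mass fraction of the particle compound
#'   (1.0 for elemental gold).
#' @return An object of class \code{spiq_standard}.
#' @export
reference_particle_standard <- function(label = "NIST 8012", diameter = 27.6,
                                        density = 19.3,
                                        mass_concentration = 50,
                                        mass_fraction = 1) {
  stopifnot(diameter > 0, density > 0, mass_concentration > 0,
            mass_fraction > 0, mass_fraction <= 1)
  structure(list(label = as.character(label), diameter = diameter,
                 density = density, mass_concentration = mass_concentration,
                 mass_fraction = mass_fraction),
            class = "spiq_standard")
}

#' Mass of one reference particle
#'
#' Spherical particle mass \eqn{m = (\pi/6) d^3 \rho} with the diameter
#' converted from nm to cm.
#'
#' @param std A [reference_particle_standard()].
#' @return Particle mass in g.
#' @export
particle_mass_of_standard <- function(std) {
  stopifnot(inherits(std, "spiq_standard"))
  (pi / 6) * nm_to_cm(std$diameter)^3 * std$density
}

#' Matrix-matched transport efficiency by the particle-frequency method
#'
#' The number concentration of the reference suspension is its mass
#' concentration divided by the single-particle mass; multiplied by the
#' sample flow rate this gives the rate at which particles are introduced
#' into the nebulizer. The transport efficiency is the ratio of the
#' detected event rate to that introduced rate.
#'
#' @param detected_rate Detected particle events per minute (averaged over
#'   replicate measurements of the reference standard).
#' @param std A [reference_particle_standard()].
#' @param flow_rate Sample flow rate in uL/min.
#' @param medium Matrix label the efficiency applies to.
#' @return An object of class \code{spiq_te}: \code{medium},
#'   \code{efficiency}, \code{detected_rate}, \code{introduced_rate}
#'   (both per minute), \code{standard}.
#' @export
transport_efficiency <- function(detected_rate, std, flow_rate = 500,
                                 medium = "H2O") {
  stopifnot(inherits(std, "spiq_standard"), detected_rate >= 0, flow_rate > 0)
  m_ref <- particle_mass_of_standard(std)
  number_conc <- (std$mass_concentration * 1e-9) / m_ref   # particles per L
  introduced <- number_conc * ul_per_min_to_L_per_min(flow_rate)
  if (introduced <= 0) stop("introduced particle rate is zero")
  eta <- detected_rate / introduced
  if (eta > 1)
    stop(sprintf("transport efficiency %.3g > 1: detected rate inconsistent with standard", eta))
  structure(list(medium = as.character(medium), efficiency = eta,
                 detected_rate = detected_rate, introduced_rate = introduced,
                 standard = std),
            class = "spiq_te")
}

#' Construct a transport-efficiency result from a known value
#'
#' Used when the efficiency was determined elsewhere (or, in simulations,
#' is known exactly) rather than measured from a reference-standard scan.
#'
#' @param efficiency Transport efficiency in (0, 1].
#' @param medium Matrix label.
#' @return An object of class \code{spiq_te}.
#' @export
known_transport_efficiency <- function(efficiency, medium = "H2O") {
  stopifnot(efficiency > 0, efficiency <= 1)
  structure(list(medium = as.character(medium), efficiency = efficiency,
                 detected_rate = NA_real_, introduced_rate = NA_real_,
                 standard = NULL),
            class = "spiq_te")
}

#' @export
print.spiq_te <- function(x, ...) {
  cat(sprintf("Transport efficiency [%s]: %.4f", x$medium, x$efficiency))
  if (!is.na(x$detected_rate))
    cat(sprintf(" (detected %.0f/min of %.0f/min introduced)",
                x$detected_rate, x$introduced_rate))
  cat("\n")
  invisible(x)
}
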