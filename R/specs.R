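# Physical constants used throughout. Standard gravity as printed on
# centrifuge RCF scales and in Stokes-law sedimentation tables.
.g_standard <- 9.81  # m/s2

#' Fluid properties for sedimentation
#'
#' @param density Fluid density, g/cm3.
#' @param viscosity Dynamic viscosity, mPa s (= cP). Default is water at
#'   20 degC, 1.0016 mPa s.
#' @param temperature Annotation only, degC; no viscosity lookup is applied.
#' @return Object of class `fluid_spec`.
#' @export
fluid_spec <- function(density = 1.0, viscosity = 1.0016, temperature = 20) {
  if (density <= 0) stop("fluid density must be positive")
  if (viscosity <= 0) stop("fluid viscosity must be positive")
  structure(list(density = density, viscosity = viscosity,
                 temperature = temperature),
            class = "fluid_spec")
}

#' Water at 20 degC
#'
#' Convenience constructor: density 1.0 g/cm3, viscosity 1.0016 mPa s.
#' @return A [fluid_spec()].
#' @export
water_20C <- function() fluid_spec(1.0, 1.0016, 20)

#' Spherical particle specification
#'
#' @param diameter Particle diameter in the unit given by `unit`.
#' @param unit One of `"nm"`, `"um"`, `"mm"`, `"m"`.
#' @param density Particle density, g/cm3. Defaults to the polymer's
#'   registry density when `polymer` is supplied.
#' @param polymer Optional [polymer_spec()] for carbon arithmetic.
#' @return Object of class `particle_spec`; diameter stored in metres.
#' @examples
#' ps1000 <- particle_spec(1000, "nm", polymer = get_polymer("PS"))
#' @export
particle_spec <- function(diameter, unit = c("nm", "um", "mm", "m"),
                          density = NULL, polymer = NULL) {
  unit <- match.arg(unit)
  if (diameter < 0) stop("diameter must be non-negative")
  scale <- c(nm = 1e-9, um = 1e-6, mm = 1e-3, m = 1)[[unit]]
  if (is.null(density)) {
    if (is.null(polymer) || is.na(polymer$density))
      stop("supply 'density' or a polymer with a registry density")
    density <- polymer$density
  }
  if (density <= 0) stop("particle density must be positive")
  structure(list(diameter = diameter * scale, density = density,
                 polymer = polymer),
            class = "particle_spec")
}

#' @export
print.particle_spec <- function(x, ...) {
  cat(sprintf("<particle_spec> d = %g nm, density %.3f g/cm3%s\n",
              x$diameter * 1e9, x$density,
              if (!is.null(x$polymer)) paste0(", polymer ", x$polymer$name) else ""))
  invisible(x)
}

#' Centrifuge run description (swing-bucket rotor at full deflection)
#'
#' Radial geometry of the fluid column plus spin speed and duration. The tube
#' axis is taken parallel to the radius, so the liquid meniscus sits at
#' `r_top` and the tube bottom at `r_bottom` (both measured from the rotor
#' axis). Either `angular_speed` (rad/s) or `rpm` must be given.
#'
#' @param r_top,r_bottom Radial positions, mm; `0 < r_top < r_bottom`.
#' @param duration Spin time, s.
#' @param angular_speed Angular speed, rad/s.
#' @param rpm Rotational speed, revolutions per minute (alternative input).
#' @param fluid A [fluid_spec()]; defaults to water at 20 degC.
#' @return Object of class `centrifuge_run` with fields `r_top`, `r_bottom`,
#'   `column_height` (mm), `omega` (rad/s), `duration` (s), `fluid`.
#' @export
centrifuge_run <- function(r_top, r_bottom, duration,
                           angular_speed = NULL, rpm = NULL,
                           fluid = water_20C()) {
  if (!(r_top > 0 && r_bottom > r_top))
    stop("need 0 < r_top < r_bottom (mm)")
  if (duration <= 0) stop("duration must be positive")
  if (is.null(angular_speed)) {
    if (is.null(rpm)) stop("supply 'angular_speed' (rad/s) or 'rpm'")
    angular_speed <- rpm * 2 * pi / 60
  }
  if (angular_speed <= 0) stop("angular speed must be positive")
  structure(list(r_top = r_top, r_bottom = r_bottom,
                 column_height = r_bottom - r_top,
                 omega = angular_speed, duration = duration, fluid = fluid),
            class = "centrifuge_run")
}

#' @export
print.centrifuge_run <- function(x, ...) {
  cat(sprintf(paste0("<centrifuge_run> r %.1f-%.1f mm (column %.1f mm), ",
                     "%.0f rpm, %.1f min; RCF %.0f-%.0f g\n"),
              x$r_top, x$r_bottom, x$column_height, x$omega * 60 / (2 * pi),
              x$duration / 60, rcf_at(x, x$r_top), rcf_at(x, x$r_bottom)))
  invisible(x)
}

#' Relative centrifugal force at a radial position
#'
#' RCF (in multiples of g) varies linearly with radius: `omega^2 r / g`.
#'
#' @param run A [centrifuge_run()].
#' @param r_mm Radial position, mm.
#' @return RCF in g-units.
#' @export
rcf_at <- function(run, r_mm) run$omega^2 * (r_mm / 1000) / .g_standard

#' Convert between rpm and RCF at a given radius
#'
#' @param rpm Rotational speed, rev/min.
#' @param rcf Relative centrifugal force, g-units.
#' @param radius_mm Radius at which the RCF applies, mm.
#' @return `rpm_to_rcf()` gives RCF; `rcf_to_rpm()` gives rpm.
#' @export
rpm_to_rcf <- function(rpm, radius_mm) {
  (rpm * 2 * pi / 60)^2 * (radius_mm / 1000) / .g_standard
}

#' @rdname rpm_to_rcf
#' @export
rcf_to_rpm <- function(rcf, radius_mm) {
  sqrt(rcf * .g_standard / (radius_mm / 1000)) * 60 / (2 * pi)
}

#' One component of a particle suspension
#'
#' @param particle A [particle_spec()].
#' @param mass_concentration Mass concentration, mg/L.
#' @param name Component label; defaults to the diameter in nm.
#' @return Object of class `suspension_component`.
#' @export
suspension_component <- function(particle, mass_concentration,
                                 name = sprintf("%g nm", particle$diameter * 1e9)) {
  if (mass_concentration < 0) stop("mass concentration must be >= 0")
  structure(list(particle = particle,
                 mass_concentration = mass_concentration, name = name),
            class = "suspension_component")
}
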