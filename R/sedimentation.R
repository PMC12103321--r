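# Internal: Stokes exponential rate constant k = d^2 (rho_p - rho_f) w^2 / (18 mu)
# in 1/s, so that a particle at radius r0 follows r(t) = r0 * exp(k t).
.stokes_k <- function(diameter_m, particle_density, run) {
  drho <- (particle_density - run$fluid$density) * 1000      # kg/m3
  mu <- run$fluid$viscosity * 1e-3                           # Pa s
  diameter_m^2 * drho * run$omega^2 / (18 * mu)
}

#' Stokes settling speed under constant acceleration
#'
#' Terminal settling speed of a sphere, `v = d^2 (rho_p - rho_f) a / (18 mu)`,
#' reported in cm/min as customary on sedimentation tables. Negative for
#' buoyant particles (density below the fluid's).
#'
#' @param particle A [particle_spec()].
#' @param fluid A [fluid_spec()].
#' @param acceleration Acceleration, m/s2; defaults to standard gravity.
#' @return Settling speed, cm/min.
#' @examples
#' ps90 <- particle_spec(90, "um", density = 1.05)
#' stokes_settling_speed(ps90, water_20C())  # ~1.32 cm/min
#' @export
stokes_settling_speed <- function(particle, fluid = water_20C(),
                                  acceleration = 9.81) {
  drho <- (particle$density - fluid$density) * 1000
  mu <- fluid$viscosity * 1e-3
  v_ms <- particle$diameter^2 * drho * acceleration / (18 * mu)
  v_ms * 100 * 60
}

#' Reconstruct rotor geometry from a printed g-force gradient
#'
#' In a spinning rotor the RCF grows linearly with radius, so the RCF values
#' at the meniscus and tube bottom fix the two radii once the column height
#' is known: `r_top / r_bottom = rcf_top / rcf_bottom` and
#' `r_bottom - r_top = column_height`. The angular speed follows from the
#' bottom RCF: `omega = sqrt(rcf_bottom * g / r_bottom)`.
#'
#' @param rcf_top,rcf_bottom RCF at the liquid meniscus and tube bottom,
#'   g-units; `0 < rcf_top < rcf_bottom`.
#' @param column_height Liquid column height, mm.
#' @param duration Spin time, s.
#' @param fluid A [fluid_spec()].
#' @return A [centrifuge_run()] with the reconstructed geometry.
#' @examples
#' c1 <- geometry_from_rcf_gradient(1042, 1976, 60, duration = 14 * 60)
#' @export
geometry_from_rcf_gradient <- function(rcf_top, rcf_bottom, column_height,
                                       duration, fluid = water_20C()) {
  if (!(rcf_top > 0 && rcf_bottom > rcf_top))
    stop("need 0 < rcf_top < rcf_bottom: equal or inverted gradient is geometrically impossible")
  if (column_height <= 0) stop("column height must be positive")
  r_bottom <- column_height / (1 - rcf_top / rcf_bottom)
  r_top <- r_bottom - column_height
  omega <- sqrt(rcf_bottom * .g_standard / (r_bottom / 1000))
  centrifuge_run(r_top = r_top, r_bottom = r_bottom, duration = duration,
                 angular_speed = omega, fluid = fluid)
}

#' Effective size cutoff of a centrifugation run
#'
#' The diameter whose exponential radial trajectory,
#' `r(t) = r_top * exp(k t)`, traverses the whole fluid column in exactly the
#' run duration:
#' `d = sqrt( 18 mu ln(r_bottom / r_top) / ((rho_p - rho_f) omega^2 t) )`.
#' Particles larger than this reach the pellet from any starting depth.
#'
#' @param run A [centrifuge_run()].
#' @param particle_density Particle density, g/cm3; must exceed the fluid's.
#' @return Cutoff diameter, nm.
#' @examples
#' c1 <- geometry_from_rcf_gradient(1042, 1976, 60, duration = 14 * 60)
#' effective_cutoff_diameter(c1, 1.05)  # ~1341 nm
#' @export
effective_cutoff_diameter <- function(run, particle_density) {
  if (particle_density <= run$fluid$density)
    stop("particle density must exceed fluid density: no sedimentation cutoff")
  drho <- (particle_density - run$fluid$density) * 1000
  mu <- run$fluid$viscosity * 1e-3
  d <- sqrt(18 * mu * log(run$r_bottom / run$r_top) /
              (drho * run$omega^2 * run$duration))
  d * 1e9
}

#' Spin time needed for a target size cutoff
#'
#' Inverse of [effective_cutoff_diameter()] in `"effective"` mode. In
#' `"nominal"` mode it reproduces the planning convention in which the set
#' RCF is taken as uniform over the column and a particle at the meniscus
#' must traverse the full column height at constant Stokes speed — the
#' "theoretical cutoff" convention used when choosing run durations.
#'
#' @param target_diameter Cutoff diameter, nm.
#' @param run A [centrifuge_run()] (`"effective"` mode; its `duration` is
#'   ignored). For `"nominal"` mode supply `set_rcf` and `column_height`
#'   instead.
#' @param particle_density Particle density, g/cm3.
#' @param mode `"effective"` (radius-resolved gradient) or `"nominal"`
#'   (uniform field at the set RCF).
#' @param set_rcf Set-point RCF, g-units (nominal mode).
#' @param column_height Column height, mm (nominal mode).
#' @param fluid A [fluid_spec()] (nominal mode).
#' @return Duration in seconds, with attribute `mode` recording the
#'   convention used.
#' @export
spin_time_for_cutoff <- function(target_diameter, run = NULL,
                                 particle_density = 1.05,
                                 mode = c("effective", "nominal"),
                                 set_rcf = NULL, column_height = NULL,
                                 fluid = water_20C()) {
  mode <- match.arg(mode)
  d <- target_diameter * 1e-9
  if (mode == "effective") {
    if (is.null(run)) stop("'run' required in effective mode")
    if (particle_density <= run$fluid$density)
      stop("particle density must exceed fluid density")
    drho <- (particle_density - run$fluid$density) * 1000
    mu <- run$fluid$viscosity * 1e-3
    t <- 18 * mu * log(run$r_bottom / run$r_top) / (drho * run$omega^2 * d^2)
  } else {
    if (is.null(set_rcf) || is.null(column_height))
      stop("'set_rcf' and 'column_height' required in nominal mode")
    if (particle_density <= fluid$density)
      stop("particle density must exceed fluid density")
    drho <- (particle_density - fluid$density) * 1000
    mu <- fluid$viscosity * 1e-3
    v <- d^2 * drho * set_rcf * .g_standard / (18 * mu)   # m/s
    t <- (column_height / 1000) / v
  }
  structure(t, mode = mode)
}

#' Pelleted mass fraction of one particle size in a spin
#'
#' Assuming the component is uniformly distributed along the fluid column at
#' the start of the run (homogeneous suspension, tube axis along the radius),
#' the fraction of its mass that reaches the tube bottom in time `t` is
#' `f = min(1, (r_bottom / H) * (1 - exp(-k t)))` with
#' `k = d^2 (rho_p - rho_f) omega^2 / (18 mu)`: the particles that arrive are
#' exactly those starting at `r0 >= r_bottom * exp(-k t)`. Buoyant particles
#' give 0.
#'
#' @param particle A [particle_spec()].
#' @param run A [centrifuge_run()].
#' @return Pellet mass fraction in \[0, 1\].
#' @examples
#' c1 <- geometry_from_rcf_gradient(1042, 1976, 60, duration = 14 * 60)
#' pellet_fraction(particle_spec(1000, "nm", density = 1.05), c1)  # ~0.633
#' @export
pellet_fraction <- function(particle, run) {
  if (particle$density <= run$fluid$density) return(0)
  k <- .stokes_k(particle$diameter, particle$density, run)
  min(1, (run$r_bottom / run$column_height) * (1 - exp(-k * run$duration)))
}

#' Sequential centrifugal fractionation of a polydisperse mixture
#'
#' Applies a chain of spins to a mixture, each acting on the previous
#' supernatant. Per stage and component: pellet mass = remaining mass x
#' [pellet_fraction()]; the unsettled remainder stays in the supernatant at
#' unchanged total volume (pellet liquid volume and sampling aliquots are not
#' deducted). Mass is conserved exactly along the chain.
#'
#' @param mixture List of [suspension_component()]s.
#' @param runs List of [centrifuge_run()]s, applied in order.
#' @param stage_names Optional character names for the stages (default
#'   `"F1"`, `"F2"`, ...).
#' @return A `data.frame` of class `fractionation_result` with one row per
#'   stage x component: `stage`, `component`, `diameter_nm`,
#'   `input_mg_L` (entering the stage), `pellet_fraction`, `pellet_mg_L`
#'   (referred to the original volume), `share_pct` (of that stage's pellet
#'   mass), `supernatant_mg_L`.
#' @examples
#' reg <- polymer_registry()
#' mix <- lapply(c(200, 500, 1000), function(d)
#'   suspension_component(particle_spec(d, "nm", polymer = reg$PS), 5))
#' c1 <- geometry_from_rcf_gradient(1042, 1976, 60, duration = 14 * 60)
#' simulate_sequential_fractionation(mix, list(c1))
#' @export
simulate_sequential_fractionation <- function(mixture, runs,
                                              stage_names = paste0("F", seq_along(runs))) {
  if (length(mixture) < 1L) stop("mixture must contain at least one component")
  if (length(runs) < 1L) stop("need at least one centrifuge run")
  remaining <- vapply(mixture, `[[`, numeric(1), "mass_concentration")
  comp_names <- vapply(mixture, `[[`, character(1), "name")
  dia_nm <- vapply(mixture, function(m) m$particle$diameter * 1e9, numeric(1))
  rows <- vector("list", length(runs))
  for (s in seq_along(runs)) {
    f <- vapply(mixture, function(m) pellet_fraction(m$particle, runs[[s]]),
                numeric(1))
    pellet <- remaining * f
    supern <- remaining - pellet
    total_pellet <- sum(pellet)
    share <- if (total_pellet > 0) 100 * pellet / total_pellet else rep(0, length(pellet))
    rows[[s]] <- data.frame(
      stage = stage_names[s], component = comp_names, diameter_nm = dia_nm,
      input_mg_L = remaining, pellet_fraction = f, pellet_mg_L = pellet,
      share_pct = share, supernatant_mg_L = supern,
      stringsAsFactors = FALSE
    )
    remaining <- supern
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fractionation_result", class(out))
  out
}

#' Write fractionation results as tidy CSV
#'
#' @param result A [simulate_sequential_fractionation()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fractionation_csv <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}
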