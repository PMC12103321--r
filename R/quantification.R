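#' Polymer mass concentration from a TOC reading
#'
#' Divides the organic-carbon concentration by the polymer's carbon mass
#' fraction: a suspension of pure PS at 1 mg/L contributes 0.9226 mg C/L.
#'
#' @param toc Organic carbon concentration, mg C/L (numeric or [meas()]).
#' @param polymer A [polymer_spec()].
#' @return Polymer mass concentration, mg/L (same class as `toc`).
#' @export
mass_concentration_from_toc <- function(toc, polymer) {
  if (polymer$carbon_fraction <= 0) stop("polymer carbon fraction must be positive")
  if (inherits(toc, "meas")) toc / meas(polymer$carbon_fraction, 0)
  else toc / polymer$carbon_fraction
}

#' Spike design: particles added to a water matrix
#'
#' @param polymers List of [polymer_spec()]s, one per spiked component.
#' @param concentrations Spiked mass concentrations, mg/L (same length).
#' @param native_toc_unfiltered,native_toc_filtered Native TOC of the
#'   unspiked matrix, mg C/L ([meas()] or numeric), optional.
#' @return Object of class `spike_design`.
#' @export
spike_design <- function(polymers, concentrations,
                         native_toc_unfiltered = NULL,
                         native_toc_filtered = NULL) {
  if (length(polymers) != length(concentrations))
    stop("one concentration per spiked polymer required")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  structure(list(polymers = polymers, concentrations = concentrations,
                 native_toc_unfiltered = native_toc_unfiltered,
                 native_toc_filtered = native_toc_filtered),
            class = "spike_design")
}

#' Expected organic-carbon addition of a spike
#'
#' Sum over components of spiked mass concentration times carbon mass
#' fraction: e.g. 1 mg/L PS 1000 nm + 1 mg/L PS 50 nm adds
#' (1 + 1) x 0.9226 = 1.8452 mg C/L.
#'
#' @param design A [spike_design()].
#' @return Expected added TOC, mg C/L.
#' @export
spike_equivalent_carbon <- function(design) {
  if (length(design$polymers) == 0L) return(0)
  w <- vapply(design$polymers, `[[`, numeric(1), "carbon_fraction")
  sum(design$concentrations * w)
}

#' Recovery of a measured quantity against its expected value
#'
#' `100 * measured / expected`, with the standard uncertainty propagated for
#' a ratio (relative uncertainties in quadrature by default, or summed
#' linearly with `rule = "linear"`).
#'
#' @param measured,expected [meas()] or numeric values in the same units;
#'   `expected` must be positive.
#' @param rule Uncertainty combination rule, `"quadrature"` or `"linear"`.
#' @param numerator,denominator Provenance strings recorded in the result.
#' @return Object of class `recovery_value`: `value` (%), `u` (%), `rule`,
#'   `numerator`, `denominator`.
#' @examples
#' recovery(meas(1.637, 0.131), meas(1.712, 0.014))  # 95.6 ± 7.7 %
#' @export
recovery <- function(measured, expected, rule = c("quadrature", "linear"),
                     numerator = "measured", denominator = "expected") {
  rule <- match.arg(rule)
  m <- as_meas(measured); e <- as_meas(expected)
  if (any(e$value <= 0)) stop("expected value must be positive")
  val <- 100 * m$value / e$value
  rel <- switch(rule,
                quadrature = sqrt(.rel_u(m)^2 + .rel_u(e)^2),
                linear = abs(.rel_u(m)) + abs(.rel_u(e)))
  structure(list(value = val, u = abs(val) * rel, rule = rule,
                 numerator = numerator, denominator = denominator),
            class = "recovery_value")
}

#' @export
print.recovery_value <- function(x, ...) {
  cat(sprintf("<recovery_value> %.1f ± %.1f %% (%s / %s, %s rule)\n",
              x$value, x$u, x$numerator, x$denominator, x$rule))
  invisible(x)
}

#' Round a recovery to the displayed integer percent
#'
#' @param x A [recovery()] result.
#' @return Integer percent (half away from zero), as tabulated in reports.
#' @export
recovery_display <- function(x) .round_half_up(x$value)

#' Subtract the native matrix TOC from a spiked measurement
#'
#' Difference with quadrature-propagated uncertainty. A negative net value
#' (possible with noisy low-level measurements or contamination) is returned
#' unclipped with attribute `negative` set and a warning.
#'
#' @param spiked_toc,native_toc [meas()] or numeric, mg C/L.
#' @return Net TOC as a [meas()], attribute `negative`.
#' @export
background_subtract <- function(spiked_toc, native_toc) {
  net <- as_meas(spiked_toc) - as_meas(native_toc)
  neg <- net$value < 0
  if (any(neg))
    warning("negative net TOC after background subtraction: possible contamination or interference")
  attr(net, "negative") <- neg
  net
}

#' Convert between number and mass concentration of spherical particles
#'
#' `mass [mg/L] = number [1/mL] * (pi/6) d^3 rho * 1e9` with `d` in cm and
#' `rho` in g/cm3 (1 g/mL = 1e6 mg/L and 1/mL = 1e3 /L). The two functions
#' are exact inverses.
#'
#' @param number_per_mL Number concentration, particles/mL.
#' @param mass_mg_L Mass concentration, mg/L.
#' @param particle A [particle_spec()].
#' @return Mass concentration in mg/L, or number concentration in
#'   particles/mL.
#' @examples
#' ps1000 <- particle_spec(1000, "nm", density = 1.05)
#' number_to_mass_concentration(1, ps1000)  # 5.5e-7 mg/L
#' @export
number_to_mass_concentration <- function(number_per_mL, particle) {
  mass_g <- pi / 6 * (particle$diameter * 100)^3 * particle$density  # g/particle
  number_per_mL * mass_g * 1e6                                      # mg/L
}

#' @rdname number_to_mass_concentration
#' @export
mass_to_number_concentration <- function(mass_mg_L, particle) {
  mass_g <- pi / 6 * (particle$diameter * 100)^3 * particle$density
  mass_mg_L / (mass_g * 1e6)
}

#' Estimate a counting-blind component by subtraction
#'
#' When the particle counter cannot see one size class (e.g. below its
#' detection range), its mass concentration is estimated as the total from
#' TOC minus the counted components: `residual = total - sum(components)`.
#' The recovery against the nominal concentration and the propagated
#' uncertainty (rule selectable) are attached.
#'
#' @param total_mass_conc Total mass concentration from TOC, [meas()] or
#'   numeric, mg/L.
#' @param counted_components List (possibly empty) of [meas()]/numeric
#'   component concentrations, mg/L.
#' @param nominal Nominal concentration of the residual component, mg/L.
#' @param rule Uncertainty rule, `"quadrature"` (default) or `"linear"`.
#' @return List: `residual` ([meas()], flagged if negative), `recovery`
#'   (a `recovery_value`).
#' @examples
#' subtraction_estimator(meas(14.745, 1.05),
#'                       list(meas(5.415, 0.5), meas(5.25, 0.4)), nominal = 5)
#' @export
subtraction_estimator <- function(total_mass_conc, counted_components = list(),
                                  nominal, rule = c("quadrature", "linear")) {
  rule <- match.arg(rule)
  total <- as_meas(total_mass_conc)
  res <- total
  for (comp in counted_components) {
    comp <- as_meas(comp)
    res <- if (rule == "quadrature") res - comp
           else meas(res$value - comp$value, res$u + comp$u)
  }
  if (any(res$value < 0))
    warning("negative residual: counted components exceed the total")
  rec <- recovery(res, nominal, rule = rule,
                  numerator = "total - counted components",
                  denominator = "nominal concentration")
  list(residual = res, recovery = rec)
}

#' AF4 fractionation recoveries with ISO compliance flag
#'
#' Absolute recovery is each collected fraction's mass over the injected
#' mass; relative recovery is over the mass eluted without crossflow (the
#' F0 reference). Totals sum the fractions. The total recovery is compared
#' against the ISO acceptability threshold for AF4 (>= 70% by default).
#'
#' @param fraction_masses Named or unnamed numeric vector of collected
#'   fraction masses, ug.
#' @param injected_mass Injected analyte mass, ug (> 0).
#' @param no_crossflow_reference_mass Mass collected without crossflow, ug;
#'   required for relative recoveries.
#' @param iso_threshold Compliance threshold on the total recovery, percent.
#' @return `data.frame` with rows per fraction plus `"total"`:
#'   `fraction`, `mass_ug`, `absolute_pct`, `relative_pct` (`NA` without a
#'   reference), and attribute `iso_compliant` (logical, on the total
#'   absolute recovery, and relative when available).
#' @examples
#' af4_recovery(c(F1 = 30, F2 = 100), injected_mass = 150,
#'              no_crossflow_reference_mass = 125)
#' @export
af4_recovery <- function(fraction_masses, injected_mass,
                         no_crossflow_reference_mass = NULL,
                         iso_threshold = 70) {
  if (injected_mass <= 0) stop("injected mass must be positive")
  if (any(fraction_masses < 0)) stop("fraction masses must be >= 0")
  nm <- names(fraction_masses)
  if (is.null(nm)) nm <- paste0("F", seq_along(fraction_masses))
  abs_pct <- 100 * fraction_masses / injected_mass
  rel_pct <- if (is.null(no_crossflow_reference_mass)) rep(NA_real_, length(fraction_masses))
             else {
               if (no_crossflow_reference_mass <= 0)
                 stop("no-crossflow reference mass must be positive for relative recovery")
               100 * fraction_masses / no_crossflow_reference_mass
             }
  out <- data.frame(
    fraction = c(nm, "total"),
    mass_ug = c(fraction_masses, sum(fraction_masses)),
    absolute_pct = c(abs_pct, sum(abs_pct)),
    relative_pct = c(rel_pct, if (all(is.na(rel_pct))) NA_real_ else sum(rel_pct)),
    stringsAsFactors = FALSE
  )
  total <- out[out$fraction == "total", ]
  attr(out, "iso_threshold") <- iso_threshold
  attr(out, "iso_compliant") <- c(
    absolute = total$absolute_pct >= iso_threshold,
    relative = if (is.na(total$relative_pct)) NA else total$relative_pct >= iso_threshold
  )
  out
}

#' Filtration recovery
#'
#' Ratio of filtrate to pre-filtration concentration, as a percentage with
#' propagated uncertainty; a recovery near 100% indicates no loss on the
#' filter.
#'
#' @param filtrate_conc,pre_filtration_conc [meas()] or numeric
#'   concentrations in the same units; pre-filtration must be positive.
#' @param rule Uncertainty rule.
#' @return A `recovery_value`.
#' @export
filtration_recovery <- function(filtrate_conc, pre_filtration_conc,
                                rule = c("quadrature", "linear")) {
  recovery(filtrate_conc, pre_filtration_conc, rule = match.arg(rule),
           numerator = "filtrate", denominator = "pre-filtration")
}
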