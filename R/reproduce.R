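# The packaged study conditions: both centrifugation steps of the
# polydisperse PS experiment, reconstructed from the printed RCF-gradient
# endpoints over the 60 mm fluid column.
.study_c1 <- function(fluid = water_20C())
  geometry_from_rcf_gradient(1042, 1976, 60, duration = 14 * 60, fluid = fluid)
.study_c2 <- function(fluid = water_20C())
  geometry_from_rcf_gradient(1668, 3161, 60, duration = 30 * 60, fluid = fluid)

#' The equimassic three-size PS mixture of the fractionation study
#'
#' 5 mg/L each of PS 200, 500 and 1000 nm.
#'
#' @param registry Material registry.
#' @return List of three [suspension_component()]s.
#' @export
study_ps_mixture <- function(registry = polymer_registry()) {
  ps <- get_polymer("PS", registry)
  lapply(c(200, 500, 1000), function(d)
    suspension_component(particle_spec(d, "nm", polymer = ps), 5,
                         name = sprintf("PS %d nm", d)))
}

#' The two centrifugation runs of the fractionation study
#'
#' C1: gradient 1042-1976 RCF over a 60 mm column, 14 min. C2: 1668-3161
#' RCF, 60 mm, 30 min. Water at 20 degC.
#'
#' @param fluid A [fluid_spec()].
#' @return Named list of two [centrifuge_run()]s.
#' @export
study_centrifuge_runs <- function(fluid = water_20C()) {
  list(C1 = .study_c1(fluid), C2 = .study_c2(fluid))
}

#' Recompute the study's headline quantities
#'
#' Runs every packaged computation whose result the study reports: the
#' effective centrifugal cutoffs, the theoretical pellet composition shares,
#' the expected injected particle counts, the carbon mass fractions of the
#' calibration materials, the spike carbon equivalent, the spiked-water
#' recoveries and the subtraction estimate for the counter-blind 200 nm
#' component. Each row carries the reported reference value and an
#' agreement flag at the stated tolerance.
#'
#' @param uncertainty_rule Rule for propagated uncertainties
#'   (`"quadrature"` or `"linear"`); central values are unaffected.
#' @return `data.frame` of class `reproduction_report`: `quantity`, `units`,
#'   `computed`, `reference`, `tolerance`, `pass`.
#' @examples
#' \donttest{reproduce_study()}
#' @export
reproduce_study <- function(uncertainty_rule = c("quadrature", "linear")) {
  uncertainty_rule <- match.arg(uncertainty_rule)
  reg <- polymer_registry()
  ps <- reg$PS
  runs <- study_centrifuge_runs()
  frac <- simulate_sequential_fractionation(study_ps_mixture(reg), runs,
                                            stage_names = c("F1", "F2"))
  share <- function(stage, comp)
    frac$share_pct[frac$stage == stage & frac$component == comp]

  cnt30 <- expected_particles_injected(
    5, 50, particle_spec(30, "um", polymer = ps))$rounded
  cnt90 <- expected_particles_injected(
    25, 500, particle_spec(90, "um", polymer = ps))$rounded

  spike <- spike_design(list(ps, ps), c(1, 1))
  lake <- recovery(meas(1.637, 0.131), meas(1.712, 0.014),
                   rule = uncertainty_rule)
  vario <- recovery(meas(0.577, 0.265), meas(0.830, 0.004),
                    rule = uncertainty_rule)
  subt <- subtraction_estimator(
    total_mass_conc = meas(0.983 * 15, 0.071 * 15),
    counted_components = list(meas(1.083 * 5, 0.102 * 5),
                              meas(1.050 * 5, 0.082 * 5)),
    nominal = 5, rule = uncertainty_rule)

  rows <- list(
    list("effective cutoff C1", "nm",
         effective_cutoff_diameter(runs$C1, ps$density), 1341, "0.5%"),
    list("effective cutoff C2", "nm",
         effective_cutoff_diameter(runs$C2, ps$density), 724, "0.5%"),
    list("F1 pellet share PS 1000 nm", "%", share("F1", "PS 1000 nm"), 75.1, "0.3"),
    list("F1 pellet share PS 500 nm", "%", share("F1", "PS 500 nm"), 21.3, "0.3"),
    list("F2 pellet share PS 500 nm", "%", share("F2", "PS 500 nm"), 49.5, "0.3"),
    list("F2 pellet share PS 1000 nm", "%", share("F2", "PS 1000 nm"), 39.9, "0.3"),
    list("injected particles, 30 um standard plan", "count", cnt30, 18, "0"),
    list("injected particles, 90 um modified plan", "count", cnt90, 34, "0"),
    list("carbon fraction PS", "%", 100 * ps$carbon_fraction, 92.26, "0.005"),
    list("carbon fraction KHP", "%", 100 * reg$KHP$carbon_fraction, 47.05, "0.005"),
    list("carbon fraction Na2CO3", "%", 100 * reg$Na2CO3$carbon_fraction, 11.33, "0.005"),
    list("spike carbon equivalent", "mg C/L", spike_equivalent_carbon(spike),
         1.8452, "1e-4"),
    list("lake unfiltered spike recovery", "%", recovery_display(lake), 96, "1"),
    list("river filtered spike recovery", "%", recovery_display(vario), 70, "1"),
    list("PS 200 nm recovery by subtraction", "%", subt$recovery$value, 81.5, "0.3")
  )
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(quantity = r[[1]], units = r[[2]], computed = r[[3]],
               reference = r[[4]], tolerance = r[[5]],
               stringsAsFactors = FALSE)))
  tol_abs <- mapply(function(tol, ref) {
    if (grepl("%$", tol)) ref * as.numeric(sub("%$", "", tol)) / 100
    else as.numeric(tol)
  }, out$tolerance, out$reference)
  out$pass <- abs(out$computed - out$reference) <= tol_abs + 1e-12
  class(out) <- c("reproduction_report", class(out))
  out
}

#' @export
print.reproduction_report <- function(x, ...) {
  df <- as.data.frame(x)
  df$computed <- signif(df$computed, 6)
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("\n%d/%d quantities within tolerance\n", sum(x$pass), nrow(x)))
  invisible(x)
}
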