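# Shared fixtures: the study's materials, runs and mixture, built in code.
reg <- polymer_registry()
ps <- reg$PS

ps_particle <- function(d, unit = "nm") particle_spec(d, unit, polymer = ps)

study_c1 <- function() geometry_from_rcf_gradient(1042, 1976, 60, duration = 14 * 60)
study_c2 <- function() geometry_from_rcf_gradient(1668, 3161, 60, duration = 30 * 60)

equimassic_mixture <- function() study_ps_mixture(reg)

# modify fields of a centrifuge_run while keeping its class
mod_run <- function(run, ...) {
  args <- list(...)
  run[names(args)] <- args
  run
}
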