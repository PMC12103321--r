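#' Scenario for synthetic measurement generation
#'
#' Describes a ground-truth suspension plus the instrument noise structure:
#' replicate CVs for the TC/TIC channels, an instrument CV for the particle
#' counter, the matrix carbon background, and the syringe-settling loss
#' mechanism for unstirred samples. A single seed fixes every random draw;
#' generator functions take a `stream` offset so that independent draws
#' within one scenario remain reproducible.
#'
#' @param components List of [suspension_component()]s (the true
#'   composition).
#' @param doc_background Dissolved organic carbon of the matrix, mg C/L.
#' @param tic_background Inorganic carbon of the matrix, mg C/L.
#' @param cv_tc,cv_tic,cv_spes Instrument coefficients of variation, percent.
#' @param stirred If `FALSE`, each component is attenuated by the settling
#'   loss factor `max(0, 1 - v_settle * dead_time / intake_height)` before
#'   noise is applied.
#' @param dead_time_s Syringe dead time before aspiration, s.
#' @param intake_height_cm Height of the intake zone, cm.
#' @param noise Noise law for replicate draws: `"lognormal"` (default;
#'   mean-matched, keeps concentrations positive) or `"normal"`.
#' @param seed Integer seed governing all draws.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(components, doc_background = 0.03,
                          tic_background = 0, cv_tc = 2, cv_tic = 2,
                          cv_spes = 10, stirred = TRUE, dead_time_s = 0,
                          intake_height_cm = 2,
                          noise = c("lognormal", "normal"), seed = 1L) {
  if (any(c(cv_tc, cv_tic, cv_spes) < 0)) stop("CVs must be >= 0")
  if (intake_height_cm <= 0) stop("intake height must be positive")
  structure(list(components = components, doc_background = doc_background,
                 tic_background = tic_background, cv_tc = cv_tc,
                 cv_tic = cv_tic, cv_spes = cv_spes, stirred = stirred,
                 dead_time_s = dead_time_s,
                 intake_height_cm = intake_height_cm,
                 noise = match.arg(noise), seed = as.integer(seed)),
            class = "scenario_spec")
}

# Mean-matched noisy draws: lognormal parametrised so E[X] = mean exactly,
# or truncated-at-zero normal for small CVs.
.noisy_draws <- function(n, mean, cv_pct, noise) {
  if (mean == 0 || cv_pct == 0) return(rep(mean, n))
  cv <- cv_pct / 100
  if (noise == "lognormal") {
    sdlog <- sqrt(log1p(cv^2))
    stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
  } else {
    pmax(0, stats::rnorm(n, mean, cv * mean))
  }
}

# Settling attenuation for unstirred samples: linear depletion of the
# intake zone during the syringe dead time. Illustrative, not calibrated.
.settling_loss_factor <- function(component, scenario, fluid = water_20C()) {
  if (scenario$stirred || scenario$dead_time_s == 0) return(1)
  v <- stokes_settling_speed(component$particle, fluid)   # cm/min
  max(0, 1 - v * (scenario$dead_time_s / 60) / scenario$intake_height_cm)
}

#' True channel concentrations implied by a scenario
#'
#' TC carries the particulate carbon (after any settling loss), the
#' dissolved organic background and the inorganic carbon; TIC carries the
#' inorganic carbon only, so that TC - TIC recovers the organic content.
#'
#' @param scenario A [scenario_spec()].
#' @return Named numeric: `TC`, `TIC` (mg C/L).
#' @export
scenario_true_channels <- function(scenario) {
  particulate <- sum(vapply(scenario$components, function(cmp) {
    if (is.null(cmp$particle$polymer))
      stop("every scenario component needs a polymer reference")
    cmp$mass_concentration * cmp$particle$polymer$carbon_fraction *
      .settling_loss_factor(cmp, scenario)
  }, numeric(1)))
  c(TC = particulate + scenario$doc_background + scenario$tic_background,
    TIC = scenario$tic_background)
}

#' Simulate TC/TIC replicate streams
#'
#' Draws replicate readings around the scenario's true channel values with
#' the stated CVs. With a fixed scenario seed and stream the output is
#' bit-identical across calls.
#'
#' @param scenario A [scenario_spec()].
#' @param n_samples Number of samples to simulate.
#' @param n_replicates Replicates per channel (2 or 3; default 3 so the
#'   acceptance rule always has a third available).
#' @param stream Integer substream offset added to the scenario seed.
#' @return `data.frame`: `sample_id`, `channel`, `replicate_no`,
#'   `value_mg_L`.
#' @export
simulate_toc_replicates <- function(scenario, n_samples = 1,
                                    n_replicates = 3, stream = 0L) {
  stopifnot(n_replicates %in% 2:3)
  true <- scenario_true_channels(scenario)
  withr::with_seed(scenario$seed + as.integer(stream), {
    rows <- lapply(seq_len(n_samples), function(i) {
      rbind(
        data.frame(sample_id = i, channel = "TC",
                   replicate_no = seq_len(n_replicates),
                   value_mg_L = .noisy_draws(n_replicates, true[["TC"]],
                                             scenario$cv_tc, scenario$noise)),
        data.frame(sample_id = i, channel = "TIC",
                   replicate_no = seq_len(n_replicates),
                   value_mg_L = .noisy_draws(n_replicates, true[["TIC"]],
                                             scenario$cv_tic, scenario$noise))
      )
    })
    do.call(rbind, rows)
  })
}

# SPES optical detection window (single-particle counting).
.spes_dmin <- 250e-9
.spes_dmax <- 5e-6

#' Simulate single-particle counter observations
#'
#' Components outside the counter's 250 nm - 5 um window are invisible.
#' Visible components yield Poisson counts with mean equal to the true
#' number concentration times the analyzed volume, plus a multiplicative
#' instrument error with the scenario's SPES CV. The reported uncertainty
#' combines the Poisson standard error with the instrument CV in
#' quadrature.
#'
#' @param scenario A [scenario_spec()].
#' @param analyzed_volume_mL Analyzed sample volume, mL (> 0).
#' @param stream Integer substream offset.
#' @return `data.frame`: `component`, `diameter_nm`, `detected`,
#'   `number_per_mL`, `u_number_per_mL`, `mass_mg_L`, `u_mass_mg_L`.
#' @export
simulate_spes_counts <- function(scenario, analyzed_volume_mL = 20,
                                 stream = 1L) {
  if (analyzed_volume_mL <= 0) stop("analyzed volume must be positive")
  withr::with_seed(scenario$seed + as.integer(stream), {
    rows <- lapply(scenario$components, function(cmp) {
      d <- cmp$particle$diameter
      detected <- d >= .spes_dmin && d <= .spes_dmax
      true_n <- mass_to_number_concentration(cmp$mass_concentration,
                                             cmp$particle)   # 1/mL
      if (!detected || true_n == 0) {
        n_hat <- 0; u_n <- 0
      } else {
        lambda <- true_n * analyzed_volume_mL
        count <- if (lambda < 2^30) stats::rpois(1, lambda)
                 else round(stats::rnorm(1, lambda, sqrt(lambda)))
        gain <- .noisy_draws(1, 1, scenario$cv_spes, scenario$noise)
        n_hat <- gain * count / analyzed_volume_mL
        u_n <- n_hat * sqrt(1 / max(count, 1) + (scenario$cv_spes / 100)^2)
      }
      data.frame(component = cmp$name, diameter_nm = d * 1e9,
                 detected = detected, number_per_mL = n_hat,
                 u_number_per_mL = u_n,
                 mass_mg_L = number_to_mass_concentration(n_hat, cmp$particle),
                 u_mass_mg_L = number_to_mass_concentration(u_n, cmp$particle),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Generate a full synthetic fractionation experiment
#'
#' Runs the deterministic sequential-fractionation model to obtain ground
#' truth, then generates TOC replicate streams and particle-counter
#' observations for the pre-spin sample, each pellet and the final
#' supernatant. Ground truth is stored alongside the observations so
#' recovery of the true composition can be tested end-to-end.
#'
#' @param mixture List of [suspension_component()]s.
#' @param runs List of [centrifuge_run()]s.
#' @param scenario A [scenario_spec()] (its `components` field is ignored;
#'   the mixture defines the truth).
#' @param analyzed_volume_mL Counter volume per fraction, mL.
#' @return List of class `fractionation_experiment`: `ground_truth` (the
#'   [simulate_sequential_fractionation()] table), `fractions` — a named
#'   list (pre-spin, pellets, final supernatant), each with `true_mg_L`
#'   (named per component), `toc_replicates`, `toc` (accepted TOC as a
#'   [meas()], uncertainty from the declared CVs), and `spes`.
#' @export
generate_fractionation_experiment <- function(mixture, runs, scenario,
                                              analyzed_volume_mL = 20) {
  truth <- simulate_sequential_fractionation(mixture, runs)
  stages <- unique(truth$stage)
  comp_names <- vapply(mixture, `[[`, character(1), "name")

  # Fraction compositions referred to the original volume: the untouched
  # mixture, each pellet, and the final supernatant.
  fractions <- list(pre = vapply(mixture, `[[`, numeric(1), "mass_concentration"))
  names(fractions$pre) <- comp_names
  for (s in stages) {
    sub <- truth[truth$stage == s, ]
    fractions[[paste0("pellet_", s)]] <- stats::setNames(sub$pellet_mg_L, sub$component)
  }
  last <- truth[truth$stage == stages[length(stages)], ]
  fractions$supernatant <- stats::setNames(last$supernatant_mg_L, last$component)

  # Pellets are redispersed in clean water: no matrix background there.
  has_background <- c(TRUE, rep(FALSE, length(stages)), TRUE)

  out <- vector("list", length(fractions))
  names(out) <- names(fractions)
  for (i in seq_along(fractions)) {
    conc <- fractions[[i]]
    comps <- lapply(seq_along(mixture), function(j)
      suspension_component(mixture[[j]]$particle, conc[[j]],
                           name = comp_names[j]))
    sc <- scenario
    sc$components <- comps
    if (!has_background[i]) { sc$doc_background <- 0; sc$tic_background <- 0 }
    reps <- simulate_toc_replicates(sc, stream = 10L + i)
    red <- reduce_replicate_table(reps, cv_threshold = 2)
    toc_val <- red$TOC[1]
    # Type-B uncertainty from the declared instrument CVs (mean of 2 reps).
    u_toc <- sqrt((sc$cv_tc / 100 * red$TC[1])^2 / 2 +
                    (sc$cv_tic / 100 * red$TIC[1])^2 / 2)
    out[[i]] <- list(
      true_mg_L = conc,
      toc_replicates = reps,
      toc = meas(toc_val, u_toc),
      spes = simulate_spes_counts(sc, analyzed_volume_mL, stream = 100L + i)
    )
  }
  structure(list(ground_truth = truth, fractions = out,
                 scenario = scenario),
            class = "fractionation_experiment")
}

#' Read a scenario from YAML
#'
#' Expected top-level keys mirror [scenario_spec()] arguments; components
#' are given as a list of maps with `polymer` (registry name),
#' `diameter_nm` and `mass_mg_L` (optional `density` overrides the registry
#' value).
#'
#' @param path YAML file path.
#' @param registry Material registry, default [polymer_registry()].
#' @return A [scenario_spec()].
#' @export
read_scenario_yaml <- function(path, registry = polymer_registry()) {
  y <- yaml::read_yaml(path)
  comps <- lapply(y$components, function(cm) {
    pol <- get_polymer(cm$polymer, registry)
    suspension_component(
      particle_spec(cm$diameter_nm, "nm",
                    density = if (is.null(cm$density)) NULL else cm$density,
                    polymer = pol),
      cm$mass_mg_L)
  })
  args <- y[setdiff(names(y), "components")]
  do.call(scenario_spec, c(list(components = comps), args))
}
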