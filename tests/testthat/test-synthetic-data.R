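ps_only_scenario <- function(conc = 5, d_nm = 500, cv_tc = 2, cv_tic = 2,
                             seed = 1, ...) {
  scenario_spec(list(suspension_component(ps_particle(d_nm), conc)),
                doc_background = 0, tic_background = 0,
                cv_tc = cv_tc, cv_tic = cv_tic, seed = seed, ...)
}

test_that("noiseless stirred scenario reproduces the exact carbon content", {
  sc <- ps_only_scenario(cv_tc = 0, cv_tic = 0)
  reps <- simulate_toc_replicates(sc)
  tc <- reps$value_mg_L[reps$channel == "TC"]
  expect_equal(tc, rep(5 * ps$carbon_fraction, 3), tolerance = 1e-12)
  expect_equal(reps$value_mg_L[reps$channel == "TIC"], rep(0, 3))
})

test_that("identical seeds give bit-identical streams, new seeds differ", {
  sc <- ps_only_scenario(seed = 123)
  expect_identical(simulate_toc_replicates(sc), simulate_toc_replicates(sc))
  expect_identical(simulate_spes_counts(sc, 20), simulate_spes_counts(sc, 20))
  sc2 <- ps_only_scenario(seed = 124)
  expect_false(identical(simulate_toc_replicates(sc),
                         simulate_toc_replicates(sc2)))
  # substreams decouple draws within one scenario
  expect_false(identical(simulate_toc_replicates(sc, stream = 0),
                         simulate_toc_replicates(sc, stream = 1)))
})

test_that("unstirred large particles are lost in the syringe dead time", {
  # 90 um PS settles ~1.32 cm/min; a 2 min dead time empties a 2 cm intake
  sc_lost <- ps_only_scenario(d_nm = 90e3, cv_tc = 0, cv_tic = 0)
  sc_lost$stirred <- FALSE
  sc_lost$dead_time_s <- 120
  sc_lost$intake_height_cm <- 2
  expect_equal(scenario_true_channels(sc_lost)[["TC"]], 0)
  # stirring restores the full contribution
  sc_stirred <- ps_only_scenario(d_nm = 90e3, cv_tc = 0, cv_tic = 0)
  expect_equal(scenario_true_channels(sc_stirred)[["TC"]],
               5 * ps$carbon_fraction)
  # colloidal particles are essentially unaffected
  sc_small <- ps_only_scenario(d_nm = 500, cv_tc = 0, cv_tic = 0)
  sc_small$stirred <- FALSE; sc_small$dead_time_s <- 120
  expect_equal(scenario_true_channels(sc_small)[["TC"]],
               5 * ps$carbon_fraction, tolerance = 1e-4)
})

test_that("the counter sees only its 250 nm - 5 um window, with Poisson error", {
  mix <- equimassic_mixture()
  sc <- scenario_spec(mix, cv_spes = 0, seed = 5)
  spes <- simulate_spes_counts(sc, analyzed_volume_mL = 20)
  expect_false(spes$detected[spes$component == "PS 200 nm"])
  expect_equal(spes$number_per_mL[spes$component == "PS 200 nm"], 0)
  expect_true(all(spes$detected[spes$component %in% c("PS 500 nm", "PS 1000 nm")]))
  # Poisson relative SE ~ 1/sqrt(count)
  for (d in c("PS 500 nm", "PS 1000 nm")) {
    row <- spes[spes$component == d, ]
    count <- row$number_per_mL * 20
    expect_equal(row$u_number_per_mL / row$number_per_mL, 1 / sqrt(count),
                 tolerance = 1e-6)
  }
  # zero concentration yields zero counts
  sc0 <- scenario_spec(list(suspension_component(ps_particle(500), 0)), seed = 2)
  expect_equal(simulate_spes_counts(sc0, 20)$number_per_mL, 0)
})

test_that("full synthetic experiments carry ground truth and observations", {
  mix <- equimassic_mixture()
  runs <- list(study_c1(), study_c2())
  sc <- scenario_spec(mix, cv_tc = 0, cv_tic = 0, cv_spes = 0,
                      doc_background = 0, seed = 9)
  exp0 <- generate_fractionation_experiment(mix, runs, sc)
  expect_named(exp0$fractions, c("pre", "pellet_F1", "pellet_F2", "supernatant"))
  # noiseless: the pipeline estimate equals ground truth exactly
  for (fr in exp0$fractions) {
    est_total <- meas_value(mass_concentration_from_toc(fr$toc, ps))
    expect_equal(est_total, sum(fr$true_mg_L), tolerance = 1e-9)
    visible <- fr$spes[fr$spes$detected, ]
    expect_equal(visible$mass_mg_L,
                 unname(fr$true_mg_L[visible$component]), tolerance = 2e-2)
  }
  # determinism end to end
  expect_identical(generate_fractionation_experiment(mix, runs, sc)$fractions,
                   exp0$fractions)
})

test_that("pipeline estimates cover the truth within 3 combined sigma", {
  # parameter recovery across seeded scenarios: simulate TC/TIC replicates,
  # reduce them with the instrument rule, convert TOC to polymer mass, and
  # compare with the true concentration at 3 combined standard
  # uncertainties (type-B, from the declared CVs)
  true_conc <- 5
  hits <- vapply(seq_len(200), function(seed) {
    sc <- ps_only_scenario(conc = true_conc, cv_tc = 2, cv_tic = 2, seed = seed)
    sc$tic_background <- 0.5
    red <- reduce_replicate_table(simulate_toc_replicates(sc))
    u_toc <- sqrt((0.02 * red$TC)^2 / 2 + (0.02 * red$TIC)^2 / 2)
    est <- mass_concentration_from_toc(meas(red$TOC, u_toc), ps)
    abs(meas_value(est) - true_conc) <= 3 * meas_u(est)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("seeded subtraction-estimator study is unbiased and covers truth", {
  mix <- equimassic_mixture()
  runs <- list(study_c1(), study_c2())
  recoveries <- vapply(seq_len(100), function(seed) {
    sc <- scenario_spec(mix, doc_background = 0, cv_tc = 7, cv_tic = 0,
                        cv_spes = 10, seed = 1000 + seed)
    pre <- generate_fractionation_experiment(mix, runs, sc)$fractions$pre
    total <- mass_concentration_from_toc(pre$toc, ps)
    counted <- lapply(which(pre$spes$detected), function(i)
      meas(pre$spes$mass_mg_L[i], pre$spes$u_mass_mg_L[i]))
    subtraction_estimator(total, counted, nominal = 5)$recovery$value
  }, numeric(1))
  # unbiasedness at the Monte-Carlo resolution
  se <- sd(recoveries) / sqrt(length(recoveries))
  expect_lt(abs(mean(recoveries) - 100), 3 * se)
  # the distribution straddles the truth and has the expected noise scale
  expect_gt(mean(recoveries >= 100), 0.2)
  expect_lt(mean(recoveries >= 100), 0.8)
  expect_equal(sd(recoveries), 25, tolerance = 0.4)
})

test_that("scenarios round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "components:",
    "  - {polymer: PS, diameter_nm: 500, mass_mg_L: 5}",
    "  - {polymer: PS, diameter_nm: 1000, mass_mg_L: 5}",
    "doc_background: 0.2",
    "cv_tc: 7",
    "seed: 11"
  ), path)
  sc <- read_scenario_yaml(path, reg)
  expect_s3_class(sc, "scenario_spec")
  expect_length(sc$components, 2)
  expect_equal(sc$doc_background, 0.2)
  expect_equal(sc$cv_tc, 7)
  expect_equal(sc$seed, 11L)
  expect_equal(sc$components[[2]]$particle$diameter, 1e-6)
})
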