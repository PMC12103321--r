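test_that("TOC converts to polymer mass via the carbon fraction", {
  expect_equal(mass_concentration_from_toc(0.9226, ps), 1.000, tolerance = 1e-4)
  expect_equal(mass_concentration_from_toc(4.613, ps), 5.0, tolerance = 1e-4)
  pure_c <- polymer_spec("graphite", "C")
  expect_equal(mass_concentration_from_toc(1.0, pure_c), 1.0)
  m <- mass_concentration_from_toc(meas(0.9226, 0.09226), ps)
  expect_equal(meas_value(m), 1, tolerance = 1e-4)
  expect_equal(meas_u(m) / meas_value(m), 0.1, tolerance = 1e-12)
})

test_that("spike designs sum carbon equivalents over components", {
  expect_equal(spike_equivalent_carbon(spike_design(list(ps, ps), c(1, 1))),
               1.8452, tolerance = 1e-4)
  expect_equal(spike_equivalent_carbon(spike_design(list(), numeric(0))), 0)
  cell <- reg$cellulose
  expect_equal(spike_equivalent_carbon(spike_design(list(cell), 2)),
               2 * cell$carbon_fraction)
  expect_equal(spike_equivalent_carbon(spike_design(list(cell), 2)),
               0.889, tolerance = 1e-3)
})

test_that("spiked-water recoveries reproduce the tabulated percentages", {
  lake <- recovery(meas(1.637, 0.131), meas(1.712, 0.014))
  expect_equal(recovery_display(lake), 96)
  expect_equal(round(lake$u), 8)
  vario <- recovery(meas(0.577, 0.265), meas(0.830, 0.004))
  expect_equal(recovery_display(vario), 70)
  expect_equal(round(vario$u), 32)
  perfect <- recovery(meas(1, 0), meas(1, 0))
  expect_equal(perfect$value, 100)
  expect_equal(perfect$u, 0)
  expect_error(recovery(1, 0), "positive")
})

test_that("recoveries are scale invariant", {
  a <- recovery(meas(1.2, 0.1), meas(1.5, 0.05))
  b <- recovery(meas(1.2 * 7, 0.1 * 7), meas(1.5 * 7, 0.05 * 7))
  expect_equal(a$value, b$value, tolerance = 1e-12)
  expect_equal(a$u, b$u, tolerance = 1e-12)
})

test_that("background subtraction is a quadrature difference with flags", {
  net <- background_subtract(meas(2.509, 0.1), meas(0.872, 0.05))
  expect_equal(meas_value(net), 1.637, tolerance = 1e-12)
  expect_equal(meas_u(net), sqrt(0.1^2 + 0.05^2), tolerance = 1e-12)
  expect_equal(meas_value(background_subtract(meas(3, 0.2), 0)), 3)
  expect_warning(neg <- background_subtract(meas(0.5, 0.1), meas(0.8, 0.1)),
                 "negative")
  expect_equal(meas_value(neg), -0.3)
  expect_true(attr(neg, "negative"))
})

test_that("quadrature propagation matches a Monte-Carlo oracle", {
  # 1e5-draw normal propagation for the tabulated ratio and difference
  withr::with_seed(7, {
    n <- 1e5
    cases <- list(list(m = c(1.637, 0.131), e = c(1.712, 0.014)),
                  list(m = c(0.788, 0.223), e = c(0.830, 0.004)),
                  list(m = c(0.577, 0.265), e = c(0.830, 0.004)))
    for (cs in cases) {
      draws <- 100 * rnorm(n, cs$m[1], cs$m[2]) / rnorm(n, cs$e[1], cs$e[2])
      mc_u <- sd(draws)
      r <- recovery(meas(cs$m[1], cs$m[2]), meas(cs$e[1], cs$e[2]))
      expect_equal(r$u, mc_u, tolerance = 0.05)
      diff_draws <- rnorm(n, cs$m[1], cs$m[2]) - rnorm(n, cs$e[1], cs$e[2])
      d <- as_meas(meas(cs$m[1], cs$m[2]) - meas(cs$e[1], cs$e[2]))
      expect_equal(meas_u(d), sd(diff_draws), tolerance = 0.05)
    }
  })
})

test_that("number/mass conversion is an exact cubic round trip", {
  p1000 <- particle_spec(1000, "nm", density = 1.05)
  expect_equal(number_to_mass_concentration(1, p1000), 5.50e-7,
               tolerance = 1e-3)
  n <- mass_to_number_concentration(5, p1000)
  expect_equal(number_to_mass_concentration(n, p1000), 5, tolerance = 1e-12)
  p2000 <- particle_spec(2000, "nm", density = 1.05)
  expect_equal(number_to_mass_concentration(1, p2000),
               8 * number_to_mass_concentration(1, p1000), tolerance = 1e-12)
})

test_that("subtraction estimator recovers the counter-blind component", {
  est <- subtraction_estimator(
    total_mass_conc = meas(0.983 * 15, 0.071 * 15),
    counted_components = list(meas(1.083 * 5, 0.102 * 5),
                              meas(1.050 * 5, 0.082 * 5)),
    nominal = 5)
  expect_equal(est$recovery$value, 81.5, tolerance = 4e-3)
  # no counted components: recovery of the total itself
  solo <- subtraction_estimator(meas(4, 0.1), list(), nominal = 5)
  expect_equal(solo$recovery$value, 80)
  # exact cancellation
  zero <- subtraction_estimator(meas(10, 0), list(meas(6, 0), meas(4, 0)),
                                nominal = 5)
  expect_equal(meas_value(zero$residual), 0)
  expect_warning(subtraction_estimator(meas(5, 0), list(meas(6, 0)), nominal = 5),
                 "negative")
})

test_that("subtraction estimator is linear in its inputs", {
  est1 <- subtraction_estimator(meas(14.745, 1), list(meas(5.4, 0.5)), nominal = 5)
  est2 <- subtraction_estimator(meas(2 * 14.745, 2), list(meas(2 * 5.4, 1)),
                                nominal = 2 * 5)
  expect_equal(2 * meas_value(est1$residual), meas_value(est2$residual),
               tolerance = 1e-12)
  expect_equal(est1$recovery$value, est2$recovery$value, tolerance = 1e-12)
})

test_that("linear and quadrature rules share central values", {
  q <- subtraction_estimator(meas(14.745, 1.065),
                             list(meas(5.415, 0.51), meas(5.25, 0.41)),
                             nominal = 5, rule = "quadrature")
  l <- subtraction_estimator(meas(14.745, 1.065),
                             list(meas(5.415, 0.51), meas(5.25, 0.41)),
                             nominal = 5, rule = "linear")
  expect_equal(q$recovery$value, l$recovery$value)
  expect_gt(l$recovery$u, q$recovery$u)   # linear addition is more pessimistic
})

test_that("AF4 recoveries compute absolute, relative and the ISO flag", {
  full <- af4_recovery(c(F1 = 50, F2 = 100), injected_mass = 150)
  expect_equal(full$absolute_pct[full$fraction == "total"], 100)
  expect_true(attr(full, "iso_compliant")[["absolute"]])

  r <- af4_recovery(c(30, 100), injected_mass = 150,
                    no_crossflow_reference_mass = 125)
  expect_equal(r$absolute_pct[1:2], c(20, 100 * 100 / 150), tolerance = 1e-9)
  expect_equal(r$relative_pct[1:2], c(24, 80))
  expect_equal(r$relative_pct[r$fraction == "total"], 104)

  zero <- af4_recovery(c(F1 = 0, F2 = 0), injected_mass = 150)
  expect_equal(zero$absolute_pct[zero$fraction == "total"], 0)
  expect_false(attr(zero, "iso_compliant")[["absolute"]])

  expect_error(af4_recovery(c(1, 2), injected_mass = 0), "positive")
  expect_error(af4_recovery(c(1, 2), 10, no_crossflow_reference_mass = 0),
               "reference")
})

test_that("filtration recovery wraps the ratio with propagation", {
  expect_equal(filtration_recovery(1, 1)$value, 100)
  expect_equal(filtration_recovery(0.99, 1.00)$value, 99.0)
  expect_equal(recovery_display(filtration_recovery(meas(0.577, 0.265),
                                                    meas(0.830, 0.004))), 70)
})
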