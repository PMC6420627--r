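test_that("step_volume matches hand geometry and scales as expected", {
  s <- unit_syringe()            # area exactly 100 mm^2
  p <- pump_config()             # 200 steps/rev, 1 mm lead, 1:1
  expect_equal(step_volume(s, p), 0.5)   # 100 mm^2 * 1/200 mm
  # published-style rounded diameter agrees to printed precision
  s2 <- syringe_spec(11.2838, 5000, 51)
  expect_equal(step_volume(s2, p), 0.5, tolerance = 1e-5)
  # proportionality: gear 2 halves, doubling steps/rev halves
  expect_equal(step_volume(s, pump_config(gear_ratio = 2)), 0.25)
  expect_equal(step_volume(s, pump_config(steps_per_revolution = 400)), 0.25)
  expect_error(syringe_spec(-1, 100, 10), class = "fl_invalid_config")
  # capacity consistency: 5000 uL cannot come out of a tiny barrel
  expect_error(syringe_spec(2, 5000, 10), class = "fl_invalid_config")
})

test_that("step_volume is monotone in each geometry parameter", {
  set.seed(11)
  for (i in 1:20) {
    d <- runif(1, 3, 20); lead <- runif(1, 0.5, 3)
    gear <- runif(1, 0.5, 5); spr <- sample(50:400, 1)
    s <- syringe_spec(d, 10, 51)
    base <- step_volume(s, pump_config(spr, lead, gear))
    expect_gt(step_volume(syringe_spec(d * 1.1, 10, 51),
                          pump_config(spr, lead, gear)), base)
    expect_gt(step_volume(s, pump_config(spr, lead * 1.1, gear)), base)
    expect_lt(step_volume(s, pump_config(spr, lead, gear * 1.1)), base)
    expect_lt(step_volume(s, pump_config(spr * 2, lead, gear)), base)
  }
})

test_that("volume/step conversion rounds half to even and inverts", {
  s <- unit_syringe(); p <- pump_config()
  expect_identical(volume_to_steps(0, s, p), 0L)
  expect_identical(volume_to_steps(100, s, p), 200L)
  expect_identical(volume_to_steps(100.2, s, p), 200L)
  expect_equal(steps_to_volume(0, s, p), 0)
  expect_equal(steps_to_volume(200, s, p), 100)
  expect_error(volume_to_steps(-1, s, p), class = "fl_invalid_argument")
  expect_error(volume_to_steps(6000, s, p), class = "fl_capacity_error")
  expect_error(steps_to_volume(-1, s, p), class = "fl_invalid_argument")
})

test_that("round trip error is at most half a step volume", {
  s <- unit_syringe(); p <- pump_config()
  vs <- step_volume(s, p)
  set.seed(5)
  v <- runif(200, 0, s$capacity)
  back <- vapply(v, function(x) steps_to_volume(volume_to_steps(x, s, p), s, p),
                 numeric(1))
  expect_true(all(abs(back - v) <= vs / 2 + 1e-9))
})

test_that("flow rate converts to step period", {
  s <- unit_syringe(); p <- pump_config()
  expect_equal(flow_rate_to_step_period(300, s, p), 100)  # 0.5 uL at 300 uL/min
  expect_equal(flow_rate_to_step_period(600, s, p), 50)   # doubling rate halves
  expect_error(flow_rate_to_step_period(0, s, p), class = "fl_invalid_argument")
  expect_error(flow_rate_to_step_period(-5, s, p), class = "fl_invalid_argument")
})

test_that("simulate_dispense: identity, quantization bound, determinism", {
  s <- unit_syringe(); p <- pump_config()
  ident <- dispense_error_model()
  expect_equal(simulate_dispense(500, s, p, ident), 500)
  # quantization-only bound for arbitrary nominals
  set.seed(3)
  for (v in runif(25, 0, 4000)) {
    m <- simulate_dispense(v, s, p, ident)
    expect_lte(abs(m - v), step_volume(s, p) / 2 + 1e-9)
    expect_identical(m, steps_to_volume(volume_to_steps(v, s, p), s, p))
  }
  m42 <- dispense_error_model(per_step_jitter_sd = 0.01,
                              diameter_tolerance = 0.02, seed = 42L)
  a <- simulate_dispense(300, s, p, m42, replicate = 7)
  b <- simulate_dispense(300, s, p, m42, replicate = 7)
  expect_identical(a, b)
  # different replicates draw different jitter
  expect_false(simulate_dispense(300, s, p, m42, replicate = 8) == a)
})

test_that("empirical jitter SD recovers the configured model within 10%", {
  s <- stock_syringes()[["5 mL"]]; p <- pump_config(address = 0)
  m <- dispense_error_model(per_step_jitter_sd = 0.01, seed = 9L)
  v <- vapply(1:1000, function(r) simulate_dispense(300, s, p, m, r), numeric(1))
  n_steps <- volume_to_steps(300, s, p)
  expected_sd <- 0.01 * step_volume(s, p) * sqrt(n_steps)
  expect_lt(abs(sd(v) - expected_sd) / expected_sd, 0.10)
})

test_that("backlash removes steps only on direction reversal", {
  s <- unit_syringe(); p <- pump_config()
  m <- dispense_error_model(backlash_steps = 4)
  expect_equal(simulate_dispense(100, s, p, m, reversed = FALSE), 100)
  expect_equal(simulate_dispense(100, s, p, m, reversed = TRUE),
               100 - 4 * 0.5)
})
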