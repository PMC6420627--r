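test_that("accuracy and precision match their definitions", {
  d <- data.frame(nominal_ul = 100, measured_ul = c(98, 102))
  expect_equal(dispense_accuracy(d), 0)
  expect_equal(dispense_precision(d), 100 * sqrt(8) / 100, tolerance = 1e-9)
  expect_equal(round(dispense_precision(d), 2), 2.83)

  d2 <- data.frame(nominal_ul = 100, measured_ul = c(95, 95, 95))
  expect_equal(dispense_accuracy(d2), -5)
  expect_equal(dispense_precision(d2), 0)

  d3 <- data.frame(nominal_ul = 100, measured_ul = 100)
  expect_equal(dispense_accuracy(d3), 0)
  expect_error(dispense_precision(d3), class = "fl_insufficient_replicates")

  mixed <- data.frame(nominal_ul = c(100, 200), measured_ul = c(100, 200))
  expect_error(dispense_accuracy(mixed), class = "fl_invalid_grouping")

  # scale invariance of the relative measures
  d10 <- data.frame(nominal_ul = 1000, measured_ul = c(980, 1020))
  expect_equal(dispense_precision(d10), dispense_precision(d))
  expect_equal(dispense_accuracy(d10), dispense_accuracy(d))
})

test_that("accuracy/precision agree with a brute-force recomputation", {
  set.seed(8)
  d <- data.frame(nominal_ul = 300,
                  measured_ul = 300 + rnorm(50, 1.5, 4))
  err <- d$measured_ul - 300
  acc_bf <- 100 * sum(err) / length(err) / 300
  prec_bf <- 100 * sqrt(sum((err - mean(err))^2) / (length(err) - 1)) / 300
  expect_equal(dispense_accuracy(d), acc_bf)
  expect_equal(dispense_precision(d), prec_bf)
})

test_that("fit_calibration recovers a 1.05 volume scale within 1%", {
  s <- stock_syringes()[["5 mL"]]; p <- pump_config(address = 0)
  ident <- dispense_error_model()
  set.seed(21)
  rows <- lapply(rep(c(100, 300, 500), each = 10), function(nom) {
    base <- simulate_dispense(nom, s, p, ident)   # quantized nominal
    data.frame(nominal_ul = nom,
               measured_ul = 1.05 * base + rnorm(1, 0, 0.002 * nom))
  })
  meas <- do.call(rbind, rows)                    # 30 measurements
  f <- fit_calibration(meas)
  expect_lt(abs(f - 1.05) / 1.05, 0.01)
  # identity model: factor 1 up to quantization
  meas0 <- do.call(rbind, lapply(c(100, 300, 500), function(nom)
    data.frame(nominal_ul = nom,
               measured_ul = simulate_dispense(nom, s, p, ident))))
  expect_equal(fit_calibration(meas0), 1, tolerance = 1e-3)
  # applying the correction then refitting is idempotent
  meas$measured_ul <- meas$measured_ul / f
  expect_equal(fit_calibration(meas), 1, tolerance = 1e-3)
  expect_error(fit_calibration(data.frame(nominal_ul = c(100, 100),
                                          measured_ul = c(99, 101))),
               class = "fl_invalid_design")
})

test_that("fit_calibration recovers the simulator's own diameter scale", {
  s <- stock_syringes()[["5 mL"]]; p <- pump_config(address = 0)
  m <- dispense_error_model(diameter_tolerance = 0.05, seed = 3L)
  meas <- do.call(rbind, lapply(c(100, 300, 500), function(nom)
    data.frame(nominal_ul = nom, measured_ul = vapply(1:10, function(r)
      simulate_dispense(nom, s, p, m, r), numeric(1)))))
  truth <- fluidloop:::pump_volume_scale(m, p)
  expect_lt(abs(fit_calibration(meas) - truth) / truth, 0.01)
})

test_that("characterize passes the 5% bound with the calibrated model", {
  rep <- characterize(seed = 42)
  expect_identical(nrow(rep$conditions), 12L)
  expect_true(all(rep$conditions$n == 10))
  expect_true(rep$pass)
  expect_lte(rep$worst, 5)
  # worst agrees with recomputation from the raw measurement table
  worst_bf <- max(vapply(seq_len(nrow(rep$conditions)), function(i) {
    sub <- rep$measurements[
      rep$measurements$syringe == rep$conditions$syringe[i] &
      rep$measurements$nominal_ul == rep$conditions$nominal_ul[i], ]
    max(abs(dispense_accuracy(sub)), dispense_precision(sub))
  }, numeric(1)))
  expect_equal(rep$worst, worst_bf)
})

test_that("a grossly out-of-tolerance pump fails characterization", {
  bad <- dispense_error_model(per_step_jitter_sd = 0.003,
                              diameter_tolerance = 0.10, seed = 1L)
  rep <- characterize(model = bad)
  expect_false(rep$pass)   # 10% diameter tolerance -> up to ~21% bias
  expect_error(characterize(plan = data.frame()), class = "fl_invalid_argument")
})

test_that("single-replicate conditions are flagged, not fatal", {
  plan <- data.frame(syringe = c("5 mL", "5 mL"), nominal_ul = c(100, 300),
                     n = c(1L, 5L))
  rep <- characterize(plan = plan)
  expect_identical(rep$conditions$flag[rep$conditions$nominal_ul == 100],
                   "insufficient replicates")
  expect_true(is.na(rep$conditions$precision_pct[1]))
})

test_that("measurement tables round-trip through CSV", {
  rep <- characterize(plan = data.frame(syringe = "1 mL", nominal_ul = 50,
                                        n = 3L))
  path <- tempfile(fileext = ".csv")
  write_measurements(rep$measurements, path)
  back <- read_measurements(path)
  expect_equal(back$measured_ul, rep$measurements$measured_ul)
})
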