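# scaled-down closed-loop fixture: 12 FOVs at 256 px, schedule such that
# the deciding (3rd-of-12) FOV crosses at 20 min
small_run <- function(schedule = c(rep(15, 2), rep(20, 2), rep(60, 8)),
                      duration = 60, protocol = NULL, n_pumps = 4,
                      fault_after = Inf, hooks = NULL, seed = 42) {
  exp <- generate_experiment(length(schedule), schedule, n_cells = 4,
                             size = 256, seed = seed)
  clk <- sim_clock()
  ch <- chamber_model(2000)
  bus <- demo_bus(n_pumps, clk, chamber = ch)
  if (is.finite(fault_after)) inject_bus_fault(bus, fault_after)
  protocol <- protocol %||% mitotic_fixation_protocol(chamber = ch)
  run <- new_run(acquisition_plan(n_fov = length(schedule)),
                 trigger_config(), protocol, experiment_source(exp), bus,
                 clk, hooks = hooks, duration = duration)
  list(run = run, exp = exp, clk = clk, bus = bus)
}

test_that("the closed loop reproduces the 35-min activation timeline", {
  fx <- small_run()
  run_experiment(fx$run)
  run <- fx$run
  expect_identical(run$phase, "DONE")
  expect_equal(run$event_time, 20)
  expect_equal(run$activation_time, 35)
  expect_equal(run$activation_time - run$event_time, 15)  # delay identity
  act <- run$log[run$log$action == "pumps_activated", ]
  expect_identical(nrow(act), 1L)
  expect_equal(act$time_min, 35)
  # live imaging continued through the 15-min delay
  expect_true(any(run$log$action == "acquire_live" & run$log$time_min == 30))
  # exactly one event per run
  expect_identical(sum(run$log$action == "event_detected"), 1L)
  # z-stack entries per FOV after fluidics
  expect_identical(sum(grepl("^zstack", run$log$action)), 12L)
  # notifications at the critical stages, in order
  expect_identical(run$notifications$stage[1], "event")
  expect_true(all(c("fluidics", "postfix") %in% run$notifications$stage))
})

test_that("no rounding means DONE without fluidics", {
  fx <- small_run(schedule = rep(Inf, 6), duration = 30)
  run_experiment(fx$run)
  expect_identical(fx$run$phase, "DONE")
  expect_true(is.na(fx$run$event_time))
  expect_false(any(fx$run$log$action == "pumps_activated"))
})

test_that("a bus fault during fixation fails the run and notifies", {
  stages <- character(0)
  hook <- function(stage, message, time) stages <<- c(stages, stage)
  fx <- small_run(fault_after = 10, hooks = list(hook))
  # the live phase sends no bus commands; the 11th protocol command fails
  run_experiment(fx$run)
  expect_identical(fx$run$phase, "FAILED")
  expect_true("failure" %in% stages)
  expect_true(any(fx$run$log$outcome == "failed"))
})

test_that("manual triggering mirrors the automatic event", {
  fx <- small_run(schedule = rep(Inf, 4), duration = 60)
  manual_trigger(fx$run, at = 42)
  run_experiment(fx$run)
  expect_equal(fx$run$event_time, 42)
  expect_equal(fx$run$activation_time, 57)    # delay still applies
  expect_identical(fx$run$phase, "DONE")
  expect_error(manual_trigger(fx$run, at = 50), class = "fl_invalid_state")

  # delay 0: fluidics starts at the manual trigger time itself
  exp <- generate_experiment(4, rep(Inf, 4), n_cells = 4, size = 256,
                             seed = 1)
  clk <- sim_clock()
  ch <- chamber_model(2000)
  bus <- demo_bus(4, clk, chamber = ch)
  run <- new_run(acquisition_plan(n_fov = 4),
                 trigger_config(post_trigger_delay = 0),
                 mitotic_fixation_protocol(chamber = ch),
                 experiment_source(exp), bus, clk, duration = 60)
  manual_trigger(run, at = 42)
  run_experiment(run)
  expect_equal(run$activation_time, 42)
  act <- run$log[run$log$action == "pumps_activated", ]
  expect_equal(act$time_min, 42)
})

test_that("TIFF replay reproduces the synthetic run exactly", {
  schedule <- c(10, 20, Inf, Inf)
  dir <- file.path(tempdir(), "fl_replay")
  exp <- generate_experiment(4, schedule, n_cells = 1, size = 128,
                             duration = 30, seed = 13, dir = dir)
  mk <- function(src) {
    clk <- sim_clock()
    ch <- chamber_model(2000)
    bus <- demo_bus(4, clk, chamber = ch)
    run <- new_run(acquisition_plan(n_fov = 4, frame_interval = 5),
                   trigger_config(), mitotic_fixation_protocol(chamber = ch),
                   src, bus, clk, duration = 30)
    run_experiment(run)
    run
  }
  live <- mk(experiment_source(exp))
  replay <- mk(tiff_source(dir))
  expect_identical(replay$phase, live$phase)
  expect_identical(replay$event_time, live$event_time)
  expect_identical(replay$activation_time, live$activation_time)
  expect_identical(replay$trigger_trace, live$trigger_trace)
  expect_identical(replay$log, live$log)
  unlink(dir, recursive = TRUE)
})

test_that("notification hooks never throw into the control loop", {
  bad_hook <- function(stage, message, time) stop("smtp down")
  rec <- notify(list(bad_hook), "event", "hello", 12)
  expect_false(rec$delivered)
  rec2 <- notify(NULL, "event", "log only", 1)
  expect_true(rec2$delivered)
})
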