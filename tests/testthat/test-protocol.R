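test_that("overflow loading delivers the full aliquot under plug flow", {
  ch <- chamber_model()
  expect_equal(overflow_dispense(100, 500, ch), 100)
  expect_equal(overflow_dispense(100, 60, ch), 60)
  expect_equal(overflow_dispense(100, 0, ch), 0)
  expect_error(overflow_dispense(-1, 10, ch), class = "fl_invalid_argument")
})

test_that("validation reports findings instead of throwing", {
  bus <- demo_bus(4)
  prot <- mitotic_fixation_protocol()
  expect_identical(validate_protocol(prot, bus), character(0))

  small <- demo_bus(1, syringe = stock_syringes()[["1 mL"]],
                    chamber = chamber_model(5000))
  over <- protocol("big stroke", list(
    protocol_step("INFUSE", pump = 0L, reagent = "x", volume = 2000,
                  rate = 500)), chamber_model(5000))
  f <- validate_protocol(over, small)
  expect_length(f, 1L)
  expect_match(f, "exceeds syringe capacity")
  expect_identical(validate_protocol(over, small, allow_split = TRUE),
                   character(0))

  ghost <- protocol("ghost pump", list(
    protocol_step("INFUSE", pump = 9L, reagent = "x", volume = 100,
                  rate = 500)))
  expect_match(validate_protocol(ghost, bus), "unknown pump 9")

  overfill <- protocol("overfill", list(
    protocol_step("INFUSE", pump = 0L, reagent = "x", volume = 900,
                  rate = 500),
    protocol_step("INFUSE", pump = 1L, reagent = "y", volume = 900,
                  rate = 500)), chamber_model(1000))
  expect_match(paste(validate_protocol(overfill, bus), collapse = " "),
               "overfill")
})

test_that("total_duration sums motion and incubation times", {
  motion <- protocol("motion only", list(
    protocol_step("INFUSE", pump = 0L, reagent = "x", volume = 500,
                  rate = 500)))
  expect_equal(total_duration(motion), 1)
  wash <- protocol("wash x3", list(
    protocol_step("WAIT", duration = 10, repeat_n = 3L)))
  expect_equal(total_duration(wash), 30)
})

test_that("the fixation/staining sequence incubates for 155 minutes", {
  prot <- mitotic_fixation_protocol()
  waits <- vapply(prot$steps, function(s)
    if (s$kind == "WAIT") s$duration * s$repeat_n else 0, numeric(1))
  expect_equal(sum(waits), 155)          # 15 + 3x10 + 30 + 60 + 2x10
  # motion time at the default high rate: 16 strokes of 500 uL at 6000 uL/min
  expect_equal(total_duration(prot), 155 + 16 * 500 / 6000)
  expect_equal(total_duration(prot), 155, tolerance = 0.01)
})

test_that("execution runs in order on the simulated clock", {
  clk <- sim_clock()
  ch <- chamber_model(2000)
  bus <- demo_bus(2, clk, syringe = unit_syringe(), chamber = ch)
  prot <- protocol("wait then infuse", list(
    protocol_step("WAIT", duration = 15),
    protocol_step("INFUSE", pump = 0L, reagent = "PFA", volume = 300,
                  rate = 600)), ch)
  log <- execute(prot, bus, clk)
  expect_identical(attr(log, "status"), "done")
  expect_equal(log$time_min[1], 15)
  expect_equal(log$time_min[2] - log$time_min[1], 0.5, tolerance = 1e-6)
  expect_true(!is.unsorted(log$time_min))
})

test_that("AWAIT_EVENT applies the post-trigger delay from the event time", {
  clk <- sim_clock()
  ch <- chamber_model(2000)
  bus <- demo_bus(2, clk, chamber = ch)
  prot <- protocol("await", list(
    protocol_step("AWAIT_EVENT", delay = 15),
    protocol_step("INFUSE", pump = 0L, reagent = "PFA", volume = 60,
                  rate = 6000)), ch)
  log <- execute(prot, bus, clk, event = list(time = 20))
  expect_equal(log$time_min[log$action == "AWAIT_EVENT"], 35)
  expect_error(execute(prot, demo_bus(2, sim_clock(), chamber = ch)),
               class = "fl_precondition_error")  # no event supplied
})

test_that("planner and executor agree on protocols without AWAIT_EVENT", {
  clk <- sim_clock()
  ch <- chamber_model(2000)
  bus <- demo_bus(2, clk, syringe = unit_syringe(), chamber = ch)
  prot <- wash_protocol(3, chamber = ch)
  log <- execute(prot, bus, clk)
  expect_equal(max(log$time_min), total_duration(prot))
})

test_that("volume is conserved per reagent through an execution", {
  clk <- sim_clock()
  ch <- chamber_model(800, residual_floor = 80)
  bus <- demo_bus(3, clk, chamber = ch)
  prot <- protocol("mix", list(
    protocol_step("INFUSE", pump = 0L, reagent = "PFA", volume = 500,
                  rate = 1000),
    protocol_step("EXTRACT", volume = 300, rate = 1000),
    protocol_step("INFUSE", pump = 1L, reagent = "PBS", volume = 300,
                  rate = 1000),
    protocol_step("EXTRACT", volume = 200, rate = 1000),
    protocol_step("INFUSE", pump = 2L, reagent = "stain", volume = 200,
                  rate = 1000)), ch)
  execute(prot, bus, clk)
  # spills over the chamber rim are tracked per reagent too
  fluidloop:::chamber_add(ch, "PBS", 1000)
  for (r in names(ch$infused)) {
    inf <- ch$infused[[r]]
    ext <- if (r %in% names(ch$extracted)) ch$extracted[[r]] else 0
    spill <- if (r %in% names(ch$spilled)) ch$spilled[[r]] else 0
    net <- if (r %in% names(ch$contents)) ch$contents[[r]] else 0
    expect_equal(inf - ext - spill, net, tolerance = 1e-9)
  }
  expect_lte(chamber_total(ch), ch$working_volume + 1e-9)
})

test_that("execution logs are deterministic", {
  run_once <- function() {
    clk <- sim_clock()
    ch <- chamber_model(2000)
    bus <- demo_bus(4, clk, chamber = ch)
    execute(mitotic_fixation_protocol(chamber = ch), bus, clk)
  }
  expect_identical(as.data.frame(run_once()), as.data.frame(run_once()))
})

test_that("a bus fault halts the run: done, failed, then skipped", {
  clk <- sim_clock()
  ch <- chamber_model(2000)
  bus <- demo_bus(2, clk, syringe = unit_syringe(), chamber = ch)
  prot <- wash_protocol(3, chamber = ch)
  seen <- list()
  hook <- function(stage, message, time)
    seen[[length(seen) + 1L]] <<- stage
  inject_bus_fault(bus, 3)   # wash 1 = 2 frames, wash 2 fails on its 2nd
  log <- execute(prot, bus, clk, hooks = list(hook))
  expect_identical(attr(log, "status"), "failed")
  infuses <- log[log$action == "INFUSE" | log$outcome != "done", ]
  expect_identical(log$outcome[log$step == 1], "done")
  expect_true("failed" %in% log$outcome[log$step == 3])
  expect_true(all(log$outcome[log$step > 3] == "skipped"))
  expect_identical(unlist(seen), "failure")
})

test_that("NOTIFY fires its hook exactly once per step, in order", {
  clk <- sim_clock()
  ch <- chamber_model(2000)
  bus <- demo_bus(1, clk, chamber = ch)
  msgs <- character(0)
  hook <- function(stage, message, time) msgs <<- c(msgs, message)
  prot <- protocol("notifier", list(
    protocol_step("NOTIFY", message = "one"),
    protocol_step("WAIT", duration = 1),
    protocol_step("NOTIFY", message = "two")), ch)
  execute(prot, bus, clk, hooks = list(hook))
  expect_identical(msgs, c("one", "two"))
})

test_that("protocols survive a JSON round trip", {
  prot <- mitotic_fixation_protocol(await_event = 15)
  path <- tempfile(fileext = ".json")
  write_protocol(prot, path)
  back <- read_protocol(path)
  expect_identical(back$name, prot$name)
  expect_equal(length(back$steps), length(prot$steps))
  expect_equal(total_duration(back), total_duration(prot))
  expect_equal(back$chamber$working_volume, prot$chamber$working_volume)
})

test_that("the shipped example protocol file loads and validates", {
  path <- system.file("extdata", "mitotic_fixation.json",
                      package = "fluidloop")
  prot <- read_protocol(path)
  expect_s3_class(prot, "fl_protocol")
  expect_identical(prot$steps[[1]]$kind, "AWAIT_EVENT")
  expect_identical(validate_protocol(prot, demo_bus(4)), character(0))
})
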