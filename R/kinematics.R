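#' Syringe geometry
#'
#' Describes a syringe mounted on a pump. The barrel cross-section together
#' with the drivetrain ([pump_config()]) fixes the volume moved per motor
#' step. Geometry must be self-consistent: the stated capacity may not
#' exceed cross-section area times plunger travel by more than 5%.
#'
#' @param inner_diameter Barrel inner diameter, mm.
#' @param capacity Usable volume, uL.
#' @param plunger_travel Usable plunger travel, mm.
#' @param label Free-text identifier (e.g. `"5 mL"`).
#' @return An object of class `fl_syringe`.
#' @export
#' @examples
#' syringe_spec(12.06, 5000, 44, "5 mL")
syringe_spec <- function(inner_diameter, capacity, plunger_travel, label = "") {
  fl_check(is_number(inner_diameter) && inner_diameter > 0,
           "inner_diameter must be > 0", "fl_invalid_config")
  fl_check(is_number(capacity) && capacity > 0,
           "capacity must be > 0", "fl_invalid_config")
  fl_check(is_number(plunger_travel) && plunger_travel > 0,
           "plunger_travel must be > 0", "fl_invalid_config")
  area <- pi * inner_diameter^2 / 4        # mm^2; 1 mm^3 == 1 uL
  geom_cap <- area * plunger_travel
  fl_check(capacity <= geom_cap * 1.05,
           sprintf(paste0("capacity %.1f uL inconsistent with geometry ",
                          "(area x travel = %.1f uL)"), capacity, geom_cap),
           "fl_invalid_config")
  structure(list(inner_diameter = inner_diameter, capacity = capacity,
                 plunger_travel = plunger_travel, label = label),
            class = "fl_syringe")
}

#' Pump drivetrain configuration
#'
#' Drivetrain constants converting motor steps to plunger displacement,
#' plus the pump's bus address (0--127; the bus supports exactly 128
#' units). The defaults (200 steps/rev, 1 mm lead, 1:1 gearing) are
#' generic stepper/lead-screw values, not measured hardware constants.
#'
#' @param steps_per_revolution Full motor steps per motor revolution.
#' @param lead_pitch Lead-screw advance per lead-screw revolution, mm/rev.
#' @param gear_ratio Motor revolutions per lead-screw revolution.
#' @param address Integer bus address in `[0, 127]`.
#' @return An object of class `fl_pump_config`.
#' @export
pump_config <- function(steps_per_revolution = 200, lead_pitch = 1,
                        gear_ratio = 1, address = 0L) {
  fl_check(is_number(steps_per_revolution) && steps_per_revolution >= 1,
           "steps_per_revolution must be >= 1", "fl_invalid_config")
  fl_check(is_number(lead_pitch) && lead_pitch > 0,
           "lead_pitch must be > 0", "fl_invalid_config")
  fl_check(is_number(gear_ratio) && gear_ratio > 0,
           "gear_ratio must be > 0", "fl_invalid_config")
  fl_check(is_number(address) && address == as.integer(address) &&
             address >= 0 && address <= 127,
           "address must be an integer in [0, 127]", "fl_address_error")
  structure(list(steps_per_revolution = steps_per_revolution,
                 lead_pitch = lead_pitch, gear_ratio = gear_ratio,
                 address = as.integer(address)),
            class = "fl_pump_config")
}

#' Stock syringe geometries
#'
#' Three disposable-syringe classes (1, 5 and 10 mL) with typical barrel
#' diameters, used as default calibration conditions.
#'
#' @return Named list of [syringe_spec()] objects.
#' @export
stock_syringes <- function() {
  list(
    "1 mL"  = syringe_spec(4.78, 1000, 57, "1 mL"),
    "5 mL"  = syringe_spec(12.06, 5000, 45, "5 mL"),
    "10 mL" = syringe_spec(14.50, 10000, 62, "10 mL")
  )
}

#' Volume dispensed per motor step
#'
#' `lead_pitch / (gear_ratio * steps_per_revolution) * pi * d^2 / 4`,
#' in uL (1 mm^3 = 1 uL). Strictly increasing in diameter and lead pitch,
#' strictly decreasing in gear ratio and steps per revolution.
#'
#' @param syringe A [syringe_spec()].
#' @param pump A [pump_config()].
#' @return Step volume in uL.
#' @export
#' @examples
#' s <- syringe_spec(11.2838, 5000, 51, "area-100")
#' step_volume(s, pump_config())  # 0.5 uL/step
step_volume <- function(syringe, pump) {
  fl_check(inherits(syringe, "fl_syringe") && inherits(pump, "fl_pump_config"),
           "expected fl_syringe and fl_pump_config", "fl_invalid_config")
  advance <- pump$lead_pitch / (pump$gear_ratio * pump$steps_per_revolution)
  advance * pi * syringe$inner_diameter^2 / 4
}

#' Convert a commanded volume to motor steps
#'
#' Rounds half to even so that quantization bias is symmetric across a
#' calibration series. The inverse contract holds:
#' `steps_to_volume(volume_to_steps(v))` differs from `v` by at most half
#' a step volume.
#'
#' @param volume Volume in uL; must lie in `[0, capacity]`.
#' @inheritParams step_volume
#' @return Integer step count.
#' @export
volume_to_steps <- function(volume, syringe, pump) {
  fl_check(is_number(volume) && volume >= 0, "volume must be >= 0")
  if (volume > syringe$capacity)
    fl_abort(sprintf("volume %.1f uL exceeds syringe capacity %.1f uL",
                     volume, syringe$capacity), "fl_capacity_error")
  # round() in R rounds half to even
  as.integer(round(volume / step_volume(syringe, pump)))
}

#' Convert motor steps back to volume
#'
#' @param steps Non-negative step count.
#' @inheritParams step_volume
#' @return Volume in uL.
#' @export
steps_to_volume <- function(steps, syringe, pump) {
  fl_check(is_number(steps) && steps >= 0, "steps must be >= 0")
  steps * step_volume(syringe, pump)
}

#' Step period for a target flow rate
#'
#' @param rate Flow rate in uL/min; must be positive.
#' @inheritParams step_volume
#' @return Milliseconds per step.
#' @export
#' @examples
#' s <- syringe_spec(11.2838, 5000, 51)
#' flow_rate_to_step_period(300, s, pump_config())  # 100 ms/step
flow_rate_to_step_period <- function(rate, syringe, pump) {
  fl_check(is_number(rate) && rate > 0, "rate must be > 0")
  60000 * step_volume(syringe, pump) / rate
}

#' Dispense error model
#'
#' Stochastic model of how a real pump deviates from the commanded volume.
#' Components, applied in this order: a per-pump barrel-diameter deviation
#' fixed at construction (drawn uniformly in `[-tol, +tol]` relative, so
#' the tolerance is a hard bound, as a manufacturing tolerance is); step
#' quantization (round-half-even); independent per-step volume jitter
#' (Gaussian, sd relative to one step volume); and a fixed step loss on
#' direction reversal (backlash). With all terms zero the model passes the
#' quantized nominal through unchanged.
#'
#' @param step_quantization Apply step rounding (default `TRUE`).
#' @param per_step_jitter_sd Relative sd of one step's volume (fraction).
#' @param diameter_tolerance Relative barrel-diameter tolerance (fraction).
#' @param backlash_steps Steps lost when the motor reverses direction.
#' @param seed Integer seed; fixes all draws of the model.
#' @return An object of class `fl_error_model`.
#' @export
dispense_error_model <- function(step_quantization = TRUE,
                                 per_step_jitter_sd = 0,
                                 diameter_tolerance = 0,
                                 backlash_steps = 0,
                                 seed = 1L) {
  fl_check(per_step_jitter_sd >= 0 && diameter_tolerance >= 0 &&
             backlash_steps >= 0, "relative error terms must be >= 0",
           "fl_invalid_config")
  structure(list(step_quantization = isTRUE(step_quantization),
                 per_step_jitter_sd = per_step_jitter_sd,
                 diameter_tolerance = diameter_tolerance,
                 backlash_steps = as.integer(backlash_steps),
                 seed = as.integer(seed)),
            class = "fl_error_model")
}

# Deterministic sub-seed, kept below 2^31. Mixes a base seed with stream
# ids so independent draws (per pump, per replicate) are reproducible.
fl_sub_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  h <- 0
  for (v in ids) h <- (h * 7919 + (as.numeric(v) %% 104729) + 1) %% 2147483629
  as.integer(h)
}

# Run `expr` under a local RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Per-pump true-to-nominal volume scale implied by the diameter tolerance.
# Fixed at "construction": depends only on model seed and pump address.
pump_volume_scale <- function(model, pump) {
  if (model$diameter_tolerance == 0) return(1)
  eps <- with_seed(fl_sub_seed(model$seed, 1299709, pump$address),
                   runif(1, -model$diameter_tolerance, model$diameter_tolerance))
  (1 + eps)^2
}

#' Simulate one dispense on an imperfect pump
#'
#' Stands in for weighing the dispensed volume on an analytical scale.
#' Deterministic for a fixed model seed, pump address and replicate index;
#' with the identity error model the result is exactly
#' `steps_to_volume(volume_to_steps(nominal))`.
#'
#' @param nominal Commanded volume, uL (within syringe capacity).
#' @inheritParams step_volume
#' @param model A [dispense_error_model()].
#' @param replicate Replicate index; selects the jitter stream.
#' @param reversed Did the motor reverse direction since the last move?
#'   If so, `backlash_steps` are lost.
#' @return Simulated measured volume, uL.
#' @export
simulate_dispense <- function(nominal, syringe, pump,
                              model = dispense_error_model(),
                              replicate = 1L, reversed = FALSE) {
  steps <- if (model$step_quantization) {
    volume_to_steps(nominal, syringe, pump)
  } else {
    fl_check(is_number(nominal) && nominal >= 0, "volume must be >= 0")
    if (nominal > syringe$capacity)
      fl_abort("volume exceeds syringe capacity", "fl_capacity_error")
    nominal / step_volume(syringe, pump)
  }
  if (isTRUE(reversed)) steps <- max(0, steps - model$backlash_steps)
  v_step <- step_volume(syringe, pump) * pump_volume_scale(model, pump)
  vol <- steps * v_step
  if (model$per_step_jitter_sd > 0 && steps > 0) {
    # sum of `steps` independent per-step jitters: sd scales with sqrt(n)
    jit <- with_seed(fl_sub_seed(model$seed, 104651, pump$address, replicate),
                     rnorm(1, 0, model$per_step_jitter_sd * v_step * sqrt(steps)))
    vol <- vol + jit
  }
  max(0, vol)
}
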