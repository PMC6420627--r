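#' In-memory simulated pump bus
#'
#' A flat bus with 128 addresses (0--127) for syringe pumps plus one
#' optional peristaltic extraction pump, driven entirely by a simulated
#' clock. Motion started by [dispatch()] progresses as the clock advances;
#' status queries are computed lazily from elapsed time, so nothing
#' sleeps. Every frame exchanged is recorded in a transcript.
#'
#' @param clock A [sim_clock()]; created if missing.
#' @return An environment of class `fl_bus`.
#' @export
sim_bus <- function(clock = sim_clock()) {
  bus <- new.env(parent = emptyenv())
  bus$clock <- clock
  bus$pumps <- new.env(parent = emptyenv())
  bus$peristaltic <- NULL
  bus$transcript <- list()
  bus$fail_after <- Inf        # fault injection: error after N commands
  bus$n_commands <- 0
  class(bus) <- "fl_bus"
  bus
}

#' Inject a transport fault
#'
#' After `n` further successfully dispatched command frames, the bus
#' raises a transport error on every subsequent command. Used to test the
#' halt-and-notify failure policy without hardware.
#'
#' @param bus An [sim_bus()].
#' @param after_n_commands Commands to allow before failing.
#' @export
inject_bus_fault <- function(bus, after_n_commands) {
  bus$fail_after <- bus$n_commands + after_n_commands
  invisible(bus)
}

bus_log <- function(bus, direction, text) {
  bus$transcript[[length(bus$transcript) + 1L]] <-
    list(time_min = bus$clock$now, direction = direction, frame = text)
  invisible(NULL)
}

#' Bus transcript as a data frame
#' @param bus An [sim_bus()].
#' @return Data frame with columns `time_min`, `direction`, `frame`.
#' @export
bus_transcript <- function(bus) {
  if (!length(bus$transcript))
    return(data.frame(time_min = numeric(), direction = character(),
                      frame = character()))
  do.call(rbind, lapply(bus$transcript, function(e)
    data.frame(time_min = e$time_min, direction = e$direction,
               frame = e$frame)))
}

#' Attach a syringe pump at an address
#'
#' @param bus An [sim_bus()].
#' @param address Integer address in `[0, 127]`; must be free.
#' @param syringe A [syringe_spec()].
#' @param config A [pump_config()]; its address field is overridden by
#'   `address`.
#' @export
attach_pump <- function(bus, address, syringe, config = pump_config()) {
  fl_check(inherits(bus, "fl_bus"), "not a bus")
  fl_check(is_number(address) && address == as.integer(address) &&
             address >= 0 && address <= 127,
           sprintf("address %s out of range [0, 127]", format(address)),
           "fl_address_error")
  key <- as.character(as.integer(address))
  if (!is.null(bus$pumps[[key]]))
    fl_abort(sprintf("address %d already occupied", as.integer(address)),
             "fl_conflict_error")
  config$address <- as.integer(address)
  p <- new.env(parent = emptyenv())
  p$syringe <- syringe
  p$config <- config
  p$volume_scale <- 1          # calibration correction, see fit_calibration()
  p$motion <- NULL
  p$dispensed_ul <- 0          # cumulative infused volume (simulated)
  bus$pumps[[key]] <- p
  invisible(bus)
}

#' Attach the peristaltic extraction pump
#'
#' A single roller pump that continuously withdraws fluid from the open
#' imaging chamber while switched on, keeping the chamber volume constant
#' during exchanges.
#'
#' @param bus An [sim_bus()].
#' @param rate Withdrawal rate, uL/min.
#' @param chamber Optional [chamber_model()] the pump drains.
#' @export
attach_extraction_pump <- function(bus, rate = 500, chamber = NULL) {
  fl_check(is_number(rate) && rate > 0, "rate must be > 0")
  e <- new.env(parent = emptyenv())
  e$rate <- rate
  e$on <- FALSE
  e$since <- NA_real_
  e$chamber <- chamber
  e$removed_ul <- 0
  bus$peristaltic <- e
  invisible(bus)
}

#' Enumerate attached pump addresses
#'
#' Probes every possible address with a STATUS frame and returns the ones
#' that acknowledge, sorted ascending.
#'
#' @param bus An [sim_bus()].
#' @return Integer vector of addresses (length <= 128).
#' @export
enumerate_pumps <- function(bus) {
  fl_check(inherits(bus, "fl_bus"), "not an open bus", "fl_bus_error")
  addrs <- sort(as.integer(ls(bus$pumps)))
  bus_log(bus, "tx", sprintf("PROBE -> %d pumps", length(addrs)))
  addrs
}

#' Build a command frame
#'
#' @param address Pump address, or `NA` for broadcast.
#' @param verb One of `INFUSE`, `WITHDRAW`, `STOP`, `STATUS`,
#'   `EXTRACT_ON`, `EXTRACT_OFF`.
#' @param steps Step count for motion verbs.
#' @param step_period_ms Milliseconds per step; required (> 0) for motion.
#' @param sequence_id Optional integer tag echoed in the transcript.
#' @return A list of class `fl_frame`.
#' @export
command_frame <- function(address, verb, steps = 0, step_period_ms = NA,
                          sequence_id = NA_integer_) {
  verbs <- c("INFUSE", "WITHDRAW", "STOP", "STATUS", "EXTRACT_ON", "EXTRACT_OFF")
  if (!(is.character(verb) && length(verb) == 1L && verb %in% verbs))
    fl_abort("malformed frame: unknown verb", "fl_protocol_error")
  if (!(is.numeric(steps) && length(steps) == 1L && steps >= 0))
    fl_abort("malformed frame: steps must be >= 0", "fl_protocol_error")
  motion <- verb %in% c("INFUSE", "WITHDRAW")
  if (motion && !(is_number(step_period_ms) && step_period_ms > 0))
    fl_abort("malformed frame: motion verbs need step_period_ms > 0",
             "fl_protocol_error")
  structure(list(address = address, verb = verb, steps = as.numeric(steps),
                 step_period_ms = step_period_ms, sequence_id = sequence_id),
            class = "fl_frame")
}

status_frame <- function(address, state, steps_remaining = 0,
                         error_code = NA_character_) {
  structure(list(address = address, state = state,
                 steps_remaining = steps_remaining, error_code = error_code),
            class = "fl_status")
}

# Lazily resolve a pump's motion against the clock.
pump_sync <- function(pump, now_min) {
  m <- pump$motion
  if (is.null(m)) return(invisible(NULL))
  elapsed_ms <- (now_min - m$start_min) * 60000
  done <- min(m$steps, floor(elapsed_ms / m$step_period_ms))
  m$steps_done <- done
  if (done >= m$steps) {
    if (m$verb == "INFUSE")
      pump$dispensed_ul <- pump$dispensed_ul +
        m$steps * step_volume(pump$syringe, pump$config)
    pump$motion <- NULL
  } else {
    pump$motion <- m
  }
  invisible(NULL)
}

# Integrate the peristaltic pump against the chamber since its last sync.
peristaltic_sync <- function(bus) {
  e <- bus$peristaltic
  if (is.null(e) || !e$on) return(invisible(NULL))
  dt <- bus$clock$now - e$since
  if (dt > 0) {
    vol <- e$rate * dt
    removed <- if (!is.null(e$chamber)) chamber_remove(e$chamber, vol) else vol
    e$removed_ul <- e$removed_ul + removed
    e$since <- bus$clock$now
  }
  invisible(NULL)
}

#' Dispatch a command frame to the bus
#'
#' Motion verbs start simulated motion that consumes
#' `steps * step_period_ms` of simulated time; a second motion command to
#' a pump that is still MOVING is rejected with a busy error (queueing is
#' the protocol engine's job). `STOP` halts immediately and keeps the
#' partial step count; `STATUS` is side-effect-free.
#'
#' @param bus An [sim_bus()].
#' @param frame A [command_frame()].
#' @return A status frame (list with `address`, `state`, `steps_remaining`,
#'   `error_code`).
#' @export
dispatch <- function(bus, frame) {
  fl_check(inherits(bus, "fl_bus"), "not a bus")
  if (!inherits(frame, "fl_frame"))
    fl_abort("malformed frame", "fl_protocol_error")
  bus$n_commands <- bus$n_commands + 1
  if (bus$n_commands > bus$fail_after)
    fl_abort("bus transport failure (injected fault)", "fl_bus_error")
  bus_log(bus, "tx", sprintf("%s addr=%s steps=%g period=%s",
                             frame$verb, format(frame$address),
                             frame$steps, format(frame$step_period_ms)))
  now <- bus$clock$now

  if (frame$verb %in% c("EXTRACT_ON", "EXTRACT_OFF"))
    return(extraction_pump(bus, frame$verb == "EXTRACT_ON"))

  key <- as.character(as.integer(frame$address))
  pump <- bus$pumps[[key]]
  if (is.null(pump))
    fl_abort(sprintf("no acknowledge from address %s", format(frame$address)),
             "fl_no_ack")
  pump_sync(pump, now)

  if (frame$verb == "STATUS") {
    m <- pump$motion
    st <- if (is.null(m)) status_frame(frame$address, "IDLE", 0)
          else status_frame(frame$address, "MOVING", m$steps - m$steps_done)
    bus_log(bus, "rx", sprintf("STATUS addr=%s state=%s remaining=%g",
                               format(frame$address), st$state,
                               st$steps_remaining))
    return(st)
  }
  if (frame$verb == "STOP") {
    m <- pump$motion
    if (!is.null(m)) {
      if (m$verb == "INFUSE")
        pump$dispensed_ul <- pump$dispensed_ul +
          m$steps_done * step_volume(pump$syringe, pump$config)
      pump$last_partial <- m$steps_done
      pump$motion <- NULL
    }
    return(status_frame(frame$address, "IDLE", 0))
  }
  # INFUSE / WITHDRAW
  if (!is.null(pump$motion))
    fl_abort(sprintf("pump %s is busy", format(frame$address)), "fl_busy")
  pump$motion <- list(verb = frame$verb, steps = frame$steps,
                      step_period_ms = frame$step_period_ms,
                      start_min = now, steps_done = 0)
  status_frame(frame$address, "MOVING", frame$steps)
}

#' Switch the peristaltic extraction pump on or off
#'
#' Idempotent: repeating the current state is a no-op. While on, the pump
#' removes fluid from its chamber model at its configured rate as the
#' simulated clock advances.
#'
#' @param bus An [sim_bus()].
#' @param on Logical.
#' @return A status frame for the peristaltic unit.
#' @export
extraction_pump <- function(bus, on) {
  e <- bus$peristaltic
  if (is.null(e))
    fl_abort("no peristaltic extraction pump attached", "fl_no_ack")
  peristaltic_sync(bus)
  if (isTRUE(on) && !e$on) {
    e$on <- TRUE
    e$since <- bus$clock$now
  } else if (!isTRUE(on) && e$on) {
    e$on <- FALSE
    e$since <- NA_real_
  }
  status_frame("peristaltic", if (e$on) "MOVING" else "IDLE", 0)
}
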