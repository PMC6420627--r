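#' One step of a fluid-exchange protocol
#'
#' Step kinds and their required fields:
#' * `INFUSE` / `WITHDRAW` -- `pump`, `volume` (uL), `rate` (uL/min);
#'   `reagent` labels what is moved.
#' * `EXTRACT` -- `volume`, `rate`: run the peristaltic pump until
#'   `volume` uL have been withdrawn (bounded by the chamber's residual
#'   floor).
#' * `WAIT` -- `duration` minutes of incubation.
#' * `AWAIT_EVENT` -- block until the experiment-level event fires, then
#'   wait a further `delay` minutes before proceeding (default 15 min, the
#'   post-trigger delay that lets a rounding cell progress into mitosis
#'   before fixation).
#' * `NOTIFY` -- invoke the notification hook with `message`.
#'
#' @param kind Step kind, see above.
#' @param pump Pump address for motion kinds.
#' @param reagent Free-text reagent name.
#' @param volume Volume in uL (motion kinds).
#' @param rate Flow rate in uL/min (motion kinds).
#' @param duration Duration in minutes (`WAIT`).
#' @param repeat_n How many times to run the step (>= 1).
#' @param message Notification text (`NOTIFY`).
#' @param delay Post-event delay in minutes (`AWAIT_EVENT`).
#' @return A list of class `fl_step`.
#' @export
protocol_step <- function(kind, pump = NA_integer_, reagent = "",
                          volume = NA_real_, rate = NA_real_,
                          duration = NA_real_, repeat_n = 1L,
                          message = "", delay = 15) {
  kinds <- c("INFUSE", "WITHDRAW", "EXTRACT", "WAIT", "AWAIT_EVENT", "NOTIFY")
  fl_check(is.character(kind) && length(kind) == 1L && kind %in% kinds,
           "unknown step kind", "fl_protocol_error")
  fl_check(is_number(repeat_n) && repeat_n >= 1,
           "repeat_n must be >= 1", "fl_protocol_error")
  if (kind %in% c("INFUSE", "WITHDRAW")) {
    fl_check(is_number(pump) || (is_number(volume) && is_number(rate)),
             "motion steps need pump, volume and rate", "fl_protocol_error")
    fl_check(is_number(volume) && volume > 0 && is_number(rate) && rate > 0,
             "motion steps need volume > 0 and rate > 0", "fl_protocol_error")
    fl_check(is_number(pump), "motion steps need a pump address",
             "fl_protocol_error")
  }
  if (kind == "EXTRACT")
    fl_check(is_number(volume) && volume > 0 && is_number(rate) && rate > 0,
             "EXTRACT needs volume > 0 and rate > 0", "fl_protocol_error")
  if (kind == "WAIT")
    fl_check(is_number(duration) && duration > 0,
             "WAIT needs duration > 0", "fl_protocol_error")
  if (kind == "AWAIT_EVENT")
    fl_check(is_number(delay) && delay >= 0, "delay must be >= 0",
             "fl_protocol_error")
  structure(list(kind = kind, pump = as.integer(pump), reagent = reagent,
                 volume = volume, rate = rate, duration = duration,
                 repeat_n = as.integer(repeat_n), message = message,
                 delay = delay),
            class = "fl_step")
}

#' A named, ordered fluid-exchange protocol
#'
#' @param name Protocol name.
#' @param steps List of [protocol_step()]s; must be non-empty.
#' @param chamber A [chamber_model()] the protocol runs against.
#' @return A list of class `fl_protocol`.
#' @export
protocol <- function(name, steps, chamber = chamber_model()) {
  fl_check(is.list(steps) && length(steps) >= 1L &&
             all(vapply(steps, inherits, logical(1), "fl_step")),
           "steps must be a non-empty list of protocol_step objects",
           "fl_protocol_error")
  structure(list(name = name, steps = steps, chamber = chamber),
            class = "fl_protocol")
}

#' Validate a protocol against a bus
#'
#' Returns findings rather than throwing: an empty character vector means
#' the protocol is executable as-is. Checks that referenced pumps are
#' attached, per-stroke volumes fit the mounted syringe (unless
#' `allow_split`, in which case oversized strokes are executed as repeated
#' refill/infuse cycles), that an `EXTRACT` step has an extraction pump to
#' run on, and that the chamber bookkeeping never overfills.
#'
#' @param protocol A [protocol()].
#' @param bus An [sim_bus()], or `NULL` for structure-only checks.
#' @param allow_split Permit strokes larger than one syringe capacity.
#' @return Character vector of findings (empty if executable).
#' @export
validate_protocol <- function(protocol, bus = NULL, allow_split = FALSE) {
  fl_check(inherits(protocol, "fl_protocol"), "not a protocol",
           "fl_protocol_error")
  findings <- character(0)
  level <- chamber_total(protocol$chamber)
  floor_ul <- protocol$chamber$residual_floor
  for (i in seq_along(protocol$steps)) {
    s <- protocol$steps[[i]]
    tag <- sprintf("step %d (%s)", i, s$kind)
    if (s$kind %in% c("INFUSE", "WITHDRAW")) {
      if (!is.null(bus)) {
        p <- bus$pumps[[as.character(s$pump)]]
        if (is.null(p)) {
          findings <- c(findings, sprintf("%s: unknown pump %d", tag, s$pump))
          next
        }
        if (s$volume > p$syringe$capacity && !allow_split)
          findings <- c(findings, sprintf(
            "%s: stroke %.0f uL exceeds syringe capacity %.0f uL",
            tag, s$volume, p$syringe$capacity))
      }
      if (s$kind == "INFUSE") {
        level <- level + s$volume * s$repeat_n
        if (level > protocol$chamber$working_volume) {
          findings <- c(findings, sprintf(
            "%s: chamber would overfill (%.0f of %.0f uL); add an EXTRACT",
            tag, level, protocol$chamber$working_volume))
          level <- protocol$chamber$working_volume
        }
      } else {
        level <- max(floor_ul, level - s$volume * s$repeat_n)
      }
    } else if (s$kind == "EXTRACT") {
      if (!is.null(bus) && is.null(bus$peristaltic))
        findings <- c(findings, sprintf(
          "%s: no peristaltic extraction pump attached", tag))
      level <- max(floor_ul, level - s$volume * s$repeat_n)
    }
  }
  findings
}

#' Planned duration of a protocol
#'
#' Sum over steps of motion time (`volume / rate` minutes) plus `WAIT`
#' durations, each multiplied by its repeat count. `AWAIT_EVENT` steps are
#' unbounded and contribute zero; `NOTIFY` is instantaneous.
#'
#' @param protocol A [protocol()] that passes structural validation.
#' @return Duration in minutes.
#' @export
total_duration <- function(protocol) {
  fl_check(inherits(protocol, "fl_protocol"), "not a protocol",
           "fl_protocol_error")
  total <- 0
  for (s in protocol$steps) {
    per <- switch(s$kind,
      INFUSE = , WITHDRAW = , EXTRACT = s$volume / s$rate,
      WAIT = s$duration,
      0)
    if (!is.finite(per))
      fl_abort("protocol not executable: motion step without volume/rate",
               "fl_precondition_error")
    total <- total + per * s$repeat_n
  }
  total
}

log_entry <- function(time_min, step, action, pump = NA_integer_,
                      reagent = NA_character_, volume = NA_real_,
                      outcome = "done") {
  data.frame(time_min = time_min, step = step, action = action,
             pump = pump, reagent = reagent, volume_ul = volume,
             outcome = outcome, stringsAsFactors = FALSE)
}

#' Execute a protocol against a bus
#'
#' Runs steps strictly in order on the simulated clock. `INFUSE` adds its
#' reagent to the chamber (after step quantization), `EXTRACT` drains
#' mixed fluid through the peristaltic pump down to the residual floor,
#' `AWAIT_EVENT` blocks until the supplied event time and then applies the
#' step's post-trigger delay, and `NOTIFY` invokes the notification hook.
#' On a hardware error the failing step is logged as `failed`, all later
#' steps as `skipped`, the failure hook fires, and execution halts --
#' never silently continue over a suspect sample.
#'
#' @param protocol A [protocol()].
#' @param bus An [sim_bus()] with all referenced pumps attached.
#' @param clock The [sim_clock()] shared with the bus.
#' @param hooks Optional list of notification hooks, see [notify()].
#' @param event Optional event record `list(time = minutes)` consumed by
#'   `AWAIT_EVENT` steps; executing an `AWAIT_EVENT` without one is an
#'   error.
#' @return The execution log (data frame of class `fl_log`, one terminal
#'   entry per step occurrence) with attribute `status` = `"done"` or
#'   `"failed"`.
#' @export
execute <- function(protocol, bus, clock = bus$clock, hooks = NULL,
                    event = NULL) {
  findings <- validate_protocol(protocol, bus)
  fl_check(length(findings) == 0,
           paste0("protocol failed validation: ",
                  paste(findings, collapse = "; ")), "fl_precondition_error")
  has_await <- any(vapply(protocol$steps, function(s)
    s$kind == "AWAIT_EVENT", logical(1)))
  if (has_await)
    fl_check(!is.null(event) && is_number(event$time),
             "protocol contains AWAIT_EVENT but no event was supplied",
             "fl_precondition_error")
  ch <- protocol$chamber
  if (!is.null(bus$peristaltic)) bus$peristaltic$chamber <- ch
  entries <- list()
  add <- function(e) entries[[length(entries) + 1L]] <<- e
  failed <- FALSE

  occurrences <- list()
  for (i in seq_along(protocol$steps)) {
    s <- protocol$steps[[i]]
    for (r in seq_len(s$repeat_n))
      occurrences[[length(occurrences) + 1L]] <- list(i = i, s = s, r = r)
  }
  for (k in seq_along(occurrences)) {
    oc <- occurrences[[k]]
    s <- oc$s
    if (failed) {
      add(log_entry(clock$now, oc$i, s$kind, outcome = "skipped"))
      next
    }
    res <- tryCatch({
      switch(s$kind,
        INFUSE = , WITHDRAW = {
          p <- bus$pumps[[as.character(s$pump)]]
          vs <- step_volume(p$syringe, p$config) * p$volume_scale
          # per-stroke split for volumes beyond one syringe capacity
          remaining <- s$volume
          while (remaining > 1e-9) {
            stroke <- min(remaining, p$syringe$capacity)
            steps <- as.integer(round(stroke / vs))
            period <- 60000 * vs / s$rate
            dispatch(bus, command_frame(s$pump, s$kind, steps, period))
            clock$advance(steps * period / 60000)
            dispatch(bus, command_frame(s$pump, "STATUS"))
            moved <- steps * vs
            if (s$kind == "INFUSE") chamber_add(ch, s$reagent, moved)
            else chamber_remove(ch, moved)
            remaining <- remaining - stroke
          }
          add(log_entry(clock$now, oc$i, s$kind, s$pump, s$reagent, s$volume))
        },
        EXTRACT = {
          dispatch(bus, command_frame(NA, "EXTRACT_ON"))
          clock$advance(s$volume / s$rate)
          dispatch(bus, command_frame(NA, "EXTRACT_OFF"))
          add(log_entry(clock$now, oc$i, "EXTRACT", NA, "waste", s$volume))
        },
        WAIT = {
          clock$advance(s$duration)
          add(log_entry(clock$now, oc$i, "WAIT", volume = NA))
        },
        AWAIT_EVENT = {
          fl_check(!is.null(event) && is_number(event$time),
                   "AWAIT_EVENT step but no event supplied",
                   "fl_precondition_error")
          resume <- event$time + s$delay
          if (resume > clock$now) clock$set(resume)
          add(log_entry(clock$now, oc$i, "AWAIT_EVENT"))
        },
        NOTIFY = {
          notify(hooks, "protocol", s$message, clock$now)
          add(log_entry(clock$now, oc$i, "NOTIFY"))
        })
      TRUE
    }, fluidloop_error = function(e) {
      add(log_entry(clock$now, oc$i, s$kind, outcome = "failed"))
      notify(hooks, "failure",
             sprintf("step %d (%s) failed: %s", oc$i, s$kind,
                     conditionMessage(e)), clock$now)
      FALSE
    })
    if (!isTRUE(res)) failed <- TRUE
  }
  log <- do.call(rbind, entries)
  class(log) <- c("fl_log", class(log))
  attr(log, "status") <- if (failed) "failed" else "done"
  log
}

#' The unsupervised fixation/staining sequence
#'
#' The five-phase in-situ protocol executed once the rounding event fires:
#' fixation (4% PFA in PEM, 15 min), three 10-min PBS washes,
#' permeabilisation/blocking (30 min), phalloidin-AF647 + DAPI staining
#' (1 h) and two final 10-min PBS washes -- 155 min of incubation in
#' total, plus a small amount of pump motion time.
#'
#' @param pfa,pbs,block,stain Pump addresses holding each reagent.
#' @param volume Per-exchange volume, uL.
#' @param rate Dispense rate, uL/min (fast, so motion time is
#'   negligible next to incubations).
#' @param chamber A [chamber_model()].
#' @param await_event Prepend an `AWAIT_EVENT` step with the given delay
#'   (minutes); `NULL` to start immediately.
#' @return A [protocol()].
#' @export
mitotic_fixation_protocol <- function(pfa = 0L, pbs = 1L, block = 2L,
                                      stain = 3L, volume = 500, rate = 6000,
                                      chamber = chamber_model(),
                                      await_event = NULL) {
  rep_phase <- function(pump, reagent, incubate_min, n) {
    out <- list()
    for (i in seq_len(n)) {
      out <- c(out,
               list(protocol_step("EXTRACT", volume = volume, rate = rate),
                    protocol_step("INFUSE", pump = pump, reagent = reagent,
                                  volume = volume, rate = rate),
                    protocol_step("WAIT", duration = incubate_min)))
    }
    out
  }
  steps <- c(
    if (!is.null(await_event))
      list(protocol_step("AWAIT_EVENT", delay = await_event)),
    list(protocol_step("NOTIFY", message = "fixation starting")),
    rep_phase(pfa, "PFA 4% in PEM", 15, 1),
    rep_phase(pbs, "PBS 1X", 10, 3),
    rep_phase(block, "BSA 5% + Triton-X 0.05%", 30, 1),
    rep_phase(stain, "phalloidin-AF647 + DAPI", 60, 1),
    rep_phase(pbs, "PBS 1X", 10, 2),
    list(protocol_step("NOTIFY", message = "staining complete"))
  )
  protocol("mitotic fixation and staining", steps, chamber)
}

#' Read / write a protocol as JSON
#'
#' Versioned on-disk schema: `{"version": 1, "name": ..., "chamber":
#' {...}, "steps": [...]}`. Volumes are uL, rates uL/min, durations and
#' delays minutes.
#'
#' @param path File path.
#' @return `read_protocol()` returns a [protocol()].
#' @export
read_protocol <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  fl_check(identical(doc$version, 1L) || identical(doc$version, 1),
           "unsupported protocol schema version", "fl_protocol_error")
  ch <- do.call(chamber_model, doc$chamber %||% list())
  steps <- lapply(doc$steps, function(s) {
    do.call(protocol_step, c(list(kind = s$kind),
                             s[setdiff(names(s), "kind")]))
  })
  protocol(doc$name %||% "unnamed", steps, ch)
}

#' @rdname read_protocol
#' @param protocol A [protocol()].
#' @export
write_protocol <- function(protocol, path) {
  steps <- lapply(protocol$steps, function(s) {
    s <- unclass(s)
    s[!vapply(s, function(x) length(x) == 1 && is.na(x), logical(1))]
  })
  doc <- list(version = 1L, name = protocol$name,
              chamber = list(
                working_volume = protocol$chamber$working_volume,
                residual_floor = protocol$chamber$residual_floor,
                tubing_dead_volume = protocol$chamber$tubing_dead_volume),
              steps = steps)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an execution log as CSV
#' @param log An execution log from [execute()] or [run_experiment()].
#' @param path File path.
#' @export
write_log_csv <- function(log, path) {
  write.csv(as.data.frame(log), path, row.names = FALSE)
  invisible(path)
}
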