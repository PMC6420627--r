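#' Acquisition plan
#'
#' Live-phase cadence plus the post-fixation imaging plan. Defaults
#' reflect the published unsupervised experiment: tens of fields of view
#' imaged every 5 min live, and a post-fixation 3D z-stack of 30--40
#' planes spaced 0.5 um in four channels.
#'
#' @param n_fov Number of fields of view (>= 1).
#' @param frame_interval Live cadence, minutes.
#' @param live_channels Channels acquired live.
#' @param z_planes Post-fixation z planes.
#' @param z_spacing Plane spacing, um.
#' @param postfix_channels Post-fixation channels.
#' @return A list of class `fl_acq_plan`.
#' @export
acquisition_plan <- function(n_fov = 45, frame_interval = 5,
                             live_channels = c("GFP", "mCherry"),
                             z_planes = 35, z_spacing = 0.5,
                             postfix_channels = c("DAPI", "GFP", "mCherry",
                                                  "AF647")) {
  fl_check(is_number(n_fov) && n_fov >= 1, "n_fov must be >= 1",
           "fl_invalid_config")
  fl_check(is_number(frame_interval) && frame_interval > 0,
           "frame_interval must be > 0", "fl_invalid_config")
  fl_check(is_number(z_spacing) && z_spacing > 0, "z_spacing must be > 0",
           "fl_invalid_config")
  structure(list(n_fov = as.integer(n_fov), frame_interval = frame_interval,
                 live_channels = live_channels, z_planes = as.integer(z_planes),
                 z_spacing = z_spacing, postfix_channels = postfix_channels),
            class = "fl_acq_plan")
}

#' Send a notification through the registered hooks
#'
#' Pluggable transport for the e-mail-style notifications that keep an
#' absent user informed as the workflow reaches critical stages. Hooks
#' are plain functions `(stage, message, time)`; a failing hook is
#' recorded but never throws into the control loop. With no hooks the
#' record is still produced (log-only delivery).
#'
#' @param hooks List of hook functions (may be `NULL`).
#' @param stage Short stage tag, e.g. `"event"`, `"fluidics"`.
#' @param message Human-readable text.
#' @param time Simulated time, minutes.
#' @return One-row delivery record data frame.
#' @export
notify <- function(hooks, stage, message, time) {
  delivered <- TRUE
  for (h in hooks %||% list()) {
    ok <- tryCatch({ h(stage, message, time); TRUE },
                   error = function(e) FALSE)
    delivered <- delivered && ok
  }
  rec <- data.frame(time_min = time, stage = stage, message = message,
                    delivered = delivered)
  reg <- notification_register()
  reg$records[[length(reg$records) + 1L]] <- rec
  rec
}

# Session-level register so execute()/run() can collect what was sent.
notification_register <- local({
  reg <- new.env(parent = emptyenv())
  reg$records <- list()
  function() reg
})

notifications_since <- function(mark) {
  reg <- notification_register()
  recs <- reg$records
  if (length(recs) <= mark) return(data.frame(
    time_min = numeric(), stage = character(), message = character(),
    delivered = logical()))
  do.call(rbind, recs[(mark + 1L):length(recs)])
}

#' Set up an unsupervised live-to-fixed run
#'
#' Creates the mutable run handle for [run_experiment()]. The run starts
#' in phase `LIVE` and advances monotonically through `TRIGGERED_WAIT`,
#' `FLUIDICS`, `POSTFIX` to `DONE` (`FAILED` is reachable from anywhere).
#'
#' @param plan An [acquisition_plan()].
#' @param trigger_cfg A [trigger_config()].
#' @param protocol The fixation/staining [protocol()] to run on trigger.
#' @param image_source A frame source, see [experiment_source()].
#' @param bus An [sim_bus()] with the protocol's pumps attached.
#' @param clock The shared [sim_clock()].
#' @param hooks Notification hooks, see [notify()].
#' @param duration Live-phase horizon in minutes; if no event fires by
#'   then the run ends `DONE` without fluidics.
#' @return A run handle (environment of class `fl_run`).
#' @export
new_run <- function(plan, trigger_cfg, protocol, image_source, bus,
                    clock = bus$clock, hooks = NULL, duration = 60) {
  fl_check(inherits(plan, "fl_acq_plan") &&
             inherits(trigger_cfg, "fl_trigger_config") &&
             inherits(protocol, "fl_protocol"),
           "plan, trigger_cfg and protocol must be their respective types")
  findings <- validate_protocol(protocol, bus)
  fl_check(length(findings) == 0,
           paste0("protocol failed validation: ",
                  paste(findings, collapse = "; ")), "fl_precondition_error")
  run <- new.env(parent = emptyenv())
  run$plan <- plan
  run$cfg <- trigger_cfg
  run$protocol <- protocol
  run$source <- image_source
  run$bus <- bus
  run$clock <- clock
  run$hooks <- hooks
  run$duration <- duration
  run$phase <- "LIVE"
  run$states <- lapply(seq_len(plan$n_fov), fov_state)
  run$event_time <- NA_real_
  run$activation_time <- NA_real_
  run$manual_at <- NA_real_
  run$trigger_trace <- list()
  run$log <- list()
  class(run) <- "fl_run"
  run
}

run_log_add <- function(run, ...) {
  run$log[[length(run$log) + 1L]] <- log_entry(...)
  invisible(NULL)
}

#' Fire the rounding event by hand
#'
#' The human-in-the-loop variant: equivalent to the automatic event
#' firing at time `at` (default: now). The configured post-trigger delay
#' still applies. Only legal while the run is in phase `LIVE` and no
#' event has fired yet.
#'
#' @param run A run handle from [new_run()].
#' @param at Event time in minutes.
#' @export
manual_trigger <- function(run, at = run$clock$now) {
  fl_check(inherits(run, "fl_run"), "not a run handle")
  if (run$phase != "LIVE" || !is.na(run$event_time))
    fl_abort("manual trigger only allowed during LIVE before the event",
             "fl_invalid_state")
  fl_check(is_number(at) && at >= 0, "at must be >= 0")
  run$manual_at <- at
  invisible(run)
}

#' Execute the closed-loop live-to-fixed experiment
#'
#' The live loop acquires one frame per FOV per cadence, segments it,
#' updates the per-FOV trigger states and checks the experiment-level
#' event rule. When the event fires (automatically or via
#' [manual_trigger()]) the run keeps imaging through the post-trigger
#' delay, then executes the fluidics protocol at
#' `activation = event + delay`, performs the post-fixation z-stack plan
#' (logged, not rendered) and finishes. Protocol failure moves the run to
#' `FAILED` and sends a failure notification. Exactly one event can fire
#' per run.
#'
#' @param run A run handle from [new_run()].
#' @return The run handle, now carrying `$phase`, `$event_time`,
#'   `$activation_time`, `$log` (data frame), `$trigger_trace` (per-frame
#'   per-FOV data frame) and `$notifications`.
#' @export
run_experiment <- function(run) {
  fl_check(inherits(run, "fl_run") && run$phase == "LIVE",
           "run already executed", "fl_invalid_state")
  mark <- length(notification_register()$records)
  cfg <- run$cfg
  frame_times <- seq(0, run$duration, by = run$plan$frame_interval)
  fire <- function(t_event) {
    run$event_time <- t_event
    run$activation_time <- t_event + cfg$post_trigger_delay
    run$phase <- "TRIGGERED_WAIT"
    notify(run$hooks, "event",
           sprintf("rounding event at %.1f min; pumps at %.1f min",
                   t_event, run$activation_time), t_event)
    run_log_add(run, t_event, NA_integer_, "event_detected")
  }
  for (t in frame_times) {
    # fire between frames if the activation time falls before this frame
    if (run$phase == "TRIGGERED_WAIT" && run$activation_time < t) break
    if (run$phase == "LIVE" && !is.na(run$manual_at) && run$manual_at < t) {
      fire(run$manual_at)
      if (run$activation_time < t) break
    }
    run$clock$set(max(run$clock$now, t))
    exhausted <- FALSE
    for (f in seq_len(run$plan$n_fov)) {
      img <- run$source(f, t)
      if (is.null(img)) { exhausted <- TRUE; break }
      cells <- segment_cells(img, min_area = cfg$min_cell_area,
                             opening_radius = cfg$opening_radius)
      run$states[[f]] <- update_fov(run$states[[f]], cells, t, cfg)
      st <- run$states[[f]]
      run$trigger_trace[[length(run$trigger_trace) + 1L]] <-
        data.frame(time_min = t, fov = f, n_cells = st$n_cells,
                   mean_circularity = st$mean_circularity,
                   triggered = st$triggered)
    }
    if (exhausted) break
    run_log_add(run, t, NA_integer_, "acquire_live", outcome = "done")
    if (run$phase == "LIVE") {
      ev <- check_event(run$states, cfg)
      if (!is.na(run$manual_at) && run$manual_at <= t) {
        fire(run$manual_at)
      } else if (ev$fired) {
        fire(ev$time)
      }
    }
    if (run$phase == "TRIGGERED_WAIT" && run$activation_time <= t) break
  }

  if (run$phase != "TRIGGERED_WAIT") {
    run$phase <- "DONE"
    run_log_add(run, run$clock$now, NA_integer_, "live_complete_no_event")
    finish_run(run, mark)
    return(invisible(run))
  }

  # fluidics at activation = event + delay (exact on the simulated clock)
  run$clock$set(max(run$clock$now, run$activation_time))
  run$phase <- "FLUIDICS"
  notify(run$hooks, "fluidics", "fixation/staining protocol starting",
         run$clock$now)
  run_log_add(run, run$clock$now, NA_integer_, "pumps_activated")
  plog <- execute(run$protocol, run$bus, run$clock, run$hooks,
                  event = list(time = run$event_time))
  run$protocol_log <- plog
  if (attr(plog, "status") == "failed") {
    run$phase <- "FAILED"
    notify(run$hooks, "failure", "fluidics protocol failed; run halted",
           run$clock$now)
    finish_run(run, mark)
    return(invisible(run))
  }
  notify(run$hooks, "fluidics", "fixation/staining protocol complete",
         run$clock$now)

  run$phase <- "POSTFIX"
  for (f in seq_len(run$plan$n_fov)) {
    run_log_add(run, run$clock$now, NA_integer_, sprintf(
      "zstack fov=%d planes=%d spacing=%.2fum channels=%s", f,
      run$plan$z_planes, run$plan$z_spacing,
      paste(run$plan$postfix_channels, collapse = "+")))
  }
  notify(run$hooks, "postfix", "post-fixation imaging complete",
         run$clock$now)
  run$phase <- "DONE"
  finish_run(run, mark)
  invisible(run)
}

finish_run <- function(run, mark) {
  run$log <- {
    l <- do.call(rbind, run$log)
    if (!is.null(run$protocol_log))
      l <- rbind(l, as.data.frame(run$protocol_log))
    l <- l[order(l$time_min), ]
    rownames(l) <- NULL
    l
  }
  run$trigger_trace <- if (length(run$trigger_trace))
    do.call(rbind, run$trigger_trace) else data.frame()
  run$notifications <- notifications_since(mark)
  invisible(run)
}

#' @export
print.fl_run <- function(x, ...) {
  cat(sprintf("fluidloop run: phase %s, %d FOVs\n", x$phase, x$plan$n_fov))
  if (!is.na(x$event_time))
    cat(sprintf("  event at %.1f min, pumps activated at %.1f min\n",
                x$event_time, x$activation_time))
  invisible(x)
}
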