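#' Trigger configuration for the mitotic-rounding detector
#'
#' Default values follow the published unsupervised experiment: a
#' field-of-view (FOV) triggers when its mean cell circularity exceeds
#' 0.82; the experiment-level "cell rounding event" fires once at least
#' 25% of FOVs have triggered; fixation starts a further 15 min later so
#' the rounding cells progress into mitosis; frames arrive every 5 min.
#'
#' @param circularity_threshold FOV statistic threshold, in `(0, 1]`.
#' @param fov_fraction Fraction of triggered FOVs that fires the event,
#'   in `(0, 1]` (compared with `>=`, so exactly 25% fires).
#' @param post_trigger_delay Minutes between event and pump activation.
#' @param min_cell_area Segmentation exclusion floor, px^2.
#' @param frame_interval Acquisition cadence, minutes.
#' @param mode `"fov_mean"` (a FOV triggers when its mean circularity
#'   exceeds the threshold; default) or `"any_cell"` (a FOV triggers when
#'   any single cell exceeds it -- the per-cell phrasing used alongside
#'   the published figure; with about one tracked cell per FOV the two
#'   coincide).
#' @param opening_radius Disc radius of the morphological opening, px.
#' @return A list of class `fl_trigger_config`.
#' @export
trigger_config <- function(circularity_threshold = 0.82,
                           fov_fraction = 0.25,
                           post_trigger_delay = 15,
                           min_cell_area = 200,
                           frame_interval = 5,
                           mode = c("fov_mean", "any_cell"),
                           opening_radius = 2) {
  mode <- match.arg(mode)
  fl_check(is_number(circularity_threshold) && circularity_threshold > 0 &&
             circularity_threshold <= 1, "threshold must be in (0, 1]",
           "fl_invalid_config")
  fl_check(is_number(fov_fraction) && fov_fraction > 0 && fov_fraction <= 1,
           "fov_fraction must be in (0, 1]", "fl_invalid_config")
  fl_check(is_number(post_trigger_delay) && post_trigger_delay >= 0,
           "post_trigger_delay must be >= 0", "fl_invalid_config")
  structure(list(circularity_threshold = circularity_threshold,
                 fov_fraction = fov_fraction,
                 post_trigger_delay = post_trigger_delay,
                 min_cell_area = min_cell_area,
                 frame_interval = frame_interval,
                 mode = mode, opening_radius = opening_radius),
            class = "fl_trigger_config")
}

#' Per-FOV trigger state
#'
#' @param fov_id Identifier of the field of view.
#' @return A list of class `fl_fov_state`: `triggered` is monotone (a FOV
#'   never un-triggers) and `first_trigger_time` is set iff triggered.
#' @export
fov_state <- function(fov_id) {
  structure(list(fov_id = fov_id, triggered = FALSE,
                 first_trigger_time = NA_real_,
                 mean_circularity = NA_real_, n_cells = 0L,
                 last_time = -Inf),
            class = "fl_fov_state")
}

#' Update one FOV's trigger state from a frame's cells
#'
#' Computes the FOV statistic (mean circularity, or the max in
#' `"any_cell"` mode) and latches the trigger the first time it strictly
#' exceeds the threshold ("exceeded" is read as `>`). Zero cells update
#' the bookkeeping but never change the trigger.
#'
#' @param state A [fov_state()].
#' @param cells Data frame from [segment_cells()] (needs a `circularity`
#'   column).
#' @param t Frame time, minutes; must not precede the previous update.
#' @param cfg A [trigger_config()].
#' @return The updated state.
#' @export
update_fov <- function(state, cells, t, cfg = trigger_config()) {
  fl_check(inherits(state, "fl_fov_state"), "not a fov_state")
  fl_check(is_number(t) && t >= state$last_time,
           "updates must be in time order")
  state$last_time <- t
  state$n_cells <- nrow(cells)
  if (nrow(cells) == 0) {
    state$mean_circularity <- NA_real_
    return(state)
  }
  state$mean_circularity <- mean(cells$circularity)
  stat <- switch(cfg$mode,
                 fov_mean = state$mean_circularity,
                 any_cell = max(cells$circularity))
  if (!state$triggered && stat > cfg$circularity_threshold) {
    state$triggered <- TRUE
    state$first_trigger_time <- t
  }
  state
}

#' Experiment-level event decision
#'
#' The "cell rounding event" fires at the first time the fraction of
#' triggered FOVs reaches `fov_fraction` (inclusive). The event time is
#' the latest `first_trigger_time` among the FOVs counted at firing --
#' i.e. the moment the deciding FOV triggered.
#'
#' @param states Non-empty list of [fov_state()]s.
#' @param cfg A [trigger_config()].
#' @return List: `fraction` triggered, `fired` flag, `time` (event time,
#'   `NA` if not fired).
#' @export
check_event <- function(states, cfg = trigger_config()) {
  fl_check(is.list(states) && length(states) >= 1L &&
             all(vapply(states, inherits, logical(1), "fl_fov_state")),
           "states must be a non-empty list of fov_state objects")
  trig <- vapply(states, function(s) s$triggered, logical(1))
  fraction <- mean(trig)
  fired <- fraction >= cfg$fov_fraction
  time <- if (fired) {
    max(vapply(states[trig], function(s) s$first_trigger_time, numeric(1)))
  } else NA_real_
  list(fraction = fraction, fired = fired, time = time)
}
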