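#' Specification of one synthetic cell
#'
#' A cell starts as a spread, elongated ellipse (axis ratio >= 3, analytic
#' circularity < 0.7) and rounds into a disc (circularity ~1) by linear
#' interpolation of its semi-axes over a morphing window centred on
#' `rounding_time`. Centring the window on the scheduled time makes the
#' circularity-threshold crossing happen at that time: halfway through the
#' morph the shape's analytic circularity (~0.9 for a 3:1 spread) is
#' already above the 0.82 trigger threshold, while at the window start it
#' is still far below.
#'
#' @param cx,cy Centroid, px.
#' @param a,b Spread-shape semi-axes, px (`a / b >= 3`).
#' @param r Rounded-disc radius, px; default preserves area
#'   (`sqrt(a * b)`).
#' @param rounding_time Scheduled rounding time, minutes; `Inf` for a
#'   cell that never rounds.
#' @param intensity Peak intensity above background, counts.
#' @param morph_duration Width of the morphing window, minutes.
#' @return A list of class `fl_cell_spec`.
#' @export
cell_spec <- function(cx, cy, a = 36, b = 12, r = sqrt(a * b),
                      rounding_time = Inf, intensity = 900,
                      morph_duration = 10) {
  fl_check(a > 0 && b > 0 && r > 0, "semi-axes must be > 0",
           "fl_invalid_config")
  fl_check(a / b >= 3, "spread shape must have axis ratio >= 3",
           "fl_invalid_config")
  structure(list(cx = cx, cy = cy, a = a, b = b, r = r,
                 rounding_time = rounding_time, intensity = intensity,
                 morph_duration = morph_duration),
            class = "fl_cell_spec")
}

# Analytic circularity of an ellipse with semi-axes a, b (Ramanujan's
# perimeter approximation). Used by tests as the closed-form oracle.
#' Analytic ellipse circularity
#' @param a,b Semi-axes.
#' @return `4 * pi * A / P^2` using Ramanujan's perimeter approximation.
#' @export
ellipse_circularity <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  p <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  4 * pi * (pi * a * b) / p^2
}

#' A synthetic field-of-view scenario
#'
#' @param fov_id Identifier.
#' @param size Image side length, px (square FOV).
#' @param cells List of [cell_spec()]s; shapes must fit in the FOV.
#' @param frame_interval Minutes between frames.
#' @param duration Total duration, minutes; frame count is
#'   `duration / frame_interval + 1`.
#' @param background Background level, counts.
#' @param gaussian_sd Read-noise sd, counts.
#' @param poisson Apply Poisson shot noise to the expected signal.
#' @param seed Integer seed; fixes every rendered pixel exactly.
#' @return A list of class `fl_fov_scenario`.
#' @export
fov_scenario <- function(fov_id, size = 512, cells = list(),
                         frame_interval = 5, duration = 60,
                         background = 100, gaussian_sd = 2,
                         poisson = TRUE, seed = 1L) {
  fl_check(is_number(size) && size >= 64, "size must be >= 64 px",
           "fl_invalid_config")
  fl_check(is_number(frame_interval) && frame_interval > 0 &&
             is_number(duration) && duration >= 0,
           "need frame_interval > 0 and duration >= 0", "fl_invalid_config")
  for (cl in cells) {
    ext <- max(cl$a, cl$b, cl$r)
    fl_check(cl$cx - ext >= 1 && cl$cx + ext <= size &&
               cl$cy - ext >= 1 && cl$cy + ext <= size,
             "cell shapes must fit within the FOV", "fl_invalid_config")
  }
  structure(list(fov_id = fov_id, size = as.integer(size), cells = cells,
                 frame_interval = frame_interval, duration = duration,
                 background = background, gaussian_sd = gaussian_sd,
                 poisson = isTRUE(poisson), seed = as.integer(seed)),
            class = "fl_fov_scenario")
}

# Interpolated semi-axes of a cell at time t: morphing window of width
# morph_duration centred on rounding_time, linear in the semi-axes.
cell_axes_at <- function(cell, t) {
  if (!is.finite(cell$rounding_time)) return(c(cell$a, cell$b))
  if (cell$morph_duration <= 0) {
    s <- if (t >= cell$rounding_time) 1 else 0
  } else {
    s <- (t - (cell$rounding_time - cell$morph_duration / 2)) /
      cell$morph_duration
    s <- min(1, max(0, s))
  }
  c(cell$a + s * (cell$r - cell$a), cell$b + s * (cell$r - cell$b))
}

#' Render one frame of a scenario
#'
#' Each cell is drawn at its time-interpolated shape with a ~1 px
#' anti-aliased edge, on a flat background; Poisson shot noise and
#' Gaussian read noise are then applied and the result clamped to the
#' 16-bit range. Bit-identical for a fixed scenario seed and time.
#'
#' @param scenario A [fov_scenario()].
#' @param t Time in minutes, within `[0, duration]`.
#' @return Numeric matrix of size `size x size`.
#' @export
render_frame <- function(scenario, t) {
  fl_check(inherits(scenario, "fl_fov_scenario"), "not a scenario")
  if (!(is_number(t) && t >= 0 && t <= scenario$duration))
    fl_abort(sprintf("t = %s outside [0, %s]", format(t),
                     format(scenario$duration)), "fl_invalid_argument")
  n <- scenario$size
  img <- matrix(scenario$background, n, n)
  for (cell in scenario$cells) {
    ab <- cell_axes_at(cell, t)
    a <- ab[1]; b <- ab[2]
    ext <- ceiling(max(a, b)) + 2L
    xs <- max(1L, floor(cell$cx - ext)):min(n, ceiling(cell$cx + ext))
    ys <- max(1L, floor(cell$cy - ext)):min(n, ceiling(cell$cy + ext))
    dx <- (xs - cell$cx) / a
    dy <- (ys - cell$cy) / b
    d <- sqrt(outer(dy^2, dx^2, "+"))      # rows = y, cols = x
    # ~1 px soft edge: distance to boundary approximated by (1 - d) * b
    alpha <- pmin(pmax(0.5 + (1 - d) * b, 0), 1)
    img[ys, xs] <- img[ys, xs] + cell$intensity * alpha
  }
  frame_idx <- round(t / scenario$frame_interval)
  with_seed(fl_sub_seed(scenario$seed, 7561, scenario$fov_id, frame_idx), {
    if (scenario$poisson) img <- matrix(rpois(n * n, img), n, n)
    if (scenario$gaussian_sd > 0)
      img <- img + rnorm(n * n, 0, scenario$gaussian_sd)
  })
  pmin(pmax(round(img), 0), 65535)
}

# Deterministic jittered-grid placement of n_cells within a FOV.
place_cells <- function(n_cells, size, margin, seed) {
  per_side <- ceiling(sqrt(n_cells))
  centres <- seq(margin, size - margin, length.out = per_side)
  g <- expand.grid(cx = centres, cy = centres)[seq_len(n_cells), , drop = FALSE]
  jit <- with_seed(fl_sub_seed(seed, 86243),
                   matrix(runif(2 * n_cells, -8, 8), ncol = 2))
  g$cx <- g$cx + jit[, 1]
  g$cy <- g$cy + jit[, 2]
  g
}

#' Generate a multi-FOV synthetic rounding experiment
#'
#' Builds one scenario per FOV in which all of the FOV's cells round at
#' the scheduled time, emulating a live experiment in which 30--50 fields
#' of view are imaged every 5 min while cells enter mitosis. Stacks can
#' be kept in memory, written as one multi-page 16-bit TIFF per FOV, or
#' both; a JSON manifest records the ground-truth schedule.
#'
#' @param n_fov Number of fields of view.
#' @param schedule Named or positional map FOV id -> rounding time in
#'   minutes (`Inf` = never rounds). Must reference FOVs `1..n_fov` only.
#' @param n_cells Cells per FOV.
#' @param size,frame_interval,duration,background,gaussian_sd,seed See
#'   [fov_scenario()].
#' @param dir If non-`NULL`, directory to write `fov_###.tif` stacks and
#'   `manifest.json` into.
#' @return An object of class `fl_experiment`: list with `scenarios`,
#'   `schedule`, `frame_times` and (if written) `paths`.
#' @export
generate_experiment <- function(n_fov, schedule, n_cells = 5, size = 512,
                                frame_interval = 5, duration = 60,
                                background = 100, gaussian_sd = 2,
                                seed = 42L, dir = NULL) {
  fl_check(is_number(n_fov) && n_fov >= 1, "n_fov must be >= 1")
  ids <- as.integer(names(schedule) %||% seq_along(schedule))
  if (is.null(names(schedule))) ids <- seq_along(schedule)
  fl_check(all(ids >= 1 & ids <= n_fov),
           "schedule references unknown FOV ids", "fl_invalid_argument")
  times <- rep(Inf, n_fov)
  times[ids] <- as.numeric(schedule)
  margin <- 60
  scenarios <- vector("list", n_fov)
  for (f in seq_len(n_fov)) {
    pos <- place_cells(n_cells, size, margin, fl_sub_seed(seed, 3571, f))
    cells <- lapply(seq_len(n_cells), function(i)
      cell_spec(pos$cx[i], pos$cy[i], rounding_time = times[f]))
    scenarios[[f]] <- fov_scenario(f, size, cells, frame_interval, duration,
                                   background, gaussian_sd, seed = seed)
  }
  frame_times <- seq(0, duration, by = frame_interval)
  out <- structure(list(scenarios = scenarios, schedule = times,
                        frame_times = frame_times, n_fov = n_fov),
                   class = "fl_experiment")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(n_fov)
    for (f in seq_len(n_fov)) {
      stack <- lapply(frame_times, function(t) render_frame(scenarios[[f]], t))
      paths[f] <- file.path(dir, sprintf("fov_%03d.tif", f))
      write_tiff(stack, paths[f])
    }
    jsonlite::write_json(
      list(n_fov = n_fov, frame_interval = frame_interval,
           duration = duration, seed = seed,
           schedule = unname(ifelse(is.finite(times), times, -1)),
           files = basename(paths)),
      file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}

#' Frame sources for the orchestrator
#'
#' A frame source is a function `(fov_id, t)` returning the FOV's frame
#' at time `t`, or `NULL` when exhausted. `experiment_source()` renders
#' from in-memory scenarios; `tiff_source()` replays stacks written by
#' [generate_experiment()].
#'
#' @param experiment An `fl_experiment` from [generate_experiment()].
#' @return A frame-source function.
#' @export
experiment_source <- function(experiment) {
  fl_check(inherits(experiment, "fl_experiment"), "not an experiment")
  function(fov_id, t) {
    sc <- experiment$scenarios[[fov_id]]
    if (t > sc$duration) return(NULL)
    render_frame(sc, t)
  }
}

#' @rdname experiment_source
#' @param dir Directory holding `fov_###.tif` stacks and `manifest.json`.
#' @export
tiff_source <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  stacks <- lapply(file.path(dir, manifest$files), read_tiff)
  interval <- manifest$frame_interval
  function(fov_id, t) {
    idx <- round(t / interval) + 1L
    st <- stacks[[fov_id]]
    if (idx > length(st)) return(NULL)
    st[[idx]]
  }
}
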