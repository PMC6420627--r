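#' Dispense accuracy and precision
#'
#' For one condition (a fixed pump/syringe/nominal-volume combination),
#' accuracy is the mean dispense error and precision the sample standard
#' deviation (n - 1 denominator) of the error, both expressed as percent
#' of the nominal injected volume. Mass measurements convert to volume at
#' water density 1.000 g/mL.
#'
#' @param measurements Data frame with columns `nominal_ul` and
#'   `measured_ul`; all rows must share one nominal volume.
#' @return Percent of nominal.
#' @export
#' @examples
#' d <- data.frame(nominal_ul = 100, measured_ul = c(98, 102))
#' dispense_accuracy(d)   # 0
#' dispense_precision(d)  # 2.83
dispense_accuracy <- function(measurements) {
  check_condition(measurements, min_n = 1L)
  nom <- measurements$nominal_ul[1]
  100 * mean(measurements$measured_ul - nom) / nom
}

#' @rdname dispense_accuracy
#' @export
dispense_precision <- function(measurements) {
  check_condition(measurements, min_n = 2L)
  nom <- measurements$nominal_ul[1]
  100 * sd(measurements$measured_ul - nom) / nom
}

check_condition <- function(measurements, min_n) {
  fl_check(is.data.frame(measurements) &&
             all(c("nominal_ul", "measured_ul") %in% names(measurements)),
           "measurements need columns nominal_ul and measured_ul")
  if (nrow(measurements) < min_n)
    fl_abort(sprintf("need at least %d replicates", min_n),
             "fl_insufficient_replicates")
  if (length(unique(measurements$nominal_ul)) != 1L)
    fl_abort("one condition must share a single nominal volume",
             "fl_invalid_grouping")
  invisible(TRUE)
}

#' Fit a per-pump calibration correction
#'
#' Least-squares slope through the origin of measured versus nominal
#' volume across at least two distinct nominals. The slope is the pump's
#' true-to-nominal volume scale; dividing commanded step counts by it (or
#' equivalently scaling the pump's effective step volume) zeroes the
#' accuracy on the training data up to step quantization.
#'
#' @param measurements Data frame with `nominal_ul`, `measured_ul`
#'   spanning >= 2 distinct nominal volumes.
#' @return The correction factor (uL-per-step multiplier), a single
#'   number near 1.
#' @export
fit_calibration <- function(measurements) {
  fl_check(is.data.frame(measurements) &&
             all(c("nominal_ul", "measured_ul") %in% names(measurements)),
           "measurements need columns nominal_ul and measured_ul")
  if (length(unique(measurements$nominal_ul)) < 2L)
    fl_abort("calibration needs >= 2 distinct nominal volumes",
             "fl_invalid_design")
  x <- measurements$nominal_ul
  y <- measurements$measured_ul
  sum(x * y) / sum(x * x)
}

#' Default calibration measurement plan
#'
#' Ten replicates of each of 50, 100, 300 and 500 uL on each of the three
#' stock syringe classes -- 12 conditions in all.
#'
#' @param nominals Nominal volumes, uL.
#' @param syringes Named list of [syringe_spec()]s.
#' @param replicates Replicates per condition.
#' @return Data frame with one row per condition.
#' @export
default_calibration_plan <- function(nominals = c(50, 100, 300, 500),
                                     syringes = stock_syringes(),
                                     replicates = 10L) {
  plan <- expand.grid(syringe = names(syringes), nominal_ul = nominals,
                      stringsAsFactors = FALSE)
  plan$n <- replicates
  plan
}

#' Run a simulated dispense characterization
#'
#' Executes the measurement plan against the dispense simulator (one pump
#' per syringe class), groups the resulting measurements by condition and
#' reports accuracy and precision per condition plus an overall pass flag
#' against `bound` (default 5% of nominal, the published hardware
#' specification). Conditions with fewer than two replicates are flagged
#' in the report rather than crashing it.
#'
#' @param plan Data frame with columns `syringe`, `nominal_ul`, `n` (see
#'   [default_calibration_plan()]).
#' @param model A [dispense_error_model()]; the default emulates a
#'   calibrated pump (step quantization, 0.3% per-step jitter, 1%
#'   residual diameter tolerance).
#' @param syringes Named list of syringes referenced by the plan.
#' @param bound Pass bound, percent of nominal.
#' @param seed Seed for the simulated dispenses (overrides the model's).
#' @return A list of class `fl_calibration_report`: `conditions` data
#'   frame (`syringe`, `nominal_ul`, `n`, `accuracy_pct`,
#'   `precision_pct`), `measurements` (the raw table), `worst` =
#'   max over conditions of `max(|accuracy|, precision)`, and `pass`.
#' @export
characterize <- function(plan = default_calibration_plan(),
                         model = dispense_error_model(
                           per_step_jitter_sd = 0.003,
                           diameter_tolerance = 0.01, seed = 42L),
                         syringes = stock_syringes(),
                         bound = 5, seed = NULL) {
  fl_check(is.data.frame(plan) && nrow(plan) >= 1L,
           "plan must be a non-empty data frame")
  if (!is.null(seed)) model$seed <- as.integer(seed)
  fl_check(all(plan$syringe %in% names(syringes)),
           "plan references unknown syringes")
  pump_for <- stats::setNames(seq_along(syringes) - 1L, names(syringes))
  rows <- list()
  for (i in seq_len(nrow(plan))) {
    syr <- syringes[[plan$syringe[i]]]
    pump <- pump_config(address = pump_for[[plan$syringe[i]]])
    for (r in seq_len(plan$n[i])) {
      rows[[length(rows) + 1L]] <- data.frame(
        pump = pump$address, syringe = as.character(plan$syringe[i]),
        nominal_ul = plan$nominal_ul[i],
        measured_ul = simulate_dispense(plan$nominal_ul[i], syr, pump, model,
                                        replicate = i * 1000L + r),
        replicate = r)
    }
  }
  meas <- do.call(rbind, rows)
  conds <- unique(meas[c("syringe", "nominal_ul")])
  out <- list()
  for (i in seq_len(nrow(conds))) {
    sub <- meas[meas$syringe == conds$syringe[i] &
                  meas$nominal_ul == conds$nominal_ul[i], ]
    out[[i]] <- data.frame(
      syringe = conds$syringe[i], nominal_ul = conds$nominal_ul[i],
      n = nrow(sub),
      accuracy_pct = dispense_accuracy(sub),
      precision_pct = if (nrow(sub) >= 2) dispense_precision(sub) else NA_real_)
  }
  tab <- do.call(rbind, out)
  tab$flag <- ifelse(is.na(tab$precision_pct), "insufficient replicates", "")
  worst <- max(pmax(abs(tab$accuracy_pct), tab$precision_pct), na.rm = TRUE)
  structure(list(conditions = tab, measurements = meas, worst = worst,
                 bound = bound, pass = worst <= bound),
            class = "fl_calibration_report")
}

#' @export
print.fl_calibration_report <- function(x, ...) {
  cat(sprintf("Dispense characterization: %d conditions, bound %.1f%% of nominal\n",
              nrow(x$conditions), x$bound))
  print(x$conditions, row.names = FALSE)
  cat(sprintf("worst |accuracy| / precision: %.2f%% -> %s\n", x$worst,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Read / write dispense measurement tables
#'
#' CSV columns: `pump`, `syringe`, `nominal_ul`, `measured_ul`,
#' `replicate`.
#'
#' @param path CSV path.
#' @return `read_measurements()` returns the data frame.
#' @export
read_measurements <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  fl_check(all(c("nominal_ul", "measured_ul") %in% names(d)),
           "CSV needs nominal_ul and measured_ul columns")
  d
}

#' @rdname read_measurements
#' @param measurements Data frame of measurements.
#' @export
write_measurements <- function(measurements, path) {
  write.csv(measurements, path, row.names = FALSE)
  invisible(path)
}
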