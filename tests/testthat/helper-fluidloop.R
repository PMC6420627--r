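# Shared fixtures, all generated in code.

# syringe whose cross-section is exactly 100 mm^2 -> 0.5 uL/step with the
# default drivetrain
unit_syringe <- function() {
  syringe_spec(sqrt(400 / pi), 5000, 51, "area-100")
}

demo_bus <- function(n_pumps = 4, clock = sim_clock(), syringe = NULL,
                     extraction_rate = 1000, chamber = NULL) {
  bus <- sim_bus(clock)
  syringe <- syringe %||% stock_syringes()[["5 mL"]]
  for (a in seq_len(n_pumps) - 1L)
    attach_pump(bus, a, syringe, pump_config(address = a))
  attach_extraction_pump(bus, extraction_rate, chamber)
  bus
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# anti-aliased renders of analytic shapes on a flat background, the
# fixtures for the circularity oracle tests
render_ellipse_image <- function(a, b, size = 256, cx = size / 2 + 0.3,
                                 cy = size / 2 + 0.6, bg = 100, fg = 900) {
  xs <- seq_len(size)
  dx <- (xs - cx) / a
  dy <- (xs - cy) / b
  d <- sqrt(outer(dy^2, dx^2, "+"))
  bg + fg * pmin(pmax(0.5 + (1 - d) * min(a, b), 0), 1)
}

render_square_image <- function(side, size = 256, cx = size / 2 + 0.3,
                                cy = size / 2 + 0.6, bg = 100, fg = 900) {
  xs <- seq_len(size)
  sx <- pmin(pmax(0.5 + side / 2 - abs(xs - cx), 0), 1)
  sy <- pmin(pmax(0.5 + side / 2 - abs(xs - cy), 0), 1)
  bg + fg * outer(sy, sx)
}

# measured circularity of the single cell in an image
measure_circ <- function(img, ...) {
  cells <- segment_cells(img, ...)
  stopifnot(nrow(cells) == 1L)
  cells$circularity
}

# a small wash-only protocol used in several engine tests
wash_protocol <- function(n_wash = 3, volume = 300, rate = 600,
                          chamber = chamber_model()) {
  steps <- list()
  for (i in seq_len(n_wash)) {
    steps <- c(steps, list(
      protocol_step("INFUSE", pump = 1L, reagent = "PBS",
                    volume = volume, rate = rate),
      protocol_step("WAIT", duration = 10)))
  }
  protocol("wash", steps, chamber)
}
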