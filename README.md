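# fluidloop

Hardware-agnostic R implementation of an open-source microscope
fluid-exchange automation stack: multiplexed Lego-class syringe pumps, a
peristaltic extraction pump, declarative fixation/staining protocols, and
an **event-driven "smart microscopy" loop** in which live imaging itself
decides when to fix the sample.

The motivating experiment is unsupervised live-to-fixed imaging of
mitosis: adherent cells retract and become near-spherical ("mitotic
rounding") as they enter division. Frames from tens of fields of view
(FOVs) are segmented continuously; each cell's circularity

        C = 4 pi A / P^2        (1 for a circle, lower when elongated)

is computed from its area *A* and perimeter *P*. A FOV *triggers* when
its mean circularity exceeds 0.82; once 25% of FOVs have triggered, the
"cell rounding event" fires, and after a 15-min grace period the pumps
run an in-situ fixation/staining sequence (4% PFA 15 min, 3 × 10 min PBS
washes, 30 min permeabilisation/blocking, 1 h phalloidin + DAPI, 2 × 10
min washes — 155 min of incubation), followed by post-fixation z-stack
imaging. Everything runs on a simulated clock against a simulated pump
bus (128 addresses), so the complete closed loop is testable with no
hardware: a synthetic time-lapse generator renders rounding cells with
realistic noise and a ground-truth schedule.

Who this is for: microscopy-automation developers who want to test
event-driven acquisition logic off-line; lab users validating
fluid-exchange protocols and pump calibration before running them on an
instrument.

## Worked example: the closed loop at desk scale

Twelve synthetic FOVs; FOVs 1–2 round at 15 min, 3–4 at 20 min, the
rest at 60 min. The fourth FOV is the deciding one: 4/12 = 33% ≥ 25% at
20 min, so the pumps must activate at 20 + 15 = 35 min.

```r
library(fluidloop)

sched <- c(rep(15, 2), rep(20, 2), rep(60, 8))
exp   <- generate_experiment(12, sched, n_cells = 4, size = 256, seed = 42)

clk <- sim_clock(); ch <- chamber_model(2000); bus <- sim_bus(clk)
for (a in 0:3)
  attach_pump(bus, a, stock_syringes()[["5 mL"]], pump_config(address = a))
attach_extraction_pump(bus, 1000, ch)

run <- new_run(acquisition_plan(n_fov = 12), trigger_config(),
               mitotic_fixation_protocol(chamber = ch),
               experiment_source(exp), bus, clk, duration = 60)
run_experiment(run)
print(run)
#> fluidloop run: phase DONE, 12 FOVs
#>   event at 20.0 min, pumps activated at 35.0 min

subset(run$trigger_trace, fov == 3)[1:6, ]
#>    time_min fov n_cells mean_circularity triggered
#> 3         0   3       4        0.6611829     FALSE
#> 15        5   3       4        0.6603083     FALSE
#> 27       10   3       4        0.6608725     FALSE
#> 39       15   3       4        0.6617854     FALSE
#> 51       20   3       4        0.8922206      TRUE
#> 63       25   3       4        0.9968275      TRUE
```

Reading the trace: spread cells measure C ≈ 0.66, far below the 0.82
threshold; at the scheduled rounding time the FOV mean jumps above it
and latches. The execution log records `event_detected` at 20 min and
`pumps_activated` at 35 min, then every fluidics step and the post-fix
z-stacks.

Pump calibration in simulation (accuracy = mean error, precision =
sample SD of error, both % of nominal; bound 5%):

```r
characterize(seed = 42)
#> Dispense characterization: 12 conditions, bound 5.0% of nominal
#>  syringe nominal_ul  n accuracy_pct precision_pct flag
#>     1 mL         50 10   -1.4549114   0.011698151
#>     5 mL         50 10   -0.3040133   0.035474649
#>    10 mL         50 10    2.5598954   0.043038773
#>  ...
#> worst |accuracy| / precision: 2.56% -> PASS
```

## Package layout

| Part | Contents |
|---|---|
| `R/kinematics.R` | syringe/drivetrain geometry, volume↔step conversion, dispense-error simulator |
| `R/bus.R`, `R/chamber.R` | simulated 128-address pump bus, peristaltic extraction, open-chamber bookkeeping |
| `R/protocol.R` | protocol steps, validation, duration planning, execution with logging and JSON I/O |
| `R/segmentation.R`, `R/trigger.R`, `src/` | Otsu + opening + labelling, sub-pixel contour perimeter, circularity, FOV/event trigger rules |
| `R/synth.R`, `R/tiff.R` | synthetic rounding time-lapses, minimal 16-bit TIFF stack I/O |
| `R/calibration.R` | accuracy/precision analysis, per-pump calibration fit, characterization report |
| `R/orchestrator.R` | closed-loop run state machine, manual trigger, notification hooks |
| `inst/cli/fluidloop.R` | command-line interface (probe / send / run / synth / calibrate) |
| `vignettes/fluidloop-methods.Rmd` | models, assumptions, parameter rationale, limitations |
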