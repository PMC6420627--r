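---
title: "fluidloop: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fluidloop: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluidloop)
```

## What the package models

fluidloop is a hardware-agnostic implementation of a microscope
fluid-exchange automation stack built around low-cost multiplexed syringe
pumps. The real system exchanges reagents in an open imaging chamber on
the microscope stage, so that fixation, washing, permeabilisation and
staining can run unattended — and, crucially, can be *triggered by the
image itself*. The flagship use case is event-driven fixation: adherent
cells retract and become near-spherical as they enter mitosis ("mitotic
rounding"), and the system watches live frames, detects the rounding cue,
waits a short grace period, and then fixes and stains the sample in place.

Everything here runs against a simulated clock and a simulated pump bus,
so the full closed loop — imaging, detection, fluidics, post-fixation
acquisition — is testable on a laptop with no hardware and no real data.

## Pump kinematics

A syringe on a lead-screw drivetrain moves

$$ v_\mathrm{step} \;=\; \frac{\mathrm{lead}}{\mathrm{gear} \times
   \mathrm{steps/rev}} \cdot \frac{\pi d^2}{4} \quad [\mu L / \mathrm{step}] $$

per motor step. Commanded volumes are quantised to steps with
round-half-to-even (symmetric bias over a calibration series), and a flow
rate maps to a per-step period of $60000\, v_\mathrm{step} / \mathrm{rate}$
milliseconds. Units are fixed package-wide — µL, µL/min, minutes (ms for
step periods), mm — with no unit inference.

The default drivetrain constants (200 steps/rev, 1 mm lead, 1:1 gearing)
are generic stepper/lead-screw values, deliberately labelled as
non-measured placeholders: the physical build's exact gearing is not
reproduced here. The three stock syringes (1, 5, 10 mL classes with
typical disposable-syringe barrel diameters) define the default
calibration conditions.

### Dispense error model

`dispense_error_model()` composes, in order:

1. a per-pump barrel-diameter deviation, drawn once per pump from
   Uniform(−tol, +tol) — a tolerance is a *bound*, so the uniform support
   makes the worst-case volume bias exactly $(1+\mathrm{tol})^2 - 1$
   (≈ 2% at the 1% default);
2. step quantisation (round-half-even);
3. independent per-step Gaussian jitter: a dispense of $N$ steps has
   total sd $\mathrm{jitter}\cdot v_\mathrm{step}\sqrt{N}$, i.e. relative
   sd $\mathrm{jitter}/\sqrt{N}$. Independence across steps is the
   physically conservative choice; it means per-step jitter contributes
   little to whole-dispense error, which is dominated by the diameter
   term;
4. a fixed step loss on direction reversal (backlash).

With every term zero the model returns the quantised nominal exactly.
All draws are keyed off a user seed, the pump address and the replicate
index, so simulated experiments are bit-reproducible.

### Calibration and QC

Accuracy is the mean dispense error and precision the sample sd
($n-1$) of the error, both as percent of nominal; mass weighings convert
at water density 1.000 g/mL. `fit_calibration()` estimates a per-pump
volume scale as the least-squares slope through the origin of measured
vs. nominal, applied as a multiplicative step-volume correction.
`characterize()` runs a conditions × replicates plan (default
3 syringes × 4 volumes × 10 replicates) and checks every condition
against the 5%-of-nominal bound. The cross-condition ANOVA the original
analysis ran in a commercial stats package is intentionally not
reimplemented; the raw table exports as tidy CSV.

## Event detection

Cells are segmented by Otsu global thresholding, a binary opening with a
disc (radius 2 px default) to remove speckle, and 8-connected
labelling. Components below 200 px² or touching the image border
(partial cells distort shape) are discarded. Circularity is the shape
factor

$$ C = \frac{4\pi A}{P^2}, $$

1 for a circle and lower for elongated shapes, clipped to 1.

**Perimeter estimation.** Pixel-counting perimeters bias $C$ badly, so
the choice of estimator matters more than anything else in this module.
We measured the candidates on rasterised analytic shapes: 4-direction
Crofton (integral-geometry LUT) recovers circles and ellipses well but
clips corners of axis-aligned squares ($C$ error ≈ +0.08); chain-code
estimators with Vossepoel–Smeulders or Kulpa weights behave the same or
worse. The implemented estimator is instead the *marching-squares
iso-contour length of the intensity image at the segmentation threshold*,
computed per component with linear sub-pixel interpolation. On
anti-aliased renderings the absolute circularity error is below 0.01 for
circle, square and 3:1/4:1 ellipses — an order of magnitude inside the
0.05 oracle band the tests enforce. The estimator assumes ~1 px soft
edges (true for microscopy images and for the synthetic renderer); on
hard binary masks it degrades to the corner-cut midpoint polygon, which
is still exact for squares but under-reads circles by ≈ 0.13 — one
reason the test fixtures are anti-aliased renders, as real data would be.

**Trigger logic.** A field of view (FOV) *triggers* the first time its
mean cell circularity strictly exceeds the threshold (default 0.82);
triggers latch (a FOV never un-triggers). The experiment-level rounding
event fires when the triggered fraction reaches the FOV fraction
(default 25%, compared inclusively so exactly 25% fires); the event time
is the deciding FOV's first-trigger time. Pump activation follows after
the post-trigger delay (default 15 min) so the detected cells progress
into mitosis before fixation.

The source material describes the statistic both as a per-FOV mean and
as a fraction of individual rounded cells; with roughly one tracked cell
per FOV the two coincide. The mean-circularity form is the default;
`trigger_config(mode = "any_cell")` exposes the per-cell reading (a FOV
triggers when any single cell exceeds the threshold).

## Synthetic time-lapse generator

Each synthetic cell is an anti-aliased ellipse that morphs from a spread
shape (axis ratio ≥ 3, analytic $C \le 0.66$) to an area-preserving disc
($C \to 1$) by linear interpolation of its semi-axes over a 10-min
window. The window is *centred* on the scheduled rounding time: halfway
through the morph the analytic circularity (≈ 0.9 for a 3:1 spread)
already exceeds 0.82, while at the window start it is far below, so with
a 5-min cadence the threshold crossing lands exactly on the scheduled
frame. (Anchoring the window to *end* at the scheduled time would cross
one frame early — this was measured, and is why the window is centred.)

Defaults state the emulated world: 512 × 512 px FOVs, background
100 counts, cell intensity 900 counts above background, Poisson shot
noise plus 2-count Gaussian read noise (edge SNR ≈ 28), 5 cells per FOV
on a jittered grid with border margins, frames every 5 min for 60 min.
Rendering is bit-reproducible from the scenario seed, and
`generate_experiment()` can write one multi-page 16-bit TIFF per FOV
plus a JSON ground-truth manifest.

What the generator does **not** emulate: optics (no PSF, no defocus),
photobleaching, stage drift, cell migration, touching/overlapping cells,
debris, or uneven illumination. A green end-to-end test therefore
establishes that the detection logic and timing are correct under clean
imaging, not that segmentation is robust to difficult real data.

## Protocol engine and chamber bookkeeping

Protocols are ordered lists of steps — INFUSE, WITHDRAW, EXTRACT (via
the peristaltic pump), WAIT, AWAIT_EVENT, NOTIFY — with repeat counts.
Validation returns findings (unknown pump, stroke beyond syringe
capacity, chamber overfill) rather than throwing; oversized strokes can
optionally split into refill cycles. The open chamber mixes perfectly
and instantaneously; extraction can only draw down to a residual floor
(default 10% of the working volume — a film always covers the sample),
and infusion beyond the working volume spills over the rim. Spills and
extractions are tracked per reagent, so volume is conserved exactly:
infused − extracted − spilled = net content change, which the tests
assert after every executed protocol.

The bundled fixation/staining sequence maps the published bench protocol
step-for-step: each phase is EXTRACT + INFUSE + WAIT with the stated
incubation (15 min fixation, 3 × 10 min washes, 30 min
permeabilisation/blocking, 60 min staining, 2 × 10 min washes = 155 min
of incubation, plus ≈ 1.3 min of pump motion at the default 6 mL/min).
Failure policy is halt-and-notify: the failing step logs `failed`, later
steps log `skipped`, and the failure hook fires — the engine never
continues over a suspect sample. Overflow loading (small aliquot flushed
by a larger carrier) follows a plug-flow model: delivered reagent is
`min(aliquot, flush)`, so a flush exceeding the aliquot plus tubing dead
volume guarantees complete delivery.

## Orchestration

`run_experiment()` advances a run through LIVE → TRIGGERED_WAIT →
FLUIDICS → POSTFIX → DONE (FAILED reachable from anywhere). Each cadence
it pulls one frame per FOV from an abstract frame source (synthetic
renderer, TIFF replay, or a user adapter), updates trigger states, and
evaluates the event rule; imaging *continues through the post-trigger
delay* (the published experiment shows frames up to the activation
minute). Activation time is exactly event time + delay on the simulated
clock. `manual_trigger()` provides the human-in-the-loop variant: it is
equivalent to the automatic event firing at the given time, delay
included, and is only legal before any event has fired — one event per
run, ever. Post-fixation z-stack acquisition is represented as log
entries (planes × channels per FOV), not rendered images: its content is
biology, not algorithm. Notifications (event, fluidics start/end,
post-fix, failure) go through pluggable hooks that are never allowed to
throw into the control loop; delivery, including failures, is recorded.

## Numerical choices and edge cases

* Otsu's criterion is computed in doubles over a 256-bin histogram (the
  between-class product overflows 32-bit integers at 512² px); constant
  images return no threshold, a warning, and zero cells.
* "Exceeded" is read strictly (`>`) for the circularity threshold,
  inclusively (`>=`) for the FOV fraction, so exactly-25% fires.
* Step quantisation uses round-half-to-even; because physical step
  volumes are irrational, exact ties are not asserted in tests — the
  inverse contract (round-trip error ≤ half a step) is.
* Marching-squares saddle cells are disambiguated by the cell-centre
  mean; contour extraction is restricted to a dilated neighbourhood of
  each component so neighbouring cells and background speckle contribute
  nothing.
* All derived seeds stay below $2^{31}$; every stochastic routine
  restores the caller's RNG state.

## Known limitations

* The serial/firmware transport is simulated only; the bus is flat
  (0–127) with no daisy-chain topology.
* Chamber mixing is ideal; no transport delay, diffusion, or laminar-flow
  dead zones.
* The detector does not track individual cells across frames; a FOV's
  statistic is recomputed per frame from whatever segments.
* The TIFF codec reads only the baseline layout it writes (uncompressed
  16-bit grayscale little-endian); arbitrary third-party TIFFs are out
  of scope.
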