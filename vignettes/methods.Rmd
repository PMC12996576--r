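---
title: "Models and methods behind petaif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind petaif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petaif)
```

`petaif` processes arterial input functions (AIF) for mouse dynamic PET:
calibration of a continuous arterial detector trace, parametric input
function fitting, dispersion and delay handling, image-derived input
functions (IDIF), objective curve features, compartmental and graphical
kinetic modelling, repeated-injection correction, and group statistics.
Because real shunt-cannulation datasets are terminal, low-throughput
experiments, the package ships a forward simulator that generates
subjects with known ground truth; every inverse step is validated as the
(approximate) inverse of the corresponding forward step.

This vignette records the models, the defaults and why they were chosen,
the numerical decisions, and what the simulator does and does not
emulate.

## The input-function model

Arterial curves after an intravenous bolus are modelled with the Feng
four-exponential form,

$$c_p(t) = \bigl(A_1 (t - t_0) - A_2 - A_3\bigr)\,e^{-\lambda_1 (t-t_0)}
  + A_2\,e^{-\lambda_2 (t-t_0)} + A_3\,e^{-\lambda_3 (t-t_0)},
  \qquad t \ge t_0,$$

zero before the onset $t_0$, with $\lambda_1 > \lambda_2 > \lambda_3 > 0$.
The linear-times-exponential term carries the first-pass peak; the two
slower exponentials carry redistribution and clearance. The ordering
constraint is enforced structurally in `fit_feng()`: the optimiser works
on log-increments between eigenvalues, so no iterate can violate it.
Fitting uses `minpack.lm::nls.lm` from five deterministic starting
points built from curve heuristics (peak location/height, log-linear
tail fit); the lowest SSE wins. A curve without a discernible peak (max
not clearly above the tail mean) is refused rather than fitted.

### Fitting through the measurement operator

What the detector records is not $c_p$: the bolus is widened by the
injection duration (convolution with a unit-area boxcar of width $D$)
and smeared by transport through the withdrawal tubing (convolution with
$\tau^{-1} e^{-t/\tau}$), plus a pure transit delay. A bare Feng fit to
such a curve systematically flattens the peak, and that bias propagates
into kinetic parameters of fast-uptake tissues. When the protocol knobs
are known — $D$ from the pump program, $\tau$ from the withdrawal-rate
calibration — `fit_feng(..., measure = )` therefore fits the bolus model
*through* the measurement operator. The fitted model then lives in bolus
space: evaluating it directly gives the dispersion-free arterial curve
(used for kinetic modelling), while pushing it back through the operator
gives the measured-space curve (used for curve features, which by
convention describe what the detector sees). The transit delay is
absorbed by the fitted $t_0$ and subtracted afterwards.

`correct_dispersion()` implements the classical kernel inverse
$c(t) + \tau\,dc/dt$ with central differences; it is kept as the
standalone correction (and validated by round-trip tests for
$\tau \in [0, 30]$ s), but the pipeline prefers the model-based route
above because differentiation amplifies noise and grid-scale curvature.

## The simulator

`simulate_subject()` composes, in order: Feng bolus (onset 5 s) →
injection boxcar → \{detector branch: dispersion + delay + calibration
factor + count noise\} and \{tissue branch: 2TCM responses, frame
averaging, partial-volume mixing, count noise\}, plus three late-scan
manual blood samples. Defaults follow the reference protocol of a
systematic mouse FDG variability design: 15 MBq in 100 µl over 30 s,
withdrawal at 120 µl/min, PET/CT geometry, 45.5 min scan on a
30×2 s/14×5 s/10×10 s/10×30 s/22×100 s schedule, recovery coefficient
0.42.

Choices a user may want to revisit:

* **Feng defaults** (`default_feng_model()`): $A_1$ was solved so that
  the reference-protocol *measured* curve peaks at 8.78 SUV, the scale
  reported for calibrated mouse FDG arterial curves; the washout terms
  ($A_2 = 4$, $\lambda_2 = 0.02$/s, $A_3 = 1.5$,
  $\lambda_3 = 3\times10^{-4}$/s) put the tail near 0.9 SUV at scan end
  with a peak-to-tail area ratio near 0.1.
* **Dispersion–withdrawal link**: $\tau = \kappa / r$ with
  $\kappa = 600$ s·µl/min, i.e. $\tau(120\ \mu l/min) = 5$ s; PET/MR
  adds 10 s of $\tau$ and 30 s of delay for its longer tubing. The
  baseline delay is 30.4 s, a measured detector-to-animal transit time
  for this geometry. Real tubing dispersion is only qualitatively an
  exponential kernel; the inverse-rate scaling is a modelling choice.
* **Noise**: zero-mean Gaussian with SD
  $s\sqrt{\max(c,0)/\Delta t}$ — the duration weighting approximates
  decay-corrected Poisson counting. Default scale $s = 0.05$ for
  detector traces and TACs (≈2 % at the peak of a 1 s sample, larger
  relatively in the tail), 5 % CV for manual samples.
* **Biological variability** (`cohort_spec()`): mean-preserving
  log-normal draws with 15 % CV on Feng and kinetic parameters. The true
  between-animal covariance is unknown; 15 % reproduces the order of
  the confidence intervals such studies report, and it is configurable.
* **Tissue defaults**: brain $K_1 = 0.24$, $k_2 = 0.43$, $k_3 = 0.05$,
  $k_4 = 0.004$/min, $v_B = 0.03$; myocardium $K_1 = 1.14$,
  $k_2 = 2.6$, $k_3 = 0.15$, $k_4 = 0.04$/min, $v_B = 0.15$ — reference
  mouse FDG values.

Two forward models are deliberately idealised so that the IDIF
construction has an exact inverse: the left ventricle is mixed in framed
space, $LV = RC \cdot blood + (1-RC) \cdot myocardium$, precisely the
spill model that `pvc_left_ventricle()` inverts; and the liver is a
scaled blood-pool copy ($0.6\times$ whole blood), which makes the
sample-scaled liver tail exact. Real livers add parenchymal uptake and
real LV spill is frame- and geometry-dependent, so passing the IDIF
inverse-property tests demonstrates the correctness of the composition
logic, not the biological fidelity of IDIFs. The simulator also works in
TAC space only — no voxels, no reconstruction correlations, no
scatter/randoms structure.

## IDIF construction

`build_idif()` uses the partial-volume-corrected LV before the hand-over
time and the blood-sample-scaled liver after it. The hand-over is the
post-peak maximum of the smoothed second difference of the LV curve
(3-frame moving average by default; the smoothing bandwidth is a free
choice, exposed as `smooth_window`). Second differences use the
non-uniform three-point formula since frame durations grow through the
scan. Ties resolve to the earliest frame. A relative discontinuity
larger than 15 % at the junction raises a QC warning.

## Curve features and the break point

Features are SUVmax, time-to-peak, FWHM (half-max crossings by linear
interpolation), and the AUC split at a break point defined from
derivative landmarks: the post-peak minimum of $c'$ (steepest descent),
the second positive peak of $c''$ (the concavity change at the end of
the peak; on idealised curves with a single positive post-peak maximum,
that one is used), and
$t_{break} = t_{infl} + (t_{infl} - t_{minslope})/2$. On parametric fits
the derivatives are analytic; on tabulated curves they are smoothed
finite differences (window 5 samples by default) — the landmark
positions, not the feature integrals, use the smoothed curve. For
$c(t) = t e^{-t}$ the landmarks are exactly $t = 2, 3$ and the break
$3.5$, which the tests verify together with the closed-form area split
($AUC_{tail} = 4.5 e^{-3.5}$).

## Kinetic modelling

The reversible 2TCM is solved analytically: the impulse response is a
sum of two exponentials with rates
$\alpha_{1,2} = \tfrac12\bigl(s \mp \sqrt{s^2 - 4 k_2 k_4}\bigr)$,
$s = k_2+k_3+k_4$, convolved with the plasma input by a recursion that
is exact for piecewise-linear inputs (implemented via a recursive filter,
so it runs at C speed; the same kernel primitive drives the dispersion
convolution). A generic stiff ODE integrator serves as the independent
oracle in the tests, not as the implementation. Rate constants are
per-minute (the field's convention) while curves run on a seconds axis;
the conversion happens once inside the forward model.

`fit_2tcm()` minimises duration-weighted least squares on frame-averaged
model curves, bounds $K_1, k_2, k_3, k_4 \in [0,5]$, $v_B \in [0,1]$,
five deterministic starts. Weighting by frame duration reflects counting
statistics; the true acquisition weights are scanner-specific.
Degenerate corners where $k_3 \approx 0$ and $k_4 \approx 0$ trade off
are handled in validation by asserting recovery of the macro-parameter
$K_i = K_1 k_3/(k_2+k_3)$ instead of the individual rates.

`fit_patlak()` regresses $C_T(t)/c_p(t)$ on
$\int_0^t c_p\,du / c_p(t)$ for frame mid-times past $t^\ast$ (default
600 s — the curves' late phase is well linear there; configurable). The
slope is reported per minute. For reversible tracers the slope
underestimates $K_i$, which the tests assert as a direction, not a bug.

## Repeated-injection correction

`correct_triple_injection()` follows the subtract-and-refit scheme: fit
the parametric model to the first segment, subtract its extrapolation
from the second segment before fitting that, subtract both from the
third, then align all three curves to the first injection time. Two
implementation decisions matter:

* A purely sequential pass cannot pin the slowest eigenvalue from one
  15-minute window, and the three overlapping tails are nearly
  collinear, so the tail split wanders even on noiseless data. By
  default the three models are therefore re-fitted *jointly* to the full
  calibrated trace with the washout eigenvalues shared across
  injections — within one animal and session the clearance eigenvalues
  belong to the tracer and physiology, not to the injection. Sharing
  them makes the split well-posed; amplitudes and onsets stay free.
* When the injection duration and dispersion constant are supplied, the
  joint fit runs through the measurement operator (see above), removing
  the model-mismatch freedom that otherwise leaks between components.

The triple-injection protocol simulates three 30 µl boluses 15 min
apart. The injection duration defaults to 9 s: the reference protocol
pushes 100 µl in 30 s (200 µl/min), and the same pump rate delivers
30 µl in 9 s; the calibration sample is drawn 10 min after each
injection from the *total* circulating concentration, as a real sample
would be.

## Statistics

Group comparisons use the Mann–Whitney U test (reported statistic
$U = \min(U_a, U_b)$ with midranks), exact by enumeration when
$n_a + n_b \le 16$ without ties — which covers the 4–9 animal groups
this design uses — and the tie/continuity-corrected normal approximation
otherwise. The p-value computation delegates to `stats::wilcox.test`
with the branch chosen by those rules; an independent full-enumeration
oracle in the test suite confirms equality on every size up to
$n_a = n_b = 8$. Summaries are mean ± t-based 95 % CI (the CI
construction is a choice; normal-based intervals differ only at these
small $n$). No multiplicity correction is applied: each comparison is
reported at its own $\alpha = 0.05$, matching the reporting style of
one-variable-at-a-time designs, and the package's null simulations
measure the per-test type-I error, not a family-wise one.

## Numerical choices and degenerate inputs

* Dense curves live on a regular 1 s grid; frames are half-open
  `[start, end)` intervals, and frame averages are exact trapezoidal
  time-averages, so AUC bookkeeping is consistent everywhere.
* All convolutions (dispersion, 2TCM exponentials, running integrals)
  use the piecewise-linear-exact recursion; the boxcar uses cumulative
  integrals, preserving area to rounding.
* Every stochastic operation is a pure function of `(inputs, seed)`
  via `withr::with_seed`; cohort and study drivers derive per-subject
  seeds deterministically from the top-level seed.
* Degenerate inputs fail loudly: overlapping frames, non-numeric cells
  (named row), flat curves offered to peak-based fits, zero traces at
  calibration times, monotone LV curves, sub-3-frame Patlak windows.
  Clipping only happens where it is physically motivated (negative
  excursions after dispersion correction), and it warns past 10 %.

## Validation scale

The test-suite and acceptance problems are sized for a single CPU:
cohorts of 9 subjects per group (the reference group size), 20 noise
replicates for kinetic recovery, 1000 replicate null cohorts for the
type-I check, 2731-point dense grids, 86-frame schedules. These sizes
were chosen as the smallest that exercise each property at its stated
tolerance.

## Known limitations

* The dispersion kernel is mono-exponential; real catheters show
  multi-exponential and flow-regime-dependent smearing.
* Plasma conversion defaults to a ratio of 1 (constant or user-supplied
  function); no metabolite correction is provided.
* The IDIF forward model is deliberately invertible (see above); the
  package does not claim IDIF fidelity on real image data beyond the
  composition logic.
* Decay correction is assumed already applied to all curves (flagged in
  `experiment_config()`); the package never applies decay factors
  itself.
* No voxelwise modelling, model selection, or population input
  functions.
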