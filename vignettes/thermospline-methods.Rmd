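---
title: "Methods: spline compression and neural-network quantification of thermally modulated gas-sensor sweeps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spline compression and neural-network quantification of thermally modulated gas-sensor sweeps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermospline)
```

## The measurement problem

A metal-oxide-semiconductor (MOS) chemiresistor responds to any reducing
gas: both ethanol and acetone lower its resistance, so a single reading at
one operating temperature cannot tell the two apart, let alone quantify a
mixture. Thermal modulation restores identifiability: ramping the
integrated heater voltage $V_H$ from 0 to 5 V sweeps the film through a
range of temperatures, and the output voltage recorded across a load
resistor in a voltage divider,

$$V_\mathrm{OUT}(V_H) = V_C \frac{R_L}{R_S(V_H) + R_L},$$

traces a temperature-indexed curve whose *shape* is gas-specific: on this
sensor the ethanol response rises earlier in the ramp while the acetone
response rises later but climbs to a higher peak. The package implements a
two-stage analysis of such sweeps:

1. **Compression.** Each 501-point sweep is approximated by a cubic
   least-squares B-spline whose knot vector is thinned by greedy backward
   elimination from 51 uniform knots down to 6; the 8 remaining
   control-point ordinates are the feature vector.
2. **Quantification.** A feed-forward network with 8 inputs, one hidden
   layer and 2 linear outputs maps the features to $\log_2$ analyte
   concentrations. The topology (hidden size 2–9, hidden activation linear,
   logistic, exponential or tanh) is chosen by a grid search with repeated
   random restarts, each network trained by BFGS on a sum-of-squares loss.

## The synthetic sweep generator

The experimental recordings this methodology was developed on are not
publicly deposited, so the package carries a forward model of the sensor
that emulates the study conditions and serves as the test bed. It is a
deliberately minimal phenomenological model, not a physical simulation of
the sensing film.

**Air baseline.** The film resistance in clean air falls with heater power;
we interpolate log-linearly between `r_air_high = 50` (cold heater) and
`r_air_low = 8` (full power), in units of the load resistance. These two
constants put the air sweep well below 1 V output across the whole ramp,
matching the qualitative position of an air trace under the single-gas
curves.

**Gas response.** Each gas divides the baseline by a logistic-gated
power-law term,

$$R_S(V_H) = \frac{R_\mathrm{air}(V_H)}
 {1 + \sum_g A_g \,\sigma\!\left(\frac{V_H - v_{\mathrm{on},g}}{w_g}\right)
 \left(\frac{c_g}{c_\mathrm{ref}}\right)^{\beta_g}},$$

with $\sigma$ the logistic function. The gate encodes the onset behaviour
(no response until the film is hot enough, then saturation), and the
power law with $\beta = 0.6$ gives the sub-linear growth with
concentration typical of MOS sensors. Shape constants are
$v_\mathrm{on} = 1.6$ V, $w = 0.5$ V for ethanol and $v_\mathrm{on} = 2.4$ V,
$w = 0.35$ V for acetone: ethanol rises first, acetone later and more
steeply, which is the qualitative single-gas phenomenology on this sensor.
This functional form guarantees three properties the analysis relies on:
the output voltage is bounded by the divider to $(0, V_C)$, it is monotone
increasing in each concentration at any fixed heater voltage, and the two
gases produce differently shaped curves.

**Calibration.** The two amplitudes $A_g$ are not hand-picked: they are
solved in closed form so that the noise-free single-gas sweep at the 0.5 %
reference concentration peaks at exactly the measured values, 4.65 V for
acetone and 4.13 V for ethanol. Because the baseline falls and the gate
opens monotonically along the ramp, $R_S$ is strictly decreasing in $V_H$
and the peak sits at the ramp end, where inverting the divider gives
$R_\mathrm{peak} = R_L (V_C - V_\mathrm{peak})/V_\mathrm{peak}$ and
$A = (R_\mathrm{air}(v_\mathrm{end})/R_\mathrm{peak} - 1)/\sigma((v_\mathrm{end}-v_\mathrm{on})/w)$.

**Design grid and noise.** The default dataset is the study design: all
13 × 13 combinations of the serial-dilution ladder
$2^{-7}, 2^{-6.5}, \dots, 2^{-1}$ % (78–5000 ppm), in triplicate, each sweep
sampled at 501 points on the 0–5 V ramp. Measurement noise is additive
Gaussian on the output voltage, clipped to the divider range. No noise
statistics were reported for the physical sensor; we use sd = 0.02 V, i.e.
about 0.4 % of full scale, a realistic magnitude for a benchtop
divider readout, and state it once here rather than tuning it. Per-sweep
seeds are derived from one master seed by integer hashing (kept below
$2^{31}$), so the full factorial is reproducible and any single sweep can
be regenerated in isolation.

**What the generator does not emulate.** Humidity, temperature drift,
hysteresis, sensor aging, headspace mass-transfer kinetics, and any
time-dependence of the film response (the ramp is represented by its
voltage grid only; the 0.5 V/min rate is metadata). Consequently, passing
the recovery tests below shows that the *algorithm* can invert its own
forward model under realistic noise — it does not certify performance on
physical recordings, whose disturbances are richer.

## Spline compression

The fit is a classical least-squares B-spline: for a fixed knot vector the
spline is linear in its control-point ordinates, so the coefficients solve
one QR least-squares problem per fit. Degree is fixed at 3 (cubic):
industry practice for smooth sensor curves, and the only degree for which
the 6-knot target yields exactly 8 coefficients
($|\mathrm{coefficients}| = \mathrm{interior} + \mathrm{degree} + 1$).
Boundary knots carry multiplicity 4 so the spline is unconstrained at the
endpoints.

Elimination starts from 51 knots (49 interior, every 0.1 V) and repeats:
refit once per interior knot with that knot deleted, permanently remove the
knot whose deletion increases the sum of squared residuals least, refit,
and continue until six knots remain. Because deleting a knot restricts the
spline space to a subspace, the error path is provably non-decreasing —
asserted along every elimination in the tests, together with agreement of
the greedy step with an exhaustive single-removal oracle on small
instances. Ties in the removal criterion are broken towards the leftmost
candidate; the criterion itself is the post-refit SSE (the error measure
was otherwise unspecified, and SSE is the quantity the fit minimizes).

Two open choices were resolved as follows. First, the feature vector is
the 8 coefficient *ordinates*, not 8 (x, y) pairs: the quantification
network has exactly 8 input neurons, and the abscissae (Greville points)
are determined by the knots, so they carry no independent information once
knots are fixed. Second, elimination runs independently per sweep by
default, which mirrors reading the control points off each experimental
waveform separately; a `shared_knots` mode is provided that selects one
consensus knot vector minimizing the summed SSE over a calibration set,
for users who prefer a feature space with identical abscissae across
sweeps. On the synthetic data the per-sweep default is already sufficient
for near-perfect recovery, so consistency was not forced.

A regression guard (not a claim about the physical study) checks that the
6-knot fit's RMS residual stays below 5× the simulated noise sd: the
compression should discard noise, not signal.

## Network training and topology search

Targets are $\log_2$ concentrations in percent, so the serial-dilution
ladder becomes the uniform grid $-7, -6.5, \dots, -1$ and a given absolute
error means the same relative concentration error everywhere in the range.
Samples are split 70/15/15 into learning/test/validation subsets by a
seeded permutation (169 samples → 119/25/25); floor rounding on the test
and validation counts, remainder to learning.

Inputs are standardized with learning-subset means and standard
deviations; targets are mapped per-output to $[-1, 1]$ using the
learning-subset range. Both are required for the saturating activations to
operate in their useful region. Weights initialize uniform
$(-0.5, 0.5)/\sqrt{\mathrm{fan\,in}}$ from a restart-specific seed.
Training minimizes the sum of squared errors over the learning subset with
BFGS (`stats::optim`), using analytic gradients (verified against finite
differences in the tests). The "exponential" hidden activation is
$e^{-x}$, a bounded-below convention common in classical neural-network
toolboxes. Output neurons are always linear.

The test subset monitors training: every weight vector evaluated during
optimization is scored on the test subset and the snapshot with the lowest
test error is returned, an early-stopping variant that matches the test
set's stated role of verifying operation *during* learning. Reported
errors are mean squared error per sample per output on the scaled-target
scale; this is an internal, relative measure whose normalization differs
between toolboxes, so absolute comparisons of these error numbers across
software are not claimed.

The grid search trains `restarts` networks in every (hidden size,
activation) cell and selects the global minimum-validation-error network.
The desk default is 20 restarts (640 networks, about a minute on one CPU);
`restarts = 1000` reproduces the full 32,000-network search. An optional
parsimony rule (`prefer_smallest_within`) selects the smallest hidden
layer whose best validation error is within a tolerance of the global
minimum, for users who want the simplest adequate topology rather than
the raw argmin; it is off by default so that selection is purely
validation-driven.

## Evaluation

MAE $= \frac1n \sum |C_E - C_M|$ and RMSE $= \sqrt{\frac1n \sum (C_E - C_M)^2}$
are computed on the linear concentration scale in percent (the scale on
which the quantities are reported), per analyte and per subset, together
with $R^2 = 1 - SS_\mathrm{res}/SS_\mathrm{tot}$; the same metrics on the
$\log_2$ scale are emitted as secondary columns since that is the scale
the network is trained on. RMSE ≥ MAE holds on every cell by the
power-mean inequality and is asserted throughout. $R^2$ is undefined for a
constant reference vector and is flagged `NA` with a warning.

## Numerical choices and degenerate inputs

* Rank-deficient spline designs (an interior knot span containing no data)
  abort the fit with the offending span named, rather than silently
  dropping basis functions.
* `initial_knot_vector` uses a small tolerance when counting interior
  knots so a spacing that divides the domain exactly (0.1 into 5.0) is not
  corrupted by floating-point drift; spacing at least the domain width
  degenerates to endpoints only.
* Zero concentrations are legal in the simulator (air and single-gas
  sweeps) but illegal as network targets ($\log_2 0$); the factorial
  generator therefore uses the strictly positive dilution ladder.
* A non-finite training loss marks the restart failed; failed restarts are
  excluded from cell statistics and a cell with no survivors is excluded
  from selection.
* Simulated output voltages are clipped to $[0, V_C]$ after noise, as a
  real divider readout cannot leave that range.

## Problem sizes used in the shipped experiments

The shipped tests run the full 169-sweep factorial (single replicate) for
the recovery experiments — compression of 2 × 169 sweeps and two
640-network grid searches, a few minutes on one CPU — and small 3 × 3
grids for the pipeline plumbing tests. The recovery criteria are:
validation $R^2 > 0.99$ for both analytes on noise-free data (features
determine concentrations by construction, so failure would indicate an
implementation defect), $R^2 > 0.9$ at 0.02 V noise, and mean validation
error of linear-activation cells exceeding that of tanh cells, the
qualitative topology-search pattern.

## Known limitations

* The forward model is phenomenological; its shape constants were chosen
  once for qualitative fidelity (onset order, peak heights, bounded
  monotone response) and the peak calibration pins only two points of the
  curve family. Real sweeps contain structure (drift, humidity response,
  kinetic asymmetry) the model does not generate.
* Per-sweep knot elimination means feature $k$ does not correspond to the
  same abscissa in every sweep; the network tolerates this on synthetic
  data, but `shared_knots` may be preferable on noisier material.
* The greedy elimination is locally optimal per step only; it does not
  search over knot subsets globally.
* Scaled-target training errors are not comparable across datasets with
  different target ranges.
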