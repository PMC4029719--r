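---
title: "Methods: decoding elbow angle from surface EMG and driving a pneumatic-muscle pair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decoding elbow angle from surface EMG and driving a pneumatic-muscle pair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promyo)
```

## Overview

`promyo` implements a proportional myoelectric control loop for a one
degree-of-freedom elbow exoskeleton driven by an antagonistic pair of
McKibben pneumatic muscles. Four surface-EMG channels (biceps brachii and
brachioradialis as flexion agonist/synergist; triceps brachii and anconeus
for extension) are conditioned and windowed into RMS features, a small
back-propagation network decodes the elbow angle, and the angle is
inverted through the actuator model into a differential-pressure / valve-
voltage command. Because no recordings for this protocol are publicly
deposited, the package also defines a synthetic world — a seeded generator
of EMG + angle trials — against which every stage is tested.

This vignette records the models, the tunable parameters and why their
defaults are what they are, and the design decisions taken where the
problem statement was genuinely open.

## The signal chain

Raw EMG sampled at 1,024 Hz passes, per channel and strictly causally:

1. high-pass, 4th-order Butterworth, 50 Hz cutoff (motion artifact and
   baseline removal);
2. full-wave rectification;
3. low-pass, 4th-order Butterworth, 10 Hz cutoff (amplitude envelope);
4. overlapped windows of 200 ms advancing by 50 ms; per window and muscle
   the RMS $\sqrt{\tfrac1N \sum_i v_i^2}$.

**Causality.** The controller runs in real time, so the offline pipeline
uses the identical forward-only filters with zero initial state; training
and deployment therefore see the same features. The price is a startup
transient (about three low-pass time constants, ~50 ms) and an envelope
group delay of a few tens of milliseconds, which becomes part of the
decoding problem. Whether an offline zero-phase variant was ever used for
analysis in comparable studies is usually unstated; causal everywhere is
the conservative choice.

**Window step.** Only "overlapped windowing" with a 200 ms window and a
sub-300 ms total latency budget is prescribed anywhere; the default step
of 50 ms (75% overlap) keeps a fresh command every 50 ms within that
budget and is configurable. Trailing partial windows are dropped rather
than zero-padded: a streaming controller never has future samples to pad
with.

**Filter design.** No signal-processing package is assumed; coefficients
come from the analog Butterworth prototype via bilinear transform with
frequency pre-warping, so the response at the design frequency is exactly
$1/\sqrt2$. The test suite pins the coefficients against an independently
computed reference design and checks stability and DC behaviour.

## The decoder

A 4-3-1 network: four RMS inputs, three hidden sigmoid units, one sigmoid
output. Three hidden nodes keep the hidden layer smaller than the input
layer (an over-training guard for so small a feature space).

Choices the architecture statement leaves open, and what this package
does:

* **Biases** are included in both layers. A bias-free sigmoid output
  cannot produce angle 0 at zero input; this is a documented deviation
  from the textbook weighted-sum-only formulation.
* **Scaling.** Inputs are min-max scaled to $[0,1]$ on the *training*
  features only; the target angle maps affinely from $[0°, 90°]$ onto
  $[0.05, 0.95]$ because a sigmoid cannot reach its asymptotes — the
  margin keeps extreme targets off the saturated tail.
* **Loss and optimizer.** Mean squared error of the scaled output under
  plain full-batch gradient descent — the simplest faithful
  back-propagation. Defaults: learning rate 2, at most 3,000 epochs,
  stop when the epoch improvement falls below $10^{-8}$. A smaller rate
  (0.5) with 2,000 epochs was evaluated first and demonstrably stops
  short of convergence (final training loss 0.0090 vs 0.0084 converged);
  the default was raised on that training-loss evidence alone.
  Multi-start training was evaluated and rejected: random inits all reach
  the same plateau, so restarts buy nothing.
* **Analytic gradients** are verified against central finite differences
  on random instances (worst relative error below $10^{-6}$).

Data splitting is at **whole-trial granularity**: 60 movement sets split
80/20 into 48 training and 12 testing trials. Window-level splitting
would leak temporally correlated windows of the same movement across the
split and overstate performance.

## The actuator model

A McKibben muscle of initial diameter $D_0 = 20$ mm and braiding angle
$\theta_0 = 25°$ produces
$F = P\,[a(1-\varepsilon)^2 - b]$ with
$a = 3\pi D_0^2/(4\tan^2\theta_0)$, $b = \pi D_0^2/(4\sin^2\theta_0)$;
force vanishes at $\varepsilon^\ast = 1 - 1/(\sqrt3\cos\theta_0) \approx
0.363$. Two such muscles on a joint axis of radius $R = 0.03$ m, with
initial contraction $\varepsilon_0$ at base pressure $P_0$, satisfy
$\varepsilon_{a,b} = \varepsilon_0 \pm \theta_2 \pi R/(180 L_0)$; the
differential-pressure inversion

$$\Delta P = \frac{F_a}{2[a(1-\varepsilon_a)^2-b]} -
             \frac{F_b}{2[a(1-\varepsilon_b)^2-b]}$$

is the exact algebraic inverse of the forward force pair, which the tests
check to $10^{-9}$ relative over 1,000 random admissible states.

**Unstated constants.** $L_0$, $\varepsilon_0$ and $P_0$ are never given
numerically in the hardware description. Defaults $L_0 = 0.40$ m,
$\varepsilon_0 = 0.125$, $P_0 = 0.3$ MPa were chosen once so the full
0-90° range is reachable inside the 25% maximum contraction and the
0.6 MPa ceiling: at 90° the pair sits at contractions 0.2428 / 0.0072.

**Force closure.** The inversion needs a force *pair*, but nothing ties
the pair to a torque model. Default closure: the antagonist keeps the
force it would produce at base pressure at its new length, and the
agonist balances it plus the gravity torque $mgl\sin\theta_2$ of the 1-kg
load at $l = 0.25$ m. Under this closure the required $\Delta P$ is
monotone in angle but **saturates** near full flexion at the default
$P_0$ (absolute pressure would exceed the ceiling); the streaming path
clamps (a real-time loop must degrade gracefully, and the clamp keeps
monotonicity), while `clamp = FALSE` raises a hard error for offline use.
An alternative `"symmetric"` closure (constant total force $2F_0$, the
force *difference* supplies the torque) stays inside the envelope over
the whole range.

**Valve map.** The pressure-to-voltage relationship is hardware-specific
and undocumented; the default is affine over the symmetric headroom onto
0-10 V with 5 V at $\Delta P = 0$, and a monotone calibration table can
be supplied.

## The synthetic world

Each trial is one flexion-extension cycle
$\theta_2(t) = 45(1 - \cos 2\pi t/T)$ at period $T \in \{2, 4, 8\}$ s —
smooth, 0-90°, with acceleration scaling as $1/T^2$. Activation
envelopes in $[0,1]$ drive band-limited carriers:

* **Flexor drive** $= k_{vel}\max(\dot\theta,0)/\dot\theta_{ref} +
  k_{load}\sin(\theta_2)\,m$; extensors mirror with
  $\max(-\dot\theta,0)$; synergists are scaled by 0.6.
* **Carrier**: white Gaussian noise band-passed to 20-500 Hz, unit
  variance, scaled by the envelope and an 800 µV amplitude, clipped at
  the 1,600 µV sensor ceiling.

**Why load-dominated.** At 2-8 s periods the gravity torque of the 1-kg
load exceeds the inertial torque roughly tenfold, so the flexor envelope
must track $\sin\theta_2$ with only a modest velocity modulation
($k_{load} = 0.65$ per kg, $k_{vel} = 0.15$ of the 4-s peak velocity).
This is also what makes the decoding problem well posed: during
development an early velocity-dominated parameterization was shown to
make the angle *non-identifiable* from instantaneous features (even a
50×50-unit oracle network capped at $R^2 \approx 0.29$), because
flexor-minus-extensor activation is then non-injective in angle. A
load-dominated envelope is both the physically right regime and the one
in which an EMG-angle decoder can work at all.

**Period-dependent degradations** are deliberately built in, separately
switchable, and stochastic:

* `k_accel_distort` (default 0.03): each channel receives an independent
  slowly varying zero-mean modulation whose instantaneous SD is
  proportional to $|\ddot\theta|$, normalized to the 4-s peak — a 2-s
  trial sees 4× the 4-s level. Rapid movements are modeled as *noisier*,
  not merely stronger: a deterministic acceleration term was tried first
  and rejected because, being a function of movement phase shared across
  channels, it *informed* the decoder instead of degrading it (2-s trials
  came out easiest, inverting the intended ordering).
* `k_drift` (default 0.04): independent per-channel random walks with
  variance growing linearly in elapsed time — the longer the period, the
  larger the accumulated wander (emulating the inability to hold a
  constant slow speed). A walk shared across channels would cancel in
  flexor-minus-extensor contrasts, hence per-channel.

With these defaults the 4-s condition is the mild-noise reference and the
held-out decoder lands at RMSE ≈ 9.5-10.1°, $R^2$ ≈ 0.89-0.91 over master
seeds 1-5, with the 2-s and 8-s conditions clearly worse — the same
performance scale and the same period ordering as the motivating
single-subject experiment, *by construction*, not as an independent
reproduction. The distortion gains were frozen after a noise-budget
analysis (decoding floor ≈ 7.6° from carrier noise, causal-chain lag and
4-3-1 capacity; distortions sized so 2-s and 8-s separate from 4-s) and
are not meaningful beyond that role.

**What the generator does not emulate:** motor-unit statistics,
electrode crosstalk, fatigue-induced spectral shifts, impedance changes,
day-to-day electrode placement variability. A green test therefore
establishes that the *pipeline* is correct and that decoding succeeds in
a world with the stated structure — not that any particular human subject
would yield these numbers.

## The controller

Per 200 ms window: four-channel RMS → noise gate → prediction → clamp to
[0°, 90°] → pressure command. The gate passes when *any* channel's RMS
reaches the threshold (any active muscle indicates movement onset; ties
pass), and a gated tick outputs a voltage of exactly 0 — bit-exact, which
the acceptance suite asserts. No threshold value is prescribed anywhere;
`calibrate_threshold()` implements the conventional choice of 3× the
rest-segment RMS. Predicted angles are clamped before actuation because
the inverse angle scaler can step slightly outside its margins.

## Numerical and degenerate-input policy

* Filters: zero initial conditions; inputs must be finite; signals
  shorter than three filter orders are rejected.
* RMS windows: traces shorter than one window raise an error in the
  feature path but are skipped (with a warning count) when building
  datasets from trial collections.
* Training: non-finite loss aborts with the epoch number; learning rate
  must be positive; a zero-variance feature maps to the scaler constant 0.
* Statistics: $R^2$ and the regression line refuse zero-variance inputs
  rather than returning NaN.
* Determinism: every stochastic step (trial carriers, envelope noise,
  session seeds, split, init) is seeded; per-trial seeds derive from the
  master seed by a counter scheme below $2^{31}$.

## Known limitations

* The force closure is an assumption layered on the actuator algebra; the
  published hardware description does not determine it, and the default
  closure saturates near full flexion at the default base pressure.
* Pneumatic dynamics (flow, valve lag, hysteresis), joint inertia and the
  exoskeleton's own weight are out of scope; the command is quasi-static.
* The decoder capacity (three hidden units) and the causal-chain lag set
  a floor of roughly 7-8° RMSE in the synthetic world even with all
  degradations off; larger networks or anti-causal filtering would lower
  it but would no longer be the method under study.
* Synthetic acceptance thresholds (held-out $R^2 \ge 0.85$, RMSE
  $\le 10°$ at the 4-s period) are statements about the stated world and
  its seeds, not about human data.
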