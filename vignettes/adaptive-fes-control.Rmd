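---
title: "Adaptive reflexive control of multichannel FES: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive reflexive control of multichannel FES: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reflexfes)
```

## The control problem

Functional electrical stimulation (FES) walking assistance applies low-energy
current pulses to leg muscles so that their contractions support the wearer's
own gait. A *reflexive* controller does not track a reference joint
trajectory; it maps discrete gait events to stimulation bursts, the way
spinal reflexes couple foot contact to muscle activity. Four muscles per leg
are stimulated: tibialis anterior (TA, ankle dorsiflexion), lateral
gastrocnemius (LG, ankle push-off), biceps femoris (BF, knee flexion / hip
extension) and rectus femoris (RF, knee extension / hip flexion) — eight
channels in total.

`reflexfes` implements this controller as a hardware-free toolkit with three
layers plus a synthetic gait generator:

1. **Gait phase detection** (`detect_stream()`): binarizes heel/toe insole
   forces and the sagittal shank angle and runs an IF-THEN finite state
   machine over the bits.
2. **Reflexive stimulation** (`reflexive_stimulation()`,
   `controller_tick()`): convolves the gait-event impulses with normalized
   impulse-response envelopes, gated by the current gait phase.
3. **Iterative learning adaptation** (`adaptive_state()`, `record_cycle()`):
   nudges each channel's envelope time coefficient and the LG pulse width
   once per gait cycle, from the deviation of per-cycle feedback against its
   five-cycle history.

## The stimulation envelope

Each burst follows the impulse response

$$H(t) = g\,\frac{1}{\tau}\,e^{-1.5\,t/\tau}\,\sin\!\left(\frac{3t}{2\tau}\right),$$

a second-order low-pass (Bessel-type) form whose time coefficient $\tau$
(seconds) sets the burst profile; the associated cut-off frequency is
$f_c = 1/(2\pi\tau)$. The gain $g$ normalizes the peak to exactly 1, so the
envelope maps linearly onto the calibrated current range: the commanded
amplitude of a gated channel is $\Delta c \cdot H(t - t_{\mathrm{impulse}}) +
C_{\min}$ with $\Delta c = C_{\max} - C_{\min}$, where $C_{\min}$ is the
smallest current producing a visible contraction and $C_{\max}$ the largest
comfortable one (both measured per participant and supplied as
configuration).

Three analytic identities drive the implementation, all exposed as
functions:

* the peak sits at $t_{\mathrm{peak}} = \pi\tau/6$ (`peak_time()`), where
  $\tan(1.5t/\tau) = 1$;
* the normalizing gain is $g = \tau\sqrt{2}\,e^{\pi/4}$
  (`normalizing_gain()`), obtained by solving $H(t_{\mathrm{peak}}) = 1$;
* the first post-peak zero crossing is at $2\pi\tau/3$
  (`activation_duration()`).

The response time is therefore exactly one-fourth of the activation time for
every $\tau$ — the ratio that motivates the 0.04 s update dead zone below.

**Truncation.** The printed sinusoid goes negative after $2\pi\tau/3$;
negative current commands are meaningless, and amplitudes below $C_{\min}$
produce no visible contraction. `impulse_response()` therefore returns 0
beyond the first post-peak zero crossing, which makes every burst a single
positive lobe.

**Restart, not superposition.** If a new qualifying impulse arrives while a
branch's envelope is still active, the branch clock restarts rather than
summing envelopes. The branches are gated by mutually exclusive phases and
the command must never exceed $C_{\max}$; restart satisfies both by
construction (amplitudes are additionally clamped to $[0, C_{\max}]$, with
clamping observable in the trace).

## Phase detection

Two binary contact signals $S_H$ (heel) and $S_T$ (toe) are derived by
**relative hysteresis**: a sensor switches on when its force exceeds
$\theta_{on} = 0.20$ of an exponentially decayed running maximum and off
below $\theta_{off} = 0.10$ of it (decay horizon about three nominal
cycles). Thresholds relative to a running maximum make the bits invariant
under rescaling of the force units and robust to slow drift; the specific
algorithm is this package's choice, as only the existence of an adaptive
threshold is prescribed by the control scheme. A third bit $S_\phi$ flags
the sagittal shank angle $\phi_S$ reaching the sagittal threshold angle
(default 15°, configurable); it is only interpreted during swing. Edges
must persist for 2 samples (20 ms at the default 100 Hz) to be accepted —
force-sensing resistors chatter — and an accepted edge keeps the time of its
first sample, so the confirmation delay does not bias event times.

The FSM emits five events and four controller impulses:

| transition (previous → current bits) | phase | impulse | event |
|---|---|---|---|
| $S_H=S_T=0$ → any contact | LR | $I_{LR}$ | HS |
| both in contact ≥ 50 ms (debounce) | ST | — | FF |
| $S_H=S_T=1$ → $S_H=0, S_T=1$ | PS | $I_{PS}$ | HO |
| any contact → $S_H=S_T=0$ | SW | $I_{SW}$ | TO |
| swing, $S_\phi: 0 \to 1$ (armed) | TSW | $I_{TSW}$ | STA |

Initial contact by *any* foot part starts load response, so forefoot-first
(pathological) gait is detected; cycle boundaries prefer heel-first strikes
and fall back to any-contact strikes when none occur. Unexpected bit
patterns never error — the current phase is simply held.

Two behaviours are deliberately stricter than the transition table alone:

* **STA arming.** The $S_\phi$ rising edge only counts after the angle has
  been observed *below* threshold within the current swing, and at most once
  per swing. Without arming, a toe-off angle above the threshold (common at
  higher speeds) would trigger terminal swing immediately at swing onset.
* **Foot flat.** No printed impulse ends load response; LR ends once both
  sensors have been in continuous contact for 50 ms, which defines the FF
  event.

## Channel wiring and gating

| channel | trigger(s) | gate on during |
|---|---|---|
| TA | $I_{SW}$ | SW, TSW |
| LG | $I_{LR}$; $I_{PS}$ | LR; PS |
| BF | $I_{SW}$ | SW, TSW |
| RF | $I_{LR}$; $I_{TSW}$ | LR; TSW |

With a gate on but no active envelope a channel rests at $C_{\min}$; with
all gates off it outputs 0. LG and RF each produce two bursts per cycle
(their two branches), TA and BF one. The printed TA equation carries an
LR-subscripted envelope convolved with $I_{SW}$; the package treats the
subscript as a labelling slip and triggers TA from $I_{SW}$, which is the
only reading consistent with TA's swing gate. Likewise, TA/BF/RF activity in
terminal swing arises from gates staying on, not from an $I_{TSW}$ term in
their equations.

## Iterative learning updates

Per gait cycle (heel strike to next heel strike of the same foot) two
feedback quantities are measured from the commanded trace:

* $t_s$, the stimulation time of each channel: total time its amplitude
  exceeds $C_{\min}$ (gate on *and* envelope positive);
* $\phi_{TO}$, the raw shank angle at the detected toe-off.

Each is compared against the mean of the previous **five** cycles, and the
parameters step by a fixed amount outside a dead zone:

$$\tau(n{+}1) = \begin{cases} \tau(n) + L & \Delta t < -0.04\,\mathrm{s} \\
\tau(n) - L & \Delta t > 0.04\,\mathrm{s} \\ \tau(n) & \text{otherwise}
\end{cases} \qquad
PW(n{+}1) = \begin{cases} PW(n) + L_{PW} & \Delta\phi_{TO} < -2° \\
PW(n) - L_{PW} & \Delta\phi_{TO} > 2° \\ PW(n) & \text{otherwise}
\end{cases}$$

with $L = 0.01$, $L_{PW} = 20\,\mu s$, $\tau \in [0.01, 1]$ s and
$PW \in [250, 500]\,\mu s$ (LG only; other channels keep a fixed pulse
width, default 300 µs). The dead-zone comparisons are strict, exactly as
printed: a deviation equal to the threshold is a no-op. After every change
of $\tau$ the channel's cut-off frequency is available via
`cutoff_frequency()`.

Decisions the update law leaves open, resolved here:

* **Warm-up.** No updates until the buffer holds five complete cycles; the
  first adapted cycle is the sixth. The current cycle enters the buffer
  *after* the comparison, so the history is strictly the previous five.
* **Initial values.** $\tau = 0.1$ s and $PW_{LG} = 300\,\mu s$ for all
  channels, configurable; no initial values are prescribed by the control
  scheme.
* **Update direction.** As printed, a shorter-than-average stimulation time
  *lengthens* the envelope ($\tau{+}L$). Whether that is the intended sign
  depends on whether $t_s$ means delivered burst duration or available phase
  duration, which is ambiguous; `adaptive_state(flip_tau_sign = TRUE)`
  selects the opposite convention without changing anything else. The
  default is the printed rule.
* Channel updates are independent; permuting their order cannot change the
  result (property-tested).

## The synthetic gait generator

`generate_protocol()` emulates a treadmill session of the standard
speed-ramp design: 1.0 → 2.0 km/h and back in 0.2 km/h steps, 15 cycles per
visited level — 11 visited levels, 165 cycles per leg. What it generates,
and the defaults chosen where the protocol prescribes none:

* **Cadence.** Cycle duration falls linearly with belt speed, 1.4 s at
  1.0 km/h to 1.0 s at 2.0 km/h — slow-walking durations typical of
  treadmill work at these speeds; configurable via `cycle_duration_fn`.
* **Phase schedule.** LR 10%, ST 30%, PS 10%, SW 37%, TSW 13% of the cycle,
  standard able-bodied proportions with stance ≈ 50% including the
  double-support sub-phases; configurable.
* **Contact forces.** Heel plateau over LR+ST, toe plateau ending at
  toe-off. Toe contact starts 50 ms before the LR/ST boundary so that the
  detector's foot-flat debounce completes exactly at the scheduled boundary
  — the generator and detector agree on FF by construction.
* **Shank angle.** A piecewise-linear knot trajectory: 20° at heel strike,
  $\phi_{TO}$ at toe-off, a mid-swing dip to 0°, an upward crossing of the
  sagittal threshold exactly at the terminal-swing boundary, and back to
  20°. $\phi_{TO}$ follows the speed map $10 + 15(v-1)$ degrees (10–25° over
  the ramp), so speed transitions move $\phi_{TO}$ by 3° — clearly across
  the 2° dead zone — while cycles within a level sit inside it.
* **Noise.** Additive Gaussian noise on forces and angle, default off; the
  labelled-truth guarantees below are stated for the noise-free generator.
* The right leg runs half a cycle behind the left; legs are processed as
  independent state machines.

On noise-free output the FSM provably recovers every scheduled event within
one sample period (events are grid-aligned up to rounding), which the test
suite asserts for full 165-cycle sessions: 100% recall for all five event
kinds at a 50 ms matching tolerance and mean latencies below 10 ms at
100 Hz.

**What passing these tests does and does not show.** The generator produces
idealized plateaus, a piecewise-linear angle and stationary noise. It does
not emulate FSR creep, partial foot contact, spasticity, step-to-step
variability of phase fractions, or any musculoskeletal response to the
stimulation — the loop is open on the plant side: stimulation does not
change the next cycle's kinematics. Perfect detection and clean adaptation
trajectories here therefore validate the *algorithms*, not their clinical
performance; human joint-kinematics outcomes are outside this package's
scope.

## Numerical choices and degenerate inputs

* Envelope truncation happens at the analytic zero crossing; sampled traces
  resolve it to within half a sample period.
* The running-maximum seed comes from the first nominal cycle of data (or
  explicit seeds via `binarize_state()`); an all-zero stream keeps a tiny
  floor value so no bit ever turns on and no event is emitted.
* Streams shorter than one cycle yield an empty cycle list, not an error.
* `measure_stimulation_time()` uses a strict comparison with a 1 nA guard
  band, so resting exactly at $C_{\min}$ never counts as stimulation.
* Event matching in `evaluate_detection()` is greedy one-to-one per kind in
  time order (nearest unmatched detection within tolerance); accuracy is
  per-event recall — the natural denominator for event detection — and is
  reported as `NA` when a kind has no truth events.
* Dead-zone boundaries compare with strict inequalities on doubles; the
  tests exercise the boundary with exactly representable values.

## Problem sizes in the test suite

The suite generates everything at run time: full 165-cycle two-leg sessions
(~20 000 samples per leg at 100 Hz) for the detection checks, 10-second
random impulse/phase instances for the controller-vs-oracle comparison
(maximum absolute deviation below $10^{-9}$ mA against an independent
per-sample brute-force scan), and several hundred randomized learning
cycles for the bounds fuzzing. The whole suite runs in well under a minute
on one core.

## Limitations

* No plant: stimulation has no effect on the generated kinematics, so
  closed-loop *convergence* of the learning layer can only be studied
  against scripted feedback, not emergent gait changes.
* The $\tau$ update direction ambiguity is surfaced, not resolved (see
  `flip_tau_sign`).
* Pulse-level waveform synthesis (biphasic pulses, stimulation frequency
  scheduling) and stimulator transport protocols are out of scope; commands
  are amplitude samples at the sensor rate.
* Statistical comparison utilities summarize synthetic runs only and do not
  reproduce human-subject results.
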