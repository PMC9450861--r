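# reflexfes

Adaptive reflexive control of multichannel functional electrical
stimulation (FES) for walking assistance — as a hardware-free R toolkit.

FES neuroprostheses assist gait by delivering current pulses to leg muscles
in time with the wearer's own walking. A *reflexive* controller maps
discrete gait events to stimulation bursts instead of tracking joint
trajectories: heel strike, heel off, toe off and a terminal-swing shank
angle crossing each trigger envelopes on the muscles they reflexively
recruit (tibialis anterior, lateral gastrocnemius, biceps femoris, rectus
femoris — both legs, eight channels). `reflexfes` implements that controller
end to end, for control engineers and neurorehabilitation researchers who
want to develop and test the algorithms without a stimulator, insoles or an
IMU in the loop:

* **Gait phase detection** — relative-hysteresis binarization of heel/toe
  force and shank angle, plus an IF-THEN finite state machine over the
  binary signals yielding five phases (LR, ST, PS, SW, TSW), five events
  (HS, FF, HO, TO, STA) and the four controller impulses.
* **Reflexive controller** — each channel's amplitude is
  `(Δc · H(t − t_impulse) + C_min) · S(phase)`, where
  `H(t) = g (1/τ) exp(−1.5 t/τ) sin(3t/(2τ))` is a peak-normalized
  second-order low-pass impulse response (truncated to its first positive
  lobe), `Δc = C_max − C_min` spans the per-muscle calibrated current range,
  and `S` is the phase gate.
* **Iterative learning adaptation** — once per gait cycle, each channel's
  time coefficient τ steps by `L = 0.01` when its stimulation time deviates
  from the previous-five-cycle mean by more than 0.04 s (clamped to
  `[0.01, 1]` s; cut-off frequency `f_c = 1/(2πτ)`), and the LG pulse width
  steps by `L_PW = 20 µs` when the toe-off shank angle deviates by more than
  2° (clamped to `[250, 500] µs`).
* **Synthetic treadmill sessions** — a labeled gait generator covering the
  standard 1.0 → 2.0 → 1.0 km/h ramp (0.2 km/h steps, 15 cycles per visited
  level, 165 cycles per leg), so every layer is testable against ground
  truth.

See the methods vignette (`vignettes/adaptive-fes-control.Rmd`) for the
models, the tunable parameters and the design decisions.

## Worked example

```r
library(reflexfes)

session <- generate_protocol(
  speed_protocol(start = 1.0, stop = 2.0, step = 0.2, cycles_per_level = 15),
  seed = 1)
session
#> Synthetic treadmill session: 1.0 -> 2.0 -> 1.0 km/h (step 0.2), 15 cycles/level
#>   11 visited speed levels, 165 gait cycles per leg, 20160 samples/leg at 100 Hz
#>   noise sd: force 0, angle 0 deg

run <- closed_loop_run(session)          # detect -> stimulate -> adapt
run
#> Closed-loop FES run (adaptive reflexive): 165 gait cycles per leg
#>   left event detection: 100.0% recall, mean |latency| 1.7 ms
#>   right event detection: 100.0% recall, mean |latency| 1.7 ms
#>   final parameters:
#> Adaptive FES state after 330 recorded cycle(s)
#>   tau (s): left.TA=0.1, left.LG=0.1, left.BF=0.1, left.RF=0.1, right.TA=0.1, ...
#>   LG pulse width (us): left=450, right=450

summary(run)$by_level
#>    level speed n_cycles mean_t_s mean_tau  mean_pw
#> 1      1   1.0       15   0.2400      0.1 300.0000
#> 2      2   1.2       15   0.2350      0.1 264.0000
#> 3      3   1.4       15   0.2250      0.1 250.6667
#> 4      4   1.6       15   0.2150      0.1 250.0000
#> 5      5   1.8       15   0.2050      0.1 250.0000
#> 6      6   2.0       15   0.1975      0.1 250.0000
#> 7      7   1.8       15   0.2050      0.1 286.0000
#> 8      8   1.6       15   0.2150      0.1 326.0000
#> 9      9   1.4       15   0.2250      0.1 366.0000
#> 10    10   1.2       15   0.2350      0.1 406.0000
#> 11    11   1.0       15   0.2400      0.1 446.0000
```

Reading the output: event detection on the noise-free streams is perfect
(100% recall within a 50 ms tolerance, latencies well under one 10 ms
sample). Per-channel stimulation time (`mean_t_s`) shortens as the belt
speeds up — at the default τ the bursts are envelope-limited, so the
deviations stay inside the 0.04 s dead zone and τ holds at 0.1 s. The
toe-off shank angle, however, rises 3° per speed step, so the pulse-width
rule narrows the LG pulses on the way up (clamping at the 250 µs floor) and
widens them again on the way down — the per-cycle trajectories are in
`run$adaptation`, and `plot(run)` draws the stimulation bursts and the
parameter trajectories.

The detection layer can also be run alone:

```r
det <- detect_stream(session$streams$left)
evaluate_detection(det$events, session$truth$left$events, tol = 0.05)
#>   kind n_truth n_detected n_matched accuracy_pct mean_latency_ms
#> 1   HS     166        166       166          100        0.000000
#> 2   FF     165        165       165          100        3.636364
#> 3   HO     165        165       165          100        3.636364
#> 4   TO     165        165       165          100        0.000000
#> 5  STA     165        165       165          100        1.090909
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/fes.R` (subcommands `simulate`, `detect`, `control`,
`run-closed-loop`, `evaluate`, `normalize`).

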