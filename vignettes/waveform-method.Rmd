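---
title: "The waveform method: models, rules and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The waveform method: models, rules and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventwave)
```

## The physiological model

Everything in this package rests on one observation: a relaxed
respiratory system empties (or fills) through its resistance, so its
flow decays exponentially with the time constant `tau = R * C` of the
single-compartment equation of motion

```
Paw(t) + Pmus(t) = R * flow(t) + V(t)/C + PEEP
```

where `Paw` is airway pressure (cmH2O), `Pmus` the pressure generated
by the inspiratory muscles (cmH2O, applied as a negative pleural
swing), `R` resistance (cmH2O s/L), `C` compliance (L/cmH2O), `V`
volume above the relaxation volume (L) and flow is in L/s, inspiratory
positive. An exponential decay of flow is therefore the waveform
signature of a passive patient, in inspiration or expiration; any
deviation from it announces muscle activity. During synchronous
pressure support, passive conditions should appear only in the
ventilator's expiratory phase: passivity during the inspiratory phase
indicates auto-triggering or delayed cycling, and deviation from
passivity during the expiratory phase indicates trigger delay,
ineffective effort or early cycling.

## Detection rules and how "sudden" is quantified

The verbal rules name shapes, not numbers. The operational choices,
all exposed in `wave_config()` / `pes_config()`:

* **Decay segmentation** (`detect_decay_segments`). Maximal intervals
  where `log(abs(flow))` is linear with negative slope, fitted by
  least squares with region growing on flow smoothed by a centered
  0.05-s moving average. A window qualifies with `R^2 >= 0.98`, or
  with a log-space RMSE below 0.04 — the second gate keeps shallow
  stretches of a genuine decay (little dynamic range relative to
  noise) from being rejected. Samples below an amplitude floor of
  0.02 L/s are excluded, fitted time constants above 5 s are plateaus,
  and growth stops when a point misses the fitted curve by more than
  0.05 L/s or when a one-sided positive residual persists (an emerging
  effort, which the segment must not absorb). Segments of either phase
  are treated as credible passive phases only when their time constant
  is consistent (ratio within 0.5–2) with the recording's expiratory
  time constant, estimated from the long expiratory segments:
  effort-rise artifacts masquerade as fast decays and relaxation tails
  as slow ones.

* **Effort onset** (`detect_wave_ti_start`). A sudden positive
  deflection is a flow excess of at least 0.05 L/s over the value
  extrapolated from the preceding passive segment, sustained for at
  least 0.1 s — the sustain requirement also rejects cardiogenic
  oscillations, whose lobes are shorter. The crossing must begin
  before the next machine pressurization (the machine explains any
  later deviation) and before the next passive segment (passivity
  resuming is not an effort). Efforts that begin before enough passive
  decay has accumulated are caught against the *next* passive segment
  extrapolated backward. The reported onset is refined below the
  threshold by a footpoint construction: muscle pressure develops
  smoothly from zero slope, so the early deviation grows
  quadratically and `sqrt(dev)` extrapolates linearly to its root.
  The Paw rule — a drop of at least 0.5 cmH2O below a stable
  (±0.5 cmH2O) expiratory baseline — runs in parallel; when both rules
  fire within one effort window the earlier marker wins, and two
  onsets are merged unless passivity resumed between them.

* **Effort end** (`detect_wave_ti_end`). The end is pinpointed at the
  start of the first credible passive decay after the onset,
  irrespective of flow direction, and refined to the midpoint of the
  transition between effort-perturbed flow and the backward-
  extrapolated decay — mirroring the mid-relaxation convention of the
  esophageal reference. Two special regimes around the machine cycling
  point: after an early cycling the effort's residual peak is still
  visible beyond the release transient and the midpoint rule applies
  to it; when relaxation instead straddles the cycling point the
  midpoint is hidden inside the machine inspiration, and the end is
  estimated as the relaxation-start kink (the sharp minimum of the
  flow slope) plus `tau_relax * log(2)`, with the relaxation time
  constant fitted from the post-cycling residual decay (default
  0.1 s when unfittable).

* **Auto-triggering** (`is_passive_inflation`). A breath whose flow
  decays exponentially from its peak through at least 85% of the
  inspiration — with the decay beginning promptly at the peak — is a
  passive inflation; onset candidates that merely announce such a
  breath are suppressed. Under large cardiogenic ripple (measured as
  the 90th percentile of the high-frequency flow residual) the decay
  segmentation fragments, and a prompt but fragmented cover of at
  least 50% is accepted instead.

* **Pes reference** (`detect_efforts_pes`). Raw Pes carries the
  chest-wall recoil component `Ecw * V`, whose expiratory slope can
  rival a weak effort's deflection, so the detector first subtracts an
  internally estimated recoil component (the robust median ratio of
  the Pes derivative to flow over expiratory samples) and then applies
  the slope (2 cmH2O/s) and minimum-drop (2 cmH2O within 0.5 s)
  criteria on a heavily smoothed copy — cardiogenic bursts would
  otherwise dominate both the derivative and any local-maximum search.
  The end is the midpoint between the post-onset nadir and the plateau
  where the recovery slope collapses below 10% of its post-nadir
  maximum.

## The simulator and what it does (not) emulate

`simulate_recording()` integrates the equation of motion at 1000 Hz
(explicit Euler, decimated to the 100 Hz output grid) with flow
computed algebraically from the state at every step, so the recorded
state satisfies the defining equation to machine precision
(`eom_residual()` verifies ~1e-15 cmH2O). The ventilator is a
flow-triggered, pressure-targeted state machine with first-order
pressurization and flow-fraction cycling; intrinsic PEEP is not a
parameter but emerges when expiration is truncated. Muscle pressure
rises as a raised cosine and relaxes exponentially; the ground-truth
effort end is the mid-relaxation time `onset + rise + tau_relax *
log(2)`, the conventional surrogate for flow reversal in unassisted
breathing. Efforts whose relaxation is not contained in the recording
are not scoreable and are excluded from the truth table.

Three deliberate touches of realism matter to the detectors: a small
demand-valve resistance (2 cmH2O s/L) seen by inspiratory-direction
flow during expiration produces the Paw dip that precedes triggering
on real circuits; cardiac activity is a damped-sinusoid burst train at
1.2 Hz on Pes, attenuated on Paw, and coupled into the pneumatic
dynamics when `autotrigger_sensitivity` is on (so cardiogenic flow can
reach the trigger); and Gaussian sensor noise (defaults 0.01 L/s on
flow, 0.02/0.05 cmH2O on Paw/Pes, chosen as typical of proximal
sensors) is applied to the recorded channels while the clean state is
kept for invariant checks. No deposited recordings exist for this
problem, so the noise magnitudes are calibration choices, exposed in
the scenario schema.

The simulator does **not** emulate nonlinear or multi-compartment
mechanics, leaks and mask ventilation, expiratory muscle recruitment,
secretions, or the idiosyncratic servo behaviour of specific
ventilator brands. Passing the synthetic suite therefore shows that
the rules are implemented faithfully and work under textbook
mechanics with realistic noise — not that they reach the same accuracy
on arbitrary clinical recordings.

```{r presets}
sim <- simulate_recording(scenario_preset("obstructive", seed = 1))
table(sim$truth$classes$class)
```

## Pairing, statistics and conventions

`pair_events()` attributes a machine breath to an effort when its
inspiratory start falls within the effort interval extended by a
0.3-s tolerance (the pairing tolerance is a free choice; the
classification is insensitive to it over a wide range). One effort
with two or more breaths is double-triggered, with delays computed
against the first breath's start and the last breath's end, consistent
with the effort spanning both. Boundary convention: a timing gap of
exactly ±250 ms is *not* an asynchrony (strict inequalities); the
expiratory-time-constant classes place 0.4 s and 0.7 s in "normal".
Total asynchrony time takes absolute values of both the trigger and
the cycling gap of assisted (and double-triggered) breaths, plus the
durations of auto-triggered breaths and ineffective efforts.

The expiratory time constant is the negative inverse slope of flow
against cumulative volume over passive expirations, skipping 0.3 s
after the expiratory peak because residual muscle relaxation (a few
relaxation time constants long) biases the early relation upward;
flow is lightly smoothed first, since sensor noise otherwise dilutes
the regression at short time constants.

`agreement()` aligns two breath classifications by greedy
nearest-start matching; unmatched reference breaths form a fifth
"missed" category, a treatment under which the rebuilt published
confusion matrix reproduces its Cohen's kappa regardless of how the
undetected efforts are booked. `roc_auc()` is a threshold sweep with
trapezoidal integration, which equals the Mann–Whitney concordance
probability with midrank ties — a property test asserts the identity
exhaustively. The exact continuous score behind a real ROC for
trigger-delay detection is not recoverable from a published summary;
the intended use here is the waveform-estimated timing gap against
reference binary labels.

The proportion-CI sample-size helper uses the exact normal quantile by
default; clinical protocols conventionally round the 99% quantile to
2.58, which is what reproduces a printed requirement of about 4160
breaths for a ±2% half-width at worst-case prevalence.

```{r samplesize}
sample_size_proportion(conf_level = 0.99, half_width = 0.02)          # exact
sample_size_proportion(conf_level = 0.99, half_width = 0.02, z = 2.58)
```

## Numerical choices and degenerate inputs

Ingestion rejects non-monotonic time and more than 1% jitter in the
sampling step rather than resampling silently; `resample_recording()`
exists for deliberate rate changes. Detection is translation-
equivariant to within the sampling grid, and with
`relative_thresholds = TRUE` the flow thresholds scale with the
recording's flow amplitude, making detected times invariant under
flow rescaling. Zero or constant flow yields no decay segments;
constant Paw yields no machine breaths; recordings without Pes raise a
capability error from the reference method rather than silently
skipping. Efforts whose end cannot be located (no passive decay before
the next onset) are dropped with a warning; partial events at the
recording edges are discarded.

## Validation battery and problem sizes

`validation_scenarios()` defines 20 deterministic scenarios of 30 s at
100 Hz (about 180 breaths): the five presets at two seeds each, plus a
ten-point sweep of the expiratory time constant over 0.2–1.2 s used
for the mechanics-recovery check. `run_validation()` runs both
detectors against ground truth and reports detection and timing
fractions (agreement within 0.1 s), breath-class kappa, the maximum
relative error of the time-constant recovery, the maximum
equation-of-motion residual and the asynchrony-time bookkeeping error.
These sizes keep the whole battery under a minute on one CPU while
providing enough breaths for stable percentages; the same battery
backs `scripts/acceptance.R`.

## Known limitations

* The effort-end marker during a machine inspiration relies on the
  relaxation kink of flow; very gradual relaxations (time constants
  well above ~0.3 s) blur it.
* Efforts beginning within ~0.25 s of the cycling release sit inside
  the release transient, where neither forward nor backward
  extrapolation is reliable; a small fraction of such efforts is
  missed, the analogue of the sub-percent miss rate the method shows
  against its reference.
* Expiratory muscle activity is named by the general principles as a
  cause of deviation from passivity but has no dedicated rule, here as
  in the source method.
* The chest-wall compensation of the Pes detector assumes a roughly
  linear recoil over the tidal range and some passive expiratory data
  in the recording.
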