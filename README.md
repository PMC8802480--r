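# ventwave

Detection of patient inspiratory effort from ventilator waveforms
during pressure support ventilation (PSV).

## The problem

During PSV the ventilator should pressurize while the patient's
inspiratory muscles are active and release when they relax. In
practice the two are often out of step: trigger delays, early and late
cycling ("minor" asynchronies), and ineffective efforts, auto-triggered
or double-triggered breaths ("major" asynchronies) are frequent and
associated with worse outcomes. The reference way to time the
patient's effort is an esophageal pressure (Pes) catheter, which is
invasive and rarely available. `ventwave` implements the **waveform
method**: a rule-based algorithm that detects the start and end of
each inspiratory effort using only the airway pressure (Paw) and flow
signals every ventilator already measures.

The package provides, for ICU researchers and ventilation engineers:

* **the waveform method** — effort start (wave Ti-start) where a
  sudden positive flow deflection interrupts a phase of exponential
  flow decay (or a negative Paw deflection interrupts stable
  expiratory Paw); effort end (wave Ti-end) where a passive
  exponential decay of flow resumes, inspiratory or expiratory;
* **the Pes reference method** — effort start at the sudden negative
  Pes deflection, effort end at the midpoint of the fast Pes recovery
  after its inspiratory nadir (mid-relaxation);
* **breath classification and asynchrony statistics** — pairing of
  efforts with machine breaths (assisted / auto-triggered /
  double-triggered / ineffective), trigger and cycling delays with the
  ±250 ms convention, asynchrony index, total asynchrony time, the
  expiratory time constant from the flow–volume relation, Cohen's
  kappa, sensitivity/specificity/PPV/NPV and ROC AUC;
* **a patient–ventilator simulator** — a single-compartment lung
  (`Paw + Pmus = R·flow + V/C + PEEP`) driven by a muscle-pressure
  generator and a flow-triggered, pressure-targeted ventilator state
  machine, producing ground-truth-labelled recordings of every
  asynchrony phenotype.

## The core rules

A passive (relaxed) respiratory system empties or fills through its
resistance, so its flow decays exponentially with time constant
`tau = R·C`; any exponential decay of flow therefore signals absent
muscle activity, in inspiration or expiration. The detector segments
flow into such decays (log-linear least squares with region growing),
declares an effort onset where flow exceeds the decay-extrapolated
value by a sustained margin, and places the effort end at the
resumption of passive decay, refined to the midpoint of the
effort-to-passive transition to mirror the mid-relaxation convention
of the Pes reference. A pure exponential decay through the whole
inspiration marks an auto-triggered (passive) inflation.

## Worked example

```r
library(ventwave)

sim <- simulate_recording(scenario_preset("obstructive", seed = 1))
pv  <- pv_interaction(sim$recording, method = "waveform")
print(pv)
#> <pv_interaction> method = waveform
#> Patient-ventilator interaction over 30.0 s
#>   breaths: 12 (assisted 8, auto-triggered 0, double-triggered 0, ineffective 4)
#>   asynchrony index: 33.3%
#>   total asynchrony time: 11.92 s (39.7% of recording)
```

The obstructive preset (tau = 0.9 s, low cycling threshold, short
expirations) produces dynamic hyperinflation: a third of the simulated
efforts fail to trigger the ventilator, and the waveform method —
using flow and Paw only — recovers them and the late-cycling delays of
the assisted breaths. Against the simulator's ground truth:

```r
ev <- detect_efforts_waveform(sim$recording)
head(as.data.frame(ev), 3)
#>   event_kind  start_s    end_s   source label
#> 1     effort 1.540578 2.148498 waveform  <NA>
#> 2     effort 4.019554 4.639315 waveform  <NA>
#> 3     effort 6.343305 6.928865 waveform  <NA>
```

(truth: efforts at 1.597, 4.034 and 6.381 s ending at 2.152, 4.589 and
6.937 s). The expiratory time constant and mechanics class come from
the flow–volume relation of passive expirations — here on the
synchronous preset, since every expiration of the hyperinflated
obstructive scenario contains an effort:

```r
sim2 <- simulate_recording(scenario_preset("synchronous", seed = 1))
ev2  <- detect_efforts_waveform(sim2$recording)
expiratory_time_constant(sim2$recording, sim2$truth$machine_breaths,
                         efforts = ev2)[c("tau_e_s", "mechanics_class")]
#> $tau_e_s
#> [1] 0.5033545
#> $mechanics_class
#> [1] "normal"
```

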