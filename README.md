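# nadyn — intracellular sodium dynamics in compartmental neuron models

Most conductance-based neuron models hold the intracellular sodium
concentration fixed. `nadyn` treats [Na⁺]ᵢ as a slow, per-compartment
state variable of a multicompartment cable model and follows its three
downstream consequences:

1. **Amplitude adaptation.** Sodium loading lowers the local Nernst
   potential, E_Na = (RT/F)·ln([Na⁺]ₒ/[Na⁺]ᵢ) — about 15 mV per 10 mM at
   physiological baselines — shrinking spikes and EPSPs during repeated
   activity.
2. **Prolonged after-hyperpolarization.** The electrogenic 3:2 Na⁺/K⁺
   pump, modelled by a two-reaction kinetic scheme with the closed-form
   steady-state current
   I = (F/3)·ρ·(k₁k₃[Na]ᵢ³ − k₂k₄[Na]ₒ³)/(k₁[Na]ᵢ³ + k₄[Na]ₒ³ + k₂ + k₃),
   turns accumulated sodium into a lingering outward current.
3. **Synaptic tagging.** The Na⁺/Ca²⁺ exchanger (Courtemanche form,
   reversing at V = 3E_Na − 2E_Ca) sets a *stable-state* [Ca²⁺]ᵢ that
   rises with [Na⁺]ᵢ, so recently active dendritic sites stay marked by
   elevated calcium for seconds — amplified by coincident
   back-propagating spikes or climbing-fiber volleys.

Sodium moves between compartments by conservative longitudinal diffusion
(D = 0.3 µm²/ms; ×0.1 "spine correction" available); calcium is buffered
and pumped locally. The stepping core (backward-Euler Hines solve +
exponential gate updates + flux-form diffusion) is C++ via Rcpp.

The package ships three reduced archetypes (`mitral_like`,
`pyramidal_like`, `purkinje_like`), an SWC reader/writer, the stimulation
protocols (calibrated pulse trains, deterministic synaptic trains with
Na⁺/K⁺-split conductances, climbing-fiber volleys, stochastic distributed
cortical/thalamic input) and analytics (sodium entry ratio, effective
capacitance by clamp transient, stable-state Ca²⁺ curves, amplitude
series, rate histograms). See the methods vignette
(`vignettes/sodium-dynamics.Rmd`) for the model, its assumptions and the
design decisions.

## Worked example

A 30 Hz, 2 s pulse train on the mitral-like archetype, with the pulse
amplitude auto-calibrated to one spike per pulse, against the
conventional frozen-[Na⁺]ᵢ control:

```r
library(nadyn)
model <- build_model("mitral_like")
res <- exp_spike_train(model, frequency = 30, duration = 2, t_post = 4)

at <- function(x, t) x$value[which.min(abs(x$t - t))]
na_ais  <- trace_at(res$trace, "Na", region = "AIS")
na_soma <- trace_at(res$trace, "Na", region = "soma")
v_dyn   <- trace_at(res$trace, "V", region = "soma")
v_frz   <- trace_at(res$trace_frozen, "V", region = "soma")
```

This prints (exact output of the run above):

```
calibrated pulse amplitude (nA): 0.456
spikes evoked: 60
AIS  [Na+]i at train end: 51.2 mM
soma [Na+]i at train end: 11.04 mM
spike amplitude, first -> last: 121.4 -> 117.4 mV
soma V 1 s after the train: dynamic -70.05 mV vs frozen -69.65 mV
```

Reading: the thin axon initial segment loads dramatically (51 mM from a
10 mM baseline) while the voluminous soma barely moves; the falling AIS
E_Na trims ~4 mV off the spike amplitude along the train (the frozen
control shows no reduction); and one second after the train the dynamic
model is still ~0.4 mV hyperpolarized relative to the control — the
pump-mediated afterpotential.

The published absolute benchmarks of the full reconstructed models
(sodium entry ratios 1.76/3.6/5.6, 17 % EPSP reduction, 400 pA pump
current) require parameter sets hosted on ModelDB (185332, 230326) that
are not bundled; `reference_benchmarks()` records them. The reduced
archetypes reproduce the *orderings and mechanisms*, which is what the
test suite asserts.

## Command line

`inst/cli/nadyn` is a thin Rscript front end:

```sh
nadyn run config.json --out-dir out/     # config-driven experiment
nadyn curves stable-ca --out curve.csv   # analytic curves (ena|pump|stable-ca)
nadyn make-inputs --n-cortical 1000 --seed 7 --out inputs.csv
nadyn analyze out/trace.csv spikes
```
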