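---
title: "Modelling intracellular sodium as a slow state variable"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling intracellular sodium as a slow state variable}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nadyn)
```

## The problem

Compartmental neuron models almost always treat the intracellular sodium
concentration, $[\mathrm{Na}^+]_i$, as a constant. That assumption fails
exactly where it is most interesting: during bouts of spiking or repeated
synaptic input, enough Na$^+$ enters thin compartments (axon initial
segment, distal dendrites) to shift the local Na$^+$ Nernst potential by
tens of millivolts, to multiply the Na$^+$/K$^+$ pump current several-fold,
and to stall or reverse Ca$^{2+}$ extrusion through the Na$^+$/Ca$^{2+}$
exchanger. Because Na$^+$ is unbuffered, its only fast redistribution
pathway is longitudinal diffusion, so its dynamics are set by morphology:
compartments without good diffusion sinks integrate activity over seconds
to minutes.

`nadyn` adds $[\mathrm{Na}^+]_i$ (and a coupled $[\mathrm{Ca}^{2+}]_i$) as
per-compartment state variables of an otherwise conventional
conductance-based cable model, and packages the stimulation protocols and
analytics needed to exercise the three downstream effects: spike/EPSP
amplitude adaptation through $E_{\mathrm{Na}}$, prolonged
after-hyperpolarisation through the pump, and synaptic tagging through the
exchanger-controlled stable-state Ca$^{2+}$.

## The model

### Electrical skeleton

Each segment is a cylinder with specific capacitance $c_m$ (1 µF/cm²,
0.05 µF/cm² for myelin), axial resistivity $R_a$ (150 Ω·cm) and
Hodgkin–Huxley-style channels. Gates follow Boltzmann steady states
$x_\infty(V) = 1/(1+e^{-(V-v_h)/k})$ with constant or bell-shaped
$\tau(V)$; all gate parameters are plain numbers in the channel
specification, so ported parameter sets load from configuration without
code changes. Na$^+$ channels always use the *instantaneous* Nernst
potential $E_{\mathrm{Na}} = (RT/F)\ln([\mathrm{Na}^+]_o/[\mathrm{Na}^+]_i)$
recomputed from the local state every step; Ca$^{2+}$ channels use the GHK
(constant-field) flux, because $E_{\mathrm{Ca}}$ is far from the operating
range and the GHK form behaves correctly at nanomolar internal Ca$^{2+}$;
K$^+$ uses a fixed reversal (external and internal K$^+$ are not state
variables here).

### Sodium bookkeeping

For each segment, with net Na$^+$ membrane current $I_{\mathrm{Na}}$
(outward positive) and volume $V$,
$$\frac{d[\mathrm{Na}^+]_i}{dt} = -\frac{I_{\mathrm{Na}}}{F\,V},$$
i.e. 1 nA of inward current into 1000 µm³ raises the concentration by
1.0364×10⁻² mM per ms. The Na$^+$ ledger includes voltage-gated channels,
the Na$^+$ fraction of synaptic currents, three ions per pump cycle and
three ions per exchanger cycle. A conservative flux-form scheme exchanges
ion *amounts* between adjacent segments,
$J = D\,(C_k - C_j)\,A_\times/\Delta x$, with $D_{\mathrm{Na}} =
0.3\ \mu m^2/ms$ (the experimental dendritic value) and an optional
*spine correction* that multiplies the dendritic coefficient by 0.1 — a
linear stand-in for the anomalous diffusion created by spines. Ca$^{2+}$
does not diffuse by default.

### The pump

The Na$^+$/K$^+$ pump is a two-reaction kinetic scheme: the pump binds
three internal Na$^+$ (rates $k_1$, $k_2$) and releases them externally
(rates $k_3$, $k_4$), moving one net charge per cycle (3 Na$^+$ out /
2 K$^+$ in; K$^+$ is fixed, so only the charge is booked). Assuming the
loaded state is at equilibrium gives the closed-form steady-state current
$$I_{\mathrm{pump}} = \frac{F}{3}\,\rho\,
\frac{k_1 k_3 [\mathrm{Na}]_i^3 - k_2 k_4 [\mathrm{Na}]_o^3}
     {k_1 [\mathrm{Na}]_i^3 + k_4 [\mathrm{Na}]_o^3 + k_2 + k_3},$$
which is the default mode; the explicit occupancy ODE is available
(`na_pump_kinetic = TRUE`) and agrees with the closed form to <0.1 % at
equilibrium (tested). The default constants put the pump's zero at
10 mM and its half-saturation near 40 mM, so the current rises steeply
above ~20 mM — the regime the pump-current figure of the source work
describes. Densities follow the printed distribution (mol/cm²: soma
1×10⁻¹¹, axon/AIS 5×10⁻¹², dendrites 1×10⁻¹⁵). The plasma-membrane
Ca$^{2+}$ pump reuses the same scheme with stoichiometry 1 and two charges
per cycle, at 6× density in soma/axon relative to dendrites.

### The exchanger and stable-state calcium

The Na$^+$/Ca$^{2+}$ exchanger follows the Courtemanche formulation;
positive (outward) current is reverse mode: three Na$^+$ out, one
Ca$^{2+}$ in, reversing at $V = 3E_{\mathrm{Na}} - 2E_{\mathrm{Ca}}$.
Because one cycle moves one Ca$^{2+}$ and one net charge, the molar
Ca$^{2+}$ flux is exactly $I_{\mathrm{NCX}}/F$ — this resolves, on
physical grounds, the question of whether the balance prefactor should be
$I/F$ or $I/2F$.

With voltage-gated Ca$^{2+}$ channels closed, the Ca$^{2+}$ balance
(exchanger in, pump out) has a single positive equilibrium — the
*stable-state* $[\mathrm{Ca}^{2+}]_i$ — which is a function of the local,
slowly varying $[\mathrm{Na}^+]_i$. The exchanger numerator is linear in
$[\mathrm{Ca}^{2+}]_i$ and the pump is a ratio of linear terms, so the
equilibrium is the positive root of a quadratic; `stable_state_ca()`
evaluates the closed form and, as an independent check, brackets the same
balance with `uniroot()` on [10⁻⁹ mM, Ca$_o$] (agreement <10⁻⁸ is an
acceptance property). Elevated Na$^+$ raises the stable state; scaling the
exchanger and pump densities *together* leaves the curve untouched while
setting the relaxation time toward it — the package exploits this to put
the tagging sites in the retention regime (actual Ca$^{2+}$ lagging below
its stable state during a train, so coincident influx is kept for
seconds).

### Buffering

A single kinetic buffer (0.1 mM total, $K_d$ = 2 µM, $k_{on}$ =
50 mM⁻¹ms⁻¹) gives a resting buffer capacity of ~50, typical of
dendrites; at equilibrium the buffering flux vanishes and does not move
the stable state.

## Numerics

The voltage is advanced by backward Euler on the tree with Hines-ordered
elimination (exact for the linearised channels; GHK, pump and exchanger
currents enter explicitly at the previous voltage). Gates use the exact
exponential update at frozen voltage, which keeps them in [0, 1] for any
step. Concentrations are split off after the voltage solve: their time
scales are seconds, so first-order splitting at the default
$\Delta t = 0.025$ ms is far below the voltage discretisation error
(halving $\Delta t$ moves a spike peak by less than $\Delta t$ — tested).
Explicit diffusion is comfortably stable at these parameters
($D\,\Delta t/\Delta x^2 \approx 10^{-5}$ on archetype segments) and the
flux form conserves total amount to machine precision. Spike bookkeeping
is an upward 0 mV crossing with a 1 ms refractory period. Voltage clamp is
implemented as a Dirichlet row; the clamp current is the row residual, so
the rectangle rule recovers the capacitive impulse of a command step
exactly — this is what `effective_capacitance()` integrates.

The solver is deterministic: randomness exists only in protocol
*generation* (`make_distributed_input()`, seeded), never in the
integrator, so a schedule re-run is bit-identical.

## The archetypes and what they stand for

The source models are full reconstructions with large channel complements;
their geometry and kinetics live in ModelDB (entries 185332 and 230326),
not in print. `nadyn` ships three *reduced archetypes* — soma + AIS +
proximal/distal dendrite (mitral-like adds a tuft; Purkinje-like adds a
myelinated axon with three nodes of Ranvier and thick, climbing-fiber-
eligible proximal dendrites) — with a minimal channel set (transient and
persistent Na$^+$, delayed-rectifier K$^+$, high- and mid-threshold GHK
Ca$^{2+}$, leak). Dimensions and kinetics are package choices, documented
as such. The mitral-like cell carries active Na$^+$ conductance in its
distal dendrites; the other two have "very low" dendritic Na$^+$
conductance, so their dendritic sodium responds to synaptic input only.
The pyramidal-like apical tuft doubles as the Ca$^{2+}$-channel hot zone:
its mid-threshold channel (half-activation −38 mV, with inactivation)
lets somatically driven depolarisations deposit Ca$^{2+}$ there, which is
the coincidence-detection substrate.

A green qualitative test on an archetype therefore establishes that the
*mechanisms* — sodium loading profiles, E$_{\mathrm{Na}}$ adaptation,
pump after-hyperpolarisation, exchanger-mediated tagging, distributed-
input suppression — behave and order as described; it does not establish
the published absolute numbers (SER 1.76/3.6/5.6, 17 % EPSP reduction,
400 pA pump current), which require the ported full-model parameter sets
(`reference_benchmarks()` records them as such).

## Protocols, defaults and deliberate deviations

* **Pulse trains** (30 Hz, 2 s): the amplitude is auto-calibrated by
  binary search for one spike per pulse, then re-checked on the full train
  and scaled up if late pulses fail — sodium accumulation genuinely raises
  the threshold along the train, which is part of the phenomenon.
* **Synaptic trains** (5 Hz, 4 s, probes +2 s and +9 s): 5 nS peak,
  τ 0.5/10 ms, reversal +10 mV split into fixed Na$^+$/K$^+$ conductance
  fractions from the resting potentials; the *dynamic* E$_{\mathrm{Na}}$
  enters the voltage equation through the Na$^+$ component — without this
  the EPSP adaptation effect cannot exist.
* **Calcium tagging**: default 2.5 nS (1 nS at the hot zone in the tests);
  at the full 5 nS the reduced geometry's sodium load saturates the
  exchanger response. The stable-state trajectory is evaluated on the
  *recorded* local Na$^+$ and V; its closed-channel assumption holds at
  the plain distal site (where the <10 % tracking property is asserted,
  from 1.5 s after the train, past the documented convergence transient)
  but not at the hot zone.
* **Distributed input**: the full-size protocol (1,000 cortical + 1,000
  thalamic trains, 5 contacts each) is the default of
  `distributed_input_spec()`; driving the *reduced* cell with it produces
  >100 Hz firing, so the experiment and tests use 25 + 25 trains, which
  recovers the ~7 Hz background of the full-size setting. All assertions
  on this protocol are orderings, not rates.
* **Thalamic epochs** are 2.5 s by default (the protocol quotes "2–3 s");
  the duration is a configuration value.

## Known limitations

* Compartments are well-mixed radially; no spine compartments (the 10×
  diffusion reduction is the stand-in) and no ER Ca$^{2+}$ stores.
* External K$^+$ and internal Cl$^-$ are fixed.
* The archetypes target orderings; absolute magnitudes (e.g. somatic
  sodium rises, pump-current peaks) differ from the full reconstructions.
* GHK, pump and exchanger currents are explicit in the voltage step;
  at pathological parameter choices (orders of magnitude above the
  presets) this could require a smaller `dt`.
* No Na$^+$-gated K$^+$ (Slick/Slack) channels, by design.
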