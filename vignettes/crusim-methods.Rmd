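---
title: "Model and methods: stochastic release-unit simulation of a ventricular myocyte"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(crusim)
```

## The model

`crusim` simulates excitation–contraction coupling in a guinea-pig-like
ventricular myocyte with *local control*: instead of one lumped SR release
flux, the cell contains thousands of calcium release units (CRUs).  Each
CRU couples a cluster of 14 L-type Ca²⁺ channels and 49 RyR2 channels
through a dyadic subspace to its own junctional SR (JSR) compartment.
Channel gating is stochastic (Markov chains sampled per time step);
everything else — membrane potential, Hodgkin–Huxley gates, bulk
myoplasmic and network-SR Ca²⁺ — is deterministic, so whole-cell
behaviour emerges from the summed activity of the stochastic units.

Compartments and fluxes:

* **Myoplasm** (25.84 pL): receives Ca²⁺ from every subspace
  (`g_xfer`), loses it to SERCA uptake and NCX extrusion; buffered by
  troponin and calmodulin (rapid-buffering approximation).
* **Network SR** (2.1 pL): filled by SERCA, drains into each JSR
  (`g_tr`) and through a small leak.
* **Junctional SR** (per CRU): buffered by calsequestrin; feeds the
  dyad through open RyR2s (`g_rel` per open channel, driven by the
  JSR–dyad gradient).
* **Dyadic subspace** (per CRU, 10⁻¹⁸ L): receives L-type (GHK) and RyR2
  flux, relaxes to the myoplasm; a fixed anionic buffer slows its
  dynamics.

### RyR2 gating

Each RyR2 is a three-state chain: closed (C1) → open (O2) → adapted
(C3) → C1.  The opening rate is

    k_open = Phi([Ca]jsr) * k_open_max * ca_ds^h / (ca_ds^h + k_ca^h),
    Phi    = phi_m * [Ca]jsr + phi_b

so openings are triggered by dyad Ca²⁺ (Hill coefficient `h = 3` — steep
enough that the resting dyad hardly ever triggers, shallow enough that a
single open L-type channel recruits the cluster) and multiplied by the
affine luminal regulation function `Phi`.  `Phi` is the lever of the
calsequestrin-null scenario: the mutant raises `phi_m` by 90%, so a
loaded SR drives both more frequent spark initiation and faster
re-opening after refill.  Closing, adaptation and recovery are
Ca-independent constants; adaptation is what terminates a release episode
in the wild type (whose buffered JSR depletes slowly), while in the
mutant episodes also self-terminate by local JSR depletion, which is why
the same kinetics produce discrete repetitive sparks under Ca overload.

### L-type gating

The six-state chain has closed C1, open O2/O3, Ca-inactivated C4,
voltage-inactivated C5 and a deep closed state C6.  Activation and
deactivation are Boltzmann functions of voltage; Ca-dependent
inactivation is linear in subspace Ca²⁺ with a saturation cap
(`ca_inact_max`) so that extreme dyad concentrations cannot violate the
gating step cap.  C6 is entered from C1 at strong depolarisation and
recovers slowly at rest: it accumulates at fast pacing and contributes to
rate-dependent loss of L-type availability.  The chain as printed leaves
the resting occupancy in C1 (the source material is ambiguous about
whether C1 or C6 holds resting channels; we chose C1, with C6 as a
reserve state, because a resting C6 majority would make the first beat
unexcitable).  Unitary flux uses the GHK constant-field equation with the
singularity at 0 mV expanded in series.

### Membrane currents

The current set follows the classic guinea-pig ventricular formulations:
fast Na⁺ (m³hj), time-dependent K⁺ (x gate with inward rectification),
time-independent K1, plateau K⁺, Na⁺/K⁺ pump, 3Na:1Ca exchanger (NCX)
and linear backgrounds.  Two deliberate departures:

* `x_beta_scale` multiplies only the closing rate of the x gate.  With
  the textbook kinetics the gate barely deactivates between fast beats,
  and APD collapses far more steeply with rate than the calibration
  envelopes allow; a faster deactivation flattens restitution without
  touching the 1 Hz action potential.
* SERCA uses the stated `J = 2 * vcycle * Ap` with a forward Hill
  dependence on myoplasmic Ca²⁺ times a luminal back-inhibition factor
  `1/(1 + ([Ca]nsr / k_nsr)^4)`.  The factor is ≈1 at physiological
  loads (≤ 1% at the wild-type operating point) and only matters in the
  calsequestrin-null scenarios, where the absence of luminal buffering
  would otherwise let free SR Ca²⁺ grow without bound.

Na⁺ and K⁺ pools are clamped by default (`ions$clamp_na_k`): the
protocols of interest last ≤ 30 s, and letting the slow ion pools drift
over that horizon adds confounds without adding science.  The balance
equations are implemented and can be enabled.

## Numerics

The integrator is explicit Euler with operator splitting:

* global step `dt = 0.02 ms` for membrane potential, HH gates and bulk
  Ca²⁺;
* CRU substep `dt * cru_every` (default 0.06 ms) for stochastic gating
  and the local dyad/JSR compartments.

Between CRU substeps the engine caches `sum(ca_ds)`, `sum(ca_jsr)` and
the open L-type channel sums, so the whole-cell L-type current and the
transfer fluxes are still re-evaluated against the *fresh* voltage and
bulk concentrations at every global step.  Gating uses the frozen-rate
scheme: each channel leaves its state with probability
`1 - exp(-k_exit * dt)`, destinations drawn proportionally to the
outgoing rates, sampled as aggregated binomial/multinomial counts
(channels within a state are exchangeable — this applies to the 14
L-type channels as well as the RyR2 cluster; the per-channel and
count representations are distributionally identical).  Exits are exact
exponentials at frozen rates; what the scheme neglects is a channel
making two transitions within one substep, which the engine bounds by
a cap on per-channel exit probability mass and the test suite bounds by
comparing against an exact Gillespie simulation as `dt -> 0`.

The defaults were chosen against two gates: halving `dt` changes
beat-averaged Ca²⁺ maxima by < 1% on a short paced run, and a sealed
membrane (all sarcolemmal fluxes off) conserves total cell Ca²⁺ to
< 0.1% over 10 s.  A 10 ns time step, appropriate for a GPU
implementation resolving single-channel shot noise, is neither feasible
nor necessary on one CPU for the beat-scale observables this package
reports.

Randomness: one master seed spawns an independent `mt19937_64` stream
per CRU, so traces are bit-reproducible for a given configuration and
extending `n_cru` leaves the existing units' streams unchanged.

## Desk scale and rescaling

The full-scale cell has 20,000 CRUs; the desk-scale default simulates
`n_cru = 2000` of them and scales the bulk volumes and membrane area by
`n_cru / 20000`, so concentrations and currents per capacitance are
`n_cru`-invariant in expectation while stochastic fluctuations are
√10 larger.  Spark *counts* scale linearly with `n_cru`; reported rates
are rescaled by `20000 / n_cru` when full-scale-equivalent numbers are
quoted.

## Scenarios

Four named scenarios map onto parameter multipliers applied to the
wild-type baseline:

| scenario        | phi_m | SERCA Ap | JSR vol | NSR vol | CASQ btot | P_dhpr |
|-----------------|------:|---------:|--------:|--------:|----------:|-------:|
| wt_control      | 1     | 1        | 1       | 1       | 1         | 1      |
| mutant_control  | 1.9   | 1        | 1.5     | 1.5     | 0.05      | 1      |
| wt_bar          | 1     | 1.5      | 1       | 1       | 1         | 1.4    |
| mutant_bar      | 1.9   | 1.5      | 1.5     | 1.5     | 0.05      | 1.4    |

The mutant rows model the calsequestrin-null morphology (SR volume +50%,
luminal buffer −95%, luminal regulation slope +90%); the `bar` rows model
β-adrenergic stimulation as static increases of L-type permeability
(+40%) and SERCA concentration (+50%).  The composition is a two-way
factorial: `mutant_bar` is exactly the product of the two multiplier
sets, and `apply_scenario()` is order-independent because the multipliers
act on disjoint fields.

## Calibration

The structural composition (20,000 CRUs, 49+14 channels each, the
scenario multipliers) is fixed by the biology; the numeric rate constants
are not published alongside it, so every kinetic constant lives in the
parameter list and the bundled defaults are a calibration.  The
calibration targets were, in order of priority: the wild-type 1 Hz state
(Ca²⁺ transient peak and diastolic level, APD90, whole-cell spark rate),
the wild-type 6 Hz APD (restitution flatness), and the qualitative
scenario phenotypes.  The main levers and what they control:

* `g_k`, `x_beta_scale` — APD90 at 1 Hz and its rate dependence;
* `p_dhpr`, `k_ncx`, `g_cab` — membrane Ca²⁺ influx/extrusion balance,
  hence diastolic Ca²⁺ and steady SR load;
* `g_rel`, `casq$btot`, `serca` — transient amplitude and decay;
* `phi_b`, `k_ca`, `k_open_max` — diastolic spark rate;
* `k_adapt`, `k_recover`, `g_tr` — spark termination and restitution
  (re-firing), which dominate the overload phenotypes.

Initial conditions are the paced steady state of the wild type (SR load
included), mirroring the practice of equilibrating at 1 Hz before every
protocol; scenario runs inherit them and settle into their own load
within a few beats.

## Spark definition

A spark is a maximal episode during which a CRU's open-RyR2 count is at
least `spark_threshold`, episodes separated by less than `spark_gap`
(5 ms) merged.  No operational definition accompanies the reported spark
counts, so this is necessarily a package convention; the bundled
calibration counts with `threshold = 3` because a threshold of 2 counts
large numbers of two-channel blips during the systolic release phase and
inflates the wild-type rate ~40% above its calibration envelope.  Both
knobs are arguments of `run_protocol()` and `detect_spark_events()`, and
the engine's online counter is validated against the R reference
implementation at full recording resolution.

## What the synthetic-trace generator does and does not emulate

`generate_synthetic_trace()` builds piecewise-linear action potentials
and raised-cosine Ca²⁺ transients with implanted ground truth: APD
alternans of known magnitude, EAD bumps of known rise/duration, skipped
beats at known indices.  It exists to close the loop on the detectors —
every detector must reproduce the implanted labels exactly — and it
deliberately does *not* emulate channel noise, restitution, or any
feedback between beats.  A green detector suite therefore establishes
that the analytics measure what they claim on waveforms of known
structure, not that the simulator produces physiological waveforms; the
latter is what the calibration envelopes and phenotype tests are for.

## Detector conventions

* **APD**: APD90 by default (time from maximum upstroke velocity to 90%
  repolarisation, linear interpolation), the level being configurable;
  the repolarisation level is not stated alongside the reported values,
  and APD90 is the field's default reading.
* **AP amplitude**: both peak overshoot and peak-minus-diastolic are
  computed; overshoot is the default comparator (the reported ~38 mV
  values are consistent with overshoot, not range).
* **EAD**: a sustained (`>= 5 ms`) net depolarisation (`>= 2 mV`) after
  the plateau apex and before the voltage first returns within 10 mV of
  rest.  The apex is located on a heavily smoothed copy of the trace and
  a 60 ms post-upstroke blanking window is applied, so that neither the
  Na⁺ spike nor the normal spike-notch-dome rebound counts as an event.
* **Alternans**: consecutive beat-to-beat differences alternating in
  sign over ≥ 4 beats with mean |Δ| above 5% of the window mean.
* **Diastolic interval**: APD90-end of the previous beat to the next
  upstroke.  (The printed diastolic-interval values in the source tables
  appear unit-garbled and are not used as calibration targets.)
* **Welch's t-test**: implemented from the textbook formula
  (Welch–Satterthwaite degrees of freedom, two-sided p); `stats::t.test`
  is the independent cross-check in the test suite.

## Known limitations

* There is no inter-CRU Ca²⁺ diffusion, so the model cannot produce
  propagating Ca²⁺ waves — only whole-cell-coupled (common-pool)
  synchronisation through bulk Ca²⁺.
* Phosphorylation is represented only by the static β-adrenergic
  multipliers; there is no kinase cascade, no mode switching of RyR2.
* The calsequestrin-null scenarios reproduce the qualitative overload
  phenotypes only partially, and the acceptance suite reports the misses
  honestly rather than loosening them:
  - the 1 Hz mutant Ca²⁺-transient envelope is not attained — with 95%
    of the luminal buffer removed, releasable JSR content is bounded by
    free luminal Ca²⁺ and the NSR→JSR refill rate, and the achievable
    transient peak stays below the reported mutant value under every
    parameterisation we explored that preserves the wild-type
    calibration (variants with fast RyR2 adaptation recovery reach it,
    but inflate the wild-type spark rate ~1.8× and destabilise the wild
    type at 6 Hz);
  - in the slow–rapid–slow protocol the second slow phase shows SR
    overload, larger transients and longer APDs than the first, but the
    full reported magnitudes (APD ≈ 330 ms with afterdepolarisations,
    a doubled spark rate) are not reproduced — without fast cluster
    cycling the post-overload release is not synchronised enough to
    bend repolarisation;
  - under sustained 6 Hz pacing the model cell is only metastable: it
    paces regularly for a few seconds and then tips into overload-driven
    alternans at most seeds.  The 6 Hz analyses therefore use the
    quasi-steady window (beats 13–24 of a 4 s run); in that window the
    wild type and the unstimulated mutant pace stably while the
    stimulated mutant alternates, as reported — but β-adrenergic
    stimulation alone also destabilises the wild type at 6 Hz, which
    the reference matrix says it should not.
* Na⁺/K⁺ pools are clamped by default (see above).
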