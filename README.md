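# crusim

Stochastic, local-control simulation of excitation–contraction coupling
in a guinea-pig-like ventricular myocyte, built to study how a
calsequestrin-null (CPVT2-type) mutation turns β-adrenergic stimulation
and pacing rate into arrhythmia.

## The problem and the model

Calsequestrin-2 (CASQ2) is the high-capacity Ca²⁺ buffer of the
junctional sarcoplasmic reticulum (SR) and a luminal regulator of the
cardiac ryanodine receptor (RyR2).  Truncating CASQ2 mutations cause
catecholaminergic polymorphic ventricular tachycardia: hearts that beat
normally at rest but develop alternans, early afterdepolarisations
(EADs) and skipped beats under adrenergic stress.  Whole-cell models with
a single lumped SR release flux cannot express the underlying physics —
sparks, local SR depletion, stochastic re-opening — so `crusim`
implements a *local-control* cell:

* `n_cru` calcium release units (20,000 at full scale, 2,000 at the
  desk scale used by default), each a dyadic subspace coupling **14
  L-type channels** (6-state Markov chains, voltage- and Ca-dependent
  inactivation, GHK unitary flux) to a cluster of **49 RyR2 channels**
  (3-state Markov chains with adaptation) and a private junctional-SR
  compartment;
* RyR2 opening is multiplied by the affine luminal regulation function
  `Φ = φ_m·[Ca²⁺]_SR + φ_b`, the lever by which SR load controls spark
  rate and by which the mutation (+90% `φ_m`) destabilises release;
* a Luo–Rudy-style membrane (I_Na, I_K, I_K1, I_Kp, I_NaK, NCX,
  backgrounds) driven by the summed stochastic L-type current;
* SERCA uptake `J = 2·v_cycle·A_p`, rapid-buffering Ca²⁺ handling
  (troponin/calmodulin, calsequestrin, dyad buffer), and
  volume-consistent mass balance (a sealed membrane conserves total cell
  Ca²⁺ to < 0.1% over 10 s).

Four built-in scenarios form a two-way factorial: `wt_control`,
`mutant_control` (SR volumes ×1.5, calsequestrin ×0.05, `φ_m` ×1.9),
`wt_bar` (β-adrenergic: L-type permeability ×1.4, SERCA ×1.5) and
`mutant_bar` (both).  Protocols are constant pacing (1–6 Hz) and the
slow–rapid–slow 1-5-1 Hz protocol; analytics cover APD90, Ca-transient
statistics, spark counting, alternans, EAD and skipped-beat detection,
and Welch's t-test for group comparisons.

## Worked example

```r
library(crusim)

params <- default_parameters()            # calibrated wild type, 2000 CRUs
proto  <- build_protocol("constant", f_slow = 1, durations = 10)
cfg    <- simulation_config(seed = 1, protocol = proto)
trace  <- run_protocol(params, cfg, spark_threshold = 3)

beats <- beat_metrics(trace)
mean(tail(beats$ca_max, 5))        # 0.6917  uM  Ca transient peak
mean(tail(beats$ca_diastolic, 5))  # 0.1258  uM  diastolic Ca
mean(beats$apd90, na.rm = TRUE)    # 180.8   ms  APD90
spark_statistics(trace$sparks, segment_beats(trace),
                 trace$n_cru)$rate_full_scale   # 64177 sparks/s (full scale)
```

The numbers printed above are from the run shown (seed 1): a 0.69 µM
transient over a 0.126 µM diastolic floor, a 181 ms action potential and
a full-scale-equivalent spark rate of ~64,000/s — the wild-type
operating point the bundled parameters are calibrated to.  Switching
`scenario = "mutant_bar"` in the configuration and
`build_protocol("srs", 1, 5)` reproduces the slow–rapid–slow stress
protocol; at 6 Hz the stimulated mutant develops APD and Ca-transient
alternans that the wild type does not (`analyze_trace()` reports the
verdicts).

A thin command-line wrapper is installed with the package
(`system.file("cli", "crusim", package = "crusim")`) with subcommands
`simulate`, `analyze`, `scenarios`, `calibrate-stimulus` and
`make-fixture`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from fresh simulations at the desk scale: the wild-type
1 Hz Ca-transient maximum and diastolic level, APD90 and
full-scale-equivalent spark rate; the first- and second-slow-phase APD90
and the second-phase spark rate of the mutant+β-adrenergic
slow–rapid–slow run; and the wild-type 6 Hz APD90.  Results are written
as a JSON object keyed `t1` … `t8`.
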