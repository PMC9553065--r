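# monpool

Reconstruction of the recruitment and firing behaviour of a **complete
motoneuron (MN) pool** from a small sample of experimentally identified
motor-unit spike trains and a synchronized whole-muscle force trace.

## Who this is for

High-density surface EMG (HDEMG) decomposition yields the discharge times
of a few tens of motor units during a voluntary contraction — a small,
high-threshold-biased sample of a pool of several hundred. Neuroscientists
studying motor control and modellers building MN-driven muscle models need
the complete pool. `monpool` reconstructs it in four steps:

1. **Mapping.** Identified units are placed at locations `N_i` in a pool of
   `N` units ranked by force recruitment threshold, by inverting the
   muscle-specific threshold distribution
   `Fth(j) = k1*(k2*j/N + ΔF^((j/N)^k3))`
   (tibialis anterior: `k1 = 0.50`, `k2 = 58.12`, `k3 = 1.83`, `ΔF = 120`).
2. **Common current input.** The cumulative spike train of the sample,
   low-pass filtered at 10 Hz, estimates the common synaptic input; a
   coherence-based representativeness check guards the assumption. The
   input current is the affine image of that signal anchored at the
   rheobases `Ith(j) = 3.9 nA * 9.1^((j/N)^1.18)` of the lowest- and
   highest-threshold identified units.
3. **LIF calibration.** Each identified MN is a leaky integrate-and-fire
   model whose parameters reduce to its surface area `S`
   (`R = kR/S^2.43`, `C = Cm*S`, `Ith = ΔVth/R`) plus an inert period `IP`
   capping its firing rate at `1/IP` (extracted from discharge-rate
   saturation). `S_i` is calibrated against the Hann-smoothed discharge
   rate; pool-wide distributions `S(j) = Smin*2.4^((j/N)^c)` and
   `IP(j) = a*j^b` are fitted, along with derecruitment-hysteresis
   parameters (`R^d`, `Cm^d`).
4. **Pool simulation.** `N` calibrated LIF models driven by the common
   current predict every spike train in the pool; the 0–4 Hz low-passed
   cumulative spike train is the effective neural drive to the muscle,
   validated against the normalized force. A multi-motor-unit Hill-type
   stage (two-stage calcium/calcium–troponin activation, linear force
   summation) converts the spike trains into isometric force.

The original recordings have no public accession, so the package ships a
synthetic fixture generator (`make_reference_fixture()`, `generate_truth()`,
`sample_identified()`) that emulates their statistical structure —
trapezoidal contractions, size-principle-ordered property distributions,
and the decomposition bias toward high-threshold units — making every
stage testable end to end.

## Worked example

Reconstruct a pool of 400 tibialis anterior MNs from a synthetic
"DTA35-like" dataset (35 %MVC trapezoid, 32 identified units, bias
exponent 2):

```r
library(monpool)
fx    <- make_reference_fixture("DTA35-like")
truth <- generate_truth(fx)                 # ground-truth pool + drive
ds    <- sample_identified(truth)           # biased 32-unit sample
rec   <- reconstruct_pool(ds$trains, ds$force, ds$protocol, n_pool = 400)
print(rec$coherence)
print(rec)
```

```
<coherence_report> half-sample coherence 0.64, extrapolated 0.78
  CSC vs force: r2 0.94, nRMSE 18.8% -> representative
<pool_reconstruction> 32 identified MNs -> pool of 400
<ip_distribution> IP(j) = 0.0269 * j^0.151 s (fit on 16 MNs); 1/IP(1) = 37.2 Hz
<size_distribution> S(j) = 1.63e-07 * 2.40^((j/400)^1.61) m^2, range [1.63, 3.92] e-7 m^2
  eND_N  vs force: <validation_metrics> nRMSE 8.35%, r2 0.954, nME 24.32%
  eND_Nr vs force: <validation_metrics> nRMSE 18.77%, r2 0.942, nME 43.27%
```

Reading this: the identified sample passes the representativeness check
(extrapolated coherence 0.78 > 0.7); the reconstructed pool's effective
neural drive tracks the ground-truth drive with nRMSE 8.4% and r² 0.95,
substantially better than the drive computed from the biased 32-unit
sample alone (nRMSE 18.8%) — the reconstruction recovers the
low-threshold activity that HDEMG decomposition misses. The fitted size
distribution spans 1.6–3.9 · 10⁻⁷ m², within the classic motoneuron
range.

`leave_one_out()` validates per-MN predictions, `sensitivity_to_n()`
sweeps the assumed pool size, `simulate_muscle()` produces the summed
motor-unit force, and `run_all()` drives the whole workflow from a YAML
config (a thin CLI lives in `exec/monpool`). The methods vignette
(`vignettes/pool-reconstruction.Rmd`) documents the model, every default
and the known limitations.

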