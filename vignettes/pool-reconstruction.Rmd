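---
title: "Reconstructing a complete motoneuron pool from identified motor-unit spike trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing a complete motoneuron pool from identified motor-unit spike trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monpool)
```

## The problem

High-density surface EMG (HDEMG) decomposition identifies the discharge
times of a few tens of motor units (MUs) during a voluntary contraction —
typically 10–40 units out of a pool of several hundred, and with a strong
bias toward the large, high-threshold units whose action potentials
dominate the surface signal. Many questions in motor control and most
motoneuron(MN)-driven muscle models, however, need the behaviour of the
*complete* pool. `monpool` implements a four-step workflow that
reconstructs the recruitment and firing behaviour of the full pool of $N$
MNs from the identified sample of $N_r$ spike trains and the synchronized
whole-muscle force trace of a trapezoidal isometric contraction.

## The model, step by step

**Step 1 — mapping.** The pool is ranked $j = 1..N$ by increasing force
recruitment threshold, following Henneman's size principle. A
muscle-specific threshold distribution
$$F^{th}(j) = k_1\left(k_2\,\tfrac{j}{N} + \Delta_F^{(j/N)^{k_3}}\right)$$
(for the tibialis anterior: $k_1 = 0.50$, $k_2 = 58.12$, $k_3 = 1.83$,
fold range $\Delta_F = 120$) is inverted by monotone root finding to
assign each identified MN, with recorded threshold $F_i^{th}$, a location
$N_i$ in the pool. The same distribution is reused for the gastrocnemius
medialis, for which no muscle-specific literature partition exists.

**Step 2 — common current input.** The cumulative spike train (CST) of
the identified sample, low-pass filtered in the 0–10 Hz band relevant for
force generation, estimates the effective neural drive, assimilated (in
arbitrary units) to the common synaptic input (CSI). Whether the sample
is *representative enough* for this to hold is checked by (i) the
magnitude-squared coherence between cumulative spike trains of
complementary random half-samples, averaged over 1–10 Hz and 20
permutations, extrapolated to the full sample size, and (ii) agreement of
the 0–4 Hz common synaptic control with the normalized force
(acceptance rule: extrapolated coherence > 0.7, $r^2 > 0.7$,
nRMSE < 30%). The CSI is then rescaled into a current drive anchored on a
published rheobase distribution
$I^{th}(j) = 3.9\,\mathrm{nA}\cdot 9.1^{(j/N)^{1.18}}$:
$I(t)$ is zero until the first identified MN fires, jumps to
$I^{th}_{N_1}$ there, and follows
$I(t) = I^{th}_{N_1} + G\,(CSI(t) - CSI(ft^1_{N_1}))$ with the gain $G$
chosen so that $I(ft^1_{N_r}) = I^{th}_{N_r}$ exactly. The plain gain
form $I^{th}_{N_1} + G\,CSI(t)$ satisfies its two anchors only when the
CSI is zero at onset; the anchored-affine form used here guarantees them
for any CSI normalization and reduces to the plain form in that special
case.

**Step 3 — LIF calibration.** Each MN is a single-compartment leaky
integrate-and-fire model whose five electrophysiological parameters
reduce to the membrane surface area $S$ through
$R = k_R / S^{2.43}$, $C = C_m S$, $\tau = RC$,
$I^{th} = \Delta V_{th}/R$ (Ohm's law), with $C_m = 1.3\,\mu F/cm^2$ and
$\Delta V_{th} = 27$ mV, plus an *inert period* (IP) during which the
membrane is held at rest after each spike, capping the firing rate at
$1/IP$ — a phenomenological stand-in for the rate saturation produced by
persistent inward currents. MNs whose sixth-order polynomial
discharge-rate trendline reaches 90% of its plateau mean during the ramp
(up to one second before the plateau) are detected as *saturating* and
get $IP = 1/\max(\text{trend})$; a power law $IP(j) = a\,j^b$ fitted to
the saturating MNs supplies the rest. The remaining free parameter
$S_i$ is calibrated per MN by bounded scalar (Brent) minimization of the
RMS difference between simulated and experimental Hann-smoothed discharge
rates over the window from contraction onset to the middle of the
plateau; the pool-wide size distribution
$S(j) = S_{min}\,\Delta_S^{(j/N)^c}$ ($\Delta_S = 2.4$ fixed) is then
fitted to the $(N_i, S_i)$ pairs. Derecruitment hysteresis (MNs stop
firing at lower current and rate than at recruitment) is captured by an
apparent resistance increase $R^d = R/k^{dth}_{th}$, with $k^{dth}_{th}$
the zero-intercept slope of derecruitment on recruitment current, and an
apparent specific-capacitance increase $C_m^d$ selected by grid search
(0.1 $\mu F/cm^2$ steps) minimizing
$J(C_m) = (\overline{nRMSE} + 100\,(1 - \overline{r^2}))/2$ on the
derecruitment window.

**Step 4 — pool simulation.** A cohort of $N$ LIF models parameterized by
$S(j)$ and $IP(j)$, all receiving $I(t)$, predicts the complete pool's
spike trains. The effective neural drive of the reconstruction,
$eND_N$ (0–4 Hz low-passed CST of the $N$ simulated trains), is validated
against the normalized force trace; leave-one-out prediction of each
identified train validates the per-MN behaviour.

A multi-MU Hill-type muscle stage converts spike trains into force: each
discharge drives a two-stage first-order excitation–contraction model
(calcium impulse with 20 ms decay; calcium–troponin binding at
30 s$^{-1}$, unbinding at 15 s$^{-1}$; saturating Hill nonlinearity with
half-activation 0.4), the MU force is the active state scaled by a
100-fold exponential distribution of maximal tetanic forces, and the
muscle force is the plain sum. The excitation–contraction constants are
modelling choices of this package (chosen for a ~50 ms twitch rise and
tetanic fusion near 100 Hz), validated by properties (fusion, twitch/
tetanus ratio, monotonicity), not against published force traces.
Force–length, force–velocity, tendon and passive-tissue dynamics are
deliberately absent: the target experiments are isometric at optimal
length.

## Numerical choices

* **Grid.** All derived signals live on the recording grid (2048 Hz by
  default), which makes binarization lossless to one sample. LIF
  integration uses the grid step (≈ 0.49 ms, well under the 1 ms bound);
  the default integrator is the forward scheme
  $V_m[n] = e^{-T/\tau} V_m[n-1] + (RT/\tau) I[n]$, and an exact
  exponential-integrator mode
  ($R(1-e^{-T/\tau})$ coefficient) serves as a cross-check — the two agree
  on steady-state rates to better than 1% at the default step.
* **Filters.** "Low-pass" is realized as a 4th-order Butterworth applied
  forward–backward (zero phase) with reflection padding; the mean is
  removed before filtering and restored after, so DC passes exactly.
* **Discharge-rate smoothing.** The instantaneous discharge frequency
  (IDF) places an impulse $1/(ft^{k+1}-ft^k)$ at each firing instant. Its
  400 ms Hann smoothing is implemented as a kernel-weighted moving
  average over the firing instants
  ($FIDF = \sum_k IDF_k w(t-ft_k) / \sum_k w(t-ft_k)$), which keeps the
  output on the discharge-rate scale: a constant-rate train maps to its
  rate. A plain unit-sum convolution would scale the output by the ratio
  of firing rate to grid rate and would not. Away from any discharge the
  FIDF is zero.
* **Coherence.** Welch estimator, 1 s Hann segments, 50% overlap,
  averaged over bins in 1–10 Hz. The extrapolation from half-sample to
  full-sample coherence inverts the composite-coherence relation
  $C_k = k\gamma/(1+(k-1)\gamma)$ at $k = N_r/2$ and evaluates it at
  $k = N_r$ — an analytic, reproducible stand-in for the figure lookup
  used in the source literature; it is an approximation.
* **Fits.** The threshold distribution is fitted by Levenberg–Marquardt
  to the per-index bin-midpoint step function with the boundary points
  $F^{th}(1)$ and $F^{th}(N)$ weighted 100:1 (the boundary conditions are
  stated in the literature without weights; 100:1 makes them effectively
  hard while keeping the problem smooth). Power laws ($IP(j)$, $S(j)$)
  are fitted in log space; $\Delta_S$ stays fixed at 2.4.
* **Determinism.** The LIF engine carries its own xorshift/Box–Muller
  generator so spike trains are bit-reproducible across platforms;
  per-MN seeds are `master_seed + j`, so enlarging the pool never
  perturbs existing trains. IP noise ($o \sim N(0, IP/10)$, truncated at
  $-IP$ so the refractory period cannot be negative) is disabled inside
  calibration objectives to keep them deterministic.
* **Degenerate inputs.** Trains with fewer than two discharges yield
  flagged empty rate series; a target MN with no discharges inside the
  calibration window is rejected with a clear error (it cannot be
  calibrated); fewer than two saturating MNs aborts with instructions to
  supply auxiliary IP anchor points (the documented remedy for sparse
  high-threshold-only samples); coincident discharges of one MN on one
  grid sample are an error by default, mergeable on request.

## What the synthetic fixtures emulate — and what they do not

The source datasets (trapezoidal contractions of tibialis anterior and
gastrocnemius medialis at 30–50 %MVC, 14–32 identified units at 2048 Hz)
have no machine-readable accession, so the package generates synthetic
stand-ins with the same statistical structure: a ground-truth pool with
the published threshold, rheobase, size and inert-period distributions; a
trapezoid common current scaled so the recruited fraction on the plateau
matches the threshold distribution at the plateau level (≈ 80% at
35 %MVC); derecruitment hysteresis with $k^{dth}_{th} = 0.9$ and
$C_m^d = 2.0\,\mu F/cm^2$; and an identified subsample drawn with
probability $\propto (j/N)^\beta$ ($\beta = 2$ by default), emulating the
documented bias of HDEMG decomposition toward high-threshold units. The
common drive carries band-limited (0–10 Hz) Gaussian fluctuations with a
10% coefficient of variation — without common fluctuations the coherence
analysis would be meaningless, since complementary half-samples would
share nothing but the near-DC trapezoid; 10% is a typical magnitude for
common synaptic fluctuations in steady isometric contractions. The
fixture's "experimental force" is the normalized ground-truth drive,
consistent with the premise that normalized force tracks the common
synaptic control in isometric contraction.

The fixtures do **not** emulate decomposition errors (missed or spurious
discharges), MN-specific synaptic noise, force-transducer dynamics,
fatigue, or nonlinear (PIC-mediated) input–output gain — all outside the
model being reconstructed. Passing the fixture-based tests therefore
shows that the workflow recovers what its own model family generates
under realistic sampling bias; it does not certify performance on real
recordings.

## Design choices where the design was open

* **Resistance anchor $k_R$.** The resistance–size law needs a scale
  never printed alongside it; the package anchors it at
  $(S, R) = (0.25\,mm^2, 2.0\,M\Omega)$, the midpoints of the classic cat
  motoneuron ranges ($[0.15, 0.36]\,mm^2$, $[0.5, 4.1]\,M\Omega$), which
  reproduces the quoted resistance span ratio (8.4 vs 8.2). It is a
  config parameter. Note the quoted rheobase distribution and resistance
  range are not mutually consistent under strict Ohm's law; both are kept
  as published.
* **Typographically ambiguous relations** are interpreted on physical
  grounds: $R = k_R/S^{2.43}$ (larger MNs have lower resistance, as the
  size principle requires) and $I^{th} = \Delta V_{th}/R$ (Ohm). The
  derecruitment cost $J(C_m)$ is read as the equal-weight combination
  $(\overline{nRMSE} + 100(1-\overline{r^2}))/2$, both terms on a 0–100
  scale, consistent with "lowest output" selection and the observed
  parabolic behaviour.
* **$r^2$** is the squared Pearson correlation of the compared traces
  (the convention in this literature for normalized trace agreement);
  nRMSE and nME normalize by the range of the reference trace.
* **Saturation window** "[ramp start, plateau start − 1 s]" follows the
  stated reading "the rate reached one second before the plateau".
* **Spike timing** is reported at the grid sample where threshold is
  crossed, matching the discrete recurrence; no sub-step interpolation.
* **Calibration determinism.** Whether IP noise is active inside the
  calibration objective is unstated in the source description; it is
  disabled here so the objective is deterministic and Brent minimization
  is well-posed.

## Problem sizes used in the tests

The test-suite fixtures use the full reference configuration
($N = 400$, $N_r = 32$, 30 s at 2048 Hz) for the end-to-end and
emergent-physiology checks, a 20-unit evenly spread sample for
leave-one-out validation, and 5–12 s protocols for unit-level checks;
these sizes keep the whole suite within a few minutes on one CPU while
exercising every stage at realistic scale.

## Known limitations

* The reconstructed current is an affine image of the sample CST; when
  the sample's recruitment density over time differs from the pool's, the
  current inherits a shape distortion that per-MN size calibration can
  absorb only pointwise. The fitted fixed-fold-range power law $S(j)$
  then carries systematic residuals of a few percent at mid-to-high pool
  indices, and near the plateau — where the current flattens — small
  rheobase errors translate into recruitment-time errors of seconds for
  held-out units. This is the dominant error mode of leave-one-out
  validation here, as it is in the source datasets' last-recruited
  quartile.
* Before the first identified MN fires, the current is identically zero,
  so every lower-threshold unit of the reconstruction recruits
  simultaneously at that onset; samples missing the low-threshold half of
  the pool degrade accordingly (the documented failure mode of sparse
  high-threshold-only datasets).
* The LIF + inert-period model has no true rate adaptation, no
  conductance synapses and no explicit PIC dynamics; $R^d$ and $C_m^d$
  are phenomenological descriptions of hysteresis, not mechanisms.
* The muscle stage omits force–length/velocity and tendon dynamics by
  design and its excitation–contraction constants are package defaults,
  so its outputs are meaningful in normalized form only.
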