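---
title: "Models and methods behind presynaptica"
author: "presynaptica authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind presynaptica}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(presynaptica)
```

# Scope

`presynaptica` analyses whole-cell recordings of evoked and spontaneous
excitatory postsynaptic currents (EPSCs) and presynaptic calcium-imaging
stacks, and ships a generative simulator of the presynaptic terminal so
that every analysis stage can be validated against known ground truth.
The scientific setting is short-term plasticity at small glutamatergic
synapses: during a high-frequency train (20 Hz, 40 action potentials over
2 s) the readily releasable pool (RRP) of vesicles is depleted by release
and refilled by recruitment, and the balance of the two sets whether the
response depresses (STD) or is enhanced (STE). A calcium-activated
TRPC-like conductance provides a secondary, perisynaptic calcium-entry
pathway that accelerates recruitment; the simulator makes that hypothesis
executable.

# The generative model

## Bulk calcium

Bulk presynaptic calcium C (nM) follows

$$\frac{dC}{dt} = -\frac{C - c_{rest}}{\tau_{clear}}
  + J_{TRPC}\,\frac{C^{n}}{C^{n} + EC_{50}^{n}},$$

with an instantaneous increment $\Delta C_{AP}$ at every action
potential. The Hill term models calcium-activated TRPC-like channels with
$EC_{50} = 635$ nM; the Hill coefficient is not constrained by available
measurements, so the package defaults to $n = 2$ (configurable), a
typical value for cooperative calcium activation. Integration starts at
the resting fixed point $c_0$ of the equation (found by root solving), so
a stimulus-free simulation is stationary by construction; a rest-stability
test verifies drift below 1% over 60 s.

Defaults ($c_{rest} = 100$ nM, $\Delta C_{AP} = 100$ nM,
$\tau_{clear} = 0.1$ s) were chosen once so that a 20-Hz train drives
bulk calcium from rest to a few hundred nM without TRPC influx, i.e. into
the foot of the 635-nM activation curve, which is the regime in which a
calcium-activated secondary pathway can act as a switch. $J_{TRPC}$ spans
0 (knockout-like) to 8000 nM/s (strong-expression-like); the default
4000 nM/s produces an intermediate, wild-type-like phenotype.

## Vesicle pool

Pool occupancy N evolves between APs by

$$\frac{dN}{dt} = k_0\,(n_{max} - N)
  + k_{Ca}\,(C - c_0)_+\,(f_{over}\,n_{max} - N),$$

and each AP releases $\mathrm{Binomial}(N, p_r)$ vesicles synchronously
(expectation $N p_r$ in deterministic mode). The first term is baseline
refilling towards the resting capacity $n_{max}$ (and drains transient
excess back to $n_{max}$ after activity); the second is calcium-dependent
recruitment from the reserve pool, gated by supra-resting calcium, which
can transiently overfill the pool up to $f_{over} n_{max}$
(default 1.8). The overfill term is essential: with a hard ceiling at
$n_{max}$ the 10th-to-1st amplitude ratio can never exceed 1, whereas
transient overfilling by activity-dependent reserve-pool mobilisation is
exactly what synaptic enhancement during a train requires. Gating with
$(C - c_0)_+$ rather than raw C keeps the rest state exactly at
$n_{max}$.

Asynchronous release is an inhomogeneous Poisson process with rate
$\alpha (C - c_0)_+ N / n_{max}$, each event consuming one vesicle, so
synchronous, asynchronous and evoked charges all draw on a single pool
ledger. Spontaneous minis are Poisson at `miniRate0` plus the same
calcium-dependent term but do not consume the pool; this is how a
TRPC agonist (modelled as an added calcium influx plus a smooth direct
inward current) raises mini frequency.

Default rates ($n_{max} = 300$, $p_r = 0.3$, $k_0 = 0.3\,s^{-1}$,
$k_{Ca} = 0.017\,nM^{-1}s^{-1}$) place the depletion/recruitment balance
so that the deterministic amplitude ratio crosses 1 within the swept
$J_{TRPC}$ range; they are calibrated to qualitative phenotype
directions, not to any absolute charge values.

## Drug modes

* **EGTA (slow chelation)**: all bulk calcium increments and the TRPC
  influx are scaled by $1/(1+\kappa_E)$ (default $\kappa_E = 9$); phasic
  release is untouched because slow chelators cannot intercept calcium in
  the nanodomain of an open channel before it triggers fusion. The
  closed-form utility `egtaCaptureLength()` quantifies that separation:
  with $D_{Ca} = 2.2\times10^{-6}\,cm^2/s$ and a 100-µs chelation time
  constant, calcium diffuses $\sqrt{6 D \tau} \approx 363$ nm before
  capture, so entry sites beyond ~350 nm from the active zone are
  silenced while the release trigger is spared.
* **TEA (K-channel block)**: broadened APs are summarised as
  $\Delta C_{AP} \times f_{TEA}$ and $p_r \times f_{pr}$ (defaults 2 and
  1.5) — more influx *at* the active zone, hence a larger first EPSC and
  a lower paired-pulse ratio, without modelling AP waveforms.
* **Agonist**: a direct inward current (default 500 pA, raised-cosine
  edges) plus a constant calcium influx during the application window.

## Current rendering

Each quantum contributes a peak-normalised double-exponential kernel
$A\,(e^{-t/\tau_d} - e^{-t/\tau_r})/k$ with lognormal amplitudes
(mean 30 pA, CV 0.3; evoked and spontaneous quanta share the
distribution). Synchronous quanta sit at AP time + 1 ms, with 0.3-ms
Gaussian jitter in stochastic mode only, keeping the
synchronous/asynchronous decomposition crisp. Deterministic
(expectation) mode renders expected quanta and the continuous
release-rate trace without sampling or noise; stochastic mode adds
Gaussian recording noise (default 3 pA SD). Rendering convolves an
impulse train with the kernel via an FFT padded to a power-of-two
length. Traces store inward currents as negative; every analysis flips
the sign internally and reports magnitudes.

# Analysis conventions

**Charge decomposition.** Per stimulus, the total charge integrates the
sign-flipped, pre-train-baseline-subtracted current over the
interstimulus interval; the asynchronous charge is the mean current over
the final 5 ms of the interval times the interval duration; synchronous
charge is the difference. The 5-ms window width is the package's choice:
at 20 Hz it sits 10 decay time constants after the synchronous peak, so
the decaying synchronous tail no longer contaminates the steady-state
estimate.

**Amplitudes.** Peaks are searched 1–10 ms after each stimulus (the
first 1 ms is blanked to cover the depolarisation artifact) against a
local 1-ms pre-stimulus baseline by default, which tolerates summation
on a standing asynchronous current; a global pre-train baseline is
available via `analysisConfig(amplitudeBaseline = "global")`.

**RRP back-extrapolation.** Ordinary least squares on the last 5 points
of the cumulative synchronous charge, extrapolated to stimulus 0. Figure
conventions in the field vary between the last 5 and the last 4 points;
both regressions take their span from the configuration (default 5) and
the values used are logged in the result's `fitDiagnostics`. A negative
intercept — which arises whenever late-train charges accelerate, i.e.
precisely in strongly enhancing cells — is reported as undefined with a
flag, never clamped to zero, since clamping would bias group summaries.
Steady state is declared when the mean synchronous charge of the last
five stimuli is within 15% of the previous five; the comparison scale is
floored at 1% of the first-stimulus charge so that a fully depleted
(essentially zero) tail still counts as steady.

**Release probability and replenishment.** Pr is the first synchronous
charge divided by the RRP charge, undefined whenever the RRP is. The
replenishment rate is the OLS slope of cumulative total charge over the
last 5 points; because figure axes in the field are ambiguous between
per-stimulus and per-second units, both are reported (pC per stimulus,
and times the train frequency as pC/s).

**Recovery kinetics.** Fractions (test amplitude / first train
amplitude) at eight intervals from 20 ms to 4.15 s are fitted with
$f(t) = k_{off} + EPSC_\infty (1 - e^{-t/\tau})$ by multi-start
Levenberg–Marquardt ($\tau$ starting at 0.1, 0.5 and 2 s, bounded
positive). Flat data make $\tau$ unidentifiable; the fit is then flagged
degenerate rather than silently reported.

**Sucrose.** The steady-state current is the mean over the final 10% of
the application window; the RRP transient is the integral above it,
negative excursions truncated at zero. A pre-application baseline is
subtracted when at least 100 ms of pre-window trace exist.

**Minis.** The acceptance criteria are a peak amplitude above 5 baseline
noise SDs *and* a charge above 25 fC. The detector around them is the
package's own: candidate onsets from threshold crossings of the smoothed
first derivative (threshold 4 robust SDs of the derivative, floored so a
candidate must be able to reach the amplitude criterion within 5 ms),
local-baseline peak measurement with window extension for late peaks, a
2-ms refractory merge, and charge integrated from onset until the trace
returns within one noise SD of baseline, capped at 50 ms. The charge
window is unspecified in common practice; the return-to-baseline rule
with a cap is bounded and deterministic. Noise SD is a
median-absolute-deviation estimate on the running-median-detrended trace
outside detected events.

**Agonist responses.** Frequency fold change is the drug-window event
rate over the baseline rate; a cell responds at a fold change of 1.2 or
above (strictly below 1.2 is a failure to respond). The maximal inward
current is measured on a 100-ms-smoothed trace relative to the
baseline-window median.

**Imaging.** F0 is the ROI mean of the 3 prestimulus images;
$\Delta F_n/F_0 = (\bar F_n - \bar F_0)/\bar F_0$ per 4×4-pixel ROI. The
background noise SD pools ROI-sized tiles of the non-ROI area across the
post-baseline frames: background tiles are stimulus-free, so all their
frames are valid noise samples, while the baseline frames are excluded
because they share the F0 estimate and would bias the SD low — with only
3 baseline frames that bias is large enough to roughly double the
false-responsive rate of the 3-SD rule. Responsiveness requires the
maximal $\Delta F/F_0$ to exceed 3 background SDs strictly. The slope
metrics regress $\Delta F/F_0$ on frame index over data points 6–13
(during the train, for a train starting at frame 4 of a 5-Hz series) and
14–20 (after it); indices are 1-based over the whole acquired series
including the baseline frames, and configurable, since conventions
differ on whether such points are counted from trace start or stimulus
onset.

# Reporter model

Imaging stacks are rendered from the simulated calcium as
$F = F_{rest}\,(1 + R_{max}\,\mathrm{hill}(\bar C; K_d, n))$ per frame
(frame-averaged calcium), plus Poisson photon noise; background pixels
sit at $F_{rest}$. The default $K_d$ of 1000 nM is deliberately higher
than typical high-affinity indicators: it keeps the reporter within its
dynamic range over the simulated bulk-calcium excursions so that
rank-order comparisons of $\Delta F/F_0$ slopes remain faithful to the
underlying calcium. With a high-affinity indicator the during-train
signal saturates and slope comparisons compress; users modelling a
specific indicator should set `gcampParams()` accordingly.

# Numerical choices

* Fixed-step explicit Euler, dt = 0.1 ms, for both calcium and pool:
  all time constants are ≥ 100 ms, so the scheme is stable with local
  error well below measurement noise, and it is exactly reproducible.
  Instability (negative or divergent calcium) raises an error advising a
  smaller step.
* One RNG stream per run, seeded from the user seed; the pool simulation
  seeds the stream and the renderer continues it, so a (params,
  protocol, seed) triple yields bit-identical traces. Derived seeds
  (`seed + i`) index replicate runs.
* Stimulus-free stochastic recordings shortcut to homogeneous Poisson
  sampling of the closed-form stationary state — identical in law to the
  stepped simulation, without the integration cost.
* Validation problem sizes: 200 stochastic depletion runs for
  RRP/Pr recovery; 20 two-minute recordings for the mini-detection
  operating point (fixed 16-pA quanta on 2-pA noise, i.e. SNR 8 by
  construction — with the default lognormal CV a fraction of events
  falls below the 5-SD amplitude criterion itself, which no detector
  honouring the criteria could accept); 100 noisy recovery curves;
  30 stacks × 64 background tiles for the responsiveness calibration.

# What the synthetic data do and do not show

The simulator emulates train depression/enhancement, asynchronous
buildup, recovery test pulses, sucrose applications, spontaneous and
agonist-evoked minis, and 5-Hz reporter stacks — with full ground truth.
It does not model conductance-based AP/channel biophysics, spatial
calcium diffusion (the 363-nm estimate is a closed-form utility, not a
PDE), postsynaptic receptor kinetics beyond the fixed quantal kernel,
series-resistance or dendritic filtering artifacts, or slow drifts and
seal instabilities of real recordings. Passing the validation battery
therefore certifies the *analysis implementations* (unbiasedness,
oracle-equivalence of the regressions, detector operating points,
threshold calibrations) and the *directional logic* of the
calcium-recruitment hypothesis; it does not certify absolute parameter
values for real synapses, and the simulator's defaults are not fits to
any experimental data set.

# Known limitations

* The back-extrapolation RRP estimator is biased low whenever
  recruitment is strong during the train; in the enhancing regime it is
  undefined by design (negative intercept). The sucrose route is the
  appropriate estimator there, as in experimental practice.
* The mini detector is threshold-based by design (the published criteria
  are thresholds); heavily overlapping events at very high rates merge
  under the 2-ms refractory rule.
* Deterministic mode renders expectations, so quantities that are
  nonlinear in the event process (e.g. peak summation statistics) differ
  slightly from stochastic means; the expectation-consistency test
  bounds the difference for the quantities the pipeline reports.
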