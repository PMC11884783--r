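---
title: "A hippocampo-thalamo-cortical neural-mass model and the NREM coupling pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hippocampo-thalamo-cortical neural-mass model and the NREM coupling pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`somnet` couples two things that are usually studied separately: a
population-level (neural mass) firing-rate model of the network linking
the hippocampus (CA3, CA1), two interconnected cortical networks (CX,
CX'), and three thalamic nuclei (mediodorsal MD, reticular TRN, and the
midline reuniens REU); and the NREM-sleep electrophysiology pipeline —
staging, slow-wave / spindle / sharp-wave-ripple (SWR) detection,
phase-amplitude coupling via a synchronization index, spike analysis,
and evoked-response quantification — that is normally applied to real
recordings. A seeded synthetic-data module generates signals with exact
ground truth so every stage of the pipeline is testable without any
recordings.

# The rate model

Each population is described by its mean membrane potential $V$ (mV).
Cortical, hippocampal and reuniens populations fire at a sigmoid rate

$$r(V) = r_0 + \frac{r_1}{1+\exp(-(V-V^*)/g)},$$

with $r_0 = 0.1$ Hz and $r_1 = 70$ Hz. MD and TRN carry a second,
burst-mode sigmoid; the two are blended by $e^{Lu}$ where $u \le 0$ is a
burst variable driven by a voltage switch: $b = -200$ (or the calibrated
value) while the cell is hyperpolarized below its switch threshold
($-0.1$ mV for MD, $0$ mV for TRN), $b = 0$ above, and
$\dot u = (b-u)/\tau_u$. An additional current
$-f_{\max}/(1+\exp((u+f_{th})/q))$ activates when $u$ is strongly
negative; with the calibrated negative $f_{\max}$ it depolarizes the
primed cell, i.e. it acts as a low-threshold (T-type-like) rebound
current. Excitatory-to-excitatory synapses onto cortical and
hippocampal excitatory populations are scaled by a spike-frequency
adaptation sigmoid $J(c) = J_0/(1+\exp((c-c^*)/g_c))$ whose variable
$c$ integrates presynaptic excitatory firing.

The full model is seventeen coupled rate equations (two cortical E-I
pairs with adaptation, CA3 E-I with adaptation, CA1 E-I with
adaptation on its extrinsic inputs, MD and TRN with their burst
variables, and a single reuniens population), integrated with a
fixed-step fourth-order Runge-Kutta scheme at $dt = 1$ ms. The compiled
integrator and the exported R derivative (`model_derivatives()`) are
independent transcriptions, cross-checked in the test suite.

## Rhythm generation

* **Slow oscillation (0.5–2 Hz).** The cortical E-I pairs are
  excitable: recurrent excitation ignites an up state, adaptation
  terminates it, and the barrier to re-ignition makes the cycle
  irregular under the background input (below). Up states last about
  0.5–0.8 s at 0.2–0.5 per second.
* **Sharp waves / ripples.** CA3 is a relaxation oscillator (strong
  recurrent excitation, fast adaptation) producing brief sharp-wave
  depolarizations about once per second. These drive the CA1 E-I pair,
  whose steep rate sigmoids and fast membranes form a 150–200 Hz
  resonator; each sharp wave rings it, producing a ripple transient on
  the CA1 excitatory potential.
* **Spindle-band transients.** During down states, tonic TRN output
  holds MD below its burst switch and primes $u$; at the down-to-up
  transition, cortical drive to TRN transiently inhibits MD further and
  the rebound current then launches a train of MD bursts at ~8–14 Hz,
  relayed to the cortex by the MD→CX' projection and to the reuniens by
  TRN inhibition.
* **Reuniens.** REU is driven mainly by CX, with a membrane time
  constant of 0.18 s; its slow waves are a lagged copy of the cortical
  ones (median trough lag ~0.11 s). CA1 input adds SWR-locked
  depolarizations and the REU→CA1 projection feeds cortical timing back
  to the hippocampus, which is what phase-locks detected SWRs to the
  cortical slow wave.

## Parameters

Every constant of the rate equations is addressable by name in
`inst/extdata/model_params_default.txt` (e.g. `J.ee.CA3_CA1`,
`tau.REU`, `RT.MD`). All numeric values are this package's own
calibration: the sources that specified the original network constants
are not available, so the defaults were tuned until the isolated
subnetworks generate their characteristic rhythms and the coupled
network reproduces the NREM coupling regime (slow-wave dominance of the
cortical trace, ripple transients during sharp waves, thalamic
spindle-band transients during up states, reuniens slow waves lagging
cortical ones). Two published constants were deliberately recalibrated:
the burst switch amplitude for MD (`b.MD = -450` rather than $-200$;
deeper priming gives multi-cycle rebound trains) and the sign of
`f.max` (negative, making the burst-switch current a rebound
depolarization — with the printed sign the primed state is absorbing
and the thalamus locks up).

## Background input and determinism

The equations are deterministic, and `simulate_network()` defaults to
the deterministic system; the fully deterministic network settles into
a periodic orbit, which is incompatible with the SD-relative detection
rules (no event ever exceeds mean + 3 SD of a perfectly periodic
signal) and with the event-timing dispersion the modelled statistics
require. The calibrated configuration therefore includes a seeded
additive Gaussian input (`noise.sd = 2` mV·s^-1/2) on the cortical and
CA3 membrane potentials — background synaptic bombardment of the
forebrain populations; the thalamus, reuniens and CA1 receive their
fluctuations through the connectivity. `simulate_nrem_session()`
applies this level; the same seed gives bit-identical traces.

## Numerical choices

$dt = 1$ ms; a 20 s burn-in is discarded. RK4 against the closed-form
leak solution is accurate to $<10^{-6}$ relative error, and step
halving shows the expected high-order convergence on a smooth
configuration (the burst switch is a discontinuity, so the order test
disables it). The burst variables are clamped at $u \le 0$; user
states with $u>0$ are rejected. Non-finite states abort the
integration with the offending variable and time.

# The analysis pipeline

* **Staging** follows the two-threshold rule on 5 s bins of squared
  signals (mPFC and delta power above mean + 1 SD, EMG below mean − 1
  SD; wake bins with low EMG and EOG above mean + 1 SD become REM),
  majority-labelled into 20 s epochs with ties as Transition. A
  consequence of the mean ± 1 SD rule worth knowing: with bimodal bin
  distributions the EMG gate only separates states when more than half
  of the session is high-EMG (wake-majority sessions); the synthetic
  staging fixtures respect this.
* **Slow waves**: 0.5–4 Hz zero-phase FIR (order = 3 cycles of the low
  cut-off), positive peaks above 2.5 SD with peak-to-peak above 4 SD,
  kept only when the enclosing positive-to-negative zero-crossing pair
  of the 0.5–2 Hz signal spans 0.5–2 s. The down-state (trough) time is
  taken from the 0.5–2 Hz signal — the same signal that defines the
  cycle — because the 0.5–4 Hz minimum is biased by waveform asymmetry
  when comparing channels with different spectral content. Both the
  experimental (peak) and model (trough) reference conventions are
  exposed.
* **Spindles**: 7–15 Hz, Hilbert amplitude, 300 ms Gaussian smoothing,
  candidates above mean + 3 SD extended to the 2.5 SD crossings, merged
  within 0.5 s, kept at 0.5–3 s duration.
* **SWRs**: 150–200 Hz, RMS envelope (squared signal, 50 ms Gaussian,
  square root), above median + 4 SD for at least 30 ms. The
  median-plus-SD mix is implemented literally.
* **Synchronization index**: $SI = m^{-1}\sum_j e^{i(\theta_{sw}(j)-
  \theta_{amp}(j))}$ over ±0.25 s around the slow-wave reference;
  $\theta_{amp}$ is the Hilbert phase of the spindle-band amplitude
  envelope filtered in the slow-wave band (the short-time-Fourier
  route of `event_locked_tfr()` is equivalent up to smoothing
  bandwidth). Rayleigh p uses the standard large-sample approximation;
  a Watson-Williams two-sample test is provided.
* **Spikes**: robust (median/0.6745) SD estimate for the −4 SD
  threshold, 0.75 ms shadow, 1.5 ms snippets, per-channel
  peak-to-trough/trough/max-channel features, PCA to two components,
  Gaussian mixture with BIC-selected component count, Mahalanobis
  pruning at radius 4. On a Gaussian background the −4 SD threshold
  admits chance crossings at roughly 0.3–0.5 per second (Rice's rate);
  the clustering stage is what removes them.
* **PETHs** are z-scored against 100 surrogate PETHs with event times
  jittered within ±0.5 s; any bin beyond ±2 SD in the 150 ms
  post-onset window classifies a unit as activated/suppressed (the
  any-bin rule is the default; the window is a parameter).
* **Evoked responses**: 4-parameter logistic fit to the rising phase;
  latency at 10% of fitted amplitude, slope $A/(4\,\mathrm{scale})$,
  hyperpolarization measured from the fitted lower asymptote;
  orthodromic/antidromic classification by latency SD (default
  threshold 0.3 ms) with a two-cluster check for mixed responses.

# The synthetic-data module

`gen_nrem_lfp()` builds $1/f$ background plus biphasic slow waves,
Hann-enveloped spindle bursts and Gaussian-windowed 180 Hz ripple
packets. Two deliberate design points: the spindle envelope is a Hann
window because its waxing-waning component is a pure tone at
1/duration Hz — with duration equal to the slow-wave period the
coupling phase $\varphi_0$ transfers to the synchronization index
without distortion; and ripples can be tied to spindle onsets with a
configurable lead to emulate SWR-before-spindle timing.
`gen_session()` concatenates state segments with state-appropriate
spectra (EMG/EOG are white noise: broadband channels with stable 5 s
bin power). What these fixtures do not emulate: non-stationary
amplitude drift, movement artifacts, volume conduction, electrode
noise; passing tests demonstrate correctness of the implementations,
not field-readiness for arbitrary recordings.

# Reproduction of the modelled statistics, and known limitations

At the shipped calibration a 1000 s session (20 s burn-in discarded)
yields roughly 0.36 slow waves and 0.29 SWRs per second. The reuniens
slow-wave trough lag reproduces the modelled value (~0.113 s median),
and SWRs are significantly phase-locked to the cortical slow wave with
a mean phase a few tens of degrees before the peak.

The main known limitation is spindle expression. The thalamocortical
loop at this calibration is subcritical: rebound-burst trains ring for
roughly three to seven cycles (0.2–0.45 s of elevated 7–15 Hz
envelope) instead of self-sustaining for the 0.5 s the experimental
duration criterion requires, so the spindle detector returns few or no
events on model traces, the spindle-onset lag and the SWR-rate lead
before spindle onset are often not computable, and the
synchronization-index strength is dominated by slow-wave-locked
spectral leakage (medians near 1 rather than the modelled 0.58/0.66 —
though the reuniens-above-cortex ordering does hold). The acceptance
suite states these checks at their original tolerances and they fail
honestly; `analysis/` and `scripts/acceptance.R` compute whatever the
detectors yield and omit statistics whose event sets are too small
rather than substituting values.

# Problem sizes used

The acceptance analyses use one 1000 s session at 1 kHz; the
connectivity sweep defaults to 3 × 3 cells at 220 s each; unit-test
fixtures are 30–1500 s at 250–20000 Hz depending on the stage under
test. Every stochastic step is seeded and reproducible.
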