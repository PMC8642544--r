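---
title: "Distilling rate networks into robust spiking networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distilling rate networks into robust spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Mixed-signal neuromorphic processors implement leaky integrate-and-fire
(LIF) neurons and synapses in analog silicon. Analog circuits suffer from
*device mismatch*: fabrication-induced, frozen variation of time
constants, thresholds and effective weights between nominally identical
units, typically 10--20% relative spread, plus thermal noise and coarse
weight quantisation. A spiking network trained offline and copied onto
such a device therefore runs with parameters it was never trained for.
Per-device calibration or on-chip learning is expensive; the alternative
pursued here is to train networks that are robust *by construction*.

`adsnet` implements a two-stage supervised pipeline:

1. **Teacher.** A non-spiking recurrent tanh rate network is trained on
   the task by backpropagation through time (BPTT) on a mean-squared-error
   loss,
   $$\tau_j \dot{\hat x}_j = -\hat x_j + (\hat F c)_j +
     (\hat\Omega \tanh \hat x)_j + b_j, \qquad \hat y = \hat D \hat x .$$
2. **Spiking mimic.** A population of $N$ LIF neurons (the "arbitrary
   dynamical system" network) learns to reproduce the teacher's *state
   trajectory* $\hat x(t)$, not just its output. The population decodes as
   $\tilde x = F r$ from the slow-filtered spike trains $r$, using a
   random encoder $F$. During training the decoding error
   $e = \hat x - \tilde x$ is fed back as a membrane current $k F^\top e$
   that clamps the spiking network to the teacher trajectory, while the
   slow recurrent weights learn with the local rule
   $$\Delta\Omega^s_{ij} = \eta\, (F^\top e)_i\, r_j$$
   applied every step. At inference the feedback is removed ($k = 0$) and
   the spiking network replaces the teacher entirely:
   $\tilde y = \hat D \tilde x$.

Robustness comes from the *efficient balanced network* structure: fast
recurrent feedback $\Omega^f = s\,(F^\top F + \mu I)$ makes the population
code redundant and self-correcting, so that parameter perturbations and
even sudden silencing of a large subpopulation are compensated in real
time by the remaining neurons.

## Neuron and synapse model

Membrane dynamics (forward Euler, step $\Delta t$):
$$\tau_{\mathrm{mem}} \dot V = V_{\mathrm{rest}} - V + I_{\mathrm{inp}}
  + I_{\mathrm{fast}} + I_{\mathrm{slow}} + I_e, \qquad
  o = V > V_{\mathrm{thresh}},$$
with reset to $V_{\mathrm{reset}}$ regardless of overshoot, no refractory
period, and at most one spike per neuron per step by construction. Both
synapse channels follow
$\tau_{\mathrm{syn}} \dot I = -I + (W o)\,\tau_{\mathrm{syn}}/\Delta t$:
a unit-weight spike injects a PSP of height 1 whose discrete integral is
exactly $\tau_{\mathrm{syn}}$. Defaults (all configurable through
`lif_params()`):

| parameter | default | meaning |
|---|---|---|
| `tau_mem` | 50 ms | membrane time constant |
| `v_reset`, `v_rest`, `v_thresh` | 0, 0.5, 1 | reset / rest / threshold |
| `tau_fast` | 1 ms | fast (balancing) synapse, carries $-\Omega^f o$ |
| `tau_slow` | 70 ms | slow (learned) synapse, carries $+\Omega^s o$; also the decoding filter |
| `dt` | 1 ms | simulation step |

The decoded trace `r` and the slow synaptic current use the same
exponential kernel; the decoder reads the trace as it stands at the
beginning of each step (spikes take effect from the following step, a
one-step latency inherent to the clocked simulation).

## Voltage units and the current scale

The balanced-network theory behind the fast weights defines per-neuron
thresholds of order $\lVert F_i\rVert^2/2$ — tiny numbers for an encoder
whose entries are $N(0, 1/\hat N)$. Hardware instead fixes a uniform
threshold gap $V_{\mathrm{thresh}} - V_{\mathrm{reset}}$. The two pictures
are related by a linear change of voltage units: the package rescales the
Gram matrix into $\Omega^f$ with the scalar
$s = (V_{\mathrm{thresh}} - V_{\mathrm{reset}}) /
\operatorname{mean}\operatorname{diag}(F^\top F + \mu I)$ and applies the
*same* scalar to the feed-forward drive $s\,F^\top(\hat F c)$, so that a
spike's self-reset through $-\Omega^f$ spans exactly the threshold-to-reset
gap while the input drive keeps its balanced-network proportions. Without
this conversion the input drive is two orders of magnitude below
threshold and the free-running network is silent — the method cannot
ignite. The error-feedback rate $k$ and the learning rate $\eta$, by
contrast, act on the raw teacher-space projection $F^\top e$, which keeps
their values (75 and $10^{-5}$ for the XOR task) independent of the
hardware voltage scale. `ads_network()` stores the factor as
`current_scale`.

The error sign convention: the package feeds back $k F^\top(\hat x -
\tilde x)$, the direction that *clamps* the network onto the teacher
trajectory (positive feedback on the deviation would diverge), and the
learning rule uses the same projected error as its postsynaptic factor,
so the slow weights absorb exactly the current the clamp was providing.

## The error-feedback schedule

With $k$ large the network is held close to $\hat x$ and the learning
rule sees clean errors; but a network trained only at large $k$ learns to
*rely* on the clamp and fails once it is removed. `feedback_schedule()`
holds $k$ fixed over blocks of samples; two presets ship:

* `"xor"` — fixed $k = 75$, $\eta = 10^{-5}$, single stage;
* `"speech"` — $k$ stepping $200 \to 25$ in 8 even stages,
  $\eta = 10^{-4}$ (5 epochs of 1000 samples).

`evaluate_ads()` always runs at $k = 0$: inference never sees a teacher.

## Tasks

**Temporal XOR** (`generate_xor_sample()`): 1 s single-channel signals at
1 ms; two Gaussian-smoothed bumps of sign $\pm 1$ and width uniform in
66--157 ms are placed without overlap (20 ms margin, placement uniform
over the admissible gaps) in the first two thirds; the target is a single
smoothed bump in the last third, positive iff the input signs differ.
Readout: first $\pm 0.5$ crossing inside the target window; no crossing
counts as an error. Unstated geometry chosen once and exposed as config:
smoothing s.d. 10 ms, target-bump width 120 ms, centred in its window.

**Filterbank front-end** (`filterbank_features()`): 16 second-order
Butterworth band-passes centred 0.4--2.8 kHz (even spacing, bandwidth one
channel spacing), `abs` rectifier, second-order low-pass at 0.3 kHz,
causal single-pass filtering, downsampled to the network step. The
`synthetic_keyword()` generator stands in for a wake-phrase corpus: a
stereotyped three-chirp sequence embedded in coloured noise at 10 dB SNR
against noise-only or order-shuffled negatives. It emulates the
spectro-temporal *structure* of keyword audio (band-limited formant-like
events in noise), not real speech variability — results on it say nothing
about real-speech accuracy, which is out of scope here.

## Robustness models

* **Device mismatch** (`apply_mismatch()`): every targeted parameter
  $\theta$ is redrawn as $\theta' \sim N(\theta, \delta\lvert\theta\rvert)$
  — the linear mean--variance relationship measured on analog LIF arrays;
  study levels $\delta = 5, 10, 20\%$. All five weight matrices and the
  per-neuron thresholds, resting potentials (the membrane bias term) and
  time constants are targeted; perturbed time constants are floored at
  0.1 ms and thresholds at 1% of the gap above reset. Zero-valued
  parameters stay exactly zero.
* **Quantisation** (`quantize_weights()`): per-matrix grid
  $\rho = (\max W - \min W)/(2^b - 1)$, $W_q = \rho\,\lfloor W/\rho\rceil$
  with half-away-from-zero rounding, applied post-training; sweep 2--6
  bits.
* **Thermal noise**: each Euler step adds
  $N(0, \sigma (V_{\mathrm{thresh}} - V_{\mathrm{reset}}))$ to every
  membrane potential, $\sigma \in \{1, 5, 10\%\}$. (Modelled as a direct
  per-step membrane perturbation; expressed as a current it corresponds to
  a $\tau_{\mathrm{mem}}/\Delta t$-scaled noise current.)
* **Silencing** (`silence_spec()`): a random fraction (study value 40%)
  of membranes clamped to $V_{\mathrm{reset}}$ mid-trial.

`run_robustness_suite()` sweeps a grid, pairing trial seeds across levels
so that level effects are not confounded with task sampling, and
`compare_distributions()` provides the two-sided Mann–Whitney U test
(exact for small tie-free samples) and Levene variance test used to
compare architectures.

## Numerical and design choices

* **Teacher trainables** are $\tau$, $\hat F$, $\hat\Omega$, $b$; the
  readout $\hat D$ is a fixed random projection (entries
  $N(0, 1/\sqrt{\hat N})$). Time constants are clipped at 1 ms after each
  update and initialised linearly spaced over 10--100 ms.
* **Optimiser**: Adam, learning rate $5\times 10^{-3}$, minibatch 10,
  recurrent init gain 1.2. These were chosen (once) for reliable escape
  from the zero-output plateau that the delayed-XOR loss surface exhibits;
  the loss trace is returned so users can verify convergence.
* **Slow weights start at zero**, so the untrained spiking network is a
  pure balanced autoencoder; training divergence is detected (Frobenius
  norm guard) rather than clipped.
* **Learning is per step** — the rule is a differential equation and is
  Euler-discretised with the simulation `dt`, applied online during the
  clamped simulation.
* **Regulariser** $\mu = 2\times 10^{-4}(V_{\mathrm{thresh}} -
  V_{\mathrm{reset}})$ stabilises near-duplicate encoder columns.
* **Error current during evaluation**: none; inference is strictly
  $k = 0$.
* **Degenerate inputs**: constant weight matrices pass through the
  quantiser unchanged (with a warning); non-finite membrane states abort
  with the neuron and step named; diverging teachers abort with the step
  named.

## What the tests demonstrate (and what they do not)

The test-suite experiments run at reduced problem sizes chosen to keep a
full run inside a package-check session: the teacher at the study size
(64 units, 20 epochs × 500 samples) but the spiking network at
$N = 160$ with 2000 distillation samples, and robustness grids with 10
perturbation draws per level. At these sizes the pipeline demonstrates
the core behaviours: the clamped reconstruction error falls severalfold
over training, the free-running network performs the task far above the
degenerate (silent) baseline, and mismatch degrades the output MSE
monotonically.

Several quantitative gaps at this scale are worth stating plainly.
First,
free-running task accuracy after distillation remains well below the
teacher's: closing that gap requires the overcomplete population and a
training budget (the full $N = 320$ and many thousands of samples) far
beyond what a test session can run — the returned training record lets
users verify that accuracy is still improving when training stops.
Second, a partially-trained spiking network is *helped* by small
parameter or state perturbations: jitter desynchronises the population
and lifts sub-threshold outputs past the readout gate, so accuracy under
mild mismatch or thermal noise can exceed the unperturbed value even as
the output MSE grows. Monotone accuracy decay should only be expected
from a converged network. Third, the matched-seed silencing comparison
between equally-trained twins (with and without fast feedback) is close
to a coin flip at this scale — the fast-feedback advantage it probes sits
below the trial-to-trial variability of partially-trained networks.

The synthetic tasks sample exactly the stated generative families; they
do not probe real-audio variability, long-range temporal structure
beyond 1 s, or actual silicon measurements (the mismatch model is the
measured mean--variance law, not a device trace).
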