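---
title: "Associative-learning supervision for spiking networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Associative-learning supervision for spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(alsasnn)
```

## The model

`alsasnn` simulates networks of conductance-based leaky integrate-and-fire
(LIF) neurons. The membrane potential of each neuron obeys

$$\tau_m \frac{dV}{dt} = -(V - V_L) - \frac{g_E}{g_L}(V - V_E)
  - \frac{g_I}{g_L}(V - V_I),$$

with conductances expressed in units of the leak conductance $g_L$, so only
$\tau_m = C_m/g_L$ and the $g/g_L$ ratios matter. Each synaptic channel decays
exponentially ($\tau_E\,dg_E/dt = -g_E$) and jumps by the synaptic weight when
a presynaptic spike arrives. When $V$ crosses the firing threshold the neuron
emits a spike, $V$ resets to $V_L$, a refractory period $T_0$ begins, and the
threshold itself jumps by $V_{thr\Delta}$ before decaying back toward
$V_{thrBase}$ with time constant $\tau_{thr}$. This adaptive threshold is the
model's homeostatic mechanism: neurons that fire a lot become harder to fire,
which keeps firing rates of competing neurons in a common range.

Synaptic learning uses a modified spike-timing-dependent plasticity rule.
Whenever a postsynaptic neuron fires, every plastic incoming synapse is
updated by

$$\Delta w = \begin{cases}
\eta\,(\alpha + \beta e^{-ISI/\tau_p})\, w(1-w) & ISI > 0\\
0 & \text{otherwise,}
\end{cases}$$

where $ISI = t_{post} - t_{pre}$ is the difference between the most recent
post- and presynaptic spike times (nearest-spike pairing; earlier presynaptic
spikes are forgotten). Three properties follow:

* **LTP window.** For $\alpha < 0 < \beta$ the update is positive exactly when
  $0 < ISI < \tau_p \ln(\beta/-\alpha)$; `isi_zero_crossing()` returns this
  boundary.
* **Heterosynaptic LTD.** A presynaptic neuron that has been silent for a long
  time — or has never spiked, the $ISI \to \infty$ limit — contributes
  $\eta\alpha w(1-w) < 0$ at every postsynaptic spike. Firing thus depresses
  all synapses from inactive inputs, with no separate mechanism.
* **Soft bounds.** The factor $w(1-w)$ confines weights to $[0,1]$ with
  vanishing updates at the borders; for $|\eta(\alpha+\beta)| \le 1$ the
  interval is invariant under any update sequence.

There is deliberately no depression branch for $ISI < 0$: with independent
high-rate pre/post firing a classic pair-based rule averages to strong
depression, whereas this rule converges to reliable potentiation once the
common firing rate exceeds a crossover. For equal-rate Poisson trains the
expected update per postsynaptic spike is proportional to
$\alpha + \beta\,r\tau_p/(1000 + r\tau_p)$ ($r$ in Hz, $\tau_p$ in ms), so
the crossover rate is $r^* = -1000\,\alpha / ((\alpha+\beta)\tau_p)$ —
decreasing in $\tau_p$. `freq_sweep()` measures exactly this curve by
simulation, and the test suite compares the Monte-Carlo mean with the
closed form.

**ALSA** (associative-learning supervision) turns this unsupervised rule into
a supervised trainer without changing it. A teacher layer with one source
neuron per class is wired one-to-one onto the output layer with strong frozen
synapses. During training, only the true class's teacher neuron fires (20 Hz
Poisson by default), inducing spikes in the corresponding output neuron.
Because the output neuron now fires while the pattern's active inputs fire,
those synapses fall in the LTP window; synapses from silent inputs experience
heterosynaptic LTD; synapses onto output neurons of other classes, which do
not fire, are untouched. Supervision is therefore only an induced-activity
signal — the weight dynamics remain local and unsupervised, which is the
method's point. Setting `teacher_rate = 0` makes `train_supervised()`
bitwise-identical to `train_unsupervised()`; a test asserts this.

Prediction presents a stimulus with the teacher silent and plasticity frozen
and takes the output neuron with the most spikes; ties break by earliest
first spike, then lowest index; no output spikes at all is an abstention and
counts as an error.

## Numerical scheme

The simulator is clock-driven with a default step of `dt = 0.5` ms. Within a
step the order is: source-layer emission, delivery of those spikes plus LIF
spikes of the previous step, membrane integration, threshold crossing,
plasticity. Conductances and the adaptive threshold decay by exact
exponential factors; the membrane equation, linear in $V$ once conductances
are fixed, is advanced analytically with each conductance held at its exact
step average $g\,(\tau/dt)(1 - e^{-dt/\tau})$. This makes the update
unconditionally stable at any step size and keeps it close to a fine
explicit-Euler reference: on a deterministic strong-volley script the default
step reproduces the 0.01 ms Euler spike train with equal counts and spike
times within half a step. Delivery precedes integration precisely so that
this agreement holds; with the opposite order every crossing is detected
between one and two steps late.

Two tie conventions matter at finite `dt`. LIF-to-LIF spikes propagate with
one step of delay. Scripted source spikes (latency codes, replayed
recordings) keep their exact sub-step event times in the nearest-spike cache,
so a scripted presynaptic spike that lands in the same step as the
postsynaptic spike retains its true positive ISI; only genuinely simultaneous
events (grid-coincident times, Poisson emissions drawn on the grid) fall in
the $\Delta w = 0$ branch, honouring the rule's strict inequality.

Rate stimuli are emitted as per-step Bernoulli draws ($p = r\,dt$), which is
the standard discrete approximation of a Poisson process; `regular = TRUE`
instead emits a deterministic periodic train at the same rate (spike $k$ at
$(k - \tfrac12)/f$). All randomness flows from a single seed set at the start
of each run, and each stimulated layer draws from its own substream derived
from that seed — so changing one layer's stimulus (say, the teacher rate)
leaves every other layer's spike realisation unchanged, which makes
manipulations such as the teacher-rate sensitivity analysis properly paired.
Identical seeds give bitwise-identical spike records.

## Parameters

Printed, method-defining constants (plasticity and protocol) are the
defaults of the corresponding pipeline functions:

| parameter | iris pipeline | digit pipeline (input→feature / feature→output) |
|---|---|---|
| $\eta$ | 0.015 | 0.015 / 0.001 |
| $\alpha$ | −0.1 | −0.3 / −0.003 |
| $\beta$ | 1 | 1.3 / 2 |
| $\tau_p$ (ms) | 50 | 20 / 100 |
| init weights | U(0.2, 0.3) | U(0.01, 0.11) / U(0.1, 0.2) |
| teacher rate | 20 Hz | 20 Hz |
| presentation / gap | 200 / 50 ms | 200 / 50 ms |
| encoder | 4 × 12 triangle, $h$ = 20 Hz, $w$ = 2 | latency, threshold 0.3 |

The LIF constants are not method-defining and follow common cortical-LIF
practice: $V_L = -65$ mV, $V_E = 0$ mV, $V_I = -80$ mV, $\tau_m = 20$ ms,
$\tau_E = 5$ ms, $\tau_I = 10$ ms, $V_{thrBase} = -52$ mV, $T_0 = 5$ ms. The
per-layer threshold-adaptation constants are free parameters of the artifact:

* iris output layer: $V_{thr\Delta} = 0.1$ mV, $\tau_{thr} = 5$ s. Large
  enough that an output neuron beginning to respond to another class's
  patterns handicaps itself, small enough that the encoder drive alone can
  still fire the trained output at evaluation.
* digit feature layer: $V_{thr\Delta} = 3$ mV, $\tau_{thr} = 100$ s,
  $\tau_I = 20$ ms, lateral inhibition weight 5. The large increment forces
  winner rotation so all 400 feature neurons participate.
* teacher synapses: frozen weight 2 (in $g_L$ units), roughly 8× a typical
  plastic weight — a single teacher spike reliably drives its output neuron.
* digit readout neurons: $\tau_E = 25$ ms. The latency-coded feature layer is
  sparse (tens of spikes per presentation), so the readout integrates over
  the presentation rather than over single volleys.

## Encoders

The triangle population code maps a scalar $v$ onto $n$ neurons with
preferred values $a_i$ as $f_i = \max(0, h - h|a_i - v|/w)$. For tabular data
each feature is min–max scaled onto $[0, n-1]$ using the training split's
ranges, centers sit on the integers, and $w$ is measured in center spacings —
so $w = 2$ spans ±2 neighbours. The code is continuous and piecewise linear
in $v$, and the rate-weighted mean of centers inverts it to within half a
spacing inside the covered range.

The latency code maps pixels $p \in [0,1]$ with $p > \theta$ to a single
spike at $t = \mathrm{lead}\,(1 - (p-\theta)/(1-\theta))$: brighter pixels
fire strictly earlier, pixels at or below the threshold never fire, and the
pixel just above threshold fires last (at `lead` = 100 ms inside the 200 ms
presentation). `repeat_period` (25 ms in the digit pipeline) re-emits the
pattern periodically so the feature layer sees several volleys per
presentation.

During iris training the encoder emits Poisson trains (the stochasticity
regularises the learned weights); at evaluation the pipeline switches to the
deterministic regular mode, which removes Poisson counting noise from the
spike-count readout while leaving rates — the quantity the network learned —
unchanged. Both modes are exposed; the choice is reported here because it is
an evaluation-protocol decision, not part of the learning rule.

## What the experiments show

**Conditioning fixture** (`run_pavlov()`): an unconditioned input with a
strong frozen synapse, a to-be-conditioned input and a never-paired input
with weak plastic synapses, one output neuron. Before pairing the
conditioned input alone cannot fire the output; after 40 paired
presentations its weight has taken most of its headroom and the input alone
drives the output on every probe, while the never-paired input's weight has
decayed — associative transfer plus heterosynaptic depression in the
smallest possible network. The output neuron's threshold adaptation is
disabled in this fixture so the probe isolates the synaptic change.

**Iris** (`run_iris()`): 48 triangle encoders → 3 outputs + teacher, the
printed parameter set, five class-balanced groups of 30 (10 per class), four
train and one held out, four trials differing only in the random initial
weights. Four epochs over the 120 training rows is the convergence point; the
suite asserts the trial-mean held-out accuracy at these conditions (±3
points around the reference level) and that varying the teacher rate over
10–40 Hz moves accuracy by under 5 points — the homeostatic threshold, not
the teacher intensity, regulates how much the output fires. A known
limitation: training well past convergence (≳ 6 epochs) slowly degrades
accuracy again, because outputs begin to fire — and therefore potentiate —
during presentations of overlapping classes; the adaptive threshold slows
this drift but does not eliminate it at this network size.

**Digits** (`run_digits()`): latency-coded images → 400-neuron
winner-take-all feature layer (lateral inhibition + adaptive thresholds,
unsupervised rule) → ALSA-trained readout, trained layer-wise (features
first, then frozen while the readout learns). Two additions beyond the bare
rule are standard practice for this architecture and are flagged as such:
divisive normalisation of each feature's incoming weight column to a fixed
total (without it, a single "common-stroke" template outcompetes every
specialised one), and the slow-integrator readout described above.

Because the reference digit corpus is not bundled (the package never
downloads data), the pipeline is exercised on synthetic glyph images: fixed
7×5 digit bitmaps upscaled to 28×28, placed with ±2-pixel jitter,
multiplicative stroke-intensity noise and additive background noise. These
share the geometry the encoder cares about (bright strokes on dark
background, class-consistent shape) but not real handwriting's shape
variability, so passing the smoke test demonstrates that the pipeline wiring
and learning dynamics work, not that the full-corpus accuracies are
reproduced. Those full-scale numbers require multi-day training and are
stretch references documented in the README only.

### Desk-scale calibration of the digit pipeline

The printed readout constants ($\eta = 0.001$, $\alpha = -0.003$) are tuned
for tens of thousands of presentations. The readout's equilibrium is set by
the balance $p \cdot \mathrm{LTP} \gtrless (1-p)|\alpha|$, where $p$ is the
probability that a feature fires during a presentation of a given class;
both the number of presentations and $p$ are far smaller at desk scale, so
the smoke experiment scales $\eta_{sup}$ to 0.1, $\alpha_{sup}$ to −0.03 and
$\eta_{unsup}$ to 0.05. This is a calibration of rates to the training
budget, not a change of the rule.

## Degenerate inputs and edge conventions

* `delta_w` with $w \notin [0,1]$ is an error; $ISI = \infty$ is the
  documented "never spiked" limit; $ISI \le 0$ (including exact ties) is 0.
* A neuron's "never spiked" state is the sentinel $-\infty$, so
  $t - t_{last}$ is $+\infty$ and the LTD limit emerges without a special
  case.
* Empty projection lists, zero-rate stimuli and `gap = 0` are valid no-ops;
  negative rates, dangling layer references, malformed init ranges and
  out-of-range labels are errors.
* Inhibitory projections are frozen by construction and exclude
  self-connections when recurrent.
* Evaluation freezes plasticity everywhere (including gaps), so "evaluation
  changes no weight" is a structural guarantee, checked bitwise in the tests.
* Adaptive thresholds are retained (not reset) between training and
  evaluation; `evaluate_network(freeze_thresholds = TRUE)` pins them for
  studies that need a frozen readout.

## Problem sizes used by the test suite

The suite runs the iris pipeline at its natural size (150 rows, 4 trials ×
4 epochs), the frequency sweep at the stated conditions (100 s, 50 trials,
four $\tau_p$ values), the conditioning fixture at 40 pairings, and the
digit smoke at 400 features with 2000 synthetic training images — sizes
chosen so the whole suite completes in minutes on one core while keeping
every stated study condition intact.
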