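---
title: "Model and methods: audio-visual spatial integration in a two-layer ring network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: audio-visual spatial integration in a two-layer ring network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The phenomenon and the model

When a sound and a flash occur together but a few tens of degrees apart, the
perceived sound location is drawn toward the flash (the ventriloquism
effect). After repeated exposure to a consistent audio-visual disparity,
sounds presented *alone* are still mislocalized in the direction of the
previously paired flashes (the ventriloquism aftereffect). `avring`
implements a mechanistic firing-rate model in which both phenomena emerge
from the same small set of circuit ingredients.

The network consists of two chains of $N = 180$ neurons — one auditory, one
visual — each neuron preferring one degree of azimuth, with the array closed
into a ring to avoid border artifacts. Each unit $j$ of modality
$m \in \{a, v\}$ obeys first-order rate dynamics

$$\tau_y \frac{dy_j^m}{dt} = -y_j^m + F(u_j^m), \qquad
F(u) = \frac{1}{1 + e^{-s (u - \theta)}},$$

so activities are dimensionless rates normalized to a saturation of 1. The
net input is the sum of three terms:

$$u_j^m = E_j^m + \sum_k L_{jk}^m\, y_k^m + W\, y_j^{\bar m},$$

an external input, a lateral intra-area input, and a cross-modal input from
the unit at the *same* position in the other layer (one-to-one excitatory
coupling of gain $W$).

The external input is a circular Gaussian
$E_j^m = E_0^m \exp(-d_j^2 / 2\sigma_m^2)$ where $d_j$ is the shorter-arc
distance between unit $j$ and the stimulus position. The width $\sigma_m$
encodes cue reliability: the basal model uses a narrow visual input
($\sigma_v = 4°$) and a broad auditory one ($\sigma_a = 32°$), reflecting
the far better spatial resolution of vision.

Lateral weights start as a Mexican hat, the difference of two Gaussians of
inter-unit distance (excitation: peak $L_{ex0} = 2.4$, width
$\sigma_{ex} = 2°$; inhibition: peak $L_{in0} = 1.4$, width
$\sigma_{in} = 24°$), with no self-loops. Near-range excitation sharpens
bumps; long-range inhibition makes distant bumps compete.

Ventriloquism arises without any plasticity: a visually-driven bump feeds
the auditory unit at the same position through $W$; that seed of auditory
activity is amplified by the positive inter-area loop and then out-competes
the broad bump at the true sound position through lateral inhibition. The
decoded sound position lands between the two, strongly biased toward the
flash.

## Decoding a percept

Three decoders map an activity profile to a perceived position. Because the
space covers 180° with circular topology, unit labels are doubled onto the
full circle (unit $k \mapsto 2k$ degrees) so every decoder is well defined
across the wrap:

* **population vector** — the resultant of unit vectors weighted by
  activity; half its phase is the percept. This is the package's default,
  and the metric used for all headline numbers.
* **barycenter** — the activity-weighted mean position, computed after
  re-centering the position axis on the circular mean. A unit exactly
  antipodal to the center is equidistant both ways; its offset contribution
  is split evenly (i.e. cancels) so the decoder stays reflection-symmetric.
* **winner-takes-all** — the preferred position of the most active unit;
  ties resolve to the circular midpoint of the tied set, and a fully
  symmetric tie (a flat profile) degenerates to the smallest tied position.

On the disparity sweep the vector and barycenter metrics give nearly
identical graded bias curves, while winner-takes-all jumps all the way to
the visual position at moderate disparities and not at all beyond — which is
why the vector metric is the default.

## Hebbian plasticity and the aftereffect

During an adaptation trial the lateral synapses of both layers (never the
inter-area gain $W$) are updated at every integration step by a Hebbian rule
gated by a post-synaptic threshold:

$$\Delta L^{ex}_{jk} = \frac{\Delta t}{\tau_L}\,
\alpha_{ex}(L^{ex}_{jk})\, [y_j - \theta_{post}]^+\, y_k, \qquad
\Delta L^{in}_{jk} = -\frac{\Delta t}{\tau_L}\,
\alpha_{in}(L^{in}_{jk})\, [y_j - \theta_{post}]^+\, y_k.$$

Correlated activity potentiates excitation and depresses inhibition, but
only onto strongly active targets ($\theta_{post} = 0.5$ gates changes to
neurons above half their maximal rate, which also makes reciprocal synapses
between unequally active neurons modify asymmetrically). Two physiological
constraints complete the rule:

* **saturation** — the excitatory learning factor tapers linearly from
  $\alpha_{ex0}$ at zero strength to 0 at $L_{max}$, so no synapse exceeds
  $L_{max}$; the inhibitory factor grows linearly with the synapse value
  (capped at $\alpha_{in0}$ from its pre-training peak $L_{in0}$ upward), so
  depression halts smoothly at zero. The linear forms are the simplest
  functions consistent with both endpoints.
* **normalization** — after every step, the incoming excitatory and
  incoming inhibitory synapses of each neuron are independently rescaled
  (multiplicatively) to their pre-training sums. Potentiating some inputs
  therefore depresses the others; depressing some inhibitory inputs makes
  the remaining ones stronger. Multiplicative rescaling was chosen over
  subtractive because it preserves nonnegativity by construction and keeps
  silent inputs silent.

After training with a fixed 20° disparity, an auditory neuron near the
trained visual position receives net *excitation* from units ~30° to its
left (where residual activity at the true sound position persisted during
training) and stronger inhibition from its right. A later unimodal sound in
that region generates extra excitation to its right and is decoded with a
rightward bias — the aftereffect — without any change to the feed-forward
input or the cross-modal coupling.

## Parameters

| name | value | units | role |
|---|---|---|---|
| $E_0$ | 15 | — | input strength (both modalities) |
| $\sigma_v$, $\sigma_a$ | 4, 32 | deg | input widths (cue reliability) |
| $\theta$, $s$ | 12, 0.6 | — | sigmoid center and slope |
| $\tau_y$ | 3 | ms | membrane time constant |
| $L_{ex0}$, $\sigma_{ex}$ | 2.4, 2 | —, deg | lateral excitation |
| $L_{in0}$, $\sigma_{in}$ | 1.4, 24 | —, deg | lateral inhibition |
| $W$ | 5 | — | inter-area gain |
| $\alpha_{ex0}$, $\alpha_{in0}$ | 0.015, 0.025 | — | max learning factors |
| $\theta_{post}$ | 0.5 | — | plasticity gate |
| $L_{max}$ | 2.4 | — | excitatory saturation |
| $\tau_L$ | 0.5 | ms | learning time constant |
| $dt$ | 0.1 | ms | Euler step |

All are exposed through `av_params()` and YAML configs (`load_config()`).
$\tau_L$ deserves comment: the Hebbian rule fixes the learning factors and
the trial structure (200 ms per exposure) but the time constant that
converts them into a per-step increment is a free scale. It was calibrated
once against the canonical adaptation outcome — the variable-position
20°-disparity paradigm must yield its characteristic ~7.5° uniform
aftereffect (about 37% of the adapting disparity) — and fixed at 0.5 ms.
The same value then reproduces the fixed-position paradigm's localized
~8.5° aftereffect and the ~10° combined post-training capture without
further adjustment, which is the intended cross-validation.

## Numerical choices

* **Integration** — explicit Euler, $dt = 0.1$ ms (about 3% of $\tau_y$),
  from null initial conditions, stimuli constant from $t = 0$ (no onset
  ramp). Halving $dt$ changes steady-state activities by well under
  $10^{-3}$ (asserted in the tests). Activities are never clipped; leaving
  $[0, 1]$ beyond a $10^{-9}$ guard aborts with a diagnostic, since that
  signals a genuine instability rather than harmless drift.
* **Steady state** — integration stops when every unit's $|dy/dt|$ falls
  below $10^{-6}$ per ms, with a hard cap of 500 ms. Basal-parameter runs
  converge in 100–250 ms. The criterion is a package choice: any
  threshold a few orders below typical transient rates gives
  indistinguishable percepts in the basal regime.
* **Matched-width regimes** — when the two inputs have (nearly) equal
  widths, the two bumps are evenly matched and the winner-take-all
  competition acquires an extremely slow drift mode (residuals around
  $10^{-4}$/ms persisting for over a second of simulated time). The
  gain-coded-reliability protocol therefore defines its operating point as
  the end of the fast transient and decodes at $t = 100$ ms
  (`run_gain_coding_variant(eval_time = 100)`); the activity profiles are
  settled there for all practical purposes, and the decoded percepts match
  the protocol's reference values. Letting the drift run to full
  convergence (~1.2 s) moves both percepts by about 1° toward the midpoint.
* **Plasticity bookkeeping** — per step, only rows of the weight matrices
  whose post-synaptic unit exceeds $\theta_{post}$ can change, and only
  those rows are renormalized; diagonals are pinned to zero. Pre- and
  post-synaptic activities entering the rule are those of the current step
  (before the Euler update). Conservation of each neuron's incoming sums
  holds to machine precision throughout training. Excitatory clipping at
  $L_{max}$ after normalization triggers at most one rescale-and-clip pass;
  in practice the linear taper keeps weights strictly below saturation.
* **Schedules** — paradigm 2a/2b orderings are drawn per block with a local
  RNG seeded from the schedule seed, leaving the global RNG stream
  untouched; the seed is recorded in schedules and manifests.
* **Degenerate inputs** — an all-zero activity profile has no percept and
  decoding errors out rather than returning an arbitrary position; a row
  whose incoming synapses sum to zero cannot be normalized and raises a
  diagnostic.

## What the simulations do and do not show

All experiments here are self-contained simulations: the "data" are the
network's own steady states, so reproducing the reference numbers validates
the implementation of the model, not the model against behavior. The
emulated conditions are idealized — punctate stimuli, no neural noise, a
single shared time constant for both modalities, a 1-D azimuthal ring, and
deterministic dynamics; real psychophysics adds response variability,
eccentricity effects and temporal asynchronies that this package does not
model. Sizes used throughout: 180 units per layer, steady states within
500 ms of simulated time, adaptation runs of 10 exposures (fixed-position
paradigms) or 90 exposures (variable-position paradigms) of 200 ms each.

Known limitations: the exact shapes of the learning-factor tapers are a
modeling choice (only their endpoints are constrained), normalization is
multiplicative by choice, and near-matched input widths the notion of
"steady state" is protocol-dependent as described above. Within those
choices, the full set of reference simulations — unimodal controls,
coincident and disparate stimulation, the bias-versus-disparity curve and
its sensitivity analysis, the four adaptation paradigms, post-training
cross-modal tests, degraded-vision and gain-coded variants — is reproduced
by the test suite and the acceptance script.

## Session

```{r, eval = FALSE}
library(avring)
net <- av_network(av_params())
st <- simulate_network(net, list(av_stimulus("auditory", 100, 15),
                                 av_stimulus("visual", 120, 15)))
decode_position(st$y_a, "vector", av_params())
```
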