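---
title: "A multiscale model of gustatory transduction and neural taste coding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiscale model of gustatory transduction and neural taste coding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gustnet)
```

## The model

`gustnet` simulates the taste pathway from chemistry to population code.
A stimulus is a 4-vector of concentrations — Na\+ (salty, mM), H\+ (sour,
mM), a sweet ligand and a bitter ligand (model units).  It is processed in
three stages.

**Transduction.**  Each input-layer taste receptor cell carries a set of
detectors.  Salty and sour act through non-voltage-gated electrodiffusive
channels: the reversal potential of each ion follows the
Goldman–Hodgkin–Katz relation
$E_x = \frac{RT}{zF}\ln\frac{[X]_{out}}{[X]_{in}}$ and the current is ohmic
in the driving force.  Sweet and bitter act through metabotropic receptors
(T1R2/T1R3 and T2R families) whose open fraction follows Hill kinetics
$O = L^n/(L^n + K_a^n)$, driving a conductance that reverses at the
voltage-gated Na\+ potential.  The receptor currents add to a classical
squid-axon-type membrane (Na, K, leak), integrated with fourth-order
Runge–Kutta; the membrane spikes when driven above threshold.

Two conventions deserve note.  First, all currents use a
depolarizing-positive sign convention, $I = g(E - V_m)$: an inward cation
flux at $V_m < E$ must depolarize the cell, so it enters
$C_m \dot V_m = I_{tot} + I_{pd}$ with a positive sign.  (The equivalent
form $I = g(V_m - E)$ with a subtracted ionic term is common in the
literature; the two differ only in where the minus sign lives.)  Second,
the chemical gating of the Na\+/H\+ channels is not specified by any
standard model: we use a first-order saturation $g_{eff} = g \cdot
c/(c + K_{1/2})$ in the stimulus concentration, the minimal monotone dose
dependence, which vanishes at zero stimulus and recovers the nominal
conductance at saturation.

**Spike handoff and synapses.**  Voltage traces are binarized into 5 ms
bins (a bin is 1 if the trace reaches −50 mV anywhere inside it).  Each
input spike releases glutamate with a rectified alpha-function time course
$\alpha(t) = (t/\tau)e^{1-t/\tau}$, peaking at 1 exactly at $t=\tau$
(τ = 2.5 ms, amplitude A = 1.2 mM).  The postsynaptic conductance pools a
phosphorylated (high-affinity, $K_{Phos}$ = 0.3 mM) and an
unphosphorylated ($K_{unPhos}$ = 1.5 mM) AMPA receptor fraction:

$$g_{syn} = \sum_i g_{AMPA} N_{tot,i}\left[\mathrm{Phos}_i
\frac{G_i}{G_i + K_{Phos}} + (1-\mathrm{Phos}_i)
\frac{G_i}{G_i+K_{unPhos}}\right]$$

with $g_{AMPA}$ = 10 pS per receptor.  The synaptic current
$g_{syn}(E_{AMPA} - V)$, $E_{AMPA}$ = 0 mV, drives the downstream neurons.

**Network.**  Three fully connected feedforward hidden layers of 20
Izhikevich neurons (regular-spiking constants a = 0.02, b = 0.2, c = −65,
d = 8, forward Euler at 0.5 ms) follow the input layer.  Hidden spikes are
passed between layers at their native times; the *output pattern* is the
60-bin × m binary matrix of output-population spikes at 5 ms resolution
over the 300 ms trial.

## Training

Synaptic weights are governed by two biological quantities per edge: the
AMPA receptor count $N_{tot}$ (evolved) and the phosphorylation fraction
$\mathrm{Phos}$ (adapted online).  The genetic algorithm uses a population
of 100 networks, rank selection keeping the top half, uniform crossover of
receptor counts, and Gaussian mutation with per-locus scale
$\sigma = 0.1\,N_{tot,i}$.  Phosphorylation follows the synchrony rule
$\Delta\mathrm{Phos} = \eta\,\bar S\,(1-\mathrm{Phos})$, η = 0.05, where
$S_j = 0.5 - (d_j + \Delta t)/D$ scores the minimal pre/post spike-time
difference $d_j$ against the largest interval $D$ observed in the batch;
the mean increment over the surviving half is applied to every individual
(a shared plasticity field) and clamped to [0, 1].

Two objectives are available.  *Task 1* (hedonic encoding) asks the
network to preserve distances in pleasantness space: the hedonic value of
a stimulus is the Gaussian product
$\prod_i \exp(-(S_i-\theta_i)^2/w_i^2)$ around the optimum θ = (100, 0.1,
15000, 1) with widths w = (50, 2, 10000, 5).  *Task 2* (discrimination)
uses $\|A\|_1 + \|B\|_1$ for two pure tastes and
$\tfrac12\|A-B\|_2$ otherwise.  Both are compared against the variation
of information between the two output patterns,
$D_{res} = H(X,Y) - MI(X;Y)$, estimated by pooling the per-(bin, neuron)
binary symbols of the two patterns into one empirical joint distribution
(plug-in, base-2 logs).  The loss is the mean absolute mismatch of the two
distances, negated, so the maximized fitness approaches 0 from below.

### Normalization and sign choices

The input and output distances live in different units (pleasantness,
concentration norms, bits), so the mismatch $|D_{in} - D_{res}|$ is only
meaningful after normalization.  Input distances map to [0, 1]: hedonic
distances by their theoretical maximum (1), task-2 input distances by
their batch maximum.  The output distance is normalized by the *marginal*
support ceiling of the binary-symbol estimator — 1 bit — so the
normalized $D_{res}$ is simply the variation of information in bits.
This choice is the survivor of an explicit analysis of the alternatives,
each rejected on the evidence of training runs:

* the estimator's *joint* ceiling (2 bits) pins realistic output
  distances far below the task-2 input distances — binary spike patterns
  never approach 2 bits of VI — and the training optimum collapses to a
  silent network;
* a *batch-maximum* normalizer is scale-invariant to a fault: estimator
  noise on near-identical patterns is rescaled to full range, and
  training drifts into saturated, undecodable codes;
* the *entropy-normalized* distance $\mathrm{VI}/H(X,Y)$ is
  density-invariant, sitting near 1 for any two distinct active patterns
  until they become literally identical — a cliff landscape on which the
  genetic algorithm stalls.

Against the 1-bit ceiling, a normalized output distance of 1 is attained
by a pair of independent sparse patterns near 11% occupancy (two
independent Bernoulli symbol streams have $\mathrm{VI} = 2h(p)$, and
$2h(0.11) \approx 1$), silence and saturation both map to 0, and
over-dense codes overshoot past 1 and are penalized.  The optimum is
therefore a sparse, reproducible, selectively similar fingerprint code,
with a smooth activity gradient toward it.  Combined with the negated
mean in the loss, the genetic algorithm *maximizes agreement* between the
two geometries; reading the loss sign literally together with a
maximizing algorithm would reward mismatch instead, which cannot be the
intent.

A second open point is the task-1 evaluation panel.  Almost every randomly
assembled stimulus is far from the four-dimensional hedonic optimum, so
unstratified panels have hedonic distances collapsing to zero and the
encoding task degenerates (any output geometry trivially matches).  The
panel generator therefore draws, alongside pure tastes (40%) and random
mixtures (30%), "palatable" mixtures within ±20% of the optimum (30%),
which spread the hedonic axis over its full range.  Pairs are drawn from
one fixed panel per training run so fitness trajectories are comparable
across generations.

Phosphorylation fractions are excluded from crossover (they are an online
state, not a gene); a child inherits the first parent's fractions.  The
refill is elitist: survivors are retained unchanged and offspring fill the
remaining slots, the standard (μ+λ) arrangement.

## Numerical choices

* **Receptor-cell step.**  The classical membrane is stiff at the spike
  upstroke (the Na activation time constant drops to ~0.1 ms), and
  explicit Runge–Kutta at millisecond steps diverges there.  The default
  is 0.02 ms, at which binned spike counts are identical to a 0.01 ms
  reference for the default cells across the stimulus range (a convergence
  test asserts this).  Gate variables are clamped to [0, 1] at every
  stage evaluation.
* **Izhikevich step.**  0.5 ms forward Euler (guarded at 1 ms), both
  derivatives evaluated at the old state, reset applied after the update —
  the compiled kernel and the R-level `step_izhikevich()` implement the
  identical discretization and are cross-checked in the tests.
* **Alpha-kernel truncation.**  Kernels are dropped 10τ after each spike
  (below 0.1% of peak), bounding per-step cost.
* **Input gain.**  Synaptic current (pA) is scaled by 0.25 per pA into the
  Izhikevich current term, calibrated once so that a single saturated
  synapse (500 pS at rest) sustains firing.
* **Degenerate inputs.**  Synchrony over spikeless trains is defined as 0
  (no interval exists, no plasticity evidence); an all-zero task-2 batch
  normalizer leaves the distances at zero; selection ties break by stable
  index order.

## The stimulus generator and what the tests show

All inputs are synthetic; the generator *is* the experiment definition.
Pure stimuli place one modality at a low/mid/high level (levels centered
on the hedonic optima: Na 30/100/300 mM, H 0.01/0.1/1 mM, sweet
3000/15000/45000, bitter 0.3/1/3); mixtures combine two or three; sweeps
are log-spaced.  The default input layer has eight cells — one narrowly
tuned cell per modality plus four dual-detector cells — so mixtures
recruit overlapping populations.

Trial-to-trial variability, needed for entropy and decoding statistics, is
modeled as a zero-mean Gaussian noise current (default σ = 30 pA,
resampled every 1 ms) injected into the input cells.  The value was chosen
so that near-threshold cells show a few milliseconds of first-spike
jitter, comparable to peripheral gustatory variability, while strongly
driven cells stay reliable.  The generator emulates concentration-driven
rate and latency structure; it does not emulate receptor adaptation,
intracellular Ca²⁺/IP₃ cascades, lateral or feedback circuitry, or
multisensory context.  Passing tests therefore certify the simulator and
the training machinery, not quantitative agreement with in-vivo taste
responses.

## Analyses

* `spike_pattern_entropy()` sums per-(neuron, bin) binary entropies of the
  across-trial firing probabilities (independent-Bernoulli plug-in), at
  3 ms bins over the first 60 ms by default.  Its maximum equals the slot
  count — 1200 bits for the 60-neuron output population — which is the
  only estimator consistent with that stated maximum; bias-corrected
  estimators are out of scope.
* `classify_stimuli()` decodes stimulus identity by nearest centroid in
  Hamming distance, odd trials forming centroids and even trials held
  out.  It is deliberately the minimal-assumption decoder.
* `robustness_experiment()` rescales every receptor count, phosphorylation
  fraction and intrinsic neuron parameter by independent Uniform(1−f, 1+f)
  factors (default f = 0.2) and reports the mean accuracy drop over
  draws against the same noisy trials.

## Problem sizes

Training runs used throughout the package's own analyses are a population
of 100 over 100 generations, 10 stimulus pairs drawn from an 8-stimulus
panel per evaluation; entropy uses 20 noisy trials per stimulus on the
6-class default panel; robustness uses 20 perturbation draws with 8 trials
per class.  These sizes give stable statistics while keeping a full
reproduction run in the minutes range on one core.

## Known limitations

The fitness landscape of the receptor-count genome is high-dimensional
(960 loci for the default architecture) and the prescribed operators move
the population's aggregate synaptic strength slowly, so fitness histories
plateau gradually rather than sharply; reported "converged" magnitudes
depend on run length.  The shared phosphorylation field couples all
individuals, which can transiently lower the best fitness between
generations (elitism guarantees monotonicity only with the online rule
disabled, as the degenerate-case test asserts).  Umami is not modeled; no
inhibitory or recurrent circuitry is included; the entropy and robustness
results depend on the chosen noise amplitude, which is a model parameter,
not a measured quantity.
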