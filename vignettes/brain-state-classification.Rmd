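---
title: "Model-driven classification of epileptic brain states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-driven classification of epileptic brain states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epistates)
```

## The problem

Hippocampal recordings from temporal-lobe epilepsy traverse a small set of
recurring activity regimes: quiet interictal background, a preonset regime
with sporadic high-amplitude spikes, a seizure-onset regime of low-voltage
fast (15–40 Hz) oscillations, and the ictal regime of sustained rhythmic
4–10 Hz discharges. Labeling five-second segments with one of these four
states normally requires expert visual review. `epistates` replaces the
expert with a generative model: a neural mass simulator produces
prototypical examples of each state, and any data segment is labeled by its
nearest prototype in a low-dimensional feature space. The classifier is
therefore fully unsupervised — no labeled training data enter it at any
point — and every prototype is mechanistically interpretable as a specific
balance of synaptic excitation and inhibition.

## The generative model

The simulator is the Wendling neural mass model: four interacting neuronal
populations (pyramidal cells, excitatory interneurons, slow dendritic
inhibitory interneurons, fast somatic inhibitory interneurons). Each
synaptic pathway is a second-order linear kernel, so each of the five
postsynaptic-potential channels $y_i$ obeys

$$\ddot y_i = K k\, u_i(t) - 2k\,\dot y_i - k^2 y_i,$$

with gain/rate pairs $(K, k)$ equal to $(A, a)$ for the two excitatory
channels, $(B, b)$ for the two slow-inhibitory channels, and $(G, g)$ for
the fast-inhibitory channel. Population firing rates come from the sigmoid
$S(v) = 2e_0 / (1 + e^{r(v_0 - v)})$. The inputs are: $S(y_1-y_2-y_3)$ for
the pyramidal output channel, $p(t) + C_2 S(C_1 y_0)$ for the excitatory
feedback (where $p(t)$ is the external drive), $C_4 S(C_3 y_0)$ for slow
inhibition of pyramidal cells, $C_7 S(C_5 y_0 - C_6 y_4)$ for fast
inhibition, and $S(C_3 y_0)$ for the slow-inhibitory projection onto the
fast interneurons. The simulated signal — the analogue of an intracranial
EEG channel — is the summed potential $y_1 - y_2 - y_3$ on the pyramidal
population.

Fixed parameters (units in the reference manual): $a = 100$, $b = 30$,
$g = 350$ s$^{-1}$; connectivities derived from $C = 135$ as $C_1 = C$,
$C_2 = C_7 = 0.8C$, $C_3 = C_4 = 0.25C$, $C_5 = 0.3C$, $C_6 = 0.1C$;
sigmoid $v_0 = 6$ mV, $e_0 = 2.5$ s$^{-1}$, $r = 0.56$ mV$^{-1}$; drive
noise mean 90 and SD 30 s$^{-1}$. The three synaptic gains select the
brain state:

```{r}
t(sapply(wendling_state_configs(), function(p) c(A = p$A, B = p$B, G = p$G)))
```

## Numerical choices in the simulator

**Integration.** Fixed-step Euler at the output rate (`fs_int = fs`,
dt = 1/512 s by default), one Gaussian draw of $p(t)$ per step, all-zero
initial state, and a 2 s burn-in discarded before the retained window.
dt = 1/512 is comfortably inside the Euler stability bound $2/g = 1/175$ s
for the fastest kernel. The choice of stepping at the sampling rate is
substantive, not cosmetic: the drive noise is an input firing rate, not a
Wiener increment, so its per-step variance is *not* rescaled with dt.
Refining the grid while keeping the draw-per-step convention therefore
lowers the effective noise spectral density. The onset state's fast rhythm
is a noise-driven resonance of the pyramidal–fast-interneuron loop (the
deterministic system settles to a fixed point for all relevant constant
drives — see the zero-noise tests), and with a 4x finer grid that rhythm
visibly fades and the four states blur together. `fs_int` stays
configurable (an integer multiple of `fs`, output decimated) for users who
want to study exactly this sensitivity.

**Seeds.** One master seed per segment set; segment $i$ uses seed
`master + i`, which keeps realizations independent, reproducible, and
below the 32-bit integer limit for any sane master seed.

**No clipping.** Sigmoid arguments and outputs are left untruncated; the
divergence guard in the integrator reports the offending step if a
parameterization explodes.

## Features

Each five-second segment is summarized by eleven features: signal mean;
average band power in 0–0.5, 0.5–4, 4–12, 12–64 and >64 Hz; the 0.95–0.05
inter-quantile distance (`alphdiff`); the number of samples outside the
Tukey fences $Q_1 - 1.5\,\mathrm{IQR}$ and $Q_3 + 1.5\,\mathrm{IQR}$
(`spikeabs`); variance; autocorrelation at 5 ms lag; and line length
$\sum_i |x_{i+1} - x_i|$.

Choices a practitioner should know:

* **Spectral estimator**: Welch periodogram with 1 s Hann windows, 50%
  overlap, per-window mean removal. "Average band power" is the mean PSD
  over bins whose center falls in the half-open band $[lo, hi)$; the upper
  edge of the >64 Hz band is the segment's own Nyquist frequency. Because
  windows are demeaned, the 0–0.5 Hz feature captures within-segment drift
  rather than the raw DC offset (the offset is already the `mean` feature),
  and a constant segment has zero power in every band.
* **Quantiles** use the linear-interpolation convention (R type 7); the
  Tukey fences inherit it.
* **`spikeabs` counts samples, not merged events** — the most literal
  reading of an outlier count; a single spike spanning several samples
  counts each sample.
* **Autocorrelation lag** is `round(0.005 * fs)` samples, at least 1
  (3 samples at 512 Hz, 5 at 1 kHz); a zero-variance segment returns 0
  with a warning.
* **z-normalization** is column-wise with the sample (n−1) SD, across all
  segments of one individual (or all 400 simulated segments). The
  statistics are stored and reusable. Normalizing per dataset is what
  makes features comparable across species and hardware with different
  gain and sampling rate.

A related, deliberately distinct quantity is `dominant_band()`: the band
with the largest *integrated* power among 0.5–4, 4–12, 12–64, >64 Hz.
Integrated power matches the visual impression of which rhythm dominates a
trace; a per-bin average would penalize wide bands (the onset state's
12–64 Hz rhythm loses to the narrow 4–12 Hz band under a per-bin average
while carrying several times more total power). For the *features*, the
per-bin mean is kept: after z-scoring the two definitions differ only by a
per-feature constant, so the classifier is unaffected.

## Prototypes

The fitted object of the package comes from `fit_prototypes()`:

1. z-normalize the prototype dataset's 11-feature matrix;
2. PCA with four components (on the model dataset these capture ~98% of
   the variance; loadings are sign-fixed so the largest-magnitude entry of
   each column is positive, making serialized projections reproducible);
3. k-means with k = 4 on the four-dimensional scores. Hartigan–Wong with
   50 random restarts is used; restarts serve the same robustness purpose
   as a seeded k-means++ initialization, and the winning restart is
   deterministic given the recorded seed;
4. Voronoi voting: every simulated model segment (projected into this PC
   space after z-normalization with its own dataset statistics) votes in
   the cell of its nearest centroid; each centroid takes the majority
   label of its cell. An empty cell drops its centroid. If two centroids
   win the same label, the one backed by more label-defining votes is
   kept. Vote ties break toward the lower label and equal backing toward
   the lower centroid index, each with a warning — degenerate situations
   the study data can produce but that have no principled resolution.

Distances are unweighted Euclidean in the full four-dimensional score
space; components are not re-weighted by explained variance.

Because the voting set is always simulated, even *data-driven* prototypes
(clusters found in a rat or human recording) get their labels without any
expert input. On real data fewer than four prototypes can survive — e.g. a
dataset with no onset-like cluster simply never wins the onset label.

## Classification and evaluation

`predict()` z-normalizes the new dataset with its **own** statistics (the
per-individual convention; `norm = "prototype"` is available for
sensitivity analysis), projects with the prototype set's stored
coefficients, and assigns each segment the label of the nearest centroid,
ties toward the lower label with a warning.

Performance: per-type sensitivity $TP/(TP+FN)$ and PPV $TP/(TP+FP)$ from
the 4×4 confusion matrix, macro-averaged over types with a defined
denominator. A type absent from the truth is excluded from the sensitivity
average; a type that is predicted but never true contributes PPV = 0,
penalizing false alarms while keeping the average defined.

Significance uses Markov-chain surrogates: the true-label transition
matrix is estimated by maximum likelihood, 1000 label sequences of the
same length are simulated from it, each is scored against the truth as if
it were the classifier's output, and the p-value is the fraction of
realizations — surrogates plus the single original — with a metric at
least as high as observed, so $p \in (0, 1]$ with floor $1/(n+1)$. The
surrogate's initial state is drawn from the stationary distribution of the
estimated chain (uniform for the balanced model data); a state observed
only as the final sample gets a flagged self-transition row. The group
test draws one chain per individual per realization and compares group
means. The choice to replace the *predicted* sequence rather than re-run
the whole pipeline makes the null "a labeler with the right temporal
statistics but no access to the signal", which is the relevant chance
model for a classifier.

## What the synthetic data do and do not show

The simulator's defaults are the study conditions: 100 segments per state,
5 s at 512 Hz. Fixture generators add a continuous recording that cycles
through the four states (known labels per window), degenerate signals
(constant, pure sinusoid, single spike) for the guard paths, and
multi-subject collections with unequal state frequencies and ±10% jitter
on the synaptic gains, including a subject with no onset segments at all.

These emulate the *structure* of the study's real datasets, not their
difficulty: real recordings contain measurement noise, artifacts,
non-epileptic brain processes, and segments of mixed type at state
transitions, none of which the generator produces. Passing the synthetic
acceptance checks therefore demonstrates the pipeline's correctness and
its near-perfect separability of cleanly generated states (mean
sensitivity and PPV ≈ 0.99, four PCs ≈ 98% variance); it does not predict
the substantially lower rat/human numbers, which require the deposited
recordings and expert labels to reproduce.

Problem sizes used by the test suite: the full 400-segment experiment at
five seeds for the headline metrics; 100 seeds per state for the spectral
signatures; 200 replicates of 250-surrogate tests (sequence length 120)
for the null-uniformity check; 1000 surrogates for the significance check.

## Known limitations

* Single-channel only; the study design is one channel per subject.
* No temporal smoothing of predicted label sequences — segments are
  classified independently, so isolated flips at state boundaries are
  expected.
* The number of components and clusters is fixed at four by design; no
  automatic model selection.
* Euler integration at the sampling rate is the canonical discrete
  implementation for this model but makes the fine spectral detail of the
  onset regime dt-dependent; users comparing against other integrators
  should match the noise convention first.
* Human recordings at 1 kHz are featurized at native rate rather than
  resampled; the >64 Hz band then integrates to a different upper edge,
  which per-dataset z-scoring absorbs but does not eliminate.
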