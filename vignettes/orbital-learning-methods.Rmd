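---
title: "Orbital learning at desk scale: models, assessors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orbital learning at desk scale: models, assessors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orbitlearn)
```

## The problem

A network of healthcare units wants to learn a shared diagnostic model
without moving patient data. Classical federated averaging treats all
clients alike: one poisoned client (noisy sensors, shuffled labels,
malicious tampering) degrades the global model for everyone, and clients
with very different demographics pull the average in conflicting
directions. Orbital learning replaces the single global average with
*actively orchestrated groups*: a central node assesses every client's
impact on the shared intelligence — without ever seeing its data — and
places clients with similar impact and similar training tempo into
*orbits*. Intelligence (a section of shared neural-network layers)
circulates cyclically inside an orbit only; outer orbits may *pull*
layers from inner orbits, never the reverse; and a client whose assessed
impact drifts outside its orbit's acceptance band is expelled and, if no
orbit accepts it, isolated in a singleton orbit where it can do no harm.
At inference time a client ensembles all shared-layer copies currently
in its orbit (bagging by probability averaging).

This package is a desk-scale simulator of that protocol: every
experiment runs in seconds to minutes on one CPU, with a synthetic
ECG-like data generator standing in for clinical waveform archives.

## The simulated network

One *melioration* is a bounded local training pass (a few epochs of
Adam at learning rate 0.001). The protocol runs

1. **Assessment** — two client-side assessors reduce a client to a
   scalar pair, so no data or parameters leave the client:
   * *weight similarity*: Spearman's rank-order correlation
     \(\rho = 1 - 6\sum d_i^2 / (n(n^2-1))\) between the client's
     flattened parameters and the central reference model's (the
     closed form holds tie-free; with ties the product-moment
     correlation of average ranks is used, which reduces to the closed
     form otherwise);
   * *data similarity*: each probe signal is pushed through an
     autoencoder trained on the central benchmark dataset, and the
     dynamic-time-warping (DTW) distance between the signal and its
     reconstruction is aggregated to one score. In-distribution data
     reconstructs well (low score); out-of-distribution or tampered
     data does not.
2. **Initiation** — the central node trains the reference model and the
   assessor autoencoder on its benchmark dataset, copies the reference
   model to every client, lets each client run `n_init` (default 5)
   meliorations without sharing, assesses everyone, standardises the
   feature triple (weight similarity, data distance, melioration rate)
   and clusters it with K-means, selecting K by maximum mean silhouette
   width. Orbits are ordered by decreasing mean weight similarity
   (innermost = most reference-like).
3. **Maintenance** — per round, every orbit member trains the
   shared-layer packet it currently holds, is re-assessed *before* the
   packet moves on, and deviants (|rho − orbit mean of the others| >
   0.015) are expelled. An expelled client joins the orbit with the
   nearest mean rho *within* 0.015 whose mean data distance is also
   within a factor-2 band of its own — otherwise it becomes a singleton
   orbit. Rings then rotate one step (clockwise by default). Isolated
   singletons that later fit an orbit again are re-admitted at the ring
   end.
4. **Inference** — a client predicts with the unweighted mean of the
   probability vectors obtained by running its private front section,
   each orbit packet's shared section, and its private back section.

All timing runs on a simulated clock: a melioration's duration is
`base_duration × multiplier(client, melioration)`, and each ring
rotation waits only for its own members. Slow clients therefore delay
exactly their own orbit, and every run is bit-reproducible from its
seed.

## The synthetic waveform generator

Each record is a 10-second, 100 samples/s beat train: per beat, five
Gaussian bumps (P, Q, R, S, T) plus an ST-segment offset bump, with
per-beat amplitude and interval jitter, low-frequency baseline wander
and additive sensor noise (sd 0.03 in raw units). Class morphology
follows the standard five-superclass ECG taxonomy and is fully
documented in `class_param_table()`: ST/T change shifts the ST offset
(−0.15) and flattens the T bump (×0.33); conduction disturbance widens
the QRS bumps (×1.9); hypertrophy raises R voltage (×1.6); myocardial
infarction inverts and exaggerates the Q bump (×−3) and depresses ST
(−0.10). Heart rate (80 − 0.25·(age − 18) bpm) and amplitude
(×(1.05 − 0.003·(age − 18))) decline monotonically with age, giving the
age covariate real signal. Multi-channel records are derived from one
base trace through a fixed lead-mixing vector plus small independent
channel noise.

What the generator emulates: learnably separable diagnostic classes,
demographic structure, non-IID client mixes (Dirichlet-skewed label
proportions, or hard age partitioning into the six decades
18–39 … 80–89), and the two tampering operators — additive uniform
noise on `[0, 0.2]` applied to z-scored signals, and uniform label
shuffling. What it does not emulate: true 12-lead electrophysiology,
pathology co-occurrence, inter-patient record correlation, artefact
taxonomies of real Holter/clinical recordings, or class-prevalence
imbalance of clinical archives. Passing tests therefore demonstrate
that the *orchestration mechanics* behave as designed under controlled
anomalies — not that any clinical performance level would be attained
on real ECGs.

```{r waveforms, fig.width = 7, fig.height = 4, eval = FALSE}
oldpar <- par(mfrow = c(2, 1), mar = c(2, 4, 2, 1))
for (lab in c(0, 2)) {
  w <- generate_waveform(lab, age = 55, seed = 3)
  plot(w$samples[1:400, 1], type = "l", ylab = names(class_labels())[lab + 1])
}
par(oldpar)
```

## The split model and its sections

No deep-learning framework is assumed: the classifier is a compact
1-D convolutional stack implemented directly on matrix algebra (im2col
gathers compiled in C++, BLAS matrix products, Adam). The desk-scale
default (`arch = "desk"`) is three strided conv blocks and a dense
softmax head (~1250 parameters); `arch = "deep"` provides a five-block
stack closer to a clinical model. Sections: the first conv block is
`private_front`, the remaining conv blocks are `shared` (the section
that circulates), the head is `private_back`. Parameter flattening
follows a fixed construction-time order, so flattened vectors are
comparable across clients bitwise.

The assessor autoencoder is dense
(input → 128 ReLU → 32 linear bottleneck → 128 ReLU → linear output),
trained with Adam/MSE on the benchmark only.

## Numerical and design choices

* **Probe preprocessing (data assessor).** Probe signals enter the
  assessor *as stored*. Z-scoring probes would erase scale anomalies —
  exactly the signature that the noise-tampering operator leaves (it
  z-scores before adding noise) — and pilots confirmed that a z-scored
  pipeline cannot distinguish tampered from clean clients at this
  reconstruction quality. Training signals for the autoencoder are
  per-record *centred* (mean removed, no rescaling): with zero-mean
  reconstructions, positive-mean tamper noise cannot drift a signal
  *toward* its reconstruction, and the DTW score responds
  monotonically to the tamper amplitude.
* **DTW.** Classical dynamic program, absolute-difference local cost,
  unit steps; assessment uses a Sakoe–Chiba band of 15 samples
  (0.15 s), wide enough to absorb beat-phase jitter yet narrow enough
  that warping freedom does not absorb genuine noise. Aggregation over
  the probe is by *mean* (default): the median's sampling discreteness
  can mask the small, distributed score shift that low-amplitude
  tampering produces. Multi-channel distance is the sum over channels.
* **Weight comparison section.** The orchestrator compares the *full*
  parameter vector by default (`rho_section = "all"`, switchable to
  `"shared"`). Once packets have circulated, all shared sections inside
  an orbit embody the same ring history and become nearly
  indistinguishable; the private head never leaves the client and
  therefore keeps carrying client-specific signal. The assessment is
  client-side either way — only the scalar is reported.
* **Orbit acceptance.** Entry into an orbit (after expulsion, or
  re-admission of an isolated client) requires both assessed
  characteristics to match: |rho − orbit mean| ≤ 0.015 *and* data
  distance within ×2 of the orbit mean. Weight similarity alone proved
  insufficient in pilots: client drift can make a clean client's rho
  transiently adjacent to a tampered orbit's mean, and data quality is
  precisely the characteristic the protocol claims to police.
* **K selection.** Seeded K-means (10 restarts) for k = 2…min(n−1,
  kmax), mean silhouette width maximised, ties to the smallest k;
  k = 1 is used when fewer than 3 clients exist or features are
  degenerate (all clients identical).
* **Degenerate inputs.** Constant vectors make rank correlation
  undefined — an error, never NaN. Zero-variance signals cannot be
  z-scored and are skipped with a warning by the noise operator.
  Classes absent from a client's test split yield `NA` per-class AUROC
  and are excluded from that client's micro pooling.
* **Training intensity.** Desk defaults: 4 local epochs per
  melioration, batch 16, Adam 0.001, 8 total meliorations (5
  initiation) for the tamper studies, 300 records per client, 6
  clients. Intensity is the desk-scale surrogate for the ~100 local
  repeats a full-scale run would use: below roughly 2 epochs/batch 32,
  local training moves weights so little that the ±0.015 acceptance
  band cannot see label tampering at all. The federated baseline uses
  the identical recipe and identical client datasets per seed, so
  comparisons are paired.
* **Problem sizes in the test-suite studies.** Isolation and
  superiority studies run 10 seeds per scenario; the monotonicity study
  runs 10 seeds × 4 amplitudes with a 48-record probe. These sizes were
  chosen so that a full check remains a coffee-break computation on a
  single CPU.

## What the protocol achieves in simulation

At the defaults above (run by the package's test suite, not restated
here from any external source): noise-tampered clients separate at
initiation through their data-distance score and end isolated from all
clean orbits; label-shuffled clients — whose data looks perfectly
normal — are caught by the weight assessor instead, because training
against shuffled labels produces conflicting gradients that leave their
models anomalously *close* to the reference while genuine learners
drift away coherently; and clean clients' micro-average AUROC under
orbital learning matches or exceeds the paired federated baseline in
the tamper scenarios, because the baseline averages the poisoned
updates into everyone's model.

## Known limitations

* The generator's bump-sum morphology is a caricature of real ECG;
  absolute AUROC values and DTW score ranges are properties of this
  synthetic world and transfer to no clinical dataset.
* The acceptance band (±0.015) is a protocol constant taken at face
  value; its interaction with training intensity means that very weak
  local training makes all clients look identical, and very strong
  training fragments clean orbits into singletons. The defaults sit
  deliberately between those regimes.
* The weight assessor detects label shuffling through the
  *stay-near-the-reference* signature. Adversaries that tamper while
  mimicking normal weight drift are out of scope, as are
  model-inversion and other privacy attacks.
* Orbit ordering (inner = highest mean weight similarity) is a proxy
  for data quality that label-shuffled clients subvert: their
  stay-near-the-reference weights can place an isolated tampered
  singleton *inner* of clean orbits. The simulator never pulls
  inner-orbit layers automatically, so this affects only explicit
  `pull_inner_orbit_layers()` calls; users orchestrating manual pulls
  should gate them on the assessment log.
* Network transport, encryption and authentication are not simulated;
  the event log is the ground truth of what happened, not a wire
  protocol.
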