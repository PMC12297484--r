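---
title: "Domain-knowledge-guided self-supervised contrastive learning for wearable signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-knowledge-guided self-supervised contrastive learning for wearable signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Wearable devices produce long, unlabeled streams of physiological waveforms
— ECG, EEG, PPG, accelerometry. Supervised deep learning on such data is
bottlenecked by annotation. Self-supervised contrastive learning (SSCL)
sidesteps labels by pulling two augmented views of the same segment together
in an embedding space while pushing all other segments away. Its known
weakness on physiological data is the *false negative* problem: two
different segments from two different people with the same arrhythmia are
treated as a negative pair and actively separated, and the easiest thing for
the instance-discrimination objective to learn is often *who* the wearer is
rather than *what* the physiology shows.

`wearssl` implements a framework that counters both failure modes with
"old-school" domain features — heart-rate-variability statistics, waveform
morphology indices, spectral band powers, motion statistics — computed once,
offline, per segment:

1. **Instance level.** For each anchor segment in a mini-batch, its nearest
   neighbours in *domain-feature space* are promoted from negatives to
   additional positives.
2. **Prototype level.** k-means on the domain features (run once, before
   training) assigns every segment to one of $K$ clusters; each cluster
   keeps a prototype vector in embedding space, updated online, and every
   embedding is pulled toward its own prototype and away from the others.

## The objectives

Embeddings $z$ are $\ell_2$-normalized projector outputs, so inner products
are cosine similarities. The instance loss for anchor $i$ with positive set
$P(i) = \{p\} \cup S(i)$ (the augmentation sibling $p$ plus the domain
neighbours $S(i)$) and pruned negative set $N^*(i)$ (all other views in the
batch minus $S(i)$) is

$$\mathcal{L}^{ins}(i) = -\frac{1}{|P(i)|} \sum_{p^* \in P(i)}
\log\frac{\exp(z_i^\top z_{p^*}/\tau)}
{\exp(z_i^\top z_{p^*}/\tau) + \sum_{n \in N^*(i)} \exp(z_i^\top z_n/\tau)}.$$

Each positive's denominator contains only that positive and the pruned
negatives — the other positives do not appear. (The supervised-contrastive
variant that includes them is deliberately not what this loss computes; the
tests pin this exact form via a brute-force double-loop oracle.) With no
neighbours, the loss is exactly batch InfoNCE.

Neighbours are the `n_neighbors` views closest to the anchor by Euclidean
distance on z-normalized domain features, excluding the anchor and its
sibling; ties break by view index. The default selects both views of the two
most similar source segments (4 views). Because the two views of one
segment share one feature vector, neighbour views arrive in sibling pairs,
which also keeps the negative set consistent: a pulled neighbour's sibling
is never simultaneously pushed.

Prototypes are updated per batch by an exponential moving average of their
members' embeddings, $c_k' = \alpha c_k + (1-\alpha)\bar z_k$ with
$\alpha = 0.5$, and then re-normalized to unit length so that $z^\top c$
stays a cosine, commensurate with the instance-level terms (a documented
deviation from the raw update; switch it off with
`normalize_prototypes = FALSE`). The prototype loss is

$$\mathcal{L}^{proto}(i) = -\log\frac{\exp(z_i^\top c_{k_i}/\tau_{k_i})}
{\sum_{j=1}^{K} \exp(z_i^\top c_j/\tau_j)},$$

where each denominator term uses *its own* cluster's temperature. The
per-cluster temperatures follow member dispersion,
$\tau_k = \sum_i \lVert z_i - c_k\rVert_2 / (n_k \ln(n_k + m))$ with
smoothing count $m = 10$ and the natural logarithm, are refreshed at the end
of every epoch from distances accumulated batch-by-batch during that epoch
(streaming, against the prototype current at each batch — a second full
pass would double the epoch cost), and are rescaled by a single constant so
their mean equals the base temperature. Clusters unseen in an epoch keep
their previous temperature.

The total loss ramps the prototype term in over epochs:
$\mathcal{L} = \mathcal{L}^{ins} + \min(\max((T - T_0)/T_{max}, 0), 1)\,
\mathcal{L}^{proto}$. By convention here, the denominator is the *total* epoch
count, so with $T_0 > 0$ the weight never reaches 1 within a run; the
alternative denominator $T_{max} - T_0$ is available behind
`ramp_denominator = "span"`, off by default.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `base_tau` | 0.1 | softmax temperature, both levels (dimensionless; 0.1 is common SSCL practice) |
| `K` | 8 (desk) / 128 (large preset) | prototype count |
| `alpha` | 0.5 | EMA momentum |
| `m` | 10 | temperature smoothing count |
| `n_neighbors` | 2 (core default) / 4 (comparison preset) | neighbour views per anchor |
| `T0` | 10% of epochs (core default) | ramp start epoch |
| `lr` | 1e-3 pretrain, 5e-4 fine-tune | Adam step sizes |
| `warmup_epochs` | 2 (desk) / 5 (large preset) | linear learning-rate warm-up |

The `"large"` preset (`train_preset("large")`) is the GPU-scale
configuration this kind of model is normally trained at — batch 1024,
1000 epochs, $K = 128$ — for users with the hardware to match; everything
in this package's test suite runs at the `"desk"` scale.

`T0` deserves a note: the schedule leaves it free, and at desk scale it
matters a great deal. Prototypes are initialized from the mean of
their members' first-epoch embeddings, which early in training are poor;
if the prototype loss activates while the instance loss is still spreading
the embedding, the (mutually similar) prototypes generate large opposing
gradients — each term's scale is $1/\tau_k$ — and the run can collapse.
The desk comparison preset therefore starts the ramp at 80% of the
schedule; at 1000-epoch scale a 10% start leaves ample pure-instance
training, and the slow ramp achieves the same protection there.

## The encoder

A compact 1-D residual convolutional network written in base R: a strided
stem convolution, one stride-2 residual block per configured width (two
convolutions plus a 1×1-projected shortcut), global average pooling to the
*representation* $h$, and a two-layer projector to the normalized
*projection* $z$. There is no batch normalization or dropout, so inference
equals training mode and every embedding is bit-reproducible. Probes and
fine-tuning heads consume $h$ (pre-projector), the standard convention;
the contrastive losses consume $z$. Backpropagation is hand-derived
(im2col convolutions; gradients through the $\ell_2$ normalization use
$\partial z/\partial v = (I - zz^\top)/\lVert v\rVert$) and is verified
against central finite differences in the test suite. Prototypes receive no
gradient — they evolve only through the EMA, as the update rule specifies.

## The synthetic cohort

The generator emulates the structure that motivates the method: each
*class* is a rhythm/morphology regime — mean beat rate, beat-to-beat
interval jitter, main-bump width, and the amplitude of a delayed secondary
bump — and each *subject* carries nuisance: an amplitude gain (0.5–2×), a
baseline offset, a white-noise level (σ 0.05–0.4), and a resting-rate
factor (0.85–1.15×) so that the mean rate is partially subject-confounded
while interval *irregularity* and morphology stay class-determined (as with
arrhythmias, where irregularity rather than rate defines the class). A
segment is an impulse train at the realized rate convolved with a smooth
Gaussian-mixture beat kernel, then gain/baseline/noise are applied. The
impulse locations are retained as ground truth, which makes the beat
detector exactly testable.

`class_sep` scales every class parameter's deviation from the across-class
midpoint: 0 makes classes identical (probes must fall to chance — tested),
1 is the documented separable default.

What the generator does *not* emulate: clinically faithful waveform shapes
(no dynamical ECG model), non-stationarity within a segment, sensor
artifacts such as motion spikes or electrode pops, and class imbalance.
Passing tests therefore demonstrate that the machinery behaves as specified
under controlled class/subject structure, not that any particular clinical
performance would be attained on real recordings.

## The comparison experiment

The headline property — domain guidance improves label efficiency — is
checked on a cohort of 30 subjects × 12 segments with subject-disjoint
6:2:2 splits. Three encoders are compared by a linear probe (multinomial
logistic regression on frozen representations, train split → test split):
the full domain-guided model, an instance-only ablation (no neighbours, no
prototypes — plain SimCLR-style training), and a randomly initialized
encoder. Following the protocol of probing the validation split during
self-supervised training and keeping the best checkpoint, weights are
snapshotted every 5 epochs and the snapshot with the best validation
macro-F1 is selected. Fine-tuning from the domain-guided checkpoint at a
10% label fraction is compared with fine-tuning from random initialization
under balanced softmax cross-entropy. At that fraction the labeled subset
is ~21 segments — a single mini-batch — so one fine-tuning "epoch" is one
gradient step; the comparison runs 200 steps at the fine-tuning rate
(5e-4) so that both the head and the encoder actually converge on the
tiny labeled set.

Scale choices for one CPU: batch 72 (a third of the 216-segment train
split, so in-batch nearest neighbours are meaningful), 50 epochs with
cosine learning-rate decay, ramp start at epoch 40, prototype count 8.
Augmentation magnitudes (scaling σ 0.35, noise σ 0.2, jitter up to 1 s,
warp σ 0.2, cutout 15%) are sized to the generator's nuisance ranges: the
contrastive task demands invariance to exactly the nuisance the data
carries. The ordering of mean macro-F1 over three seeds
(domain-guided ≥ instance-only ≥ random) mirrors the qualitative ordering
the method reports on real datasets; at this scale the margins are a few
points of F1, so individual seeds can deviate even when the means order
correctly.

## Numerical choices and degenerate inputs

- All softmax-style terms use max-shifted log-sum-exp.
- SDNN, RMSSD, feature z-scores and amplitude statistics use *population*
  normalization (divide by $n$), making small hand-computed cases exact.
- Constant feature columns (population σ < 1e-12) z-score to 0; missing
  features are mean-imputed with fitting-split means before normalization,
  and an all-missing column is an error naming the column.
- Fewer than two detected beats yields `NA` sentinels for interval
  features (imputed at the matrix level); a flat signal yields zero
  detections, not an error.
- The beat detector's refractory period adapts to the dominant period of
  the energy envelope (autocorrelation), so a delayed intra-beat component
  is not double-counted; its energy floor treats a numerically flat signal
  as beatless.
- k-means uses greedy farthest-point initialization under a derived seed,
  then Lloyd iterations; assignments are computed once and never revisited
  during training.
- The incomplete final batch of each epoch is dropped so neighbour pools
  and cluster occupancy are size-consistent across steps.
- Empty negative sets make the InfoNCE term 0 (numerator equals
  denominator); `K = 1` makes the prototype loss identically 0.
- Checkpoint resume requires the same total-epoch configuration because the
  ramp weight depends on `Tmax`; `stop_after` exists to interrupt a long
  schedule for exact resumption.

## Design choices where the method left room

- **Feature banks.** The exact per-modality feature lists of the source
  pipelines are not reproducible here; the banks cover the same families —
  rhythm/HRV (including the rate-normalized CVNN/CVSD), morphology and
  quality indices, band powers, motion statistics — with fixed, documented
  names and order. The framework consumes any feature vector, and its
  robustness to feature-set composition is one of its claims.
- **Normalization statistics** for features default to train-split-only
  (leak-free), with the statistics object exposed so the choice is
  auditable.
- **Which embedding feeds the EMA** is taken to be the projector output,
  consistent with the similarity space of the prototype loss; the
  representation-space alternative would decouple the two.
- **Both views** of a segment contribute to the EMA mean — the update rule
  speaks of all assigned samples without distinguishing views, and using
  both is symmetric.
- **Semi-supervised label fractions** are stated inconsistently in the
  source (5/10/20% in the protocol, 10/20/50/100% in the results); the
  tools accept any fraction list and default to {0.05, 0.1, 0.2, 0.5, 1}.

## Known limitations

- Desk-scale runs are two orders of magnitude smaller than the GPU-scale
  regime this family of methods is usually trained in; absolute F1 values
  here say nothing about real-data performance, and the comparison margins
  are small relative to seed noise.
- The encoder is a compact residual network, not a ResNet18; the framework
  is architecture-agnostic, but representation capacity differs.
- The hand-written training loop is single-threaded R: adequate for
  hundreds of segments, not for hours of raw recordings.
- PPG-specific fiducial biomarkers and device-format readers (WFDB/EDF) are
  out of scope; the CSV/JSON container and the generic banks stand in.
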