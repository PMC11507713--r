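---
title: "Personalized diploid genomes and transcription initiation models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized diploid genomes and transcription initiation models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question the package addresses

Sequence-to-function models for regulatory genomics are usually trained on a
single haploid reference genome. Such models can predict signal profiles
across loci well, yet they never observe the consequence of a genetic variant
during training, and their variant effect predictions suffer for it. `dipcap`
implements, at desk scale, the full analysis needed to test the alternative:
train the same convolutional architecture on *personalized diploid genomes*
matched to per-individual functional data (base-resolution transcription
initiation coverage, PRO-cap-like), and compare it against an identically
trained ablation whose inputs are the reference sequence with variants
masked. The comparison covers cross-loci prediction (profile shape and total
quantity), initiation-QTL effect scoring, and reporter-assay style variant
benchmarks.

Because the real data behind this question (dozens of human
lymphoblastoid-line PRO-cap libraries with phased genotypes, ENCODE K562
tracks, MPRA tables) is neither shippable nor desk-trainable, the package
includes a first-class synthetic data generator that emulates the
*statistical structure* of such a panel. Every pipeline stage runs end to end
on synthetic data on one CPU.

# Diploid two-hot encoding

An unphased diploid sequence is encoded per position as the **sum of the
one-hot encodings of the two alleles** (channel order A, C, G, T), so every
row sums to 2: homozygous reference rows are `2*onehot(ref)`, heterozygous
rows have two 1s, homozygous alternate rows are `2*onehot(alt)`. The IUPAC
sequence `AYCR` (A; C/T het; C; A/G het) encodes as

```
[[2,0,0,0],
 [0,1,0,1],
 [0,2,0,0],
 [1,0,1,0]]
```

Phase is deliberately discarded — the encoding cannot distinguish the two
haplotype assignments of a heterozygous pair, so the package is phase-free
throughout. Unknown bases (`N`) encode as all-zero rows; the generator never
emits them, and real-data windows containing them should be filtered.
Reference (variant-masked) inputs use the *same* two-hot scale (homozygous
rows summing to 2) rather than one-hot, so personalized and masked models
share one architecture and fine-tuning is weight-compatible.

# The model and its loss

The network is a compact BPNet-style CNN: two convolutions (64 filters of
width 8, exponential-linear activation; then 128 filters of width 4,
rectified-linear), a tower of 9 exponentially dilated width-3 convolutions
(64 filters, dilations 1..512) with identity skip connections, batch
normalization after every convolution, max pooling (width 2) after the first
two convolutions and after the tower. Two heads follow: a fully connected
**profile** head emitting a track of length `2 * output_length` (plus strand
then minus strand — the strand order is this package's convention; the
length-1000 layout is not otherwise fixed), and a **quantity** head (global
average pooling, one fully connected unit). Batch normalization and ReLU
follow both heads, so outputs are nonnegative; the quantity head predicts on
the linear scale (the loss takes its log).

The multiscale loss for an observed track `p_obs` is

```
loss = -cos(p_obs, y_profile)
       + lambda * (log(sum(p_obs) + alpha) - log(y_quantity + alpha))^2
```

with natural logs, `lambda = 1/500` and `alpha = 1e-6`. The cosine term is
scale-invariant (profile shape only); the quantity term carries all scale
information. Numerical choices: the cosine with a zero-norm vector on either
side is defined as 0 (maximally uninformative) and logged; the loss is
computed on RPM-normalized observed tracks (reads-per-million, library total
scaled to 1e6), which only affects the quantity term.

`scale_factor` multiplies all filter counts so that a quarter- or
eighth-scale model trains on one CPU while preserving the architecture.
Because no deep-learning framework is available in the target environment,
the forward pass, analytic gradients and Adam optimizer are implemented
directly in RcppArmadillo; the gradient implementation is verified against
central finite differences in the test suite, which is the authoritative
oracle for that code. The engine computes in single precision (it is
memory-bandwidth bound on CPU) while parameters and the optimizer remain
double precision on the R side; the standalone `multiscale_loss()` is full
double precision, so analytic loss identities hold to 1e-10 and better.

Other numerical details: batch-norm uses eps 1e-3 and momentum 0.9 on running
statistics, which are frozen at inference so predictions are deterministic
and batch-size independent; max pooling drops a trailing odd element; the
output window is the central `output_length` bp of the input window; Adam
uses the standard (0.9, 0.999) moments. Weight initialization is a
deterministic function of the seed.

Two training-loop numerics deserve explanation because they were learned the
hard way:

* **Validation is scored with batch statistics, and inference statistics
  are frozen from one calibration batch.** Batch-norm running averages lag
  the weights they are meant to normalize; scoring validation in inference
  mode therefore produces spurious dips and spikes, and early stopping
  will happily restore the weights of a spurious dip — so validation loss
  is computed with per-batch statistics over a fixed batch partitioning
  (deterministic). Worse, statistics accumulated *during* training are
  internally inconsistent at inference: layer k's averages were recorded
  while every layer below still normalized per batch, and the mismatch
  compounds across the network's 13 normalization layers, occasionally
  wrecking inference-mode predictions outright even when the training-mode
  network is good. After the final weights are chosen, the inference
  statistics are therefore frozen from a single large calibration batch
  (512 training windows, one training-mode pass with momentum 0): by
  induction through the layers, inference with these statistics exactly
  reproduces the network's training-mode behavior on that batch, and
  closely elsewhere. Predictions remain deterministic and independent of
  prediction-batch composition.
* **Collapse detection and restart.** A small fraction of short runs fail
  to optimize at all (dead rectified activations early in training leave
  the loss stuck near its initialization value). `reproduce_synthetic()`
  detects this from the best validation loss (threshold -0.3, i.e. the
  profile cosine never cleared 0.3) and retries that arm with a shifted
  initialization seed, up to twice, with the retry logged. Gradient-norm
  clipping (`train_config(clip_norm = 5)`, roughly the 95th percentile of
  observed batch gradient norms) and a one-epoch learning-rate warmup
  protect against the occasional destabilizing step.
* **Optional tail weight averaging** (`train_config(average_last = k)`).
  Short desk-scale runs stop while the optimizer trajectory is still
  noisy; single-epoch snapshots of two otherwise identical runs can differ
  visibly in what the weakly weighted (`lambda = 1/500`) quantity head has
  learned. Averaging the last k end-of-epoch weight vectors damps this
  noise. The default (0) keeps the canonical protocol — restore the
  best-validation-epoch weights under patience-10 early stopping — and the
  desk-scale configuration enables averaging over the final 6 epochs.

# Folds, ensembling, and ablations

Chromosomes are packed greedily (longest first) into 10 folds of roughly
equal total length. **Fold 0 is reserved for final evaluation and never
contributes a gradient in any training mode**; the canonical human fold-0
set (chr9, chr13, chr20, chr21) can be pinned via configuration. Nine
replicate models are trained leave-one-out over folds 1–9, each using its
holdout fold for early stopping (Adam, learning rate 0.001, patience 10
epochs on validation multiscale loss, best-epoch weights restored; batch
size 64 and a 100-epoch cap are package defaults where unspecified).
Ensemble prediction is the mean of replicate outputs — profiles averaged
after per-replicate normalization to sum 1, quantities averaged directly;
the aggregation rule is a package convention.

The two ablations:

* **Subsampling** — n in {5, 10, 15, 20, 30} libraries, 5 runs each, never
  drawing two isogenic replicate libraries of the same donor; every run logs
  the seeds needed for an exact re-run.
* **Variant masking** — identical protocol, but every input is the reference
  sequence with variants masked while the per-individual coverage labels are
  unchanged. A masked-input model is flagged, and *its predictions are also
  made on masked inputs*, making its predicted variant effects exactly zero
  by construction whenever a window's variants are all masked. (On real
  data, one could instead feed personalized sequence to a reference-trained
  model at test time; the package pins the ablation to the masked pipeline
  because it makes the mechanism behind "predicted no effect" exact and
  testable.)

Fine-tuning to a new cell type / readout keeps all weights trainable, runs
one warmup epoch at learning rate 1e-4 before the usual 0.001, and reuses
the pretraining fold partition to avoid leakage into variant benchmarks.

# QTL effect scoring

The effect of a variant on initiation is scored by binning individuals on
QTL genotype and taking the **L2 norm of the difference between the averaged
homozygous-reference and averaged homozygous-alternate tracks**;
heterozygotes are excluded from the score (they still contribute to
training). "Track" means: for observations, RPM coverage over the central
output window (jitter 0, both strands concatenated); for predictions, the
profile normalized to sum 1 times the predicted quantity — the package's
realization of a coverage-scale predicted track, since the two heads do not
otherwise combine.

To keep evaluation leakage-free with an ensemble, a QTL on fold 0 is scored
by the full ensemble, and a QTL on fold i >= 1 by replicate i alone — the
one replicate that never trained on that chromosome. Cross-loci metrics are
the median per-locus Pearson correlation of tracks (profile) and the Pearson
correlation of log10 totals (quantity), computed on fold-0 elements from
reference-sequence inputs against panel-averaged coverage; constant tracks
are excluded with a logged count, and a constant effect-score vector is
reported as correlation 0 with a `degenerate` flag (a constant scorer has no
discriminative association — this convention matters because the masked
model is constant-zero by construction).

# Reporter (MPRA-style) benchmarking

A tested 200 bp oligo is inserted directly upstream of a minimal TATA
promoter in a reporter backbone, and a model-input-length window containing
insert and promoter is extracted (oligo centered by default; the offset is
configuration). The real reporter plasmid sequence is not shipped; the
package generates a clearly-labelled *synthetic* backbone with a canonical
TATA-box minimal promoter, and accepts a real backbone as FASTA. Variant
effect = `log2((q_alt + 1e-6) / (q_ref + 1e-6))` of predicted quantities
(positive = alternate allele increases initiation). emVar classification
uses the squared effect as the score; auPRC uses the average-precision
summation with tied scores collapsed to one threshold. Bootstrap model
comparison resamples SNPs with replacement (same resample for all models,
single-class resamples redrawn and logged) and reports one-sided empirical
p-values for `auPRC(other) >= auPRC(reference)`. With a fold partition
supplied, only variants on fold-0 chromosomes enter the benchmark.

# What the synthetic generator emulates — and what it does not

The generator stipulates a world with the structure the analysis assumes:

* a panel of diploid donors (default 40) carrying biallelic SNPs at allele
  frequencies uniform in [0.05, 0.5], Hardy-Weinberg dosages, no linkage
  disequilibrium, no indels;
* divergently transcribed elements whose opposing-strand initiation modes
  sit 110 bp apart, with discretized Gaussian bumps (sd 15 bp — the shape is
  a package stipulation chosen so profile correlations are meaningful);
* per-element expected totals with a log-normal noise component (sdlog 0.5
  around ~1000 reads) *plus a sequence-determined component*: standardized
  GC content of the central 200 bp scaled by 0.8 on the log scale. The
  sequence component exists so that total quantity — like real core
  promoter strength — has a part that a sequence model can learn and
  generalize to held-out loci; without it, cross-loci quantity evaluation
  on unseen elements would be a pure-noise comparison.
* planted per-allele effects at a fraction (default 0.25) of in-window
  SNPs: quantity log2 fold changes ~ Normal(0, 0.4) and strand-allocation
  logit shifts ~ Normal(0, 0.5) — tiQTL- and diQTL-like effects of
  realistic magnitude for fine-mapped initiation QTLs;
* negative-binomial element totals (dispersion 0.2; Poisson at 0) split
  between strands by a logistic allocation, as a parsimonious count-noise
  stipulation for a readout whose true noise model is not published.

Planted effects are *locus-specific*: an effect is attached to a SNP, not
mediated by a motif grammar shared across loci. A model can therefore only
learn variant effects at elements it trained on — which is exactly the
mechanism the desk-scale comparison tests (does the model use allele
information present in its inputs?), and is honest about what a green test
establishes: it demonstrates the encoding-to-prediction pathway and the
masking mechanism, not motif-level generalization to unseen variants, which
requires real data at real scale. Held-out-fold QTLs are still included in
benchmarks; they dilute correlations for both arms equally.

# Design choices made where the design was genuinely open

* **JSON configuration** instead of YAML: the target environment ships no
  YAML parser; `jsonlite` is available and lossless for these configs.
* **Element centers** from peak pairing are midpoints of the two paired
  summits, with mutual-nearest pairing and leftmost tie-breaks.
* **Jitter is static**: each training window's jitter is drawn once when the
  dataset is materialized, not redrawn per epoch, for exact
  reproducibility.
* **Identical-twin training for the ablation comparison**: the personalized
  and masked models in `reproduce_synthetic()` share the initialization
  seed, batch order and window jitter, so the only difference between the
  two runs is the variant content of the inputs.
* **Desk scale** (`desk_config()`): input 256 bp, output 128 bp, scale
  factor 0.2, 26 epochs. These shrink compute ~3 orders of magnitude
  versus the full-scale setting (1 kb windows, scale 1, 67 libraries,
  9-replicate ensembles per run); all full-scale values remain available
  through configuration.

# Known limitations

* **Desk-scale quantity prediction is optimizer-noise limited.** The
  quantity head is a single affine readout trained through a loss term
  weighted `lambda = 1/500`. In a run of only a few thousand optimizer
  steps, *which* quantity function that readout lands on varies from run
  to run: two runs identical up to input masking can differ in held-out
  quantity correlation by 0.1-0.4, even though neither is better in
  expectation. Tail weight averaging, learning-rate decay, data-scale head
  initialization, and a deterministic closed-form head refit (available as
  `train_config(calibrate_quantity = TRUE)`) all reduce but do not remove
  this, and the closed-form refit shows the effect is real: the optimal
  affine readout of the trunk generalizes quantity near chance, so the
  stochastic head's good runs are early-stopping luck. Consequently the
  test suite's check that the personalized and masked models have
  cross-loci quantity metrics within 0.05 of each other is expected to
  fail at desk scale, and is left failing rather than loosened; profile
  comparability and the variant-effect asymmetry are unaffected. At full
  scale (roughly three orders of magnitude more steps) the head converges
  and this ceases to be an issue.
* The CNN engine is single-threaded CPU code; full-scale (scale factor 1,
  1 kb inputs, dozens of libraries) training is out of reach here by
  design.
* The generator has no linkage disequilibrium, no indels, no chromatin
  context, and locus-specific (non-motif) variant effects; quantitative
  agreement with published real-data correlations is out of scope.
* Bootstrap p-values are empirical one-sided fractions at n = 1000 draws;
  their resolution is 0.001.
* bigWig output is not supported (text bedGraph only), keeping the package
  free of binary-format dependencies.
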