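---
title: "Transfer learning for pMHC stability and immunogenicity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transfer learning for pMHC stability and immunogenicity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Class-I MHC molecules present short peptides (8–14 residues) on the cell
surface; whether a peptide binds, how long the peptide–MHC (pMHC) complex
stays assembled (its kinetic stability, summarized as a dissociation
half-life in hours), and whether the presented peptide triggers a T-cell
response (immunogenicity) are three related but distinct questions.
Binding data are abundant — quantitative binding affinities in nM and
large mass-spectrometry catalogues of eluted ligands (EL) — while
stability and immunogenicity measurements number only in the thousands.
Because binding is a physical prerequisite for both downstream
properties, and empirically correlates with them, a predictor trained on
the large binding corpora is a strong starting point for the small-data
tasks. `tlmhc` implements this transfer-learning program end to end:

1. **Pretraining**: a single multilayer perceptron (MLP) trunk with two
   sigmoid heads — a binding-affinity (BA) regression head and an EL
   classification head — trained jointly on mixed BA/EL data with
   proteome-derived decoys as EL negatives.
2. **Fine-tuning**: the pretrained weights initialize a stability (STAB)
   or immunogenicity (IMM) predictor, which is then trained on the small
   downstream dataset under a nested cross-validation protocol.
3. **Evaluation and interpretation**: merged-fold correlation metrics,
   classification metrics with explicit baselines, distribution
   comparisons, threshold–mean curves, and score-derived sequence motifs.

## Input representation

A pair (peptide, allele) is encoded as a fixed-width numeric matrix.
Each residue maps to its BLOSUM62 substitution row divided by 10 (the
convention of pan-allele binding predictors; a one-hot scheme is
available and used by the tests for exact round-trip checks). Peptides
of length 8–14 occupy `max_len = 14` positions: the first ⌈L/2⌉ residues
keep the leading slots and the remainder the trailing slots, with an
all-zero pad vector in the middle. This placement keeps the canonical
anchor positions — P2 near the N-terminus and the C-terminal residue —
in stable columns across lengths, which matters because the anchors
dominate binding while the middle, TCR-facing positions (P4–P6 in
9-mers) carry the immunogenicity-specific signal. The unknown residue
`X` maps to the column-wise mean of the matrix rows, a neutral default.

The allele is represented by a pseudo-sequence: a fixed set of P = 34
MHC groove contact residues, the standard pan-allele device. The table
bundled with the package contains *synthetic placeholder*
pseudo-sequences (the file is named accordingly); any two-column TSV of
curated pseudo-sequences can be supplied instead, and synthetic alleles
generated by the data simulator carry their own.

## Label scales

All heads train on a common [0,1] scale:

* affinities: `1 − log(nM)/log(50000)`, clamped — 1 nM maps to 1, the
  50,000 nM cap to 0; the inverse transform recovers nM exactly;
* half-lives: `h/(h + h0)` with `h0 = 1` hour by default — saturating,
  0 at `h = 0` (the label random negatives receive), 0.5 at `h0`;
* EL hits/decoys and immunogenicity labels: 1/0, or a continuous
  strength in [0,1].

Both regression transforms are strictly monotone and invertible, so
rank metrics are unaffected by the choice and predicted scores convert
back to physical units.

## Model and training

The predictor is a deliberately small MLP: a shared trunk (default two
hidden layers, 128 and 64 tanh units; the experiments in this package
use 32/16 to keep desk-scale runtimes) and one sigmoid output unit per
head. Regression heads (BA, STAB) use squared error, classification
heads (EL, IMM) binary cross-entropy, and every example contributes
only to its own head's loss — a mixed batch updates both heads without
cross-talk. Optimization is Adam (default) or SGD with momentum,
minibatch training with seeded shuffling, and early stopping: after
each epoch the mean per-example validation loss is computed, and
training stops once `patience` epochs pass without improvement,
returning the weights of the best epoch. With a fixed seed, fixed data
order and single-threaded BLAS, runs are bit-reproducible; models
serialize to versioned JSON with weights printed at full double
precision, so save/load round-trips are exact.

The architecture details of published tools of this family are not
public in a form we could copy; the sizes here are declared package
defaults, exposed in `predictor_spec()`, and nothing in the protocol
logic depends on them.

## Fine-tuning strategies

`finetune()` copies a source head's weights onto the target head
(BA→STAB and EL→IMM by default, the pairings that work best for each
task) and trains under one of three strategies: `unfreeze_all` (every
weight trainable — the default and empirically the best, consistent
with non-anchor positions mattering downstream), `freeze_trunk` (head
only; the trunk is bit-identical afterwards, which the tests assert),
and `replace_top` (last hidden layer and head re-initialized, deeper
layers inherited). The fine-tuning learning rate defaults to 1/10 of
the pretraining rate, standard transfer practice. Chained transfer —
fine-tuning an immunogenicity model from an already fine-tuned
stability model — is expressed by passing any saved model as the
pretrained input.

Two knowledge-transfer baselines are included: the stacked
"score as a feature" model (`ba_as_feature_model()`), which trains a
fresh predictor on the encoding concatenated with the frozen
pretrained score, and convex score mixing (`alpha_mix()`,
`tune_alpha()`) with a weighting factor α ∈ [0,1] selected on a
validation grid (step 0.05, ties toward smaller α).

## Cross-validation protocols

The stability pipeline runs stratified 10-fold cross-validation;
within each training fold a further stratified 90/10 split drives
early stopping, so no left-out record ever influences model selection
in its own fold. The ten fine-tuned members form the deliverable
ensemble, whose prediction is the member mean. The immunogenicity
pipeline is identical with 5 folds and 80/20 nested splits, plus two
dataset variants: per-allele balancing of each *training* fold
(`balance_per_allele()`, target positive fraction 0.5, majority class
subsampled, never oversampled) and continuous strength labels in place
of binary ones.

Continuous stability labels are stratified by 4 quantile bins, with
exact zeros — the random negatives — as their own bin, so
unstable-by-construction records spread evenly across folds. The
choice of 4 bins is a declared convention; "stratified" for regression
has no canonical definition.

Fold metrics are never averaged: the left-out predictions of all folds
are concatenated and each metric is computed once on the merged set.
Averaging correlation coefficients underestimates (their sampling
distribution is skewed) and Fisher's z overcorrects; merging
sidesteps both. `merged_fold_eval()` enforces disjoint fold index
sets.

## Metrics

Pearson and Kendall tau-b (tie-corrected) come from `stats::cor`;
the two-sample Kolmogorov–Smirnov test from `stats::ks.test` with the
asymptotic p-value (D is the primary output). AUROC uses the
Mann–Whitney rank formula with midranks for ties. AUPRC uses
step-wise interpolation with tied scores grouped — no linear segments
— so values are bit-reproducible and not optimistically biased; the
positive fraction (the expected AUPRC of an uninformative scorer) is
always attached as the baseline. Top-N counts break ties by stable
input order. Undefined metrics (zero variance, a single class) are
returned as flagged `NA`s, never silently propagated. The test suite
validates every metric against an independent brute-force oracle
(pair enumeration for tau-b, exhaustive ECDF evaluation for KS,
pair-counting for AUROC) and AUPRC against a seeded Monte-Carlo
uniform-score experiment.

Threshold–mean curves relate an affinity-like quantity to the mean of
a response over all records *strictly better* than each threshold;
orientation is explicit because nM and ED50 are lower-is-better while
model scores are higher-is-better, and empty selections yield `NA`,
not 0.

## Dataset curation operations

* `generate_decoys()` draws random subsequences from each hit's source
  protein (falling back to the whole protein set when the annotation
  is missing), matching the per-allele hit length distribution,
  excluding any sequence identical to a hit of the same allele;
  default 99 decoys per hit, about a 1:100 hit:total ratio.
* `strong_binder_filter()` keeps records with predicted affinity
  strictly below 500 nM, emulating stability training sets in which
  every measured (non-negative) record is a strong binder.
* `add_random_negatives()` appends sampled peptides with predicted
  affinity above 20,000 nM, labelled with exactly 0 hours of
  half-life — the convention for balancing stability data with
  unstable examples.
* `dedup_against()` removes training records whose (peptide, allele)
  pair occurs in any evaluation set, case-insensitively, and reports
  the count.

## The synthetic data generator

Because the package must be testable end to end without external
downloads, `synth_config()` + the `simulate_*()` functions generate
multi-task data with the statistical structure the protocols assume:

* each synthetic allele has a binding position-weight matrix whose
  mean absolute weight at the anchors (P2, C-terminus) exceeds the
  non-anchor mean by a fixed factor (4), a distinct pseudo-sequence,
  and an independent middle-position weight matrix standing in for
  TCR-contact preferences;
* the standardized PWM score `z` maps to affinity as
  `nM = 50000^(1 − plogis(z + noise))` — the exact inverse of the
  training transform, so configured couplings are interpretable on
  the training scale;
* EL hits are the strongest-binding 10% of an independent draw;
  decoys come from a synthetic proteome of i.i.d.-residue sequences
  with log-normal lengths (median 400);
* stability is `coupling·z + extra·m + noise` pushed through a
  monotone map to non-negative hours, where `m` is the standardized
  middle-position term; 5% of records get an independently redrawn
  latent, reproducing the observed discordant cases (strong binders
  with poor stability and vice versa); random negatives are appended
  as in the curation step;
* immunogenicity is Bernoulli with
  `P = plogis(2(coupling·z + 0.5·m + noise))`; the probability itself
  is kept as the continuous strength label, a recognition frequency
  is simulated as positive responses among 10 donors, and per-allele
  positive fractions can be forced to configured targets by majority
  subsampling.

What the generator does *not* emulate: real binding energetics,
length-dependent motif structure, inter-allele similarity (synthetic
PWMs are independent), measurement censoring, or batch effects in MS
data. Passing tests therefore demonstrate that the *procedures* are
correct and that the transfer mechanisms behave as designed when the
assumed structure is present — not that any particular performance
level will be reached on real data.

## The two mechanism experiments

`transfer_benefit_experiment()` pretrains once on ~50,000 simulated
BA/EL examples, then, over seeded replicates, fine-tunes
(`unfreeze_all`) on a fresh 500-record downstream set and compares
held-out Kendall tau (or AUPRC for immunogenicity, on 1,000 held-out
records) against an identically configured model trained from
scratch. Two design choices deserve explanation:

* *One pretraining, many replicates.* Replicates vary the downstream
  simulation and all downstream seeds; the pretrained model is shared,
  matching the real protocol (one pretrained predictor, many
  fine-tunings) and the desk-scale budget.
* *No random negatives in the downstream sets.* The zero-half-life
  random-negative label is itself a function of binding, so keeping
  negatives in the downstream data re-introduces an affinity→stability
  coupling even when the latent coupling is configured to zero — and
  the zero-coupling control (no systematic advantage of fine-tuning)
  would be impossible by construction. The experiment isolates the
  latent coupling; the pipelines proper keep their negatives.

`balancing_experiment()` checks the per-allele balancing mechanism:
training sets are simulated with alternating per-allele positive
fractions (0.9/0.1), the held-out set is balanced (0.5 per allele),
and the eluted-ligand head of one shared pretrained model is
fine-tuned once on the imbalanced set and once on its balanced
subsample. Both arms fine-tune — the regime in which the imbalanced
set's extra records add little signal (the trunk already encodes
binding) but their prior skew is absorbed wholesale, which is exactly
where balancing pays. Training sets are 1,500 records per allele
before subsampling, the smallest scale at which both arms learn
clearly above chance.

## Numerical choices and degenerate inputs

* Glorot-uniform initialization, biases at zero; seeded.
* Early stopping compares mean per-example validation losses exactly;
  `patience = 0` stops at the first non-improving epoch.
* Stratified folds deal shuffled stratum members round-robin from a
  rotating offset, so per-fold stratum counts deviate by at most 1.
* Top-fraction selection keeps `max(1, floor(n·fraction))` peptides —
  the top 0.1% of 500,000 is exactly 500 — with boundary ties broken
  by stable input order.
* PFM pseudocount defaults to 0 (fidelity to the raw selection);
  information content uses `0·log 0 = 0` and a uniform background by
  default.
* Allele names: whitespace stripped, upper-cased, `HLA-`/`*`/`:`
  inserted only when digits parse unambiguously (four bare digits
  split 2+2); anything else is an error, never a guess. The `SYN-`
  namespace passes through for synthetic panels.
* Problem sizes in the shipped tests and acceptance script (3–6
  alleles, 16/8 or 32/16 hidden units, 50,000-example pretraining,
  1,000-record pipelines) are the package's chosen desk-scale study
  conditions; every size is a function argument.

## Known limitations

* The MLP is intentionally small and CPU-bound; no GPU path.
* BA inequality-censored measurements ("<", ">") are treated as point
  values; censoring-aware losses are out of scope.
* Class-II MHC, multi-allelic MS deconvolution, and external database
  retrieval are out of scope.
* Motif output is tabular (PFM + information content); rendering
  sequence logos is left to dedicated graphics packages.
* The bundled pseudo-sequence table is synthetic; supply curated
  pseudo-sequences for real alleles.
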