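---
title: "phasekit: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phasekit: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`phasekit` predicts, from sequence, whether a protein undergoes
liquid–liquid phase separation (LLPS) and, if so, whether it
phase-separates by self-assembly (PS-Self) or only with partner
macromolecules (PS-Part). This vignette documents the models, the
parameters that matter, the synthetic data the package is tested on, and
the places where the design was genuinely open.

## Input representations

**Sequences.** Canonical 20-letter protein sequences. Admission follows
two rules applied by `filter_admissible()`: length within [50, 5000]
residues, and no non-canonical letters (B, J, O, U, X, Z cause rejection
with a machine-readable reason; there is no silent substitution).
Redundancy reduction (clustering at 40% identity) is a documented
preprocessing step performed by external tools and is out of scope here.

**Evolutionary profiles.** Two per-sequence L×20 matrices: a PSI-BLAST
position-specific scoring matrix (the log-odds block of POSSUM-style ASCII
output) and an HHsuite HMM profile whose integer-coded match-state scores
h are converted to frequencies by h' = 2^(−0.001·h), with the `*`
sentinel mapping to exactly 0. Internally every matrix uses the
alphabetical residue-column order `ACDEFGHIKLMNPQRSTVWY`; each reader
re-maps from its dialect's native order (PSI-BLAST's
`ARNDCQEGHILKMFPSTWYV`; HHsuite is already alphabetical) at parse time, so
only the boundary code knows about dialects. The two profiles are
channel-stacked (PSSM block first — the fusion order is a fixed
convention, not given by any reference) and zero-padded to a standard
length `n_max`. PSSM scores are passed raw by default; min–max scaling is
available behind a flag since no reference scaling is specified.

`n_max` defaults to 5000, the upper admissible sequence length; it is a
dataset bound rather than an algorithmic constant, so it is configurable
and the test suite runs at `n_max = 256` to keep the convolution stack at
desk scale.

**Physicochemical features.** The AAIndex-weighted composition
`F_j = Σ_i f(x_i)·A_ij` embeds a variable-length sequence into one value
per retained AAIndex property (531 with the full AAIndex1 release;
properties containing `NA` are dropped at parse time). The multimodal
vector (27 components) concatenates the amino-acid composition with seven
phase-separation features in a fixed order: IDR fraction, longest PS IDR
length, PS potential, prion-like-domain score, granule propensity — all
provider-supplied — then hydropathy (mean Kyte–Doolittle; a windowed
statistic was an alternative reading, the mean was adopted) and Shannon
entropy. The 12-component analysis panel adds LCR score, FCR, NCPR,
Kappa, Omega, PPII propensity and π-π score.

Scores produced by third-party tools (disorder predictors, PLAAC-type
prion-domain scores, granule propensity, CIDER patterning parameters) are
*consumed, never re-derived*: a `feature_provider()` reads them from a TSV
keyed by sequence id or from a function. Histidine is treated as uncharged
in FCR/NCPR (the common CIDER convention; configurable). For offline
testing the package ships `patterning_simple()`, a blob-based mixing
statistic over 5- and 6-residue windows that orders sequences from
well-mixed to blocky like the CIDER Kappa/Omega do — it is explicitly
labeled non-reference and exists only so synthetic fixtures can populate
those slots.

## Task 1: the LLPS network

Two parallel 1-D convolution branches (kernel widths 3 and 7, no bias
terms) read the padded profile tensor; their feature maps are
concatenated channel-wise and gated by squeeze-excitation channel
attention (masked global average pool → bottleneck dense with reduction
ratio 4 → sigmoid gate). Pooling — both the attention's average and the
final global max — is masked to each sequence's true length, and the
convolutions carry no bias, so predictions are exactly invariant to the
amount of zero padding (asserted in the tests). A BiLSTM reads the
27-component multimodal vector as a length-27 scalar sequence (one
feature per time step; an embedded-sequence reading was the alternative),
taking the final hidden state of each direction. Both branch outputs pass
through small dense layers, are concatenated, and a dense sigmoid head
yields `p_LLPS`.

The five architecture parameters — CNN1 filters, CNN2 filters, CNN dense
units, BiLSTM units, BiLSTM dense units — take values in
{16,32,64}×{16,32,64}×{8,16,32}×{16,32,64}×{8,16,32}, a 243-point grid
(`enumerate_grid()`), searched by stratified 10-fold cross-validation and
ranked by AUC with ties broken by sensitivity. The reference optimum
(64, 32, 32, 32, 8) is the package default. "CNN1/CNN2" are interpreted
as parallel branches with distinct kernel widths (multi-scale motif
detection); serial stacking was the other reading of an ambiguous
description.

Training: binary cross-entropy, Adam (lr 1e-3), batch size 32, optional
early stopping on a 15% validation split with patience 5 — all standard
defaults, none prescribed by a reference. Early stopping is automatically
disabled when the planned validation split would hold fewer than 30
samples: below that, epoch-to-epoch noise in the validation loss dominates
and weight restoration can pick an early, underfit epoch (observed
directly in training diagnostics at 15 validation samples). The implementation is
self-contained base R (im2col convolutions, backpropagation through time,
Adam); its gradients are validated against central finite differences in
the test suite, which is the strongest correctness check available for a
hand-written network. Training is deterministic given the configuration
seed. The decision threshold of the cascade is 0.5.

## Task 2: mechanism classification and feature selection

PS-Self vs PS-Part is decided by gradient-boosted trees (positive class
PS-Self — polarity is a package convention recorded in the model object)
on features chosen by a three-step pipeline sharing one seed-pinned fold
assignment:

1. **RFE** under extremely-randomized-trees impurity importance
   (`ranger`, `splitrule = "extratrees"`), eliminating 10% of features
   per round (the elimination schedule is not prescribed anywhere; 10% is
   a conventional choice), scoring each requested target dimension by
   cross-validated boosted-tree AUC. Constant features are removed first
   and logged.
2. **Importance sweep**: features re-ranked by split-count importance —
   the number of times a feature is selected as a weak classifier, i.e.
   split frequency, not gain — then nested top-k subsets (k = 5, 10, …)
   are scored by cross-validation and the smallest subset attaining the
   best AUC wins. Importance ties are broken by stable column order and
   flagged.
3. **IFS**: greedy forward addition over the sequence-property candidates
   not already represented (hydropathy, Omega, FCR, NCPR, Kappa, PPII,
   entropy, in that documented order); a candidate is kept only on
   *strict* AUC improvement (ties reject — the lenient alternative was
   considered and rejected to keep the final set minimal).

Cross-validation reports pooled out-of-fold metrics as primary (per-fold
mean ± sd are also emitted); pooling is the less noisy choice for small
samples. MCC with a degenerate confusion table is reported as 0 and
flagged; other undefined ratios surface as flagged `NA`, never a silent 0.

A subtlety worth stating: the CV AUC reported by the selection stages is
an *optimized* quantity, so on null data it sits above chance — selecting
~35 of 100 noise features by maximizing CV AUC over ~25 candidate subsets
inflates the apparent signal. The unbiased end-to-end estimate is
`nested_pipeline_cv()`, which re-runs the whole selection inside each
outer training fold and scores untouched outer test folds; on null
feature tables this is chance-level, as the acceptance checks verify.
Class balancing (e.g. drawing 285 of 496 partner-dependent proteins to
match 285 self-assembling ones) is seed-parameterized
(`balance_classes()`) since any particular subsample is unknowable.

`classifier_zoo()` compares boosted trees, dart-boosted trees, stochastic
gradient boosting, random forest, extremely-randomized trees and an RBF
SVM under one fold assignment. The two extra gradient-boosting entries
are xgboost variants (dart, and subsampled boosting); they stand in the
comparison where other boosting frameworks would otherwise appear.

## Interpretation: saturation mutagenesis

`ism_saturate()` evaluates exactly L×19 single-residue mutants against
any deterministic sequence-to-probability scorer (by default the
mechanism model behind a feature pipeline; the LLPS network can be
wrapped the same way). The importance score is |p_ref − p_mut|, zero on
the diagonal. Positions are partitioned into S contiguous segments by
`floor((i−1)·S/L)+1` — deterministic, sizes differing by at most one; no
partition rule is prescribed anywhere, and this one makes segment sums
exactly conserve the total score for every S (25 and 50 are the
conventional choices). Sequences shorter than S leave trailing segments
empty with score 0. The residue-by-segment map attributes scores to the
*introduced* residue by default; the reference-residue reading is
available behind a flag because the convention is ambiguous.

## What the synthetic generators emulate — and what they do not

`gen_sequences()` draws two classes differing in length (log-normal,
means ~700 aa for the phase-separating class and ~213 aa for the folded
reference, matching the curated-set averages; sdlog 0.6, clipped to
[50, n_max]) and composition (Dirichlet-perturbed background; the PS-like
class enriched ~1.8× in G, P, S, Q, N and depleted ~0.55× in
hydrophobic/aromatic residues, concentration 150 — chosen once as
realistic per-protein variation). `gen_profile_pair()` produces profiles
whose rows peak at the observed residue, with integer-coded HMM scores
constructed to be exactly invertible through the frequency transform.
`gen_feature_table()` plants Gaussian class-mean shifts of a requested
effect size among noise features. `gen_provider_table()` shifts
disorder-type scores upward for the positive class.

These fixtures exercise every parser, encoder, model and invariant
offline. They do *not* reproduce real evolutionary correlation structure,
position-dependent conservation, domain architecture, or the actual
feature distributions of curated LLPS databases — so passing tests
demonstrate correctness of the machinery and recoverability of planted
signal at the stated effect sizes, not benchmark performance on real
proteomes. Reported reference-scale results (e.g. AUC ≈ 0.97 for task 1
on curated data) require the original datasets and full profile
databases and are explicitly out of scope.

## Problem sizes and numerical choices

The test and acceptance runs use: `n_max = 256`, 100 sequences per class
for network smoke training (2-fold split, 10 epochs); feature tables of
400 samples × (10 informative + 90 noise) at effect 1.5 sd for recovery
and effect 0 for null calibration (nested CV, 5 outer × 5 inner folds);
100+ random inputs per encoder oracle at tolerance 1e-9; and a
60-residue sequence for the full mutant-by-mutant ISM cross-check. These
sizes were chosen so each property is tested with adequate statistical
power: the label-permutation control, for instance, is evaluated on a
100-sequence held-out set because the null AUC's sampling sd at that size
(~0.06) comfortably resolves the chance band, which a 50-sequence test
set would not.

Other numerics: 0·log2(0) is treated as 0 in the entropy; BCE
probabilities are clipped at 1e-12; Glorot-uniform initialization with
forget-gate bias 1; stratified folds are dealt round-robin over
class-blocked shuffled indices so fold sizes differ by at most one
overall and per class; all library RNG use is confined to resumable,
seed-scoped streams that never disturb the caller's `.Random.seed`.

## Known limitations

- The built-in Kappa/Omega are simplified stand-ins, not CIDER.
- The network is CPU-only base R; at `n_max = 5000` and realistic sample
  sizes, training is possible but slow — the architecture is
  length-agnostic (parameter count independent of `n_max`), so models can
  be trained at one padded length and applied at another.
- Probability calibration of both classifiers on small synthetic runs is
  rough; rankings (AUC) are the reliable output at desk scale.
- PSSM parsing takes the log-odds block; if a profile source emits only
  percentage frequencies the reader will need the scaling flag.
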