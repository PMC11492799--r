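# phasekit

Two-task prediction of liquid–liquid phase separation (LLPS) proteins from
sequence, for computational biologists studying biomolecular condensates.

Proteins that drive the formation of membraneless organelles demix from the
cytoplasm by liquid–liquid phase separation. Some do so by self-assembly
(PS-Self), others only together with partner macromolecules (PS-Part).
`phasekit` implements a two-stage predictor of this behavior:

1. **Task 1 — LLPS vs non-LLPS.** A hybrid network over two inputs:
   evolutionary profiles (a PSI-BLAST PSSM and an HHsuite HMM profile,
   channel-stacked into an `N_max x 40` zero-padded tensor) are read by two
   parallel 1-D convolution branches (kernel widths 3 and 7) with
   squeeze-excitation channel attention and length-masked global pooling,
   while a 27-component multimodal vector — the amino-acid composition
   (AAC) plus seven phase-separation features (IDR fraction, longest PS
   IDR, PS potential, prion-like-domain score, granule propensity,
   hydropathy, Shannon entropy) — is read by a bidirectional LSTM. The
   branch outputs are fused by a dense sigmoid head. The five architecture
   parameters span a 3^5 = 243-point grid; the reference optimum is
   `(64, 32, 32, 32, 8)`.
2. **Task 2 — PS-Self vs PS-Part.** Gradient-boosted trees on
   physicochemical features selected in three steps from the
   AAIndex-weighted composition `F_j = Σ_i f(x_i) A_ij`: recursive feature
   elimination under extra-trees importance, a split-count importance sweep
   over nested top-k subsets (step 5), and incremental forward selection
   over the remaining sequence-property candidates.

A sequence is classified by the cascade: if `p_LLPS ≥ 0.5` the mechanism
model assigns PS-Self or PS-Part; otherwise the call is non-LLPS. Trained
models are interpreted by in-silico saturation mutagenesis (ISM): every
residue is mutated to the 19 alternatives, the probability change
`|p_ref − p_mut|` is the importance score, and per-position scores are
aggregated into 50- or 25-segment "position ratio" profiles and a
residue-by-region importance map.

Everything runs offline: the `gen_*` generators produce labeled sequence
sets with realistic class structure (phase-separating sequences average
~700 aa and are enriched in G/P and polar residues; the folded reference
class averages ~213 aa), profile files in both supported dialects, AAIndex
fixture files and external-feature tables.

Key formulas (canonical notation):

- AAC: `f(x) = N(x)/N` over the 20 residues
- AAIndex-weighted composition: `F_j = Σ_i f(x_i) · A_ij`
- Shannon entropy: `H = −Σ p_i log2 p_i` (bits)
- HMM match-state frequency: `h' = 2^(−0.001 h)` (`*` sentinel → 0)
- Metrics: Sn, Sp, Acc, MCC, Pre, F1 from the confusion counts, plus
  rank-based (Mann–Whitney) AUC

## Worked example

```r
library(phasekit)

# synthetic study set: 100 LLPS-like + 100 non-LLPS sequences with
# profiles and provider features, padded to 256 positions
ds <- gen_task1_dataset(n_per_class = 100, n_max = 256, seed = 7)

folds <- stratified_folds(ds$y, k = 2, seed = 7)
tr <- folds != 1
fit <- llps_net(ds$evo[tr], ds$mm[tr, ], ds$y[tr],
                config = task1_config(seed = 7))
fit
#> LLPS network (conv + BiLSTM fusion)
#>   architecture: CNN1=64 CNN2=32 cnn_dense=32 bilstm=32 lstm_dense=8 attention=TRUE
#>   padded length: 256; parameters: 33737; epochs trained: 10

p <- predict(fit, ds$evo[!tr], ds$mm[!tr, ])
round(metric_set(ds$y[!tr], p), 3)
#>    sn    sp   acc   mcc   pre    f1   auc
#> 1.000 0.400 0.700 0.500 0.625 0.769 0.989
```

The held-out AUC of 0.989 shows the network ranks the two classes well
after 10 epochs on 100 training sequences; the thresholded metrics (acc
0.700) are weaker because probability calibration at n = 100 is rough —
rankings, not 0.5-threshold calls, are the meaningful output at this
scale.

Feature selection with a planted signal:

```r
labels <- rep(c(1L, 0L), each = 100L)
ft <- gen_feature_table(labels, n_informative = 8, n_noise = 42,
                        effect = 1.5, seed = 7)
sel <- select_features(ft$x, ft$labels, target_dims = c(40, 25, 10),
                       step = 5, k = 5, seed = 7)
sel
#> Three-step feature selection report (k = 5 , seed = 7 )
#>   baseline          dim   50  AUC 0.983  Acc 0.935
#>   rfe               dim   10  AUC 0.990  Acc 0.955
#>   importance_sweep  dim    5  AUC 0.991  Acc 0.940
#>   ifs               dim    5  AUC 0.991  Acc 0.940
#> final features: 5
```

The pipeline compresses 50 features to 5, all of them planted signal
features, while the cross-validated AUC rises from 0.983 to 0.991.

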