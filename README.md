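# histoexpr

Predicting spot-resolved gene expression from H&E histology images.

Spatial transcriptomics (ST) assays measure gene expression at barcoded
spots on a tissue section together with a high-resolution H&E image of the
same section, but the assays are costly. `histoexpr` implements a hybrid
neural regression model that predicts the spot-by-gene expression matrix
from the image alone, for computational biologists who want a
self-contained, CPU-trainable implementation of this model family with a
verifiable mathematical core.

Per spot, a square image patch centred on the spot is encoded by an
**omni-dimensional dynamic convolution** stack — convolution with an
attention-weighted mixture of kernels,

    Y = (α_w1 ⊙ α_k1 ⊙ α_c1 ⊙ α_o1 ⊙ W_1 + … + α_wn ⊙ α_kn ⊙ α_cn ⊙ α_on ⊙ W_n) * X,

followed by a **capsule stage** (squash activation
u = (1 − e^{−‖s‖}) s/‖s‖ and self-attention routing of capsule
predictions). Patch features are fused with learned array-coordinate
position embeddings, contextualised across the whole section by a
**transformer encoder** (softmax(QKᵀ/√d_k)V per head), refined over the
**4-nearest-neighbour spot graph** by graph attention
(α_ij = softmax_{j∈Ω(v_i)} LeakyReLU(e_ij)), and projected linearly to the
gene panel. Training is mean-squared-error regression against
log-CPM-normalised expression with leave-one-out cross-validation over
sections; evaluation uses per-gene Pearson correlation (PCC) and the
adjusted Rand index (ARI) of K-means spatial-domain clustering. Because no
deep-learning framework is available for R, the package ships its own
tape-based reverse-mode autodiff core (gradient-checked against finite
differences in the test suite).

The package also provides the surrounding pipeline: readers for spot
tables, TSV/MatrixMarket count matrices and PNG/TIFF slides; patch
extraction with zero-padded borders; the standard ST filters (sections with
> 180 spots, genes expressed in ≥ 1000 spots, ln(1 + CPM×10⁶)
normalisation, top-1000 highly-variable genes, final panel = the
intersection); and a negative-binomial synthetic-section generator whose
image→expression signal path is known exactly, so the whole method is
testable offline at desk scale.

## Worked example

Generate the default synthetic study (4 sections, 8×8 spots, 20 genes,
strong image signal), train with LOOCV at the desk-scale configuration and
evaluate — a few minutes on one CPU:

```r
library(histoexpr)
res <- syntheticBenchmark(synthConfig(seed = 0), deskModelConfig(seed = 1))
res$report
```

```
EvalReport: 20 genes x 4 sections
  mean held-out PCC per section:
  sec1   sec2   sec3   sec4
0.6396 0.7008 0.8164 0.8409
  ARI per annotated section:
  sec1   sec2   sec3   sec4
0.4222 0.5555 0.7074 0.7619
```

Each column is one held-out section: the mean over the 20 genes of the
Pearson correlation between predicted and observed log-normalised
expression across its 64 spots (an oracle reading the true generator mean
tops out near 0.93 on these data), and the adjusted Rand index between
K-means (k = 2) clusters of the predicted expression and the generator's
ground-truth spatial domains. A null run with `synthConfig(beta = 0)` — the
image–expression link severed — gives mean PCC ≈ 0, confirming the signal
is read from the image rather than memorised.

Individual stages are exported and oracle-tested: `odconvForward()`,
`squash()`, `capsuleStage()`, `multiHeadAttention()`, `buildKnnGraph()`,
`pcc()`, `ari()`, …; `inst/cli/histoexpr.R` wraps simulate / preprocess /
train for shell use.

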