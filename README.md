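# qrgfusion

Hybrid quantum-classical multimodal fusion for radiogenomics: an R package
that integrates imaging-derived and genomic feature tables into a single
calibrated binary diagnostic model, with the quantum components evaluated
by exact statevector simulation.

## The problem and who this is for

Radiogenomic modelling pairs quantitative image descriptors (e.g. lesion
intensity, shape and texture from mammography) with molecular profiles
(e.g. RNA-Seq expression) for the same patients. The joint feature space
is wide relative to realistic cohort sizes, so two questions dominate:
*which few features should enter the model*, and *are the predicted
probabilities calibrated well enough to act on*. This package implements a
hybrid pipeline addressing both, aimed at methods researchers who want a
fully testable, dependency-light reference implementation:

* **Feature selection as a QUBO solved by QAOA.** Relevance
  (point-biserial correlation with the label) is rewarded, pairwise
  redundancy (absolute inter-feature correlation) is penalised with weight
  `alpha`, and a soft cardinality term `beta * (sum(z) - k)^2` pins the
  subset size:

      C(z) = -sum_i r_i z_i + alpha * sum_{i<j} rho_ij z_i z_j
             + beta * (sum_i z_i - k)^2

  The Quantum Approximate Optimization Algorithm alternates the diagonal
  cost phase `exp(-i gamma_j H_C)` with transverse-field mixers
  `RX(2 beta_j)` for `p` layers from a uniform superposition; Nelder-Mead
  tunes the angles and the subset is read from the measurement
  distribution. An exhaustive brute-force oracle verifies every instance
  with at most 20 features.

* **Quantum feature encoding.** Selected features are angle-encoded,
  `cos(x/2)|0> + sin(x/2)|1>` per qubit, passed through a depth-`L`
  variational circuit (RY/RZ rotations + CNOT ring per layer), and read
  out as per-qubit Pauli-Z expectations `z_q` in `[-1, 1]`.

* **Classical encoders and fusion.** A compact self-attention
  (transformer) encoder embeds the genomic vector, a dense (or residual
  convolutional, for raw patches) encoder embeds the imaging input, and
  the concatenation `[z_img || z_gen || z_q]` feeds a fully connected head
  with a logistic output.

* **Calibration-penalised training.** The loss is cross-entropy plus
  `lambda` times a differentiable soft-binned surrogate of the expected
  calibration error (ECE); classical gradients come from explicit reverse
  passes, circuit-angle gradients from the parameter-shift rule. Early
  stopping uses the composite validation score `AUC - w * ECE`.

* **Evaluation.** Stratified 70/15/15 patient-level splits and
  site-held-out splits; accuracy, precision, recall, F1, Mann-Whitney AUC,
  hard-binned ECE, ROC and reliability curves.

Everything runs on synthetic paired cohorts with planted ground truth
(`generateCohort()`), so the whole pipeline is testable without any
external downloads.

## Worked example

```r
library(qrgfusion)

co <- generateCohort(syntheticConfig(n_patients = 300, effect_size = 2, seed = 42))
co
#> SyntheticCohort: 300 patients, 16 imaging + 24 genomic features
#>   sites: site1, site2, site3  positives: 149
#>   planted informative: img { 2,6,13 } gen { 3,13,16 }
#>   missing genomic entries: 391

sp <- patientSplit(co, seed = 42)
arch <- fusionArch(d_in_img = ncol(imgFeatures(co)), n_gen = ncol(genFeatures(co)),
                   gen = genomicEncoderConfig(token_size = 8, d_model = 16,
                                              n_heads = 2, n_layers = 1,
                                              d_gen = 8, seed = 1),
                   vqc = vqcConfig(Q = 6, L = 2, seed = 2), seed = 3)
fit <- trainFusion(co, sp, arch = arch,
                   train = trainConfig(max_epochs = 15, patience = 6, seed = 7),
                   qaoa = qaoaConfig(p = 3, restarts = 3, seed = 8))

fit$model@fitted$selIdx          # pooled indices chosen by QAOA
#> [1]  2  6 13 16 17 32

y <- cohortLabels(co); names(y) <- patientIds(co)
p <- predictFusion(fit, co, sp$test)
computeMetrics(p, y[sp$test])
#> MetricsReport (threshold 0.5)
#>   ACC 0.9556  P 0.9545  R 0.9545  F1 0.9545  AUC 0.9842  ECE 0.0468
#>   confusion: TP=21 TN=22 FP=1 FN=1
```

The planted informative features in the pooled (imaging-then-genomic)
indexing are `{2, 6, 13, 19, 29, 32}`; of the six selected features, four
are planted signals recovered directly (2, 6, 13, 32), index 17 is the
generated redundant copy of planted feature 19, and the remaining slot
goes to the next-most-relevant column. The test-split report shows strong
discrimination (AUC 0.984) with a calibration error under 0.05 at
`lambda = 0.1`.

The full pipeline (simulate, preprocess, split, select, encode, train,
evaluate on both protocols, every artifact written to a run directory) is
one call:

```r
res <- runPipeline(defaultRunConfig(seed = 1), outdir = "run1")
```

and a thin command-line wrapper lives at
`inst/scripts/qrgfusion-cli.R` (`--config`, `--seed`, `--outdir`,
`--stage run-all|ablate`, repeatable `--set key=value` overrides).

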