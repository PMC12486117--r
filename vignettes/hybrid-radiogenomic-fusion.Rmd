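---
title: "Hybrid quantum-classical fusion of imaging and genomic features: methods"
author: "qrgfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid quantum-classical fusion of imaging and genomic features: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qrgfusion)
```

# The model

`qrgfusion` implements a hybrid quantum-classical pipeline for binary
diagnosis from paired imaging-derived and genomic feature tables. Four
components are chained:

1. **QAOA feature selection.** Candidate features are scored by relevance
   $r_i = |\mathrm{corr}(X_i, y)|$ (point-biserial) and pairwise redundancy
   $\rho_{ij} = |\mathrm{corr}(X_i, X_j)|$, and a selection cost over binary
   indicator vectors $z$ is assembled as
   $$C(z) = -\sum_i r_i z_i
          + \alpha \sum_{i<j} \rho_{ij} z_i z_j
          + \beta \Big(\sum_i z_i - k\Big)^2 .$$
   This quadratic unconstrained binary optimisation (QUBO) is the diagonal
   cost Hamiltonian $H_C$ of a Quantum Approximate Optimization Algorithm:
   starting from the uniform superposition $|+\rangle^{\otimes n}$, $p$
   layers of $e^{-i\gamma_j H_C}$ and the transverse-field mixer
   $e^{-i\beta_j X}$ (an $RX(2\beta_j)$ rotation on every qubit) are applied;
   the $2p$ angles are tuned by seeded Nelder-Mead restarts to minimise
   $\langle H_C \rangle$, and the feature subset is read off the final
   measurement distribution. Because $H_C$ is diagonal, the phase step is
   applied exactly per basis state; no gate decomposition is involved. An
   exhaustive enumeration oracle (`bruteForceSelect()`) provides the ground
   truth for every instance with $n \le 20$.

2. **Angle encoding and the variational circuit.** The $k = Q$ selected
   features are min-max scaled (training split only) to angles in $[0,\pi]$
   and encoded as the product state
   $\bigotimes_i \big(\cos(x_i/2)|0\rangle + \sin(x_i/2)|1\rangle\big)$.
   A depth-$L$ hardware-efficient ansatz — per layer an $RY$ and an $RZ$
   rotation on each qubit followed by a CNOT ring — is applied, and the
   per-qubit Pauli-Z expectations $z_q \in [-1, 1]^Q$ are the quantum
   features. At $L = 0$ this collapses to $z_q = \cos(x)$ elementwise, a
   closed form used as a test oracle.

3. **Classical encoders.** The genomic vector is chunked into tokens,
   linearly projected, given sinusoidal positional encodings, and passed
   through multi-head self-attention
   $\mathrm{softmax}(QK^\top/\sqrt{d_k})V$ with feed-forward blocks,
   residual connections and layer normalisation; token-mean pooling and a
   linear map give $z_{gen}$. The image branch is a dense encoder over the
   imaging feature table; a residual convolutional patch encoder
   (`encodeImage()`: conv stem, two-conv identity-skip blocks, stride-2
   average pooling, global average pooling) is provided for raw lesion
   patches, and either its embeddings or radiomic descriptors can serve as
   the image table.

4. **Fusion and calibrated training.** The joint embedding
   $z_{fusion} = [z_{img} \,\|\, z_{gen} \,\|\, z_q]$ feeds one ReLU hidden
   layer and a logistic output. Training minimises the hybrid loss
   $$\mathcal{L} = -\tfrac1N \sum_i \big[y_i \log \hat y_i +
     (1-y_i)\log(1-\hat y_i)\big] + \lambda \cdot \mathrm{ECE}_{soft},$$
   cross-entropy in nats plus a calibration penalty. Classical parameters
   are updated by explicitly written reverse passes (there is no autodiff
   framework underneath); the circuit angles follow the parameter-shift rule
   $\partial z_q / \partial\theta = \tfrac12\big(z_q(\theta + \pi/2) -
   z_q(\theta - \pi/2)\big)$, evaluated in training through an adjoint
   reverse sweep that is algebraically identical (a tested invariant at
   $10^{-10}$) but costs two gate applications per gate rather than two
   circuit evaluations per parameter.

## The differentiable calibration penalty

The reported expected calibration error bins the confidence
$c_i = \max(\hat y_i, 1 - \hat y_i)$ into $M$ equal-width bins on
$[0.5, 1]$ and sums $\tfrac{|B_m|}{n}\,|\mathrm{acc}(B_m) -
\mathrm{conf}(B_m)|$. That quantity is piecewise constant in $\hat y$, so
the training loss uses a soft-binned surrogate: triangular (hat-function)
memberships centred on the bin centres replace the hard assignment, giving
soft per-bin accuracy and confidence whose weighted absolute gap is
differentiable almost everywhere. The surrogate exists only to carry
gradients — every reported ECE in the package is the hard-binned
definition — and the two agree within 0.02 on 1000-sample prediction sets
(a tested invariant).

# Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| $k = Q$ | 10 qubits | subset size = encoder width, so the selected subset fills the register; 10 is the configured optimum, tests run 3–6 for speed |
| $L$ | 6 | circuit depth; $L=0$ is the cosine baseline |
| $p$ | 3 | QAOA layers |
| $\alpha$ | 0.25 | redundancy penalty; see below |
| $\beta$ | $2\max_i r_i$ | cardinality penalty, scaled to dominate any single relevance gain so $|S| = k$ is respected |
| $\lambda$ | 0.1 | calibration penalty weight; $\lambda = 0$ recovers plain cross-entropy |
| $M$ | 10 | calibration bins (both the surrogate and the reported ECE) |
| learning rate | 0.01 | Adam on all classical parameters and $\theta$ |
| early stop | AUC $- w\cdot$ECE, $w=1$, patience 10 | composite validation score; best checkpoint kept |

**Why $\alpha = 0.25$.** Under an additive mean-shift class model, any two
informative features are correlated *through the label*: for a standardized
shift $e$ and balanced classes their correlation is approximately
$\tfrac{e^2/4}{1 + e^2/4}$ — about $0.5$ at $e = 2$. A redundancy weight
near 1 therefore makes the QUBO optimum actively avoid selecting several
truly informative features at once, which defeats the purpose of the
selection stage. Requiring that swapping an informative feature for a noise
feature never pays demands roughly
$\alpha < \bar r / \big((k-1)\,\rho_{label}\big) \approx 0.47$ at the
default conditions; $\alpha = 0.25$ sits safely below that bound while still
separating genuine duplicates ($\rho \approx 0.97$), for which the penalty
difference ($\alpha(0.97 - 0.5)$) exceeds the relevance difference. The
package's selection tests confirm both properties: the planted set is the
enumerated optimum, and a parent and its noisy copy are never co-selected.

**Candidate pre-screening.** Exact statevector simulation caps the QUBO at
20 variables, so `trainFusion()` first screens the pooled feature table to
the `n_candidates = 12` most label-correlated features (training split
only) and runs QAOA on that pool. On real cohorts with thousands of
features this screen would be the standard univariate filter that precedes
any wrapper method.

# The synthetic cohort generator

`generateCohort()` emulates a paired radiogenomic cohort with known ground
truth: Bernoulli labels at the configured prevalence; informative features
drawn $N(0,1)$ in class 0 and $N(e, 1)$ in class 1; redundant features as a
parent plus $N(0, 0.25^2)$ noise; everything else pure noise; one additive
per-site offset $N(0, \sigma_{site}^2)$ shared by all features of a site's
patients; genomic entries masked missing completely at random. Image
fixtures are elliptical blobs (label-dependent radius and intensity) on
Gaussian background with an optional planted multiplicative quadratic bias
field rescaled to $[0.7, 1.3]$; count fixtures are negative-binomial with a
$\ge 4\times$ library-size span and gene lengths on $[0.2, 20]$ kb.

Default study conditions: 400 patients, 16 imaging + 24 genomic features,
3 + 3 informative, 4 redundant copies, effect size 1.0–2.0 depending on the
experiment, 3 sites with offset scale 0.3, 5% genomic missingness, balanced
classes. Site effects are additive and modality-wide, which is the minimal
mechanism that makes site-held-out evaluation strictly harder than a
patient-level split; missingness is unconditional (MCAR), matching the
unconditional k-nearest-neighbour imputation used downstream.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: realistic mammographic texture, nonlinear or
interaction effects, covariance (rather than mean) class differences,
informative missingness, label noise, site-by-feature interactions, and
batch effects in the genomic covariance structure. Results on this
generator validate the machinery, not clinical performance.

# Numerical choices

* **Statevector convention.** Qubit 0 is the least-significant bit of the
  basis index; feature $i$ maps to qubit $i-1$. Norms are preserved to
  $10^{-9}$ and `measureExpectations()` refuses states off the unit sphere
  by more than $10^{-6}$.
* **Tie-breaks.** All subset ties (QAOA sampling and brute force) resolve
  to the lexicographically smallest bitstring, feature 1 first; kNN
  distance ties resolve by sample order; split-size rounding uses
  largest-remainder apportionment, reconciled so the global 70/15/15 sizes
  are exact under stratification.
* **Degenerate cases.** Constant features score 0 relevance/redundancy by
  convention; a constant feature maps to the angle $\pi/2$; zero-variance
  patches z-score to all zeros; zero-denominator precision/recall are 0
  with a flag; probabilities are clamped to $[10^{-7}, 1-10^{-7}]$ with a
  warning before the loss.
* **Bias-field correction** fits a log-domain polynomial (order 2 default)
  and removes it; the log-domain re-centering preserves the mean only to
  first order, so the output is rescaled to preserve mean brightness
  exactly. The perimeter in the radiomic descriptors multiplies the
  boundary-edge count by the Cauchy-Crofton factor $\pi/4$; the raw edge
  count overestimates diagonal boundaries and would score a rasterized disc
  at circularity $\approx 0.62$ rather than $\approx 1$.
* **ECE binning.** Confidence exactly 0.5 falls into the first bin; bins
  are half-open $(\ell, u]$ above the first.

# Problem sizes in the test suite

The tests exercise the full architecture at reduced width so the suite
stays interactive: selection oracles at $n = 8$–12 qubits, circuits at
$Q \le 6$, $L \le 3$, training runs on 60–400 patients with 1-layer
transformers, and the reproducibility checks on 60-patient cohorts with
$Q = 3$. Depth/width defaults ($Q = 10$, $L = 6$) are exercised by the
forward-path timing test and available to `runPipeline()`; the pipeline's
default epoch budget (8) reflects that a strongly signalled cohort
converges within a handful of epochs.

# Known limitations

* Exact simulation limits selection to 20 candidate features per QUBO and
  encoding to 14 qubits; there is no shot-noise or hardware-noise model.
* The image branch trains on feature tables; the convolutional patch
  encoder runs forward with seeded filters, so end-to-end gradient training
  of raw pixels is out of scope at this scale.
* The transformer, conv encoder and optimiser are compact, desk-scale
  re-implementations; they are deliberately small, not performant
  replacements for a deep-learning framework.
* Site effects in the generator are additive scalars, the easiest case for
  z-scoring; cross-site generalisation on real multi-centre data is a much
  harder problem than the synthetic one solved here.
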