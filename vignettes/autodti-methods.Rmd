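---
title: "Densified denoising-autoencoder prediction of drug-target interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Densified denoising-autoencoder prediction of drug-target interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autodti)
```

## The problem

Chemogenomic screens give a binary interaction matrix $Y \in \{0,1\}^{n
\times m}$ between $n$ small-molecule drugs and $m$ protein targets;
$Y_{dt} = 1$ records a known interaction. On the classic gold-standard
benchmarks (nuclear receptors, GPCRs, ion channels, enzymes) only 1-6% of
pairs are known, and the zeros are unlabeled, not confirmed negatives. The
goal is to rank the unknown pairs so that true but unrecorded interactions
surface at the top, including for *cold-start* drugs or targets with no
training interactions at all.

## The model

The method is a three-stage pipeline.

**1. Densification.** Each drug carries a binary substructure fingerprint;
stacking them gives $Z \in \{0,1\}^{f \times n}$ (bits $\times$ drugs, $f =
800$ for the PaDEL fingerprints used on the public benchmarks). The product

$$W = Z\,Y,\qquad W_{kt} = \#\{d : Z_{kd} = 1 \wedge Y_{dt} = 1\}$$

links substructures to targets through the drugs that contain them. $W$ is
min-max normalized and binarized (any positive count becomes 1), giving a
matrix roughly an order of magnitude denser than $Y$ — the premise being
that if a drug hits a target, the target plausibly interacts with the
drug's substructures, not just with that one molecule.

**2. Masked denoising autoencoder.** Each target's fingerprint profile (a
column of $W$, length $f$) is one training sample. The network is a mirrored
sigmoid autoencoder $f \to 15 \to 5 \to 15 \to f$. Observed positions (the
ones of the binary $W$) are corrupted by masking a random fraction to zero;
the loss re-weights prediction against reconstruction:

$$L_{\alpha,\beta}(x,\tilde{x}) = \alpha \sum_{j \in C(\tilde{x})}
\left(x_j - nn(\tilde{x})_j\right)^2 + \beta \sum_{j \notin C(\tilde{x})}
\left(x_j - nn(\tilde{x})_j\right)^2 + \frac{\lambda}{2}
\left(\lVert V \rVert_F^2 + \lVert W_{dec} \rVert_F^2\right),$$

where both sums run over *observed* positions only: missing entries are
zeroed on the input edges and their back-propagated error is zeroed, so
they contribute nothing to the gradient. $\alpha$ weights the corrupted
(prediction) term, $\beta$ the uncorrupted (reconstruction) term.

**3. Projection.** With the trained network, $\hat{W} = nn(W)$ and the
drug-target scores are $\hat{Y} = Z^{\mathsf T} \hat{W}$: the score of pair
$(d,t)$ is the dot product of drug $d$'s bits with target $t$'s
reconstructed substructure profile. Scores are unnormalized dot products,
deliberately not probabilities; AUC and AUPR are rank-based so any strictly
monotone rescaling is irrelevant (a per-drug bit-count normalization is
available but off by default).

## Parameters and defaults

| parameter | default | status |
|---|---|---|
| hidden sizes | (15, 5) | published setting |
| activation | sigmoid, every layer | published setting |
| $\alpha$, $\beta$ | 0.4, 0.6 (each constrained to (0,1)) | published setting |
| $\lambda$ (L2) | 10; use 1 for the small NR-scale data | published setting |
| minibatch | 100 | published setting |
| corruption rate | 0.2 | not published; package default, flagged |
| learning rate | 0.1 (plain gradient descent) | not published; package default |
| epochs | 200, no early stopping | not published; package default |
| initialization | uniform $\pm 1/\sqrt{\text{fan-in}}$, seeded | package choice, scale-stable for sigmoid |

The optimizer is plain minibatch gradient descent because the source method
names only gradient-based back-propagation; momentum methods are a
pluggable extension, not a default. Weight matrices are regularized; biases
are not (conventional; `regularize_biases` flips this). The regularizer is
the squared Frobenius norm of all weight matrices — the source's notation
for it is internally inconsistent and this is the reading its own objective
function supports.

## Design choices where the design was open

**Sample orientation.** Columns of $W$ (targets, as length-$f$ profiles)
are the training samples. The input dimension must be $f$ for hidden sizes
(15, 5) to make sense at $f = 800$, the projection step indexes $\hat{W}$
by target columns, and the model embeds targets into the latent space. The
row-wise variant on $Y$ (drug profiles as samples, the no-densification
ablation) is exposed as `train_drug_autoencoder()`.

**What counts as observed.** On the binary $W$, ones are treated as known
and zeros as missing (zeroed inputs, zeroed errors). This matches counting
"known" fingerprint-target interactions as the ones. Because the reading is
ambiguous, `zeros_are_observed = TRUE` treats every position as known.

**Min-max scope.** One global min/max over the whole matrix, not
per-column: the subsequent binarization maps any positive raw count to 1
under either scope, so the choice only affects the normalized intermediate,
and global is the simplest to reproduce. A constant matrix normalizes to
zeros rather than dividing 0/0. One degenerate case matters: if the raw
minimum itself is positive (every bit-target cell linked), min-max sends
those minimum cells to 0 although their raw count was positive; the
normalized stage therefore records the raw minimum and binarization
promotes everything to 1 in that case, keeping the "raw count > 0" rule
exact. This cannot occur on sparse real data.

**Pairwise CV universe.** Ten-fold pairwise CV partitions all $n \times m$
pairs, so each test fold carries its own negatives; `positives_only = TRUE`
folds only the known interactions and uses every zero pair as a test
negative (the source is ambiguous; both are provided). Cold-start folds
mask entire drug rows (or target columns) to zero — including in the
densification product, which is recomputed from the masked matrix each
fold, so no held-out interaction can leak through $Z\,Y$.

**AUPR convention.** Non-interpolated step summation $\sum_i (R_i -
R_{i-1}) P_i$ with tied scores grouped at one threshold; interpolated
average precision inflates scores on data this small. A constant predictor
then scores exactly the positive prevalence, which is the null baseline the
tests use. AUC is the Mann-Whitney statistic with ties counting one half.

**Corruption.** Each observed position is masked independently with
probability equal to the corruption rate, so the corrupted set is a
uniformly random subset with binomial size. Positions that are missing are
never corrupted — they are already zero.

**Seeds.** One master seed governs everything; stage and per-fold seeds
derive from it by a documented base-31 string hash (`derive_seed`), kept
below $2^{31}$. Identical seed, identical results, bit for bit — the run
manifests the CLI writes are sufficient to re-execute any run.

## The synthetic generator

Real benchmark data cannot be redistributed here, so tests run on a
generator that plants the structure the method assumes. Latent drug factors
$u_d$ and target factors $v_t$ (standard normal, rank 3 by default) give a
true affinity $u v^{\mathsf T}$; the top `interaction_density` fraction of
affinities become the ones of $Y$ (0.064 by default, the sparsity of the
smallest public benchmark at its published 54 x 26 shape). Each fingerprint
bit has a heterogeneous baseline prevalence (Beta(2, 8), mean 0.2, like
real substructure fingerprints) modulated on the logit scale along a random
unit latent direction with strength `coupling` (default 2), so fingerprints
carry signal about interactions — without that coupling the projection
$Z^{\mathsf T}\hat{W}$ could not work even in principle, and a
coupling-zero dataset is the package's own negative control. Label noise
relocates a fraction of the ones to random zero cells rather than flipping
entries independently, so the interaction count — and hence the sparsity
the fixture asserts — is preserved exactly.

What the generator does *not* emulate: real substructure co-occurrence
(bits here are conditionally independent given the latent factors), SMILES
chemistry, target sequence similarity, and the biased, literature-driven
missingness of real interaction data. A green recovery test therefore
establishes that the pipeline recovers planted low-rank structure through
the fingerprint channel at realistic sparsity — not that it reproduces the
published benchmark figures, which require the original downloads
(`autodti evaluate` on those files is the documented, non-CI experiment).

## Numerical notes and limitations

- Gradients are exact backpropagation, verified against central finite
  differences to relative error $10^{-5}$ in the tests; the loss is checked
  against a per-position loop oracle at $10^{-12}$.
- Training aborts with a diagnostic on a non-finite epoch loss rather than
  returning garbage.
- Novel-pair ranking breaks score ties lexicographically by (drug, target)
  identifier, so reports are stable across runs.
- Single-class CV test folds (possible at extreme sparsity) are recorded as
  `NA`, excluded from means, and warned about — not silently dropped.
- Everything is dense in memory: at benchmark scale (max 445 x 664, f =
  800) this is a few megabytes; the package is not intended for
  proteome-scale matrices.
- With only-positive observations the decoder sees no explicit negatives;
  ranking quality comes from the bottleneck and corruption, which is the
  method's design and also its main limitation on very sparse targets.
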