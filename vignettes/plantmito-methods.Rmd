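---
title: "Predicting plant mitochondrial proteins: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting plant mitochondrial proteins: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Most tools that predict mitochondrial targeting look for a cleavable
N-terminal pre-sequence (transit peptide): a 5–50 residue stretch
enriched in positively charged (Arg, Lys, His) and hydrophobic (Leu,
Ala, Ile, Trp, Tyr) residues and depleted in acidic ones (Asp, Glu).
A substantial fraction of plant mitochondrial proteins, however,
carries no recognisable N-terminal signal and is imported through
internal signals. `plantmito` therefore combines N-terminal sequence
information with two *global* information sources — whole-sequence
evolutionary profiles and gene co-expression — so that both classes of
mitochondrial protein are recoverable.

## Feature blocks

Each protein is encoded as the concatenation of four blocks, always in
this order:

1. **AAFreq.NT** (length 20): frequencies of the 20 standard residues
   in the first `L` residues (default `L = 22`). Ambiguity codes
   (X, B, Z, U, O) are excluded from the denominator, so the entries
   sum to one. If the sequence is shorter than `L`, the whole sequence
   is used.
2. **PSSM.NT** (length 20·L = 440): the first `L` rows of the scaled
   position-specific scoring matrix, flattened position-major;
   sequences shorter than `L` are zero-padded.
3. **PSSM** (length 400): for each residue type, the mean of the
   scaled profile rows at positions carrying that residue — an
   average-pooled, length-invariant "generalised amino-acid
   frequency"; types absent from the sequence contribute a zero row.
4. **Coexpr** (length 5): k-nearest-neighbour co-expression scores at
   five neighbourhood sizes (see below); proteins without a reference
   gene mapping get five zeros.

The full default vector has length 20 + 440 + 400 + 5 = 865. The block
layout travels with every feature matrix and is fingerprinted into
trained models; prediction refuses matrices built under a different
layout.

### Profile scaling

Profiles are parsed from PSI-BLAST ASCII PSSM files (columns remapped
onto the fixed alphabet ACDEFGHIKLMNPQRSTVWY, residue column
cross-checked against the sequence) and scaled linearly to \[-1, 1\]
with the per-protein affine map `x -> 2(x - min)/(max - min) - 1`; a
constant matrix maps to zeros. Per-protein min–max was chosen over a
database-global affine because it is the simplest reading of "scaled
linearly" and makes each protein self-contained; both conventions
order entries identically within a protein, which is what the RBF
kernel sees. When no profile is available, a fallback built from
BLOSUM62 rows (ambiguity codes giving zero rows) keeps the tool
runnable without any database search; predictions made this way are
flagged `substitution_fallback` in all outputs, because a substitution
matrix carries no family-specific information.

### Co-expression scores

Expression matrices (genes × samples, log2 scale; unlogged inputs are
transformed as `log2(x + 1)`) yield one Pearson correlation matrix
per dataset. Datasets are combined meta-analytically: each correlation
is clamped to |r| ≤ 1 − 1e−6, Fisher z-transformed, averaged with
inverse-variance weights (n − 3), and back-transformed with `tanh`.
Pairs covered by no dataset stay missing and rank below all covered
pairs — they are deliberately not imputed as zero correlation, because
"never measured together" is weaker evidence than "measured and
uncorrelated".

For a query gene, training genes are ranked by meta-correlation
(descending, ties broken by gene id so runs are reproducible; the
query never counts itself), and the fraction of positives among the
top `k = max(1, round(K/100 · N_train))` is recorded for
K ∈ {0.25, 0.5, 1, 2, 4}% — five scores in \[0, 1\]. Proteins are
attached to reference genes through an externally produced best-hit
table; the package never performs the homology search itself, which
keeps it fully offline.

## Classifiers

**RBF-SVM.** A radial-basis support vector machine (libsvm via e1071)
with defaults `cost = 10`, `gamma = 0.1`. `grid_search_svm()` tunes
both over the decade grids 1e−3..1e3 (cost) and 1e−5..1e5 (gamma) by
mean stratified 10-fold cross-validated AUC, breaking ties toward the
smaller cost and then the smaller gamma (prefer the less complex
model). Raw decision values are used for ranking and calibration; no
probability transform is applied.

**Maxout/dropout network.** A feed-forward network with maxout hidden
units (max over 5 linear pieces per unit), dropout 0.5 on every hidden
layer, and a 2-way softmax output, trained by minibatch SGD
(learning rate 0.01, momentum rising linearly from 0.5 to 0.7 over the
epochs, cap 250 epochs). The default architecture is 500–500–300
hidden units; hidden sizes, batch size and the epoch cap are
configurable so the model also runs at desk scale. After each epoch
the validation AUC is measured and the best snapshot is kept
(validation AUC is the selection criterion; the minibatch size default
of 100 is a package choice). Dropout is implemented in the inverted
convention so prediction needs no rescaling; the backward pass routes
gradients through the argmax piece of each maxout unit. Training is
bit-deterministic for a fixed seed. The deployed model is an ensemble:
the training set is split into 10 stratified folds and each rotation
reserves one fold for validation while the other nine train a member;
the prediction is the mean of the 10 members' positive-class
probabilities.

**Cross-validation protocols.** The SVM protocol trains on 9 folds
and tests on 1 per rotation. The network protocol holds out one fold
for testing and the next (cyclically) for validation, training on the
remaining eight, so each fold serves as validation or test exactly
once.

## Specificity calibration

Raw scores are converted to decisions through the empirical score
distribution of a held-out negative reference set. For a requested
specificity `s`, the threshold is the smallest value `t` such that at
most `floor((1 − s)·n)` negatives score ≥ `t`; ties among negative
scores are counted conservatively (all tied values as above), and if
no value qualifies the threshold is placed strictly above the maximum
negative score. This guarantees empirical specificity ≥ `s` on the
calibration set for every level, and makes thresholds and positive
calls monotone in the level. Raw quantiles are stored rather than a
parametric fit — the guarantee is exact by construction and needs no
distributional assumption; the cost is step-function granularity of
about 1/n between achievable levels. The boundary convention is
`score ≥ threshold ⇒ positive`.

## Evaluation toolkit

Confusion metrics (sensitivity, specificity, accuracy, precision, F1,
MCC) follow the standard definitions; zero-denominator metrics are
reported as `NA` and flagged, with MCC falling back to 0.
`counts_from_rates()` reconstructs integer confusion counts from
published rounded rates under round-half-up — this rule reproduces all
reconstructed table cells exactly, which round-half-even does not.
ROC and precision–recall curves enumerate one point per distinct
threshold with ties grouped; AUC is the trapezoidal integral, which on
tie-free scores equals the Mann–Whitney concordance probability (an
identity the test suite checks against a brute-force pair count). The
bootstrap AUC comparison resamples example indices with replacement
within each class (paired, stratified — the default behaviour of the
usual ROC tools), and reports the fraction of replicates where the
first AUC does not exceed the second, counting exact ties with weight
1/2 so that comparing a score vector against itself gives 0.5.

`window_sweep()` re-evaluates the N-terminal blocks at each window
length under one shared fold assignment, so between-window differences
are paired. The sweep is run at the package's default SVM operating
point (`cost = 10`, `gamma = 0.1`) rather than with a per-window
`1/d` gamma: under an adaptive gamma the added dimensions beyond the
signal are absorbed into the kernel width and the AUC curve plateaus,
whereas under the fixed operating point windows that drag in
uninformative positions pay a distance penalty and the curve peaks at
the true signal length.

## The synthetic generator

`generator_config()` defines the study conditions under which the
package tests itself:

* 400 positives / 400 negatives by default;
* 70% of positives carry an N-terminal signal: their first 22 residues
  are drawn from the background composition reweighted ×2 for
  R, W, H, L, K, A, Y, I and ×0.5 for D, E, V, N, G, P, M — the
  enrichment/depletion directions of real transit peptides; the
  magnitudes are free parameters of the generator;
* the background composition is uniform over the 20 residues
  (simplicity; any named 20-vector can be supplied);
* 3 expression datasets of 20 samples; in each, positive genes load
  with strength 1 on a shared latent factor plus unit noise (giving
  within-positive correlations around 0.5), negatives are pure noise;
* 10% of proteins are withheld from the gene mapping to exercise the
  five-zero co-expression fallback;
* profiles are the BLOSUM62 fallback plus integer-rounded Gaussian
  noise (sd 1), written and re-read as ASCII PSSM files so the real
  parse path is exercised;
* sequence lengths are uniform on 80–300 residues (all ≥ 50, the
  package's length filter).

What the generator does *not* emulate: realistic amino-acid
background composition, microarray noise structure and
probe-collapsing artefacts, homology between related proteins
(redundancy), and evolutionary signal in profiles (the fallback is
composition-driven). Passing the recovery suite therefore shows the
pipeline is wired correctly and can extract exactly the signal types
it models — it does not certify performance on real proteomes.

## Problem sizes and numerical choices

The package's own test battery runs the full pipeline at
400/400 with the reduced network (32, 32, 16 hidden units, batch 50,
epoch cap 60 — enough SGD updates to converge at that sample size),
the signal-free null at 200/200, the window sweep over windows
{5, 10, ..., 50} (at 400/400 in the reproduction script, where the
peak location stabilises; smaller cohorts leave the 10-vs-20
comparison inside sampling noise because the marginal information of
residues 11–20 is small relative to feature-estimation error), and
calibration properties over 100 random score sets. Correlations are clamped at |r| = 1 − 1e−6 before the
Fisher transform; neighbour counts round half-up with a floor of one;
redundancy reduction uses greedy longest-first clustering on a k-mer
containment identity estimate (k = 5) and is documented as an
approximation to external clustering tools, with a cluster-table
import path for exact fidelity.

## Known limitations

* The redundancy estimate is k-mer based, not alignment based; at the
  40% identity threshold it is conservative for highly diverged
  homologues.
* The substitution-fallback profile carries no evolutionary
  information; predictions based on it are flagged and should be
  treated as composition-only.
* The meta-analysis assumes correlations are estimated from
  independent samples within each dataset; dependent samples (time
  courses) inflate the effective n.
* Specificity calibration guarantees hold on the calibration set;
  transfer to a new negative population is only as good as that
  population's resemblance to the reference negatives.
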