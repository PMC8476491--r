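---
title: "Variant effect prediction with a born-again autoregressive sequence model"
author: "banvep authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant effect prediction with a born-again autoregressive sequence model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Whether a single amino-acid substitution damages a protein can often be
read off the protein's evolutionary record: across a family of related
sequences, positions and residues that matter are conserved, and
substitutions rarely seen in the family tend to be deleterious in
humans. `banvep` implements a fully unsupervised predictor built on this
idea. It trains a deep autoregressive generative model on the multiple
sequence alignment (MSA) of one protein family and scores variants by how
much less probable the mutant sequence is than the wild type. Because no
labelled variants enter training, the predictor cannot suffer from the
train/test circularity that inflates the reported performance of many
supervised tools.

## The model

An aligned sequence $x = (x_1, \dots, x_L)$ over the 21-symbol alphabet
(20 amino acids + gap) is modelled autoregressively:

$$p(x \mid \theta) = \prod_{i=1}^{L} p(x_i \mid x_{<i}, \theta).$$

The conditional at each position is produced by a temporal convolutional
network: the input is shifted right by one position (a begin-of-sequence
token conditions position 1), embedded, passed through a stack of dilated
causal convolution blocks with residual connections, then through a
causally masked self-attention layer, and finally through a position-wise
linear layer whose softmax gives the 21-way conditional distribution.
Causality is structural: the output at position $i$ depends only on
symbols at positions $< i$, so the factorisation above is exact and the
model's likelihoods sum to one over sequence space (asserted exhaustively
on small alphabets in the tests).

Two architecture notes:

* **Positional embedding.** A learned per-position vector is added to the
  token embedding. Without it the network must infer column identity
  from the content of the preceding context, which is unreliable at
  weakly conserved columns; with it, site-specific conditional
  distributions are directly representable. The positional index is
  known a priori, so this does not affect causality.
* **Attention and receptive field.** The convolutional receptive field is
  $1 + (k-1)\sum_d d$ preceding positions (kernel $k$, dilations $d$).
  With the attention layer enabled (the default) the model conditions on
  the entire preceding context regardless of the dilation schedule;
  setting `attentionHeads = 0` gives the pure convolutional model, which
  is what the receptive-field probes in the test-suite exercise.

Non-canonical residue letters (B, J, O, U, Z, X) fold into a single
input-only "unknown" code: the model can condition on them, but they are
never a prediction target and never receive probability mass.

## Alignment preparation

* **Column filtering.** Columns with *more than* 30% gaps are dropped; a
  column with exactly 30% gaps is kept. Variants falling in dropped
  columns (or at positions where the focus sequence itself is gapped)
  are excluded from prediction and reported with their reason rather
  than silently ignored.
* **Sequence reweighting.** Each sequence is weighted by
  $w_i = 1/|\{j : \mathrm{id}(i,j) \ge 0.8\}|$, the reciprocal of its
  80%-identity neighbourhood size (itself included); identity is the
  fraction of identical symbols over retained columns, gaps counting as
  symbols. Mini-batches are sampled with probability proportional to
  $w$, so a heavily resampled sub-family contributes one effective
  sequence. The sum $n_\mathrm{eff} = \sum_i w_i$ is the effective
  family size. The threshold is configurable; 0.8 is the convention of
  the alignment-reweighting literature this family of models inherits.

## Born-again training

Training happens twice with identical capacity:

1. **Teacher.** Minimise the *label loss* — the mean over positions of
   the negative conditional log-probability of the input sequence (the
   per-position negative log-likelihood) — over weighted mini-batches.
2. **Student.** Re-initialise the same architecture from a fresh seed
   and minimise the unweighted sum of the label loss and the *teacher
   loss*: the cross-entropy between the student's output distribution
   and the teacher's temperature-softened distribution
   $p_i \propto \exp(z_i/T)$ with $T = 4$. The teacher is frozen
   (hash-verified). Softening exposes the relative probabilities the
   teacher assigns to symbols it does not predict — the "dark
   knowledge" whose transfer lets an equal-capacity student outperform
   its teacher.

By default the student's own distribution is softened at the same
temperature inside the teacher loss, the standard distillation
formulation; `distillStudentTemperature = FALSE` gives the literal
one-sided reading in which only the teacher output is softened. No
$T^2$ gradient rescaling is applied and the two loss terms are summed
without a mixing coefficient. Optimisation uses Adam with the two-rate
schedule: learning rate 0.001 while the iteration index is below 3000
and 0.0001 from iteration 3000 onwards (the boundary iteration uses the
lower rate). The published setting trains each network for 500,000
iterations with batch size 128 (200,000 in the server setting); those
remain the `trainingConfig()` defaults, while tests and the bundled
analyses use desk-scale runs (described below).

## From likelihoods to predictions

For a variant mapped to retained column $c$:

* **Log-probability score**
  $\log p(x^\mathrm{mut}\mid\theta) - \log p(x^\mathrm{wt}\mid\theta)$,
  where $x^\mathrm{mut}$ is the focus sequence with the single
  substitution applied. Lower is more deleterious.
* **z-score**: the score standardised against the mean and population
  standard deviation of the scores of *all* $19 \times L'$ possible
  single substitutions of the focus sequence, removing
  protein-to-protein scale differences.
* **Probability of deleteriousness**: the z-score range of a labelled
  calibration set is divided into equal-width bins (default 20,
  configurable); the fraction of deleterious variants in the bin
  containing a variant's z-score is its calibrated probability.
  Out-of-range z-scores clamp to the end bins; empty bins inherit the
  nearest non-empty bin's proportion, the lower-z side winning ties.
  Monotone (isotonic) calibration is deliberately not imposed — the
  reported probability is the raw empirical proportion.
* **Label**: deleterious exactly when the z-score is strictly below the
  cutoff; the cutoff is the calibration bin edge that maximises
  classification accuracy on the labelled set, the smallest edge
  winning ties.

## Evaluation metrics

`metricsReport()` computes ROC-AUC, PR-AUC, accuracy, MCC, precision,
specificity, sensitivity, F-score and NPV. ROC-AUC is the rank
(Mann–Whitney U) statistic with ties counting one half; PR-AUC is
step-wise average precision (no linear interpolation in PR space).
Ranking metrics use $-z$ as the deleteriousness score. Degenerate
denominators fall back to 0 so reports are always total. In the tests,
`pROC` serves as an independent cross-check of the ROC-AUC
implementation, and small confusion matrices are verified against
brute-force recomputation from expanded label vectors.

`reconstructConfusion()` inverts a printed metrics row: it searches all
integer confusion matrices with the stated class sizes whose
sensitivity, specificity, precision and NPV round (half-up, 3 decimals)
to the printed values and demands a unique solution, from which the
remaining point metrics must follow. This is how the package checks a
published benchmark row for internal consistency.

## The synthetic family generator

Real protein families have unknown ground truth, so the test harness
generates families whose truth is known exactly. Column profiles
$\pi_\ell$ are drawn from a symmetric Dirichlet($\alpha$) over the 20
amino acids ($\alpha = 0.1$ gives strongly conserved columns, the
regime of a well-aligned domain); sequences are sampled independently
per column; the consensus (profile argmax) is the designated focus
sequence; gaps can be injected at a configurable per-cell rate, and a
redundancy block (founders duplicated with a per-site mutation rate)
emulates the sampling bias that sequence reweighting corrects. Because
columns are independent, the true effect of a substitution has the
closed form $\log \pi_\ell(\mathrm{mut}) - \log \pi_\ell(\mathrm{wt})$
— exactly the quantity the model's log-probability score estimates, in
nats. Labelled variant sets are drawn uniformly over substitutions and
labelled by thresholding the true effect (default: its median),
balanced by rejection.

What the generator does *not* emulate: pairwise couplings between
columns (epistasis), phylogenetic correlation between sequences,
realistic indel processes, and substitution-matrix-structured mutation.
Passing the recovery tests therefore shows that the implementation
learns site-specific constraints from a reweighted alignment, not that
it captures covariation in real families.

## Desk-scale study conditions

The bundled end-to-end analyses (tests and `scripts/acceptance.R`) use
a family of $N = 2000$ sequences of length $L = 40$ at $\alpha = 0.1$,
a model with embedding 16, 32 channels, kernel 2, dilations (1, 2, 4,
8), one attention head, and 3000 training iterations per network at
batch size 128 — sizes chosen so a single-CPU run finishes in minutes
while leaving the method itself untouched. Under these conditions the
teacher's Spearman correlation between variant scores and ground-truth
effects exceeds 0.8 (a smoothed plug-in frequency estimator — the
ceiling for any site-marginal learner — reaches about 0.85–0.89 on the
same families), and the born-again student matches or exceeds the
teacher, reproducing the qualitative teacher-to-student improvement at
desk scale. The published headline AUCs on human variant benchmarks are
not recomputable here: they require the published alignment collection,
curated variant sets, and $10^5$-plus-iteration training per protein.
The package instead ships the published benchmark row as a plain-text
reference table and verifies it for internal consistency.

## Numerical choices and degenerate inputs

* Softmax and log-sum-exp are computed with max-subtraction; the
  tempered softmax is invariant to constant logit shifts.
* z-standardisation uses the population standard deviation; a model
  assigning identical scores to all variants (zero variance) is an
  error, not a silent division.
* Calibration with a single distinct z-value, a single-class labelled
  set, or fewer than two bins is an error; prediction for z-scores
  outside the calibrated range clamps to the end bins.
* An alignment whose columns are all gap-filtered is an error; variant
  exclusion (dropped column, wild-type mismatch, out-of-range) is a
  reported outcome, never an error.
* Training aborts with the iteration index if the loss becomes
  non-finite.
* All randomness (profile draws, sequence sampling, initialisation,
  mini-batch streams) flows through explicit integer seeds; identical
  seeds give bitwise-identical parameters, logs and outputs.

## Known limitations

Only single substitutions at retained, focus-aligned columns are
scorable — variants at heavily gapped columns are excluded by design.
The model is trained per family; there is no cross-protein parameter
sharing. The distillation is a single teacher-to-student generation;
multi-generation ensembles are out of scope. Weight decay, dropout and
gradient clipping are off by default (the training recipe specifies
only the rates and schedule); they can be added by extending the
optimiser but are not part of the published recipe.
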