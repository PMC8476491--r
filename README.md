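# banvep

Unsupervised prediction of the deleteriousness of single amino-acid
variants from a protein family's multiple sequence alignment, for
computational biologists who want variant effect scores free of the
train/test circularity that affects supervised predictors.

The core is a deep autoregressive generative model of aligned sequences
— an embedding of the right-shifted input, dilated causal convolution
blocks with residual connections, a causally masked self-attention
layer, and a softmax output — trained by maximum likelihood on the
gap-filtered, redundancy-reweighted alignment, then re-trained as a
**born-again network**: a same-capacity student minimises the sum of the
label loss and a distillation loss against the teacher's
temperature-softened output distribution (T = 4),

```
p_i = exp(z_i / T) / sum_j exp(z_j / T),
```

which lets the student match or exceed the teacher. A variant is scored
by the log-probability ratio

```
score = log p(x_mutant | theta) - log p(x_wildtype | theta)
```

(lower = more deleterious), standardised to a z-score against all 19 × L
possible substitutions of the focus sequence, converted to a probability
of deleteriousness by equal-width z-score binning of a labelled
calibration set, and labelled by an accuracy-maximising z-cutoff. The
package also ships the nine standard evaluation metrics (ROC-AUC as the
rank statistic, PR-AUC as average precision, accuracy, MCC, precision,
specificity, sensitivity, F-score, NPV), a confusion-matrix
reconstructor for checking published metric rows, and a synthetic family
generator with closed-form ground-truth effects.

## Worked example

Train teacher and student on a synthetic conserved family and score
every possible substitution:

```r
library(banvep)

fam  <- sampleFamily(familySpec(L = 12, N = 300, alpha = 0.1, seed = 7))
mask <- computeGapMask(fam$msa)          # drop columns with > 30% gaps
enc  <- encodeMsa(fam$msa, mask)
w    <- computeSequenceWeights(enc)      # 80%-identity reweighting
w
#> SequenceWeights: N = 301, identity threshold 0.80, n_eff = 290.00

mcfg <- modelConfig(seqLength = ncol(enc@matrix), embeddingDim = 8,
                    convChannels = 16, dilations = c(1, 2, 4),
                    attentionHeads = 1, attentionDim = 16)
tcfg <- trainingConfig(iterations = 400, batchSize = 64, seed = 7)
teacher <- trainTeacher(buildModel(mcfg, seed = 7), enc, w, tcfg)
student <- trainStudent(buildModel(mcfg, seed = 8), teacher$model, enc, w, tcfg)

scores <- zscoreAllVariants(student$model, enc)   # 19 x 12 = 228 variants
lab    <- labelledVariants(fam$truth, 150)        # synthetic labelled set
cal    <- calibrate(scores$z_score[match(lab$variant, scores$variant)],
                    lab$label, nBins = 10)
pred   <- predictVariants(scores, cal)
head(pred[order(pred$z_score), ], 3)
#>  variant log_prob_score   z_score prob_deleterious predicted_label
#>     T10N      -19.69468 -3.950863                1     deleterious
#>      N7V      -14.93254 -2.565738                1     deleterious
#>      S6V      -14.76087 -2.515804                1     deleterious
```

The most negative scores are substitutions the family almost never
tolerates at its most conserved columns; their calibrated probability of
deleteriousness is the deleterious fraction of their z-score bin, and
the label applies the strict `z < cutoff` rule. Evaluating the labels
against the synthetic truth:

```r
z <- scores$z_score[match(lab$variant, scores$variant)]
round(metricsReport(-z, lab$label,
                    ifelse(z < cal@zCutoff, "deleterious", "benign")), 3)
#>     roc_auc      pr_auc    accuracy         mcc   precision specificity
#>       0.839       0.798       0.767       0.594       0.685       0.547
#> sensitivity     f_score         npv
#>       0.987       0.809       0.976
```

Even this deliberately small run ranks variants well (ROC-AUC 0.84
against the generating profiles; a 400-iteration model is far from
converged — the desk-scale analyses below use 3000 iterations and reach
Spearman > 0.8 against ground truth). The same workflow is available as
config-driven commands (`cmdSimulate`, `cmdTrain`, `cmdScore`,
`cmdEvaluate`) and a thin command-line wrapper in `inst/cli/banvep.R`
for FASTA/A2M alignments and `A123V`-style variant lists; predictions
for variants at gap-filtered columns are reported as excluded with a
reason rather than dropped.

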