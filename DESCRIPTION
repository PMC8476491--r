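Package: banvep
Title: Variant Effect Prediction with a Born-Again Autoregressive Sequence Model
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised prediction of the deleteriousness of single
    amino-acid variants from a protein family multiple sequence alignment.
    An autoregressive generative model (embedding, dilated causal
    convolutions, causal self-attention, softmax output) is trained on the
    reweighted alignment; a same-capacity student network is then re-trained
    against the teacher's temperature-softened output distributions
    (Born-Again Networks distillation). Variants are scored by the
    log-probability ratio of mutant to wild-type sequence, standardised
    against all possible single substitutions, calibrated to a probability
    of deleteriousness by equal-width z-score binning, and labelled by an
    accuracy-maximising cutoff. Includes alignment filtering and sequence
    reweighting, a synthetic family generator with ground-truth variant
    effects, and the standard binary-classification evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
biocViews: Sequencing, Alignment, VariantAnnotation, Classification
RoxygenNote: 7.3.3
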