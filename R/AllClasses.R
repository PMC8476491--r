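#' @import methods
#' @importFrom stats rnorm runif rgamma sd cor quantile
#' @importFrom utils write.table read.table head tail
#' @useDynLib banvep, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Amino-acid alphabet used throughout the package
#'
#' The ordered symbol set: the 20 canonical amino acids, the gap character
#' \code{"-"}, and the unknown symbol \code{"X"}. Integer codes are the
#' positions in this vector; the model predicts over the first 21 symbols
#' (amino acids + gap) while \code{"X"} is an input-only code that never
#' receives probability mass.
#'
#' @format Character vector of length 22.
#' @export
AA_ALPHABET_GAP <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-", "X")

#' @rdname AA_ALPHABET_GAP
#' @export
GAP_CODE <- 21L

#' @rdname AA_ALPHABET_GAP
#' @export
UNKNOWN_CODE <- 22L

# non-canonical residue letters folded into the unknown code at encoding time
NONCANONICAL <- c("B", "J", "O", "U", "Z", "X", "*")

#' ProteinMsa: an aligned protein family with a designated focus sequence
#'
#' Holds the rows of a multiple sequence alignment as uppercase residue
#' strings (gap \code{"-"}), the record identifiers, and the index of the
#' focus (target / wild-type) sequence whose variants are to be scored.
#'
#' @slot ids character vector of sequence identifiers.
#' @slot rows character vector of aligned residue strings, all of equal width.
#' @slot focusIndex integer index of the focus sequence.
#' @slot nCols alignment width.
#'
#' @export
setClass("ProteinMsa", representation(
  ids = "character",
  rows = "character",
  focusIndex = "integer",
  nCols = "integer"
))

setValidity("ProteinMsa", function(object) {
  if (length(object@rows) == 0L) return("alignment has no sequences")
  w <- unique(nchar(object@rows))
  if (length(w) != 1L) return("aligned rows have unequal lengths")
  if (w != object@nCols) return("nCols does not match row width")
  if (length(object@ids) != length(object@rows))
    return("ids and rows differ in length")
  fi <- object@focusIndex
  if (length(fi) != 1L || is.na(fi) || fi < 1L || fi > length(object@rows))
    return("focusIndex does not address a valid row")
  TRUE
})

#' ColumnMask: per-column gap statistics and the retained-column map
#'
#' Records, for each alignment column, the fraction of gap symbols and
#' whether the column is retained (gap fraction at or below the threshold;
#' columns with more than the threshold fraction of gaps are dropped).
#' \code{colMap} maps each retained column at which the focus sequence is
#' non-gap to its original column index and its 1-based focus-sequence
#' position; only these columns are addressable by variants.
#'
#' @slot gapFraction numeric per-column gap fraction in [0, 1].
#' @slot kept logical per-column retention flag.
#' @slot maxGapFraction the threshold used (default 0.30).
#' @slot colMap data.frame with columns \code{retained} (index into the
#'   kept-column matrix), \code{original} (original column index) and
#'   \code{focusPos} (1-based focus-sequence position).
#'
#' @export
setClass("ColumnMask", representation(
  gapFraction = "numeric",
  kept = "logical",
  maxGapFraction = "numeric",
  colMap = "data.frame"
))

setValidity("ColumnMask", function(object) {
  if (length(object@gapFraction) != length(object@kept))
    return("gapFraction and kept differ in length")
  if (any(object@gapFraction < 0 | object@gapFraction > 1))
    return("gap fractions must lie in [0, 1]")
  disagree <- object@kept != (object@gapFraction <= object@maxGapFraction)
  if (any(disagree))
    return("kept flags disagree with the gap-fraction threshold")
  cm <- object@colMap
  if (nrow(cm) > 0L) {
    if (is.unsorted(cm$original, strictly = TRUE))
      return("colMap original columns must be strictly increasing")
    if (anyDuplicated(cm$focusPos))
      return("colMap focus positions must be unique")
  }
  TRUE
})

#' SequenceWeights: inverse-redundancy weights for alignment rows
#'
#' Each sequence is weighted by the reciprocal of the number of alignment
#' rows within the identity threshold of it (itself included), so clusters
#' of near-identical sequences contribute one effective observation. The
#' sum of weights is the effective number of sequences.
#'
#' @slot w numeric per-sequence weight in (0, 1].
#' @slot identityThreshold pairwise-identity threshold used for clustering.
#' @slot nEff effective number of sequences, \code{sum(w)}.
#'
#' @export
setClass("SequenceWeights", representation(
  w = "numeric",
  identityThreshold = "numeric",
  nEff = "numeric"
))

setValidity("SequenceWeights", function(object) {
  if (any(object@w <= 0 | object@w > 1))
    return("weights must lie in (0, 1]")
  if (abs(object@nEff - sum(object@w)) > 1e-8)
    return("nEff must equal sum(w)")
  n <- length(object@w)
  if (object@nEff < 1 - 1e-9 || object@nEff > n + 1e-9)
    return("nEff must lie in [1, N]")
  TRUE
})

#' EncodedMsa: the integer-encoded alignment restricted to kept columns
#'
#' @slot matrix integer matrix, one row per sequence, one column per
#'   retained alignment column; entries are codes into \code{alphabet}.
#' @slot alphabet the ordered symbol set.
#' @slot focusRow encoded focus sequence (the row at the focus index).
#' @slot keptColumns original indices of the retained columns.
#' @slot colMap copy of the scoring map from the \linkS4class{ColumnMask}.
#'
#' @export
setClass("EncodedMsa", representation(
  matrix = "matrix",
  alphabet = "character",
  focusRow = "integer",
  keptColumns = "integer",
  colMap = "data.frame"
))

setValidity("EncodedMsa", function(object) {
  m <- object@matrix
  if (!is.integer(m)) return("matrix must be integer")
  K <- length(object@alphabet)
  if (any(m < 1L | m > K)) return("matrix entries outside the alphabet")
  if (ncol(m) != length(object@keptColumns))
    return("matrix width must equal the number of kept columns")
  if (length(object@focusRow) != ncol(m))
    return("focusRow length must equal matrix width")
  TRUE
})

#' ModelConfig: architecture of the autoregressive sequence model
#'
#' The model factorises the probability of an aligned sequence
#' autoregressively: an embedding of the right-shifted input (a
#' begin-of-sequence token conditions position 1) feeds a stack of dilated
#' causal convolution blocks with residual connections, optionally a
#' causally masked self-attention layer, and a position-wise linear output
#' producing softmax logits over the alphabet.
#'
#' @slot alphabetSize number of output classes (21 for proteins: 20 amino
#'   acids + gap).
#' @slot seqLength model input length (number of retained columns).
#' @slot embeddingDim embedding dimension.
#' @slot convChannels channels of the convolution blocks.
#' @slot kernelSize convolution kernel size (taps per block).
#' @slot dilations integer dilation of each convolution block.
#' @slot attentionHeads number of attention heads; 0 disables the layer.
#' @slot attentionDim total attention dimension (split across heads).
#' @slot hasUnknown whether an input-only unknown code follows the alphabet.
#'
#' @export
setClass("ModelConfig", representation(
  alphabetSize = "integer",
  seqLength = "integer",
  embeddingDim = "integer",
  convChannels = "integer",
  kernelSize = "integer",
  dilations = "integer",
  attentionHeads = "integer",
  attentionDim = "integer",
  hasUnknown = "logical"
))

setValidity("ModelConfig", function(object) {
  dims <- c(object@alphabetSize, object@seqLength, object@embeddingDim,
            object@convChannels, object@kernelSize)
  if (any(dims < 1L)) return("all dimensions must be positive")
  if (length(object@dilations) < 1L || any(object@dilations < 1L))
    return("dilations must be positive integers")
  h <- object@attentionHeads
  if (h < 0L) return("attentionHeads must be >= 0")
  if (h > 0L && object@attentionDim %% h != 0L)
    return("attentionDim must be divisible by attentionHeads")
  TRUE
})

#' SequenceModel: a parameterised autoregressive model of aligned sequences
#'
#' @slot params named list of parameter matrices.
#' @slot config the \linkS4class{ModelConfig}.
#' @slot seed the seed used at initialisation.
#' @slot columnMapHash provenance hash of the column map the model was
#'   trained against ("" before training).
#'
#' @export
setClass("SequenceModel", representation(
  params = "list",
  config = "ModelConfig",
  seed = "integer",
  columnMapHash = "character"
))

#' TrainingConfig: optimisation settings for teacher and student phases
#'
#' Defaults follow the published schedule: temperature 4 for distillation,
#' mini-batches of 128, learning rate 0.001 until iteration 3000 and
#' 0.0001 from then on. The published runs train each network for 500,000
#' iterations (200,000 in the server setting); desk-scale runs use fewer.
#'
#' @slot temperature softening temperature for the teacher loss.
#' @slot iterations number of training iterations for one network.
#' @slot batchSize mini-batch size.
#' @slot lrHigh,lrLow,lrSwitch learning-rate schedule: \code{lrHigh} while
#'   the iteration index is below \code{lrSwitch}, \code{lrLow} afterwards.
#' @slot seed RNG seed for initialisation and batch sampling.
#' @slot distillStudentTemperature if TRUE (default) the student's own
#'   distribution is softened at the same temperature inside the teacher
#'   loss, as in standard distillation; FALSE matches the literal reading
#'   in which only the teacher output is softened.
#' @slot logEvery checkpoint interval for the training log.
#'
#' @export
setClass("TrainingConfig", representation(
  temperature = "numeric",
  iterations = "integer",
  batchSize = "integer",
  lrHigh = "numeric",
  lrLow = "numeric",
  lrSwitch = "integer",
  seed = "integer",
  distillStudentTemperature = "logical",
  logEvery = "integer"
))

setValidity("TrainingConfig", function(object) {
  if (object@temperature <= 0) return("temperature must be > 0")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@iterations < 1L) return("iterations must be >= 1")
  if (object@lrHigh <= 0 || object@lrLow <= 0) return("learning rates must be > 0")
  TRUE
})

#' CalibrationTable: equal-width z-score bins with deleterious proportions
#'
#' Built from a labelled variant set: the z-score range is divided into
#' equal-width intervals, the fraction of deleterious variants in each
#' interval is the calibrated probability of deleteriousness, and the bin
#' edge maximising classification accuracy of the rule "z below cutoff =>
#' deleterious" is the label cutoff.
#'
#' @slot binEdges ascending equal-width bin edges (length nBins + 1).
#' @slot proportionDeleterious per-bin deleterious fraction in [0, 1].
#' @slot nPerBin per-bin labelled-variant counts.
#' @slot zCutoff the accuracy-maximising cutoff (one of the edges).
#'
#' @export
setClass("CalibrationTable", representation(
  binEdges = "numeric",
  proportionDeleterious = "numeric",
  nPerBin = "integer",
  zCutoff = "numeric"
))

setValidity("CalibrationTable", function(object) {
  e <- object@binEdges
  if (length(e) < 3L) return("need at least 2 bins")
  w <- diff(e)
  if (any(w <= 0)) return("bin edges must be strictly increasing")
  if (max(w) - min(w) > 1e-9 * max(abs(e), 1))
    return("bins must have equal width")
  p <- object@proportionDeleterious
  if (length(p) != length(e) - 1L)
    return("one proportion per bin required")
  if (any(p < 0 | p > 1)) return("proportions must lie in [0, 1]")
  if (min(abs(object@zCutoff - e)) > 1e-9)
    return("cutoff must coincide with a bin edge")
  TRUE
})

#' ConfusionCounts: binary-classification confusion matrix
#'
#' @slot tp,tn,fp,fn non-negative integer counts.
#'
#' @export
setClass("ConfusionCounts", representation(
  tp = "integer", tn = "integer", fp = "integer", fn = "integer"
))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@tn, object@fp, object@fn)
  if (any(is.na(v)) || any(v < 0L)) return("counts must be non-negative")
  TRUE
})

setMethod("show", "ProteinMsa", function(object) {
  cat(sprintf("ProteinMsa: %d sequences x %d columns, focus '%s' (row %d)\n",
              length(object@rows), object@nCols,
              object@ids[object@focusIndex], object@focusIndex))
})

setMethod("show", "ColumnMask", function(object) {
  cat(sprintf(
    "ColumnMask: %d/%d columns kept (gap fraction <= %.2f), %d scorable focus positions\n",
    sum(object@kept), length(object@kept), object@maxGapFraction,
    nrow(object@colMap)))
})

setMethod("show", "SequenceWeights", function(object) {
  cat(sprintf("SequenceWeights: N = %d, identity threshold %.2f, n_eff = %.2f\n",
              length(object@w), object@identityThreshold, object@nEff))
})

setMethod("show", "EncodedMsa", function(object) {
  cat(sprintf("EncodedMsa: %d x %d integer matrix over %d symbols\n",
              nrow(object@matrix), ncol(object@matrix),
              length(object@alphabet)))
})

setMethod("show", "SequenceModel", function(object) {
  cfg <- object@config
  np <- sum(vapply(object@params, length, 1L))
  cat(sprintf(
    "SequenceModel: K=%d, L=%d, emb=%d, channels=%d, kernel=%d, dilations=%s, heads=%d (%s params)\n",
    cfg@alphabetSize, cfg@seqLength, cfg@embeddingDim, cfg@convChannels,
    cfg@kernelSize, paste(cfg@dilations, collapse = ","),
    cfg@attentionHeads, format(np, big.mark = ",")))
})

setMethod("show", "CalibrationTable", function(object) {
  cat(sprintf("CalibrationTable: %d equal-width bins on [%.3f, %.3f], cutoff %.4f\n",
              length(object@nPerBin), min(object@binEdges),
              max(object@binEdges), object@zCutoff))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%d TN=%d FP=%d FN=%d\n",
              object@tp, object@tn, object@fp, object@fn))
})
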