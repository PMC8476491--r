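#' Create a model configuration
#'
#' Defaults give a compact architecture whose causal context covers
#' typical domain lengths: with attention enabled the model conditions on
#' the full preceding context regardless of the convolutional receptive
#' field; without attention the receptive field is
#' \code{1 + (kernelSize - 1) * sum(dilations)} preceding positions.
#'
#' @param seqLength model input length (number of retained columns).
#' @param alphabetSize number of output classes; 21 for proteins.
#' @param embeddingDim embedding dimension.
#' @param convChannels channels per convolution block.
#' @param kernelSize taps per causal convolution (default 2).
#' @param dilations dilation of each block.
#' @param attentionHeads number of causal attention heads (0 disables).
#' @param attentionDim total attention dimension.
#' @param hasUnknown add the input-only unknown code (TRUE for proteins).
#' @return A \linkS4class{ModelConfig}.
#' @export
modelConfig <- function(seqLength,
                        alphabetSize = 21L,
                        embeddingDim = 32L,
                        convChannels = 128L,
                        kernelSize = 2L,
                        dilations = c(1L, 2L, 4L, 8L),
                        attentionHeads = 1L,
                        attentionDim = convChannels,
                        hasUnknown = alphabetSize == 21L) {
  new("ModelConfig",
      alphabetSize = as.integer(alphabetSize),
      seqLength = as.integer(seqLength),
      embeddingDim = as.integer(embeddingDim),
      convChannels = as.integer(convChannels),
      kernelSize = as.integer(kernelSize),
      dilations = as.integer(dilations),
      attentionHeads = as.integer(attentionHeads),
      attentionDim = as.integer(attentionDim),
      hasUnknown = hasUnknown)
}

# config as the flat list the C++ routines expect
cfgList <- function(config) {
  list(K = config@alphabetSize,
       Kin = config@alphabetSize + as.integer(config@hasUnknown) + 1L,
       L = config@seqLength,
       De = config@embeddingDim,
       C = config@convChannels,
       kernel = config@kernelSize,
       dil = config@dilations,
       heads = config@attentionHeads,
       Da = config@attentionDim)
}

#' Build (deterministically initialise) an autoregressive sequence model
#'
#' The same configuration and seed always produce identical parameters.
#' Weight matrices use scaled normal initialisation, biases start at zero,
#' and the output layer starts near zero so the initial conditionals are
#' close to uniform.
#'
#' @param config a \linkS4class{ModelConfig}.
#' @param seed integer RNG seed.
#' @return A \linkS4class{SequenceModel}.
#' @export
buildModel <- function(config, seed = 1L) {
  validObject(config)
  cl <- cfgList(config)
  rmat <- function(nr, nc, sd) matrix(rnorm(nr * nc, sd = sd), nr, nc)
  zrow <- function(nc) matrix(0, 1L, nc)
  p <- list()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  p$emb <- rmat(cl$Kin, cl$De, 0.1)
  p$pos <- rmat(cl$L, cl$De, 0.1)   # learned positional embedding
  p$W_in <- rmat(cl$De, cl$C, sqrt(2 / cl$De))
  p$b_in <- zrow(cl$C)
  for (b in seq_along(cl$dil)) {
    for (j in seq_len(cl$kernel))
      p[[sprintf("Wc_%d_%d", b, j)]] <- rmat(cl$C, cl$C, sqrt(2 / (cl$kernel * cl$C)))
    p[[sprintf("bc_%d", b)]] <- zrow(cl$C)
  }
  if (cl$heads > 0L) {
    p$Wq <- rmat(cl$C, cl$Da, sqrt(1 / cl$C))
    p$Wk <- rmat(cl$C, cl$Da, sqrt(1 / cl$C))
    p$Wv <- rmat(cl$C, cl$Da, sqrt(1 / cl$C))
    p$Wo <- rmat(cl$Da, cl$C, 0.01)
    p$bo <- zrow(cl$C)
  }
  p$W_out <- rmat(cl$C, cl$K, 0.01)
  p$b_out <- zrow(cl$K)
  new("SequenceModel", params = p, config = config,
      seed = as.integer(seed), columnMapHash = "")
}

# preserve the caller's RNG stream around seeded initialisation
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# encoded sequences -> B x L integer matrix of codes
asCodesMatrix <- function(seqs, L) {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    m <- matrix(as.integer(seqs), nrow = 1L)
  }
  if (ncol(m) != L)
    stop("sequence length ", ncol(m), " does not match model length ", L)
  storage.mode(m) <- "integer"
  m
}

#' Per-position conditional log distributions
#'
#' Row i of the result is the model's log conditional distribution over
#' the alphabet at position i given the begin-of-sequence token and the
#' symbols at positions before i. Rows exponentiate-and-sum to 1.
#'
#' @param model a \linkS4class{SequenceModel}.
#' @param seq encoded sequence (integer codes) of model length.
#' @return L x K matrix of log probabilities.
#' @export
conditionalLogProbs <- function(model, seq) {
  L <- model@config@seqLength
  X <- asCodesMatrix(seq, L)
  if (nrow(X) != 1L) stop("one sequence expected")
  cpp_forward_logp(model@params, cfgList(model@config), X)
}

# batched conditionals: list of L x K matrices, one per row of X
batchLogProbs <- function(model, X) {
  L <- model@config@seqLength
  X <- asCodesMatrix(X, L)
  lp <- cpp_forward_logp(model@params, cfgList(model@config), X)
  lapply(seq_len(nrow(X)), function(b) lp[((b - 1L) * L + 1L):(b * L), , drop = FALSE])
}

#' Autoregressive sequence log-likelihood
#'
#' Sum over positions of the conditional log probability of the observed
#' symbol; always non-positive. Accepts a single encoded sequence or a
#' matrix of sequences (one per row), returning one value per sequence.
#' Positions carrying an input-only code (the unknown symbol) are
#' conditioned on but contribute no likelihood term, mirroring their
#' treatment in the training loss.
#'
#' @param model a \linkS4class{SequenceModel}.
#' @param seq encoded sequence(s).
#' @return log probability in nats (vector for matrix input).
#' @export
sequenceLogLikelihood <- function(model, seq) {
  L <- model@config@seqLength
  X <- asCodesMatrix(seq, L)
  lp <- cpp_forward_logp(model@params, cfgList(model@config), X)
  K <- model@config@alphabetSize
  out <- numeric(nrow(X))
  for (b in seq_len(nrow(X))) {
    rows <- ((b - 1L) * L + 1L):(b * L)
    codes <- X[b, ]
    valid <- codes <= K
    out[b] <- sum(lp[cbind(rows[valid], codes[valid])])
  }
  if (nrow(X) == 1L) out[1] else out
}

#' Temperature-softened softmax
#'
#' \code{p_i = exp(z_i / T) / sum_j exp(z_j / T)}. Higher temperatures
#' give softer (higher-entropy) distributions; the computation is
#' stabilised by subtracting the maximum logit and is invariant to
#' constant shifts of the logits.
#'
#' @param logits numeric vector.
#' @param temperature positive softening temperature.
#' @return probability vector summing to 1.
#' @export
temperedSoftmax <- function(logits, temperature = 1) {
  if (!is.numeric(temperature) || temperature <= 0)
    stop("temperature must be > 0")
  z <- logits / temperature
  e <- exp(z - max(z))
  e / sum(e)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file embedding the parameters, the
#' configuration, and a manifest (initialisation seed, alphabet size,
#' column-map hash) for provenance checks at scoring time.
#'
#' @param model a \linkS4class{SequenceModel}.
#' @param path checkpoint path.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(params = model@params, config = model@config,
               seed = model@seed, columnMapHash = model@columnMapHash),
          path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  new("SequenceModel", params = x$params, config = x$config,
      seed = x$seed, columnMapHash = x$columnMapHash)
}
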