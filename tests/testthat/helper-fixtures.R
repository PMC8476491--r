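# shared fixture builders; everything is generated in code

tinyMsa <- function() {
  proteinMsa(c("ACDEF", "ACDEG", "ACDE-"),
             ids = c("focus", "s2", "s3"), focusIndex = 1L)
}

tinyConfig <- function(L = 5L, K = 4L, heads = 1L, dilations = c(1L, 2L)) {
  modelConfig(seqLength = L, alphabetSize = K, embeddingDim = 6L,
              convChannels = 8L, dilations = dilations,
              attentionHeads = heads, attentionDim = 8L,
              hasUnknown = FALSE)
}

# a site-independent oracle model: conditionals at position t equal the
# given profile row exactly, independent of context (built by zeroing the
# network except position -> log-profile logits)
profileOracleModel <- function(logProfiles) {
  L <- nrow(logProfiles)
  K <- ncol(logProfiles)
  cfg <- modelConfig(seqLength = L, alphabetSize = as.integer(K),
                     embeddingDim = as.integer(L), convChannels = as.integer(L),
                     dilations = 1L, attentionHeads = 0L,
                     attentionDim = as.integer(L), hasUnknown = FALSE)
  m <- buildModel(cfg, seed = 1L)
  for (nm in names(m@params)) m@params[[nm]][] <- 0
  m@params$pos <- diag(L)
  m@params$W_in <- diag(L)
  m@params$W_out <- logProfiles        # H = relu(pos) = I, logits = rows
  m
}

# small trained family for scoring tests, cached per test run
scoredFamilyFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    fam <- sampleFamily(familySpec(L = 12L, N = 300L, alpha = 0.1, seed = 7))
    mask <- computeGapMask(fam$msa)
    enc <- encodeMsa(fam$msa, mask)
    w <- computeSequenceWeights(enc)
    mc <- modelConfig(seqLength = ncol(enc@matrix), embeddingDim = 8L,
                      convChannels = 16L, dilations = c(1L, 2L, 4L),
                      attentionHeads = 1L, attentionDim = 16L)
    tc <- trainingConfig(iterations = 400L, batchSize = 64L, seed = 7,
                         logEvery = 100L)
    fit <- trainTeacher(buildModel(mc, 7L), enc, w, tc)
    cache <<- list(fam = fam, mask = mask, enc = enc, w = w,
                   model = fit$model, log = fit$log)
    cache
  }
})

writeTempFasta <- function(ids, rows) {
  f <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", ids, "\n", rows), f)
  f
}
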