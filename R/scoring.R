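#' Log-probability score of a mapped variant
#'
#' \code{log p(mutant) - log p(wild-type)} under the trained model, where
#' the mutant sequence is the focus row with exactly one retained-column
#' symbol substituted. More negative scores indicate more deleterious
#' variants.
#'
#' @param model trained \linkS4class{SequenceModel}.
#' @param encoded the \linkS4class{EncodedMsa} the model was trained on.
#' @param retained kept-column index of the variant (from
#'   \code{\link{mapVariants}}).
#' @param mutCode integer code of the substituted residue.
#' @return log-probability ratio in nats.
#' @export
logProbScore <- function(model, encoded, retained, mutCode) {
  focus <- encoded@focusRow
  mutant <- focus
  mutant[retained] <- as.integer(mutCode)
  ll <- sequenceLogLikelihood(model, rbind(mutant, focus))
  ll[1] - ll[2]
}

#' Score all possible single substitutions of the focus sequence
#'
#' Builds the 19 non-wild-type substitutions at every scorable focus
#' position (retained columns where the focus sequence is non-gap),
#' computes each log-probability score, and standardises the scores to
#' z-scores against the mean and population standard deviation of this
#' full set, absorbing protein-to-protein differences in the score
#' distribution.
#'
#' @param model trained \linkS4class{SequenceModel}.
#' @param encoded the \linkS4class{EncodedMsa}.
#' @param batchSize forward-pass batch size.
#' @return data.frame with columns \code{variant, wt, pos, mut, retained,
#'   log_prob_score, z_score}; exactly 19 rows per scorable position.
#' @export
zscoreAllVariants <- function(model, encoded, batchSize = 256L) {
  cm <- encoded@colMap
  focus <- encoded@focusRow
  cm <- cm[focus[cm$retained] <= 20L, , drop = FALSE]  # canonical wt only
  if (nrow(cm) == 0L) stop("no scorable focus positions")
  aa <- 1:20
  rows <- do.call(rbind, lapply(seq_len(nrow(cm)), function(i) {
    wtCode <- focus[cm$retained[i]]
    muts <- setdiff(aa, wtCode)
    data.frame(pos = cm$focusPos[i], retained = cm$retained[i],
               wtCode = wtCode, mutCode = muts)
  }))
  L <- model@config@seqLength
  seqs <- matrix(rep(focus, each = nrow(rows)), nrow = nrow(rows))
  seqs[cbind(seq_len(nrow(rows)), rows$retained)] <- rows$mutCode
  storage.mode(seqs) <- "integer"
  wtLL <- sequenceLogLikelihood(model, matrix(focus, nrow = 1L))
  scores <- numeric(nrow(rows))
  for (start in seq(1L, nrow(rows), by = batchSize)) {
    end <- min(start + batchSize - 1L, nrow(rows))
    scores[start:end] <-
      sequenceLogLikelihood(model, seqs[start:end, , drop = FALSE]) - wtLL
  }
  sdev <- sqrt(mean((scores - mean(scores))^2))   # population sd
  if (sdev == 0) stop("degenerate model: all variant scores identical")
  alpha <- encoded@alphabet
  data.frame(
    variant = paste0(alpha[rows$wtCode], rows$pos, alpha[rows$mutCode]),
    wt = alpha[rows$wtCode], pos = rows$pos, mut = alpha[rows$mutCode],
    retained = rows$retained,
    log_prob_score = scores,
    z_score = (scores - mean(scores)) / sdev,
    stringsAsFactors = FALSE
  )
}

#' Calibrate z-scores against a labelled variant set
#'
#' Divides the labelled z-score range into \code{nBins} equal-width
#' intervals and records the proportion of deleterious variants in each;
#' that proportion is the calibrated probability of deleteriousness for
#' any variant whose z-score falls in the interval. Bins containing no
#' labelled variants inherit the proportion of the nearest non-empty bin
#' (preferring the lower-z side). The accuracy-maximising bin edge becomes
#' the label cutoff (see \code{\link{selectCutoff}}).
#'
#' @param z numeric z-scores of the labelled variants.
#' @param label character/logical labels; \code{"deleterious"}/TRUE or
#'   \code{"benign"}/FALSE.
#' @param nBins number of equal-width bins (default 20).
#' @return A \linkS4class{CalibrationTable}.
#' @export
calibrate <- function(z, label, nBins = 20L) {
  lab <- normaliseLabels(label)
  if (length(z) != length(lab)) stop("z and label differ in length")
  if (length(unique(lab)) < 2L)
    stop("both deleterious and benign labels are required")
  if (nBins < 2L) stop("nBins must be >= 2")
  lo <- min(z); hi <- max(z)
  if (hi <= lo) stop("calibration requires more than one distinct z value")
  edges <- seq(lo, hi, length.out = nBins + 1L)
  bin <- binIndex(z, edges)
  nPer <- tabulate(bin, nBins)
  nDel <- tabulate(bin[lab], nBins)
  prop <- ifelse(nPer > 0L, nDel / nPer, NA_real_)
  # empty bins inherit from the nearest non-empty bin, lower side preferred
  if (anyNA(prop)) {
    filled <- which(!is.na(prop))
    for (b in which(is.na(prop))) {
      d <- abs(filled - b)
      nearest <- filled[d == min(d)]
      prop[b] <- prop[min(nearest)]
    }
  }
  tab <- new("CalibrationTable", binEdges = edges,
             proportionDeleterious = prop, nPerBin = as.integer(nPer),
             zCutoff = edges[1])
  tab@zCutoff <- selectCutoff(z, lab, tab)
  tab
}

# bin membership for equal-width edges; top edge closes the last bin
binIndex <- function(z, edges) {
  nBins <- length(edges) - 1L
  w <- (edges[length(edges)] - edges[1]) / nBins
  b <- floor((z - edges[1]) / w) + 1L
  pmin(pmax(b, 1L), nBins)
}

normaliseLabels <- function(label) {
  if (is.logical(label)) return(label)
  if (is.numeric(label)) return(label != 0)
  l <- tolower(as.character(label))
  if (!all(l %in% c("deleterious", "benign")))
    stop("labels must be 'deleterious' or 'benign'")
  l == "deleterious"
}

#' Accuracy-maximising z-score cutoff
#'
#' Evaluates the rule "z strictly below cutoff is deleterious" at every
#' bin edge of the calibration table and returns the edge with the
#' highest classification accuracy on the labelled set; ties resolve to
#' the smallest maximising edge.
#'
#' @param z labelled z-scores.
#' @param label labels as in \code{\link{calibrate}}.
#' @param table a \linkS4class{CalibrationTable}.
#' @return the selected cutoff (a bin edge).
#' @export
selectCutoff <- function(z, label, table) {
  lab <- normaliseLabels(label)
  acc <- vapply(table@binEdges, function(e) {
    mean((z < e) == lab)
  }, numeric(1))
  table@binEdges[which.max(acc)]
}

#' Assign probabilities of deleteriousness and labels to scored variants
#'
#' Looks each z-score up in the calibration table: the probability of
#' deleteriousness is the deleterious proportion of the containing bin
#' (z-scores outside the calibrated range clamp to the end bins), and the
#' predicted label is deleterious exactly when the z-score is strictly
#' below the cutoff.
#'
#' @param scores data.frame with a \code{z_score} column
#'   (\code{\link{zscoreAllVariants}} output or a subset of it).
#' @param table a \linkS4class{CalibrationTable}.
#' @return \code{scores} with added columns \code{prob_deleterious} and
#'   \code{predicted_label}.
#' @export
predictVariants <- function(scores, table) {
  b <- binIndex(scores$z_score, table@binEdges)
  scores$prob_deleterious <- table@proportionDeleterious[b]
  scores$predicted_label <- ifelse(scores$z_score < table@zCutoff,
                                   "deleterious", "benign")
  scores
}

#' Write a calibration table as tab-separated text
#'
#' Edges and proportions, one bin per row, with the cutoff recorded in a
#' commented header line.
#'
#' @param table a \linkS4class{CalibrationTable}.
#' @param path output path.
#' @export
writeCalibrationTable <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# z_cutoff\t%.10g", table@zCutoff), con)
  tab <- data.frame(
    bin_low = head(table@binEdges, -1L),
    bin_high = tail(table@binEdges, -1L),
    proportion_deleterious = table@proportionDeleterious,
    n = table@nPerBin
  )
  suppressWarnings(write.table(tab, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}
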