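#' Create a training configuration
#'
#' Defaults are the published schedule: distillation temperature 4,
#' mini-batch size 128, learning rate 0.001 below iteration 3000 and
#' 0.0001 from iteration 3000 onwards, 500,000 iterations per network.
#' Desk-scale runs pass a smaller \code{iterations}.
#'
#' @param iterations training iterations for one network.
#' @param temperature distillation temperature (teacher loss).
#' @param batchSize mini-batch size.
#' @param lrHigh,lrLow,lrSwitch the two-rate learning schedule.
#' @param seed RNG seed for mini-batch sampling.
#' @param distillStudentTemperature soften the student distribution at the
#'   same temperature inside the teacher loss (standard distillation,
#'   default) or leave it unsoftened (literal two-temperature reading).
#' @param logEvery checkpoint interval of the training log.
#' @return A \linkS4class{TrainingConfig}.
#' @export
trainingConfig <- function(iterations = 500000L,
                           temperature = 4,
                           batchSize = 128L,
                           lrHigh = 0.001,
                           lrLow = 0.0001,
                           lrSwitch = 3000L,
                           seed = 1L,
                           distillStudentTemperature = TRUE,
                           logEvery = 100L) {
  new("TrainingConfig",
      temperature = temperature,
      iterations = as.integer(iterations),
      batchSize = as.integer(batchSize),
      lrHigh = lrHigh, lrLow = lrLow, lrSwitch = as.integer(lrSwitch),
      seed = as.integer(seed),
      distillStudentTemperature = distillStudentTemperature,
      logEvery = as.integer(logEvery))
}

#' Sample a weighted mini-batch of encoded sequences
#'
#' Rows are drawn with replacement with probability proportional to the
#' sequence weights, so redundant sequences do not dominate training.
#'
#' @param encoded an \linkS4class{EncodedMsa}.
#' @param weights a \linkS4class{SequenceWeights} aligned with its rows.
#' @param batchSize number of sequences to draw.
#' @return integer matrix of encoded sequences (batchSize rows).
#' @export
sampleMinibatch <- function(encoded, weights, batchSize) {
  if (batchSize < 1L) stop("batchSize must be >= 1")
  if (length(weights@w) != nrow(encoded@matrix))
    stop("weights not aligned with the encoded alignment")
  idx <- sample.int(nrow(encoded@matrix), batchSize, replace = TRUE,
                    prob = weights@w)
  encoded@matrix[idx, , drop = FALSE]
}

#' Label loss: cross-entropy of a target sequence under the model output
#'
#' The mean over positions of the negative conditional log probability of
#' the target symbol; equals \code{-sequenceLogLikelihood / L}.
#'
#' @param dists L x K matrix of conditional log probabilities
#'   (\code{\link{conditionalLogProbs}}).
#' @param target encoded target sequence.
#' @return non-negative scalar (nats per position).
#' @export
labelLoss <- function(dists, target) {
  target <- as.integer(target)
  if (length(target) != nrow(dists))
    stop("target length does not match the distribution rows")
  if (any(target < 1L | target > ncol(dists)))
    stop("target codes outside the predicted alphabet")
  -mean(dists[cbind(seq_len(nrow(dists)), target)])
}

#' Teacher loss: cross-entropy against the softened teacher distribution
#'
#' Mean over positions of the cross-entropy between the teacher's
#' temperature-softened softmax output and the student's output
#' distribution. With \code{distillStudentTemperature = TRUE} (default)
#' the student logits are softened at the same temperature, so the loss is
#' minimised exactly when the two softened distributions coincide.
#'
#' @param studentLogits,teacherLogits L x K logit matrices.
#' @param temperature softening temperature.
#' @param distillStudentTemperature soften the student side as well.
#' @return non-negative scalar.
#' @export
teacherLoss <- function(studentLogits, teacherLogits, temperature = 4,
                        distillStudentTemperature = TRUE) {
  if (!all(dim(studentLogits) == dim(teacherLogits)))
    stop("logit matrices must have identical shape")
  if (temperature <= 0) stop("temperature must be > 0")
  Ts <- if (distillStudentTemperature) temperature else 1
  tot <- 0
  for (i in seq_len(nrow(studentLogits))) {
    pt <- temperedSoftmax(teacherLogits[i, ], temperature)
    zs <- studentLogits[i, ] / Ts
    logq <- zs - max(zs) - log(sum(exp(zs - max(zs))))
    tot <- tot - sum(pt * logq)
  }
  tot / nrow(studentLogits)
}

# pre-sample the whole mini-batch index stream (reproducible per seed)
batchIndexStream <- function(n, weights, iterations, batchSize, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  matrix(sample.int(n, iterations * batchSize, replace = TRUE,
                    prob = weights),
         nrow = iterations, ncol = batchSize)
}

runTraining <- function(model, encoded, weights, config, teacher = NULL) {
  if (ncol(encoded@matrix) != model@config@seqLength)
    stop("encoded alignment width does not match the model length")
  batches <- batchIndexStream(nrow(encoded@matrix), weights@w,
                              config@iterations, config@batchSize,
                              config@seed)
  tp <- if (is.null(teacher)) NULL else teacher@params
  res <- cpp_train(model@params, cfgList(model@config), encoded@matrix,
                   batches,
                   list(lrHigh = config@lrHigh, lrLow = config@lrLow,
                        lrSwitch = config@lrSwitch,
                        logEvery = config@logEvery),
                   tp, config@temperature,
                   config@distillStudentTemperature)
  model@params <- res$params
  list(model = model, log = as.data.frame(res$log))
}

#' Train the teacher network on the weighted alignment
#'
#' Minimises the label loss (negative log-likelihood per position) over
#' weighted mini-batches with Adam under the two-rate learning schedule.
#'
#' @param model an initialised \linkS4class{SequenceModel}.
#' @param encoded the \linkS4class{EncodedMsa}.
#' @param weights the \linkS4class{SequenceWeights}.
#' @param config a \linkS4class{TrainingConfig}.
#' @return list with elements \code{model} (trained) and \code{log}
#'   (data.frame: iteration, lr, label_loss, teacher_loss).
#' @export
trainTeacher <- function(model, encoded, weights, config) {
  runTraining(model, encoded, weights, config)
}

#' Train a born-again student against a frozen teacher
#'
#' The student has the same capacity as the teacher (identical
#' configuration — the born-again premise) and starts from a fresh random
#' initialisation. Its loss is the unweighted sum of the label loss and
#' the teacher loss at the configured temperature; the teacher's
#' parameters are frozen (verified by hash).
#'
#' @param student an initialised \linkS4class{SequenceModel}.
#' @param teacher the trained teacher \linkS4class{SequenceModel}.
#' @inheritParams trainTeacher
#' @return list with elements \code{model} and \code{log}; the log carries
#'   both loss components at every checkpoint.
#' @export
trainStudent <- function(student, teacher, encoded, weights, config) {
  if (!identical(cfgList(student@config), cfgList(teacher@config)))
    stop("student and teacher must share the same configuration")
  before <- paramHash(teacher@params)
  out <- runTraining(student, encoded, weights, config, teacher = teacher)
  if (!identical(paramHash(teacher@params), before))
    stop("teacher parameters changed during student training")
  out
}

# md5 of serialized parameters, for frozen-teacher and provenance checks
paramHash <- function(params) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(params, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

#' Write a training log as a tab-separated table
#'
#' @param log data.frame returned by \code{\link{trainTeacher}} /
#'   \code{\link{trainStudent}}.
#' @param path output path.
#' @export
writeTrainingLog <- function(log, path) {
  write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
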