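#' Read a run configuration from YAML
#'
#' Sections: \code{paths} (alignment, variants, labelled, outdir),
#' \code{family} (synthetic generator), \code{model}, \code{training},
#' \code{scoring} (nBins), and a top-level \code{seed}. Missing values
#' fall back to package defaults.
#'
#' @param path YAML file path.
#' @return nested list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

cfgGet <- function(config, ..., default = NULL) {
  x <- config
  for (k in c(...)) {
    if (is.null(x[[k]])) return(default)
    x <- x[[k]]
  }
  x
}

writeManifest <- function(outdir, step, seed, inputs = character()) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(step = step, seed = seed,
                   package_version = as.character(utils::packageVersion("banvep")),
                   inputs = hashes, time = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(outdir, paste0(step, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Generate a synthetic family on disk
#'
#' @param config run configuration list (see \code{\link{readRunConfig}}).
#' @return invisibly, the output directory.
#' @export
cmdSimulate <- function(config) {
  outdir <- cfgGet(config, "paths", "outdir", default = ".")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfgGet(config, "seed", default = 1L)
  spec <- familySpec(
    L = cfgGet(config, "family", "L", default = 40L),
    N = cfgGet(config, "family", "N", default = 2000L),
    alpha = cfgGet(config, "family", "alpha", default = 0.1),
    gapRate = cfgGet(config, "family", "gapRate", default = 0),
    nFounders = cfgGet(config, "family", "nFounders",
                       default = cfgGet(config, "family", "N", default = 2000L)),
    copiesPerFounder = cfgGet(config, "family", "copiesPerFounder", default = 1L),
    copyMutationRate = cfgGet(config, "family", "copyMutationRate", default = 0),
    seed = seed)
  fam <- sampleFamily(spec)
  paths <- writeFamily(fam, outdir)
  writeManifest(outdir, "simulate", seed, paths)
  invisible(outdir)
}

prepareAlignment <- function(config) {
  alnPath <- cfgGet(config, "paths", "alignment")
  if (is.null(alnPath)) stop("paths$alignment is required")
  msa <- readAlignment(alnPath,
                       format = cfgGet(config, "paths", "format", default = "fasta"),
                       focusId = cfgGet(config, "paths", "focusId", default = "first"))
  mask <- computeGapMask(msa, cfgGet(config, "scoring", "maxGapFraction",
                                     default = 0.30))
  encoded <- encodeMsa(msa, mask)
  weights <- computeSequenceWeights(
    encoded, cfgGet(config, "scoring", "identityThreshold", default = 0.8))
  list(msa = msa, mask = mask, encoded = encoded, weights = weights)
}

modelFromConfig <- function(config, L, seed) {
  modelConfig(
    seqLength = L,
    embeddingDim = cfgGet(config, "model", "embeddingDim", default = 32L),
    convChannels = cfgGet(config, "model", "convChannels", default = 128L),
    kernelSize = cfgGet(config, "model", "kernelSize", default = 2L),
    dilations = cfgGet(config, "model", "dilations", default = c(1L, 2L, 4L, 8L)),
    attentionHeads = cfgGet(config, "model", "attentionHeads", default = 1L),
    attentionDim = cfgGet(config, "model", "attentionDim",
                          default = cfgGet(config, "model", "convChannels",
                                           default = 128L)))
}

trainingFromConfig <- function(config, seed) {
  trainingConfig(
    iterations = cfgGet(config, "training", "iterations", default = 500000L),
    temperature = cfgGet(config, "training", "temperature", default = 4),
    batchSize = cfgGet(config, "training", "batchSize", default = 128L),
    lrHigh = cfgGet(config, "training", "lrHigh", default = 0.001),
    lrLow = cfgGet(config, "training", "lrLow", default = 0.0001),
    lrSwitch = cfgGet(config, "training", "lrSwitch", default = 3000L),
    seed = seed,
    distillStudentTemperature = cfgGet(config, "training",
                                       "distillStudentTemperature",
                                       default = TRUE),
    logEvery = cfgGet(config, "training", "logEvery", default = 100L))
}

#' Filter, weight, encode and train teacher (and student) on an alignment
#'
#' Runs the full training workflow: gap-column filtering, sequence
#' reweighting, integer encoding, teacher training, and (unless
#' \code{training$teacherOnly}) born-again student training. Checkpoints,
#' training logs, the column map, the weights and a manifest are written
#' to the output directory.
#'
#' @param config run configuration list.
#' @return invisibly, the output directory.
#' @export
cmdTrain <- function(config) {
  outdir <- cfgGet(config, "paths", "outdir", default = ".")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfgGet(config, "seed", default = 1L)
  prep <- prepareAlignment(config)
  writeColumnMap(prep$mask, file.path(outdir, "column_map.tsv"))
  writeWeights(prep$weights, prep$msa@ids, file.path(outdir, "weights.tsv"))
  L <- ncol(prep$encoded@matrix)
  mcfg <- modelFromConfig(config, L, seed)
  tcfg <- trainingFromConfig(config, seed)
  cmHash <- columnMapHash(prep$mask)

  teacher <- buildModel(mcfg, seed = seed)
  teacherFit <- trainTeacher(teacher, prep$encoded, prep$weights, tcfg)
  teacherFit$model@columnMapHash <- cmHash
  saveModel(teacherFit$model, file.path(outdir, "teacher.rds"))
  writeTrainingLog(teacherFit$log, file.path(outdir, "teacher_log.tsv"))

  if (!isTRUE(cfgGet(config, "training", "teacherOnly", default = FALSE))) {
    student <- buildModel(mcfg, seed = seed + 1L)  # fresh initialisation
    studentFit <- trainStudent(student, teacherFit$model, prep$encoded,
                               prep$weights, tcfg)
    studentFit$model@columnMapHash <- cmHash
    saveModel(studentFit$model, file.path(outdir, "student.rds"))
    writeTrainingLog(studentFit$log, file.path(outdir, "student_log.tsv"))
  }
  writeManifest(outdir, "train", seed,
                cfgGet(config, "paths", "alignment"))
  invisible(outdir)
}

#' Score variants with a trained checkpoint
#'
#' Reads the checkpoint and the variant list, recomputes the alignment
#' filtering to map variant coordinates (verifying the column-map hash
#' against the checkpoint), scores every possible substitution for the
#' z-score normalisation, and writes a prediction table covering every
#' input variant: scored rows carry the log-probability score and
#' z-score (plus probability and label when a calibration table is
#' available), excluded rows carry their exclusion reason. No input
#' variant is dropped.
#'
#' @param config run configuration list.
#' @return the prediction table (also written to
#'   \code{predictions.tsv}), invisibly.
#' @export
cmdScore <- function(config) {
  outdir <- cfgGet(config, "paths", "outdir", default = ".")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfgGet(config, "seed", default = 1L)
  prep <- prepareAlignment(config)
  ckpt <- cfgGet(config, "paths", "checkpoint",
                 default = file.path(outdir, "student.rds"))
  model <- loadModel(ckpt)
  if (nzchar(model@columnMapHash) &&
      !identical(model@columnMapHash, columnMapHash(prep$mask)))
    stop("checkpoint was trained against a different column map")

  allScores <- zscoreAllVariants(model, prep$encoded)
  calPath <- cfgGet(config, "paths", "calibration")
  cal <- if (!is.null(calPath)) readCalibrationTable(calPath) else NULL

  varPath <- cfgGet(config, "paths", "variants")
  if (is.null(varPath)) {
    out <- allScores
    out$status <- "scored"
    if (!is.null(cal)) out <- predictVariants(out, cal)
  } else {
    variants <- parseVariants(readLines(varPath, warn = FALSE))
    mapped <- mapVariants(prep$mask, prep$msa, variants$variant)
    key <- paste(allScores$pos, allScores$mut)
    sc <- mapped$scorable
    hit <- match(paste(sc$pos, sc$mut), key)
    scored <- data.frame(
      variant = sc$variant,
      log_prob_score = allScores$log_prob_score[hit],
      z_score = allScores$z_score[hit],
      status = "scored", stringsAsFactors = FALSE)
    if (!is.null(cal)) {
      pv <- predictVariants(data.frame(z_score = scored$z_score), cal)
      scored$prob_deleterious <- pv$prob_deleterious
      scored$predicted_label <- pv$predicted_label
    } else {
      scored$prob_deleterious <- NA_real_
      scored$predicted_label <- NA_character_
    }
    excl <- mapped$excluded
    excluded <- data.frame(
      variant = excl$variant, log_prob_score = NA_real_,
      z_score = NA_real_, status = paste0("excluded(", excl$reason, ")"),
      prob_deleterious = NA_real_, predicted_label = NA_character_,
      stringsAsFactors = FALSE)
    out <- rbind(scored, excluded)
    out <- out[match(variants$variant, out$variant), , drop = FALSE]
    rownames(out) <- NULL
  }
  write.table(out, file.path(outdir, "predictions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeManifest(outdir, "score", seed, ckpt)
  invisible(out)
}

#' Evaluate predictions against truth labels
#'
#' Joins a prediction table with a labelled truth table (columns
#' \code{variant}, \code{label}) and writes the single-row nine-metric
#' report; ranking metrics use the negated z-score as the
#' deleteriousness score.
#'
#' @param config run configuration list.
#' @return the named metrics vector, invisibly.
#' @export
cmdEvaluate <- function(config) {
  outdir <- cfgGet(config, "paths", "outdir", default = ".")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  predPath <- cfgGet(config, "paths", "predictions",
                     default = file.path(outdir, "predictions.tsv"))
  truthPath <- cfgGet(config, "paths", "labelled")
  if (is.null(truthPath)) stop("paths$labelled is required")
  pred <- read.table(predPath, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  truth <- read.table(truthPath, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  joined <- merge(pred[pred$status == "scored", , drop = FALSE],
                  truth[, c("variant", "label")], by = "variant")
  if (nrow(joined) == 0L) stop("no scored variants match the truth table")
  metrics <- metricsReport(-joined$z_score, joined$label,
                           joined$predicted_label)
  writeMetricsReport(metrics, file.path(outdir, "metrics.tsv"))
  writeManifest(outdir, "evaluate", cfgGet(config, "seed", default = 1L),
                c(predPath, truthPath))
  invisible(metrics)
}

#' Read back a calibration table written by
#' \code{\link{writeCalibrationTable}}
#'
#' @param path table path.
#' @return A \linkS4class{CalibrationTable}.
#' @export
readCalibrationTable <- function(path) {
  header <- readLines(path, n = 1L)
  cutoff <- as.numeric(strsplit(header, "\t")[[1]][2])
  tab <- read.table(path, header = TRUE, sep = "\t", skip = 1L)
  new("CalibrationTable",
      binEdges = c(tab$bin_low, tab$bin_high[nrow(tab)]),
      proportionDeleterious = tab$proportion_deleterious,
      nPerBin = as.integer(tab$n), zCutoff = cutoff)
}
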