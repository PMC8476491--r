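# one desk-scale run through the full command workflow, shared across tests
workflowFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    outdir <- file.path(tempdir(), "wf")
    config <- list(
      seed = 11L,
      paths = list(outdir = outdir, alignment = file.path(outdir, "family.fasta"),
                   focusId = "focus"),
      family = list(L = 12L, N = 250L, alpha = 0.1),
      model = list(embeddingDim = 8L, convChannels = 16L,
                   dilations = c(1L, 2L, 4L), attentionHeads = 1L,
                   attentionDim = 16L),
      training = list(iterations = 400L, batchSize = 64L, logEvery = 100L)
    )
    cmdSimulate(config)
    cmdTrain(config)
    cache <<- config
    cache
  }
})

test_that("simulate writes a reproducible family with a manifest", {
  config <- workflowFixture()
  outdir <- config$paths$outdir
  fasta <- readLines(file.path(outdir, "family.fasta"))
  expect_equal(sum(startsWith(fasta, ">")), 251L)
  expect_true(file.exists(file.path(outdir, "simulate_manifest.json")))
  # re-running with the same seed is byte-identical
  other <- config
  other$paths$outdir <- file.path(tempdir(), "wf_rerun")
  cmdSimulate(other)
  expect_identical(readLines(file.path(other$paths$outdir, "family.fasta")),
                   fasta)
  bad <- config
  bad$family$gapRate <- 2
  bad$paths$outdir <- tempdir()
  expect_error(cmdSimulate(bad), "gapRate")
})

test_that("train produces both checkpoints, logs and the column map", {
  config <- workflowFixture()
  outdir <- config$paths$outdir
  for (f in c("teacher.rds", "student.rds", "teacher_log.tsv",
              "student_log.tsv", "column_map.tsv", "weights.tsv",
              "train_manifest.json"))
    expect_true(file.exists(file.path(outdir, f)), label = f)
  teacher <- loadModel(file.path(outdir, "teacher.rds"))
  student <- loadModel(file.path(outdir, "student.rds"))
  expect_identical(teacher@columnMapHash, student@columnMapHash)
  # student log carries both loss components
  slog <- read.table(file.path(outdir, "student_log.tsv"), header = TRUE)
  expect_true(all(is.finite(slog$teacher_loss)))
  missing <- config
  missing$paths$alignment <- file.path(tempdir(), "nope.fasta")
  expect_error(cmdTrain(missing), "not found")
})

test_that("teacher-only training skips the student checkpoint", {
  config <- workflowFixture()
  solo <- config
  solo$paths$outdir <- file.path(tempdir(), "wf_solo")
  solo$paths$alignment <- config$paths$alignment
  solo$training$teacherOnly <- TRUE
  solo$training$iterations <- 50L
  cmdTrain(solo)
  expect_true(file.exists(file.path(solo$paths$outdir, "teacher.rds")))
  expect_false(file.exists(file.path(solo$paths$outdir, "student.rds")))
})

test_that("score keeps every input variant and flags exclusions", {
  config <- workflowFixture()
  outdir <- config$paths$outdir
  fam <- sampleFamily(familySpec(L = 12L, N = 250L, alpha = 0.1, seed = 11L))
  wt <- strsplit(fam$truth@wildType, "")[[1]]
  mut <- vapply(wt, function(a) setdiff(c("A", "C", "D"), a)[1], "")
  vars <- c(paste0(wt[2], 2, mut[2]), paste0(wt[5], 5, mut[5]),
            "A99C",                                  # out of range
            paste0(setdiff(LETTERS[1:20], wt[3])[1], 3, "W"))  # wt mismatch
  varFile <- file.path(outdir, "variants.txt")
  writeLines(vars, varFile)
  config$paths$variants <- varFile
  out <- cmdScore(config)
  expect_equal(nrow(out), length(vars))
  expect_identical(out$variant, vars)
  expect_true(all(out$status[1:2] == "scored"))
  expect_match(out$status[3], "out_of_range")
  expect_match(out$status[4], "wild_type_mismatch")
  # without a calibration table, probability and label stay unavailable
  expect_true(all(is.na(out$prob_deleterious)))

  # all-variants mode: exactly 19 rows per scorable focus position
  allCfg <- config
  allCfg$paths$variants <- NULL
  allOut <- cmdScore(allCfg)
  mask <- computeGapMask(fam$msa)
  expect_equal(nrow(allOut), 19L * nrow(mask@colMap))
  expect_equal(mean(allOut$z_score), 0, tolerance = 1e-9)
})

test_that("scoring validates checkpoint provenance against the column map", {
  config <- workflowFixture()
  other <- config
  other$paths$outdir <- file.path(tempdir(), "wf_badck")
  dir.create(other$paths$outdir, showWarnings = FALSE)
  ck <- loadModel(file.path(config$paths$outdir, "student.rds"))
  ck@columnMapHash <- "0000"
  badPath <- file.path(other$paths$outdir, "student.rds")
  saveModel(ck, badPath)
  other$paths$checkpoint <- badPath
  expect_error(cmdScore(other), "column map")
})

test_that("evaluate reports the nine metrics from joined predictions", {
  config <- workflowFixture()
  outdir <- config$paths$outdir
  # calibrate on synthetic labels, then score all variants and evaluate
  fam <- sampleFamily(familySpec(L = 12L, N = 250L, alpha = 0.1, seed = 11L))
  set.seed(2)
  lab <- labelledVariants(fam$truth, 150L)
  calib <- calibrate(lab$z, lab$label, nBins = 10L)
  calPath <- file.path(outdir, "calibration.tsv")
  writeCalibrationTable(calib, calPath)
  config$paths$variants <- NULL
  config$paths$calibration <- calPath
  out <- cmdScore(config)
  expect_true(all(out$predicted_label %in% c("deleterious", "benign")))
  expect_identical(out$predicted_label == "deleterious",
                   out$z_score < calib@zCutoff)

  truthTab <- data.frame(variant = lab$variant, label = lab$label)
  truthPath <- file.path(outdir, "truth.tsv")
  write.table(truthTab[!duplicated(truthTab$variant), ], truthPath,
              sep = "\t", quote = FALSE, row.names = FALSE)
  config$paths$labelled <- truthPath
  metrics <- cmdEvaluate(config)
  expect_named(metrics, c("roc_auc", "pr_auc", "accuracy", "mcc", "precision",
                          "specificity", "sensitivity", "f_score", "npv"))
  expect_true(file.exists(file.path(outdir, "metrics.tsv")))
  # a trained model on a conserved family beats chance comfortably
  expect_gt(metrics["roc_auc"], 0.6)
})

test_that("run configurations round-trip through YAML", {
  config <- list(seed = 3L, family = list(L = 5L, N = 4L),
                 training = list(iterations = 10L))
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, f)
  back <- readRunConfig(f)
  expect_equal(back$seed, 3L)
  expect_equal(back$family$L, 5L)
  expect_error(readRunConfig(tempfile()), "not found")
})
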