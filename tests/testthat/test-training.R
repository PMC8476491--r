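test_that("mini-batch sampling is weighted and reproducible", {
  msa <- proteinMsa(c("AAAA", "CCCC", "DDDD"))
  enc <- encodeMsa(msa, computeGapMask(msa))
  w <- new("SequenceWeights", w = c(1, 1, 1), identityThreshold = 0.8,
           nEff = 3)
  set.seed(1)
  b1 <- sampleMinibatch(enc, w, 10L)
  set.seed(1)
  b2 <- sampleMinibatch(enc, w, 10L)
  expect_identical(b1, b2)
  expect_error(sampleMinibatch(enc, w, 0L), "batchSize")

  # equal weights: empirical frequencies uniform within multinomial error
  set.seed(2)
  big <- sampleMinibatch(enc, w, 100000L)
  freq <- tabulate(big[, 1], 21)[c(1, 2, 3)] # codes A=1, C=2, D=3
  chisq <- sum((freq - 100000 / 3)^2 / (100000 / 3))
  expect_lt(chisq, qchisq(0.999, df = 2))

  # strongly skewed weights: rare sequence drawn at about eps/(1+eps)
  eps <- 0.05
  wSkew <- new("SequenceWeights", w = c(1, eps, 1e-12),
               identityThreshold = 0.8, nEff = 1 + eps + 1e-12)
  set.seed(3)
  draws <- sampleMinibatch(enc, wSkew, 50000L)
  pHat <- mean(draws[, 1] == 2L)
  expect_equal(pHat, eps / (1 + eps + 1e-12), tolerance = 0.15)
})

test_that("label loss matches its closed forms and the likelihood identity", {
  cfg <- tinyConfig()
  m <- buildModel(cfg, seed = 2L)
  x <- c(1L, 2L, 3L, 4L, 2L)
  lp <- conditionalLogProbs(m, x)
  expect_equal(labelLoss(lp, x), -sequenceLogLikelihood(m, x) / 5,
               tolerance = 1e-12)
  # uniform model: log K per position
  m@params$W_out[] <- 0; m@params$b_out[] <- 0
  expect_equal(labelLoss(conditionalLogProbs(m, x), x), log(4),
               tolerance = 1e-12)
  # probability 1 on every target symbol -> loss 0
  onehot <- matrix(log(1e-30), 5, 4)
  onehot[cbind(1:5, x)] <- 0
  expect_equal(labelLoss(onehot, x), 0)
})

test_that("teacher loss reproduces hand-computed distillation values", {
  # softened teacher for logits (2, 0) at T = 4
  pt <- temperedSoftmax(c(2, 0), 4)
  expect_equal(round(pt, 4), c(0.6225, 0.3775))
  # student == teacher (both softened): cross-entropy hits the entropy floor
  tl <- teacherLoss(matrix(c(2, 0), 1), matrix(c(2, 0), 1), temperature = 4)
  expect_equal(tl, -sum(pt * log(pt)), tolerance = 1e-12)
  # hand evaluation against an arbitrary student, un-softened student side
  sLogits <- matrix(c(1, -1), 1)
  q <- temperedSoftmax(c(1, -1), 1)
  tl2 <- teacherLoss(sLogits, matrix(c(2, 0), 1), temperature = 4,
                     distillStudentTemperature = FALSE)
  expect_equal(tl2, -sum(pt * log(q)), tolerance = 1e-12)
  # uniform teacher: minimized (= log K) by the uniform student
  tl3 <- teacherLoss(matrix(0, 1, 3), matrix(0, 1, 3))
  expect_equal(tl3, log(3), tolerance = 1e-12)
  expect_error(teacherLoss(sLogits, sLogits, temperature = -1), "temperature")
})

test_that("the learning rate switches from 0.001 to 0.0001 at iteration 3000", {
  msa <- proteinMsa(rep(c("ACDE", "ACDF"), 3))
  enc <- encodeMsa(msa, computeGapMask(msa))
  w <- computeSequenceWeights(enc)
  cfg <- modelConfig(seqLength = 4L, embeddingDim = 4L, convChannels = 6L,
                     dilations = 1L, attentionHeads = 0L)
  tc <- trainingConfig(iterations = 3002L, batchSize = 4L, seed = 1,
                       logEvery = 1L)
  fit <- trainTeacher(buildModel(cfg, 1L), enc, w, tc)
  log <- fit$log
  expect_equal(log$lr[log$iteration == 2999], 0.001)
  expect_equal(log$lr[log$iteration == 3000], 0.0001)
  expect_equal(log$lr[log$iteration == 3002], 0.0001)
  expect_true(all(diff(log$iteration) > 0))
})

test_that("teacher training converges on a degenerate single-sequence family", {
  msa <- proteinMsa(rep("ACDEFGHIKL", 8))
  enc <- encodeMsa(msa, computeGapMask(msa))
  w <- computeSequenceWeights(enc)
  cfg <- modelConfig(seqLength = 10L, embeddingDim = 8L, convChannels = 12L,
                     dilations = c(1L, 2L), attentionHeads = 1L,
                     attentionDim = 12L)
  tc <- trainingConfig(iterations = 600L, batchSize = 8L, seed = 3,
                       logEvery = 100L)
  fit <- trainTeacher(buildModel(cfg, 3L), enc, w, tc)
  expect_lt(tail(fit$log$label_loss, 1), head(fit$log$label_loss, 1))
  expect_lt(tail(fit$log$label_loss, 1), 0.5)
})

test_that("training is reproducible and the student leaves the teacher frozen", {
  fix <- scoredFamilyFixture()
  cfg <- fix$model@config
  tc <- trainingConfig(iterations = 60L, batchSize = 32L, seed = 5,
                       logEvery = 20L)
  f1 <- trainTeacher(buildModel(cfg, 5L), fix$enc, fix$w, tc)
  f2 <- trainTeacher(buildModel(cfg, 5L), fix$enc, fix$w, tc)
  expect_identical(f1$model@params, f2$model@params)
  expect_identical(f1$log, f2$log)

  teacherBefore <- banvep:::paramHash(fix$model@params)
  student <- buildModel(cfg, seed = 99L)
  sFit <- trainStudent(student, fix$model, fix$enc, fix$w, tc)
  expect_identical(banvep:::paramHash(fix$model@params), teacherBefore)
  # same capacity by construction
  expect_identical(vapply(sFit$model@params, length, 1L),
                   vapply(fix$model@params, length, 1L))
  # both loss components are reported at every checkpoint
  expect_true(all(is.finite(sFit$log$teacher_loss)))
  expect_true(all(is.finite(sFit$log$label_loss)))

  # configuration mismatch is rejected
  other <- buildModel(tinyConfig(), seed = 1L)
  expect_error(trainStudent(other, fix$model, fix$enc, fix$w, tc),
               "same configuration")
})

test_that("distillation pulls the student toward the softened teacher", {
  # an untrained student trained ONLY against a fixed teacher's softened
  # outputs (no data signal beyond the shared label loss) reduces the
  # teacher-loss component over training
  fix <- scoredFamilyFixture()
  cfg <- fix$model@config
  tc <- trainingConfig(iterations = 300L, batchSize = 32L, seed = 6,
                       logEvery = 50L)
  sFit <- trainStudent(buildModel(cfg, 77L), fix$model, fix$enc, fix$w, tc)
  expect_lt(tail(sFit$log$teacher_loss, 1), head(sFit$log$teacher_loss, 1))
})
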