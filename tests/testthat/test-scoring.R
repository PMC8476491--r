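test_that("log-probability scores are exact on a site-independent oracle model", {
  # column profiles are the model's conditionals, so the score must equal
  # the closed-form log ratio of profile probabilities
  prof <- rbind(c(0.7, 0.1, 0.1, 0.1),
                c(0.25, 0.25, 0.25, 0.25),
                c(0.05, 0.05, 0.6, 0.3))
  m <- profileOracleModel(log(prof))
  wt <- c(1L, 2L, 3L)   # profile argmax per row
  enc <- new("EncodedMsa", matrix = matrix(wt, 1), alphabet = c("A", "C", "D", "E"),
             focusRow = wt, keptColumns = 1:3,
             colMap = data.frame(retained = 1:3, original = 1:3, focusPos = 1:3))
  # pi(wt) = 0.7, pi(mut) = 0.1 -> log(1/7)
  expect_equal(logProbScore(m, enc, 1L, 2L), log(0.1 / 0.7), tolerance = 1e-10)
  expect_equal(round(logProbScore(m, enc, 1L, 2L), 4), -1.9459)
  # wild type against itself scores zero
  expect_equal(logProbScore(m, enc, 1L, 1L), 0)
  # full closed-form sweep over every substitution at every column
  for (cidx in 1:3) for (mut in 1:4) {
    expect_equal(logProbScore(m, enc, cidx, mut),
                 log(prof[cidx, mut]) - log(prof[cidx, wt[cidx]]),
                 tolerance = 1e-10)
  }
})

test_that("the all-variant z-score table is complete and standardized", {
  fix <- scoredFamilyFixture()
  tab <- zscoreAllVariants(fix$model, fix$enc)
  expect_equal(nrow(tab), 19L * nrow(fix$enc@colMap))
  expect_equal(mean(tab$z_score), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(tab$z_score^2)), 1, tolerance = 1e-9)
  # z is a monotone transform of the raw score
  expect_equal(order(tab$z_score), order(tab$log_prob_score))
  expect_identical(which.min(tab$z_score), which.min(tab$log_prob_score))
  # z-scores recompute from the raw scores with the population sd
  mu <- mean(tab$log_prob_score)
  sdev <- sqrt(mean((tab$log_prob_score - mu)^2))
  expect_equal(tab$z_score, (tab$log_prob_score - mu) / sdev,
               tolerance = 1e-12)
})

test_that("population z-scores of a toy multiset match the closed form", {
  s <- c(-2, 0, 2)
  z <- (s - mean(s)) / sqrt(mean((s - mean(s))^2))
  expect_equal(round(z, 4), c(-1.2247, 0, 1.2247))
})

test_that("calibration bins count labelled deleterious proportions", {
  # 4 points, 2 bins: (-2, -1 | 1, 2) with labels (D, D | B, B)
  tab <- calibrate(c(-2, -1, 1, 2), c("deleterious", "deleterious",
                                      "benign", "benign"), nBins = 2L)
  expect_equal(tab@proportionDeleterious, c(1, 0))
  expect_equal(tab@nPerBin, c(2L, 2L))
  expect_equal(diff(tab@binEdges), rep(2, 2))
  # a bin of only deleterious variants has proportion 1
  expect_equal(tab@proportionDeleterious[1], 1)
  expect_error(calibrate(rep(1, 4), c("deleterious", "deleterious",
                                      "benign", "benign")), "distinct")
  expect_error(calibrate(1:4, rep("benign", 4)), "both")
})

test_that("empty calibration bins inherit the nearest lower proportion", {
  # z = 0..1 and 9..10 with 10 bins over [0,10]: bins 2..9 are empty
  z <- c(seq(0, 1, length.out = 8), seq(9, 10, length.out = 8))
  lab <- c(rep("deleterious", 8), rep("benign", 8))
  tab <- calibrate(z, lab, nBins = 10L)
  expect_equal(tab@proportionDeleterious[1], 1)
  expect_equal(tab@proportionDeleterious[10], 0)
  # empty bins take the nearest filled bin, lower side winning ties:
  # bins up to the midpoint inherit 1, bins nearer the benign end inherit 0
  expect_true(all(tab@proportionDeleterious[2:6] == 1))
  expect_true(all(tab@proportionDeleterious[7:9] == 0))
})

test_that("labels independent of z give flat proportions near 0.5", {
  set.seed(21)
  z <- rnorm(4000)
  lab <- ifelse(runif(4000) < 0.5, "deleterious", "benign")
  tab <- calibrate(z, lab, nBins = 8L)
  heavy <- tab@nPerBin >= 100L
  expect_true(all(abs(tab@proportionDeleterious[heavy] - 0.5) < 0.1))
  # accuracy of the selected cutoff stays near chance
  acc <- mean((z < tab@zCutoff) == (lab == "deleterious"))
  expect_lt(abs(acc - 0.5), 0.05)
})

test_that("the selected cutoff maximizes accuracy over all bin edges", {
  set.seed(8)
  z <- c(rnorm(300, -1.5), rnorm(300, 1.5))
  lab <- c(rep("deleterious", 300), rep("benign", 300))
  tab <- calibrate(z, lab, nBins = 12L)
  accs <- vapply(tab@binEdges,
                 function(e) mean((z < e) == (lab == "deleterious")),
                 numeric(1))
  expect_equal(mean((z < tab@zCutoff) == (lab == "deleterious")), max(accs))
  # smallest maximizing edge wins ties
  expect_equal(tab@zCutoff, tab@binEdges[which.max(accs)])

  # perfectly separated classes reach accuracy 1
  z2 <- c(-(5:1), 1:5)
  lab2 <- rep(c("deleterious", "benign"), each = 5)
  tab2 <- calibrate(z2, lab2, nBins = 5L)
  expect_equal(mean((z2 < tab2@zCutoff) == (lab2 == "deleterious")), 1)
})

test_that("prediction clamps out-of-range z and applies the strict cutoff rule", {
  tab <- new("CalibrationTable", binEdges = c(-1, 0, 1),
             proportionDeleterious = c(0.9, 0.2), nPerBin = c(5L, 5L),
             zCutoff = 0)
  sc <- data.frame(z_score = c(-50, -0.5, 0, 0.5, 50))
  out <- predictVariants(sc, tab)
  expect_equal(out$prob_deleterious, c(0.9, 0.9, 0.2, 0.2, 0.2))
  # z exactly at the cutoff is benign (strict inequality)
  expect_equal(out$predicted_label,
               c("deleterious", "deleterious", "benign", "benign", "benign"))
  # the label invariant holds row-wise
  expect_identical(out$predicted_label == "deleterious",
                   out$z_score < tab@zCutoff)
})

test_that("calibration tables round-trip through their text format", {
  set.seed(4)
  z <- rnorm(200)
  lab <- ifelse(z + rnorm(200) < 0, "deleterious", "benign")
  tab <- calibrate(z, lab, nBins = 6L)
  f <- tempfile(fileext = ".tsv")
  writeCalibrationTable(tab, f)
  tab2 <- readCalibrationTable(f)
  expect_equal(tab2@binEdges, tab@binEdges, tolerance = 1e-6)
  expect_equal(tab2@proportionDeleterious, tab@proportionDeleterious,
               tolerance = 1e-6)
  expect_equal(tab2@zCutoff, tab@zCutoff, tolerance = 1e-9)
})
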