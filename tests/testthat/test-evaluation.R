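## Independent brute-force oracle for the six metrics, written against
## the printed formulas and kept separate from the implementation.
bruteMetrics <- function(TP, TN, FP, FN) {
  n <- TP + TN + FP + FN
  list(accuracy = (TP + TN) / n,
       f1 = TP / (TP + 0.5 * (FP + FN)),
       mcc = (TP * TN - FP * FN) /
         sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)),
       precision = TP / (TP + FP),
       recall = TP / (TP + FN))
}

## O(n^2) pairwise AUROC oracle: P(score_pos > score_neg) + half ties.
bruteAuroc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

test_that("confusion counts partition the items", {
  cc <- confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_identical(cc, list(TP = 1L, FP = 1L, TN = 1L, FN = 1L))
  allRight <- confusionCounts(c("lncRNA", "non-lncRNA"),
                              c("lncRNA", "non-lncRNA"))
  expect_identical(allRight$FP + allRight$FN, 0L)
  expect_error(confusionCounts(integer(), integer()), "empty")
  expect_error(confusionCounts(c(1, 0), c(1)), "equal length")
})

test_that("metric formulas match hand-substituted values", {
  m <- computeMetrics(list(TP = 8L, TN = 7L, FP = 2L, FN = 3L))
  expect_equal(m$accuracy, 15 / 20, tolerance = 1e-12)
  m2 <- computeMetrics(list(TP = 8L, TN = 7L, FP = 2L, FN = 3L))
  expect_equal(m2$f1, 8 / 10.5, tolerance = 1e-12)
  expect_equal(m2$precision, 0.8, tolerance = 1e-12)
  expect_equal(m2$recall, 8 / 11, tolerance = 1e-12)
  perfect <- computeMetrics(list(TP = 5L, TN = 5L, FP = 0L, FN = 0L))
  expect_equal(perfect$mcc, 1, tolerance = 1e-12)
  flat <- computeMetrics(list(TP = 5L, TN = 5L, FP = 5L, FN = 5L))
  expect_equal(flat$mcc, 0, tolerance = 1e-12)
})

test_that("metrics match the brute-force oracle on random tables", {
  set.seed(101)
  for (i in seq_len(200L)) {
    cc <- as.list(stats::setNames(sample(1:50, 4L, TRUE),
                                  c("TP", "TN", "FP", "FN")))
    got <- computeMetrics(cc)
    want <- bruteMetrics(cc$TP, cc$TN, cc$FP, cc$FN)
    for (f in names(want))
      expect_equal(got[[f]], want[[f]], tolerance = 1e-12)
  }
})

test_that("degenerate denominators yield 0 with a warning", {
  expect_warning(
    m <- computeMetrics(list(TP = 0L, TN = 10L, FP = 0L, FN = 5L)),
    "degenerate")
  expect_identical(m$precision, 0)
})

test_that("weighted averaging reproduces the precision=recall=accuracy
           signature on symmetric errors", {
  ## with balanced support, weighted recall equals accuracy
  cc <- list(TP = 30L, FN = 20L, TN = 35L, FP = 15L)
  m <- computeMetrics(cc, average = "weighted")
  expect_equal(m$recall, m$accuracy, tolerance = 1e-12)
})

test_that("AUROC handles separation, ties, and matches the O(n^2) oracle", {
  expect_equal(aurocScore(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(aurocScore(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_equal(aurocScore(rep(0.7, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(aurocScore(c(0.1, 0.2), c(1, 1)), "both classes")
  set.seed(7)
  for (i in seq_len(200L)) {
    n <- sample(10:60, 1L)
    truth <- c(1, 0, sample(0:1, n - 2L, TRUE))
    scores <- round(stats::runif(n), sample(1:3, 1L))  # force ties
    expect_equal(aurocScore(scores, truth), bruteAuroc(scores, truth),
                 tolerance = 1e-12)
  }
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(8)
  truth <- sample(0:1, 50L, TRUE)
  truth[1:2] <- c(0, 1)
  scores <- stats::runif(50L)
  base <- aurocScore(scores, truth)
  expect_equal(aurocScore(stats::qlogis(scores * 0.98 + 0.01), truth),
               base, tolerance = 1e-12)
  expect_equal(aurocScore(scores^3, truth), base, tolerance = 1e-12)
})

test_that("MCC is symmetric under simultaneous class swap", {
  set.seed(9)
  for (i in seq_len(20L)) {
    truth <- sample(0:1, 40L, TRUE)
    pred <- sample(0:1, 40L, TRUE)
    truth[1:4] <- c(0, 1, 0, 1); pred[1:4] <- c(0, 1, 1, 0)
    m1 <- computeMetrics(confusionCounts(truth, pred))
    m2 <- computeMetrics(confusionCounts(1 - truth, 1 - pred))
    expect_equal(m1$mcc, m2$mcc, tolerance = 1e-12)
  }
})

test_that("cross-species harness: label symmetry and exact aggregation", {
  ds <- makeSeparableDataset(nPerClass = 10L, len = 60L, seed = 41L)
  ## untrained (initialization) models are cheap and deterministic
  cfgA <- tinyClassifierConfig(maxSeqLength = 64L, epochs = 0, seed = 1L)
  cfgB <- tinyClassifierConfig(maxSeqLength = 64L, epochs = 0, seed = 2L)
  mA <- trainKmerClassifier(ds, cfgA)
  mB <- trainKmerClassifier(ds, cfgB)
  swapped <- lncDataset(datasetSequences(ds),
                        label = ifelse(datasetLabels(ds) == "lncRNA",
                                       "non-lncRNA", "lncRNA"),
                        species = "simB",
                        coreStart = 0L, coreEnd = 60L, flank = 0L)
  accA <- evaluateClassifier(mA, ds)$accuracy
  accSwap <- evaluateClassifier(mA, swapped)$accuracy
  expect_equal(accSwap, 1 - accA, tolerance = 1e-12)

  res <- crossSpeciesEvaluate(
    models = list(a = mA, b = mB),
    testSets = list(a = ds, b = swapped, c = ds),
    groups = c(a = "monocot", b = "dicot", c = "dicot"))
  expect_identical(nrow(res$pairs), 6L)
  cross <- res$pairs[res$pairs$trained_species !=
                       res$pairs$test_species, ]
  for (gp in res$groupAverages$group_pair) {
    member <- cross$accuracy[cross$group_pair == gp]
    expect_equal(
      res$groupAverages$mean_accuracy[
        res$groupAverages$group_pair == gp],
      mean(member), tolerance = 1e-12)
  }
  expect_error(
    crossSpeciesEvaluate(list(a = mA), list(b = swapped),
                         groups = c(a = "monocot")),
    "missing group")
})

test_that("k-mer sweep trains one model per k and picks the best", {
  ds <- makeSeparableDataset(nPerClass = 12L, len = 60L, seed = 61L)
  sp <- splitDataset(ds, 0.25, seed = 61L)
  sw <- suppressWarnings(sweepKmerSizes(
    sp$train, sp$test, ks = c(3L, 4L),
    config = tinyClassifierConfig(maxSeqLength = 64L, epochs = 1,
                                  seed = 8L)))
  expect_identical(sw$metrics$k, c(3L, 4L))
  expect_identical(names(sw$models), c("3", "4"))
  expect_true(sw$bestK %in% c(3L, 4L))
  expect_identical(sw$models[["4"]]@config$k, 4L)
  expect_true(all(sw$metrics$accuracy >= 0 & sw$metrics$accuracy <= 1))
})
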