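## Six-metric evaluation (accuracy, AUROC, F1, MCC, precision, recall),
## confusion counts, and the cross-species / monocot-dicot transfer
## harness. The lncRNA class is positive throughout.

#' Confusion counts for binary lncRNA prediction
#'
#' @param truth,predicted vectors of equal length; either
#'   `"lncRNA"`/`"non-lncRNA"` strings, logicals, or 0/1 with 1 =
#'   lncRNA.
#' @return named list with `TP`, `FP`, `TN`, `FN`; the counts partition
#'   the items.
#' @examples
#' confusionCounts(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusionCounts <- function(truth, predicted) {
  t <- asPositive(truth)
  p <- asPositive(predicted)
  if (length(t) != length(p))
    stop("truth and predicted must have equal length")
  if (length(t) == 0L) stop("empty input")
  list(TP = sum(t & p), FP = sum(!t & p),
       TN = sum(!t & !p), FN = sum(t & !p))
}

asPositive <- function(x) {
  if (is.character(x) || is.factor(x)) as.character(x) == "lncRNA"
  else as.logical(as.integer(x))
}

#' Compute the six evaluation metrics from confusion counts
#'
#' Implements, for the positive (lncRNA) class:
#' \deqn{accuracy = (TP+TN)/(TP+TN+FP+FN)}
#' \deqn{F1 = TP / (TP + (FP+FN)/2)}
#' \deqn{MCC = (TP TN - FP FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' \deqn{precision = TP/(TP+FP), \quad recall = TP/(TP+FN)}
#' AUROC is computed only when scores are supplied. A degenerate
#' denominator yields 0 for that metric with a warning, so model sweeps
#' keep running. `average = "weighted"` instead averages the per-class
#' one-vs-rest F1/precision/recall weighted by class support.
#'
#' @param counts list with `TP`, `FP`, `TN`, `FN` from
#'   [confusionCounts()].
#' @param scores optional data.frame/list with `p_lncRNA` and `truth`
#'   (any encoding accepted by [confusionCounts()]) for AUROC.
#' @param average `"binary"` (positive class, as printed above) or
#'   `"weighted"`.
#' @return named list: `accuracy`, `auroc` (NA without scores), `f1`,
#'   `mcc`, `precision`, `recall`, `counts`, `n`.
#' @examples
#' computeMetrics(list(TP = 8, TN = 7, FP = 2, FN = 3))$accuracy  # 0.75
#' @export
computeMetrics <- function(counts, scores = NULL,
                           average = c("binary", "weighted")) {
  average <- match.arg(average)
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  n <- TP + FP + TN + FN
  if (n == 0L) stop("no evaluated items")
  safeDiv <- function(num, den, what) {
    if (den == 0) {
      warning("degenerate denominator for ", what, "; reporting 0",
              call. = FALSE)
      0
    } else num / den
  }
  prf <- function(tp, fp, fn) {
    c(precision = safeDiv(tp, tp + fp, "precision"),
      recall = safeDiv(tp, tp + fn, "recall"),
      f1 = safeDiv(tp, tp + (fp + fn) / 2, "F1"))
  }
  if (average == "binary") {
    m <- prf(TP, FP, FN)
  } else {
    pos <- prf(TP, FP, FN)
    neg <- prf(TN, FN, FP)
    wPos <- (TP + FN) / n
    m <- wPos * pos + (1 - wPos) * neg
  }
  mccDen <- sqrt(as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  mcc <- if (mccDen == 0) {
    warning("degenerate denominator for MCC; reporting 0", call. = FALSE)
    0
  } else (as.numeric(TP) * TN - as.numeric(FP) * FN) / mccDen
  auroc <- NA_real_
  if (!is.null(scores))
    auroc <- aurocScore(scores$p_lncRNA, scores$truth)
  list(accuracy = (TP + TN) / n, auroc = auroc,
       f1 = unname(m["f1"]), mcc = mcc,
       precision = unname(m["precision"]),
       recall = unname(m["recall"]),
       counts = counts, n = n)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator with tie averaging, equivalent to
#' the trapezoidal area under the curve of true-positive rate versus
#' false-positive rate over all score thresholds.
#'
#' @param scores numeric vector of `p_lncRNA` scores.
#' @param truth class labels (any encoding accepted by
#'   [confusionCounts()]); both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @examples
#' aurocScore(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))   # 1
#' aurocScore(rep(0.5, 4), c(1, 1, 0, 0))             # 0.5 under ties
#' @export
aurocScore <- function(scores, truth) {
  pos <- asPositive(truth)
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos == 0L || nNeg == 0L)
    stop("AUROC requires both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Evaluate a classifier on a labelled dataset
#'
#' Runs [predictKmerClassifier()] and assembles the full
#' [computeMetrics()] report including AUROC.
#'
#' @param model a [KmerClassifier-class].
#' @param dataset a labelled [LncDataset-class].
#' @param average metric averaging mode, see [computeMetrics()].
#' @return list as returned by [computeMetrics()], plus `predictions`.
#' @export
evaluateClassifier <- function(model, dataset,
                               average = c("binary", "weighted")) {
  preds <- predictKmerClassifier(model, dataset)
  counts <- confusionCounts(preds$label, preds$predicted_label)
  rep <- computeMetrics(counts,
                        scores = list(p_lncRNA = preds$p_lncRNA,
                                      truth = preds$label),
                        average = match.arg(average))
  rep$predictions <- preds
  rep
}

#' Sweep k-mer sizes and compare fitted models
#'
#' Trains one classifier per k in `ks` (same hyperparameters otherwise)
#' and evaluates each on the held-out set, mirroring the protocol of
#' choosing the best k per species by test accuracy.
#'
#' @param train,test labelled [LncDataset-class] partitions.
#' @param ks integer vector of k-mer sizes to try (subset of 3..6).
#' @param config base configuration; its `k` is overridden per sweep
#'   point.
#' @return list with `metrics` (data.frame: k, accuracy, auroc, f1,
#'   mcc, precision, recall), `models` (named list of fitted
#'   classifiers) and `bestK` (highest accuracy, ties to smaller k).
#' @export
sweepKmerSizes <- function(train, test, ks = 3:6,
                           config = tinyClassifierConfig()) {
  rows <- list(); models <- list()
  for (k in ks) {
    cfg <- utils::modifyList(config, list(k = as.integer(k),
                                          vocabSize = 5L + 4L^as.integer(k)))
    m <- trainKmerClassifier(train, cfg)
    rep <- evaluateClassifier(m, test)
    models[[as.character(k)]] <- m
    rows[[as.character(k)]] <- data.frame(
      k = as.integer(k), accuracy = rep$accuracy, auroc = rep$auroc,
      f1 = rep$f1, mcc = rep$mcc, precision = rep$precision,
      recall = rep$recall)
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  list(metrics = metrics, models = models,
       bestK = metrics$k[which.max(metrics$accuracy)])
}

#' Cross-species evaluation with monocot/dicot aggregation
#'
#' Every fitted model predicts the held-out set of every other species
#' (self pairs are evaluated too but excluded from group averages), and
#' pair accuracies are aggregated by lineage group: monocot-monocot,
#' dicot-dicot, monocot-dicot and dicot-monocot means.
#'
#' @param models named list of [KmerClassifier-class], one per trained
#'   species.
#' @param testSets named list of labelled [LncDataset-class], one per
#'   test species.
#' @param groups named character vector mapping every species in
#'   `models`/`testSets` to `"monocot"` or `"dicot"`.
#' @return list with `pairs` (data.frame: trained_species, test_species,
#'   group_pair, the six metrics) and `groupAverages` (data.frame:
#'   group_pair, mean_accuracy, n_pairs).
#' @export
crossSpeciesEvaluate <- function(models, testSets, groups) {
  species <- union(names(models), names(testSets))
  missing <- setdiff(species, names(groups))
  if (length(missing))
    stop("missing group assignment for: ",
         paste(missing, collapse = ", "))
  if (!all(groups[species] %in% c("monocot", "dicot")))
    stop("groups must be 'monocot' or 'dicot'")
  rows <- list()
  for (tr in names(models)) {
    for (te in names(testSets)) {
      rep <- evaluateClassifier(models[[tr]], testSets[[te]])
      rows[[length(rows) + 1L]] <- data.frame(
        trained_species = tr, test_species = te,
        group_pair = paste0(groups[[tr]], "-", groups[[te]]),
        accuracy = rep$accuracy, auroc = rep$auroc, f1 = rep$f1,
        mcc = rep$mcc, precision = rep$precision, recall = rep$recall,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  cross <- pairs[pairs$trained_species != pairs$test_species, ,
                 drop = FALSE]
  groupAverages <- if (nrow(cross)) {
    agg <- stats::aggregate(accuracy ~ group_pair, data = cross, mean)
    cnt <- stats::aggregate(accuracy ~ group_pair, data = cross, length)
    data.frame(group_pair = agg$group_pair,
               mean_accuracy = agg$accuracy, n_pairs = cnt$accuracy,
               stringsAsFactors = FALSE)
  } else data.frame(group_pair = character(), mean_accuracy = numeric(),
                    n_pairs = integer())
  list(pairs = pairs, groupAverages = groupAverages)
}
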