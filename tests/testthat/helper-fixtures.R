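## Shared fixture builders. Everything is generated in code at test time.

randomDNA <- function(n, len, gc = 0.5, seed = NULL) {
  draw <- function() {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    vapply(seq_len(n), function(i)
      paste(sample(names(probs), len, TRUE, prob = probs),
            collapse = ""), character(1L))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

## Balanced two-class set where positives carry `motif` at a random
## offset; the classifier can only separate classes via that planting.
makeSeparableDataset <- function(nPerClass = 50L, len = 120L,
                                 motif = "AAAAAAAA", seed = 7L,
                                 species = "sim") {
  withr::with_seed(seed, {
    seqs <- randomDNA(2L * nPerClass, len)
    for (i in seq_len(nPerClass)) {
      pos <- sample.int(len - nchar(motif) + 1L, 1L)
      substr(seqs[i], pos, pos + nchar(motif) - 1L) <- motif
    }
    names(seqs) <- sprintf("s%04d", seq_along(seqs))
    lncDataset(Biostrings::DNAStringSet(seqs),
               label = rep(c("lncRNA", "non-lncRNA"), each = nPerClass),
               species = species, coreStart = 0L, coreEnd = len,
               flank = 0L)
  })
}

## A tiny trained model on the separable fixture, built once per test
## run and reused wherever a fitted classifier is needed.
.fixtureCache <- new.env(parent = emptyenv())

separableModel <- function() {
  if (is.null(.fixtureCache$model)) {
    ds <- makeSeparableDataset(nPerClass = 60L, len = 120L)
    cfg <- tinyClassifierConfig(maxSeqLength = 128L, epochs = 25,
                                loggingSteps = 500L, seed = 3L)
    .fixtureCache$model <- trainKmerClassifier(ds, cfg)
    .fixtureCache$dataset <- ds
  }
  list(model = .fixtureCache$model, dataset = .fixtureCache$dataset)
}
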