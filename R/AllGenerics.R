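#' @importClassesFrom Biostrings DNAStringSet
NULL

#' Accessors for LncDataset
#'
#' @param x an [LncDataset-class].
#' @return `datasetSequences` returns the [Biostrings::DNAStringSet];
#'   `datasetLabels` the label factor; `datasetSpecies` the species tags;
#'   `coreSpans` a data.frame of 0-based half-open `start`/`end` offsets
#'   of the unflanked core within each sequence; `flankLength` the
#'   nominal flank in bases.
#' @examples
#' ds <- lncDataset(
#'   sequences = Biostrings::DNAStringSet(c(a = "ACGTACGTACGT")),
#'   label = "lncRNA", species = "sim", coreStart = 4L, coreEnd = 8L,
#'   flank = 4L)
#' datasetLabels(ds)
#' coreSpans(ds)
#' @name LncDataset-accessors
NULL

#' @rdname LncDataset-accessors
#' @export
setGeneric("datasetSequences", function(x) standardGeneric("datasetSequences"))
#' @rdname LncDataset-accessors
#' @export
setGeneric("datasetLabels", function(x) standardGeneric("datasetLabels"))
#' @rdname LncDataset-accessors
#' @export
setGeneric("datasetSpecies", function(x) standardGeneric("datasetSpecies"))
#' @rdname LncDataset-accessors
#' @export
setGeneric("coreSpans", function(x) standardGeneric("coreSpans"))
#' @rdname LncDataset-accessors
#' @export
setGeneric("flankLength", function(x) standardGeneric("flankLength"))

#' @rdname LncDataset-accessors
setMethod("datasetSequences", "LncDataset", function(x) x@sequences)
#' @rdname LncDataset-accessors
setMethod("datasetLabels", "LncDataset", function(x) x@label)
#' @rdname LncDataset-accessors
setMethod("datasetSpecies", "LncDataset", function(x) x@species)
#' @rdname LncDataset-accessors
setMethod("coreSpans", "LncDataset", function(x)
  data.frame(id = names(x@sequences), start = x@coreStart, end = x@coreEnd))
#' @rdname LncDataset-accessors
setMethod("flankLength", "LncDataset", function(x) x@flank)

#' @describeIn LncDataset-accessors number of sequences in the dataset.
#' @export
setMethod("length", "LncDataset", function(x) length(x@sequences))

#' @describeIn LncDataset-accessors sequence identifiers.
#' @export
setMethod("names", "LncDataset", function(x) names(x@sequences))

#' @describeIn LncDataset-accessors subset a dataset by index, id or
#'   logical mask.
#' @param i index vector.
#' @param j,drop,... ignored; present for generic compatibility.
#' @export
setMethod("[", "LncDataset", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@sequences))
  new("LncDataset",
      sequences = x@sequences[i],
      label = x@label[i],
      species = x@species[i],
      coreStart = x@coreStart[i],
      coreEnd = x@coreEnd[i],
      flank = x@flank)
})

#' Combine datasets with identical flank length
#'
#' @param x,... [LncDataset-class] objects to concatenate.
#' @return the concatenated [LncDataset-class].
#' @export
setMethod("c", "LncDataset", function(x, ...) {
  rest <- list(...)
  for (y in rest) {
    if (y@flank != x@flank)
      stop("cannot combine datasets with different flank lengths")
    x <- new("LncDataset",
             sequences = c(x@sequences, y@sequences),
             label = factor(c(as.character(x@label), as.character(y@label)),
                            levels = c("lncRNA", "non-lncRNA")),
             species = c(x@species, y@species),
             coreStart = c(x@coreStart, y@coreStart),
             coreEnd = c(x@coreEnd, y@coreEnd),
             flank = x@flank)
  }
  x
})

setMethod("show", "LncDataset", function(object) {
  n <- length(object)
  tab <- table(object@label)
  cat(sprintf("LncDataset with %d sequence(s): %d lncRNA, %d non-lncRNA\n",
              n, tab[["lncRNA"]], tab[["non-lncRNA"]]))
  cat(sprintf("  species: %s\n",
              paste(unique(object@species), collapse = ", ")))
  cat(sprintf("  flank: %d bp; width range: %s\n", object@flank,
              if (n) paste(range(Biostrings::width(object@sequences)),
                           collapse = "-") else "NA"))
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat(sprintf("  %d chromosome(s) x %d bp, GC %.2f\n",
              object@nChromosomes, object@chromosomeLength,
              object@gcContent))
  cat(sprintf("  %d loci of %d-%d bp, min gap %d bp\n", object@nLoci,
              object@locusLengthRange[1L], object@locusLengthRange[2L],
              object@minGap))
  cat(sprintf("  flank motifs [%s], insert prob %.2f, window %d bp\n",
              paste(object@flankMotifs, collapse = ", "),
              object@motifInsertProbability, object@motifWindow))
  cat(sprintf("  seed %d\n", object@seed))
})

setMethod("show", "KmerVocab", function(object) {
  cat(sprintf("KmerVocab: k = %d, %d tokens (4^%d k-mers + 5 specials)\n",
              object@k, length(object@tokens), object@k))
})

setMethod("show", "KmerClassifier", function(object) {
  cfg <- object@config
  cat(sprintf(
    "KmerClassifier: k = %d, %d layer(s) x %d dim x %d head(s), max %d tokens\n",
    cfg$k, cfg$nLayers, cfg$hiddenDim, cfg$nHeads, cfg$maxSeqLength))
  if (!is.null(object@trainingLog) && nrow(object@trainingLog)) {
    last <- object@trainingLog[nrow(object@trainingLog), ]
    cat(sprintf("  trained %d step(s); final train loss %.4f\n",
                last$step, last$train_loss))
    if (!is.na(last$eval_accuracy))
      cat(sprintf("  last eval: loss %.4f, accuracy %.3f\n",
                  last$eval_loss, last$eval_accuracy))
  } else {
    cat("  untrained (initialization weights)\n")
  }
})
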