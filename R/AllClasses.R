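## Central S4 containers. Interval coordinates are handled 0-based,
## half-open everywhere inside the package; GTF readers/writers convert
## to/from the 1-based inclusive GTF convention.

setClassUnion("DataFrameOrNull", c("data.frame", "NULL"))

#' Simulation configuration for synthetic genomes with planted lncRNA loci
#'
#' Parameters of the seeded simulator: background composition, number and
#' length of chromosomes, number and length range of planted lncRNA loci,
#' and the flank-motif grammar (which motifs are written into the flanking
#' windows of each locus, and with what probability).
#'
#' @slot nChromosomes number of chromosomes to simulate.
#' @slot chromosomeLength length of each chromosome in bases.
#' @slot gcContent fraction of G+C in the background, in `[0, 1]`; bases
#'   are drawn i.i.d. with `P(G) = P(C) = gc/2`.
#' @slot nLoci number of non-overlapping lncRNA loci to plant.
#' @slot locusLengthRange integer vector `c(min, max)` of locus lengths;
#'   the minimum must be at least 201 bases (lncRNAs are transcripts
#'   longer than 200 nucleotides).
#' @slot flankMotifs character vector of motifs over `{A,C,G,T}` planted
#'   in the flanking windows of each locus.
#' @slot motifInsertProbability per-flank probability that each motif is
#'   written into a flanking window.
#' @slot motifWindow width in bases of the window adjacent to each locus
#'   boundary within which motifs are planted (upstream window ends at the
#'   locus start; downstream window begins at the locus end).
#' @slot minGap minimum number of bases between planted loci (and between
#'   a locus and a chromosome end), so that flanking windows of
#'   neighbouring loci do not collide.
#' @slot seed integer seed; identical seed and configuration give
#'   byte-identical simulation output.
#' @seealso [simConfig()], [simulateGenome()], [plantLoci()]
#' @exportClass SimConfig
setClass("SimConfig", representation(
  nChromosomes = "integer",
  chromosomeLength = "integer",
  gcContent = "numeric",
  nLoci = "integer",
  locusLengthRange = "integer",
  flankMotifs = "character",
  motifInsertProbability = "numeric",
  motifWindow = "integer",
  minGap = "integer",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nChromosomes < 1L) msg <- c(msg, "nChromosomes must be >= 1")
  if (object@chromosomeLength < 1L) msg <- c(msg, "chromosomeLength must be >= 1")
  if (object@gcContent < 0 || object@gcContent > 1)
    msg <- c(msg, "gcContent must lie in [0, 1]")
  if (object@nLoci < 1L) msg <- c(msg, "nLoci must be >= 1")
  if (length(object@locusLengthRange) != 2L ||
      object@locusLengthRange[1L] > object@locusLengthRange[2L])
    msg <- c(msg, "locusLengthRange must be c(min, max) with min <= max")
  if (object@locusLengthRange[1L] < 201L)
    msg <- c(msg, "locusLengthRange minimum must be >= 201 (lncRNAs exceed 200 nt)")
  if (length(object@flankMotifs) &&
      any(grepl("[^ACGT]", object@flankMotifs)))
    msg <- c(msg, "flankMotifs must be strings over {A,C,G,T}")
  if (object@motifInsertProbability < 0 || object@motifInsertProbability > 1)
    msg <- c(msg, "motifInsertProbability must lie in [0, 1]")
  if (object@motifWindow < 1L) msg <- c(msg, "motifWindow must be >= 1")
  if (object@minGap < 0L) msg <- c(msg, "minGap must be >= 0")
  ## a loose feasibility bound; exact placement feasibility is checked at
  ## planting time with a retry cap
  need <- as.numeric(object@nLoci) *
    (object@locusLengthRange[2L] + object@minGap)
  have <- as.numeric(object@nChromosomes) * object@chromosomeLength
  if (need > have)
    msg <- c(msg, "total locus length plus spacing exceeds genome size")
  if (length(msg)) msg else TRUE
})

#' Labelled, flanked sequence dataset
#'
#' The central dataset container: DNA sequences (lncRNA loci with added
#' flanks, or length-matched random genomic controls) together with their
#' class label, species tag, flank length, and the span of the unflanked
#' core locus within each sequence (0-based, half-open offsets).
#'
#' For `label == "non-lncRNA"` controls there is no real locus; the core
#' span is the whole sequence minus nominal flanks of the same length, so
#' positional bookkeeping works identically for both classes.
#'
#' @slot sequences a [Biostrings::DNAStringSet] whose names are the
#'   sequence identifiers.
#' @slot label factor with levels `lncRNA`, `non-lncRNA`.
#' @slot species character vector of species tags.
#' @slot coreStart,coreEnd integer offsets (0-based, half-open) of the
#'   unflanked core locus within each sequence.
#' @slot flank nominal flank length in bases (single integer).
#' @seealso [lncDataset()], [extractFlankedSequences()],
#'   [generateControls()], [splitDataset()]
#' @exportClass LncDataset
setClass("LncDataset", representation(
  sequences = "DNAStringSet",
  label = "factor",
  species = "character",
  coreStart = "integer",
  coreEnd = "integer",
  flank = "integer"
))

setValidity("LncDataset", function(object) {
  n <- length(object@sequences)
  msg <- character()
  if (length(object@label) != n || length(object@species) != n ||
      length(object@coreStart) != n || length(object@coreEnd) != n)
    msg <- c(msg, "slot lengths disagree with number of sequences")
  if (!identical(levels(object@label), c("lncRNA", "non-lncRNA")))
    msg <- c(msg, "label levels must be c('lncRNA', 'non-lncRNA')")
  if (is.null(names(object@sequences)) && n > 0L)
    msg <- c(msg, "sequences must be named (sequence ids)")
  if (n > 0L) {
    w <- Biostrings::width(object@sequences)
    bad <- object@coreStart < 0L | object@coreEnd > w |
      object@coreStart > object@coreEnd
    if (any(bad))
      msg <- c(msg, sprintf("core span outside sequence for %d record(s)",
                            sum(bad)))
  }
  if (length(object@flank) != 1L || object@flank < 0L)
    msg <- c(msg, "flank must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' k-mer vocabulary
#'
#' Token vocabulary over all `4^k` k-mers plus the five special tokens
#' `PAD`, `UNK`, `CLS`, `SEP`, `MASK`. Special tokens occupy ids 1--5 and
#' k-mers follow in lexicographic order, so the mapping is bijective on
#' k-mers and disjoint from the specials.
#'
#' @slot k k-mer size, an integer in `[3, 6]`.
#' @slot tokens character vector of all tokens in id order (specials
#'   first, then the `4^k` k-mers).
#' @seealso [kmerVocabulary()], [tokenToId()], [encodeTokens()]
#' @exportClass KmerVocab
setClass("KmerVocab", representation(k = "integer", tokens = "character"))

setValidity("KmerVocab", function(object) {
  msg <- character()
  if (object@k < 3L || object@k > 6L) msg <- c(msg, "k must be in [3, 6]")
  if (length(object@tokens) != 5L + 4L^object@k)
    msg <- c(msg, "token count must be 4^k + 5 specials")
  if (anyDuplicated(object@tokens)) msg <- c(msg, "tokens must be unique")
  if (!identical(object@tokens[1:5], c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]")))
    msg <- c(msg, "tokens 1..5 must be the special tokens")
  if (length(msg)) msg else TRUE
})

#' Fitted k-mer sequence classifier
#'
#' A small self-attention encoder over k-mer tokens with learned
#' positional embeddings and a two-class softmax head on the `[CLS]`
#' position, trained from random initialization with AdamW under a linear
#' warmup / linear decay learning-rate schedule. Predictions are
#' deterministic given fixed parameters and input.
#'
#' @slot config named list of hyperparameters (see [classifierConfig()]).
#' @slot vocab the [KmerVocab-class] the model was trained with.
#' @slot weights named list of parameter matrices (opaque).
#' @slot trainingLog data.frame of `(step, lr, train_loss, eval_loss,
#'   eval_accuracy)` rows recorded every `loggingSteps` optimizer steps.
#' @seealso [trainKmerClassifier()], [predictKmerClassifier()],
#'   [saveKmerClassifier()]
#' @exportClass KmerClassifier
setClass("KmerClassifier", representation(
  config = "list",
  vocab = "KmerVocab",
  weights = "list",
  trainingLog = "DataFrameOrNull"
))

setValidity("KmerClassifier", function(object) {
  cfg <- object@config
  need <- c("k", "maxSeqLength", "nLayers", "nHeads", "hiddenDim")
  if (!all(need %in% names(cfg)))
    return(paste("config missing fields:",
                 paste(setdiff(need, names(cfg)), collapse = ", ")))
  if (cfg$hiddenDim %% cfg$nHeads != 0L)
    return("hiddenDim must be divisible by nHeads")
  if (cfg$k != object@vocab@k) return("config k and vocabulary k disagree")
  TRUE
})
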