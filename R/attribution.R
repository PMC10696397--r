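## Model interpretation: signed per-k-mer attribution for the lncRNA
## class, run-merging into candidate motifs, and importance ranking.

#' Per-k-mer attribution scores for the lncRNA class
#'
#' Computes one signed score per content k-mer of the encoded (possibly
#' 3'-truncated) sequence; positive scores support the lncRNA class.
#' Two methods are built in:
#' \describe{
#'   \item{occlusion}{`score_i = p_lncRNA(full) - p_lncRNA(token i
#'     replaced by [MASK])`. Model-agnostic and deterministic; the
#'     default.}
#'   \item{gradient_input}{gradient of the lncRNA-minus-control logit
#'     margin at the input embedding of token `i`, dotted with that
#'     embedding. One backward pass per sequence, so much faster on
#'     long inputs.}
#' }
#'
#' @param model a [KmerClassifier-class].
#' @param sequence a single DNA string (character or
#'   [Biostrings::DNAString]).
#' @param method `"occlusion"` or `"gradient_input"`.
#' @param id sequence identifier carried into the result.
#' @return data.frame with `sequence_id`, `token_index` (1-based over
#'   the encoded content tokens), `kmer`, `score`.
#' @export
attributeKmers <- function(model, sequence,
                           method = c("occlusion", "gradient_input"),
                           id = "seq") {
  stopifnot(is(model, "KmerClassifier"))
  method <- match.arg(method)
  vocab <- model@vocab
  toks <- seqToKmers(as.character(sequence), vocab@k)
  enc <- stripPad(encodeTokens(toks, vocab, model@config$maxSeqLength))
  nContent <- length(enc) - 2L
  scores <- switch(method,
    occlusion = .cpp_occlusion(model@weights, model@config, enc, MASK_ID),
    gradient_input = .cpp_grad_input(model@weights, model@config, enc))
  data.frame(sequence_id = id,
             token_index = seq_len(nContent),
             kmer = toks[seq_len(nContent)],
             score = as.numeric(scores),
             stringsAsFactors = FALSE)
}

#' Merge a run of stride-1 adjacent k-mers into one DNA string
#'
#' Consecutive k-mers must overlap by `k - 1` characters; `n` k-mers
#' reconstruct a string of length `n + k - 1`.
#'
#' @param kmers ordered character vector of k-mers.
#' @return the merged DNA string.
#' @examples
#' mergeKmerRun(c("AAA", "AAT", "ATG"))   # "AAATG"
#' @export
mergeKmerRun <- function(kmers) {
  if (!length(kmers)) stop("empty k-mer run")
  k <- nchar(kmers[1L])
  if (any(nchar(kmers) != k)) stop("k-mers of unequal length")
  if (length(kmers) > 1L) {
    suffix <- substring(kmers[-length(kmers)], 2L, k)
    prefix <- substring(kmers[-1L], 1L, k - 1L)
    if (any(suffix != prefix))
      stop("k-mers are not stride-1 adjacent (suffix/prefix mismatch)")
  }
  paste0(kmers[1L],
         paste(substring(kmers[-1L], k, k), collapse = ""))
}

#' Extract motif occurrences from an attribution track
#'
#' Finds maximal runs of consecutive strictly positive attribution
#' scores. A run of at least `minRun` k-mers (default 8, i.e. more than
#' 7 successive positively attributed k-mers) is merged into one motif
#' occurrence with [mergeKmerRun()], its attribution scores summed; a
#' zero or negative score terminates the run, and shorter runs are
#' discarded.
#'
#' @param track data.frame from [attributeKmers()] (columns
#'   `sequence_id`, `token_index`, `kmer`, `score`).
#' @param minRun minimum run length in k-mers.
#' @return data.frame with `sequence_id`, `motif_sequence`,
#'   `token_start`, `token_end`, `attribution_sum`.
#' @export
extractMotifOccurrences <- function(track, minRun = 8L) {
  stopifnot(all(c("sequence_id", "token_index", "kmer", "score") %in%
                  names(track)))
  if (is.unsorted(track$token_index))
    track <- track[order(track$token_index), , drop = FALSE]
  if (nrow(track) &&
      !identical(as.integer(track$token_index),
                 seq_len(nrow(track))))
    stop("track token indices are not a contiguous 1..n alignment")
  pos <- track$score > 0
  runs <- rle(pos)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= minRun
  out <- lapply(which(keep), function(ri) {
    idx <- starts[ri]:ends[ri]
    data.frame(sequence_id = track$sequence_id[1L],
               motif_sequence = mergeKmerRun(track$kmer[idx]),
               token_start = starts[ri], token_end = ends[ri],
               attribution_sum = sum(track$score[idx]),
               stringsAsFactors = FALSE)
  })
  if (length(out)) do.call(rbind, out) else
    data.frame(sequence_id = character(), motif_sequence = character(),
               token_start = integer(), token_end = integer(),
               attribution_sum = numeric(), stringsAsFactors = FALSE)
}

#' Rank motifs by frequency times summed attribution
#'
#' Groups occurrences by exact motif string; each motif's importance is
#' its occurrence frequency multiplied by the sum of its attribution
#' sums. Motifs are ranked by non-increasing importance, ties broken
#' lexicographically.
#'
#' @param occurrences data.frame from [extractMotifOccurrences()]
#'   (rows from many sequences may be concatenated).
#' @param topN number of top motifs to keep (default 50).
#' @return data.frame with `motif_sequence`, `frequency`,
#'   `total_attribution`, `importance`, `rank`.
#' @export
rankMotifs <- function(occurrences, topN = 50L) {
  if (!nrow(occurrences))
    return(data.frame(motif_sequence = character(),
                      frequency = integer(),
                      total_attribution = numeric(),
                      importance = numeric(), rank = integer(),
                      stringsAsFactors = FALSE))
  freq <- table(occurrences$motif_sequence)
  tot <- tapply(occurrences$attribution_sum,
                occurrences$motif_sequence, sum)
  motifs <- names(freq)
  df <- data.frame(motif_sequence = motifs,
                   frequency = as.integer(freq[motifs]),
                   total_attribution = as.numeric(tot[motifs]),
                   stringsAsFactors = FALSE)
  df$importance <- df$frequency * df$total_attribution
  df <- df[order(-df$importance, df$motif_sequence), , drop = FALSE]
  df <- utils::head(df, topN)
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Attribute a whole dataset and rank its motifs
#'
#' Convenience driver mirroring the interpretation protocol: iterate
#' over the lncRNA-labelled sequences of a dataset (optionally a random
#' subsample, for long occlusion runs), compute attribution tracks,
#' extract positive-run motif occurrences and rank them.
#'
#' @param model a [KmerClassifier-class].
#' @param dataset an [LncDataset-class]; only `lncRNA`-labelled
#'   sequences are interpreted.
#' @param method attribution method, see [attributeKmers()].
#' @param minRun minimum positive-run length in k-mers.
#' @param topN motifs kept after ranking.
#' @param sampleSize optional cap on the number of sequences
#'   interpreted, drawn reproducibly with `seed`.
#' @param seed seed for the optional subsample.
#' @return list with `occurrences`, `ranked` (see [rankMotifs()]) and
#'   `nInterpreted`.
#' @export
discoverMotifs <- function(model, dataset,
                           method = c("occlusion", "gradient_input"),
                           minRun = 8L, topN = 50L, sampleSize = NULL,
                           seed = 1L) {
  method <- match.arg(method)
  lnc <- dataset[datasetLabels(dataset) == "lncRNA"]
  if (length(lnc) == 0L) stop("dataset has no lncRNA-labelled sequences")
  idx <- seq_len(length(lnc))
  if (!is.null(sampleSize) && sampleSize < length(idx))
    idx <- withSeed(seed, sort(sample(idx, sampleSize)))
  seqs <- as.character(datasetSequences(lnc))[idx]
  ids <- names(lnc)[idx]
  occ <- lapply(seq_along(seqs), function(i) {
    track <- attributeKmers(model, seqs[[i]], method = method,
                            id = ids[[i]])
    extractMotifOccurrences(track, minRun = minRun)
  })
  occurrences <- do.call(rbind, occ)
  list(occurrences = occurrences,
       ranked = rankMotifs(occurrences, topN = topN),
       nInterpreted = length(idx))
}
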