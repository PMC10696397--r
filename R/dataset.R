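## Dataset construction: genome + lncRNA annotation (+ optional alignment
## table) -> labelled, flanked, filtered sequence datasets. Intervals are
## 0-based half-open internally; GTF I/O converts to/from 1-based
## inclusive at the boundary.

#' Construct an LncDataset
#'
#' Low-level constructor; most users will get datasets from
#' [extractFlankedSequences()], [generateControls()] or [buildDataset()].
#'
#' @param sequences a named [Biostrings::DNAStringSet].
#' @param label `"lncRNA"`/`"non-lncRNA"` per sequence (recycled if
#'   scalar).
#' @param species species tag per sequence (recycled if scalar).
#' @param coreStart,coreEnd 0-based half-open offsets of the unflanked
#'   core within each sequence.
#' @param flank nominal flank length in bases.
#' @return an [LncDataset-class].
#' @export
lncDataset <- function(sequences, label, species, coreStart, coreEnd,
                       flank) {
  n <- length(sequences)
  new("LncDataset",
      sequences = sequences,
      label = factor(rep_len(as.character(label), n),
                     levels = c("lncRNA", "non-lncRNA")),
      species = rep_len(as.character(species), n),
      coreStart = rep_len(as.integer(coreStart), n),
      coreEnd = rep_len(as.integer(coreEnd), n),
      flank = as.integer(flank))
}

#' Load a genome FASTA
#'
#' Reads all records of a FASTA file into a named
#' [Biostrings::DNAStringSet], uppercasing bases on load so downstream
#' tokenization sees a single case.
#'
#' @param path path to a FASTA file.
#' @return a named [Biostrings::DNAStringSet].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT", ">chr2", "ttttcccc"), fa)
#' Biostrings::width(readGenome(fa))
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  genome <- tryCatch(Biostrings::readDNAStringSet(path),
                     error = function(e)
                       stop("malformed FASTA '", path, "': ",
                            conditionMessage(e), call. = FALSE))
  if (length(genome) == 0L)
    stop("FASTA file '", path, "' contains no records")
  ## drop description after first whitespace, as indexing tools do
  names(genome) <- sub("\\s.*$", "", names(genome))
  Biostrings::DNAStringSet(toupper(genome))
}

#' Write loci as GTF
#'
#' Serializes a 0-based half-open locus table as GTF (feature type
#' `lncRNA`, 1-based inclusive coordinates).
#'
#' @param loci data.frame with `chrom`, `start`, `end` (0-based,
#'   half-open), optional `strand` and `locus_id`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnnotationGTF <- function(loci, path) {
  ids <- if (!is.null(loci$locus_id)) loci$locus_id else
    sprintf("locus_%04d", seq_len(nrow(loci)))
  gr <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    strand = if (!is.null(loci$strand)) loci$strand else "+")
  gr$source <- "lncKmer"
  gr$type <- "lncRNA"
  gr$gene_id <- ids
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read lncRNA loci from GTF
#'
#' Imports a GTF and returns loci as a 0-based half-open table, checking
#' every interval against the genome when one is supplied.
#'
#' @param path path to a GTF file.
#' @param genome optional [Biostrings::DNAStringSet]; when given, records
#'   on unknown chromosomes or exceeding chromosome bounds raise an error
#'   naming the record.
#' @param feature optional feature type filter (e.g. `"lncRNA"`); `NULL`
#'   keeps all records.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `locus_id`.
#' @export
readAnnotationGTF <- function(path, genome = NULL, feature = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  if (!is.null(feature) && "type" %in% names(S4Vectors::mcols(gr)))
    gr <- gr[as.character(gr$type) %in% feature]
  if (length(gr) == 0L) stop("no usable records in GTF '", path, "'")
  ids <- if ("gene_id" %in% names(S4Vectors::mcols(gr)) &&
             !anyNA(gr$gene_id)) as.character(gr$gene_id) else
               sprintf("locus_%04d", seq_along(gr))
  loci <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    locus_id = ids, stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    len <- stats::setNames(Biostrings::width(genome), names(genome))
    unknown <- !(loci$chrom %in% names(len))
    if (any(unknown))
      stop("GTF record(s) on unknown chromosome: ",
           paste(utils::head(loci$locus_id[unknown], 3L), collapse = ", "))
    bad <- loci$start < 0L | loci$end > len[loci$chrom] |
      loci$start >= loci$end
    if (any(bad))
      stop("GTF record(s) outside chromosome bounds: ",
           paste(utils::head(loci$locus_id[bad], 3L), collapse = ", "))
  }
  loci
}

#' Add flanking context to an interval, clamped at chromosome bounds
#'
#' Extends a 0-based half-open interval by `flank` bases on each side,
#' clamping so the result never exceeds `[0, chromLength]` -- flanks do
#' not extend past chromosome or scaffold boundaries.
#'
#' @param start,end 0-based half-open interval (vectorized).
#' @param flank flank length in bases.
#' @param chromLength chromosome length(s) in bases.
#' @return matrix with columns `start`, `end` of the flanked, clamped
#'   intervals.
#' @examples
#' addFlanks(300, 800, 500, 10000)   # clamps at the origin: 0..1300
#' addFlanks(9900, 9950, 500, 10000) # clamps at the terminus: 9400..10000
#' @export
addFlanks <- function(start, end, flank, chromLength) {
  stopifnot(all(start >= 0L), all(end > start), all(end <= chromLength))
  out <- clampInterval(start - flank, end + flank, chromLength)
  colnames(out) <- c("start", "end")
  out
}

#' Read a 12-column tabular alignment file
#'
#' Parses BLAST-outfmt-6-style TSV (no header) into a typed data.frame.
#'
#' @param path path to the tabular file.
#' @return data.frame with the standard 12 columns (`query_id`,
#'   `subject_id`, `percent_identity`, `alignment_length`, `mismatches`,
#'   `gap_opens`, `q_start`, `q_end`, `s_start`, `s_end`, `e_value`,
#'   `bit_score`); query coordinates 1-based inclusive.
#' @export
readAlignments <- function(path) {
  cols <- c("query_id", "subject_id", "percent_identity",
            "alignment_length", "mismatches", "gap_opens", "q_start",
            "q_end", "s_start", "s_end", "e_value", "bit_score")
  aln <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(aln) != 12L)
    stop("expected 12 tab-separated columns in '", path, "', found ",
         ncol(aln))
  names(aln) <- cols
  aln
}

#' Filter out queries highly covered by alignments
#'
#' For each query, merges its HSP query intervals (union of overlapping
#' 1-based inclusive `q_start..q_end` spans) and removes the query when
#' the covered fraction of its length strictly exceeds
#' `coverageThreshold` -- i.e. over 90 percent of its length matched an
#' mRNA-like subject under the default. Queries without alignment records
#' are retained; records referencing unknown queries are skipped with a
#' warning.
#'
#' @param queries an [LncDataset-class] of candidate sequences.
#' @param alignments data.frame from [readAlignments()] or
#'   [emitAlignmentTable()].
#' @param coverageThreshold removal threshold on the merged covered
#'   fraction (strict inequality). Default 0.9.
#' @return list with elements `retained` and `removed`, both
#'   [LncDataset-class], plus `coverage`, a data.frame of per-query
#'   merged covered fractions.
#' @export
filterBySimilarity <- function(queries, alignments,
                               coverageThreshold = 0.9) {
  stopifnot(is(queries, "LncDataset"))
  assertScalarNumber(coverageThreshold, "coverageThreshold", 0, 1)
  ids <- names(queries)
  known <- alignments$query_id %in% ids
  if (any(!known)) {
    warning(sum(!known), " alignment record(s) reference unknown queries",
            "; skipped")
    alignments <- alignments[known, , drop = FALSE]
  }
  qlen <- stats::setNames(Biostrings::width(datasetSequences(queries)), ids)
  bad <- alignments$q_start < 1L | alignments$q_end < alignments$q_start |
    alignments$q_end > qlen[alignments$query_id]
  if (any(bad))
    stop("alignment record(s) with invalid query coordinates for: ",
         paste(unique(utils::head(alignments$query_id[bad], 3L)),
               collapse = ", "))
  covered <- stats::setNames(numeric(length(ids)), ids)
  if (nrow(alignments)) {
    by <- split(seq_len(nrow(alignments)), alignments$query_id)
    for (qid in names(by)) {
      r <- IRanges::reduce(IRanges::IRanges(
        start = alignments$q_start[by[[qid]]],
        end = alignments$q_end[by[[qid]]]))
      covered[qid] <- sum(IRanges::width(r)) / qlen[qid]
    }
  }
  drop <- covered > coverageThreshold
  list(retained = queries[!drop],
       removed = queries[drop],
       coverage = data.frame(id = ids, covered_fraction = unname(covered),
                             removed = unname(drop)))
}

#' Extract flanked lncRNA sequences from a genome
#'
#' For every annotated locus, applies [addFlanks()] and extracts the
#' flanked sequence from the forward strand, recording the span of the
#' unflanked core relative to the extracted sequence. Labels everything
#' `lncRNA`.
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param loci data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and `locus_id`, e.g. from [readAnnotationGTF()] or
#'   [plantLoci()].
#' @param flank flank length in bases (default 500).
#' @param species species tag for the dataset.
#' @return an [LncDataset-class] with one sequence per locus.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = strrep("ACGT", 2500)))
#' loci <- data.frame(chrom = "chr1", start = 1000L, end = 1500L,
#'                    locus_id = "locus_0001")
#' ds <- extractFlankedSequences(g, loci, flank = 500)
#' coreSpans(ds)   # core occupies offsets 500..1000 of a 1500 bp extract
#' @export
extractFlankedSequences <- function(genome, loci, flank = 500L,
                                    species = "unknown") {
  stopifnot(is(genome, "DNAStringSet"))
  len <- stats::setNames(Biostrings::width(genome), names(genome))
  unknown <- !(loci$chrom %in% names(len))
  if (any(unknown))
    stop("locus on unknown chromosome: ",
         paste(utils::head(loci$locus_id[unknown], 3L), collapse = ", "))
  bad <- loci$start < 0L | loci$end > len[loci$chrom] |
    loci$start >= loci$end
  if (any(bad))
    stop("locus outside chromosome bounds: ",
         paste(utils::head(loci$locus_id[bad], 3L), collapse = ", "))
  fl <- addFlanks(loci$start, loci$end, flank, len[loci$chrom])
  seqs <- Biostrings::subseq(genome[loci$chrom],
                             start = fl[, "start"] + 1L,
                             end = fl[, "end"])
  names(seqs) <- if (!is.null(loci$locus_id)) loci$locus_id else
    sprintf("locus_%04d", seq_len(nrow(loci)))
  lncDataset(seqs, label = "lncRNA", species = species,
             coreStart = loci$start - fl[, "start"],
             coreEnd = loci$end - fl[, "start"],
             flank = flank)
}

#' Generate length-matched random genomic controls
#'
#' Draws one random genomic stretch per requested length, uniformly over
#' placeable positions, with zero overlap with any excluded interval
#' (shuffle-with-exclusion semantics). Controls get label `non-lncRNA`
#' and a nominal core span equal to the whole sequence minus `flank` on
#' each side, so positional bookkeeping matches the lncRNA class.
#' Controls may overlap each other (a warning reports how many do).
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param excluded data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) of intervals controls must avoid -- typically the flanked
#'   lncRNA intervals.
#' @param lengths integer vector of control lengths, typically the widths
#'   of the flanked lncRNA sequences.
#' @param seed integer seed; identical seed gives identical coordinates.
#' @param flank nominal flank recorded on the output dataset.
#' @param species species tag.
#' @param maxTries placement attempts per control before failing.
#' @return an [LncDataset-class] of controls, with the sampled
#'   coordinates in `metadata` columns of the coverage table attribute.
#' @export
generateControls <- function(genome, excluded, lengths, seed = 1L,
                             flank = 500L, species = "unknown",
                             maxTries = 1000L) {
  stopifnot(is(genome, "DNAStringSet"), length(lengths) > 0L)
  chromLen <- Biostrings::width(genome)
  chromName <- names(genome)
  exS <- split(excluded$start, excluded$chrom)
  exE <- split(excluded$end, excluded$chrom)
  withSeed(seed, {
    n <- length(lengths)
    chrom <- character(n); startv <- integer(n)
    for (i in seq_len(n)) {
      L <- as.integer(lengths[i])
      ok <- FALSE
      for (try in seq_len(maxTries)) {
        ci <- sample.int(length(chromName), 1L)
        if (chromLen[ci] < L) next
        s <- sample.int(chromLen[ci] - L + 1L, 1L) - 1L
        es <- exS[[chromName[ci]]]
        if (!is.null(es) && length(es) &&
            any(s < exE[[chromName[ci]]] & s + L > es)) next
        chrom[i] <- chromName[ci]; startv[i] <- s
        ok <- TRUE
        break
      }
      if (!ok)
        stop(sprintf(
          "could not place a control of length %d after %d tries", L,
          maxTries))
    }
    seqs <- Biostrings::subseq(genome[chrom], start = startv + 1L,
                               end = startv + as.integer(lengths))
    names(seqs) <- sprintf("control_%04d", seq_len(n))
    selfOverlap <- countSelfOverlaps(chrom, startv, as.integer(lengths))
    if (selfOverlap > 0L)
      warning(selfOverlap,
              " control pair(s) overlap each other (allowed, as in ",
              "shuffle-style placement)")
    ds <- lncDataset(seqs, label = "non-lncRNA", species = species,
                     coreStart = pmin(as.integer(flank),
                                      as.integer(lengths)),
                     coreEnd = pmax(as.integer(lengths) -
                                      as.integer(flank),
                                    pmin(as.integer(flank),
                                         as.integer(lengths))),
                     flank = flank)
    attr(ds, "coordinates") <- data.frame(
      id = names(seqs), chrom = chrom, start = startv,
      end = startv + as.integer(lengths), stringsAsFactors = FALSE)
    ds
  })
}

countSelfOverlaps <- function(chrom, start, len) {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start + 1L,
                                                start + len))
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      drop.redundant = TRUE)
  length(hits)
}

#' Stratified train/test split
#'
#' Splits a dataset into disjoint train and test partitions, sampling
#' `round(testFraction * n)` items per class so class proportions are
#' preserved within one item per class. Deterministic under `seed`.
#'
#' @param dataset an [LncDataset-class].
#' @param testFraction fraction held out per class, in (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `test` [LncDataset-class] partitions.
#' @export
splitDataset <- function(dataset, testFraction = 0.2, seed = 1L) {
  stopifnot(is(dataset, "LncDataset"))
  assertScalarNumber(testFraction, "testFraction", 0, 1)
  if (testFraction <= 0 || testFraction >= 1)
    stop("testFraction must lie strictly between 0 and 1")
  lab <- datasetLabels(dataset)
  if (any(table(lab)[unique(as.character(lab))] < 2L))
    stop("each class present must have at least 2 members to split")
  withSeed(seed, {
    testIdx <- integer()
    for (cl in levels(lab)) {
      idx <- which(lab == cl)
      if (!length(idx)) next
      nTest <- max(1L, as.integer(round(testFraction * length(idx))))
      testIdx <- c(testIdx, sort(sample(idx, nTest)))
    }
    list(train = dataset[setdiff(seq_along(lab), testIdx)],
         test = dataset[sort(testIdx)])
  })
}

#' Tokenize a sequence into overlapping k-mers
#'
#' Slides a width-`k` window with stride 1 over the sequence, preserving
#' order, giving `L - k + 1` tokens. Bases other than `A`, `C`, `G`,
#' `T`, `N` raise an error; `N`-containing tokens are kept as strings
#' here and map to the unknown token at encoding time.
#'
#' @param sequence a single DNA string (character or
#'   [Biostrings::DNAString]).
#' @param k k-mer size, an integer in `[3, 6]`.
#' @return character vector of k-mer tokens.
#' @examples
#' seqToKmers("ATCGAT", 3)   # "ATC" "TCG" "CGA" "GAT"
#' @export
seqToKmers <- function(sequence, k) {
  k <- as.integer(k)
  if (k < 3L || k > 6L) stop("k must be in [3, 6]")
  s <- toupper(as.character(sequence))
  if (length(s) != 1L) stop("sequence must be a single string")
  if (grepl("[^ACGTN]", s))
    stop("sequence contains characters other than A, C, G, T, N")
  L <- nchar(s)
  if (L < k) stop("sequence shorter than k")
  starts <- seq_len(L - k + 1L)
  substring(s, starts, starts + k - 1L)
}

#' Build a labelled dataset from genome + annotation (+ alignments)
#'
#' End-to-end dataset construction: extract flanked lncRNA sequences,
#' optionally drop candidates whose merged alignment coverage exceeds
#' the similarity threshold, generate length-matched shuffled controls
#' excluded from the flanked lncRNA intervals, and split into stratified
#' train/test partitions.
#'
#' @param genome named [Biostrings::DNAStringSet] or path to a FASTA.
#' @param loci locus data.frame (0-based half-open) or path to a GTF.
#' @param alignments optional alignment data.frame or path to a
#'   12-column TSV; used by [filterBySimilarity()].
#' @param flank flank length in bases (default 500).
#' @param coverageThreshold similarity-removal threshold (default 0.9,
#'   strict).
#' @param testFraction held-out fraction per class (default 0.2).
#' @param seed integer seed driving control placement and the split.
#' @param species species tag.
#' @return list with `train`, `test` (stratified [LncDataset-class]
#'   partitions), `full` (the combined dataset before splitting) and
#'   `filtered` (the similarity-filter report, or `NULL`).
#' @export
buildDataset <- function(genome, loci, alignments = NULL, flank = 500L,
                         coverageThreshold = 0.9, testFraction = 0.2,
                         seed = 1L, species = "unknown") {
  if (is.character(genome)) genome <- readGenome(genome)
  if (is.character(loci)) loci <- readAnnotationGTF(loci, genome = genome)
  lnc <- extractFlankedSequences(genome, loci, flank = flank,
                                 species = species)
  filtered <- NULL
  keptLoci <- loci
  if (!is.null(alignments)) {
    if (is.character(alignments)) alignments <- readAlignments(alignments)
    filtered <- filterBySimilarity(lnc, alignments,
                                   coverageThreshold = coverageThreshold)
    lnc <- filtered$retained
    keptLoci <- loci[loci$locus_id %in% names(lnc), , drop = FALSE]
  }
  if (length(lnc) == 0L) stop("no lncRNA sequences left after filtering")
  chromLen <- stats::setNames(Biostrings::width(genome), names(genome))
  flanked <- addFlanks(keptLoci$start, keptLoci$end, flank,
                       chromLen[keptLoci$chrom])
  excluded <- data.frame(chrom = keptLoci$chrom,
                         start = flanked[, "start"],
                         end = flanked[, "end"])
  ctrl <- generateControls(
    genome, excluded,
    lengths = Biostrings::width(datasetSequences(lnc)),
    seed = seed + 1L, flank = flank, species = species)
  full <- c(lnc, ctrl)
  split <- splitDataset(full, testFraction = testFraction, seed = seed)
  list(train = split$train, test = split$test, full = full,
       filtered = filtered)
}

#' Write / read a labelled dataset as TSV
#'
#' The TSV has columns `id`, `species`, `label`, `sequence`,
#' `core_start`, `core_end`, `flank`; offsets 0-based half-open.
#'
#' @param dataset an [LncDataset-class].
#' @param path file path.
#' @return `writeDatasetTSV` returns `path` invisibly; `readDatasetTSV`
#'   returns an [LncDataset-class].
#' @export
writeDatasetTSV <- function(dataset, path) {
  df <- data.frame(id = names(dataset),
                   species = datasetSpecies(dataset),
                   label = as.character(datasetLabels(dataset)),
                   sequence = as.character(datasetSequences(dataset)),
                   core_start = dataset@coreStart,
                   core_end = dataset@coreEnd,
                   flank = flankLength(dataset),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeDatasetTSV
#' @export
readDatasetTSV <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  seqs <- Biostrings::DNAStringSet(stats::setNames(df$sequence, df$id))
  lncDataset(seqs, label = df$label, species = df$species,
             coreStart = df$core_start, coreEnd = df$core_end,
             flank = df$flank[1L])
}

#' Write dataset sequences as FASTA
#'
#' @param dataset an [LncDataset-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeDatasetFASTA <- function(dataset, path) {
  Biostrings::writeXStringSet(datasetSequences(dataset), path)
  invisible(path)
}
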