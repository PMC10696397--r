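## Seeded simulator: background genomes, planted lncRNA loci with
## flank-motif grammars, and alignment-table fixtures. Everything is
## deterministic under the config seed so downstream stages are testable
## without any external download.

#' Build a simulation configuration
#'
#' Constructs and validates a [SimConfig-class]. The defaults describe
#' the reference simulation used throughout the package: a multi-megabase
#' multi-chromosome background at plant-like GC content, 1000 lncRNA loci
#' of 201--400 bp, and a single A-homopolymer 8-mer planted with
#' probability 0.9 anywhere within the 500 bp window on each side of a
#' locus. Motif plantings cover the full default flank width because
#' lncRNA-associated motifs are reported throughout the flanking regions,
#' not only immediately at the locus boundary.
#'
#' @param nChromosomes number of chromosomes.
#' @param chromosomeLength chromosome length in bases.
#' @param gcContent background G+C fraction in `[0, 1]`.
#' @param nLoci number of planted lncRNA loci.
#' @param locusLengthRange integer `c(min, max)` locus length in bases;
#'   `min` must be at least 201.
#' @param flankMotifs character vector of motifs over `{A,C,G,T}`.
#' @param motifInsertProbability per-flank insertion probability.
#' @param motifWindow window width in bases adjacent to each locus
#'   boundary within which motifs are planted.
#' @param minGap minimum spacing between loci and to chromosome ends.
#' @param seed integer seed.
#' @return a validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(nChromosomes = 1, chromosomeLength = 50000, nLoci = 10)
#' cfg
#' @export
simConfig <- function(nChromosomes = 4L,
                      chromosomeLength = 1200000L,
                      gcContent = 0.36,
                      nLoci = 1000L,
                      locusLengthRange = c(201L, 400L),
                      flankMotifs = "AAAAAAAA",
                      motifInsertProbability = 0.9,
                      motifWindow = 500L,
                      minGap = 1100L,
                      seed = 1L) {
  new("SimConfig",
      nChromosomes = as.integer(nChromosomes),
      chromosomeLength = as.integer(chromosomeLength),
      gcContent = as.numeric(gcContent),
      nLoci = as.integer(nLoci),
      locusLengthRange = as.integer(locusLengthRange),
      flankMotifs = as.character(flankMotifs),
      motifInsertProbability = as.numeric(motifInsertProbability),
      motifWindow = as.integer(motifWindow),
      minGap = as.integer(minGap),
      seed = as.integer(seed))
}

#' Simulate a background genome
#'
#' Draws each base independently with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1 - gc)/2` -- the simplest null under which any
#' classifier signal must come from the planted loci, not from
#' background composition. Identical config gives byte-identical output.
#'
#' @param config a [SimConfig-class].
#' @return a named [Biostrings::DNAStringSet] with `nChromosomes`
#'   chromosomes (`chr1`, `chr2`, ...).
#' @examples
#' g <- simulateGenome(simConfig(nChromosomes = 1,
#'   chromosomeLength = 50000, nLoci = 10))
#' Biostrings::width(g)
#' @export
simulateGenome <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  gc <- config@gcContent
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  withSeed(config@seed, {
    seqs <- vapply(seq_len(config@nChromosomes), function(i) {
      paste(sample(names(probs), config@chromosomeLength, replace = TRUE,
                   prob = probs), collapse = "")
    }, character(1L))
    names(seqs) <- paste0("chr", seq_len(config@nChromosomes))
    Biostrings::DNAStringSet(seqs)
  })
}

#' Plant lncRNA loci and flank motifs into a genome
#'
#' Places `nLoci` non-overlapping loci uniformly at random (rejection
#' sampling with a retry cap), keeping at least `minGap` bases between
#' loci and to chromosome ends so that flanking windows never collide.
#' For each locus, each `flankMotifs` entry is written (overwriting the
#' background, so coordinates never shift) into the upstream window
#' `[start - motifWindow, start)` and the downstream window
#' `[end, end + motifWindow)` independently with probability
#' `motifInsertProbability`. Exact planted positions are recorded as
#' ground truth.
#'
#' Randomness is drawn from a stream seeded with `config seed + 1` so the
#' background genome and the planting are independently reproducible.
#'
#' @param genome a [Biostrings::DNAStringSet] from [simulateGenome()].
#' @param config the same [SimConfig-class] used to build `genome`.
#' @return a list with elements
#'   \describe{
#'     \item{genome}{the genome with motifs written in,}
#'     \item{loci}{data.frame `chrom`, `start`, `end` (0-based,
#'       half-open), `strand`, `locus_id`,}
#'     \item{truth}{data.frame `motif`, `chrom`, `position` (0-based
#'       start of the planted copy), `locus_id`, `side`
#'       (upstream/downstream).}
#'   }
#' @examples
#' cfg <- simConfig(nChromosomes = 1, chromosomeLength = 60000,
#'   nLoci = 5, motifInsertProbability = 1, seed = 7)
#' sim <- plantLoci(simulateGenome(cfg), cfg)
#' head(sim$truth)
#' @export
plantLoci <- function(genome, config) {
  stopifnot(is(genome, "DNAStringSet"), is(config, "SimConfig"))
  validObject(config)
  chromLen <- stats::setNames(Biostrings::width(genome), names(genome))
  withSeed(config@seed + 1L, {
    loci <- placeLoci(chromLen, config)
    planted <- plantMotifs(genome, loci, config)
    list(genome = planted$genome, loci = loci, truth = planted$truth)
  })
}

## Rejection-sample non-overlapping loci. Occupied intervals are kept per
## chromosome as numeric vectors; a candidate is accepted when it keeps
## minGap clearance from every accepted locus and both chromosome ends.
placeLoci <- function(chromLen, config) {
  nChrom <- length(chromLen)
  gap <- config@minGap
  lmin <- config@locusLengthRange[1L]
  lmax <- config@locusLengthRange[2L]
  occStart <- vector("list", nChrom)
  occEnd <- vector("list", nChrom)
  out <- matrix(0L, nrow = config@nLoci, ncol = 3L) # chrom idx, start, end
  maxTries <- 200L * config@nLoci
  tries <- 0L
  placed <- 0L
  while (placed < config@nLoci) {
    tries <- tries + 1L
    if (tries > maxTries)
      stop(sprintf("could not place %d loci without overlap after %d tries",
                   config@nLoci, maxTries))
    ci <- sample.int(nChrom, 1L)
    len <- sample.int(lmax - lmin + 1L, 1L) + lmin - 1L
    lo <- gap
    hi <- chromLen[ci] - gap - len
    if (hi < lo) next
    start <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    end <- start + len
    os <- occStart[[ci]]
    if (length(os) && any(start - gap < occEnd[[ci]] & end + gap > os))
      next
    occStart[[ci]] <- c(os, start)
    occEnd[[ci]] <- c(occEnd[[ci]], end)
    placed <- placed + 1L
    out[placed, ] <- c(ci, start, end)
  }
  ord <- order(out[, 1L], out[, 2L])
  out <- out[ord, , drop = FALSE]
  data.frame(chrom = names(chromLen)[out[, 1L]],
             start = out[, 2L], end = out[, 3L],
             strand = "+",
             locus_id = sprintf("locus_%04d", seq_len(nrow(out))),
             stringsAsFactors = FALSE)
}

## Write flank motifs into the windows adjacent to each locus boundary.
## Chromosomes are handled as per-base character vectors so each planting
## is an O(motif length) assignment, and occupied planting intervals are
## tracked per chromosome so a draw never overwrites an earlier planting
## (recorded truth positions must re-scan to the exact motif).
plantMotifs <- function(genome, loci, config) {
  window <- config@motifWindow
  p <- config@motifInsertProbability
  motifs <- config@flankMotifs
  motif <- chrom <- locus <- side <- character()
  position <- integer()
  if (length(motifs) && nrow(loci)) {
    chars <- lapply(as.character(genome), function(s) strsplit(s, "")[[1L]])
    occS <- stats::setNames(vector("list", length(chars)), names(chars))
    occE <- occS
    for (i in seq_len(nrow(loci))) {
      ch <- loci$chrom[i]
      for (m in motifs) {
        mlen <- nchar(m)
        mchars <- strsplit(m, "")[[1L]]
        for (sd in c("upstream", "downstream")) {
          if (stats::runif(1L) > p) next
          if (sd == "upstream") {
            lo <- loci$start[i] - window
            hi <- loci$start[i] - mlen
          } else {
            lo <- loci$end[i]
            hi <- loci$end[i] + window - mlen
          }
          lo <- max(0L, lo)
          hi <- min(length(chars[[ch]]) - mlen, hi)
          if (hi < lo) next
          pos <- NA_integer_
          for (try in seq_len(25L)) {
            cand <- lo + sample.int(hi - lo + 1L, 1L) - 1L
            if (!length(occS[[ch]]) ||
                !any(cand < occE[[ch]] & cand + mlen > occS[[ch]])) {
              pos <- cand
              break
            }
          }
          if (is.na(pos)) next
          chars[[ch]][(pos + 1L):(pos + mlen)] <- mchars
          occS[[ch]] <- c(occS[[ch]], pos)
          occE[[ch]] <- c(occE[[ch]], pos + mlen)
          k <- length(motif) + 1L
          motif[k] <- m; chrom[k] <- ch; position[k] <- pos
          locus[k] <- loci$locus_id[i]; side[k] <- sd
        }
      }
    }
    genome <- Biostrings::DNAStringSet(
      vapply(chars, paste, character(1L), collapse = ""))
  }
  truth <- data.frame(motif = motif, chrom = chrom, position = position,
                      locus_id = locus, side = side,
                      stringsAsFactors = FALSE)
  list(genome = genome, truth = truth)
}

#' Simulate a species: genome, loci, truth in one call
#'
#' Convenience wrapper running [simulateGenome()] then [plantLoci()] and
#' attaching a species tag.
#'
#' @param config a [SimConfig-class].
#' @param species species tag carried through to datasets.
#' @return list with `genome`, `loci`, `truth`, `species`, `config`.
#' @examples
#' sim <- simulateSpecies(simConfig(nChromosomes = 1,
#'   chromosomeLength = 60000, nLoci = 5), species = "simA")
#' sim$loci
#' @export
simulateSpecies <- function(config, species = "sim") {
  genome <- simulateGenome(config)
  res <- plantLoci(genome, config)
  res$species <- species
  res$config <- config
  res
}

#' Emit a synthetic 12-column alignment table
#'
#' Builds BLAST-outfmt-6-style tabular records for a set of query
#' sequences: a chosen fraction of queries ("contaminants", standing in
#' for lncRNA candidates that are really mRNA-like) receive two
#' overlapping HSPs whose merged query coverage exceeds 0.9, and every
#' other query receives one HSP covering at most half its length. Used to
#' exercise the similarity filter without running an aligner.
#'
#' @param dataset an [LncDataset-class] (or any named
#'   [Biostrings::DNAStringSet]) providing query ids and lengths.
#' @param contaminateFraction fraction of queries given > 0.9 coverage;
#'   the count is `round(fraction * n)`.
#' @param seed integer seed for choosing which queries are contaminated.
#' @return data.frame in standard 12-column tabular layout (`query_id`,
#'   `subject_id`, `percent_identity`, `alignment_length`, `mismatches`,
#'   `gap_opens`, `q_start`, `q_end`, `s_start`, `s_end`, `e_value`,
#'   `bit_score`), query coordinates 1-based inclusive.
#' @examples
#' ds <- lncDataset(
#'   sequences = Biostrings::DNAStringSet(
#'     setNames(strrep(c("ACGT"), 50), paste0("q", 1:1))),
#'   label = "lncRNA", species = "sim", coreStart = 0L, coreEnd = 200L,
#'   flank = 0L)
#' emitAlignmentTable(ds, contaminateFraction = 1, seed = 1)
#' @export
emitAlignmentTable <- function(dataset, contaminateFraction, seed = 1L) {
  assertScalarNumber(contaminateFraction, "contaminateFraction", 0, 1)
  seqs <- if (is(dataset, "LncDataset")) datasetSequences(dataset) else dataset
  stopifnot(is(seqs, "DNAStringSet"), length(seqs) > 0L,
            !is.null(names(seqs)))
  lens <- Biostrings::width(seqs)
  ids <- names(seqs)
  n <- length(ids)
  nCont <- as.integer(round(contaminateFraction * n))
  withSeed(seed, {
    contaminated <- if (nCont > 0L) sample.int(n, nCont) else integer()
    rows <- lapply(seq_len(n), function(i) {
      L <- lens[i]
      if (i %in% contaminated) {
        ## two overlapping HSPs; union = [1, ceiling(0.92 L)] > 0.9 L
        q1 <- c(1L, as.integer(ceiling(0.6 * L)))
        q2 <- c(max(1L, as.integer(floor(0.5 * L))),
                as.integer(ceiling(0.92 * L)))
        qs <- rbind(q1, q2)
      } else {
        ## single HSP covering <= 0.5 of the query
        s <- max(1L, as.integer(round(0.2 * L)))
        e <- min(L, s + max(0L, as.integer(floor(0.3 * L)) - 1L))
        qs <- rbind(c(s, e))
      }
      alen <- qs[, 2L] - qs[, 1L] + 1L
      data.frame(query_id = ids[i],
                 subject_id = sprintf("mRNA_%03d", i),
                 percent_identity = round(stats::runif(nrow(qs), 95, 100), 2),
                 alignment_length = alen,
                 mismatches = as.integer(round(alen * 0.02)),
                 gap_opens = 0L,
                 q_start = qs[, 1L], q_end = qs[, 2L],
                 s_start = 1L, s_end = alen,
                 e_value = 1e-30, bit_score = round(alen * 1.85, 1),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Write an alignment table as 12-column TSV
#'
#' @param alignments data.frame from [emitAlignmentTable()] (or with the
#'   same columns).
#' @param path output path; no header is written, matching tabular
#'   aligner output.
#' @return `path`, invisibly.
#' @export
writeAlignmentTSV <- function(alignments, path) {
  utils::write.table(alignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a simulation to disk as FASTA + GTF + truth TSV
#'
#' Serializes the simulated genome (`genome.fa`), the planted loci
#' (`loci.gtf`, feature type `lncRNA`, 1-based inclusive coordinates) and
#' the ground-truth motif table (`truth.tsv`).
#'
#' @param sim result of [simulateSpecies()] (or [plantLoci()] plus a
#'   `species` element).
#' @param outdir output directory, created if needed.
#' @return named character vector of the three file paths, invisibly.
#' @export
writeSimulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(outdir, "genome.fa")
  gtf <- file.path(outdir, "loci.gtf")
  tsv <- file.path(outdir, "truth.tsv")
  Biostrings::writeXStringSet(sim$genome, fa)
  writeAnnotationGTF(sim$loci, gtf)
  utils::write.table(sim$truth, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(genome = fa, annotation = gtf, truth = tsv))
}
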