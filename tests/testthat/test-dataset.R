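test_that("readGenome loads records, uppercases, and rejects bad input", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 assembled", "acgtACGTacgt", ">chr2", "TTTTCCCC"), fa)
  g <- readGenome(fa)
  expect_identical(length(g), 2L)
  expect_identical(names(g), c("chr1", "chr2"))
  expect_identical(Biostrings::width(g), c(12L, 8L))
  expect_identical(as.character(g[["chr1"]]), "ACGTACGTACGT")
  empty <- withr::local_tempfile(fileext = ".fa")
  file.create(empty)
  expect_error(readGenome(empty), "no records|malformed")
  expect_error(readGenome("/nonexistent/x.fa"), "not found")
})

test_that("GTF writing and reading round-trips 0-based loci", {
  loci <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                     start = c(0L, 500L, 42L),
                     end = c(300L, 950L, 430L),
                     strand = "+",
                     locus_id = c("locus_0001", "locus_0002",
                                  "locus_0003"),
                     stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".gtf")
  writeAnnotationGTF(loci, path)
  ## coordinates on disk must be 1-based inclusive
  raw <- read.delim(path, header = FALSE, comment.char = "#")
  expect_identical(as.integer(raw$V4), loci$start + 1L)
  expect_identical(as.integer(raw$V5), loci$end)
  expect_true(all(raw$V3 == "lncRNA"))
  back <- readAnnotationGTF(path)
  expect_identical(back[, c("chrom", "start", "end", "locus_id")],
                   loci[, c("chrom", "start", "end", "locus_id")])
  g <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 100)))
  expect_error(readAnnotationGTF(path, genome = g), "unknown chromosome")
})

test_that("flank addition clamps at chromosome boundaries", {
  expect_identical(addFlanks(300L, 800L, 500L, 10000L),
                   matrix(c(0L, 1300L), 1L,
                          dimnames = list(NULL, c("start", "end"))))
  expect_identical(unname(addFlanks(2000L, 2600L, 500L, 10000L)),
                   matrix(c(1500L, 3100L), 1L))
  expect_identical(unname(addFlanks(9900L, 9950L, 500L, 10000L)),
                   matrix(c(9400L, 10000L), 1L))
  ## vectorized, always within [0, chromLength]
  set.seed(1)
  s <- sample.int(5000L, 200L); e <- s + sample.int(400L, 200L)
  out <- addFlanks(s, e, 500L, 5500L)
  expect_true(all(out[, "start"] >= 0L & out[, "end"] <= 5500L))
})

test_that("coverage filter merges HSPs and applies a strict threshold", {
  seqs <- Biostrings::DNAStringSet(
    c(q1 = strrep("A", 100), q2 = strrep("C", 100),
      q3 = strrep("G", 100)))
  ds <- lncDataset(seqs, "lncRNA", "sim", 0L, 100L, 0L)
  mk <- function(qid, qs, qe)
    data.frame(query_id = qid, subject_id = "m", percent_identity = 99,
               alignment_length = qe - qs + 1L, mismatches = 0L,
               gap_opens = 0L, q_start = qs, q_end = qe, s_start = 1L,
               s_end = qe - qs + 1L, e_value = 1e-30, bit_score = 100)
  ## q1: overlapping HSPs (1-50) + (40-95) -> union 95 > 90 -> removed
  ## q2: single HSP 1-90 -> exactly 0.90, not strictly above -> retained
  ## q3: no records -> retained
  aln <- rbind(mk("q1", 1L, 50L), mk("q1", 40L, 95L), mk("q2", 1L, 90L))
  res <- filterBySimilarity(ds, aln)
  expect_identical(names(res$removed), "q1")
  expect_setequal(names(res$retained), c("q2", "q3"))
  expect_equal(res$coverage$covered_fraction,
               c(0.95, 0.90, 0), tolerance = 1e-12)
  expect_warning(
    filterBySimilarity(ds, rbind(aln, mk("ghost", 1L, 10L))),
    "unknown queries")
})

test_that("coverage filter agrees with a per-base boolean oracle", {
  set.seed(42)
  for (rep in seq_len(1000L)) {
    qlen <- sample(50:200, 1L)
    nHsp <- sample(0:5, 1L)
    covered <- logical(qlen)
    rows <- list()
    for (h in seq_len(nHsp)) {
      qs <- sample.int(qlen, 1L)
      qe <- min(qlen, qs + sample.int(qlen, 1L) - 1L)
      covered[qs:qe] <- TRUE
      rows[[h]] <- data.frame(
        query_id = "q", subject_id = "s", percent_identity = 99,
        alignment_length = qe - qs + 1L, mismatches = 0L,
        gap_opens = 0L, q_start = qs, q_end = qe, s_start = 1L,
        s_end = 1L, e_value = 0, bit_score = 1)
    }
    ds <- lncDataset(
      Biostrings::DNAStringSet(c(q = paste(
        sample(c("A", "C", "G", "T"), qlen, TRUE), collapse = ""))),
      "lncRNA", "sim", 0L, qlen, 0L)
    aln <- if (nHsp) do.call(rbind, rows) else
      data.frame(query_id = character(), subject_id = character(),
                 percent_identity = numeric(),
                 alignment_length = integer(), mismatches = integer(),
                 gap_opens = integer(), q_start = integer(),
                 q_end = integer(), s_start = integer(),
                 s_end = integer(), e_value = numeric(),
                 bit_score = numeric())
    res <- filterBySimilarity(ds, aln)
    oracleFrac <- mean(covered)
    expect_equal(res$coverage$covered_fraction, oracleFrac,
                 tolerance = 1e-12)
    expect_identical(length(res$removed) == 1L, oracleFrac > 0.9)
  }
})

test_that("extraction records core spans and matches the genome", {
  g <- Biostrings::DNAStringSet(
    c(chr1 = paste(sample(c("A", "C", "G", "T"), 10000L, TRUE),
                   collapse = "")))
  loci <- data.frame(chrom = "chr1", start = c(1000L, 0L),
                     end = c(1500L, 300L),
                     locus_id = c("a", "b"), stringsAsFactors = FALSE)
  ds <- extractFlankedSequences(g, loci, flank = 500L)
  expect_identical(Biostrings::width(datasetSequences(ds)),
                   c(1500L, 800L))
  cs <- coreSpans(ds)
  expect_identical(cs$start, c(500L, 0L))
  expect_identical(cs$end, c(1000L, 300L))
  ## extracted sequence equals the genome substring at flanked coords
  expect_identical(as.character(datasetSequences(ds))[[1L]],
                   substr(as.character(g[[1L]]), 501L, 2000L))
  badLoci <- data.frame(chrom = "chr1", start = 9990L, end = 10010L,
                        locus_id = "z")
  expect_error(extractFlankedSequences(g, badLoci, 500L), "z")
})

test_that("controls are length-matched, exclusion-free, deterministic", {
  set.seed(5)
  g <- Biostrings::DNAStringSet(
    c(chr1 = paste(sample(c("A", "C", "G", "T"), 50000L, TRUE),
                   collapse = ""),
      chr2 = paste(sample(c("A", "C", "G", "T"), 50000L, TRUE),
                   collapse = "")))
  excluded <- data.frame(chrom = c("chr1", "chr2"),
                         start = c(10000L, 0L), end = c(20000L, 5000L))
  lengths <- c(1500L, 800L, 1200L, 1500L)
  c1 <- generateControls(g, excluded, lengths, seed = 9L, flank = 500L)
  c2 <- generateControls(g, excluded, lengths, seed = 9L, flank = 500L)
  expect_identical(sort(Biostrings::width(datasetSequences(c1))),
                   sort(lengths))
  expect_identical(as.character(datasetSequences(c1)),
                   as.character(datasetSequences(c2)))
  expect_identical(attr(c1, "coordinates"), attr(c2, "coordinates"))
  coords <- attr(c1, "coordinates")
  for (i in seq_len(nrow(coords))) {
    ex <- excluded[excluded$chrom == coords$chrom[i], , drop = FALSE]
    if (nrow(ex))
      expect_false(any(coords$start[i] < ex$end &
                         coords$end[i] > ex$start))
  }
})

test_that("a control is forced into the only available gap", {
  set.seed(6)
  g <- Biostrings::DNAStringSet(
    c(chr1 = paste(sample(c("A", "C", "G", "T"), 10000L, TRUE),
                   collapse = "")))
  ## everything excluded except a 2000 bp gap at 4000..6000
  excluded <- data.frame(chrom = "chr1", start = c(0L, 6000L),
                         end = c(4000L, 10000L))
  ctrl <- generateControls(g, excluded, 1500L, seed = 1L, flank = 500L)
  coords <- attr(ctrl, "coordinates")
  expect_gte(coords$start, 4000L)
  expect_lte(coords$end, 6000L)
  expect_error(
    generateControls(g, excluded, 2500L, seed = 1L, flank = 500L,
                     maxTries = 50L),
    "could not place")
})

test_that("splits are stratified, disjoint, exhaustive, deterministic", {
  seqs <- Biostrings::DNAStringSet(stats::setNames(
    randomDNA(200L, 60L, seed = 11L), sprintf("s%03d", 1:200)))
  ds <- lncDataset(seqs, rep(c("lncRNA", "non-lncRNA"), each = 100L),
                   "sim", 0L, 60L, 0L)
  sp <- splitDataset(ds, testFraction = 0.2, seed = 21L)
  expect_identical(table(datasetLabels(sp$test)),
                   table(factor(rep(c("lncRNA", "non-lncRNA"), 20L),
                                levels = c("lncRNA", "non-lncRNA"))))
  expect_length(intersect(names(sp$train), names(sp$test)), 0L)
  expect_setequal(c(names(sp$train), names(sp$test)), names(ds))
  sp2 <- splitDataset(ds, testFraction = 0.2, seed = 21L)
  expect_identical(names(sp2$train), names(sp$train))
  tiny <- ds[c(1L, 101L, 102L)]   # one lncRNA only
  expect_error(splitDataset(tiny, 0.2, 1L), "at least 2")
})

test_that("k-mer tokenization follows the sliding-window definition", {
  expect_identical(seqToKmers("ATCGAT", 3L), c("ATC", "TCG", "CGA", "GAT"))
  expect_identical(seqToKmers("AAAA", 4L), "AAAA")
  expect_error(seqToKmers("AT", 3L), "shorter than k")
  expect_error(seqToKmers("ATCGAT", 7L), "k must be")
  expect_error(seqToKmers("ATXGAT", 3L), "other than")
  ## round-trip against run merging for every k and random sequences
  set.seed(33)
  for (k in 3:6) {
    for (s in randomDNA(5L, sample(20:80, 1L))) {
      expect_identical(mergeKmerRun(seqToKmers(s, k)), s)
    }
  }
})

test_that("dataset TSV serialization round-trips", {
  ds <- makeSeparableDataset(nPerClass = 5L, len = 60L, seed = 2L)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeDatasetTSV(ds, path)
  back <- readDatasetTSV(path)
  expect_identical(as.character(datasetSequences(back)),
                   as.character(datasetSequences(ds)))
  expect_identical(datasetLabels(back), datasetLabels(ds))
  expect_identical(coreSpans(back), coreSpans(ds))
  expect_identical(flankLength(back), flankLength(ds))
})

test_that("buildDataset wires extraction, filtering, controls, split", {
  cfg <- simConfig(nChromosomes = 2L, chromosomeLength = 120000L,
                   nLoci = 30L, seed = 17L)
  sim <- simulateSpecies(cfg, "simZ")
  suppressWarnings(
    bd <- buildDataset(sim$genome, sim$loci, flank = 500L, seed = 17L))
  expect_identical(length(bd$full), 60L)
  lnc <- bd$full[datasetLabels(bd$full) == "lncRNA"]
  ctrl <- bd$full[datasetLabels(bd$full) == "non-lncRNA"]
  ## exact multiset equality of class length distributions
  expect_identical(sort(Biostrings::width(datasetSequences(lnc))),
                   sort(Biostrings::width(datasetSequences(ctrl))))
  expect_identical(length(bd$train) + length(bd$test), 60L)
})
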