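test_that("motif presence counts sequences, not occurrences", {
  expect_identical(countMotifPresence("AAT", c("AAATG", "CCCC")),
                   c(with_motif = 1L, total = 2L))
  ## presence counts "AAAA" once even though "AAA" matches twice
  expect_identical(countMotifPresence("AAA", "AAAA"),
                   c(with_motif = 1L, total = 1L))
  expect_identical(countMotifPresence("AAA", "AAAA",
                                      mode = "occurrences"), 2L)
  expect_identical(countMotifPresence("GGG", c("AAA", "TTT")),
                   c(with_motif = 0L, total = 2L))
  expect_error(countMotifPresence("", "AAA"), "non-empty")
})

test_that("chi-square matches the worked table and the null table", {
  res <- chiSquareMotif(30L, 100L, 10L, 100L)
  expect_equal(res$statistic, 12.5, tolerance = 1e-10)
  null <- chiSquareMotif(20L, 100L, 20L, 100L)
  expect_equal(null$statistic, 0, tolerance = 1e-12)
  expect_equal(null$p_value, 1, tolerance = 1e-12)
  degen <- chiSquareMotif(0L, 50L, 0L, 50L)
  expect_true(degen$degenerate)
  expect_identical(degen$p_value, 1)
})

test_that("chi-square agrees with the expected-counts formula on
           random tables and p decreases in the statistic", {
  ## independent oracle: textbook sum((O-E)^2/E) with marginal-derived E
  oracle <- function(a, n1, b, n2) {
    O <- matrix(c(a, n1 - a, b, n2 - b), 2L, byrow = TRUE)
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    sum((O - E)^2 / E)
  }
  set.seed(55)
  stats <- numeric(0)
  for (i in seq_len(500L)) {
    n1 <- sample(10:200, 1L); n2 <- sample(10:200, 1L)
    a <- sample(1:(n1 - 1L), 1L); b <- sample(1:(n2 - 1L), 1L)
    got <- chiSquareMotif(a, n1, b, n2)
    expect_equal(got$statistic, oracle(a, n1, b, n2),
                 tolerance = 1e-10)
    expect_equal(got$p_value,
                 stats::pchisq(got$statistic, 1L, lower.tail = FALSE),
                 tolerance = 1e-12)
    stats <- c(stats, got$statistic)
  }
  ps <- stats::pchisq(stats, 1L, lower.tail = FALSE)
  ord <- order(stats)
  expect_true(all(diff(ps[ord]) <= 1e-15))
})

test_that("significant motifs are kept only when lncRNA-enriched at
           p < alpha", {
  set.seed(66)
  lnc <- randomDNA(80L, 300L)
  ctrl <- randomDNA(80L, 300L)
  ## plant a motif in most lncRNAs, none in controls
  for (i in 1:60) substr(lnc[i], 10L, 19L) <- "GTACGTACGT"
  ranked <- data.frame(motif_sequence = c("GTACGTACGT", "TGCATGA"),
                       frequency = c(10L, 5L),
                       total_attribution = c(1, 1),
                       importance = c(10, 5), rank = 1:2)
  res <- significantMotifs(ranked, lnc, ctrl, alpha = 0.05)
  expect_true(res$significant[res$motif_sequence == "GTACGTACGT"])
  expect_lt(res$p_value[1L], 1e-10)
  ## a motif equally frequent in both groups is dropped
  expect_false(res$significant[res$motif_sequence == "TGCATGA"])
  expect_error(significantMotifs(ranked, character(), ctrl), "non-empty")
  ## BH adjustment only tightens decisions
  resBH <- significantMotifs(ranked, lnc, ctrl, adjust = "BH")
  expect_true(all(resBH$significant <= res$significant))
})

test_that("motif sharing counts exact and clustered intersections", {
  sets <- list(sp1 = c("AAAA", "CCGG"), sp2 = c("AAAA", "TTTT"))
  sh <- sharedMotifs(sets)
  expect_identical(sh$pairwise["sp1", "sp2"], 1L)
  expect_identical(sh$pairwise, t(sh$pairwise))
  ## per-combination counts partition the unique motifs
  expect_identical(sum(sh$combinations$n_motifs),
                   length(unique(unlist(sets))))
  ## homopolymer length variants join one substring-linkage cluster
  cl <- sharedMotifs(list(a = "AAAAAAA", b = "AAAAAAAA"),
                     cluster = TRUE)
  expect_identical(cl$pairwise["a", "b"], 0L)          # exact: disjoint
  expect_identical(cl$pairwiseClusters["a", "b"], 1L)  # clustered: shared
  expect_identical(unname(cl$clusters["AAAAAAA"]),
                   unname(cl$clusters["AAAAAAAA"]))
  ## pairwise counts bounded by set sizes
  set.seed(77)
  big <- list(x = unique(randomDNA(20L, 8L)),
              y = unique(randomDNA(20L, 8L)),
              z = unique(randomDNA(20L, 8L)))
  shb <- sharedMotifs(big)
  for (i in names(big)) for (j in names(big))
    expect_lte(shb$pairwise[i, j],
               min(length(big[[i]]), length(big[[j]])))
  expect_error(sharedMotifs(list(only = "AAA")), "at least 2")
})

test_that("positional bins map flank and body offsets correctly", {
  ## one sequence: 500 up + 1000 core + 500 down
  s <- strrep("C", 2000L)
  substr(s, 11L, 14L) <- "AAAA"     # upstream offset 10 -> bin 1
  substr(s, 31L, 34L) <- "AAAA"     # upstream offset 30 -> bin 2
  substr(s, 1491L, 1494L) <- "AAAA" # core offset 990 -> bin 40
  substr(s, 2000L, 2000L) <- "C"
  ds <- lncDataset(Biostrings::DNAStringSet(c(x = s)), "lncRNA", "sim",
                   coreStart = 500L, coreEnd = 1500L, flank = 500L)
  prof <- positionalProfile("AAAA", ds, normalized = FALSE)
  bins <- as.numeric(prof[1L, paste0("bin_", 1:60)])
  expect_identical(bins[1L], 1); expect_identical(bins[2L], 1)
  expect_identical(bins[40L], 1)
  expect_identical(sum(bins), 3)
  ## downstream offset 499 -> bin 60
  s2 <- strrep("C", 2000L)
  substr(s2, 2000L - 3L, 2000L) <- "AAAA"  # starts at offset 1996
  ds2 <- lncDataset(Biostrings::DNAStringSet(c(x = s2)), "lncRNA",
                    "sim", coreStart = 500L, coreEnd = 1500L,
                    flank = 500L)
  prof2 <- positionalProfile("AAAA", ds2, normalized = FALSE)
  expect_identical(as.numeric(prof2[1L, "bin_60"]), 1)
})

test_that("bin assignment agrees with a per-position scan oracle", {
  ## brute force: for every genome position, find the bin by explicit
  ## region comparison
  oracleBins <- function(s, motif, cs, ce, flank) {
    bins <- numeric(60L)
    L <- nchar(s); fl <- flank / 20
    for (p in 0:(L - nchar(motif))) {
      if (substr(s, p + 1L, p + nchar(motif)) != motif) next
      b <- if (p < cs) {
        d <- cs - p
        bb <- 21 - ceiling(d / fl)
        if (bb < 1) NA else bb
      } else if (p < ce) {
        min(40, 21 + floor((p - cs) / ((ce - cs) / 20)))
      } else {
        bb <- 41 + floor((p - ce) / fl)
        if (bb > 60) NA else bb
      }
      if (!is.na(b)) bins[b] <- bins[b] + 1
    }
    bins
  }
  set.seed(88)
  for (rep in seq_len(25L)) {
    core <- sample(seq(200L, 600L, 20L), 1L)
    s <- paste(sample(c("A", "C", "G", "T"), 1000L + core, TRUE,
                      prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
    ds <- lncDataset(Biostrings::DNAStringSet(c(x = s)), "lncRNA",
                     "sim", coreStart = 500L, coreEnd = 500L + core,
                     flank = 500L)
    motif <- paste(sample(c("A", "T"), 3L, TRUE), collapse = "")
    got <- as.numeric(
      positionalProfile(motif, ds, normalized = FALSE)[1L, -1L])
    expect_equal(got, oracleBins(s, motif, 500L, 500L + core, 500L),
                 tolerance = 1e-12)
  }
})

test_that("body-bin normalization rescales by bin-width ratio", {
  ## raw contribution 4 in a body bin, body bin 50 bp vs flank bin 25 bp
  contrib <- matrix(0, 1L, 60L)
  contrib[1L, 21L] <- 4
  contrib[1L, 1L] <- 4
  out <- normalizeBins(contrib, coreBinLengths = 50, flankBin = 25)
  expect_equal(out[21L], 2.0, tolerance = 1e-12)
  expect_equal(out[1L], 4, tolerance = 1e-12)       # flank untouched
  ## identity when body bin width equals flank bin width
  out2 <- normalizeBins(contrib, coreBinLengths = 25, flankBin = 25)
  expect_equal(out2[21L], 4, tolerance = 1e-12)
  expect_warning(normalizeBins(contrib, 0, 25), "zero body length")
})

test_that("normalization leaves constant-density bodies invariant to
           length doubling", {
  ## same per-base motif density, doubled core length: normalized body
  ## mass should agree in expectation
  mkDs <- function(coreLen, seed) {
    withr::with_seed(seed, {
      n <- 60L
      seqs <- vapply(seq_len(n), function(i) {
        paste(sample(c("A", "C", "G", "T"), 1000L + coreLen, TRUE),
              collapse = "")
      }, character(1L))
      names(seqs) <- sprintf("s%02d", seq_len(n))
      lncDataset(Biostrings::DNAStringSet(seqs), "lncRNA", "sim",
                 coreStart = 500L, coreEnd = 500L + coreLen,
                 flank = 500L)
    })
  }
  p1 <- positionalProfile("ACG", mkDs(400L, 1L), normalized = TRUE)
  p2 <- positionalProfile("ACG", mkDs(800L, 2L), normalized = TRUE)
  body1 <- sum(p1[1L, paste0("bin_", 21:40)])
  body2 <- sum(p2[1L, paste0("bin_", 21:40)])
  ## expectation equal; allow generous sampling slack
  expect_lt(abs(body1 - body2) / max(body1, body2), 0.2)
})

test_that("flank-planted motifs concentrate profile mass in flank bins", {
  cfg <- simConfig(nChromosomes = 2L, chromosomeLength = 200000L,
                   nLoci = 40L, flankMotifs = "GTCAGTCA",
                   motifInsertProbability = 1, seed = 31L)
  sim <- simulateSpecies(cfg, "simP")
  ds <- extractFlankedSequences(sim$genome, sim$loci, flank = 500L)
  prof <- positionalProfile("GTCAGTCA", ds, normalized = TRUE)
  bins <- as.numeric(prof[1L, paste0("bin_", 1:60)])
  flankMass <- sum(bins[c(1:20, 41:60)])
  expect_gte(flankMass / sum(bins), 0.7)
})
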