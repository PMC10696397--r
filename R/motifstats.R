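## Motif statistics: chi-square enrichment of discovered motifs in
## lncRNA versus control sequences, cross-species motif sharing, and the
## 60-bin positional profile with body-length normalization.

#' Count sequences containing a motif
#'
#' Presence semantics (how many sequences contain at least one exact
#' occurrence), mirroring line-wise grep counting; an occurrences mode
#' counts every (possibly overlapping) match instead.
#'
#' @param motif a DNA string.
#' @param sequences an [LncDataset-class], [Biostrings::DNAStringSet] or
#'   character vector.
#' @param mode `"presence"` (default) or `"occurrences"`.
#' @return for presence: named vector `c(with_motif, total)`; for
#'   occurrences: total match count across sequences.
#' @examples
#' countMotifPresence("AAT", c("AAATG", "CCCC"))   # 1 of 2
#' @export
countMotifPresence <- function(motif, sequences,
                               mode = c("presence", "occurrences")) {
  mode <- match.arg(mode)
  if (!nzchar(motif)) stop("motif must be non-empty")
  seqs <- asCharacterSeqs(sequences)
  if (mode == "presence") {
    c(with_motif = sum(vapply(seqs, function(s)
      length(findAllOccurrences(s, motif)) > 0L, logical(1L))),
      total = length(seqs))
  } else {
    sum(vapply(seqs, function(s)
      length(findAllOccurrences(s, motif)), integer(1L)))
  }
}

asCharacterSeqs <- function(sequences) {
  if (is(sequences, "LncDataset"))
    as.character(datasetSequences(sequences))
  else as.character(sequences)
}

## All (overlapping) exact match start offsets, 0-based.
findAllOccurrences <- function(seq, motif) {
  m <- gregexpr(paste0("(?=", motif, ")"), seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer() else as.integer(m) - 1L
}

#' Chi-square test of motif enrichment
#'
#' Pearson chi-square (df = 1, no continuity correction) on the 2x2
#' presence table `[[lnc_with, lnc_without], [ctrl_with,
#' ctrl_without]]`. A zero marginal makes the statistic undefined; such
#' tables are flagged and reported with `p_value = 1`.
#'
#' @param lncWith,lncTotal sequences with the motif / total, lncRNA
#'   class.
#' @param ctrlWith,ctrlTotal same for the control class.
#' @return list with `statistic`, `p_value`, `degenerate`.
#' @examples
#' chiSquareMotif(30, 100, 10, 100)$statistic   # 12.5
#' @export
chiSquareMotif <- function(lncWith, lncTotal, ctrlWith, ctrlTotal) {
  stopifnot(lncTotal > 0, ctrlTotal > 0, lncWith <= lncTotal,
            ctrlWith <= ctrlTotal, lncWith >= 0, ctrlWith >= 0)
  tab <- matrix(c(lncWith, lncTotal - lncWith,
                  ctrlWith, ctrlTotal - ctrlWith),
                nrow = 2L, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(statistic = NA_real_, p_value = 1, degenerate = TRUE))
  fit <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(fit$statistic),
       p_value = unname(fit$p.value), degenerate = FALSE)
}

#' Significance-test ranked motifs against controls
#'
#' For each ranked motif, counts presence in the lncRNA and control
#' sequences and applies [chiSquareMotif()]; motifs are kept when
#' enriched in lncRNAs with raw `p < alpha` (no multiple-testing
#' correction, matching the raw `p < 0.05` convention;
#' `adjust = "BH"` applies Benjamini-Hochberg instead).
#'
#' @param ranked data.frame from [rankMotifs()] (needs
#'   `motif_sequence`; other columns are carried through).
#' @param lncSeqs,ctrlSeqs sequence sets (see [countMotifPresence()]).
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with per-motif counts, `chi_square_statistic`,
#'   `p_value`, `significant`.
#' @export
significantMotifs <- function(ranked, lncSeqs, ctrlSeqs, alpha = 0.05,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  lnc <- asCharacterSeqs(lncSeqs)
  ctrl <- asCharacterSeqs(ctrlSeqs)
  if (!length(lnc) || !length(ctrl))
    stop("both sequence sets must be non-empty")
  if (!nrow(ranked))
    return(data.frame(motif_sequence = character(),
                      lnc_with_motif = integer(), lnc_total = integer(),
                      ctrl_with_motif = integer(),
                      ctrl_total = integer(),
                      chi_square_statistic = numeric(),
                      p_value = numeric(), significant = logical()))
  rows <- lapply(ranked$motif_sequence, function(m) {
    a <- countMotifPresence(m, lnc)
    b <- countMotifPresence(m, ctrl)
    ct <- chiSquareMotif(a[["with_motif"]], a[["total"]],
                         b[["with_motif"]], b[["total"]])
    data.frame(motif_sequence = m,
               lnc_with_motif = a[["with_motif"]],
               lnc_total = a[["total"]],
               ctrl_with_motif = b[["with_motif"]],
               ctrl_total = b[["total"]],
               chi_square_statistic = ct$statistic,
               p_value = ct$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  p <- if (adjust == "BH") stats::p.adjust(out$p_value, "BH") else
    out$p_value
  out$significant <- !is.na(out$chi_square_statistic) & p < alpha &
    out$lnc_with_motif / out$lnc_total >
      out$ctrl_with_motif / out$ctrl_total
  out
}

#' Cross-species motif sharing
#'
#' Exact-match sharing counts between species motif sets, with optional
#' similarity clustering: when `cluster = TRUE`, motifs are grouped by
#' single linkage where two motifs link iff one is a substring of the
#' other (merging homopolymer-length variants such as 7-mer and 8-mer
#' poly-A), and sharing is additionally reported at cluster level.
#'
#' @param perSpecies named list mapping species to character vectors of
#'   significant motifs.
#' @param cluster also compute substring-linkage cluster sharing.
#' @return list with `pairwise` (symmetric shared-motif count matrix),
#'   `combinations` (data.frame: species combination, motif count --
#'   upset-style membership counts over unique motifs), and, when
#'   clustering, `clusters` (motif -> cluster id) plus
#'   `pairwiseClusters`.
#' @export
sharedMotifs <- function(perSpecies, cluster = FALSE) {
  if (length(perSpecies) < 2L) stop("need at least 2 species")
  sets <- lapply(perSpecies, unique)
  sp <- names(sets)
  pairwise <- matrix(0L, length(sp), length(sp),
                     dimnames = list(sp, sp))
  for (i in seq_along(sp))
    for (j in seq_along(sp))
      pairwise[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  allMotifs <- unique(unlist(sets))
  membership <- vapply(sets, function(s) allMotifs %in% s,
                       logical(length(allMotifs)))
  if (is.null(dim(membership)))
    membership <- matrix(membership, nrow = length(allMotifs))
  combo <- apply(membership, 1L, function(r)
    paste(sp[r], collapse = "&"))
  combinations <- as.data.frame(table(combination = combo),
                                stringsAsFactors = FALSE)
  names(combinations)[2L] <- "n_motifs"
  out <- list(pairwise = pairwise, combinations = combinations)
  if (cluster) {
    cl <- substringClusters(allMotifs)
    clusterSets <- lapply(sets, function(s) unique(cl[s]))
    pc <- matrix(0L, length(sp), length(sp), dimnames = list(sp, sp))
    for (i in seq_along(sp))
      for (j in seq_along(sp))
        pc[i, j] <- length(intersect(clusterSets[[i]],
                                     clusterSets[[j]]))
    out$clusters <- cl
    out$pairwiseClusters <- pc
  }
  out
}

## Single-linkage clustering by substring containment (union-find).
substringClusters <- function(motifs) {
  n <- length(motifs)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      if (grepl(motifs[i], motifs[j], fixed = TRUE) ||
          grepl(motifs[j], motifs[i], fixed = TRUE)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  ids <- match(roots, unique(roots))
  stats::setNames(paste0("cluster_", ids), motifs)
}

#' 60-bin positional profile of motif occurrences
#'
#' Assigns every exact motif occurrence (by its start position) to one
#' of 60 bins: bins 1--20 tile the upstream flank in `flank/20`-base
#' intervals, bins 21--40 tile the locus body in `coreLength/20`-base
#' intervals, and bins 41--60 tile the downstream flank. Because body
#' length varies while flanks are fixed, each sequence's body-bin
#' contribution is rescaled by `flank-bin width / body-bin width`
#' (see [normalizeBins()]) so longer bodies are not over-counted;
#' `normalized = FALSE` returns raw counts.
#'
#' @param motifs character vector of motif strings.
#' @param dataset an [LncDataset-class]; every sequence must carry a
#'   core span.
#' @param normalized apply body-bin length normalization (default TRUE).
#' @return data.frame with `motif_sequence` and `bin_1` .. `bin_60`.
#' @export
positionalProfile <- function(motifs, dataset, normalized = TRUE) {
  stopifnot(is(dataset, "LncDataset"))
  seqs <- as.character(datasetSequences(dataset))
  cs <- dataset@coreStart
  ce <- dataset@coreEnd
  flank <- flankLength(dataset)
  if (flank <= 0L) stop("dataset flank length must be positive")
  flankBin <- flank / 20
  out <- lapply(motifs, function(m) {
    contrib <- matrix(0, nrow = length(seqs), ncol = 60L)
    coreBinLengths <- numeric(length(seqs))
    for (i in seq_along(seqs)) {
      coreLen <- ce[i] - cs[i]
      coreBinLengths[i] <- coreLen / 20
      hits <- findAllOccurrences(seqs[[i]], m)
      for (pos in hits) {
        b <- positionToBin(pos, cs[i], ce[i], nchar(seqs[[i]]),
                           flankBin, coreLen)
        if (!is.na(b)) contrib[i, b] <- contrib[i, b] + 1
      }
    }
    bins <- if (normalized)
      normalizeBins(contrib, coreBinLengths, flankBin)
    else colSums(contrib)
    stats::setNames(as.data.frame(as.list(bins)),
                    paste0("bin_", 1:60)) |>
      cbind(motif_sequence = m)
  })
  res <- do.call(rbind, out)
  res[, c("motif_sequence", paste0("bin_", 1:60))]
}

## Map a 0-based occurrence start to its bin (1..60), or NA when the
## region it falls in has zero width.
positionToBin <- function(pos, coreStart, coreEnd, seqLen, flankBin,
                          coreLen) {
  if (pos < coreStart) {
    ## upstream flank; align bin 20 to the core boundary so clamped
    ## (shortened) flanks lose their outermost bins
    d <- coreStart - pos               # distance before core start, >= 1
    b <- 21L - as.integer(ceiling(d / flankBin))
    if (b < 1L) NA_integer_ else b
  } else if (pos < coreEnd) {
    if (coreLen <= 0) return(NA_integer_)
    b <- 21L + as.integer(floor((pos - coreStart) / (coreLen / 20)))
    min(b, 40L)
  } else {
    e <- pos - coreEnd                 # offset into downstream flank
    b <- 41L + as.integer(floor(e / flankBin))
    if (b > 60L) NA_integer_ else b
  }
}

#' Length-normalize body bins of a positional profile
#'
#' Rescales each sequence's contribution to the body bins (21--40) by
#' `flankBin / coreBin`, expressing body counts per flank-bin width so
#' sequences with longer bodies do not dominate, then accumulates over
#' sequences. Flank bins are summed unchanged. Sequences with zero body
#' length are skipped with a warning.
#'
#' @param contrib numeric matrix, sequences x 60 bins, of raw per-
#'   sequence occurrence counts.
#' @param coreBinLengths per-sequence body-bin width in bases
#'   (`coreLength/20`).
#' @param flankBin flank-bin width in bases (`flank/20`).
#' @return numeric vector of 60 accumulated bin values.
#' @export
normalizeBins <- function(contrib, coreBinLengths, flankBin) {
  stopifnot(ncol(contrib) == 60L,
            nrow(contrib) == length(coreBinLengths))
  zero <- coreBinLengths <= 0
  if (any(zero)) {
    warning(sum(zero), " sequence(s) with zero body length skipped in ",
            "body-bin normalization")
  }
  scale <- ifelse(zero, 0, flankBin / coreBinLengths)
  body <- contrib[, 21:40, drop = FALSE] * scale
  out <- colSums(contrib)
  out[21:40] <- colSums(body)
  out
}
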