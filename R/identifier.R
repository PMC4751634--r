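## Reconstruction of unknown adapter sequences from paired-end data.
##
## The raw mates are aligned against each other (no adapter padding, since
## the adapters are unknown) under a stricter acceptance than trimming: a
## 1/10 mismatch rate and a minimum overlap of 11 by default, because no
## adapter anchor constrains the alignment. Pairs whose inferred insert is
## shorter than the read length read through into adapter; the read-through
## fragments are stacked into per-position base counts and a majority-rule
## consensus is called.

#' Extract putative adapter fragments from overlapping read pairs
#'
#' Aligns `seq1` against `revcomp(seq2)` for every pair; when the acceptable
#' alignment implies an insert shorter than the reads, returns the mate 1
#' suffix beyond the insert (an adapter 1 fragment) and the mate 2 suffix
#' beyond the insert (an adapter 2 fragment, already in adapter
#' orientation).
#'
#' @param reads1,reads2 mate [`FastqReads`].
#' @param mm mismatch-rate parameter for the read-to-read alignment.
#' @param minOverlap minimum alignment overlap required.
#' @param minScore minimum alignment score.
#' @return a data frame with columns `pair`, `insertLength`, `fragment1`,
#'   `fragment2`, one row per read-through pair.
#' @export
adapterFragments <- function(reads1, reads2, mm = 10, minOverlap = 11L,
                             minScore = 1L) {
  stopifnot(is(reads1, "FastqReads"), is(reads2, "FastqReads"),
            length(reads1) == length(reads2))
  r2max <- max(nchar(reads2@sequence))
  res <- cpp_trim_pe(reads1@sequence, reads2@sequence, "", "",
                     mm, as.integer(minScore), as.integer(minOverlap),
                     as.integer(r2max - 1L))
  ins <- res$insert
  len1 <- nchar(reads1@sequence)
  len2 <- nchar(reads2@sequence)
  keep <- which(!is.na(ins) & ins < len1 & ins < len2)
  data.frame(
    pair = keep,
    insertLength = ins[keep],
    fragment1 = substr(reads1@sequence[keep], ins[keep] + 1L, len1[keep]),
    fragment2 = substr(reads2@sequence[keep], ins[keep] + 1L, len2[keep]),
    stringsAsFactors = FALSE)
}

#' Accumulate one read pair into adapter fragments
#'
#' Single-pair convenience wrapper around [adapterFragments()].
#'
#' @param read1,read2 single-record [`FastqReads`].
#' @inheritParams adapterFragments
#' @return a list with `fragment1` and `fragment2`, or `NULL` when the pair
#'   does not read through into adapter.
#' @export
accumulatePair <- function(read1, read2, mm = 10, minOverlap = 11L,
                           minScore = 1L) {
  fr <- adapterFragments(read1, read2, mm, minOverlap, minScore)
  if (nrow(fr) == 0L) return(NULL)
  list(fragment1 = fr$fragment1[1], fragment2 = fr$fragment2[1])
}

.countBases <- function(fragments) {
  lens <- nchar(fragments)
  if (length(fragments) == 0L || max(lens) == 0L)
    return(matrix(0L, 5L, 0L, dimnames = list(c("A", "C", "G", "T", "N"),
                                              NULL)))
  chars <- unlist(strsplit(fragments, ""), use.names = FALSE)
  pos <- unlist(lapply(lens, seq_len), use.names = FALSE)
  tab <- table(factor(chars, levels = c("A", "C", "G", "T", "N")),
               factor(pos, levels = seq_len(max(lens))))
  m <- matrix(as.integer(tab), nrow = 5L,
              dimnames = list(c("A", "C", "G", "T", "N"), NULL))
  m
}

#' Build a consensus matrix from adapter fragments
#'
#' @param fragments a data frame from [adapterFragments()].
#' @return a [`ConsensusMatrix`][ConsensusMatrix-class].
#' @export
buildConsensusMatrix <- function(fragments) {
  new("ConsensusMatrix",
      mat1 = .countBases(fragments$fragment1),
      mat2 = .countBases(fragments$fragment2),
      nPairsUsed = nrow(fragments))
}

.consensusFromCounts <- function(m) {
  if (ncol(m) == 0L)
    return(list(consensus = "", agreement = numeric()))
  acgt <- m[c("A", "C", "G", "T"), , drop = FALSE]
  covered <- colSums(m) > 0L
  end <- if (all(covered)) ncol(m) else which(!covered)[1] - 1L
  if (end == 0L) return(list(consensus = "", agreement = numeric()))
  bases <- character(end)
  agree <- rep(NA_real_, end)
  for (j in seq_len(end)) {
    col <- acgt[, j]
    tot <- sum(col)
    if (tot == 0L) {         # position covered only by N observations
      bases[j] <- "N"
      next
    }
    top <- which(col == max(col))
    bases[j] <- if (length(top) > 1L) "N" else rownames(acgt)[top]
    agree[j] <- max(col) / tot
  }
  list(consensus = paste(bases, collapse = ""), agreement = agree)
}

#' @describeIn ConsensusMatrix-class call the majority-rule consensus for
#'   both adapters. Per position the majority base is emitted; a tie yields
#'   `N`; a position observed only as `N` emits `N`; the consensus ends at
#'   the first position no fragment reaches. The agreement fraction is the
#'   majority count over the column total (excluding `N` observations).
#' @export
setMethod("callConsensus", "ConsensusMatrix", function(x) {
  if (x@nPairsUsed < 1L)
    stop("consensus requires at least one contributing pair")
  c1 <- .consensusFromCounts(x@mat1)
  c2 <- .consensusFromCounts(x@mat2)
  list(adapter1 = c1$consensus, adapter2 = c2$consensus,
       agreement1 = c1$agreement, agreement2 = c2$agreement)
})

#' Reconstruct unknown adapter sequences from paired-end reads
#'
#' Runs [adapterFragments()], accumulates the fragments into a
#' [`ConsensusMatrix`][ConsensusMatrix-class] and calls the consensus.
#'
#' @inheritParams adapterFragments
#' @return a list with `adapter1`, `adapter2`, `agreement1`, `agreement2`,
#'   `nPairsUsed` and the `matrix` (a `ConsensusMatrix`).
#' @export
identifyAdapters <- function(reads1, reads2, mm = 10, minOverlap = 11L,
                             minScore = 1L) {
  fr <- adapterFragments(reads1, reads2, mm, minOverlap, minScore)
  cm <- buildConsensusMatrix(fr)
  if (cm@nPairsUsed == 0L)
    stop("no read-through pairs found; cannot reconstruct adapters")
  cons <- callConsensus(cm)
  c(cons, list(nPairsUsed = cm@nPairsUsed, matrix = cm))
}

#' Number of correctly reconstructed leading bases
#'
#' Length of the longest common prefix of a reconstructed adapter and the
#' true adapter (`N` positions match only `N`).
#'
#' @param consensus,truth non-empty sequences.
#' @return integer count of correct leading bases.
#' @examples
#' leadingCorrectBases("AGTTC", "AGATC") # 2
#' @export
leadingCorrectBases <- function(consensus, truth) {
  if (!nzchar(consensus) || !nzchar(truth))
    stop("sequences must be non-empty")
  a <- strsplit(consensus, "")[[1]]
  b <- strsplit(truth, "")[[1]]
  k <- min(length(a), length(b))
  same <- a[seq_len(k)] == b[seq_len(k)]
  if (all(same)) k else which(!same)[1] - 1L
}
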