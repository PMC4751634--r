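## Collapse overlapping read pairs into the reconstructed insert.
##
## Single-covered positions copy base and quality from the covering mate
## (mate 2 reverse complemented). Double-covered positions are combined by
## treating the two quality scores as a position-specific scoring matrix:
## agreeing observations reinforce each other (Phred scores add, capped),
## disagreeing observations retain the higher-quality base at the score
## difference, and an exact tie between different bases yields N at
## quality 0.

#' Combine two base observations at one position
#'
#' Vectorised. An `N` observation contributes a flat likelihood: the other
#' base is emitted with its own quality.
#'
#' @param base1,base2 observed bases in `{A,C,G,T,N}`.
#' @param q1,q2 Phred scores of the observations.
#' @param qualityCap maximum emitted Phred score.
#' @return a list with character vector `base` and integer vector `quality`.
#' @examples
#' combineBases("A", 20, "A", 20)  # A, 40
#' combineBases("A", 30, "C", 10)  # A, 20
#' combineBases("A", 15, "C", 15)  # N, 0
#' @export
combineBases <- function(base1, q1, base2, q2, qualityCap = 41L) {
  n <- max(length(base1), length(base2))
  base1 <- rep_len(toupper(base1), n); q1 <- rep_len(as.integer(q1), n)
  base2 <- rep_len(toupper(base2), n); q2 <- rep_len(as.integer(q2), n)
  base <- character(n)
  qual <- integer(n)
  n1 <- base1 == "N"
  n2 <- base2 == "N"
  agree <- !n1 & !n2 & base1 == base2
  diff1 <- !n1 & !n2 & base1 != base2 & q1 > q2
  diff2 <- !n1 & !n2 & base1 != base2 & q2 > q1
  tie <- !n1 & !n2 & base1 != base2 & q1 == q2
  base[n1 & n2] <- "N";      qual[n1 & n2] <- 0L
  base[n1 & !n2] <- base2[n1 & !n2]; qual[n1 & !n2] <- q2[n1 & !n2]
  base[!n1 & n2] <- base1[!n1 & n2]; qual[!n1 & n2] <- q1[!n1 & n2]
  base[agree] <- base1[agree]; qual[agree] <- q1[agree] + q2[agree]
  base[diff1] <- base1[diff1]; qual[diff1] <- q1[diff1] - q2[diff1]
  base[diff2] <- base2[diff2]; qual[diff2] <- q2[diff2] - q1[diff2]
  base[tie] <- "N"; qual[tie] <- 0L
  qual <- pmin(pmax(qual, 0L), as.integer(qualityCap))
  list(base = base, quality = qual)
}

#' Collapse overlapping read pairs
#'
#' Using the pair alignment from [trimPairedEnd()], emits one read spanning
#' the inferred insert for every pair whose alignment overlap reaches
#' `minOverlap`. Pass the original (or the trimmed) reads together with the
#' `TrimResult` they produced: only positions inside the inferred insert are
#' consulted.
#'
#' @param reads1,reads2 the mate [`FastqReads`] the alignment was computed
#'   from.
#' @param alignment the [`TrimResult`][TrimResult-class] from
#'   [trimPairedEnd()] on those reads.
#' @param settings a [`MergeSettings`] object.
#' @return a [`MergeResult`][MergeResult-class]: `isMerged()` flags collapsed
#'   pairs, `mergedReads()` holds their reconstructed inserts (ids taken from
#'   mate 1), `sourceOverlap()` counts double-covered positions.
#' @export
mergePairs <- function(reads1, reads2, alignment,
                       settings = mergeSettings()) {
  stopifnot(is(reads1, "FastqReads"), is(reads2, "FastqReads"),
            is(alignment, "TrimResult"), is(settings, "MergeSettings"))
  if (length(reads1) != length(alignment))
    stop("reads and alignment differ in length")
  res <- cpp_merge(reads1@sequence, reads1@quality,
                   reads2@sequence, reads2@quality,
                   alignment@insertLength, alignment@alignmentOverlap,
                   settings@minOverlap, settings@qualityCap)
  merged <- res$merged
  mlen <- rep(NA_integer_, length(merged))
  mlen[merged] <- nchar(res$sequence[merged])
  reads <- FastqReads(id = reads1@id[merged],
                      sequence = res$sequence[merged],
                      quality = res$quality[merged])
  new("MergeResult", reads = reads, merged = merged,
      mergedLength = mlen, overlap = res$overlap)
}

#' Trim and collapse paired-end reads in one step
#'
#' @param reads1,reads2 mate [`FastqReads`].
#' @param trim a [`TrimSettings`] object.
#' @param merge a [`MergeSettings`] object.
#' @return a list with elements `trim` ([`TrimResult`][TrimResult-class]) and
#'   `merge` ([`MergeResult`][MergeResult-class]).
#' @export
collapsePairs <- function(reads1, reads2, trim = trimSettings(),
                          merge = mergeSettings()) {
  tr <- trimPairedEnd(reads1, reads2, trim)
  mg <- mergePairs(reads1, reads2, tr, merge)
  list(trim = tr, merge = mg)
}
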