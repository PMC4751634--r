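## Ungapped overlap alignment kernel. An exhaustive scan over every offset at
## which the two sequences overlap by at least one base; no indels. Positions
## where either base is N are ambiguous: they contribute nothing to the score
## and are excluded from the mismatch-rate denominator.

#' Mismatch rate implied by the mm parameter
#'
#' Values of `mm` greater than 1 mean a maximum error rate of `1/mm`; values
#' in `(0, 1]` are the rate itself.
#'
#' @param settings an [`AlignmentSettings`] object (or a bare number).
#' @return the maximum tolerated mismatch rate as a fraction.
#' @examples
#' mismatchRate(alignmentSettings(mm = 5))
#' @export
mismatchRate <- function(settings) {
  mm <- if (is(settings, "AlignmentSettings")) settings@mm else settings
  if (mm > 1) 1 / mm else mm
}

#' Best ungapped overlap alignment between two sequences
#'
#' Enumerates every offset of `seqB` relative to `seqA` (from `minOffset` up
#' to `nchar(seqA) - 1`) at which the sequences overlap by at least one base,
#' counting matches, mismatches and ambiguous positions (either base `N`) at
#' each. Returns the offset maximising `score = matches - mismatches`, with
#' ties broken first by longer overlap, then by smaller offset.
#'
#' @param seqA,seqB non-empty sequences over `{A,C,G,T,N}`.
#' @param minOffset smallest offset considered; negative offsets let `seqB`
#'   start before `seqA`.
#' @return an [`AlignmentResult`][AlignmentResult-class] object.
#' @examples
#' alignOverlap("ACGTACGT", "ACGTACGT")
#' alignOverlap("ACNT", "ACGT")
#' @export
alignOverlap <- function(seqA, seqB, minOffset = 0L) {
  seqA <- toupper(seqA)
  seqB <- toupper(seqB)
  if (!nzchar(seqA) || !nzchar(seqB))
    stop("sequences must be non-empty")
  if (!grepl(.SEQ_PATTERN, seqA) || !grepl(.SEQ_PATTERN, seqB))
    stop("sequences may only contain A, C, G, T, N")
  r <- cpp_align_overlap(seqA, seqB, as.integer(minOffset))
  if (!r$valid)
    stop("no overlapping offset >= minOffset exists")
  new("AlignmentResult", offset = r$offset, overlapLength = r$overlap,
      matches = r$matches, mismatches = r$mismatches,
      ambiguous = r$ambiguous, score = r$score)
}

#' Maximum mismatches tolerated in an overlap
#'
#' `floor(effectiveOverlap * rate)`, where the effective overlap excludes
#' ambiguous positions and the rate follows [mismatchRate()].
#'
#' @param effectiveOverlap number of unambiguously compared positions
#'   (`matches + mismatches`).
#' @inheritParams mismatchRate
#' @return integer count of tolerated mismatches.
#' @examples
#' maxMismatchesAllowed(9, alignmentSettings(mm = 3)) # 3
#' maxMismatchesAllowed(9, alignmentSettings(mm = 5)) # 1
#' @export
maxMismatchesAllowed <- function(effectiveOverlap, settings) {
  stopifnot(all(effectiveOverlap >= 0))
  as.integer(floor(effectiveOverlap * mismatchRate(settings) + 1e-9))
}

#' Is an alignment acceptable evidence of adapter presence?
#'
#' An alignment is accepted when its score reaches `minScore` (default 1, so
#' the score must be positive) and its mismatches do not exceed the tolerated
#' budget for its effective overlap. The budget is
#' [maxMismatchesAllowed()], additionally capped for short alignments, which
#' carry little evidence: below 6 unambiguously called bases no mismatch is
#' tolerated, and below 10 at most one. Without this guard, short spurious 3'
#' matches with a 1-in-3 error rate would be trimmed from adapter-free reads
#' far more often than genuine read-through justifies.
#'
#' @param result an [`AlignmentResult`][AlignmentResult-class].
#' @param settings an [`AlignmentSettings`] object.
#' @return `TRUE` or `FALSE`.
#' @examples
#' isAcceptable(alignOverlap("ACGTACGT", "ACGTACGT"), alignmentSettings())
#' @export
isAcceptable <- function(result, settings) {
  stopifnot(is(result, "AlignmentResult"))
  called <- result@matches + result@mismatches
  threshold <- maxMismatchesAllowed(called, settings)
  if (called < 6L) threshold <- 0L
  else if (called < 10L) threshold <- min(threshold, 1L)
  result@score >= settings@minScore && result@mismatches <= threshold
}
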