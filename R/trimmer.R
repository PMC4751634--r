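## Single-end and paired-end adapter trimming.
##
## Single-end: each adapter's 5' end is aligned against the read at offsets
## >= 0 (the adapter may run past the read's 3' end). Paired-end: the mate 2
## adapter (reverse complemented) is prefixed to the mate 1 sequence and the
## mate 1 adapter appended to the reverse-complemented mate 2 sequence; the
## two aggregates are aligned and the inferred insert length locates the 3'
## terminus of the insert in each mate.
##
## In both modes the single best alignment (highest score; ties broken by
## longer overlap, smaller offset, then adapter list order) is selected
## across all configured adapters FIRST, and the acceptance rule is applied
## to that candidate alone: if the best alignment fails the mismatch test the
## read passes through untrimmed, even if some lesser alignment would have
## been acceptable.

.truncateReads <- function(reads, lengths) {
  new("FastqReads", id = reads@id,
      sequence = substr(reads@sequence, 1L, lengths),
      quality = substr(reads@quality, 1L, lengths))
}

#' Trim adapter sequence from single-end reads
#'
#' Aligns every configured adapter against the 3' region of each read,
#' selects the best alignment and, if it is acceptable under the settings and
#' spans at least `minAdapterOverlap` positions, truncates the read (sequence
#' and qualities) at the alignment offset. Reads without an acceptable
#' alignment pass through unmodified; a read consisting entirely of adapter
#' is trimmed to length zero.
#'
#' @param reads a [`FastqReads`] object.
#' @param settings a [`TrimSettings`] object.
#' @return a [`TrimResult`][TrimResult-class].
#' @examples
#' ad <- adapterPair("AGATCGGAAGAGC", "AGATCGGAAGAGC")
#' reads <- FastqReads("r", paste0(strrep("ACGT", 10), "AGATCGGAA"),
#'                     strrep("I", 49))
#' trimSingleEnd(reads, trimSettings(adapters = ad))
#' @export
trimSingleEnd <- function(reads, settings = trimSettings()) {
  stopifnot(is(reads, "FastqReads"), is(settings, "TrimSettings"))
  n <- length(reads)
  origLen <- nchar(reads@sequence)
  a1 <- vapply(settings@adapters, adapter1, character(1))
  res <- cpp_trim_se(reads@sequence, a1, settings@alignment@mm,
                     settings@alignment@minScore, settings@minAdapterOverlap)
  newLen <- res[, 1]
  idx <- res[, 2]
  idx[idx == 0L] <- NA_integer_
  new("TrimResult", reads1 = .truncateReads(reads, newLen),
      reads2 = FastqReads(), paired = FALSE, adapterIndex = idx,
      insertLength = rep(NA_integer_, n),
      alignmentOverlap = rep(NA_integer_, n),
      basesTrimmed1 = as.integer(origLen - newLen),
      basesTrimmed2 = integer(n))
}

#' Trim adapter read-through from paired-end reads
#'
#' For each adapter pair, builds the aggregates
#' `A = revcomp(adapter2) + seq1` and `B = revcomp(seq2) + adapter1`, aligns
#' them (allowing negative offsets down to `-(nchar(adapter2) + maxShift)`),
#' and infers the insert length from the best acceptable alignment. When the
#' inferred insert is shorter than a mate, that mate is truncated at the
#' insert boundary, removing the adapter (and any trailing) bases. Pairs with
#' no acceptable alignment pass through unmodified.
#'
#' @param reads1,reads2 mate 1 and mate 2 [`FastqReads`] (equal length,
#'   no empty sequences).
#' @param settings a [`TrimSettings`] object.
#' @return a [`TrimResult`][TrimResult-class]; [insertLengths()] gives the
#'   inferred insert length per pair (`NA` when no acceptable alignment).
#' @export
trimPairedEnd <- function(reads1, reads2, settings = trimSettings()) {
  stopifnot(is(reads1, "FastqReads"), is(reads2, "FastqReads"),
            is(settings, "TrimSettings"))
  if (length(reads1) != length(reads2))
    stop("mate sets differ in length")
  if (any(nchar(reads1@sequence) == 0L) || any(nchar(reads2@sequence) == 0L))
    stop("mate sequences must be non-empty")
  a1 <- vapply(settings@adapters, adapter1, character(1))
  a2 <- vapply(settings@adapters, adapter2, character(1))
  res <- cpp_trim_pe(reads1@sequence, reads2@sequence, a1, a2,
                     settings@alignment@mm, settings@alignment@minScore,
                     1L, settings@alignment@maxShift)
  len1 <- nchar(reads1@sequence)
  len2 <- nchar(reads2@sequence)
  ins <- res$insert
  new1 <- ifelse(is.na(ins), len1, pmin(len1, ins))
  new2 <- ifelse(is.na(ins), len2, pmin(len2, ins))
  idx <- res$adapter
  idx[idx == 0L] <- NA_integer_
  new("TrimResult", reads1 = .truncateReads(reads1, new1),
      reads2 = .truncateReads(reads2, new2), paired = TRUE,
      adapterIndex = idx, insertLength = ins,
      alignmentOverlap = res$overlap,
      basesTrimmed1 = as.integer(len1 - new1),
      basesTrimmed2 = as.integer(len2 - new2))
}

#' Select the best-matching adapter for one read or pair
#'
#' Evaluates every configured adapter (pair) against a single read (pair) and
#' returns the one whose best alignment scores highest, with ties broken by
#' adapter list order. The acceptance rule is applied to the winning
#' alignment; if it fails, the adapter index is `NA`.
#'
#' @param read a single-record [`FastqReads`] (mate 1).
#' @param settings a [`TrimSettings`] object.
#' @param read2 optional single-record mate 2 [`FastqReads`] for paired-end
#'   selection.
#' @return a list with elements `adapterIndex` (integer or `NA`) and
#'   `alignment` (the selected [`AlignmentResult`][AlignmentResult-class]).
#' @export
selectBestAdapter <- function(read, settings = trimSettings(), read2 = NULL) {
  stopifnot(is(read, "FastqReads"), length(read) == 1L)
  best <- NULL
  bestIdx <- NA_integer_
  for (j in seq_along(settings@adapters)) {
    pair <- settings@adapters[[j]]
    if (is.null(read2)) {
      aln <- alignOverlap(read@sequence, pair@adapter1, 0L)
    } else {
      rcA2 <- revComplement(pair@adapter2)
      a <- paste0(rcA2, read@sequence)
      b <- paste0(revComplement(read2@sequence), pair@adapter1)
      aln <- alignOverlap(a, b,
                          -(nchar(rcA2) + settings@alignment@maxShift))
    }
    if (is.null(best) || aln@score > best@score ||
        (aln@score == best@score &&
         (aln@overlapLength > best@overlapLength ||
          (aln@overlapLength == best@overlapLength &&
           aln@offset < best@offset)))) {
      best <- aln
      bestIdx <- j
    }
  }
  ok <- isAcceptable(best, settings@alignment) &&
    (!is.null(read2) || best@overlapLength >= settings@minAdapterOverlap)
  list(adapterIndex = if (ok) bestIdx else NA_integer_, alignment = best)
}
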