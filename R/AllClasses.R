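## Central S4 classes. Sequences are stored as plain uppercase character
## vectors over {A,C,G,T,N}; qualities as Phred+33 encoded strings, one
## character per base.

.SEQ_PATTERN <- "^[ACGTN]*$"

## ---------------------------------------------------------------------------
## FastqReads

#' Container for FASTQ records
#'
#' Holds a set of sequencing reads: identifiers, nucleotide sequences over
#' `{A,C,G,T,N}` and per-base Phred+33 encoded quality strings. Sequence and
#' quality of each record always have equal length and every quality score
#' lies in `[0, 93]`.
#'
#' @param id character vector of read identifiers.
#' @param sequence character vector of nucleotide sequences (lowercase is
#'   normalised to uppercase).
#' @param quality character vector of Phred+33 quality strings, or a list of
#'   integer Phred scores which will be encoded.
#' @param x a `FastqReads` object.
#' @param i index.
#'
#' @return `FastqReads()` returns a `FastqReads` object. `readIDs()`,
#'   `readSequences()` and `readQualities()` return character vectors;
#'   `phredScores()` returns a list of integer vectors of Phred scores.
#'
#' @examples
#' reads <- FastqReads("r1", "ACGT", "IIII")
#' phredScores(reads)
#' @aliases FastqReads readIDs readSequences readQualities phredScores
#' @export FastqReads
#' @exportClass FastqReads
setClass("FastqReads",
         representation(id = "character", sequence = "character",
                        quality = "character"))

setValidity("FastqReads", function(object) {
  n <- length(object@id)
  if (length(object@sequence) != n || length(object@quality) != n)
    return("id, sequence and quality must have equal length")
  if (any(!grepl(.SEQ_PATTERN, object@sequence)))
    return("sequences may only contain A, C, G, T, N")
  if (any(nchar(object@sequence) != nchar(object@quality)))
    return("sequence and quality lengths differ")
  qr <- range(c(33L, utf8ToInt(paste(object@quality, collapse = ""))))
  if (qr[1] < 33L || qr[2] > 126L)
    return("quality characters must encode Phred scores in [0, 93]")
  TRUE
})

FastqReads <- function(id = character(), sequence = character(),
                       quality = character()) {
  if (is.list(quality))
    quality <- vapply(quality, encodePhred, character(1))
  new("FastqReads", id = as.character(id),
      sequence = toupper(as.character(sequence)),
      quality = as.character(quality))
}

#' @rdname FastqReads-class
#' @export
setMethod("length", "FastqReads", function(x) length(x@id))

#' @rdname FastqReads-class
#' @export
setMethod("[", "FastqReads", function(x, i, j, ..., drop = TRUE) {
  new("FastqReads", id = x@id[i], sequence = x@sequence[i],
      quality = x@quality[i])
})

setMethod("show", "FastqReads", function(object) {
  n <- length(object)
  cat("FastqReads with", n, "records\n")
  if (n > 0) {
    k <- min(n, 3L)
    for (i in seq_len(k))
      cat(sprintf("  %s [%d bp]\n", object@id[i], nchar(object@sequence[i])))
    if (n > k) cat("  ...\n")
  }
})

setMethod("readIDs", "FastqReads", function(x) x@id)
setMethod("readSequences", "FastqReads", function(x) x@sequence)
setMethod("readQualities", "FastqReads", function(x) x@quality)
setMethod("phredScores", "FastqReads", function(x)
  lapply(x@quality, decodePhred))

#' Combine FastqReads objects
#' @param x,... `FastqReads` objects.
#' @return a single concatenated `FastqReads` object.
#' @export
setMethod("c", "FastqReads", function(x, ...) {
  args <- c(list(x), list(...))
  new("FastqReads",
      id = unlist(lapply(args, slot, "id")),
      sequence = unlist(lapply(args, slot, "sequence")),
      quality = unlist(lapply(args, slot, "quality")))
})

## ---------------------------------------------------------------------------
## AdapterPair

#' A pair of adapter sequences
#'
#' The adapter read into at the 3' end of mate 1 reads (`adapter1`) and the
#' adapter read into at the 3' end of mate 2 reads (`adapter2`). For
#' single-end data only `adapter1` is used.
#'
#' @param a1,a2 adapter sequences over `{A,C,G,T,N}`; `N` marks positions
#'   (such as sample indices) that match any base.
#' @param x an `AdapterPair`.
#' @return `adapterPair()` returns an `AdapterPair`; `adapter1()` and
#'   `adapter2()` return the component sequences.
#' @examples
#' adapterPair("AGATCGGAAGAGC", "AGATCGGAAGAGC")
#' @aliases adapterPair adapter1 adapter2
#' @export adapterPair
#' @exportClass AdapterPair
setClass("AdapterPair",
         representation(adapter1 = "character", adapter2 = "character"))

setValidity("AdapterPair", function(object) {
  for (a in c(object@adapter1, object@adapter2)) {
    if (length(object@adapter1) != 1L || length(object@adapter2) != 1L)
      return("adapters must be single sequences")
    if (!nzchar(a)) return("adapters must be non-empty")
    if (!grepl(.SEQ_PATTERN, a))
      return("adapters may only contain A, C, G, T, N")
  }
  TRUE
})

adapterPair <- function(a1, a2) {
  new("AdapterPair", adapter1 = toupper(a1), adapter2 = toupper(a2))
}

setMethod("adapter1", "AdapterPair", function(x) x@adapter1)
setMethod("adapter2", "AdapterPair", function(x) x@adapter2)

setMethod("show", "AdapterPair", function(object) {
  cat("AdapterPair\n  adapter1:", object@adapter1,
      "\n  adapter2:", object@adapter2, "\n")
})

## ---------------------------------------------------------------------------
## Settings

#' Alignment acceptance settings
#'
#' Parameters governing which overlap alignments are accepted as evidence of
#' adapter presence.
#'
#' @param mm mismatch-rate parameter: values greater than 1 set the maximum
#'   error rate to `1/mm` (so `mm = 3` allows one mismatch per three aligned
#'   bases); values in `(0, 1]` are used as the rate directly.
#' @param minScore minimum alignment score (`matches - mismatches`) an
#'   accepted alignment must reach. The default 1 requires positive evidence.
#' @param maxShift for paired-end alignment, how far the mates may slide past
#'   the adapter-padded aggregate start (bound on negative offsets beyond the
#'   mate 2 adapter length).
#' @return an `AlignmentSettings` object.
#' @examples
#' alignmentSettings(mm = 5)
#' @aliases alignmentSettings
#' @export alignmentSettings
#' @exportClass AlignmentSettings
setClass("AlignmentSettings",
         representation(mm = "numeric", minScore = "integer",
                        maxShift = "integer"))

setValidity("AlignmentSettings", function(object) {
  if (length(object@mm) != 1L || !is.finite(object@mm) || object@mm <= 0)
    return("mm must be a single positive number")
  if (object@maxShift < 0L) return("maxShift must be non-negative")
  TRUE
})

alignmentSettings <- function(mm = 3, minScore = 1L, maxShift = 5L) {
  new("AlignmentSettings", mm = as.numeric(mm),
      minScore = as.integer(minScore), maxShift = as.integer(maxShift))
}

setMethod("show", "AlignmentSettings", function(object) {
  cat(sprintf("AlignmentSettings: mm=%g (rate %.3g), minScore=%d, maxShift=%d\n",
              object@mm, mismatchRate(object), object@minScore,
              object@maxShift))
})

#' Trimming settings
#'
#' @param adapters an [`AdapterPair`] or a list of them; with several pairs
#'   the best-matching pair is selected per read (pair).
#' @param alignment an [`AlignmentSettings`] object.
#' @param minAdapterOverlap minimum adapter overlap (in aligned positions)
#'   required before a single-end read is trimmed. Has no effect on
#'   paired-end trimming, where the evidence comes from the mate overlap.
#' @return a `TrimSettings` object.
#' @examples
#' trimSettings(minAdapterOverlap = 3)
#' @aliases trimSettings
#' @export trimSettings
#' @exportClass TrimSettings
setClass("TrimSettings",
         representation(adapters = "list", alignment = "AlignmentSettings",
                        minAdapterOverlap = "integer"))

setValidity("TrimSettings", function(object) {
  if (length(object@adapters) < 1L)
    return("at least one adapter pair is required")
  if (!all(vapply(object@adapters, is, logical(1), "AdapterPair")))
    return("adapters must be AdapterPair objects")
  if (object@minAdapterOverlap < 0L)
    return("minAdapterOverlap must be non-negative")
  TRUE
})

trimSettings <- function(adapters = hiseqAdapterPair(),
                         alignment = alignmentSettings(),
                         minAdapterOverlap = 0L) {
  if (is(adapters, "AdapterPair")) adapters <- list(adapters)
  new("TrimSettings", adapters = adapters, alignment = alignment,
      minAdapterOverlap = as.integer(minAdapterOverlap))
}

setMethod("show", "TrimSettings", function(object) {
  cat(sprintf("TrimSettings: %d adapter pair(s), minAdapterOverlap=%d\n",
              length(object@adapters), object@minAdapterOverlap))
  show(object@alignment)
})

#' Merge (collapse) settings
#'
#' @param minOverlap minimum pair-alignment overlap length required before a
#'   pair is collapsed. The default 11 refuses collapsing when fewer than 11
#'   aligned positions support the overlap.
#' @param qualityCap maximum Phred score emitted for combined bases
#'   (default 41, the Illumina 1.8 maximum).
#' @return a `MergeSettings` object.
#' @examples
#' mergeSettings(qualityCap = 50)
#' @aliases mergeSettings
#' @export mergeSettings
#' @exportClass MergeSettings
setClass("MergeSettings",
         representation(minOverlap = "integer", qualityCap = "integer"))

setValidity("MergeSettings", function(object) {
  if (object@minOverlap < 0L) return("minOverlap must be non-negative")
  if (object@qualityCap > 93L || object@qualityCap < 0L)
    return("qualityCap must lie in [0, 93]")
  TRUE
})

mergeSettings <- function(minOverlap = 11L, qualityCap = 41L) {
  new("MergeSettings", minOverlap = as.integer(minOverlap),
      qualityCap = as.integer(qualityCap))
}

## ---------------------------------------------------------------------------
## AlignmentResult

#' Result of an ungapped overlap alignment
#'
#' Describes the best overlap between two sequences: the offset of sequence B
#' relative to sequence A, the number of compared positions, and the
#' match/mismatch/ambiguous breakdown. Positions where either base is `N` are
#' ambiguous and score-neutral; `score == matches - mismatches`.
#'
#' @aliases AlignmentResult
#' @exportClass AlignmentResult
setClass("AlignmentResult",
         representation(offset = "integer", overlapLength = "integer",
                        matches = "integer", mismatches = "integer",
                        ambiguous = "integer", score = "integer"))

setValidity("AlignmentResult", function(object) {
  if (object@matches + object@mismatches + object@ambiguous !=
      object@overlapLength)
    return("matches + mismatches + ambiguous must equal overlapLength")
  if (object@score != object@matches - object@mismatches)
    return("score must equal matches - mismatches")
  if (object@overlapLength < 0L) return("overlapLength must be >= 0")
  TRUE
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf(
    "AlignmentResult: offset=%d overlap=%d matches=%d mismatches=%d ambiguous=%d score=%d\n",
    object@offset, object@overlapLength, object@matches, object@mismatches,
    object@ambiguous, object@score))
})

## ---------------------------------------------------------------------------
## TrimResult

#' Result of adapter trimming
#'
#' Holds the trimmed reads together with, per read (pair): the index of the
#' matched adapter pair (`NA` when no acceptable alignment was found), the
#' inferred insert length (paired-end only), the pair-alignment overlap
#' length, and the number of bases removed from each mate.
#'
#' @param x a `TrimResult`.
#' @param mate which mate to return (1 or 2).
#' @aliases TrimResult trimmedReads insertLengths adapterIndices basesTrimmed
#' @exportClass TrimResult
setClass("TrimResult",
         representation(reads1 = "FastqReads", reads2 = "FastqReads",
                        paired = "logical", adapterIndex = "integer",
                        insertLength = "integer",
                        alignmentOverlap = "integer",
                        basesTrimmed1 = "integer",
                        basesTrimmed2 = "integer"))

setMethod("length", "TrimResult", function(x) length(x@reads1))

setMethod("trimmedReads", "TrimResult", function(x, mate = 1L) {
  if (mate == 1L) x@reads1 else x@reads2
})
setMethod("insertLengths", "TrimResult", function(x) x@insertLength)
setMethod("adapterIndices", "TrimResult", function(x) x@adapterIndex)
setMethod("basesTrimmed", "TrimResult", function(x, mate = 1L) {
  if (mate == 1L) x@basesTrimmed1 else x@basesTrimmed2
})

setMethod("show", "TrimResult", function(object) {
  n <- length(object)
  trimmed <- sum(object@basesTrimmed1 > 0L)
  cat(sprintf("TrimResult: %d %s read%s, %d with bases removed from mate 1\n",
              n, if (object@paired) "paired" else "single-end",
              if (n == 1) "" else "s", trimmed))
})

## ---------------------------------------------------------------------------
## MergeResult

#' Result of collapsing overlapping read pairs
#'
#' @param x a `MergeResult`.
#' @aliases MergeResult mergedReads isMerged mergedLengths sourceOverlap
#' @exportClass MergeResult
setClass("MergeResult",
         representation(reads = "FastqReads", merged = "logical",
                        mergedLength = "integer", overlap = "integer"))

setMethod("length", "MergeResult", function(x) length(x@merged))
setMethod("mergedReads", "MergeResult", function(x) x@reads)
setMethod("isMerged", "MergeResult", function(x) x@merged)
setMethod("mergedLengths", "MergeResult", function(x) x@mergedLength)
setMethod("sourceOverlap", "MergeResult", function(x) x@overlap)

setMethod("show", "MergeResult", function(object) {
  cat(sprintf("MergeResult: %d pairs, %d collapsed\n",
              length(object), sum(object@merged)))
})

## ---------------------------------------------------------------------------
## ConfusionCounts

#' Confusion-matrix tallies and derived metrics
#'
#' `confusionCounts()` stores TP/TN/FP/FN tallies; [computeMetrics()] derives
#' sensitivity, specificity, positive and negative predictive value and the
#' Matthews correlation coefficient.
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @param x a `ConfusionCounts` object.
#' @return `confusionCounts()` returns a `ConfusionCounts`;
#'   `computeMetrics()` returns a named numeric vector with elements `sen`,
#'   `spc`, `ppv`, `npv`, `mcc`. A zero denominator yields `NaN` for the
#'   affected metric, except for `mcc` where it yields 0.
#' @examples
#' computeMetrics(confusionCounts(938, 955, 45, 62))
#' @aliases confusionCounts computeMetrics
#' @export confusionCounts
#' @exportClass ConfusionCounts
setClass("ConfusionCounts",
         representation(tp = "numeric", tn = "numeric", fp = "numeric",
                        fn = "numeric"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@tn, object@fp, object@fn)
  if (any(v < 0) || any(v != round(v)))
    return("counts must be non-negative integers")
  TRUE
})

confusionCounts <- function(tp, tn, fp, fn) {
  new("ConfusionCounts", tp = as.numeric(tp), tn = as.numeric(tn),
      fp = as.numeric(fp), fn = as.numeric(fn))
}

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%g TN=%g FP=%g FN=%g\n",
              object@tp, object@tn, object@fp, object@fn))
})

## ---------------------------------------------------------------------------
## BarcodeTable

#' Table of sample barcodes for demultiplexing
#'
#' @param sample character vector of unique sample names.
#' @param barcode1 barcodes read at the 5' end of mate 1; all must have equal
#'   length.
#' @param barcode2 optional barcodes read at the 5' end of mate 2
#'   (double-indexing); all must have equal length.
#' @param maxMismatches maximum total Hamming distance (summed over mates)
#'   for a read to be assigned to a sample.
#' @return a `BarcodeTable` object.
#' @examples
#' barcodeTable(c("s1", "s2"), c("ACGT", "TTAA"))
#' @aliases barcodeTable
#' @export barcodeTable
#' @exportClass BarcodeTable
setClass("BarcodeTable",
         representation(sample = "character", barcode1 = "character",
                        barcode2 = "character", maxMismatches = "integer"))

setValidity("BarcodeTable", function(object) {
  n <- length(object@sample)
  if (anyDuplicated(object@sample)) return("sample names must be unique")
  if (length(object@barcode1) != n)
    return("one barcode1 per sample is required")
  if (length(unique(nchar(object@barcode1))) > 1L)
    return("barcode1 sequences must have equal length")
  if (length(object@barcode2) > 0L) {
    if (length(object@barcode2) != n)
      return("barcode2 must be absent or one per sample")
    if (length(unique(nchar(object@barcode2))) > 1L)
      return("barcode2 sequences must have equal length")
  }
  if (any(!grepl("^[ACGT]+$", c(object@barcode1, object@barcode2))))
    return("barcodes may only contain A, C, G, T")
  if (object@maxMismatches < 0L) return("maxMismatches must be >= 0")
  TRUE
})

barcodeTable <- function(sample, barcode1, barcode2 = character(),
                         maxMismatches = 1L) {
  if (is.null(barcode2)) barcode2 <- character()
  new("BarcodeTable", sample = as.character(sample),
      barcode1 = toupper(barcode1), barcode2 = toupper(barcode2),
      maxMismatches = as.integer(maxMismatches))
}

setMethod("show", "BarcodeTable", function(object) {
  cat(sprintf("BarcodeTable: %d samples, %s-indexed, maxMismatches=%d\n",
              length(object@sample),
              if (length(object@barcode2)) "double" else "single",
              object@maxMismatches))
})

## ---------------------------------------------------------------------------
## ConsensusMatrix

#' Per-position base counts over putative adapter fragments
#'
#' Two 5 x L count matrices (rows `A`, `C`, `G`, `T`, `N`), one per mate
#' adapter, accumulated from the read-through fragments of overlapping read
#' pairs, plus the number of pairs that contributed.
#'
#' @param x a `ConsensusMatrix`.
#' @return [callConsensus()] returns a list with elements `adapter1`,
#'   `adapter2` (majority-rule consensus sequences), `agreement1` and
#'   `agreement2` (per-position majority fractions).
#' @aliases ConsensusMatrix callConsensus
#' @exportClass ConsensusMatrix
setClass("ConsensusMatrix",
         representation(mat1 = "matrix", mat2 = "matrix",
                        nPairsUsed = "integer"))

setValidity("ConsensusMatrix", function(object) {
  for (m in list(object@mat1, object@mat2)) {
    if (nrow(m) != 5L) return("count matrices must have 5 rows (A,C,G,T,N)")
    if (ncol(m) > 0 && any(colSums(m) > object@nPairsUsed))
      return("column sums may not exceed nPairsUsed")
  }
  TRUE
})

setMethod("show", "ConsensusMatrix", function(object) {
  cat(sprintf("ConsensusMatrix: %d pairs used, lengths %d / %d\n",
              object@nPairsUsed, ncol(object@mat1), ncol(object@mat2)))
})

## ---------------------------------------------------------------------------
## SimulationConfig

#' Configuration for the paired-end read simulator
#'
#' Defaults emulate a standard short-insert Illumina library: 2 x 100 bp
#' reads from inserts drawn from a Normal(150, 75) truncated at 1 bp, the
#' standard single-indexed HiSeq adapter pair, and a substitution-error rate
#' ramping linearly from 0.1% at the first cycle to 1% at the last.
#'
#' @param nPairs number of read pairs (or single reads) to simulate.
#' @param readLength read length in bp.
#' @param insertMean,insertSd mean and standard deviation of the insert-length
#'   distribution in bp; draws below 1 are redrawn.
#' @param adapters an [`AdapterPair`] or list of pairs; with several pairs
#'   each insert is assigned one uniformly at random.
#' @param errorModel a list with elements `p` (per-position substitution
#'   probability) and `q` (emitted Phred score per position), as produced by
#'   [defaultErrorModel()].
#' @param referenceLength length of the random reference sequence.
#' @param gcContent GC fraction of the random reference (default 0.41,
#'   human-like).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param paired simulate read pairs (`TRUE`) or mate-1 reads only.
#' @return a `SimulationConfig` object.
#' @examples
#' simulationConfig(nPairs = 100, seed = 1)
#' @aliases simulationConfig
#' @export simulationConfig
#' @exportClass SimulationConfig
setClass("SimulationConfig",
         representation(nPairs = "integer", readLength = "integer",
                        insertMean = "numeric", insertSd = "numeric",
                        adapters = "list", errorP = "numeric",
                        errorQ = "integer", referenceLength = "integer",
                        gcContent = "numeric", seed = "integer",
                        paired = "logical"))

setValidity("SimulationConfig", function(object) {
  if (object@nPairs < 1L) return("nPairs must be >= 1")
  if (object@readLength < 1L) return("readLength must be >= 1")
  if (object@insertSd <= 0) return("insertSd must be positive")
  if (length(object@errorP) != object@readLength ||
      length(object@errorQ) != object@readLength)
    return("error model must provide one rate and quality per position")
  if (any(object@errorP < 0 | object@errorP > 0.75))
    return("per-position substitution rates must lie in [0, 0.75]")
  if (object@gcContent < 0 || object@gcContent > 1)
    return("gcContent must lie in [0, 1]")
  if (!all(vapply(object@adapters, is, logical(1), "AdapterPair")))
    return("adapters must be AdapterPair objects")
  TRUE
})

simulationConfig <- function(nPairs, readLength = 100L, insertMean = 150,
                             insertSd = 75,
                             adapters = hiseqAdapterPair(),
                             errorModel = defaultErrorModel(readLength),
                             referenceLength = 1000000L, gcContent = 0.41,
                             seed = 1L, paired = TRUE) {
  if (is(adapters, "AdapterPair")) adapters <- list(adapters)
  new("SimulationConfig", nPairs = as.integer(nPairs),
      readLength = as.integer(readLength), insertMean = insertMean,
      insertSd = insertSd, adapters = adapters,
      errorP = errorModel$p, errorQ = as.integer(errorModel$q),
      referenceLength = as.integer(referenceLength), gcContent = gcContent,
      seed = as.integer(seed), paired = paired)
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d %s x %d bp, insert N(%g, %g), %d adapter pair(s), seed %d\n",
    object@nPairs, if (object@paired) "pairs" else "reads",
    object@readLength, object@insertMean, object@insertSd,
    length(object@adapters), object@seed))
})
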