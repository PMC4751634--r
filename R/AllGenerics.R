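#' @rdname FastqReads-class
#' @export
setGeneric("readIDs", function(x) standardGeneric("readIDs"))

#' @rdname FastqReads-class
#' @export
setGeneric("readSequences", function(x) standardGeneric("readSequences"))

#' @rdname FastqReads-class
#' @export
setGeneric("readQualities", function(x) standardGeneric("readQualities"))

#' @rdname FastqReads-class
#' @export
setGeneric("phredScores", function(x) standardGeneric("phredScores"))

#' @rdname AdapterPair-class
#' @export
setGeneric("adapter1", function(x) standardGeneric("adapter1"))

#' @rdname AdapterPair-class
#' @export
setGeneric("adapter2", function(x) standardGeneric("adapter2"))

#' @rdname TrimResult-class
#' @export
setGeneric("trimmedReads", function(x, mate = 1L) standardGeneric("trimmedReads"))

#' @rdname TrimResult-class
#' @export
setGeneric("insertLengths", function(x) standardGeneric("insertLengths"))

#' @rdname TrimResult-class
#' @export
setGeneric("adapterIndices", function(x) standardGeneric("adapterIndices"))

#' @rdname TrimResult-class
#' @export
setGeneric("basesTrimmed", function(x, mate = 1L) standardGeneric("basesTrimmed"))

#' @rdname MergeResult-class
#' @export
setGeneric("mergedReads", function(x) standardGeneric("mergedReads"))

#' @rdname MergeResult-class
#' @export
setGeneric("isMerged", function(x) standardGeneric("isMerged"))

#' @rdname MergeResult-class
#' @export
setGeneric("mergedLengths", function(x) standardGeneric("mergedLengths"))

#' @rdname MergeResult-class
#' @export
setGeneric("sourceOverlap", function(x) standardGeneric("sourceOverlap"))

#' @rdname ConfusionCounts-class
#' @export
setGeneric("computeMetrics", function(x) standardGeneric("computeMetrics"))

#' @rdname ConsensusMatrix-class
#' @export
setGeneric("callConsensus", function(x) standardGeneric("callConsensus"))
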