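## Paired-end read simulator with ground truth.
##
## Inserts are drawn from a Normal(insertMean, insertSd) rounded to the
## nearest bp and redrawn until >= 1, sampled from a random reference
## (uniform bases at the configured GC content, random strand). Reads are the
## first readLength bases of insert + adapter; inserts shorter than
## readLength read through into the adapter, which is cycled if the read
## extends past its end. Substitution errors are injected after adapter
## appending, with a per-position rate rising linearly along the read and the
## matching Phred score emitted; N bases (the adapter's index placeholder)
## are left untouched. All randomness flows from the config seed.

.randomSequence <- function(length, gcContent) {
  p <- c((1 - gcContent) / 2, gcContent / 2, gcContent / 2,
         (1 - gcContent) / 2)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = p),
        collapse = "")
}

#' Generate a random reference sequence
#'
#' Deterministic given the seed; base frequencies converge to the target GC
#' content.
#'
#' @param length reference length in bp.
#' @param gcContent target GC fraction.
#' @param seed integer seed.
#' @return a single sequence string.
#' @examples
#' generateReference(50, 0.5, seed = 1)
#' @export
generateReference <- function(length, gcContent = 0.41, seed = 1L) {
  set.seed(as.integer(seed))
  .randomSequence(length, gcContent)
}

#' Position-dependent substitution error model
#'
#' Substitution probability rises linearly from 0.001 at the first position
#' to 0.010 at the last; the emitted Phred score is
#' `round(-10 * log10(p))` per position, and a substituted base is drawn
#' uniformly from the three alternatives.
#'
#' @param readLength read length in bp.
#' @return a list with numeric vector `p` and integer vector `q`.
#' @examples
#' defaultErrorModel(100)$q[c(1, 100)] # 30, 20
#' @export
defaultErrorModel <- function(readLength) {
  p <- if (readLength == 1L) 0.001
       else seq(0.001, 0.010, length.out = readLength)
  list(p = p, q = as.integer(round(-10 * log10(p))))
}

#' Zero-error model (for exact-reconstruction checks)
#'
#' @param readLength read length in bp.
#' @param q constant Phred score to emit.
#' @return a list with elements `p` (all zero) and `q`.
#' @export
errorFreeModel <- function(readLength, q = 40L) {
  list(p = rep(0, readLength), q = rep(as.integer(q), readLength))
}

.cycleAdapter <- function(adapter, len) {
  substr(strrep(adapter, ceiling(len / nchar(adapter)) + 1L), 1L, len)
}

#' Simulate reads with ground truth
#'
#' @param config a [`SimulationConfig`].
#' @param reference optional reference sequence; generated from the config
#'   seed when omitted.
#' @return a list with `reads1` ([`FastqReads`]), `reads2` (`NULL` for
#'   single-end configs) and `truth`, a data frame with one row per pair:
#'   `pairID`, `insertLength`, `start` and `strand` (where the insert was
#'   sampled), `adapterIndex`, `expectedLength1`, `expectedLength2`,
#'   `overlapping` (insert shorter than the summed read lengths).
#' @examples
#' sim <- simulateReads(simulationConfig(nPairs = 5, seed = 1))
#' sim$truth
#' @export
simulateReads <- function(config, reference = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(config@seed)
  n <- config@nPairs
  R <- config@readLength
  if (is.null(reference))
    reference <- .randomSequence(config@referenceLength, config@gcContent)
  refLen <- nchar(reference)

  L <- as.integer(round(rnorm(n, config@insertMean, config@insertSd)))
  while (any(L < 1L))
    L[L < 1L] <- as.integer(round(rnorm(sum(L < 1L), config@insertMean,
                                        config@insertSd)))
  if (any(L > refLen))
    stop("insert longer than the reference sequence")

  start <- floor(runif(n) * (refLen - L + 1)) + 1L
  insert <- substr(rep(reference, n), start, start + L - 1L)
  flip <- runif(n) < 0.5
  insert[flip] <- revComplement(insert[flip])

  nAd <- length(config@adapters)
  aidx <- if (nAd == 1L) rep(1L, n)
          else sample.int(nAd, n, replace = TRUE)
  pad1 <- vapply(config@adapters,
                 function(a) .cycleAdapter(a@adapter1, R), character(1))
  pad2 <- vapply(config@adapters,
                 function(a) .cycleAdapter(a@adapter2, R), character(1))

  short <- L < R
  seq1 <- character(n)
  seq1[!short] <- substr(insert[!short], 1L, R)
  seq1[short] <- paste0(insert[short],
                        substr(pad1[aidx[short]], 1L, R - L[short]))
  seq1 <- cpp_add_errors(seq1, config@errorP)

  qual <- encodePhred(config@errorQ)
  ids <- paste0("sim_", seq_len(n))
  reads2 <- NULL
  if (config@paired) {
    rcIns <- revComplement(insert)
    seq2 <- character(n)
    seq2[!short] <- substr(rcIns[!short], 1L, R)
    seq2[short] <- paste0(rcIns[short],
                          substr(pad2[aidx[short]], 1L, R - L[short]))
    seq2 <- cpp_add_errors(seq2, config@errorP)
    reads2 <- FastqReads(id = paste0(ids, "/2"), sequence = seq2,
                         quality = rep(qual, n))
  }
  reads1 <- FastqReads(id = if (config@paired) paste0(ids, "/1") else ids,
                       sequence = seq1, quality = rep(qual, n))
  truth <- data.frame(
    pairID = ids,
    insertLength = L,
    start = start,
    strand = ifelse(flip, "-", "+"),
    adapterIndex = aidx,
    expectedLength1 = pmin(R, L),
    expectedLength2 = if (config@paired) pmin(R, L) else NA_integer_,
    overlapping = L < (if (config@paired) 2L * R else R),
    stringsAsFactors = FALSE)
  list(reads1 = reads1, reads2 = reads2, truth = truth)
}

#' Write a simulator truth table
#'
#' @param truth the truth data frame from [simulateReads()].
#' @param path output path for a tab-separated file.
#' @return invisibly, `path`.
#' @export
writeTruth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
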