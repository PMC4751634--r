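## Standard adapter sequences and helpers for deriving benchmark variants.

.HISEQ_ADAPTER_1 <- paste0("AGATCGGAAGAGCACACGTCTGAACTCCAGTCACNNNNNN",
                           "ATCTCGTATGCCGTCTTCTGCTTG")
.HISEQ_ADAPTER_2 <- paste0("AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGTAGATCTC",
                           "GGTGGTCGCCGTATCATT")

#' Standard single-indexed Illumina HiSeq adapter pair
#'
#' The default adapters used for trimming: the mate 1 adapter carries a
#' six-base `N` tract at the sample-index position, which matches any base
#' during alignment.
#'
#' @return an [`AdapterPair`].
#' @examples
#' hiseqAdapterPair()
#' @export
hiseqAdapterPair <- function() {
  adapterPair(.HISEQ_ADAPTER_1, .HISEQ_ADAPTER_2)
}

#' Derive adapter pairs by nucleotide shuffling
#'
#' Generates `n` additional adapter pairs by independently permuting the
#' nucleotides of each adapter in `pair` (seeded Fisher-Yates via
#' [sample()]), as used for multi-adapter and adapter-identification
#' benchmarks. Base composition and length are preserved.
#'
#' @param pair the [`AdapterPair`] to shuffle.
#' @param n number of shuffled pairs to generate.
#' @param seed integer seed for reproducibility.
#' @return a list of `n` [`AdapterPair`] objects.
#' @examples
#' shuffledAdapterPairs(hiseqAdapterPair(), 2, seed = 7)
#' @export
shuffledAdapterPairs <- function(pair, n, seed = 1L) {
  stopifnot(is(pair, "AdapterPair"), n >= 1L)
  set.seed(as.integer(seed))
  shuffle <- function(s) {
    paste(sample(strsplit(s, "")[[1]]), collapse = "")
  }
  lapply(seq_len(n), function(i)
    adapterPair(shuffle(pair@adapter1), shuffle(pair@adapter2)))
}
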