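## Demultiplexing by maximum-mismatch barcode comparison, combined with
## barcode-aware adapter trimming: a read pair extending past the insert is
## terminated by the reverse-complemented barcode of the other mate followed
## by adapter, so the per-sample effective adapters gain the corresponding
## barcode prefix.

.hammingToBarcode <- function(prefixes, barcode) {
  ## N in the read counts as a mismatch; prefixes shorter than the barcode
  ## are handled by the caller.
  bc <- strsplit(barcode, "")[[1]]
  m <- do.call(rbind, strsplit(prefixes, ""))
  if (is.null(m)) return(integer())
  rowSums(t(t(m) != bc) | m == "N")
}

#' Assign reads to samples by barcode
#'
#' Compares the 5' prefix of each mate against every barcode (Hamming
#' distance, `N` counting as a mismatch, distances summed over mates) and
#' assigns the unique sample within `maxMismatches`. Ties at the minimal
#' distance, distances above the cap, and reads shorter than the barcode all
#' yield `NA` (unidentified).
#'
#' @param reads1 mate 1 [`FastqReads`].
#' @param table a [`BarcodeTable`].
#' @param reads2 optional mate 2 [`FastqReads`] (required when the table is
#'   double-indexed).
#' @return a data frame with columns `sample` (character, `NA` when
#'   unidentified) and `mismatches` (total distance to the best barcode).
#' @export
assignSamples <- function(reads1, table, reads2 = NULL) {
  stopifnot(is(reads1, "FastqReads"), is(table, "BarcodeTable"))
  n <- length(reads1)
  ns <- length(table@sample)
  nb1 <- nchar(table@barcode1[1])
  dbl <- length(table@barcode2) > 0L
  if (dbl && is.null(reads2))
    stop("double-indexed table requires mate 2 reads")
  d <- matrix(NA_integer_, n, ns)
  tooShort <- nchar(reads1@sequence) < nb1
  p1 <- substr(reads1@sequence, 1L, nb1)
  if (dbl) {
    nb2 <- nchar(table@barcode2[1])
    tooShort <- tooShort | nchar(reads2@sequence) < nb2
    p2 <- substr(reads2@sequence, 1L, nb2)
  }
  ok <- which(!tooShort)
  for (s in seq_len(ns)) {
    ds <- .hammingToBarcode(p1[ok], table@barcode1[s])
    if (dbl) ds <- ds + .hammingToBarcode(p2[ok], table@barcode2[s])
    d[ok, s] <- ds
  }
  best <- suppressWarnings(apply(d, 1L, min))
  nBest <- rowSums(d == best)
  assigned <- !tooShort & best <= table@maxMismatches & nBest == 1L
  sample <- rep(NA_character_, n)
  sample[assigned] <- table@sample[apply(d[assigned, , drop = FALSE], 1L,
                                         which.min)]
  data.frame(sample = sample,
             mismatches = ifelse(tooShort, NA_integer_, best),
             stringsAsFactors = FALSE)
}

#' Barcode-aware effective adapters for one sample
#'
#' A mate 1 read running through a double-indexed insert ends in
#' `revcomp(barcode2) + adapter1`; mate 2 correspondingly in
#' `revcomp(barcode1) + adapter2`. The effective adapters therefore gain the
#' reverse-complemented barcode of the *other* mate as a prefix, so ordinary
#' read-through trimming also removes barcode remnants.
#'
#' @param pair an [`AdapterPair`].
#' @param barcode1 the sample's mate 1 barcode.
#' @param barcode2 the sample's mate 2 barcode, or `NULL` for single-indexed
#'   libraries (mate 1 adapter is then unchanged).
#' @return an [`AdapterPair`] with barcode-prefixed adapters.
#' @examples
#' effectiveAdapters(adapterPair("AGATC", "AGATC"), "AACC")
#' @export
effectiveAdapters <- function(pair, barcode1, barcode2 = NULL) {
  stopifnot(is(pair, "AdapterPair"))
  a1 <- if (is.null(barcode2) || !nzchar(barcode2)) pair@adapter1
        else paste0(revComplement(barcode2), pair@adapter1)
  a2 <- paste0(revComplement(barcode1), pair@adapter2)
  adapterPair(a1, a2)
}

#' Demultiplex and trim pooled reads
#'
#' Assigns each read (pair) to a sample, strips the barcode bases (sequence
#' and qualities in lockstep), and trims each sample's reads with its
#' barcode-aware effective adapters.
#'
#' @inheritParams assignSamples
#' @param settings a [`TrimSettings`] whose adapter pairs are adjusted per
#'   sample via [effectiveAdapters()].
#' @return a list with `assignments` (from [assignSamples()]), `samples` (a
#'   named list; per sample a list with the stripped `reads1`/`reads2` and
#'   the [`TrimResult`][TrimResult-class] `trim`) and `unidentified` (the
#'   unassigned reads, untouched).
#' @export
demultiplex <- function(reads1, table, reads2 = NULL,
                        settings = trimSettings()) {
  asn <- assignSamples(reads1, table, reads2)
  nb1 <- nchar(table@barcode1[1])
  dbl <- length(table@barcode2) > 0L
  paired <- !is.null(reads2)
  stripN <- function(reads, k) {
    new("FastqReads", id = reads@id,
        sequence = substring(reads@sequence, k + 1L),
        quality = substring(reads@quality, k + 1L))
  }
  samples <- setNames(vector("list", length(table@sample)), table@sample)
  for (s in seq_along(table@sample)) {
    name <- table@sample[s]
    sel <- which(!is.na(asn$sample) & asn$sample == name)
    r1 <- stripN(reads1[sel], nb1)
    r2 <- if (paired) {
      stripN(reads2[sel], if (dbl) nchar(table@barcode2[1]) else 0L)
    }
    eff <- lapply(settings@adapters, effectiveAdapters,
                  barcode1 = table@barcode1[s],
                  barcode2 = if (dbl) table@barcode2[s])
    st <- trimSettings(adapters = eff, alignment = settings@alignment,
                       minAdapterOverlap = settings@minAdapterOverlap)
    tr <- if (paired) trimPairedEnd(r1, r2, st) else trimSingleEnd(r1, st)
    samples[[name]] <- list(reads1 = r1, reads2 = r2, trim = tr)
  }
  un <- which(is.na(asn$sample))
  list(assignments = asn, samples = samples,
       unidentified = list(reads1 = reads1[un],
                           reads2 = if (paired) reads2[un]))
}
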