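ADAPTERS <- hiseqAdapterPair()

mkReads <- function(seqs, prefix = "r") {
  FastqReads(paste0(prefix, seq_along(seqs)), seqs,
             vapply(nchar(seqs), strrep, character(1), x = "I"))
}

test_that("barcode assignment follows the maximum-mismatch rule", {
  tab <- barcodeTable(c("s1", "s2"), c("ACGTAC", "TTGACC"),
                      maxMismatches = 1L)
  set.seed(61)
  tail <- randomSeq(30)
  reads <- mkReads(c(
    paste0("ACGTAC", tail),   # exact -> s1
    paste0("ACGAAC", tail),   # 1 mismatch from s1, 5 from s2 -> s1
    paste0("ACGAAA", tail),   # 2 mismatches from s1 -> unidentified
    paste0("ACNTAC", tail),   # N counts as mismatch -> s1 at distance 1
    "ACg"))                   # shorter than barcode -> unidentified
  asn <- assignSamples(reads, tab)
  expect_equal(asn$sample, c("s1", "s1", NA, "s1", NA))
  expect_equal(asn$mismatches, c(0L, 1L, 2L, 1L, NA))

  # equidistant at the minimum: ambiguous, never first-listed
  tabEq <- barcodeTable(c("a", "b"), c("AAAA", "AAAT"), maxMismatches = 1L)
  asnEq <- assignSamples(mkReads(paste0("AAAG", tail)), tabEq)
  expect_true(is.na(asnEq$sample))

  # exact match required at maxMismatches = 0
  tab0 <- barcodeTable("s1", "ACGTAC", maxMismatches = 0L)
  expect_equal(assignSamples(mkReads(paste0("ACGTAC", tail)), tab0)$sample,
               "s1")
  expect_true(is.na(assignSamples(mkReads(paste0("ACGTAA", tail)),
                                  tab0)$sample))
})

test_that("effective adapters gain the other mate's reverse-complemented barcode", {
  pair <- adapterPair("AGATCG", "AGATCG")
  eff <- effectiveAdapters(pair, barcode1 = "ACGT", barcode2 = "AACC")
  expect_equal(adapter1(eff), paste0("GGTT", "AGATCG"))
  expect_equal(adapter2(eff), paste0("ACGT", "AGATCG"))
  # single-indexed: mate 1 adapter unchanged
  eff1 <- effectiveAdapters(pair, barcode1 = "ACGT")
  expect_equal(adapter1(eff1), "AGATCG")
  expect_equal(adapter2(eff1), paste0("ACGT", "AGATCG"))
})

test_that("well-separated barcodes give error-free collision-free assignment", {
  tab <- barcodeTable(c("s1", "s2", "s3"),
                      c("AAAAAA", "CCGGTT", "GTTACG"),
                      maxMismatches = 1L)  # pairwise distances > 2
  set.seed(62)
  truth <- sample(1:3, 60, replace = TRUE)
  reads <- mkReads(paste0(c("AAAAAA", "CCGGTT", "GTTACG")[truth],
                          vapply(rep(30, 60), randomSeq, character(1))))
  asn <- assignSamples(reads, tab)
  expect_equal(asn$sample, tab@sample[truth])
  expect_equal(asn$mismatches, rep(0L, 60))
})

test_that("a double-indexed 30 bp insert is trimmed free of barcode bases", {
  tab <- barcodeTable("s1", "ACGTAC", "TTGACC", maxMismatches = 1L)
  set.seed(63)
  insert <- randomSeq(30)
  eff <- effectiveAdapters(ADAPTERS, "ACGTAC", "TTGACC")
  core <- makePair(insert, eff, readLength = 94L)
  r1 <- FastqReads("p/1", paste0("ACGTAC", readSequences(core$reads1)),
                   strrep("I", 100))
  r2 <- FastqReads("p/2", paste0("TTGACC", readSequences(core$reads2)),
                   strrep("I", 100))
  dm <- demultiplex(r1, tab, r2)
  expect_equal(dm$assignments$sample, "s1")
  tr <- dm$samples$s1$trim
  expect_equal(readSequences(trimmedReads(tr, 1L)), insert)
  expect_equal(readSequences(trimmedReads(tr, 2L)), bruteRevComp(insert))
})

test_that("demultiplexing then trimming equals trimming pre-split files", {
  tab <- barcodeTable(c("s1", "s2"), c("AAAAAA", "CCGGTT"), c("GGTTAA", "TACGTC"),
                      maxMismatches = 1L)
  set.seed(64)
  n <- 40
  truth <- sample(1:2, n, replace = TRUE)
  lens <- sample(30:160, n, replace = TRUE)
  r1 <- r2 <- character(n)
  for (i in seq_len(n)) {
    eff <- effectiveAdapters(ADAPTERS, tab@barcode1[truth[i]],
                             tab@barcode2[truth[i]])
    core <- makePair(randomSeq(lens[i]), eff, readLength = 94L)
    r1[i] <- paste0(tab@barcode1[truth[i]], readSequences(core$reads1))
    r2[i] <- paste0(tab@barcode2[truth[i]], readSequences(core$reads2))
  }
  reads1 <- mkReads(r1, "m")
  reads2 <- mkReads(r2, "m")
  dm <- demultiplex(reads1, tab, reads2)
  expect_equal(dm$assignments$sample, tab@sample[truth])
  expect_equal(length(dm$unidentified$reads1), 0L)
  for (s in 1:2) {
    sel <- truth == s
    eff <- effectiveAdapters(ADAPTERS, tab@barcode1[s], tab@barcode2[s])
    direct <- trimPairedEnd(
      FastqReads(paste0("m", which(sel)), substring(r1[sel], 7L),
                 rep(strrep("I", 94), sum(sel))),
      FastqReads(paste0("m", which(sel)), substring(r2[sel], 7L),
                 rep(strrep("I", 94), sum(sel))),
      trimSettings(adapters = eff))
    viaDemux <- dm$samples[[tab@sample[s]]]$trim
    expect_equal(readSequences(trimmedReads(viaDemux, 1L)),
                 readSequences(trimmedReads(direct, 1L)))
    expect_equal(readSequences(trimmedReads(viaDemux, 2L)),
                 readSequences(trimmedReads(direct, 2L)))
    expect_equal(insertLengths(viaDemux), insertLengths(direct))
  }
})
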