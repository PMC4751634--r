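ADAPTERS <- hiseqAdapterPair()

test_that("an exact adapter match is trimmed at the junction", {
  set.seed(31)
  insert <- randomSeq(80)
  read <- paste0(insert, substr(adapter1(ADAPTERS), 1, 20))
  reads <- FastqReads("r", read, strrep("I", 100))
  tr <- trimSingleEnd(reads, trimSettings())
  expect_equal(nchar(readSequences(trimmedReads(tr, 1L))), 80L)
  expect_equal(readSequences(trimmedReads(tr, 1L)), insert)
  expect_equal(adapterIndices(tr), 1L)
  expect_equal(basesTrimmed(tr, 1L), 20L)
})

test_that("minAdapterOverlap vetoes short 3' matches", {
  # a poly-C read ending in A: the only positive-score alignment is the
  # 1-base match with the adapter's leading A
  reads <- FastqReads("r", paste0(strrep("C", 99), "A"), strrep("I", 100))
  tr0 <- trimSingleEnd(reads, trimSettings())
  expect_equal(nchar(readSequences(trimmedReads(tr0, 1L))), 99L)
  tr3 <- trimSingleEnd(reads, trimSettings(minAdapterOverlap = 3L))
  expect_equal(nchar(readSequences(trimmedReads(tr3, 1L))), 100L)
  expect_true(is.na(adapterIndices(tr3)))
})

test_that("single-end trim points equal a brute-force oracle on simulated reads", {
  sim <- simulateReads(simulationConfig(nPairs = 250, seed = 32,
                                        paired = FALSE))
  for (mo in c(0L, 3L)) {
    tr <- trimSingleEnd(sim$reads1, trimSettings(minAdapterOverlap = mo))
    want <- vapply(readSequences(sim$reads1), bruteTrimSE, integer(1),
                   adapter = adapter1(ADAPTERS), mm = 3,
                   minAdapterOverlap = mo, USE.NAMES = FALSE)
    expect_equal(nchar(readSequences(trimmedReads(tr, 1L))), want)
  }
})

test_that("paired-end trimming infers the insert from the mate overlap", {
  set.seed(33)
  p80 <- makePair(randomSeq(80), ADAPTERS)
  tr <- trimPairedEnd(p80$reads1, p80$reads2, trimSettings())
  expect_equal(insertLengths(tr), 80L)
  expect_equal(readSequences(trimmedReads(tr, 1L)), p80$insert)
  expect_equal(readSequences(trimmedReads(tr, 2L)), bruteRevComp(p80$insert))

  p150 <- makePair(randomSeq(150), ADAPTERS)
  tr <- trimPairedEnd(p150$reads1, p150$reads2, trimSettings())
  expect_equal(insertLengths(tr), 150L)
  expect_equal(basesTrimmed(tr, 1L), 0L)  # insert >= read length: untouched
  expect_equal(basesTrimmed(tr, 2L), 0L)

  expect_error(trimPairedEnd(FastqReads("a", "", ""),
                             FastqReads("b", "ACGT", "IIII")),
               "non-empty")
})

test_that("zero-error paired-end trimming recovers every insert length", {
  set.seed(34)
  lens <- sample(20:180, 120, replace = TRUE)
  ps <- makePairs(vapply(lens, randomSeq, character(1)), ADAPTERS)
  tr <- trimPairedEnd(ps$reads1, ps$reads2, trimSettings())
  expect_equal(insertLengths(tr), lens)
  expect_equal(nchar(readSequences(trimmedReads(tr, 1L))), pmin(100L, lens))
})

test_that("the best-matching adapter pair is selected per read pair", {
  pairs <- c(list(ADAPTERS), shuffledAdapterPairs(ADAPTERS, 4, seed = 35))
  settings <- trimSettings(adapters = pairs)
  set.seed(36)
  # single pair built with pair 3, error-free
  p <- makePair(randomSeq(70), pairs[[3]])
  sel <- selectBestAdapter(p$reads1, settings, p$reads2)
  expect_equal(sel$adapterIndex, 3L)
  # a read with no adapter and a large overlap requirement yields none
  clean <- FastqReads("r", randomSeq(100), strrep("I", 100))
  selNone <- selectBestAdapter(clean, trimSettings(minAdapterOverlap = 50L))
  expect_true(is.na(selNone$adapterIndex))
  # vectorised: the recovered index matches the generating pair whenever the
  # adapter fragment is at least 10 bases
  lens <- sample(40:90, 60, replace = TRUE)
  idx <- sample(1:5, 60, replace = TRUE)
  r1 <- r2 <- character(60)
  for (i in seq_len(60)) {
    pi <- makePair(randomSeq(lens[i]), pairs[[idx[i]]])
    r1[i] <- readSequences(pi$reads1)
    r2[i] <- readSequences(pi$reads2)
  }
  tr <- trimPairedEnd(FastqReads(paste0("m", 1:60), r1, rep(strrep("I", 100), 60)),
                      FastqReads(paste0("m", 1:60), r2, rep(strrep("I", 100), 60)),
                      settings)
  expect_equal(adapterIndices(tr), idx)
  expect_equal(insertLengths(tr), lens)
})

test_that("trimming is idempotent and conserves bases", {
  sim <- simulateReads(simulationConfig(nPairs = 150, seed = 37))
  tr <- trimPairedEnd(sim$reads1, sim$reads2, trimSettings())
  # conservation: trimmed prefix plus removed suffix is the original read
  expect_equal(nchar(readSequences(trimmedReads(tr, 1L))) + basesTrimmed(tr, 1L),
               nchar(readSequences(sim$reads1)))
  expect_equal(readSequences(trimmedReads(tr, 1L)),
               substr(readSequences(sim$reads1), 1,
                      nchar(readSequences(sim$reads1)) - basesTrimmed(tr, 1L)))
  expect_equal(readQualities(trimmedReads(tr, 2L)),
               substr(readQualities(sim$reads2), 1,
                      nchar(readQualities(sim$reads2)) - basesTrimmed(tr, 2L)))
  # idempotence on pairs truncated to the insert
  done <- !is.na(insertLengths(tr)) & insertLengths(tr) < 100L &
    insertLengths(tr) >= 20L
  again <- trimPairedEnd(trimmedReads(tr, 1L)[done],
                         trimmedReads(tr, 2L)[done], trimSettings())
  expect_equal(readSequences(trimmedReads(again, 1L)),
               readSequences(trimmedReads(tr, 1L)[done]))
  expect_equal(readSequences(trimmedReads(again, 2L)),
               readSequences(trimmedReads(tr, 2L)[done]))
})

test_that("a read consisting entirely of adapter is trimmed to length zero", {
  reads <- FastqReads("r", substr(adapter1(ADAPTERS), 1, 50), strrep("I", 50))
  tr <- trimSingleEnd(reads, trimSettings())
  expect_equal(nchar(readSequences(trimmedReads(tr, 1L))), 0L)
  expect_equal(basesTrimmed(tr, 1L), 50L)
})

test_that("raising minAdapterOverlap never lowers single-end specificity", {
  sim <- simulateReads(simulationConfig(nPairs = 800, seed = 39,
                                        paired = FALSE))
  spc <- vapply(c(0L, 3L, 6L), function(mo) {
    tr <- trimSingleEnd(sim$reads1, trimSettings(minAdapterOverlap = mo))
    cls <- classifyTrim(nchar(readSequences(trimmedReads(tr, 1L))),
                        sim$truth$insertLength, 100L)
    computeMetrics(tallyClasses(cls))[["spc"]]
  }, numeric(1))
  expect_true(all(diff(spc) >= 0))
})
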