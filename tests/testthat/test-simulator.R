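test_that("the simulator is bit-identical for identical seeds", {
  expect_identical(generateReference(100, 0.5, seed = 1),
                   generateReference(100, 0.5, seed = 1))
  a <- simulateReads(simulationConfig(nPairs = 200, seed = 71))
  b <- simulateReads(simulationConfig(nPairs = 200, seed = 71))
  expect_identical(readSequences(a$reads1), readSequences(b$reads1))
  expect_identical(readSequences(a$reads2), readSequences(b$reads2))
  expect_identical(a$truth, b$truth)
  c <- simulateReads(simulationConfig(nPairs = 200, seed = 72))
  expect_false(identical(readSequences(a$reads1), readSequences(c$reads1)))
})

test_that("the random reference hits its target base composition", {
  expect_true(grepl("^[AT]+$", generateReference(500, 0, seed = 2)))
  ref <- generateReference(1000000, 0.41, seed = 3)
  gc <- sum(strsplit(ref, "")[[1]] %in% c("G", "C")) / 1000000
  expect_gte(gc, 0.40)
  expect_lte(gc, 0.42)
})

test_that("insert lengths follow the truncated normal", {
  sim <- simulateReads(simulationConfig(nPairs = 10000, seed = 73))
  L <- sim$truth$insertLength
  expect_true(all(L >= 1L))
  # redrawing below-1 draws makes this a truncated normal; its moments
  # (computed in closed form) are what the sample must match
  alpha <- (0.5 - 150) / 75
  lambda <- dnorm(alpha) / (1 - pnorm(alpha))
  truncMean <- 150 + 75 * lambda
  truncSd <- 75 * sqrt(1 + alpha * lambda - lambda^2)
  expect_lt(abs(mean(L) - truncMean), 2.5)
  expect_lt(abs(sd(L) - truncSd), 2)
  # severe truncation still yields only positive lengths
  simT <- simulateReads(simulationConfig(nPairs = 500, insertMean = -50,
                                         insertSd = 75, seed = 74))
  expect_true(all(simT$truth$insertLength >= 1L))
})

test_that("error-free reads are reproduced exactly from the sampled inserts", {
  ref <- generateReference(50000, 0.41, seed = 75)
  cfg <- simulationConfig(nPairs = 300, seed = 76,
                          errorModel = errorFreeModel(100),
                          referenceLength = 50000L)
  sim <- simulateReads(cfg, reference = ref)
  tr <- sim$truth
  insert <- substr(rep(ref, nrow(tr)), tr$start, tr$start + tr$insertLength - 1L)
  insert[tr$strand == "-"] <- revComplement(insert[tr$strand == "-"])
  ad <- hiseqAdapterPair()
  pad1 <- strrep(adapter1(ad), 3)
  pad2 <- strrep(adapter2(ad), 3)
  expect_equal(readSequences(sim$reads1),
               substr(paste0(insert, pad1), 1, 100))
  expect_equal(readSequences(sim$reads2),
               substr(paste0(revComplement(insert), pad2), 1, 100))
  # short inserts read through: insert 80 gives 20 adapter bases
  i80 <- which(tr$insertLength == 80L)
  if (length(i80)) {
    expect_equal(substring(readSequences(sim$reads1)[i80[1]], 81),
                 substr(adapter1(ad), 1, 20))
  }
  # expected trim lengths cap at the read length
  expect_equal(tr$expectedLength1, pmin(100L, tr$insertLength))
  expect_equal(tr$overlapping, tr$insertLength < 200L)
})

test_that("adapter contamination frequency matches the insert distribution", {
  sim <- simulateReads(simulationConfig(nPairs = 10000, seed = 77))
  frac <- mean(sim$truth$insertLength < 100L)
  # truncated-normal probability of insert < 100
  p <- (pnorm(99.5, 150, 75) - pnorm(0.5, 150, 75)) /
    (1 - pnorm(0.5, 150, 75))
  expect_lt(abs(frac - p), 4 * sqrt(p * (1 - p) / 10000))
})

test_that("the error ramp injects the configured substitution load", {
  em <- defaultErrorModel(100)
  expect_equal(em$p[1], 0.001)
  expect_equal(em$p[100], 0.010)
  expect_equal(em$q[1], 30L)
  expect_equal(em$q[100], 20L)

  ref <- generateReference(50000, 0.41, seed = 78)
  # inserts always longer than the read: reads are pure reference, so every
  # difference from the errorless read is an injected substitution
  cfg <- simulationConfig(nPairs = 5000, insertMean = 400, insertSd = 10,
                          seed = 79, referenceLength = 50000L)
  sim <- simulateReads(cfg, reference = ref)
  tr <- sim$truth
  insert <- substr(rep(ref, nrow(tr)), tr$start, tr$start + tr$insertLength - 1L)
  insert[tr$strand == "-"] <- revComplement(insert[tr$strand == "-"])
  clean <- substr(insert, 1, 100)
  obs <- readSequences(sim$reads1)
  nerr <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                 obs, clean)
  rate <- sum(nerr) / (5000 * 100)
  expect_lt(abs(rate - mean(em$p)), 0.0005)
  # per-position monotone trend: later cycles err more often
  expect_gt(mean(nerr), 0)  # errors do occur
  # qualities encode the ramp
  expect_equal(phredScores(sim$reads1)[[1]], em$q)
})

test_that("simulation config validates its inputs", {
  expect_error(simulationConfig(nPairs = 0), "nPairs")
  expect_error(simulationConfig(nPairs = 10, insertSd = 0), "insertSd")
  expect_error(simulateReads(simulationConfig(nPairs = 5, insertMean = 500,
                                              insertSd = 1,
                                              referenceLength = 300L)),
               "longer than the reference")
})

test_that("shuffled adapter pairs preserve composition and are deterministic", {
  base <- hiseqAdapterPair()
  sh1 <- shuffledAdapterPairs(base, 4, seed = 80)
  sh2 <- shuffledAdapterPairs(base, 4, seed = 80)
  expect_equal(vapply(sh1, adapter1, character(1)),
               vapply(sh2, adapter1, character(1)))
  sortChars <- function(s) paste(sort(strsplit(s, "")[[1]]), collapse = "")
  for (p in sh1) {
    expect_equal(sortChars(adapter1(p)), sortChars(adapter1(base)))
    expect_equal(sortChars(adapter2(p)), sortChars(adapter2(base)))
  }
  expect_false(adapter1(sh1[[1]]) == adapter1(base))
})
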