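## Independent reference implementations used as oracles. These deliberately
## avoid the package's alignment code paths: plain R, character-by-character.

randomSeq <- function(len, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, len, replace = TRUE), collapse = "")
}

## Exhaustive ungapped overlap scan; same contract as alignOverlap.
bruteAlign <- function(a, b, minOffset = 0L) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  la <- length(ac)
  lb <- length(bc)
  best <- NULL
  for (off in max(minOffset, 1L - lb):(la - 1L)) {
    astart <- max(0L, off)
    aend <- min(la, off + lb)
    if (aend - astart < 1L) next
    ai <- (astart + 1L):aend
    bi <- ai - off
    amb <- ac[ai] == "N" | bc[bi] == "N"
    m <- sum(!amb & ac[ai] == bc[bi])
    mm <- sum(!amb & ac[ai] != bc[bi])
    cand <- list(offset = off, overlap = aend - astart, matches = m,
                 mismatches = mm, ambiguous = sum(amb), score = m - mm)
    if (is.null(best) || cand$score > best$score ||
        (cand$score == best$score &&
         (cand$overlap > best$overlap ||
          (cand$overlap == best$overlap && cand$offset < best$offset))))
      best <- cand
  }
  best
}

## Acceptance rule, restated independently: positive score and a mismatch
## budget of floor(called * rate), tightened to 0 below 6 called bases and
## to at most 1 below 10.
bruteAcceptable <- function(aln, mm = 3, minScore = 1L) {
  rate <- if (mm > 1) 1 / mm else mm
  called <- aln$matches + aln$mismatches
  budget <- floor(called * rate + 1e-9)
  if (called < 6) budget <- 0
  else if (called < 10) budget <- min(budget, 1)
  aln$score >= minScore && aln$mismatches <= budget
}

## Single-end trim oracle: best alignment of the adapter over the read at
## offsets >= 0, then the acceptance test, then the overlap guard.
bruteTrimSE <- function(seq, adapter, mm = 3, minAdapterOverlap = 0L) {
  best <- bruteAlign(seq, adapter, 0L)
  if (bruteAcceptable(best, mm) && best$overlap >= minAdapterOverlap)
    best$offset
  else
    nchar(seq)
}

## Complement oracle for reverse-complement checks.
bruteRevComp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

## Build an error-free read pair from an insert and an adapter pair,
## cycling the adapter when the read runs past its end.
makePair <- function(insert, pair, readLength = 100L, q = "I") {
  cyc <- function(ad) substr(strrep(ad, ceiling(readLength / nchar(ad)) + 1L),
                             1L, readLength)
  s1 <- substr(paste0(insert, cyc(adapter1(pair))), 1L, readLength)
  s2 <- substr(paste0(bruteRevComp(insert), cyc(adapter2(pair))),
               1L, readLength)
  list(reads1 = FastqReads("p/1", s1, strrep(q, nchar(s1))),
       reads2 = FastqReads("p/2", s2, strrep(q, nchar(s2))),
       insert = insert)
}

## Vectorised variant: one FastqReads per mate covering many inserts.
makePairs <- function(inserts, pair, readLength = 100L, q = "I") {
  cyc <- function(ad) substr(strrep(ad, ceiling(readLength / nchar(ad)) + 1L),
                             1L, readLength)
  rc <- vapply(inserts, bruteRevComp, character(1), USE.NAMES = FALSE)
  s1 <- substr(paste0(inserts, cyc(adapter1(pair))), 1L, readLength)
  s2 <- substr(paste0(rc, cyc(adapter2(pair))), 1L, readLength)
  ids <- paste0("p", seq_along(inserts))
  list(reads1 = FastqReads(ids, s1, strrep(q, nchar(s1))),
       reads2 = FastqReads(ids, s2, strrep(q, nchar(s2))))
}

randomFastq <- function(n, minLen = 0L, maxLen = 60L) {
  lens <- sample(minLen:maxLen, n, replace = TRUE)
  seqs <- vapply(lens, function(l) randomSeq(l, c("A", "C", "G", "T", "N")),
                 character(1))
  quals <- vapply(lens, function(l)
    encodePhred(sample(0:93, l, replace = TRUE)), character(1))
  FastqReads(paste0("rand_", seq_len(n)), seqs, quals)
}
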