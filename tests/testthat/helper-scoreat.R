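## Count matches/mismatches/ambiguous at one fixed offset (oracle-side).
scoreAt <- function(a, b, off) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  astart <- max(0L, off)
  aend <- min(length(ac), off + length(bc))
  ai <- (astart + 1L):aend
  bi <- ai - off
  amb <- ac[ai] == "N" | bc[bi] == "N"
  list(overlap = aend - astart,
       matches = sum(!amb & ac[ai] == bc[bi]),
       mismatches = sum(!amb & ac[ai] != bc[bi]),
       ambiguous = sum(amb))
}
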