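## FASTQ reading and writing with transparent gzip/bzip2 compression.
## Quality encoding is fixed to Phred+33 (Sanger / Illumina 1.8+).

.detectCompression <- function(path) {
  magic <- readBin(path, "raw", n = 3L)
  if (length(magic) >= 2L && magic[1] == as.raw(0x1f) &&
      magic[2] == as.raw(0x8b))
    return("gzip")
  if (length(magic) >= 3L && rawToChar(magic) == "BZh")
    return("bzip2")
  "none"
}

.compressionFromName <- function(path) {
  if (grepl("\\.gz$", path)) "gzip"
  else if (grepl("\\.bz2$", path)) "bzip2"
  else "none"
}

.openInput <- function(path, compression) {
  if (compression == "auto") compression <- .detectCompression(path)
  switch(compression,
         none = file(path, "rt"),
         gzip = gzfile(path, "rt"),
         bzip2 = bzfile(path, "rt"),
         stop("unknown compression mode: ", compression))
}

.openOutput <- function(path, compression) {
  if (compression == "auto") compression <- .compressionFromName(path)
  switch(compression,
         none = file(path, "wt"),
         gzip = gzfile(path, "wt"),
         bzip2 = bzfile(path, "wt"),
         stop("unknown compression mode: ", compression))
}

#' Decode and encode Phred+33 quality strings
#'
#' @param quality a Phred+33 encoded quality string.
#' @param scores an integer vector of Phred scores in `[0, 93]`.
#' @return `decodePhred()` returns an integer vector of Phred scores;
#'   `encodePhred()` returns a quality string.
#' @examples
#' decodePhred("II!~")
#' encodePhred(c(40, 40, 0, 93))
#' @export
decodePhred <- function(quality) {
  if (!nzchar(quality)) return(integer())
  utf8ToInt(quality) - 33L
}

#' @rdname decodePhred
#' @export
encodePhred <- function(scores) {
  if (length(scores) == 0L) return("")
  if (any(scores < 0L | scores > 93L))
    stop("Phred scores must lie in [0, 93]")
  intToUtf8(as.integer(scores) + 33L)
}

#' Read a FASTQ file
#'
#' Parses a four-line-per-record FASTQ file into a [`FastqReads`] object.
#' gzip- and bzip2-compressed input is detected from the file's magic bytes
#' when `compression = "auto"`. Lowercase bases are normalised to uppercase;
#' any base outside `{A,C,G,T,N}` is a parse error. Malformed records
#' (missing `@`/`+` markers, sequence/quality length mismatch) raise an error
#' naming the record index, and quality characters below `!` raise an
#' encoding error.
#'
#' @param path path to a FASTQ file (plain, `.gz` or `.bz2`).
#' @param compression one of `"auto"`, `"none"`, `"gzip"`, `"bzip2"`.
#' @return a [`FastqReads`] object with records in file order.
#' @seealso [writeFastq()], [readFastqPaired()]
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' readFastq(fq)
#' @export
readFastq <- function(path, compression = c("auto", "none", "gzip", "bzip2")) {
  compression <- match.arg(compression)
  con <- .openInput(path, compression)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L) return(FastqReads())
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ record at index ", length(lines) %/% 4L + 1L)
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  seqs <- toupper(lines[idx + 1L])
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]

  bad <- which(substr(hdr, 1L, 1L) != "@")
  if (length(bad))
    stop("record ", bad[1], ": header does not start with '@'")
  bad <- which(substr(plus, 1L, 1L) != "+")
  if (length(bad))
    stop("record ", bad[1], ": separator line does not start with '+'")
  bad <- which(!grepl(.SEQ_PATTERN, seqs))
  if (length(bad))
    stop("record ", bad[1], ": invalid sequence character")
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad))
    stop("record ", bad[1], ": sequence and quality lengths differ")
  allq <- utf8ToInt(paste(qual, collapse = ""))
  if (length(allq) && min(allq) < 33L)
    stop("quality character below '!': not Phred+33 encoded")
  if (length(allq) && max(allq) > 126L)
    stop("quality character above '~': not Phred+33 encoded")

  FastqReads(id = sub("^@", "", hdr), sequence = seqs, quality = qual)
}

#' Read paired FASTQ files in lockstep
#'
#' Reads two mate files (or one interleaved file) and checks that the mates
#' agree in number; a length mismatch is an error naming the first missing
#' record.
#'
#' @param path1 mate 1 FASTQ file, or the interleaved file when
#'   `interleaved = TRUE`.
#' @param path2 mate 2 FASTQ file; ignored when `interleaved = TRUE`.
#' @param interleaved single file with alternating mate 1 / mate 2 records.
#' @inheritParams readFastq
#' @return a list with `FastqReads` elements `reads1` and `reads2`.
#' @export
readFastqPaired <- function(path1, path2 = NULL, interleaved = FALSE,
                            compression = "auto") {
  if (interleaved) {
    all <- readFastq(path1, compression)
    n <- length(all)
    if (n %% 2L != 0L)
      stop("interleaved file has an unpaired record at index ", n)
    odd <- seq(1L, n, by = 2L)
    return(list(reads1 = all[odd], reads2 = all[odd + 1L]))
  }
  r1 <- readFastq(path1, compression)
  r2 <- readFastq(path2, compression)
  if (length(r1) != length(r2))
    stop("mate files differ in length: record ",
         min(length(r1), length(r2)) + 1L, " is missing from the ",
         if (length(r1) < length(r2)) "mate 1" else "mate 2", " file")
  list(reads1 = r1, reads2 = r2)
}

#' Write a FASTQ file
#'
#' Writes [`FastqReads`] as four-line FASTQ records. Compression is chosen
#' from the file extension (`.gz`, `.bz2`) when `compression = "auto"`.
#' Reading the written file with [readFastq()] reproduces the input exactly.
#'
#' @param reads a [`FastqReads`] object.
#' @inheritParams readFastq
#' @return invisibly, the number of records written.
#' @export
writeFastq <- function(reads, path,
                       compression = c("auto", "none", "gzip", "bzip2")) {
  compression <- match.arg(compression)
  stopifnot(is(reads, "FastqReads"))
  con <- .openOutput(path, compression)
  on.exit(close(con))
  n <- length(reads)
  if (n > 0L) {
    lines <- character(4L * n)
    lines[seq(1L, 4L * n, by = 4L)] <- paste0("@", reads@id)
    lines[seq(2L, 4L * n, by = 4L)] <- reads@sequence
    lines[seq(3L, 4L * n, by = 4L)] <- "+"
    lines[seq(4L, 4L * n, by = 4L)] <- reads@quality
    writeLines(lines, con)
  }
  invisible(n)
}

#' Reverse-complement nucleotide sequences
#'
#' `A<->T`, `C<->G`, `N -> N`, order reversed. Vectorised.
#'
#' @param sequence character vector of sequences over `{A,C,G,T,N}`.
#' @return character vector of reverse-complemented sequences.
#' @examples
#' revComplement("ACGTN")
#' @export
revComplement <- function(sequence) {
  if (length(sequence) == 0L) return(character())
  if (any(!grepl(.SEQ_PATTERN, sequence)))
    stop("sequences may only contain A, C, G, T, N")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(sequence)))
}
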