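#' Read a FASTQ file into a data frame of reads
#'
#' Parses a plain or gzip-compressed FASTQ file (compression is detected from
#' the file's magic bytes, not its extension) into one row per read.
#' Sequences are uppercased; `N` bases are retained.  Quality strings are
#' carried along but never used for filtering.  Mates are never paired: each
#' file is analysed independently.
#'
#' @param path Path to a FASTQ file, plain or gzipped.
#' @param mate Which mate the file contains: `"mate1"`, `"mate2"`, or
#'   `"unknown"`.  Recorded on each read; not used computationally.
#' @return A data frame of class `fastq_reads` with columns `read_id`,
#'   `sequence`, `quality`, `mate`.  An empty file yields zero rows.
#' @details Each record must be a 4-line group: an `@`-prefixed header, the
#'   sequence, a `+` separator, and a quality string of the same length as
#'   the sequence.  A malformed record raises an error naming its (1-based)
#'   record index.  Sequences may contain only `A`, `C`, `G`, `T`, `N` after
#'   uppercasing.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ttagggttaggg", "+", "IIIIIIIIIIII"), fq)
#' read_fastq(fq)
#' @export
read_fastq <- function(path, mate = c("unknown", "mate1", "mate2")) {
  mate <- match.arg(mate)
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  con <- open_maybe_gz(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  n <- length(lines)
  if (n == 0L) {
    return(empty_reads(mate))
  }
  if (n %% 4L != 0L) {
    stop("truncated FASTQ: ", path, " has ", n,
         " lines, not a multiple of 4 (record ", n %/% 4L + 1L, " incomplete)")
  }
  idx <- seq(1L, n, by = 4L)
  hdr <- lines[idx]
  seqs <- toupper(lines[idx + 1L])
  qual <- lines[idx + 3L]

  bad <- which(substr(hdr, 1L, 1L) != "@")
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1L], " in ", path,
         ": header does not start with '@'")
  }
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1L], " in ", path,
         ": sequence and quality lengths differ (",
         nchar(seqs[bad[1L]]), " vs ", nchar(qual[bad[1L]]), ")")
  }
  bad <- grep("[^ACGTN]", seqs)
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1L], " in ", path,
         ": sequence contains characters outside {A,C,G,T,N}")
  }
  out <- data.frame(
    read_id = sub("^@", "", sub("[ \t].*$", "", hdr)),
    sequence = seqs,
    quality = qual,
    mate = mate,
    stringsAsFactors = FALSE
  )
  class(out) <- c("fastq_reads", "data.frame")
  out
}

empty_reads <- function(mate = "unknown") {
  out <- data.frame(
    read_id = character(0), sequence = character(0),
    quality = character(0), mate = character(0),
    stringsAsFactors = FALSE
  )
  class(out) <- c("fastq_reads", "data.frame")
  out
}

# gzip detected from the two magic bytes so misnamed files still open
open_maybe_gz <- function(path) {
  magic <- readBin(path, "raw", n = 2L)
  if (length(magic) == 2L && magic[1L] == as.raw(0x1f) && magic[2L] == as.raw(0x8b)) {
    gzfile(path, "rt")
  } else {
    file(path, "rt")
  }
}
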