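#' Scanner parameters
#'
#' @param min_blocks Minimal number of complete six-base repeat blocks a run
#'   must have to call a read telomeric.  The default of 8 sits past the
#'   plateau of the block-count distribution of real WGBS data, where almost
#'   all shorter exact runs are genomic noise rather than telomere.
#' @param max_distribution_n Largest block count tabulated by
#'   [block_count_distribution()].
#' @return A list of class `scan_params`.
#' @export
scan_params <- function(min_blocks = 8L, max_distribution_n = 30L) {
  min_blocks <- as.integer(min_blocks)
  max_distribution_n <- as.integer(max_distribution_n)
  if (is.na(min_blocks) || min_blocks < 1L) {
    stop("min_blocks must be a positive integer")
  }
  if (is.na(max_distribution_n) || max_distribution_n < 1L) {
    stop("max_distribution_n must be a positive integer")
  }
  structure(list(min_blocks = min_blocks,
                 max_distribution_n = max_distribution_n),
            class = "scan_params")
}

#' Scan reads for telomeric repeat runs
#'
#' Finds, in each read, the longest run of consecutive complete six-base
#' telomeric blocks at any phase offset, across the two strand patterns of
#' the file's dialect, and classifies every block of a C-strand run by its
#' unconverted cytosines.
#'
#' In a directional library, read 1 (`fastq1`) reports the converted original
#' strand, so C-strand blocks match `[CT][CT][CT]TAA` and G-strand blocks are
#' `TTAGGG`; read 2 (`fastq2`) is the complement, so C-strand blocks match
#' `TTA[AG][AG][AG]` and G-strand blocks are `CCCTAA`.  Site indices always
#' refer to the C strand 5'->3' (`CCCTAA`: site1, site2 in CpC context, site3
#' in CpT context); in `fastq2` an unconverted site appears as `G` at block
#' positions 4-6, mapping by reverse complement to site3, site2, site1.
#'
#' A fully unconverted run (`CCCTAA` in fastq1, `TTAGGG` in fastq2) matches
#' the C-strand pattern and is classified as a C-strand run of N3 blocks —
#' this is what makes untreated-DNA contamination visible.  When a read holds
#' both a C-strand and a G-strand run, the longer decides the strand origin;
#' ties prefer the C strand.
#'
#' @param reads A `fastq_reads` data frame from [read_fastq()], or any data
#'   frame with `read_id` and `sequence` columns.
#' @param source_file `"fastq1"` (forward) or `"fastq2"` (reverse) dialect.
#' @param params A [scan_params()] object.
#' @param keep_blocks If `TRUE`, attach a `blocks` list-column holding each
#'   C-strand match's per-block site codes (integer 0-7; bit 1 = site1,
#'   bit 2 = site2, bit 4 = site3 unconverted).
#' @return A data frame of class `telomere_matches`, one row per matching
#'   read: `read_id`, `source_file`, `strand_origin` (`"c_strand"` /
#'   `"g_strand"`), `run_start` (0-based offset), `block_count`, block-class
#'   counts `n0`..`n3`, per-site unconverted counts `site1`..`site3`, and an
#'   `n_reads_scanned` attribute.  Non-matching reads are dropped.
#' @examples
#' reads <- data.frame(read_id = "r1",
#'                     sequence = strrep("TTTTAA", 25))
#' scan_reads(reads, "fastq1")
#' @export
scan_reads <- function(reads, source_file = c("fastq1", "fastq2"),
                       params = scan_params(), keep_blocks = FALSE) {
  source_file <- match.arg(source_file)
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in% names(reads)))
  dialect <- if (source_file == "fastq1") 1L else 2L
  res <- scan_reads_cpp(as.character(reads$sequence), dialect,
                        params$min_blocks, keep_blocks)
  hit <- res$strand != 0L
  out <- data.frame(
    read_id = reads$read_id[hit],
    source_file = rep(source_file, sum(hit)),
    strand_origin = c("c_strand", "g_strand")[res$strand[hit]],
    run_start = res$start[hit],
    block_count = res$nblocks[hit],
    n0 = res$n0[hit], n1 = res$n1[hit], n2 = res$n2[hit], n3 = res$n3[hit],
    site1 = res$s1[hit], site2 = res$s2[hit], site3 = res$s3[hit],
    stringsAsFactors = FALSE
  )
  if (keep_blocks) out$blocks <- I(res$blocks[hit])
  attr(out, "n_reads_scanned") <- nrow(reads)
  attr(out, "params") <- params
  class(out) <- c("telomere_matches", class(out))
  out
}

#' Scan a single read
#'
#' Convenience wrapper around [scan_reads()] for one read.
#'
#' @inheritParams scan_reads
#' @param read A one-row `fastq_reads` data frame or a list with `read_id`
#'   and `sequence`.
#' @return A one-row `telomere_matches` data frame, or `NULL` when the read
#'   has no run of at least `params$min_blocks` blocks.
#' @export
scan_read <- function(read, source_file = c("fastq1", "fastq2"),
                      params = scan_params(), keep_blocks = FALSE) {
  source_file <- match.arg(source_file)
  df <- data.frame(read_id = read$read_id, sequence = read$sequence,
                   stringsAsFactors = FALSE)
  m <- scan_reads(df, source_file, params, keep_blocks)
  if (nrow(m) == 0L) NULL else m
}

#' Classify one telomeric block by its unconverted cytosines
#'
#' @param block_sequence A six-base block matching the dialect's C-strand
#'   pattern.
#' @param dialect `"fastq1_cstrand"` (`[CT][CT][CT]TAA`) or
#'   `"fastq2_cstrand"` (`TTA[AG][AG][AG]`).
#' @return A list of class `block_observation` with `block_sequence`,
#'   `unconverted_count` (0-3) and `unconverted_sites` (subset of
#'   `"site1"`, `"site2"`, `"site3"`, C-strand 5'->3' indexing).
#' @examples
#' classify_block("TCTTAA", "fastq1_cstrand")  # site2 unconverted
#' classify_block("TTAAGA", "fastq2_cstrand")  # also site2, via revcomp
#' @export
classify_block <- function(block_sequence,
                           dialect = c("fastq1_cstrand", "fastq2_cstrand")) {
  dialect <- match.arg(dialect)
  b <- toupper(block_sequence)
  if (nchar(b) != 6L) stop("block_sequence must be exactly 6 bases")
  chars <- strsplit(b, "", fixed = TRUE)[[1L]]
  if (dialect == "fastq1_cstrand") {
    if (!grepl("^[CT][CT][CT]TAA$", b)) {
      stop("'", b, "' does not match the fastq1 C-strand block pattern [CT][CT][CT]TAA")
    }
    sites <- c("site1", "site2", "site3")[chars[1:3] == "C"]
  } else {
    if (!grepl("^TTA[AG][AG][AG]$", b)) {
      stop("'", b, "' does not match the fastq2 C-strand block pattern TTA[AG][AG][AG]")
    }
    # positions 4,5,6 are the complements of site3, site2, site1
    sites <- c("site3", "site2", "site1")[chars[4:6] == "G"]
    sites <- sort(sites)
  }
  structure(list(block_sequence = b,
                 unconverted_count = length(sites),
                 unconverted_sites = sites),
            class = "block_observation")
}

#' Tabulate reads by telomeric block count
#'
#' Diagnostic distribution of run lengths, tabulated per source file and
#' strand for n = 1..`max_distribution_n`.  Real WGBS data show a sharp decay
#' with a plateau from about n = 8 and a peak where reads are entirely
#' telomeric; the plateau motivates the default `min_blocks` of 8.  Matches
#' should be produced with `min_blocks = 1` for this diagnostic.
#'
#' @param matches A `telomere_matches` data frame (one or several files'
#'   worth row-bound together).
#' @param params A [scan_params()] object; supplies `max_distribution_n`.
#' @return A data frame with columns `source_file`, `strand_origin`, `n`,
#'   `reads`, covering the full grid (zero-filled).
#' @export
block_count_distribution <- function(matches, params = scan_params()) {
  files <- c("fastq1", "fastq2")
  strands <- c("c_strand", "g_strand")
  nmax <- params$max_distribution_n
  grid <- expand.grid(source_file = files, strand_origin = strands,
                      n = seq_len(nmax), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$source_file, grid$strand_origin, grid$n), ]
  rownames(grid) <- NULL
  keep <- matches$block_count >= 1L & matches$block_count <= nmax
  tab <- table(factor(matches$source_file[keep], levels = files),
               factor(matches$strand_origin[keep], levels = strands),
               factor(matches$block_count[keep], levels = seq_len(nmax)))
  grid$reads <- as.integer(tab[cbind(grid$source_file, grid$strand_origin,
                                     as.character(grid$n))])
  grid
}

#' Ratio of telomeric reads to total reads
#'
#' @param n_telomeric Number of reads with a telomeric run of at least
#'   `min_blocks` blocks.
#' @param n_total Total number of reads scanned.
#' @return `n_telomeric / n_total`.
#' @export
telomeric_read_ratio <- function(n_telomeric, n_total) {
  if (n_total == 0) stop("telomeric read ratio undefined: no reads scanned")
  if (n_telomeric > n_total) stop("n_telomeric exceeds n_total")
  if (n_telomeric < 0 || n_total < 0) stop("counts must be non-negative")
  n_telomeric / n_total
}
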