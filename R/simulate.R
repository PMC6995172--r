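#' Simulate directional paired-end WGBS reads with a truth ledger
#'
#' Generates a paired FASTQ sample containing bisulfite-converted telomeric
#' reads with known per-site unconversion probabilities, optional
#' untreated-DNA contamination, and random background reads, together with a
#' per-read truth ledger, so every stage of the analysis can be tested
#' against ground truth.
#'
#' Read 1 of a C-strand telomeric fragment is a run of six-base blocks in
#' which each cytosine site independently stays `C` with its `p_site`
#' probability and is otherwise converted to `T`; read 2 is the exact
#' reverse complement.  G-strand fragments are `(TTAGGG)n` in read 1.
#' Contaminated fragments are fully unconverted `(CCCTAA)n` — the signature
#' of untreated genomic DNA.  Background reads are uniform random sequence.
#' With `phase_jitter` the repeat phase of each telomeric read is offset by
#' 0-5 bases, as in real fragmentation; the truth ledger records only the
#' complete blocks contained in the read, which is exactly what the scanner
#' can recover.  No sequencing-error or quality model is applied by default;
#' `error_rate` adds uniform substitutions for robustness studies (the truth
#' ledger then no longer matches scan results exactly).
#'
#' @param n_reads Reads per file.
#' @param read_length Read length in bases.
#' @param telomeric_fraction Fraction of fragments that are telomeric.  The
#'   default is of the order of the telomeric share of a human genome
#'   (~46 chromosome ends of ~10 kb in ~3.1 Gb).
#' @param g_strand_fraction Fraction of telomeric fragments whose read 1 is
#'   the G strand.
#' @param p_site Length-3 vector of per-site unconversion probabilities
#'   (site1, site2, site3 of the C-strand block `CCCTAA`).
#' @param contamination_fraction Fraction of telomeric fragments emitted
#'   fully unconverted.
#' @param phase_jitter Randomize the repeat phase offset (0-5) per read.
#' @param error_rate Per-base uniform substitution probability (default 0).
#' @param out_prefix Output prefix: writes `<prefix>_1.fastq.gz`,
#'   `<prefix>_2.fastq.gz`, `<prefix>_truth.tsv`.
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @return A list of class `wgbs_truth`: `files` (named paths), `reads`
#'   (per-read ledger: `read_id`, `type`, `telomeric`, `strand`,
#'   `contamination`, `offset`, `block_count`, `n0`..`n3`,
#'   `site1`..`site3`), `tally` (aggregate expected C-strand-pattern tally),
#'   and `config`.
#' @examples
#' sim <- simulate_wgbs(n_reads = 500, telomeric_fraction = 0.1,
#'                      out_prefix = file.path(tempdir(), "sim"), seed = 7)
#' sim$tally$total_blocks
#' @export
simulate_wgbs <- function(n_reads,
                          read_length = 150L,
                          telomeric_fraction = 5e-4,
                          g_strand_fraction = 0.5,
                          p_site = c(0.004, 0.004, 0.004),
                          contamination_fraction = 0,
                          phase_jitter = TRUE,
                          error_rate = 0,
                          out_prefix,
                          seed = NULL) {
  stopifnot(n_reads >= 1, read_length >= 6)
  fracs <- c(telomeric_fraction, g_strand_fraction, contamination_fraction,
             error_rate)
  if (any(!is.finite(fracs)) || any(fracs < 0) || any(fracs > 1)) {
    stop("all fractions and rates must lie in [0, 1]")
  }
  if (g_strand_fraction + contamination_fraction > 1) {
    stop("g_strand_fraction + contamination_fraction exceed 1: ",
         "no C-strand fraction left")
  }
  if (length(p_site) != 3L || any(p_site < 0) || any(p_site > 1)) {
    stop("p_site must be three probabilities in [0, 1]")
  }
  if (missing(out_prefix)) stop("out_prefix is required")
  if (!is.null(seed)) set.seed(as.integer(seed))

  L <- as.integer(read_length)
  n_tel <- round(n_reads * telomeric_fraction)
  n_g <- round(n_tel * g_strand_fraction)
  n_k <- round(n_tel * contamination_fraction)
  n_c <- n_tel - n_g - n_k
  if (n_c < 0L) {  # rounding collision at tiny n_tel
    n_k <- n_k + n_c
    n_c <- 0L
  }
  n_b <- n_reads - n_tel
  stopifnot(n_k >= 0, n_b >= 0)

  parts <- list()
  if (n_c > 0) parts$c_strand <- sim_cstrand(n_c, L, p_site, phase_jitter)
  if (n_g > 0) parts$g_strand <- sim_repeat(n_g, L, "TTAGGG", phase_jitter,
                                            type = "g_strand")
  if (n_k > 0) parts$contamination <- sim_repeat(n_k, L, "CCCTAA",
                                                 phase_jitter,
                                                 type = "contamination")
  if (n_b > 0) parts$background <- sim_background(n_b, L)

  seq1 <- unlist(lapply(parts, `[[`, "seq1"), use.names = FALSE)
  truth <- do.call(rbind, lapply(parts, `[[`, "truth"))

  perm <- sample.int(n_reads)
  seq1 <- seq1[perm]
  truth <- truth[perm, , drop = FALSE]
  truth$read_id <- sprintf("sim_%07d", seq_len(n_reads))
  truth <- truth[, c("read_id", setdiff(names(truth), "read_id"))]
  rownames(truth) <- NULL

  if (error_rate > 0) seq1 <- add_substitutions(seq1, error_rate)
  seq2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seq1)))
  if (error_rate > 0) seq2 <- add_substitutions(seq2, error_rate)

  files <- c(fastq1 = paste0(out_prefix, "_1.fastq.gz"),
             fastq2 = paste0(out_prefix, "_2.fastq.gz"),
             truth = paste0(out_prefix, "_truth.tsv"))
  qual <- strrep("I", L)
  write_fastq_gz(files[["fastq1"]], paste0(truth$read_id, " 1:N:0"), seq1, qual)
  write_fastq_gz(files[["fastq2"]], paste0(truth$read_id, " 2:N:0"), seq2, qual)
  write.table(truth, files[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)

  cpat <- truth$telomeric & truth$strand == "c_strand"
  tally <- list(
    total_blocks = sum(truth$block_count[cpat]),
    n0 = sum(truth$n0[cpat]), n1 = sum(truth$n1[cpat]),
    n2 = sum(truth$n2[cpat]), n3 = sum(truth$n3[cpat]),
    site_unconverted = c(site1 = sum(truth$site1[cpat]),
                         site2 = sum(truth$site2[cpat]),
                         site3 = sum(truth$site3[cpat]))
  )

  structure(list(files = files, reads = truth, tally = tally,
                 config = list(n_reads = n_reads, read_length = L,
                               telomeric_fraction = telomeric_fraction,
                               g_strand_fraction = g_strand_fraction,
                               p_site = p_site,
                               contamination_fraction = contamination_fraction,
                               phase_jitter = phase_jitter,
                               error_rate = error_rate, seed = seed)),
            class = "wgbs_truth")
}

# complete blocks contained in a read of length L at phase offset o (0-5):
# block j (1-based in the underlying repeat) spans full-sequence positions
# 6(j-1)+1 .. 6j; the read covers o+1 .. o+L
contained_blocks <- function(offset, L) {
  jlo <- ifelse(offset == 0L, 1L, 2L)
  jhi <- (offset + L) %/% 6L
  cbind(jlo = jlo, jhi = jhi, count = jhi - jlo + 1L)
}

sim_cstrand <- function(n, L, p_site, phase_jitter) {
  off <- if (phase_jitter) sample(0:5, n, replace = TRUE) else rep(0L, n)
  m <- ceiling((max(off) + L) / 6)
  s1 <- matrix(runif(n * m) < p_site[1], n, m)
  s2 <- matrix(runif(n * m) < p_site[2], n, m)
  s3 <- matrix(runif(n * m) < p_site[3], n, m)

  cols <- vector("list", 6L * m)
  tee <- rep("T", n)
  aa <- rep("A", n)
  for (j in seq_len(m)) {
    k <- 6L * (j - 1L)
    tc <- c("T", "C")
    cols[[k + 1L]] <- tc[s1[, j] + 1L]
    cols[[k + 2L]] <- tc[s2[, j] + 1L]
    cols[[k + 3L]] <- tc[s3[, j] + 1L]
    cols[[k + 4L]] <- tee
    cols[[k + 5L]] <- aa
    cols[[k + 6L]] <- aa
  }
  full <- do.call(paste0, cols)
  seqs <- substring(full, off + 1L, off + L)

  cb <- contained_blocks(off, L)
  contained <- outer(seq_len(m), cb[, "jlo"], `>=`) &
    outer(seq_len(m), cb[, "jhi"], `<=`)  # m x n
  contained <- t(contained)               # n x m
  ksum <- s1 + s2 + s3
  truth <- data.frame(
    type = "c_strand", telomeric = TRUE, strand = "c_strand",
    contamination = FALSE, offset = off,
    block_count = cb[, "count"],
    n0 = rowSums(contained & ksum == 0L),
    n1 = rowSums(contained & ksum == 1L),
    n2 = rowSums(contained & ksum == 2L),
    n3 = rowSums(contained & ksum == 3L),
    site1 = rowSums(contained & s1),
    site2 = rowSums(contained & s2),
    site3 = rowSums(contained & s3),
    stringsAsFactors = FALSE
  )
  list(seq1 = seqs, truth = truth)
}

sim_repeat <- function(n, L, unit, phase_jitter, type) {
  off <- if (phase_jitter) sample(0:5, n, replace = TRUE) else rep(0L, n)
  m <- ceiling((max(off) + L) / 6)
  full <- strrep(unit, m)
  seqs <- substring(full, off + 1L, off + L)
  cb <- contained_blocks(off, L)
  contam <- type == "contamination"
  truth <- data.frame(
    type = type, telomeric = TRUE,
    strand = if (contam) "c_strand" else "g_strand",
    contamination = contam, offset = off,
    block_count = cb[, "count"],
    n0 = 0L, n1 = 0L, n2 = 0L,
    n3 = if (contam) cb[, "count"] else 0L,
    site1 = if (contam) cb[, "count"] else 0L,
    site2 = if (contam) cb[, "count"] else 0L,
    site3 = if (contam) cb[, "count"] else 0L,
    stringsAsFactors = FALSE
  )
  list(seq1 = seqs, truth = truth)
}

sim_background <- function(n, L) {
  mat <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  seqs <- do.call(paste0, lapply(seq_len(L), function(j) mat[, j]))
  truth <- data.frame(
    type = "background", telomeric = FALSE, strand = NA_character_,
    contamination = FALSE, offset = NA_integer_,
    block_count = 0L, n0 = 0L, n1 = 0L, n2 = 0L, n3 = 0L,
    site1 = 0L, site2 = 0L, site3 = 0L,
    stringsAsFactors = FALSE
  )
  truth <- truth[rep(1L, n), , drop = FALSE]
  list(seq1 = seqs, truth = truth)
}

add_substitutions <- function(seqs, rate) {
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    hit <- runif(length(ch)) < rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(b) {
        sample(setdiff(bases, b), 1L)
      }, character(1L))
    }
    paste(ch, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

write_fastq_gz <- function(path, ids, seqs, qual) {
  con <- gzfile(path, "wt")
  on.exit(close(con))
  lines <- as.vector(rbind(paste0("@", ids), seqs, "+",
                           rep(qual, length.out = length(seqs))))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
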