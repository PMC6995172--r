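# Independent oracles and fixture builders, deliberately written with string
# primitives only, so they share no code path with the package internals.

# --- FASTQ fixture writers --------------------------------------------------

write_plain_fastq <- function(path, ids, seqs, quals = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
  path
}

write_gz_fastq <- function(path, ids, seqs, quals = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  con <- gzfile(path, "wt")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), con)
  path
}

# --- block enumeration oracle -----------------------------------------------

# all 8 fastq1 C-strand block variants with their true unconverted sites,
# built by direct construction from the CCCTAA template
enumerate_fastq1_blocks <- function() {
  grid <- expand.grid(s1 = c(FALSE, TRUE), s2 = c(FALSE, TRUE),
                      s3 = c(FALSE, TRUE))
  grid$block <- apply(grid, 1, function(r) {
    paste0(ifelse(r[["s1"]], "C", "T"), ifelse(r[["s2"]], "C", "T"),
           ifelse(r[["s3"]], "C", "T"), "TAA")
  })
  grid
}

revcomp_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# the fastq2 variants are by definition the reverse complements of the
# fastq1 variants, with the same site labels
enumerate_fastq2_blocks <- function() {
  grid <- enumerate_fastq1_blocks()
  grid$block <- revcomp_chr(grid$block)
  grid
}

# --- brute-force sliding-window scanner oracle ------------------------------

block_regex <- list(
  fastq1 = list(c = "^[CT][CT][CT]TAA$", g = "^TTAGGG$"),
  fastq2 = list(c = "^TTA[AG][AG][AG]$", g = "^CCCTAA$")
)

# longest run of consecutive complete blocks starting at any position,
# found by exhaustive enumeration of every (start, extension) pair
oracle_longest_run <- function(seq, pattern) {
  L <- nchar(seq)
  best_len <- 0L
  best_start <- NA_integer_
  if (L < 6L) return(list(start = best_start, len = best_len))
  for (i in seq_len(L - 5L)) {
    len <- 0L
    j <- i
    while (j + 5L <= L && grepl(pattern, substr(seq, j, j + 5L))) {
      len <- len + 1L
      j <- j + 6L
    }
    if (len > best_len) {
      best_len <- len
      best_start <- i - 1L  # 0-based
    }
  }
  list(start = best_start, len = best_len)
}

# full oracle for one read: longest run per strand pattern, strand choice by
# the longer run with ties to the C strand, then per-block classification
oracle_scan <- function(seq, source_file, min_blocks) {
  pats <- block_regex[[source_file]]
  cr <- oracle_longest_run(seq, pats$c)
  gr <- oracle_longest_run(seq, pats$g)
  if (cr$len >= gr$len && cr$len >= min_blocks) {
    blocks <- vapply(seq_len(cr$len) - 1L, function(b) {
      substr(seq, cr$start + 6L * b + 1L, cr$start + 6L * b + 6L)
    }, character(1))
    counts <- vapply(blocks, function(b) {
      if (source_file == "fastq1") {
        sum(strsplit(substr(b, 1, 3), "")[[1]] == "C")
      } else {
        sum(strsplit(substr(b, 4, 6), "")[[1]] == "G")
      }
    }, integer(1))
    list(strand = "c_strand", start = cr$start, len = cr$len,
         unconverted = unname(counts))
  } else if (gr$len > cr$len && gr$len >= min_blocks) {
    list(strand = "g_strand", start = gr$start, len = gr$len,
         unconverted = integer(0))
  } else {
    NULL
  }
}

# random sequences enriched for telomere-like content so runs actually occur
random_telomere_like <- function(n, max_len = 60) {
  v1 <- enumerate_fastq1_blocks()$block
  v2 <- enumerate_fastq2_blocks()$block
  units <- c(v1, v2, "TTAGGG", "CCCTAA")
  vapply(seq_len(n), function(i) {
    len <- sample(6:max_len, 1)
    if (runif(1) < 0.5) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    } else {
      s <- paste(sample(units, ceiling(len / 6) + 1, replace = TRUE),
                 collapse = "")
      start <- sample.int(6L, 1)
      s <- substr(s, start, start + len - 1L)
      # sprinkle point substitutions to break some runs
      ch <- strsplit(s, "")[[1]]
      hit <- runif(length(ch)) < 0.05
      ch[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
      paste(ch, collapse = "")
    }
  }, character(1))
}

# --- misc -------------------------------------------------------------------

# independent reference inversion of R1 = 3p(1-p)^2 via stats::uniroot
uniroot_ucr <- function(r1) {
  if (r1 == 0) return(0)
  stats::uniroot(function(p) 3 * p * (1 - p)^2 - r1, c(0, 1 / 3),
                 tol = 1e-14)$root
}
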