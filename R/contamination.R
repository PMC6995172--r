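#' Assess untreated-DNA contamination from N3 block dispersion
#'
#' Under random conversion failure the expected number of fully unconverted
#' (N3) blocks is essentially zero, and the few that occur are scattered one
#' per read.  Untreated genomic DNA, by contrast, contributes whole reads of
#' unconverted repeats, so its N3 blocks cluster in a handful of N3-rich
#' reads.  The verdict is `"none"` when no N3 block exists,
#' `"suspected_contamination"` when reads holding at least `cluster_min` N3
#' blocks jointly carry at least `concentration_min` of all N3 blocks, and
#' `"dispersed"` otherwise (consistent with rare enzymatic methylation).
#'
#' The two thresholds are heuristic: the clustered/dispersed distinction is
#' qualitative and the defaults simply encode "most N3 mass sits in
#' multi-N3 reads".
#'
#' @param matches C-strand `telomere_matches` of one file.
#' @param cluster_min Minimum N3 blocks for a read to count as N3-rich.
#' @param concentration_min Minimum fraction of all N3 blocks that must sit
#'   in N3-rich reads to suspect contamination.
#' @return A list of class `contamination_assessment`: `n3_total`,
#'   `n3_rich_reads`, `n3_in_rich_reads`, `verdict`.
#' @export
assess_contamination <- function(matches, cluster_min = 2L,
                                 concentration_min = 0.5) {
  if (cluster_min < 1L) stop("cluster_min must be >= 1")
  if (concentration_min < 0 || concentration_min > 1) {
    stop("concentration_min must be in [0, 1]")
  }
  n3 <- matches$n3[matches$strand_origin == "c_strand"]
  n3_total <- sum(n3)
  rich <- n3 >= cluster_min
  n3_rich_reads <- sum(rich)
  n3_in_rich <- sum(n3[rich])
  verdict <- if (n3_total == 0L) {
    "none"
  } else if (n3_in_rich >= concentration_min * n3_total) {
    "suspected_contamination"
  } else {
    "dispersed"
  }
  structure(list(n3_total = n3_total,
                 n3_rich_reads = n3_rich_reads,
                 n3_in_rich_reads = n3_in_rich,
                 verdict = verdict),
            class = "contamination_assessment")
}
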