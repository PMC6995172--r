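#' Write a batch TSV report
#'
#' One header line plus one row per (sample, file) with the counts, ratios,
#' per-site UCRs, binomial-model fit and contamination verdict of each file.
#' Fractions are printed with 6 decimals; fields that could not be computed
#' (no C-strand blocks) are `NA`.  Output is deterministic: identical fits
#' give byte-identical files, and rows follow input order.
#'
#' Columns: `sample`, `file`, `total_reads`, `telomeric_reads`,
#' `c_strand_reads`, `g_strand_reads`, `telomeric_ratio`, `total_blocks`,
#' `n0`, `n1`, `n2`, `n3`, `ucr_site1`, `ucr_site2`, `ucr_site3`, `ucr_hat`,
#' `conversion_efficiency`, `r2_obs`, `r2_exp`, `r3_obs`, `r3_exp`,
#' `contamination_verdict`, `status`.
#'
#' @param reports A `teloconv` object or a list of them (one per sample).
#' @param out Output file path.
#' @return The rows as a data frame, invisibly.
#' @export
write_report <- function(reports, out) {
  if (inherits(reports, "teloconv")) reports <- list(reports)
  if (length(reports) == 0L) stop("no reports to write")
  stopifnot(all(vapply(reports, inherits, logical(1), "teloconv")))

  rows <- do.call(rbind, lapply(reports, function(r) {
    do.call(rbind, lapply(r$files, report_row, sample = r$sample))
  }))
  rownames(rows) <- NULL

  fr <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))
  txt <- rows
  for (col in c("telomeric_ratio", "ucr_site1", "ucr_site2", "ucr_site3",
                "ucr_hat", "conversion_efficiency", "r2_obs", "r2_exp",
                "r3_obs", "r3_exp")) {
    txt[[col]] <- fr(rows[[col]])
  }
  con <- file(out, "wb")  # binary mode: fixed '\n' endings on any platform
  on.exit(close(con))
  writeLines(paste(colnames(txt), collapse = "\t"), con, sep = "\n")
  writeLines(do.call(paste, c(unname(as.list(txt)), sep = "\t")), con,
             sep = "\n")
  invisible(rows)
}

report_row <- function(f, sample) {
  u <- f$site_ucr
  fit <- f$fit
  data.frame(
    sample = sample,
    file = f$source_file,
    total_reads = f$total_reads,
    telomeric_reads = f$telomeric_reads,
    c_strand_reads = f$c_strand_reads,
    g_strand_reads = f$g_strand_reads,
    telomeric_ratio = f$telomeric_ratio,
    total_blocks = f$tally$total_blocks,
    n0 = f$tally$n0, n1 = f$tally$n1, n2 = f$tally$n2, n3 = f$tally$n3,
    ucr_site1 = if (is.null(u)) NA_real_ else u$ucr_site1,
    ucr_site2 = if (is.null(u)) NA_real_ else u$ucr_site2,
    ucr_site3 = if (is.null(u)) NA_real_ else u$ucr_site3,
    ucr_hat = if (is.null(fit)) NA_real_ else fit$ucr_hat,
    conversion_efficiency = if (is.null(fit)) NA_real_ else fit$conversion_efficiency,
    r2_obs = if (is.null(fit)) NA_real_ else fit$r2_obs,
    r2_exp = if (is.null(fit)) NA_real_ else fit$r2_exp,
    r3_obs = if (is.null(fit)) NA_real_ else fit$r3_obs,
    r3_exp = if (is.null(fit)) NA_real_ else fit$r3_exp,
    contamination_verdict = f$contamination$verdict,
    status = f$status,
    stringsAsFactors = FALSE
  )
}
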