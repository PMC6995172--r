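#' Estimate bisulfite conversion efficiency from telomeric repeats
#'
#' The main fitting function.  Scans one sample's FASTQ file(s) for telomeric
#' repeat runs, tallies the N0-N3 block classes of C-strand runs, computes
#' per-site unconverted ratios (UCRs), inverts the binomial block model for
#' an overall UCR and conversion efficiency, and assesses untreated-DNA
#' contamination from the dispersion of N3 blocks.  No alignment or reference
#' genome is used.  The two mate files of a pair are analysed independently;
#' the forward (`fastq1`) estimates are the primary ones, because reverse
#' reads of telomeric fragments run off the telomere end and accumulate
#' spurious terminal blocks that bias their UCRs slightly upward.
#'
#' @param fastq1 Path to the forward-read FASTQ (plain or gzipped).
#' @param fastq2 Optional path to the reverse-read FASTQ.
#' @param sample Sample label used in reports; defaults to the `fastq1`
#'   basename stripped of FASTQ extensions.
#' @param params A [scan_params()] object (telomeric-run threshold and
#'   distribution range).
#' @param cluster_min,concentration_min Contamination heuristics passed to
#'   [assess_contamination()].
#' @param min_informative_blocks Below this many C-strand blocks in a file,
#'   its UCRs are still computed (when any block exists) but the file is
#'   flagged `insufficient_telomeric_reads`: ratios on tiny denominators are
#'   noise, not estimates.
#' @return An object of class `teloconv`: a list with `sample`, `params`,
#'   and a `files` list holding, per file, the read counts, strand counts,
#'   telomeric read ratio, block-count distribution, `block_tally`,
#'   `site_ucr`, `binomial_fit`, `contamination_assessment`, and a `status`
#'   string.  Methods: [print.teloconv()], [summary.teloconv()],
#'   [coef.teloconv()], [plot.teloconv()], [residuals.teloconv()],
#'   [simulate.teloconv()]; see [write_report()] for the batch TSV.
#' @examples
#' \donttest{
#' sim <- simulate_wgbs(n_reads = 2000, telomeric_fraction = 0.05,
#'                      out_prefix = file.path(tempdir(), "ex"), seed = 1)
#' fit <- teloconv(sim$files[["fastq1"]], sim$files[["fastq2"]])
#' coef(fit)
#' }
#' @export
teloconv <- function(fastq1, fastq2 = NULL, sample = NULL,
                     params = scan_params(),
                     cluster_min = 2L, concentration_min = 0.5,
                     min_informative_blocks = 100L) {
  if (is.null(sample)) {
    sample <- sub("([._][12])?\\.(fastq|fq)(\\.gz)?$", "", basename(fastq1))
  }
  paths <- list(fastq1 = fastq1)
  if (!is.null(fastq2)) paths$fastq2 <- fastq2

  files <- lapply(names(paths), function(sf) {
    analyze_file(paths[[sf]], sf, params, cluster_min, concentration_min,
                 min_informative_blocks)
  })
  names(files) <- names(paths)

  structure(list(sample = sample, params = params,
                 cluster_min = cluster_min,
                 concentration_min = concentration_min,
                 files = files),
            class = "teloconv")
}

analyze_file <- function(path, source_file, params, cluster_min,
                         concentration_min, min_informative_blocks) {
  mate <- if (source_file == "fastq1") "mate1" else "mate2"
  reads <- read_fastq(path, mate = mate)
  matches <- scan_reads(reads, source_file, params)
  # distribution diagnostic always uses threshold 1
  dist_matches <- scan_reads(reads, source_file,
                             scan_params(1L, params$max_distribution_n))
  distribution <- block_count_distribution(dist_matches, params)
  distribution <- distribution[distribution$source_file == source_file, ,
                               drop = FALSE]
  rownames(distribution) <- NULL

  n_total <- nrow(reads)
  n_tel <- nrow(matches)
  n_c <- sum(matches$strand_origin == "c_strand")
  n_g <- sum(matches$strand_origin == "g_strand")
  ratio <- if (n_total > 0) telomeric_read_ratio(n_tel, n_total) else NA_real_

  tally <- tally_blocks(matches, source_file)
  has_blocks <- tally$total_blocks > 0
  ucr <- if (has_blocks) site_ucr(tally) else NULL
  # an N1 fraction above 4/9 means the equal-rate binomial model cannot hold
  # (e.g. one site much more methylated than the others); keep going and
  # report the inconsistency rather than aborting the sample
  fit <- NULL
  model_inconsistent <- FALSE
  if (has_blocks) {
    fit <- tryCatch(fit_binomial(tally), error = function(e) {
      model_inconsistent <<- TRUE
      warning("binomial model inconsistent for ", path, ": ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
  }
  contamination <- assess_contamination(matches, cluster_min,
                                        concentration_min)
  status <- if (tally$total_blocks < min_informative_blocks) {
    "insufficient_telomeric_reads"
  } else if (model_inconsistent) {
    "binomial_model_inconsistent"
  } else {
    "ok"
  }

  list(path = path, source_file = source_file,
       total_reads = n_total, telomeric_reads = n_tel,
       c_strand_reads = n_c, g_strand_reads = n_g,
       telomeric_ratio = ratio,
       distribution = distribution,
       tally = tally, site_ucr = ucr, fit = fit,
       contamination = contamination, status = status)
}

#' @method print teloconv
#' @export
print.teloconv <- function(x, ...) {
  cat("Telomere-based bisulfite conversion QC\n")
  cat("Sample:", x$sample, "\n")
  for (f in x$files) {
    cat(sprintf("  %s: %d reads, %d telomeric (%d C-strand, %d G-strand), %d blocks",
                f$source_file, f$total_reads, f$telomeric_reads,
                f$c_strand_reads, f$g_strand_reads, f$tally$total_blocks))
    if (!is.null(f$fit)) {
      cat(sprintf("\n    UCR %.6f  conversion efficiency %.4f%%  contamination: %s",
                  f$fit$ucr_hat, 100 * f$fit$conversion_efficiency,
                  f$contamination$verdict))
    }
    if (f$status != "ok") cat("\n    status:", f$status)
    cat("\n")
  }
  invisible(x)
}

#' Summarize a teloconv fit
#'
#' @param object A `teloconv` object.
#' @param ... Unused.
#' @return `object`, invisibly, after printing per-file tallies, per-site
#'   UCRs with binomial standard errors, the model fit, and the
#'   contamination assessment.
#' @method summary teloconv
#' @export
summary.teloconv <- function(object, ...) {
  print(object)
  for (f in object$files) {
    cat(sprintf("-- %s (%s)\n", f$source_file, f$path))
    t <- f$tally
    cat(sprintf("   blocks: total %d | N0 %d  N1 %d  N2 %d  N3 %d\n",
                t$total_blocks, t$n0, t$n1, t$n2, t$n3))
    if (!is.null(f$site_ucr)) {
      u <- f$site_ucr
      cat(sprintf("   site UCRs: %.6f (SE %.2g), %.6f (SE %.2g), %.6f (SE %.2g)\n",
                  u$ucr_site1, u$se_site1, u$ucr_site2, u$se_site2,
                  u$ucr_site3, u$se_site3))
    }
    if (!is.null(f$fit)) {
      fit <- f$fit
      cat(sprintf("   model: R1 %.6f -> UCR %.6f (SE %.2g)\n",
                  fit$r1_obs, fit$ucr_hat, fit$se_ucr_hat))
      cat(sprintf("   R2 obs %.2e vs exp %.2e | R3 obs %.2e vs exp %.2e\n",
                  fit$r2_obs, fit$r2_exp, fit$r3_obs, fit$r3_exp))
    }
    ca <- f$contamination
    cat(sprintf("   N3 blocks: %d total, %d in %d N3-rich reads -> %s\n",
                ca$n3_total, ca$n3_in_rich_reads, ca$n3_rich_reads,
                ca$verdict))
  }
  invisible(object)
}

#' Extract UCR estimates from a teloconv fit
#'
#' @param object A `teloconv` object.
#' @param source_file Which file's estimates; the forward file is the
#'   primary estimate and the default.
#' @param ... Unused.
#' @return Named vector: `ucr_site1`..`ucr_site3`, `ucr_hat`,
#'   `conversion_efficiency` (all `NA` when the file had no C-strand
#'   blocks).
#' @method coef teloconv
#' @export
coef.teloconv <- function(object, source_file = "fastq1", ...) {
  f <- object$files[[source_file]]
  if (is.null(f)) stop("no such file in this fit: ", source_file)
  if (is.null(f$fit)) {
    return(c(ucr_site1 = NA_real_, ucr_site2 = NA_real_, ucr_site3 = NA_real_,
             ucr_hat = NA_real_, conversion_efficiency = NA_real_))
  }
  c(ucr_site1 = f$site_ucr$ucr_site1,
    ucr_site2 = f$site_ucr$ucr_site2,
    ucr_site3 = f$site_ucr$ucr_site3,
    ucr_hat = f$fit$ucr_hat,
    conversion_efficiency = f$fit$conversion_efficiency)
}

#' Residuals of the binomial block model
#'
#' Observed minus expected N1-N3 block fractions at the fitted UCR.  The N1
#' residual is zero by construction (the UCR is estimated from R1); nonzero
#' N2/N3 residuals beyond sampling error indicate non-random unconverted
#' cytosines (enzymatic methylation or contamination).
#'
#' @param object A `teloconv` object.
#' @param source_file Which file's fit.
#' @param ... Unused.
#' @return Named vector `c(r1, r2, r3)` of observed - expected fractions.
#' @method residuals teloconv
#' @export
residuals.teloconv <- function(object, source_file = "fastq1", ...) {
  f <- object$files[[source_file]]
  if (is.null(f) || is.null(f$fit)) {
    return(c(r1 = NA_real_, r2 = NA_real_, r3 = NA_real_))
  }
  ex <- expected_block_fractions(f$fit$ucr_hat)
  c(r1 = f$fit$r1_obs - ex[["r1"]],
    r2 = f$fit$r2_obs - ex[["r2"]],
    r3 = f$fit$r3_obs - ex[["r3"]])
}

#' Plot the telomeric block-count distribution
#'
#' Reads-per-run-length on a log10 y axis, one line per strand, per file —
#' the diagnostic used to choose the telomeric-read threshold: counts decay
#' sharply and plateau from about 8 blocks, with a terminal peak of reads
#' that are telomeric end to end.
#'
#' @param x A `teloconv` object.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @importFrom graphics legend matplot abline
#' @method plot teloconv
#' @export
plot.teloconv <- function(x, ...) {
  nf <- length(x$files)
  if (nf > 1L) {
    op <- graphics::par(mfrow = c(1L, nf))
    on.exit(graphics::par(op))
  }
  for (f in x$files) {
    d <- f$distribution
    nmax <- max(d$n)
    cmat <- cbind(
      c_strand = d$reads[d$strand_origin == "c_strand"][seq_len(nmax)],
      g_strand = d$reads[d$strand_origin == "g_strand"][seq_len(nmax)]
    )
    matplot(seq_len(nmax), log10(cmat + 1), type = "b", pch = c(1, 2),
            lty = 1, col = c("darkorange", "steelblue"),
            xlab = "telomeric blocks per read (n)",
            ylab = "log10(reads + 1)",
            main = paste(x$sample, f$source_file), ...)
    abline(v = x$params$min_blocks, lty = 3)
    legend("topright", legend = c("C strand", "G strand"),
           col = c("darkorange", "steelblue"), pch = c(1, 2), bty = "n")
  }
  invisible(x)
}

#' Simulate WGBS reads from a fitted conversion model
#'
#' Generates a synthetic paired sample via [simulate_wgbs()] with all three
#' per-site unconversion probabilities set to the fitted UCR of the forward
#' file — a parametric-bootstrap companion to [teloconv()].
#'
#' @param object A `teloconv` object with a forward-file fit.
#' @param nsim Number of samples to generate.
#' @param seed Integer seed; sample `i` uses `seed + i - 1`.
#' @param out_prefix Output path prefix; sample `i` writes
#'   `<out_prefix><i>_1.fastq.gz` etc.
#' @param n_reads,telomeric_fraction Passed to [simulate_wgbs()].
#' @param ... Further arguments passed to [simulate_wgbs()].
#' @return A list of `nsim` [simulate_wgbs()] truth objects, invisibly.
#' @method simulate teloconv
#' @export
simulate.teloconv <- function(object, nsim = 1, seed = 1,
                              out_prefix = tempfile("teloconv_sim"),
                              n_reads = 10000, telomeric_fraction = 0.01,
                              ...) {
  f <- object$files[["fastq1"]]
  if (is.null(f$fit)) stop("cannot simulate: no fitted UCR (no C-strand blocks)")
  p <- f$fit$ucr_hat
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    out[[i]] <- simulate_wgbs(
      n_reads = n_reads, telomeric_fraction = telomeric_fraction,
      p_site = c(p, p, p), out_prefix = paste0(out_prefix, i),
      seed = seed + i - 1, ...)
  }
  invisible(out)
}
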