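#' Aggregate C-strand block observations into a tally
#'
#' Sums block-class counts (N0-N3) and per-site unconverted counts over all
#' C-strand matches of one file.  Every complete block of every matched run
#' is counted exactly once.
#'
#' @param matches A `telomere_matches` data frame.
#' @param source_file Which file's C-strand matches to tally.
#' @return A list of class `block_tally`: `total_blocks`, `n0`..`n3`,
#'   `site_unconverted` (named vector over site1..site3), `source_file`.
#' @export
tally_blocks <- function(matches, source_file = c("fastq1", "fastq2")) {
  source_file <- match.arg(source_file)
  m <- matches[matches$source_file == source_file &
                 matches$strand_origin == "c_strand", , drop = FALSE]
  tally <- structure(list(
    total_blocks = sum(m$block_count),
    n0 = sum(m$n0), n1 = sum(m$n1), n2 = sum(m$n2), n3 = sum(m$n3),
    site_unconverted = c(site1 = sum(m$site1), site2 = sum(m$site2),
                         site3 = sum(m$site3)),
    source_file = source_file
  ), class = "block_tally")
  stopifnot(tally$n0 + tally$n1 + tally$n2 + tally$n3 == tally$total_blocks,
            sum(tally$site_unconverted) ==
              tally$n1 + 2L * tally$n2 + 3L * tally$n3)
  tally
}

#' Per-site unconverted ratios
#'
#' The UCR of a site is the fraction of tallied blocks in which that site's
#' cytosine survived bisulfite treatment.  It is the sum of the
#' conversion-failure rate and the residual methylation rate of the site;
#' the two components cannot be separated from sequence alone.
#'
#' @param tally A `block_tally` from [tally_blocks()].
#' @return A list of class `site_ucr`: `ucr_site1`..`ucr_site3`, their
#'   binomial standard errors `se_site1`..`se_site3`, and `denominator`.
#' @export
site_ucr <- function(tally) {
  n <- tally$total_blocks
  if (n == 0) {
    stop("no telomeric C-strand blocks tallied; per-site UCRs are undefined ",
         "(this is not the same as a UCR of zero)")
  }
  u <- tally$site_unconverted / n
  structure(list(
    ucr_site1 = u[["site1"]], ucr_site2 = u[["site2"]], ucr_site3 = u[["site3"]],
    se_site1 = sqrt(u[["site1"]] * (1 - u[["site1"]]) / n),
    se_site2 = sqrt(u[["site2"]] * (1 - u[["site2"]]) / n),
    se_site3 = sqrt(u[["site3"]] * (1 - u[["site3"]]) / n),
    denominator = n
  ), class = "site_ucr")
}

#' Expected N1-N3 block fractions under the binomial model
#'
#' With each of a block's three cytosines independently unconverted with
#' probability `ucr`, the block class counts are Binomial(3, ucr), so
#' R1 = 3 ucr (1-ucr)^2, R2 = 3 ucr^2 (1-ucr), R3 = ucr^3.
#'
#' @param ucr Per-site unconverted probability in \[0, 1\].
#' @return Named numeric vector `c(r1, r2, r3)`.
#' @examples
#' expected_block_fractions(0.1)  # 0.243, 0.027, 0.001
#' @export
expected_block_fractions <- function(ucr) {
  if (!is.finite(ucr) || ucr < 0 || ucr > 1) {
    stop("ucr must lie in [0, 1]")
  }
  c(r1 = 3 * ucr * (1 - ucr)^2,
    r2 = 3 * ucr^2 * (1 - ucr),
    r3 = ucr^3)
}

#' Invert the binomial model on the N1 fraction
#'
#' Solves 3 p (1-p)^2 = `r1_obs` for p on the identifiable branch \[0, 1/3\],
#' where the map is strictly increasing with maximum 4/9.  N1 blocks are by
#' far the most abundant unconverted class, so this single equation carries
#' almost all of the information about the UCR.  Solved by bisection to an
#' absolute tolerance of 1e-12.
#'
#' @param r1_obs Observed fraction of N1 blocks, in \[0, 4/9\].
#' @return The unique p in \[0, 1/3\] with `expected_block_fractions(p)[1] ==
#'   r1_obs`.
#' @examples
#' ucr_from_r1(0.243)  # 0.1
#' @export
ucr_from_r1 <- function(r1_obs) {
  if (!is.finite(r1_obs) || r1_obs < 0) stop("r1_obs must be a fraction in [0, 4/9]")
  if (r1_obs > 4 / 9 + 1e-15) {
    stop("observed N1 fraction ", format(r1_obs), " exceeds 4/9, the maximum ",
         "attainable under the binomial model; the model is inconsistent ",
         "with these data")
  }
  if (r1_obs == 0) return(0)
  hi <- 1 / 3
  if (r1_obs >= 4 / 9) return(hi)  # boundary maximum of the cubic
  f <- function(p) 3 * p * (1 - p)^2 - r1_obs
  lo <- 0
  if (f(hi) <= 0) return(hi)
  while (hi - lo > 1e-12) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Fit the binomial conversion model to a block tally
#'
#' Computes observed N1-N3 fractions, estimates the UCR by inverting the
#' model on the N1 fraction ([ucr_from_r1()]), and recomputes the expected
#' N2 and N3 fractions at the estimate.  Agreement of observed and expected
#' N2 is the model-adequacy check: under random, independent conversion
#' failure they match; systematic (enzymatic) methylation or contamination
#' shows up as excess N2/N3.
#'
#' @param tally A `block_tally` from [tally_blocks()].
#' @return A list of class `binomial_fit`: `r1_obs`, `r2_obs`, `r3_obs`,
#'   `ucr_hat`, `se_ucr_hat` (delta-method binomial SE), `r2_exp`, `r3_exp`,
#'   `conversion_efficiency` (= 1 - `ucr_hat`), `total_blocks`.
#' @export
fit_binomial <- function(tally) {
  n <- tally$total_blocks
  if (n == 0) stop("no telomeric C-strand blocks tallied; cannot fit model")
  r1 <- tally$n1 / n
  r2 <- tally$n2 / n
  r3 <- tally$n3 / n
  p <- ucr_from_r1(r1)
  ex <- expected_block_fractions(p)
  # delta method: se(p) = se(r1) / |dR1/dp|, dR1/dp = 3(1-p)(1-3p)
  dr1 <- 3 * (1 - p) * (1 - 3 * p)
  se_p <- if (dr1 > 0) sqrt(r1 * (1 - r1) / n) / dr1 else NA_real_
  structure(list(
    r1_obs = r1, r2_obs = r2, r3_obs = r3,
    ucr_hat = p, se_ucr_hat = se_p,
    r2_exp = ex[["r2"]], r3_exp = ex[["r3"]],
    conversion_efficiency = 1 - p,
    total_blocks = n
  ), class = "binomial_fit")
}
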