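#' Binomial proportion confidence interval
#'
#' Two-sided 95% interval for a proportion, used by the mitochondrial
#' consensus-match and X-chromosome polymorphism criteria. Wilson score is the
#' default because it behaves correctly at proportions near 0 and 1;
#' Clopper-Pearson is available as a conservative alternative.
#'
#' @param k Successes, `n` trials.
#' @param conf Confidence level (default 0.95).
#' @param method `"wilson"` or `"clopper-pearson"`.
#' @return Numeric vector `c(lower, upper)`.
#' @export
prop_ci <- function(k, n, conf = 0.95, method = c("wilson", "clopper-pearson")) {
  method <- match.arg(method)
  stopifnot(n > 0, k >= 0, k <= n)
  alpha <- 1 - conf
  if (method == "wilson") {
    z <- stats::qnorm(1 - alpha / 2)
    p <- k / n
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    c(lower = max(0, centre - half), upper = min(1, centre + half))
  } else {
    lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
    upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
    c(lower = lower, upper = upper)
  }
}

#' Terminal-deamination damage criterion
#'
#' Authentic ancient DNA carries elevated C-to-T substitutions at fragment
#' ends; the screen requires a damage rate of at least 3% at the final
#' nucleotide.
#'
#' @param damaged,total Damaged and total read counts at the terminal
#'   position.
#' @return List with `rate` and `verdict` ("pass", "fail" or
#'   "not_evaluable" when `total` is 0).
#' @export
damage_check <- function(damaged, total) {
  stopifnot(damaged >= 0, total >= 0, damaged <= total)
  if (total == 0)
    return(list(rate = NA_real_, verdict = "not_evaluable"))
  rate <- damaged / total
  list(rate = rate, verdict = if (rate >= 0.03) "pass" else "fail")
}

#' Mitochondrial consensus-match criterion
#'
#' Contaminated libraries show reads that mismatch the sample's own mtDNA
#' consensus. The screen requires the upper bound of the 95% CI of the
#' match rate to exceed 98%.
#'
#' @param match,total Reads matching the consensus and total reads.
#' @param ci_method Passed to [prop_ci()].
#' @return List with `rate`, `ci_upper`, `verdict`.
#' @export
mt_consensus_check <- function(match, total, ci_method = "wilson") {
  stopifnot(match >= 0, total >= 0, match <= total)
  if (total == 0)
    return(list(rate = NA_real_, ci_upper = NA_real_, verdict = "not_evaluable"))
  ci <- prop_ci(match, total, method = ci_method)
  list(rate = match / total, ci_upper = unname(ci["upper"]),
       verdict = if (ci["upper"] > 0.98) "pass" else "fail")
}

#' X-chromosome polymorphism (contamination) criterion
#'
#' Males carry a single X, so positions covered at least twice should be
#' monomorphic; observing both alleles indicates contamination. Evaluable
#' only in males with at least 200 such positions; passes when the lower
#' bound of the 95% CI of the polymorphic fraction is below 1%.
#'
#' @param x_poly_sites Sites (covered >= 2x) showing both alleles.
#' @param x_sites_ge2x Sites covered at least twice.
#' @param sex_call Genetic sex call ("M", "F" or "U").
#' @param ci_method Passed to [prop_ci()].
#' @return List with `rate`, `ci_lower`, `verdict`.
#' @export
x_contamination_check <- function(x_poly_sites, x_sites_ge2x, sex_call,
                                  ci_method = "wilson") {
  stopifnot(x_poly_sites >= 0, x_sites_ge2x >= 0, x_poly_sites <= x_sites_ge2x)
  if (!identical(sex_call, "M") || x_sites_ge2x < 200)
    return(list(rate = NA_real_, ci_lower = NA_real_, verdict = "not_evaluable"))
  ci <- prop_ci(x_poly_sites, x_sites_ge2x, method = ci_method)
  list(rate = x_poly_sites / x_sites_ge2x, ci_lower = unname(ci["lower"]),
       verdict = if (ci["lower"] < 0.01) "pass" else "fail")
}

#' Genetic sex assignment from X/Y read counts
#'
#' The fraction of Y-chromosome reads among X+Y reads falls in distinct
#' ranges for this kind of capture data: above 35% for males, below 3% for
#' females; ratios in between are left undetermined.
#'
#' @param y_reads Reads mapping to Y.
#' @param xy_reads Reads mapping to X or Y.
#' @return List with `ratio` and `sex` ("M", "F" or "U").
#' @export
assign_sex <- function(y_reads, xy_reads) {
  stopifnot(y_reads >= 0, xy_reads >= 0, y_reads <= xy_reads)
  if (xy_reads == 0)
    return(list(ratio = NA_real_, sex = "U", flag = "no_xy_reads"))
  ratio <- y_reads / xy_reads
  sex <- if (ratio > 0.35) "M" else if (ratio < 0.03) "F" else "U"
  list(ratio = ratio, sex = sex)
}

#' Run the four-criterion authenticity screen on a cohort
#'
#' Applies the terminal-damage, mtDNA consensus, X-polymorphism and Y-ratio
#' sex criteria to per-individual read-count summaries. An individual's
#' overall verdict is TRUE only if the damage criterion passes and no
#' evaluable criterion fails; `not_evaluable` never fails an individual.
#'
#' @param readcounts data.frame with columns `individual_id`,
#'   `terminal_ct_damaged`, `terminal_ct_total`, `mt_match`, `mt_total`,
#'   `x_poly_sites`, `x_sites_ge2x`, `y_reads`, `xy_reads`.
#' @param ci_method Passed to [prop_ci()].
#' @param mt_override Character vector of individual ids whose mtDNA
#'   criterion is manually waived (set to `not_evaluable` with a note), for
#'   low-coverage libraries vetted by haplotype-defining positions.
#' @return data.frame (class `qc_report`) with one row per individual and a
#'   `sex_tally` attribute.
#' @export
run_qc <- function(readcounts, ci_method = "wilson", mt_override = character()) {
  stopifnot(is.data.frame(readcounts))
  if (nrow(readcounts) == 0L) stop("empty read-count table")
  if (anyDuplicated(readcounts$individual_id))
    stop("duplicate individual ids in read-count table")
  rows <- lapply(seq_len(nrow(readcounts)), function(i) {
    rc <- readcounts[i, ]
    dmg <- damage_check(rc$terminal_ct_damaged, rc$terminal_ct_total)
    mt <- mt_consensus_check(rc$mt_match, rc$mt_total, ci_method)
    if (rc$individual_id %in% mt_override && mt$verdict == "fail")
      mt$verdict <- "not_evaluable"
    sx <- assign_sex(rc$y_reads, rc$xy_reads)
    xc <- x_contamination_check(rc$x_poly_sites, rc$x_sites_ge2x, sx$sex, ci_method)
    verdicts <- c(damage = dmg$verdict, mt = mt$verdict, x_contam = xc$verdict)
    reasons <- names(verdicts)[verdicts == "fail"]
    if (dmg$verdict != "pass" && !("damage" %in% reasons))
      reasons <- c("damage", reasons)
    data.frame(
      individual_id = rc$individual_id,
      damage_rate = dmg$rate, damage_pass = identical(dmg$verdict, "pass"),
      mt_rate = mt$rate, mt_ci_upper = mt$ci_upper, mt_verdict = mt$verdict,
      x_rate = xc$rate, x_ci_lower = xc$ci_lower, x_verdict = xc$verdict,
      y_ratio = sx$ratio, sex_call = sx$sex,
      overall = identical(dmg$verdict, "pass") && !any(verdicts == "fail"),
      reasons = paste(reasons, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  report <- do.call(rbind, rows)
  attr(report, "sex_tally") <- table(factor(report$sex_call, levels = c("F", "M", "U")))
  class(report) <- c("qc_report", class(report))
  report
}

#' Tally of genetic sex calls from a QC report
#' @param report A `qc_report` from [run_qc()].
#' @return Table of counts over F, M, U.
#' @export
sex_tally <- function(report) attr(report, "sex_tally")
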