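# Runs of homozygosity: length-bin summaries, inbreeding flag, and a Poisson
# maximum-likelihood estimator of recent effective population size under a
# constant-size panmictic coalescent.
#
# Model: a ROH of genetic length l arises where the two haplotypes of an
# individual coalesce t generations ago; recombination breaks such segments at
# rate 2t per Morgan. With P_N(t) = (1/2N) (1 - 1/2N)^(t-1) the coalescence-
# time law in a constant-size diploid population of effective size N, the
# expected number of segments per individual with length in [l1, l2] Morgans
# on a chromosome of length G is
#   sum_t P_N(t) * int_{l1}^{l2} [ (G - l) (2t)^2 + 2 (2t) ] exp(-2 t l) dl,
# the first term counting segments interior to the chromosome and the second
# segments truncated by either chromosome end.

#' Summarize ROH segments into length bins
#'
#' Per individual: total centimorgans in ROH longer than 4, 8, 12 and 20 cM
#' (strict >), and segment counts in the bins [4,8), [8,12), [12,20) and
#' [20, Inf) cM. Individuals with fewer than `min_snps` called SNPs are marked
#' ineligible (the ROH caller is unreliable below that coverage) and should be
#' excluded from cohort statistics.
#'
#' @param segments data.frame with `individual_id`, `chromosome`, `start_cM`,
#'   `end_cM`. May be empty.
#' @param coverage Named per-individual call counts ([snp_coverage()]); its
#'   names define the cohort, so individuals without segments still get a row.
#' @param min_snps Eligibility floor (default 400,000).
#' @return data.frame (`roh_summary`) with sums, bin counts and `eligible`.
#' @export
summarize_roh <- function(segments, coverage, min_snps = 400000) {
  stopifnot(is.data.frame(segments))
  ids <- names(coverage)
  if (is.null(ids)) stop("coverage must be a named vector")
  len <- segments$end_cM - segments$start_cM
  if (any(len <= 0)) stop("ROH segments with non-positive length")
  if (nrow(segments) && !all(segments$individual_id %in% ids))
    stop("segments for individuals absent from coverage")
  sum_gt <- function(thr, id) {
    keep <- segments$individual_id == id & len > thr
    sum(len[keep])
  }
  n_bin <- function(lo, hi, id) {
    sum(segments$individual_id == id & len >= lo & len < hi)
  }
  out <- do.call(rbind, lapply(ids, function(id) data.frame(
    individual_id = id,
    sum_gt4 = sum_gt(4, id), sum_gt8 = sum_gt(8, id),
    sum_gt12 = sum_gt(12, id), sum_gt20 = sum_gt(20, id),
    n_4_8 = n_bin(4, 8, id), n_8_12 = n_bin(8, 12, id),
    n_12_20 = n_bin(12, 20, id), n_gt20 = n_bin(20, Inf, id),
    eligible = unname(coverage[id]) >= min_snps,
    stringsAsFactors = FALSE
  )))
  class(out) <- c("roh_summary", class(out))
  out
}

#' Flag close-kin parental inbreeding
#'
#' Offspring of close kin (first or second cousins or closer) carry long
#' autozygous tracts; any ROH longer than 20 cM flags an individual.
#'
#' @param summary A `roh_summary` from [summarize_roh()].
#' @return Named logical vector.
#' @export
flag_inbreeding <- function(summary) {
  stopifnot(inherits(summary, "roh_summary"))
  stats::setNames(summary$sum_gt20 > 0, summary$individual_id)
}

# Truncation point of the coalescence-time sum: generations beyond t_cap
# contribute < eps relative mass to segments of length >= l1 Morgans; also
# capped at 8N (documented tail bound: P(t > 8N) ~ exp(-4)).
t_max_for <- function(N, l1, eps = 1e-12) {
  cap <- ceiling(-log(eps) / (2 * max(l1, 1e-4)))
  max(50L, min(ceiling(8 * N), cap))
}

#' Expected ROH count per individual in a length bin
#'
#' Closed-form bin integral of the constant-size coalescent segment-length
#' density (see the header of this file), summed over chromosomes and over
#' coalescence times. Strictly decreasing in `N`.
#'
#' @param N Diploid effective population size (>= 2).
#' @param genome_map data.frame as [default_genome_map()].
#' @param bin_morgans Numeric `c(l1, l2)` in Morgans, `0 < l1 < l2`.
#' @param t_max Optional cap on the coalescence-time sum (generations);
#'   default chooses a cap with negligible tail mass.
#' @return Expected segment count per individual (numeric scalar).
#' @export
expected_roh_counts <- function(N, genome_map = default_genome_map(),
                                bin_morgans, t_max = NULL) {
  stopifnot(N >= 2, length(bin_morgans) == 2)
  l1 <- bin_morgans[1]; l2 <- bin_morgans[2]
  if (!(l1 > 0 && l2 > l1)) stop("invalid bin: need 0 < l1 < l2")
  map <- validate_genome_map(genome_map)
  if (l1 >= max(map$length_morgans)) stop("bin lies beyond every chromosome")
  if (is.null(t_max)) t_max <- t_max_for(N, l1)
  t <- seq_len(t_max)
  p <- (1 / (2 * N)) * (1 - 1 / (2 * N))^(t - 1)
  c2t <- 2 * t
  total <- 0
  for (i in seq_len(nrow(map))) {
    G <- map$length_morgans[i]
    if (l1 >= G) next
    hi <- min(l2, G)
    E1 <- exp(-c2t * l1); E2 <- exp(-c2t * hi)
    interior <- G * c2t * (E1 - E2) -
      ((c2t * l1 + 1) * E1 - (c2t * hi + 1) * E2)
    edge <- 2 * (E1 - E2)
    total <- total + sum(p * (interior + edge))
  }
  total
}

ne_loglik <- function(N, counts, n_ind, genome_map, bins_morgans) {
  ll <- 0
  for (b in seq_along(bins_morgans)) {
    E <- expected_roh_counts(N, genome_map, bins_morgans[[b]])
    k <- counts[, b]
    ll <- ll + sum(k) * log(E) - n_ind * E - sum(lgamma(k + 1))
  }
  ll
}

#' Maximum-likelihood effective population size from ROH rates
#'
#' Jointly fits per-individual Poisson counts of ROH segments in the given
#' length bins to the constant-size coalescent expectation, maximizing over
#' log N by bounded search. The 95% confidence interval is the likelihood
#' profile: all N with log-likelihood within 1.92 units of the maximum.
#'
#' @param summary A `roh_summary`; only eligible individuals are used.
#' @param genome_map data.frame as [default_genome_map()].
#' @param bins_cm List of `c(lo, hi)` bins in centimorgans
#'   (default `[4,8), [8,12), [12,20)`).
#' @param n_range Search bounds for N (default `c(1e2, 1e7)`).
#' @return List (`ne_estimate`): `ne_hat`, `ci_low`, `ci_high`,
#'   `n_individuals`, `total_segments`, `loglik_max`, `flag`
#'   (`"ok"`, `"no_segments"` or `"at_bound"`).
#' @export
ne_mle <- function(summary, genome_map = default_genome_map(),
                   bins_cm = list(c(4, 8), c(8, 12), c(12, 20)),
                   n_range = c(1e2, 1e7)) {
  stopifnot(inherits(summary, "roh_summary"))
  elig <- summary[summary$eligible, , drop = FALSE]
  if (nrow(elig) == 0) stop("no eligible individuals")
  bins_m <- lapply(bins_cm, function(b) b / 100)
  count_col <- function(b) {
    col <- sprintf("n_%g_%g", b[1], b[2])
    if (!col %in% names(elig))
      stop("summary lacks a count column for bin [", b[1], ",", b[2], ")")
    elig[[col]]
  }
  counts <- do.call(cbind, lapply(bins_cm, count_col))
  n_ind <- nrow(elig)
  total <- sum(counts)
  obj <- function(logN) ne_loglik(exp(logN), counts, n_ind, genome_map, bins_m)
  lo <- log(n_range[1]); hi <- log(n_range[2])
  flag <- "ok"
  if (total == 0) {
    ne_hat <- n_range[2]
    llmax <- obj(hi)
    flag <- "no_segments"
  } else {
    opt <- stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-4)
    ne_hat <- exp(opt$maximum)
    llmax <- opt$objective
    if (opt$maximum > hi - 1e-3 || opt$maximum < lo + 1e-3) flag <- "at_bound"
  }
  drop_fun <- function(logN) obj(logN) - (llmax - 1.92)
  ci_low <- if (drop_fun(lo) > 0) n_range[1] else
    exp(stats::uniroot(drop_fun, c(lo, log(ne_hat)), tol = 1e-6)$root)
  ci_high <- if (total == 0 || drop_fun(hi) > 0) n_range[2] else
    exp(stats::uniroot(drop_fun, c(log(ne_hat), hi), tol = 1e-6)$root)
  structure(list(ne_hat = ne_hat, ci_low = ci_low, ci_high = ci_high,
                 n_individuals = n_ind, total_segments = total,
                 loglik_max = llmax, flag = flag),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("<ne_estimate> Ne = %.0f (95%% profile CI %.0f-%.0f), %d individuals, %d segments [%s]\n",
              x$ne_hat, x$ci_low, x$ci_high, x$n_individuals,
              x$total_segments, x$flag))
  invisible(x)
}

#' Simple window-based ROH caller for dense diploid data
#'
#' Plumbing for synthetic diploid genotypes (not a substitute for
#' haplotype-copying callers on sparse pseudo-haploid data): scans fixed
#' genetic-map windows and reports maximal runs of windows with at most
#' `max_het_per_window` heterozygous calls. Windows without SNP data carry no
#' heterozygote evidence and do not break a run; reported segments are clipped
#' to the covered range of each chromosome.
#'
#' @param mat Diploid [genotype_matrix()].
#' @param window_cm Window size in centimorgans.
#' @param max_het_per_window Maximum heterozygote calls tolerated per window.
#' @param min_length_cm Minimum reported segment length in centimorgans.
#' @return data.frame of segments: `individual_id`, `chromosome`,
#'   `start_cM`, `end_cM`, `length_cM`.
#' @export
simple_roh_caller <- function(mat, window_cm = 1, max_het_per_window = 0,
                              min_length_cm = 4) {
  stopifnot(inherits(mat, "genotype_matrix"))
  if (mat$ploidy != "diploid")
    stop("the window caller needs diploid calls")
  segs <- list()
  chroms <- unique(mat$snp$chromosome)
  for (ch in chroms) {
    rows <- which(mat$snp$chromosome == ch)
    pos_cm <- mat$snp$genetic_pos[rows] * 100
    lo <- min(pos_cm); hi <- max(pos_cm)
    win <- floor(pos_cm / window_cm) + 1L
    W <- max(win)
    for (j in seq_len(ncol(mat$calls))) {
      g <- mat$calls[rows, j]
      het_win <- tabulate(win[!is.na(g) & g == 1L], nbins = W)
      ok <- het_win <= max_het_per_window
      rl <- rle(ok)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1L
      for (k in which(rl$values)) {
        s <- max((starts[k] - 1L) * window_cm, lo)
        e <- min(ends[k] * window_cm, hi)
        if (e - s >= min_length_cm)
          segs[[length(segs) + 1L]] <- data.frame(
            individual_id = mat$ind$individual_id[j], chromosome = ch,
            start_cM = s, end_cM = e, length_cM = e - s,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(segs))
    return(data.frame(individual_id = character(), chromosome = character(),
                      start_cM = numeric(), end_cM = numeric(),
                      length_cM = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, segs)
}
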