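# f4-statistics with block-jackknife uncertainties and a reduced qpAdm:
# a target population's f4 vector against an outgroup set is expressed as a
# weighted sum of the sources' f4 vectors; weights are estimated by weighted
# least squares under the sum-to-one constraint. Deliberately reduced: no
# rank tests on the full f4 matrix and no nested-model p-values; the use case
# is a single small mixture fit.

#' Construct an allele-frequency table
#'
#' @param freq Numeric matrix of alt-allele frequencies, SNPs x populations,
#'   with column names; `NA` allowed.
#' @param snp SNP data.frame with genetic positions (as in
#'   [genotype_matrix()]); used for jackknife blocks.
#' @param counts Optional matrix of per-cell sample sizes.
#' @param truth Optional list carried through from a simulation.
#' @return A `freq_table` object.
#' @export
freq_table <- function(freq, snp, counts = NULL, truth = NULL) {
  stopifnot(is.matrix(freq), !is.null(colnames(freq)),
            is.data.frame(snp), nrow(freq) == nrow(snp))
  rng <- range(freq, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop("frequencies outside [0, 1]")
  structure(list(pops = colnames(freq), snp = snp, freq = freq,
                 counts = counts, truth = truth),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("<freq_table> %d populations x %d SNPs\n",
              length(x$pops), nrow(x$snp)))
  invisible(x)
}

delete_one_block_means <- function(d, blocks) {
  # d: n x k matrix of per-SNP statistics; returns G x k delete-one-block means
  tot <- colSums(d)
  n <- nrow(d)
  bs <- rowsum(d, blocks)
  bn <- as.vector(table(blocks)[rownames(bs)])
  sweep(sweep(-bs, 2, tot, "+"), 1, n - bn, "/")
}

#' f4 statistic with block-jackknife standard error
#'
#' `f4(A, B; C, D)` is the mean over non-missing SNPs of
#' `(p_A - p_B)(p_C - p_D)`; SNPs missing in any of the four populations are
#' dropped. The standard error is a delete-one-block jackknife over contiguous
#' genetic-map blocks.
#'
#' @param ft A [freq_table()].
#' @param A,B,C,D Population labels.
#' @param block_cm Jackknife block size, centimorgans.
#' @return List (`f4_result`): `value`, `se`, `z`, `n_snps_used`, `n_blocks`.
#' @export
f4 <- function(ft, A, B, C, D, block_cm = 5) {
  stopifnot(inherits(ft, "freq_table"))
  pops <- c(A, B, C, D)
  miss <- setdiff(pops, ft$pops)
  if (length(miss)) stop("populations not in table: ", paste(miss, collapse = ", "))
  p <- ft$freq[, pops, drop = FALSE]
  ok <- stats::complete.cases(p)
  if (!any(ok)) stop("no SNP with data in all four populations")
  d <- (p[ok, 1] - p[ok, 2]) * (p[ok, 3] - p[ok, 4])
  blocks <- map_blocks(ft$snp[ok, , drop = FALSE], block_cm)
  G <- length(unique(blocks))
  if (G < 2) stop("need at least 2 genetic-map blocks with data")
  value <- mean(d)
  jk <- delete_one_block_means(matrix(d, ncol = 1), blocks)[, 1]
  se <- sqrt((G - 1) / G * sum((jk - mean(jk))^2))
  structure(list(value = value, se = se,
                 z = if (se > 0) value / se else NA_real_,
                 n_snps_used = sum(ok), n_blocks = G,
                 quadruple = pops),
            class = "f4_result")
}

# Solve min (ft - A w)' W (ft - A w) s.t. sum(w) = 1 via the KKT system.
solve_constrained_wls <- function(A, ftv, W) {
  k <- ncol(A)
  AtWA <- crossprod(A, W %*% A)
  kkt <- rbind(cbind(2 * AtWA, rep(1, k)), c(rep(1, k), 0))
  rhs <- c(2 * crossprod(A, W %*% ftv), 1)
  sol <- tryCatch(solve(kkt, rhs), error = function(e)
    stop("singular system: sources are collinear (identical or linearly dependent)",
         call. = FALSE))
  sol[seq_len(k)]
}

#' Two-or-more-source admixture proportions (reduced qpAdm)
#'
#' Builds the f4 vector `f4(target, O1; Oj, O1)` over outgroup pairs anchored
#' on the first outgroup, the analogous vectors for each source, and solves
#' for mixture weights minimizing the Mahalanobis residual under the
#' jackknife covariance of the target vector, subject to the weights summing
#' to one. Weight standard errors come from recomputing the fit on each
#' delete-one-block replicate. SNPs missing in any involved population are
#' dropped throughout (complete-case).
#'
#' @param ft A [freq_table()].
#' @param target Target population label.
#' @param sources Character vector of >= 2 source labels.
#' @param outgroups Character vector of at least `length(sources) + 1`
#'   outgroup labels, disjoint from target and sources.
#' @param block_cm Jackknife block size, centimorgans.
#' @return List (`mixture_model`): `weights` (named, sum 1), `se_weights`,
#'   `fit_residual_stat`, `feasible` (all weights in `[0, 1]`), `n_snps_used`,
#'   `n_blocks`, plus the f4 design (`f_target`, `f_sources`).
#' @export
qpadm_lite <- function(ft, target, sources, outgroups, block_cm = 5) {
  stopifnot(inherits(ft, "freq_table"))
  if (length(sources) < 2) stop("need at least 2 sources")
  if (length(outgroups) < length(sources) + 1)
    stop("need at least length(sources) + 1 outgroups")
  all_pops <- c(target, sources, outgroups)
  if (anyDuplicated(all_pops))
    stop("target, sources and outgroups must be disjoint")
  miss <- setdiff(all_pops, ft$pops)
  if (length(miss)) stop("populations not in table: ", paste(miss, collapse = ", "))

  p <- ft$freq[, all_pops, drop = FALSE]
  ok <- stats::complete.cases(p)
  if (!any(ok)) stop("no SNP with complete data")
  p <- p[ok, , drop = FALSE]
  blocks <- map_blocks(ft$snp[ok, , drop = FALSE], block_cm)
  G <- length(unique(blocks))
  if (G < 2) stop("need at least 2 genetic-map blocks with data")

  o1 <- p[, outgroups[1]]
  base <- p[, outgroups[-1], drop = FALSE] - o1   # (p_Oj - p_O1), j = 2..m
  m <- ncol(base)
  k <- length(sources)
  # per-SNP statistic arrays: target then each source
  stat_cols <- vector("list", (k + 1) * m)
  idx <- 1L
  for (pop in c(target, sources)) {
    dpop <- p[, pop] - o1
    for (j in seq_len(m)) {
      stat_cols[[idx]] <- dpop * base[, j]
      idx <- idx + 1L
    }
  }
  D <- do.call(cbind, stat_cols)
  means <- colMeans(D)
  Ft <- means[seq_len(m)]
  Fs <- matrix(means[-seq_len(m)], nrow = m, ncol = k,
               dimnames = list(NULL, sources))
  jk <- delete_one_block_means(D, blocks)          # G x (k+1)m
  jk_t <- jk[, seq_len(m), drop = FALSE]
  ctr <- sweep(jk_t, 2, colMeans(jk_t))
  Sigma <- (G - 1) / G * crossprod(ctr)
  W <- tryCatch(solve(Sigma), error = function(e) NULL)
  if (is.null(W)) {
    warning("singular jackknife covariance; falling back to diagonal weights")
    W <- diag(1 / pmax(diag(Sigma), 1e-30), m)
  }
  w <- solve_constrained_wls(Fs, Ft, W)
  resid <- Ft - Fs %*% w
  stat <- drop(t(resid) %*% W %*% resid)
  # jackknife of the weights
  wjk <- t(vapply(seq_len(G), function(g) {
    mg <- jk[g, ]
    Ftg <- mg[seq_len(m)]
    Fsg <- matrix(mg[-seq_len(m)], nrow = m, ncol = k)
    solve_constrained_wls(Fsg, Ftg, W)
  }, numeric(k)))
  se_w <- sqrt((G - 1) / G * colSums(sweep(wjk, 2, colMeans(wjk))^2))
  names(w) <- names(se_w) <- sources
  structure(list(target = target, sources = sources, outgroups = outgroups,
                 weights = w, se_weights = se_w, fit_residual_stat = stat,
                 feasible = all(w >= 0 & w <= 1),
                 n_snps_used = nrow(p), n_blocks = G,
                 f_target = Ft, f_sources = Fs),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("<mixture_model> %s = %s\n", x$target,
              paste(sprintf("%.3f (se %.3f) %s", x$weights, x$se_weights,
                            x$sources), collapse = " + ")))
  cat(sprintf("  residual stat %.3g, %d SNPs, %d blocks, feasible: %s\n",
              x$fit_residual_stat, x$n_snps_used, x$n_blocks, x$feasible))
  invisible(x)
}
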