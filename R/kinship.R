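# Pairwise mismatch machinery on pseudo-haploid calls.
#
# For a pair of individuals, x is the fraction of jointly-called panel SNPs
# where their sampled alleles differ. With b the expected mismatch rate of two
# unrelated individuals divided by two, the relatedness coefficient is
# r = 1 - ((x - b)/b) = 2 - x/b, with expectation 2*phi (phi the kinship
# coefficient): 0 for unrelated pairs, 0.5 first degree, 1 for identical
# genomes.

# Per-block mismatch and overlap counts for all unordered pairs.
# Returns list(m, n): G x P matrices (blocks x pairs), plus pair index.
pair_block_counts <- function(mat, block_cm = 5) {
  calls <- mat$calls
  blocks <- map_blocks(mat$snp, block_cm)
  nind <- ncol(calls)
  pair_idx <- which(lower.tri(matrix(0, nind, nind)))
  G <- max(blocks)
  A <- calls == 1L; A[is.na(A)] <- FALSE; storage.mode(A) <- "double"
  B <- calls == 0L; B[is.na(B)] <- FALSE; storage.mode(B) <- "double"
  V <- !is.na(calls); storage.mode(V) <- "double"
  m <- matrix(0, G, length(pair_idx))
  n <- matrix(0, G, length(pair_idx))
  rows_by_block <- split(seq_len(nrow(calls)), blocks)
  for (g in seq_len(G)) {
    idx <- rows_by_block[[g]]
    ab <- crossprod(A[idx, , drop = FALSE], B[idx, , drop = FALSE])
    mm <- ab + t(ab)
    nn <- crossprod(V[idx, , drop = FALSE])
    m[g, ] <- mm[pair_idx]
    n[g, ] <- nn[pair_idx]
  }
  # lower.tri indices are column-major with row > col; recover (row, col)
  cols <- ((pair_idx - 1L) %/% nind) + 1L
  rows <- ((pair_idx - 1L) %% nind) + 1L
  list(m = m, n = n, row = rows, col = cols)
}

#' Pairwise mismatch rates on a pseudo-haploid genotype matrix
#'
#' @param mat A pseudo-haploid [genotype_matrix()].
#' @param min_overlap Pairs with fewer jointly-called SNPs are still listed
#'   but can be filtered by callers; set `drop_below` to remove them.
#' @param drop_below If TRUE, pairs with overlap below `min_overlap` are
#'   dropped from the result.
#' @return data.frame with `id_a`, `id_b`, `overlap_snps`, `mismatches`, `x`.
#' @export
pairwise_mismatch <- function(mat, min_overlap = 0, drop_below = FALSE) {
  stopifnot(inherits(mat, "genotype_matrix"))
  if (mat$ploidy != "pseudo_haploid")
    stop("pairwise mismatch is defined on pseudo-haploid calls; ",
         "pseudo_haploidize() diploid data first")
  if (ncol(mat$calls) < 2L) stop("need at least 2 individuals")
  pb <- pair_block_counts(mat, block_cm = 1e9)  # single block: totals only
  M <- colSums(pb$m); N <- colSums(pb$n)
  ids <- mat$ind$individual_id
  out <- data.frame(
    id_a = ids[pb$col], id_b = ids[pb$row],
    overlap_snps = as.integer(N), mismatches = as.integer(M),
    x = ifelse(N > 0, M / N, NA_real_),
    stringsAsFactors = FALSE
  )
  if (drop_below) out <- out[out$overlap_snps >= min_overlap, , drop = FALSE]
  out
}

#' Calibrate the unrelated mismatch baseline
#'
#' The expected mismatch rate of two unrelated individuals is estimated as the
#' median of all pairwise mismatch rates among individuals with more than
#' `min_snps` called SNPs (assuming most pairs are unrelated); `b` is that
#' median divided by two.
#'
#' @param mismatches data.frame from [pairwise_mismatch()].
#' @param coverage Named per-individual call counts from [snp_coverage()].
#' @param min_snps Coverage floor for the baseline cohort (default 100,000).
#' @return List (`baseline_calibration`): `base`, `b`, `qualifying_ids`,
#'   `min_snps`.
#' @export
calibrate_baseline <- function(mismatches, coverage, min_snps = 100000) {
  qual <- names(coverage)[coverage > min_snps]
  keep <- mismatches$id_a %in% qual & mismatches$id_b %in% qual &
    !is.na(mismatches$x)
  if (!any(keep))
    stop("no pair with both individuals above ", min_snps, " called SNPs")
  base <- stats::median(mismatches$x[keep])
  structure(list(base = base, b = base / 2, qualifying_ids = qual,
                 min_snps = min_snps, n_pairs = sum(keep)),
            class = "baseline_calibration")
}

#' Relatedness coefficient from a mismatch rate
#'
#' `r = 1 - ((x - b)/b)`, equivalently `2 - x/b`. Not clamped: sampling noise
#' can push estimates slightly below 0 or above 1.
#'
#' @param x Mismatch rate(s).
#' @param calibration A `baseline_calibration` from [calibrate_baseline()].
#' @return Numeric vector of r values.
#' @export
relatedness <- function(x, calibration) {
  stopifnot(inherits(calibration, "baseline_calibration"))
  if (calibration$b == 0) stop("baseline b is zero; cannot form r")
  1 - ((x - calibration$b) / calibration$b)
}

#' Default relationship-degree windows
#'
#' Lower r bound per degree, at the midpoints between the expected values
#' 1, 0.5, 0.25, 0.125, 0 on a halving scale.
#' @return Named numeric vector of lower bounds, strictly decreasing.
#' @export
default_degree_windows <- function() {
  c(identical = 0.7, first = 0.35, second = 0.1875, third = 0.09375)
}

#' Classify a relatedness coefficient into a degree
#'
#' Windows partition the r line; estimates within `2 * se_r` of a window
#' boundary are reported as `"unresolved"` rather than forced into a class.
#'
#' @param r Relatedness estimate(s).
#' @param se_r Standard error(s); use 0 to disable the unresolved rule.
#' @param windows Named lower bounds as in [default_degree_windows()].
#' @return Character vector of degrees: "identical", "first", "second",
#'   "third", "unrelated" or "unresolved".
#' @export
classify_degree <- function(r, se_r = 0, windows = default_degree_windows()) {
  if (is.unsorted(rev(windows), strictly = TRUE) || any(windows <= 0))
    stop("degree windows must be strictly decreasing positive lower bounds")
  se_r <- rep_len(se_r, length(r))
  bounds <- unname(windows)
  vapply(seq_along(r), function(i) {
    if (is.na(r[i])) return(NA_character_)
    cls <- c(names(windows), "unrelated")[findInterval(-r[i], -bounds) + 1L]
    near <- !is.na(se_r[i]) && any(abs(r[i] - bounds) < 2 * se_r[i])
    if (near) "unresolved" else cls
  }, character(1))
}

# Delete-one-block jackknife SE of r for each pair, holding the baseline b
# fixed. m, n are blocks x pairs count matrices.
jackknife_se_r <- function(m, n, b) {
  M <- colSums(m); N <- colSums(n)
  G <- nrow(m)
  if (G < 2) return(rep(NA_real_, length(M)))
  x_del <- sweep(-m, 2, M, "+") / pmax(sweep(-n, 2, N, "+"), 1)  # (M-m_g)/(N-n_g)
  r_del <- 2 - x_del / b
  r_bar <- colMeans(r_del)
  sqrt((G - 1) / G * colSums(sweep(r_del, 2, r_bar)^2))
}

#' Full kinship table for a cohort
#'
#' Computes all pairwise mismatch rates, calibrates the unrelated baseline
#' from the high-coverage subset, converts to relatedness coefficients with
#' block-jackknife standard errors, and classifies degrees. Pairs with fewer
#' than `min_overlap` jointly-called SNPs are listed but left unclassified.
#'
#' @param mat Pseudo-haploid [genotype_matrix()].
#' @param min_overlap Minimum pair overlap for degree classification
#'   (default 15,000 SNPs).
#' @param min_snps_baseline Coverage floor for the baseline cohort.
#' @param block_cm Jackknife block size on the genetic map, centimorgans.
#' @param windows Degree windows, see [classify_degree()].
#' @return List (`kinship_result`): `table` (one row per pair: ids, overlap,
#'   x, r, se_r, degree), `baseline`, `r_matrix` (square, for plotting),
#'   `close_ids` (individuals with >= 1 relative at 3rd degree or closer) and
#'   `n_close_kin`.
#' @export
kinship_table <- function(mat, min_overlap = 15000, min_snps_baseline = 100000,
                          block_cm = 5, windows = default_degree_windows()) {
  stopifnot(inherits(mat, "genotype_matrix"))
  if (mat$ploidy != "pseudo_haploid")
    stop("kinship_table requires pseudo-haploid calls")
  if (ncol(mat$calls) < 2L) stop("need at least 2 individuals")
  pb <- pair_block_counts(mat, block_cm)
  M <- colSums(pb$m); N <- colSums(pb$n)
  ids <- mat$ind$individual_id
  x <- ifelse(N > 0, M / N, NA_real_)
  coverage <- snp_coverage(mat)
  pm <- data.frame(id_a = ids[pb$col], id_b = ids[pb$row],
                   overlap_snps = as.integer(N), mismatches = as.integer(M),
                   x = x, stringsAsFactors = FALSE)
  cal <- calibrate_baseline(pm, coverage, min_snps_baseline)
  r <- relatedness(x, cal)
  se <- jackknife_se_r(pb$m, pb$n, cal$b)
  degree <- classify_degree(r, se, windows)
  degree[N < min_overlap] <- NA_character_
  tab <- cbind(pm, data.frame(r = r, se_r = se, degree = degree,
                              stringsAsFactors = FALSE))
  rmat <- matrix(NA_real_, length(ids), length(ids),
                 dimnames = list(ids, ids))
  rmat[cbind(pb$row, pb$col)] <- r
  rmat[cbind(pb$col, pb$row)] <- r
  diag(rmat) <- 1
  close <- !is.na(degree) & degree %in% c("identical", "first", "second", "third")
  close_ids <- sort(unique(c(tab$id_a[close], tab$id_b[close])))
  structure(list(table = tab, baseline = cal, r_matrix = rmat,
                 close_ids = close_ids, n_close_kin = length(close_ids)),
            class = "kinship_result")
}

#' @export
print.kinship_result <- function(x, ...) {
  cat(sprintf("<kinship_result> %d pairs, baseline %.4f (b = %.4f), %d close-kin individuals\n",
              nrow(x$table), x$baseline$base, x$baseline$b, x$n_close_kin))
  invisible(x)
}
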