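seg_df <- function(lens, id = "I1", chrom = "1") {
  starts <- cumsum(c(0, head(lens, -1) + 5))
  data.frame(individual_id = id, chromosome = chrom,
             start_cM = starts, end_cM = starts + lens,
             stringsAsFactors = FALSE)
}

test_that("ROH sums and bin counts follow the strict > thresholds", {
  s <- summarize_roh(seg_df(c(5, 9, 13, 21)), coverage = c(I1 = 500000))
  expect_equal(s$sum_gt4, 48)
  expect_equal(s$sum_gt8, 43)
  expect_equal(s$sum_gt12, 34)
  expect_equal(s$sum_gt20, 21)
  expect_equal(unlist(s[, c("n_4_8", "n_8_12", "n_12_20", "n_gt20")],
                      use.names = FALSE), c(1L, 1L, 1L, 1L))
  # individuals with no segments still appear, with zero sums
  s2 <- summarize_roh(seg_df(5)[0, ],
                      coverage = c(A = 500000, B = 350000))
  expect_equal(s2$sum_gt4, c(0, 0))
  expect_equal(s2$eligible, c(TRUE, FALSE))  # 400k floor
  expect_error(summarize_roh(data.frame(individual_id = "A", chromosome = "1",
                                        start_cM = 10, end_cM = 5),
                             coverage = c(A = 5e5)), "non-positive")
})

test_that("the >20 cM flag marks close-kin parental inbreeding only", {
  s <- summarize_roh(rbind(seg_df(c(5, 12), id = "clean"),
                           seg_df(25, id = "inbred")),
                     coverage = c(clean = 5e5, inbred = 5e5))
  fl <- flag_inbreeding(s)
  expect_false(fl[["clean"]])
  expect_true(fl[["inbred"]])
})

test_that("expected ROH counts decrease in N, vanish as N grows, and add over bins", {
  e1 <- expected_roh_counts(1000, bin_morgans = c(0.04, 0.20))
  e2 <- expected_roh_counts(10000, bin_morgans = c(0.04, 0.20))
  e3 <- expected_roh_counts(100000, bin_morgans = c(0.04, 0.20))
  expect_gt(e1, e2); expect_gt(e2, e3)
  expect_lt(expected_roh_counts(5e6, bin_morgans = c(0.04, 0.20)), 1e-2)
  # additivity over adjacent bins
  for (N in c(500, 5000, 50000)) {
    ab <- expected_roh_counts(N, bin_morgans = c(0.04, 0.08))
    bc <- expected_roh_counts(N, bin_morgans = c(0.08, 0.20))
    ac <- expected_roh_counts(N, bin_morgans = c(0.04, 0.20))
    expect_equal(ab + bc, ac, tolerance = 1e-8)
  }
  expect_error(expected_roh_counts(1000, bin_morgans = c(0.2, 0.1)), "invalid bin")
})

test_that("analytic expectation matches the Monte-Carlo segment simulator", {
  ngen <- 800
  segs <- simulate_roh_lengths(1000, n_individuals = ngen, seed = 606,
                               floor_cm = 4)
  len <- segs$end_cM - segs$start_cM
  for (bin in list(c(4, 8), c(8, 12), c(12, 20))) {
    tab <- table(factor(segs$individual_id[len >= bin[1] & len < bin[2]],
                        levels = sprintf("SIM%03d", seq_len(ngen))))
    counts <- as.numeric(tab)
    E <- expected_roh_counts(1000, bin_morgans = bin / 100)
    se <- stats::sd(counts) / sqrt(ngen)
    expect_lt(abs(mean(counts) - E), 3 * se)
  }
})

test_that("the Ne likelihood is a fixed point at exact expected counts", {
  N0 <- 5000
  bins <- list(c(4, 8), c(8, 12), c(12, 20))
  E <- vapply(bins, function(b) expected_roh_counts(N0, bin_morgans = b / 100),
              numeric(1))
  s <- data.frame(individual_id = sprintf("I%02d", 1:20),
                  sum_gt4 = 0, sum_gt8 = 0, sum_gt12 = 0, sum_gt20 = 0,
                  n_4_8 = E[1], n_8_12 = E[2], n_12_20 = E[3], eligible = TRUE)
  class(s) <- c("roh_summary", class(s))
  est <- ne_mle(s)
  expect_equal(est$ne_hat, N0, tolerance = 1e-3)
  expect_lt(est$ci_low, N0); expect_gt(est$ci_high, N0)
  # profile endpoints sit exactly 1.92 log-likelihood units below the max
  for (endpoint in c(est$ci_low, est$ci_high)) {
    ll <- paleokin:::ne_loglik(endpoint, matrix(E, 20, 3, byrow = TRUE), 20,
                               default_genome_map(), lapply(bins, function(b) b / 100))
    expect_lt(abs(ll - (est$loglik_max - 1.92)), 1e-3)
  }
})

test_that("zero observed segments push Ne to the search bound with a flag", {
  s <- data.frame(individual_id = "I01", sum_gt4 = 0, sum_gt8 = 0,
                  sum_gt12 = 0, sum_gt20 = 0,
                  n_4_8 = 0, n_8_12 = 0, n_12_20 = 0, eligible = TRUE)
  class(s) <- c("roh_summary", class(s))
  est <- ne_mle(s)
  expect_identical(est$flag, "no_segments")
  expect_equal(est$ne_hat, 1e7)
  expect_equal(est$ci_high, 1e7)
  expect_lt(est$ci_low, 1e7)
  s$eligible <- FALSE
  expect_error(ne_mle(s), "no eligible")
})

test_that("Ne recovery is scale-consistent over a doubling of the truth", {
  med <- function(N, seeds) {
    vapply(seeds, function(s) {
      segs <- simulate_roh_lengths(N, n_individuals = 27, seed = s, floor_cm = 4)
      summ <- summarize_roh(segs, setNames(rep(5e5, 27), sprintf("SIM%03d", 1:27)))
      ne_mle(summ)$ne_hat
    }, numeric(1))
  }
  n1 <- stats::median(med(2500, 1:40))
  n2 <- stats::median(med(5000, 101:140))
  expect_gt(n2 / n1, 1.5)
  expect_lt(n2 / n1, 2.6)
})

test_that("the window caller recovers homozygous tracts and ignores het-dense data", {
  # fully homozygous chromosome spanning 100 cM -> a single 100 cM segment
  pos <- seq(0, 1, length.out = 201)
  hom <- toy_matrix(matrix(0L, 201, 1), ploidy = "diploid",
                    chromosomes = rep("1", 201), genetic_pos = pos)
  seg <- simple_roh_caller(hom)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$length_cM, 100)
  # alternating het/hom calls -> nothing called
  alt <- toy_matrix(matrix(rep(c(1L, 0L), 100), 200, 1), ploidy = "diploid",
                    chromosomes = rep("1", 200),
                    genetic_pos = seq(0, 1, length.out = 200))
  expect_equal(nrow(simple_roh_caller(alt)), 0)
  expect_error(simple_roh_caller(pseudo_haploidize(hom, seed = 1)), "diploid")
})

test_that("planted autozygous tracts are recovered by the caller", {
  set.seed(17)
  n <- 5000
  pos <- sort(runif(n, 0, 2.8))
  hits <- 0
  nrep <- 100
  for (i in seq_len(nrep)) {
    p <- runif(n, 0.05, 0.95)
    g <- rbinom(n, 1, p) + rbinom(n, 1, p)
    tract <- c(1.0, 1.1)  # 10 cM autozygous tract
    inside <- pos >= tract[1] & pos < tract[2]
    hap <- rbinom(sum(inside), 1, p[inside])
    g[inside] <- 2L * hap
    m <- toy_matrix(matrix(as.integer(g), n, 1), ploidy = "diploid",
                    chromosomes = rep("1", n), genetic_pos = pos)
    segs <- simple_roh_caller(m, min_length_cm = 4)
    if (nrow(segs)) {
      ov <- pmin(segs$end_cM, 110) - pmax(segs$start_cM, 100)
      if (any(ov >= 8)) hits <- hits + 1  # >= 80% of the 10 cM tract
    }
  }
  expect_gte(hits, 90)
})

test_that("offspring of first cousins are flagged for inbreeding", {
  trios <- data.frame(
    child  = c("A", "B", "C", "D", "KID"),
    mother = c("GM", "GM", "S1", "S2", "C"),
    father = c("GF", "GF", "A", "B", "D"),
    stringsAsFactors = FALSE)
  flagged <- 0
  nrep <- 100
  for (i in seq_len(nrep)) {
    cfg <- cohort_config(seed = 7000 + i, n_snps = 120000,
                         pedigrees = list(trios), sampled_ids = "KID",
                         linked = TRUE)
    sim <- simulate_cohort(cfg)
    segs <- simple_roh_caller(sim$matrix, window_cm = 0.25, min_length_cm = 4)
    summ <- summarize_roh(segs, coverage = c(KID = 5e5))
    if (flag_inbreeding(summ)[["KID"]]) flagged <- flagged + 1
  }
  expect_gte(flagged, 95)
})

test_that("summaries are invariant to segment order and chromosome labels", {
  segs <- rbind(seg_df(c(5, 9), chrom = "1"), seg_df(c(13, 21), chrom = "2"))
  s1 <- summarize_roh(segs, coverage = c(I1 = 5e5))
  segs2 <- segs[rev(seq_len(nrow(segs))), ]
  segs2$chromosome <- ifelse(segs2$chromosome == "1", "7", "9")
  s2 <- summarize_roh(segs2, coverage = c(I1 = 5e5))
  expect_equal(s1$sum_gt4, s2$sum_gt4)
  expect_equal(s1$n_4_8, s2$n_4_8)
})
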