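test_that("pairwise mismatch arithmetic on explicit call vectors", {
  a <- c(0L, 1L, 0L, 1L, NA)
  b <- c(0L, 1L, 1L, 1L, 0L)
  m <- toy_matrix(cbind(a, b))
  pm <- pairwise_mismatch(m)
  expect_equal(pm$overlap_snps, 4L)
  expect_equal(pm$mismatches, 1L)
  expect_equal(pm$x, 0.25)

  ident <- toy_matrix(cbind(a, a))
  expect_equal(pairwise_mismatch(ident)$x, 0)
  comp <- toy_matrix(cbind(c(0L, 0L, 0L), c(1L, 1L, 1L)))
  expect_equal(pairwise_mismatch(comp)$x, 1)
  expect_error(pairwise_mismatch(toy_matrix(matrix(0L, 3, 1))), "2 individuals")
  dip <- toy_matrix(matrix(2L, 3, 2), ploidy = "diploid")
  expect_error(pairwise_mismatch(dip), "pseudo-haploid")
})

test_that("baseline is the median over pairs of high-coverage individuals", {
  pm <- data.frame(id_a = c("a", "a", "b"), id_b = c("b", "c", "c"),
                   overlap_snps = 10L, mismatches = 1L,
                   x = c(0.22, 0.24, 0.26), stringsAsFactors = FALSE)
  cov <- c(a = 150000, b = 150000, c = 150000)
  cal <- calibrate_baseline(pm, cov)
  expect_equal(cal$base, 0.24)
  expect_equal(cal$b, 0.12)
  # all-equal rates give that rate back
  pm$x <- 0.3
  expect_equal(calibrate_baseline(pm, cov)$base, 0.3)
  # coverage rule is strict >: individuals at exactly min_snps do not qualify
  cov2 <- c(a = 100000, b = 150000, c = 150000)
  cal2 <- calibrate_baseline(pm, cov2)
  expect_setequal(cal2$qualifying_ids, c("b", "c"))
  expect_error(calibrate_baseline(pm, c(a = 1, b = 1, c = 1)), "no pair")
})

test_that("relatedness formula maps base to 0, base/2 to 1, 0.75*base to 0.5", {
  cal <- structure(list(base = 0.24, b = 0.12), class = "baseline_calibration")
  expect_equal(relatedness(0.24, cal), 0)
  expect_equal(relatedness(0.12, cal), 1)
  expect_equal(relatedness(0.18, cal), 0.5)
  expect_equal(relatedness(0.27, cal), -0.25)  # noise below unrelated is not clamped
  cal0 <- structure(list(base = 0, b = 0), class = "baseline_calibration")
  expect_error(relatedness(0.1, cal0), "zero")
})

test_that("degree windows classify expectations and flag boundary estimates", {
  expect_identical(classify_degree(0.50, 0.01), "first")
  expect_identical(classify_degree(0.125, 0.01), "third")
  expect_identical(classify_degree(0.01, 0.01), "unrelated")
  expect_identical(classify_degree(0.25, 0.01), "second")
  expect_identical(classify_degree(1.0, 0.01), "identical")
  # within 2 se of a boundary -> unresolved
  expect_identical(classify_degree(0.36, 0.01), "unresolved")
  expect_identical(classify_degree(0.36, 0.001), "first")
  expect_error(classify_degree(0.5, 0, windows = c(first = 0.3, identical = 0.7)),
               "decreasing")
})

test_that("baseline of a panmictic cohort matches the closed-form expectation", {
  cfg <- cohort_config(seed = 31, n_snps = 100000,
                       sampled_ids = sprintf("U%02d", 1:8))
  sim <- simulate_cohort(cfg)
  ph <- pseudo_haploidize(sim$matrix, seed = 32)
  pm <- pairwise_mismatch(ph)
  cal <- calibrate_baseline(pm, snp_coverage(ph), min_snps = 50000)
  analytic <- mean(2 * sim$truth$freqs * (1 - sim$truth$freqs))
  expect_lt(abs(cal$base - analytic), 0.005)
})

test_that("r is symmetric and invariant to ref/alt relabelling", {
  m <- random_matrix(5000, 4, seed = 5, ploidy = "pseudo_haploid",
                     missing_rate = 0.05)
  pm <- pairwise_mismatch(m)
  # relabel alleles at a random subset of SNPs for every individual
  set.seed(6)
  flip <- sample(c(TRUE, FALSE), 5000, TRUE)
  calls2 <- m$calls
  calls2[flip, ] <- 1L - calls2[flip, ]
  pm2 <- pairwise_mismatch(toy_matrix(calls2,
                                      chromosomes = m$snp$chromosome,
                                      genetic_pos = m$snp$genetic_pos))
  expect_equal(pm$x, pm2$x)
  # symmetry: the pair list covers unordered pairs once; reversing the
  # column order gives identical mismatch rates for matching pairs
  mrev <- toy_matrix(m$calls[, 4:1], chromosomes = m$snp$chromosome,
                     genetic_pos = m$snp$genetic_pos)
  pmrev <- pairwise_mismatch(mrev)
  expect_setequal(round(pm$x, 12), round(pmrev$x, 12))
})

test_that("duplicate genomes are classified identical and full tables are coherent", {
  cfg <- cohort_config(seed = 77, n_snps = 60000,
                       sampled_ids = c(sprintf("U%02d", 1:6)))
  sim <- simulate_cohort(cfg)
  # duplicate: two pseudo-haploid samplings of the same diploid individual
  ph <- pseudo_haploidize(sim$matrix, seed = 78)
  ph2 <- pseudo_haploidize(sim$matrix, seed = 79)
  calls <- cbind(ph$calls, DUP = ph2$calls[, "U01"])
  ind <- rbind(ph$ind, data.frame(individual_id = "U01_dup", declared_sex = "U",
                                  group_label = "COHORT"))
  m <- genotype_matrix(ind, ph$snp, calls, ploidy = "pseudo_haploid")
  kin <- kinship_table(m, min_overlap = 1000, min_snps_baseline = 30000)
  tab <- kin$table
  duprow <- tab[(tab$id_a == "U01" & tab$id_b == "U01_dup") |
                  (tab$id_b == "U01" & tab$id_a == "U01_dup"), ]
  expect_identical(duprow$degree, "identical")
  expect_equal(duprow$r, 1, tolerance = 0.06)
  expect_setequal(kin$close_ids, c("U01", "U01_dup"))
  # r matrix mirrors the table symmetrically
  expect_equal(kin$r_matrix["U01", "U01_dup"], duprow$r)
  expect_equal(kin$r_matrix["U01_dup", "U01"], duprow$r)
})

test_that("jackknife SE shrinks roughly as 1/sqrt(data) on homogeneous genomes", {
  cfg <- cohort_config(seed = 55, n_snps = 80000, sampled_ids = c("A", "B"))
  sim <- simulate_cohort(cfg)
  ph <- pseudo_haploidize(sim$matrix, seed = 56)
  kin_full <- kinship_table(ph, min_overlap = 1000, min_snps_baseline = 1000)
  # restrict to 1/4 of the genome (chromosomes 1-3 hold ~25% of the map)
  keep <- ph$snp$chromosome %in% c("1", "2", "3")
  sub <- genotype_matrix(ph$ind, ph$snp[keep, ], ph$calls[keep, , drop = FALSE],
                         ploidy = "pseudo_haploid")
  kin_sub <- kinship_table(sub, min_overlap = 1000, min_snps_baseline = 1000)
  ratio <- kin_sub$table$se_r / kin_full$table$se_r
  expect_gt(ratio, 1.4)  # ~2 expected for a quarter of the data
  expect_lt(ratio, 3.2)
})
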