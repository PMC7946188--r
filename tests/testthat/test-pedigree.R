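ped_i <- function() {
  # father F with daughters D1, D2; F's brother BRO with son NEPHEW
  pedigree(data.frame(
    child  = c("F", "BRO", "D1", "D2", "NEPHEW"),
    mother = c("GM", "GM", "W1", "W1", "W2"),
    father = c("GF", "GF", "F", "F", "BRO"),
    stringsAsFactors = FALSE))
}

test_that("recursive kinship reproduces textbook coefficients", {
  ped <- ped_i()
  expect_equal(expected_kinship(ped, "F", "D1")$phi, 1 / 4)
  expect_equal(expected_kinship(ped, "F", "D1")$r, 1 / 2)
  expect_equal(expected_kinship(ped, "F", "NEPHEW")$phi, 1 / 8)   # uncle-nephew
  expect_equal(expected_kinship(ped, "D1", "NEPHEW")$phi, 1 / 16) # first cousins
  expect_equal(expected_kinship(ped, "D1", "D2")$phi, 1 / 4)      # full sisters
  expect_equal(expected_kinship(ped, "F", "W1")$phi, 0)
  expect_equal(expected_kinship(ped, "F", "F")$phi, 1 / 2)
  expect_error(expected_kinship(ped, "F", "nobody"), "not in pedigree")
  # paternal aunt and paternal half-sister are the same phi = 1/8 class
  half <- pedigree(data.frame(child = c("BOY", "HSIS"),
                              mother = c("M1", "M2"), father = c("FA", "FA")))
  expect_equal(expected_kinship(half, "BOY", "HSIS")$phi, 1 / 8)
  aunt <- pedigree(data.frame(child = c("DAD", "AUNT", "BOY"),
                              mother = c("G1", "G1", "MO"),
                              father = c("G0", "G0", "DAD")))
  expect_equal(expected_kinship(aunt, "BOY", "AUNT")$phi, 1 / 8)
})

test_that("recursive kinship agrees with gene-dropping on a pedigree battery", {
  trios <- data.frame(
    child  = c("F", "BRO", "D1", "D2", "NEPHEW", "GSON"),
    mother = c("GM", "GM", "W1", "W1", "W2", "D1"),
    father = c("GF", "GF", "F", "F", "BRO", "H1"),
    stringsAsFactors = FALSE)
  ped <- pedigree(trios)
  set.seed(99)
  cases <- list(c("F", "NEPHEW"), c("D1", "NEPHEW"), c("GSON", "F"),
                c("GSON", "D2"), c("GSON", "NEPHEW"))
  for (pair in cases) {
    phi <- expected_kinship(ped, pair[1], pair[2])$phi
    est <- gene_drop_phi(trios, pair[1], pair[2], nrep = 1e5)
    se <- sqrt(est * (1 - est) / 1e5)
    expect_lt(abs(est - phi), 3 * se + 1e-9)
  }
})

test_that("cyclic pedigrees are rejected", {
  expect_error(pedigree(data.frame(child = c("a", "b"), mother = c("b", "a"),
                                   father = c(NA, NA))), "cycle")
})

test_that("consistency rules catch lineage, degree and sex-role conflicts", {
  ped <- pedigree(data.frame(child = "SON", mother = "MOM", father = "DAD"))
  prof_ok <- data.frame(
    individual_id = c("SON", "MOM", "DAD"),
    mt_lineage = c("H1", "H1", "K2"),
    y_lineage = c("G2", NA, "G2"),
    sex_call = c("M", "F", "M"), stringsAsFactors = FALSE)
  kin <- data.frame(id_a = c("SON", "SON", "MOM"), id_b = c("MOM", "DAD", "DAD"),
                    overlap_snps = 50000L, mismatches = 0L,
                    x = 0, r = c(0.5, 0.5, 0.0), se_r = 0.01,
                    degree = c("first", "first", "unrelated"),
                    stringsAsFactors = FALSE)
  f <- check_consistency(ped, prof_ok, kin)
  expect_true(all(f$status == "ok"))
  expect_setequal(unique(f$rule_id), c("R1", "R2", "R3", "R4"))

  # mother with mismatching mt lineage -> R1 violation
  prof_bad_mt <- prof_ok; prof_bad_mt$mt_lineage[2] <- "X9"
  f1 <- check_consistency(ped, prof_bad_mt, kin)
  expect_true(any(f1$rule_id == "R1" & f1$status == "violation"))

  # son not matching father's Y -> R2 violation
  prof_bad_y <- prof_ok; prof_bad_y$y_lineage[1] <- "I2"
  f2 <- check_consistency(ped, prof_bad_y, kin)
  expect_true(any(f2$rule_id == "R2" & f2$status == "violation"))

  # proposed parent-offspring pair observed unrelated -> R3 violation
  kin_bad <- kin; kin_bad$r[1] <- 0.01; kin_bad$degree[1] <- "unrelated"
  f3 <- check_consistency(ped, prof_ok, kin_bad)
  expect_true(any(f3$rule_id == "R3" & f3$status == "violation"))

  # male sex call on the proposed mother -> R4 violation
  prof_bad_sex <- prof_ok; prof_bad_sex$sex_call[2] <- "M"
  f4v <- check_consistency(ped, prof_bad_sex, kin)
  expect_true(any(f4v$rule_id == "R4" & f4v$status == "violation"))
})

test_that("data simulated from a pedigree passes its own consistency check", {
  trios <- data.frame(
    child  = c("F", "BRO", "D1", "D2", "NEPHEW"),
    mother = c("GM", "GM", "W1", "W1", "W2"),
    father = c("GF", "GF", "F", "F", "BRO"),
    stringsAsFactors = FALSE)
  sampled <- c("F", "D1", "D2", "NEPHEW", sprintf("U%d", 1:5))
  sexes <- c(F = "M", D1 = "F", D2 = "F", NEPHEW = "M",
             GM = "F", GF = "M", W1 = "F", W2 = "F", BRO = "M",
             setNames(rep("U", 5), sprintf("U%d", 1:5)))
  violations <- 0
  nrep <- 100
  for (i in seq_len(nrep)) {
    cfg <- cohort_config(seed = 400 + i, n_snps = 200000,
                         pedigrees = list(trios), sampled_ids = sampled,
                         sexes = sexes)
    sim <- simulate_cohort(cfg)
    ph <- pseudo_haploidize(sim$matrix, seed = 4000 + i)
    kin <- kinship_table(ph)
    f <- check_consistency(pedigree(trios), sim$truth$profiles, kin)
    if (any(f$status == "violation")) violations <- violations + 1
  }
  expect_lte(violations, 5)  # >= 95% of replicates fully consistent
})

test_that("lineage diversity counts distinct labels with females excluded from Y", {
  prof <- data.frame(
    individual_id = sprintf("P%02d", 1:38),
    mt_lineage = c(sprintf("mt%02d", 1:30), sprintf("mt%02d", 1:8)),
    y_lineage = NA_character_, sex_call = "F", stringsAsFactors = FALSE)
  expect_equal(lineage_diversity(prof)$n_mt_lineages, 30)

  males <- data.frame(individual_id = c("a", "b", "c", "d"),
                      mt_lineage = "m", y_lineage = c("G2", "I2", "C-V20", "G2"),
                      sex_call = "M", stringsAsFactors = FALSE)
  expect_equal(lineage_diversity(males)$n_y_lineages, 3)
  # a female carrying a stray label must not add to the Y count
  mixed <- rbind(males, data.frame(individual_id = "e", mt_lineage = "m",
                                   y_lineage = "R1b", sex_call = "F"))
  expect_equal(lineage_diversity(mixed)$n_y_lineages, 3)
  one <- data.frame(individual_id = "x", mt_lineage = "only",
                    y_lineage = NA, sex_call = "F")
  expect_equal(lineage_diversity(one)$n_mt_lineages, 1)
})

test_that("unrelated fraction counts individuals without close kin", {
  tab <- data.frame(id_a = c("a", "c"), id_b = c("b", "d"),
                    overlap_snps = 1L, mismatches = 0L, x = 0,
                    r = c(0.5, 0.01), se_r = 0.01,
                    degree = c("first", "unrelated"), stringsAsFactors = FALSE)
  expect_equal(unrelated_fraction(tab, cohort = c("a", "b", "c", "d")), 0.5)
  expect_equal(unrelated_fraction(tab, cohort = letters[1:10]), 0.8)
  tab$degree <- "unrelated"
  expect_equal(unrelated_fraction(tab, cohort = c("a", "b")), 1.0)
  tab$degree <- "first"
  expect_equal(unrelated_fraction(tab, cohort = c("a", "b", "c", "d")), 0.0)
})
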