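# Independent oracles and small fixture builders, kept deliberately separate
# from the implementation paths they check.

# Brute-force gene-dropping estimate of the kinship coefficient: unique
# founder alleles are dropped through the pedigree trios nrep times; phi is
# the probability that one random allele from each individual is identical by
# descent.
gene_drop_phi <- function(trios, id_a, id_b, nrep = 1e5) {
  norm <- function(v) { v <- as.character(v); v[v %in% c("0", "")] <- NA; v }
  child <- as.character(trios$child)
  mother <- norm(trios$mother); father <- norm(trios$father)
  members <- unique(c(child, mother[!is.na(mother)], father[!is.na(father)]))
  alleles <- list()
  next_allele <- 1L
  # founders first
  founders <- setdiff(members, child)
  for (f in founders) {
    alleles[[f]] <- cbind(rep(next_allele, nrep), rep(next_allele + 1L, nrep))
    next_allele <- next_allele + 2L
  }
  remaining <- child
  while (length(remaining)) {
    progressed <- FALSE
    for (cc in remaining) {
      i <- match(cc, child)
      mo <- mother[i]; fa <- father[i]
      mo_ok <- is.na(mo) || !is.null(alleles[[mo]])
      fa_ok <- is.na(fa) || !is.null(alleles[[fa]])
      if (!mo_ok || !fa_ok) next
      gam <- function(parent) {
        if (is.na(parent)) {
          out <- cbind(rep(next_allele, nrep), rep(next_allele + 1L, nrep))
          next_allele <<- next_allele + 2L
          out[cbind(seq_len(nrep), sample(1:2, nrep, TRUE))]
        } else {
          h <- alleles[[parent]]
          h[cbind(seq_len(nrep), sample(1:2, nrep, TRUE))]
        }
      }
      alleles[[cc]] <- cbind(gam(mo), gam(fa))
      remaining <- setdiff(remaining, cc)
      progressed <- TRUE
    }
    if (!progressed) stop("cyclic trios in gene_drop_phi")
  }
  pick <- function(h) h[cbind(seq_len(nrep), sample(1:2, nrep, TRUE))]
  mean(pick(alleles[[id_a]]) == pick(alleles[[id_b]]))
}

# Brute-force f4: explicit per-SNP loop, complete cases only.
brute_f4 <- function(freq, A, B, C, D) {
  vals <- c()
  for (i in seq_len(nrow(freq))) {
    p <- freq[i, c(A, B, C, D)]
    if (any(is.na(p))) next
    vals <- c(vals, (p[1] - p[2]) * (p[3] - p[4]))
  }
  mean(vals)
}

# Tiny genotype matrix with explicit calls (snps x individuals).
toy_matrix <- function(calls, ploidy = "pseudo_haploid",
                       chromosomes = NULL, genetic_pos = NULL) {
  n_snp <- nrow(calls); n_ind <- ncol(calls)
  if (is.null(chromosomes)) chromosomes <- rep("1", n_snp)
  if (is.null(genetic_pos)) genetic_pos <- seq(0, 1, length.out = n_snp)
  ind <- data.frame(individual_id = sprintf("I%02d", seq_len(n_ind)),
                    declared_sex = "U", group_label = "TOY",
                    stringsAsFactors = FALSE)
  snp <- data.frame(snp_id = sprintf("rs%d", seq_len(n_snp)),
                    chromosome = chromosomes, genetic_pos = genetic_pos,
                    physical_pos = seq_len(n_snp) * 1000L,
                    ref_allele = "A", alt_allele = "G",
                    stringsAsFactors = FALSE)
  genotype_matrix(ind, snp, calls, ploidy = ploidy)
}

# Random diploid matrix for round-trip / property tests.
random_matrix <- function(n_snp, n_ind, seed, missing_rate = 0.1,
                          ploidy = "diploid") {
  set.seed(seed)
  vals <- if (ploidy == "diploid") 0:2 else 0:1
  calls <- matrix(sample(vals, n_snp * n_ind, TRUE), n_snp, n_ind)
  calls[runif(n_snp * n_ind) < missing_rate] <- NA_integer_
  toy_matrix(calls, ploidy = ploidy,
             chromosomes = sort(rep_len(c("1", "2"), n_snp)))
}

# Frequency table over a synthetic panel with populations given as columns.
toy_freq_table <- function(freq, block_spread = TRUE) {
  n <- nrow(freq)
  snp <- data.frame(snp_id = sprintf("rs%d", seq_len(n)),
                    chromosome = as.character(rep_len(1:4, n)),
                    genetic_pos = rep_len(seq(0, 1.5, by = 0.011), n),
                    physical_pos = seq_len(n) * 1000L,
                    ref_allele = "A", alt_allele = "G",
                    stringsAsFactors = FALSE)
  freq_table(freq, snp)
}
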