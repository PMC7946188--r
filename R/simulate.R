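# Synthetic-data generators with known ground truth for every pipeline stage:
# pedigreed diploid genotypes (unlinked or linked transmission), QC read-count
# profiles, coalescent ROH segment lengths under constant Ne, and drifted
# allele-frequency tables with a planted admixture proportion.
#
# Every generator is a pure function of its arguments and seed.

#' Generate a SNP panel over a genetic map
#'
#' SNP counts per chromosome proportional to genetic length, positions uniform
#' and sorted within chromosomes; physical positions on a 1 cM ~ 1 Mb scale.
#'
#' @param n_snps Total number of SNPs.
#' @param genome_map data.frame as [default_genome_map()].
#' @param seed RNG seed (`NULL`: current stream).
#' @return A SNP data.frame as used by [genotype_matrix()].
#' @export
sim_snp_panel <- function(n_snps, genome_map = default_genome_map(), seed = NULL) {
  map <- validate_genome_map(genome_map)
  with_seed(seed, {
    share <- map$length_morgans / sum(map$length_morgans)
    counts <- diff(round(cumsum(c(0, share * n_snps))))
    counts[length(counts)] <- n_snps - sum(counts[-length(counts)])
    chrom <- rep(map$chromosome, counts)
    pos <- unlist(lapply(seq_len(nrow(map)), function(i)
      sort(stats::runif(counts[i], 0, map$length_morgans[i]))), use.names = FALSE)
    data.frame(
      snp_id = sprintf("rs%07d", seq_len(n_snps)),
      chromosome = chrom,
      genetic_pos = pos,
      physical_pos = as.integer(round(pos * 1e8)) + 1L,
      ref_allele = "A", alt_allele = "G",
      stringsAsFactors = FALSE
    )
  })
}

gamete_unlinked <- function(h1, h2) {
  pick <- stats::runif(length(h1)) < 0.5
  out <- h1
  out[pick] <- h2[pick]
  out
}

# Recombinant gamete with crossovers as a Poisson process on the genetic map.
gamete_linked <- function(h1, h2, snp) {
  out <- h1
  for (ch in unique(snp$chromosome)) {
    rows <- which(snp$chromosome == ch)
    pos <- snp$genetic_pos[rows]
    G <- max(pos)
    nx <- stats::rpois(1, G)
    xp <- sort(stats::runif(nx, 0, G))
    phase <- (findInterval(pos, xp) + stats::rbinom(1, 1, 0.5)) %% 2
    swap <- rows[phase == 1]
    out[swap] <- h2[swap]
  }
  out
}

#' Cohort simulation configuration
#'
#' @param seed RNG seed (mandatory: the whole cohort is reproducible from it).
#' @param n_snps Panel size.
#' @param pedigrees List of trio data.frames (`child`, `mother`, `father`);
#'   members never appearing as children are founders and may be unsampled.
#' @param sampled_ids Ids to include in the output genotype matrix (pedigree
#'   members and/or singletons; singleton ids absent from every trio are
#'   simulated as unrelated founders).
#' @param sexes Named character vector ("M"/"F") of true sexes for sampled
#'   ids; defaults to "U".
#' @param founder_freq Range of the uniform founder allele-frequency law.
#' @param call_rate Per-individual probability that a SNP is called; scalar or
#'   named vector over sampled ids.
#' @param linked If TRUE, children receive recombinant gametes (needed for
#'   ROH realism); if FALSE, transmission is independent per SNP (sufficient
#'   and much faster for kinship expectations).
#' @param genome_map Genetic map for the panel.
#' @param founder_mt,founder_y Optional named lineage-label overrides for
#'   founders (defaults: unique mt label per founder; unique Y label per male
#'   founder patriline seed).
#' @param group_label Cohort label written to the individual table.
#' @return A validated config list.
#' @export
cohort_config <- function(seed, n_snps, pedigrees = list(), sampled_ids,
                          sexes = NULL, founder_freq = c(0.05, 0.95),
                          call_rate = 1, linked = FALSE,
                          genome_map = default_genome_map(),
                          founder_mt = NULL, founder_y = NULL,
                          group_label = "COHORT") {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  stopifnot(n_snps >= 1, length(sampled_ids) >= 1,
            all(founder_freq >= 0 & founder_freq <= 1),
            all(call_rate >= 0 & call_rate <= 1))
  for (tr in pedigrees)
    if (!all(c("child", "mother", "father") %in% names(tr)))
      stop("each pedigree needs child/mother/father columns")
  list(seed = seed, n_snps = n_snps, pedigrees = pedigrees,
       sampled_ids = as.character(sampled_ids), sexes = sexes,
       founder_freq = founder_freq, call_rate = call_rate, linked = linked,
       genome_map = genome_map, founder_mt = founder_mt,
       founder_y = founder_y, group_label = group_label)
}

combined_pedigree <- function(config) {
  trios <- if (length(config$pedigrees)) do.call(rbind, config$pedigrees) else
    data.frame(child = character(), mother = character(), father = character(),
               stringsAsFactors = FALSE)
  singles <- setdiff(config$sampled_ids, unlist(lapply(
    config$pedigrees, function(tr) unique(c(as.character(tr$child),
                                            as.character(tr$mother),
                                            as.character(tr$father))))))
  list(ped = if (nrow(trios)) pedigree(trios) else NULL, singles = singles)
}

#' Simulate a pedigreed diploid cohort with known truth
#'
#' Founders are drawn from a shared allele-frequency spectrum; children arise
#' by Mendelian transmission (unlinked per SNP, or linked via recombinant
#' gametes). The truth record carries every pairwise kinship coefficient, the
#' planted close-kin set (third degree or closer), and uniparental lineage
#' profiles propagated through the pedigree (mtDNA maternally, Y paternally).
#'
#' @param config From [cohort_config()] or [mass_burial_preset()].
#' @return List with `matrix` (diploid [genotype_matrix()] over
#'   `sampled_ids`) and `truth` (list: `phi` matrix, `close_ids`, `profiles`,
#'   `freqs`, `config`).
#' @export
simulate_cohort <- function(config) {
  cp <- combined_pedigree(config)
  ped <- cp$ped
  members <- unique(c(if (!is.null(ped)) ped$members else character(), cp$singles))
  if (!all(config$sampled_ids %in% members))
    stop("sampled ids missing from pedigree/singleton set")
  gen <- with_seed(config$seed, {
    snp <- sim_snp_panel(config$n_snps, config$genome_map, seed = NULL)
    freqs <- stats::runif(config$n_snps, config$founder_freq[1], config$founder_freq[2])
    haps <- new.env(parent = emptyenv())
    draw_founder <- function() list(
      h1 = as.integer(stats::runif(config$n_snps) < freqs),
      h2 = as.integer(stats::runif(config$n_snps) < freqs))
    make_gamete <- function(parent_id) {
      if (is.null(parent_id) || is.na(parent_id)) {
        # unsampled, unspecified parent: fresh founder gamete
        as.integer(stats::runif(config$n_snps) < freqs)
      } else {
        h <- haps[[parent_id]]
        if (config$linked) gamete_linked(h$h1, h$h2, snp)
        else gamete_unlinked(h$h1, h$h2)
      }
    }
    if (!is.null(ped)) {
      for (i in ped$topo) {
        id <- ped$members[i]
        mo <- ped$mother[i]; fa <- ped$father[i]
        if (is.na(mo) && is.na(fa)) {
          haps[[id]] <- draw_founder()
        } else {
          haps[[id]] <- list(
            h1 = make_gamete(if (is.na(mo)) NA else ped$members[mo]),
            h2 = make_gamete(if (is.na(fa)) NA else ped$members[fa]))
        }
      }
    }
    for (id in cp$singles) haps[[id]] <- draw_founder()
    calls <- matrix(NA_integer_, config$n_snps, length(config$sampled_ids))
    rate <- if (length(config$call_rate) == 1)
      stats::setNames(rep(config$call_rate, length(config$sampled_ids)),
                      config$sampled_ids) else config$call_rate
    for (j in seq_along(config$sampled_ids)) {
      id <- config$sampled_ids[j]
      g <- haps[[id]]$h1 + haps[[id]]$h2
      if (rate[id] < 1) g[stats::runif(config$n_snps) >= rate[id]] <- NA_integer_
      calls[, j] <- g
    }
    list(snp = snp, freqs = freqs, calls = calls)
  })
  snp <- gen$snp; freqs <- gen$freqs; calls <- gen$calls
  sexes <- config$sexes
  if (is.null(sexes))
    sexes <- stats::setNames(rep("U", length(config$sampled_ids)), config$sampled_ids)
  ind <- data.frame(individual_id = config$sampled_ids,
                    declared_sex = unname(sexes[config$sampled_ids]),
                    group_label = config$group_label,
                    stringsAsFactors = FALSE)
  mat <- genotype_matrix(ind, snp, calls, ploidy = "diploid")
  truth <- list(
    phi = truth_phi(ped, config$sampled_ids),
    profiles = truth_profiles(ped, cp$singles, config),
    freqs = freqs, config = config
  )
  close <- truth$phi >= 1 / 16 & !diag(TRUE, nrow(truth$phi))
  truth$close_ids <- sort(rownames(truth$phi)[rowSums(close) > 0])
  list(matrix = mat, truth = truth)
}

# Pairwise kinship coefficients among sampled ids (0 for pairs not linked
# through the pedigree).
truth_phi <- function(ped, sampled_ids) {
  n <- length(sampled_ids)
  phi <- matrix(0, n, n, dimnames = list(sampled_ids, sampled_ids))
  diag(phi) <- 0.5
  if (is.null(ped)) return(phi)
  inped <- sampled_ids[sampled_ids %in% ped$members]
  if (length(inped) >= 2) {
    combs <- utils::combn(inped, 2)
    for (k in seq_len(ncol(combs))) {
      p <- expected_kinship(ped, combs[1, k], combs[2, k])$phi
      phi[combs[1, k], combs[2, k]] <- p
      phi[combs[2, k], combs[1, k]] <- p
    }
  }
  phi
}

# Propagate uniparental lineage labels: founders get unique labels unless
# overridden; children take the mother's mt lineage, and sons the father's Y.
truth_profiles <- function(ped, singles, config) {
  members <- unique(c(if (!is.null(ped)) ped$members else character(), singles))
  sexes <- config$sexes
  sex_of <- function(id) {
    if (!is.null(sexes) && id %in% names(sexes)) sexes[[id]] else "U"
  }
  mt <- stats::setNames(sprintf("mt%03d", seq_along(members)), members)
  yl <- stats::setNames(sprintf("Y%03d", seq_along(members)), members)
  if (!is.null(config$founder_mt))
    mt[names(config$founder_mt)] <- config$founder_mt
  if (!is.null(config$founder_y))
    yl[names(config$founder_y)] <- config$founder_y
  if (!is.null(ped)) {
    for (i in ped$topo) {
      id <- ped$members[i]
      if (!is.na(ped$mother[i])) mt[id] <- mt[ped$members[ped$mother[i]]]
      if (!is.na(ped$father[i])) yl[id] <- yl[ped$members[ped$father[i]]]
    }
  }
  out <- data.frame(
    individual_id = config$sampled_ids,
    mt_lineage = unname(mt[config$sampled_ids]),
    y_lineage = unname(yl[config$sampled_ids]),
    sex_call = vapply(config$sampled_ids, sex_of, character(1)),
    stringsAsFactors = FALSE
  )
  out$y_lineage[out$sex_call != "M"] <- NA_character_
  out
}

#' Preset: a 38-individual cohort with four planted pedigrees
#'
#' Emulates the structure of the study cohort: 38 sampled individuals of whom
#' exactly 11 have a close relative (third degree or closer) among the
#' sampled, in four pedigrees:
#' (i) a father, his two daughters and his brother's son (uncle-nephew and
#' first-cousin links), (ii) two sisters and their first cousin through the
#' maternal line, (iii) a father and son, (iv) two paternal half-siblings.
#' The remaining 27 are singletons. Sexes are fixed at 20 F / 18 M, and
#' founder lineage labels are chosen so the sampled cohort carries 30 distinct
#' mtDNA lineages and 6 distinct Y lineages.
#'
#' @param seed Mandatory RNG seed.
#' @param n_snps Panel size (default 200,000; the full capture panel thinned
#'   for speed, see the methods vignette).
#' @param call_rate Call probability of well-covered individuals (default
#'   0.95).
#' @param low_call_rate Call probability of the low-coverage singletons
#'   (default 0.25: below the kinship-baseline coverage floor and the scaled
#'   ROH eligibility floor, emulating the 11 of 38 individuals excluded from
#'   the ROH screen).
#' @param linked Transmission mode, see [cohort_config()].
#' @return A config for [simulate_cohort()].
#' @export
mass_burial_preset <- function(seed, n_snps = 200000, call_rate = 0.95,
                            low_call_rate = 0.25, linked = FALSE) {
  ped1 <- data.frame( # father PED1_F, daughters, brother's son
    child  = c("PED1_F", "PED1_BRO", "PED1_D1", "PED1_D2", "PED1_NEPHEW"),
    mother = c("U_GM1", "U_GM1", "U_W1", "U_W1", "U_W2"),
    father = c("U_GF1", "U_GF1", "PED1_F", "PED1_F", "PED1_BRO"),
    stringsAsFactors = FALSE)
  ped2 <- data.frame( # sisters + maternal first cousin
    child  = c("PED2_MOM", "PED2_AUNT", "PED2_S1", "PED2_S2", "PED2_COUSIN"),
    mother = c("U_GM2", "U_GM2", "PED2_MOM", "PED2_MOM", "PED2_AUNT"),
    father = c("U_GF2", "U_GF2", "U_F2", "U_F2", "U_H2"),
    stringsAsFactors = FALSE)
  ped3 <- data.frame( # father and son
    child = "PED3_SON", mother = "U_M3", father = "PED3_F",
    stringsAsFactors = FALSE)
  ped4 <- data.frame( # paternal half-siblings
    child = c("PED4_BOY", "PED4_HSIS"),
    mother = c("U_M4A", "U_M4B"),
    father = c("U_F4", "U_F4"),
    stringsAsFactors = FALSE)
  related <- c("PED1_F", "PED1_D1", "PED1_D2", "PED1_NEPHEW",
               "PED2_S1", "PED2_S2", "PED2_COUSIN",
               "PED3_F", "PED3_SON", "PED4_BOY", "PED4_HSIS")
  singles <- sprintf("SGL%02d", 1:27)
  sampled <- c(related, singles)
  sexes <- c(PED1_F = "M", PED1_D1 = "F", PED1_D2 = "F", PED1_NEPHEW = "M",
             PED2_S1 = "F", PED2_S2 = "F", PED2_COUSIN = "M",
             PED3_F = "M", PED3_SON = "M", PED4_BOY = "M", PED4_HSIS = "F")
  # 6 M / 5 F among related; singles bring the tally to 18 M / 20 F
  single_sex <- rep(c("M", "F"), c(12, 15))
  sexes <- c(sexes, stats::setNames(single_sex, singles))
  # unsampled founder sexes (drive uniparental propagation only)
  sexes <- c(sexes, U_GF1 = "M", U_GM1 = "F", U_W1 = "F", U_W2 = "F",
             PED1_BRO = "M", U_GF2 = "M", U_GM2 = "F", U_F2 = "M",
             U_H2 = "M", PED2_MOM = "F", PED2_AUNT = "F", U_M3 = "F",
             U_M4A = "F", U_M4B = "F", U_F4 = "M")
  # mtDNA label sharing: 5 singleton pairs share a maternal lineage (distant
  # maternal kin without close kinship), so the cohort shows 30 distinct
  # lineages: 22 among the 27 singletons + 8 among the pedigree members.
  founder_mt <- stats::setNames(sprintf("mtS%02d", c(1:22, 1:5)), singles)
  # Y lineages: 6 distinct among the 18 males; patrilines within pedigrees
  # share labels by transmission.
  male_singles <- singles[single_sex == "M"]
  founder_y <- c(
    U_GF1 = "G2", PED3_F = "I2", U_F4 = "C-V20", U_H2 = "Y-A",
    stats::setNames(rep(c("Y-A", "Y-B", "Y-C", "G2"), length.out = length(male_singles)),
                    male_singles))
  rates <- stats::setNames(rep(call_rate, length(sampled)), sampled)
  rates[sprintf("SGL%02d", 17:27)] <- low_call_rate
  cohort_config(seed = seed, n_snps = n_snps,
                pedigrees = list(ped1, ped2, ped3, ped4),
                sampled_ids = sampled, sexes = sexes,
                call_rate = rates, linked = linked,
                founder_mt = founder_mt, founder_y = founder_y,
                group_label = "MASSGRAVE")
}

#' Simulate per-individual QC read-count summaries
#'
#' Terminal damage counts are binomial at `damage_rate`; mtDNA consensus
#' mismatches combine a base error rate with contamination (each
#' contaminant-derived read counted as a mismatch with probability 1/2);
#' X polymorphism at 2x-covered sites likewise; Y-read fractions are binomial
#' around 0.45 for males and 0.01 for females.
#'
#' @param sexes Named character vector of true sexes ("M"/"F").
#' @param seed RNG seed.
#' @param damage_rate True terminal C-to-T damage rate (default 0.05).
#' @param contamination True contamination fraction (default 0).
#' @param depth List of per-criterion totals: `terminal`, `mt`, `x_sites`,
#'   `xy` (defaults 1000 each).
#' @param base_error Baseline mismatch/polymorphism rate absent contamination.
#' @return data.frame of read-count summaries for [run_qc()].
#' @export
simulate_read_counts <- function(sexes, seed, damage_rate = 0.05,
                                 contamination = 0,
                                 depth = list(terminal = 1000, mt = 1000,
                                              x_sites = 1000, xy = 1000),
                                 base_error = 0.002) {
  n <- length(sexes)
  stopifnot(!is.null(names(sexes)), n > 0)
  with_seed(seed, {
    mism_p <- pmin(1, base_error + 0.5 * contamination)
    y_p <- ifelse(sexes == "M", 0.45, 0.01)
    data.frame(
      individual_id = names(sexes),
      terminal_ct_damaged = stats::rbinom(n, depth$terminal, damage_rate),
      terminal_ct_total = depth$terminal,
      mt_match = depth$mt - stats::rbinom(n, depth$mt, mism_p),
      mt_total = depth$mt,
      x_poly_sites = stats::rbinom(n, depth$x_sites, mism_p),
      x_sites_ge2x = depth$x_sites,
      y_reads = stats::rbinom(n, depth$xy, y_p),
      xy_reads = depth$xy,
      stringsAsFactors = FALSE
    )
  })
}

# Sample from the segment-level coalescence-time law P(t) * 2t / (4N): the
# size-biased geometric, realized exactly as Geo(p) + Geo(p) - 1 with
# p = 1/(2N) and Geo on {1, 2, ...}.
rtime_sizebiased <- function(n, N) {
  p <- 1 / (2 * N)
  1L + stats::rgeom(n, p) + stats::rgeom(n, p)
}

#' Monte-Carlo ROH segment lengths under constant population size
#'
#' Draws, per genome, the homozygosity-by-descent segments implied by a
#' constant-size panmictic coalescent on the genetic map: interior segments
#' arise as a Poisson process along each chromosome whose per-segment
#' coalescence time follows the size-biased geometric law and whose lengths
#' are exponential with rate 2t per Morgan; chromosome-edge segments carry the
#' plain geometric time law with an exponential residual length. Segments
#' shorter than `floor_cm` are not emitted.
#'
#' @param true_ne Diploid effective population size (>= 2).
#' @param genome_map data.frame as [default_genome_map()].
#' @param n_individuals Number of genomes.
#' @param seed RNG seed.
#' @param floor_cm Reporting floor in centimorgans (default 1).
#' @return data.frame of segments: `individual_id`, `chromosome`,
#'   `start_cM`, `end_cM`.
#' @export
simulate_roh_lengths <- function(true_ne, genome_map = default_genome_map(),
                                 n_individuals, seed, floor_cm = 1) {
  stopifnot(true_ne >= 2, n_individuals >= 1, floor_cm > 0)
  map <- validate_genome_map(genome_map)
  floor_m <- floor_cm / 100
  # times beyond t_cap cannot reach the floor except with negligible probability
  t_cap <- ceiling(-log(1e-8) / (2 * floor_m))
  tt <- seq_len(t_cap)
  p_geo <- (1 / (2 * true_ne)) * (1 - 1 / (2 * true_ne))^(tt - 1)
  w_seg <- p_geo * 2 * tt              # segment-start intensity per Morgan by t
  rate_total <- sum(w_seg)
  segs <- with_seed(seed, {
    out <- list()
    for (ind in seq_len(n_individuals)) {
      id <- sprintf("SIM%03d", ind)
      for (i in seq_len(nrow(map))) {
        G <- map$length_morgans[i]
        # segment starts along the chromosome; runs past the end are observed
        # truncated, which realizes the right-edge term of the analytic density
        n_start <- stats::rpois(1, rate_total * G)
        if (n_start > 0) {
          st <- stats::runif(n_start, 0, G)
          ts <- sample.int(t_cap, n_start, replace = TRUE, prob = w_seg)
          len <- stats::rexp(n_start, 2 * ts)
          en <- pmin(st + len, G)
        } else st <- en <- numeric(0)
        # left edge: the stationary segment covering position 0 (plain
        # geometric time law, exponential residual length by memorylessness)
        te <- 1L + stats::rgeom(1, 1 / (2 * true_ne))
        st <- c(st, 0); en <- c(en, min(stats::rexp(1, 2 * te), G))
        keep <- (en - st) >= floor_m
        if (any(keep))
          out[[length(out) + 1L]] <- data.frame(
            individual_id = id, chromosome = map$chromosome[i],
            start_cM = st[keep] * 100, end_cM = en[keep] * 100,
            stringsAsFactors = FALSE)
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  })
  if (is.null(segs))
    segs <- data.frame(individual_id = character(), chromosome = character(),
                       start_cM = numeric(), end_cM = numeric(),
                       stringsAsFactors = FALSE)
  rownames(segs) <- NULL
  segs
}

# Balding-Nichols drift of allele frequencies: Beta(p (1-F)/F, (1-p)(1-F)/F).
bn_drift <- function(p, F) {
  if (F <= 0) return(p)
  a <- p * (1 - F) / F
  b <- (1 - p) * (1 - F) / F
  stats::rbeta(length(p), a, b)
}

#' Simulate an admixed allele-frequency table with planted truth
#'
#' A two-branch population tree: an ancestral spectrum splits into two
#' lineages; each source drifts from its own lineage, and the target drifts
#' from the mixture `alpha * p_S1 + (1 - alpha) * p_S2` of the drifted source
#' frequencies. Outgroups drift from the root or from either lineage (so the
#' f4 system is informative about `alpha`): with 8 outgroups, outgroups 2-3
#' branch from the first lineage and 4-5 from the second.
#'
#' @param alpha Planted mixture proportion of source 1, in `[0, 1]`.
#' @param n_snps Panel size (default 100,000).
#' @param seed RNG seed.
#' @param F_split,F_source,F_target,F_outgroup Balding-Nichols drift
#'   parameters for the lineage split, sources, target, and outgroups.
#' @param n_outgroups Number of outgroups (default 8).
#' @param genome_map Genetic map used to place SNPs (for jackknife blocks).
#' @return List (`freq_table`): `pops`, `snp`, `freq` (snps x pops matrix)
#'   and `truth` (`alpha`, population roles).
#' @export
simulate_admixed_freqs <- function(alpha, n_snps = 100000, seed,
                                   F_split = 0.02, F_source = 0.005,
                                   F_target = 0.005, F_outgroup = 0.01,
                                   n_outgroups = 8,
                                   genome_map = default_genome_map()) {
  stopifnot(alpha >= 0, alpha <= 1, n_outgroups >= 3)
  with_seed(seed, {
    snp <- sim_snp_panel(n_snps, genome_map, seed = NULL)
    p0 <- stats::runif(n_snps, 0.05, 0.95)
    lin1 <- bn_drift(p0, F_split)
    lin2 <- bn_drift(p0, F_split)
    s1 <- bn_drift(lin1, F_source)
    s2 <- bn_drift(lin2, F_source)
    target <- bn_drift(alpha * s1 + (1 - alpha) * s2, F_target)
    onames <- sprintf("OUT%d", seq_len(n_outgroups))
    ogs <- lapply(seq_len(n_outgroups), function(j) {
      anc <- if (j %in% c(2, 3)) lin1 else if (j %in% c(4, 5)) lin2 else p0
      bn_drift(anc, F_outgroup)
    })
    freq <- cbind(TARGET = target, S1 = s1, S2 = s2,
                  do.call(cbind, stats::setNames(ogs, onames)))
    freq_table(freq, snp, truth = list(alpha = alpha, target = "TARGET",
                                       sources = c("S1", "S2"),
                                       outgroups = onames))
  })
}
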