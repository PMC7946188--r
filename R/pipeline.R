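# End-to-end orchestration: QC -> sex tally -> kinship -> pedigree checks ->
# lineage diversity -> ROH / Ne -> (optional) admixture, from a single config
# with a single seed. Every report number equals the corresponding module
# output on the same inputs; the pipeline adds no computation of its own.

config_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Pipeline run configuration
#'
#' Either a synthetic cohort config (`cohort`) or EIGENSTRAT paths
#' (`geno_path`/`snp_path`/`ind_path`) must be given. Read counts, uniparental
#' profiles and ROH segments may be supplied as data.frames; in synthetic mode
#' they default to simulated inputs derived from the cohort truth.
#'
#' @param seed Mandatory seed; all stage randomness is derived from it.
#' @param cohort A [cohort_config()] (e.g. [mass_burial_preset()]), or NULL.
#' @param geno_path,snp_path,ind_path EIGENSTRAT input (ignored when
#'   `cohort` is given).
#' @param readcounts,profiles,roh_segments Optional data.frame inputs.
#' @param true_ne Effective size used to simulate ROH segments when none are
#'   supplied in synthetic mode (default 40,000).
#' @param damage_rate,contamination Read-count simulation parameters.
#' @param admixture Optional list(`alpha`, `n_snps`) requesting the mixture
#'   stage on a simulated frequency table.
#' @param min_overlap,min_snps_baseline,block_cm,windows Kinship settings
#'   (see [kinship_table()]).
#' @param min_snps_roh ROH eligibility floor; `NULL` scales the canonical
#'   400,000-of-1.24M rule to the panel size.
#' @param ne_bins_cm Ne likelihood bins, see [ne_mle()].
#' @return Validated config list (`run_config`).
#' @export
run_config <- function(seed, cohort = NULL, geno_path = NULL, snp_path = NULL,
                       ind_path = NULL, readcounts = NULL, profiles = NULL,
                       roh_segments = NULL, true_ne = 40000,
                       damage_rate = 0.05, contamination = 0,
                       admixture = NULL, min_overlap = 15000,
                       min_snps_baseline = 100000, block_cm = 5,
                       windows = default_degree_windows(),
                       min_snps_roh = NULL,
                       ne_bins_cm = list(c(4, 8), c(8, 12), c(12, 20))) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (is.null(cohort) && (is.null(geno_path) || is.null(snp_path) || is.null(ind_path)))
    stop("either a cohort config or EIGENSTRAT paths are required")
  cfg <- list(seed = seed, cohort = cohort, geno_path = geno_path,
              snp_path = snp_path, ind_path = ind_path,
              readcounts = readcounts, profiles = profiles,
              roh_segments = roh_segments, true_ne = true_ne,
              damage_rate = damage_rate, contamination = contamination,
              admixture = admixture, min_overlap = min_overlap,
              min_snps_baseline = min_snps_baseline, block_cm = block_cm,
              windows = windows, min_snps_roh = min_snps_roh,
              ne_bins_cm = ne_bins_cm)
  class(cfg) <- "run_config"
  cfg
}

stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full cohort analysis pipeline
#'
#' @param cfg A [run_config()].
#' @return List (`cohort_report`): `qc`, `sex_tally`, `kinship`,
#'   `n_close_kin`, `unrelated_fraction`, `pedigree_findings`,
#'   `lineage_diversity`, `roh_summary`, `inbreeding_flags`, `ne`,
#'   `mixture` (or NULL), `truth` (synthetic mode), `provenance`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  truth <- NULL
  if (!is.null(cfg$cohort)) {
    stage_msg("genotypes", "simulating cohort (%d ids, %d SNPs)",
              length(cfg$cohort$sampled_ids), cfg$cohort$n_snps)
    sim <- simulate_cohort(cfg$cohort)
    mat <- sim$matrix
    truth <- sim$truth
  } else {
    stage_msg("genotypes", "reading EIGENSTRAT from %s", cfg$geno_path)
    mat <- read_eigenstrat(cfg$geno_path, cfg$snp_path, cfg$ind_path)
  }
  n_snps <- nrow(mat$snp)

  ph <- if (mat$ploidy == "diploid") pseudo_haploidize(mat, seed = cfg$seed + 1L) else mat
  coverage <- snp_coverage(ph)

  readcounts <- cfg$readcounts
  if (is.null(readcounts)) {
    if (is.null(truth)) stop("readcounts input required in file mode")
    sexes <- stats::setNames(truth$profiles$sex_call, truth$profiles$individual_id)
    readcounts <- simulate_read_counts(sexes, seed = cfg$seed + 2L,
                                       damage_rate = cfg$damage_rate,
                                       contamination = cfg$contamination)
  }
  qc <- run_qc(readcounts)
  stage_msg("qc", "%d individuals, %d pass all evaluable criteria",
            nrow(qc), sum(qc$overall))

  kin <- kinship_table(ph, min_overlap = cfg$min_overlap,
                       min_snps_baseline = cfg$min_snps_baseline,
                       block_cm = cfg$block_cm, windows = cfg$windows)
  stage_msg("kinship", "baseline %.4f over %d pairs; %d close-kin individuals",
            kin$baseline$base, nrow(kin$table), kin$n_close_kin)
  unrel <- unrelated_fraction(kin, cohort = mat$ind$individual_id)

  profiles <- cfg$profiles
  if (is.null(profiles) && !is.null(truth)) {
    profiles <- truth$profiles
    profiles$sex_call <- qc$sex_call[match(profiles$individual_id, qc$individual_id)]
  }
  findings <- NULL
  peds <- if (!is.null(cfg$cohort)) cfg$cohort$pedigrees else NULL
  if (!is.null(peds) && length(peds) && !is.null(profiles)) {
    findings <- do.call(rbind, lapply(seq_along(peds), function(i) {
      f <- check_consistency(pedigree(peds[[i]]), profiles, kin, cfg$windows)
      if (nrow(f)) f$pedigree <- i
      f
    }))
    stage_msg("pedigree", "%d findings, %d violations",
              nrow(findings), sum(findings$status == "violation"))
  }
  lin <- if (!is.null(profiles)) lineage_diversity(profiles) else NULL

  min_roh <- cfg$min_snps_roh
  if (is.null(min_roh)) min_roh <- ceiling(n_snps * 400000 / 1240000)
  segs <- cfg$roh_segments
  if (is.null(segs)) {
    eligible_ids <- names(coverage)[coverage >= min_roh]
    segs <- simulate_roh_lengths(cfg$true_ne, n_individuals = length(eligible_ids),
                                 seed = cfg$seed + 3L, floor_cm = 1)
    if (nrow(segs))
      segs$individual_id <- eligible_ids[match(segs$individual_id,
                                               sprintf("SIM%03d", seq_along(eligible_ids)))]
  }
  roh <- summarize_roh(segs, coverage, min_snps = min_roh)
  flags <- flag_inbreeding(roh)
  ne <- ne_mle(roh, bins_cm = cfg$ne_bins_cm)
  stage_msg("roh", "%d eligible individuals; Ne %.0f (%.0f-%.0f)",
            sum(roh$eligible), ne$ne_hat, ne$ci_low, ne$ci_high)

  mixture <- NULL
  if (!is.null(cfg$admixture)) {
    adm <- cfg$admixture
    ft <- simulate_admixed_freqs(adm$alpha,
                                 n_snps = if (is.null(adm$n_snps)) 100000 else adm$n_snps,
                                 seed = cfg$seed + 4L)
    mixture <- qpadm_lite(ft, ft$truth$target, ft$truth$sources, ft$truth$outgroups,
                          block_cm = cfg$block_cm)
    stage_msg("admixture", "weights %s",
              paste(sprintf("%.3f", mixture$weights), collapse = "/"))
  }

  structure(list(
    qc = qc, sex_tally = sex_tally(qc), kinship = kin,
    n_close_kin = kin$n_close_kin, close_ids = kin$close_ids,
    unrelated_fraction = unrel, pedigree_findings = findings,
    lineage_diversity = lin, roh_summary = roh, inbreeding_flags = flags,
    ne = ne, mixture = mixture, truth = truth,
    provenance = list(
      config_hash = config_hash(paste(deparse(unclass(cfg)), collapse = "")),
      seed = cfg$seed,
      package_version = as.character(utils::packageVersion("paleokin")))
  ), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  st <- x$sex_tally
  cat("<cohort_report>\n")
  cat(sprintf("  sex tally: %d F / %d M / %d U\n", st["F"], st["M"], st["U"]))
  cat(sprintf("  close kin: %d individuals (unrelated fraction %.3f)\n",
              x$n_close_kin, x$unrelated_fraction))
  if (!is.null(x$lineage_diversity))
    cat(sprintf("  lineages: %d mtDNA, %d Y\n",
                x$lineage_diversity$n_mt_lineages, x$lineage_diversity$n_y_lineages))
  cat(sprintf("  inbreeding flags: %d of %d eligible\n",
              sum(x$inbreeding_flags[x$roh_summary$eligible]),
              sum(x$roh_summary$eligible)))
  cat(sprintf("  Ne: %.0f (95%% CI %.0f-%.0f)\n", x$ne$ne_hat, x$ne$ci_low, x$ne$ci_high))
  if (!is.null(x$mixture))
    cat(sprintf("  mixture: %s\n",
                paste(sprintf("%s %.3f", x$mixture$sources, x$mixture$weights),
                      collapse = ", ")))
  invisible(x)
}
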