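Package: paleokin
Title: Authenticity Screening, Kinship, Runs of Homozygosity and
    Admixture Modelling for Ancient DNA Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the genetic analysis of low-coverage ancient DNA
    cohorts genotyped on a fixed SNP capture panel. Implements read-count
    based authenticity and contamination screening with genetic sex
    assignment, pairwise kinship estimation from pseudo-haploid mismatch
    rates with a median-calibrated unrelated baseline, pedigree consistency
    checks against uniparental (mtDNA and Y-chromosome) lineages, runs-of-
    homozygosity summaries with a Poisson maximum-likelihood estimator of
    recent effective population size under a constant-size panmictic
    coalescent, and f4-statistic based two-source admixture proportion
    estimation with block-jackknife uncertainties. Includes synthetic-data
    generators with known ground truth (pedigreed genotypes, read counts,
    coalescent ROH segment lengths, drifted allele-frequency tables) so
    every stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
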