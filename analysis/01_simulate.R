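#!/usr/bin/env Rscript
# Stage 1: generate the study cohort with known ground truth and persist every
# pipeline input: EIGENSTRAT genotypes, per-individual read-count summaries,
# and uniparental lineage profiles. Downstream stages read only these files.

library(paleokin)

seed <- 42
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- mass_burial_preset(seed = seed)
sim <- simulate_cohort(cfg)

cat(sprintf("simulated %d individuals x %d SNPs; %d with a close relative planted\n",
            nrow(sim$matrix$ind), nrow(sim$matrix$snp),
            length(sim$truth$close_ids)))

write_eigenstrat(sim$matrix, "results/data/cohort.geno",
                 "results/data/cohort.snp", "results/data/cohort.ind")

sexes <- setNames(sim$truth$profiles$sex_call, sim$truth$profiles$individual_id)
rc <- simulate_read_counts(sexes, seed = seed + 2L, damage_rate = 0.05,
                           contamination = 0)
write.table(rc, "results/data/readcounts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(sim$truth$profiles, "results/data/profiles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(close_id = sim$truth$close_ids),
            "results/data/truth_close_kin.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("wrote EIGENSTRAT + read counts + profiles under results/data/\n")
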