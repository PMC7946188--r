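#!/usr/bin/env Rscript
# Stage 4: check the proposed pedigrees against the kinship estimates, sex
# calls and uniparental lineages, and summarize lineage diversity.

library(paleokin)

seed <- 42
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

profiles <- read.delim("results/data/profiles.tsv", stringsAsFactors = FALSE)
kin_tab <- read.delim("results/tables/kinship_table.tsv", stringsAsFactors = FALSE)
peds <- mass_burial_preset(seed = seed)$pedigrees

findings <- do.call(rbind, lapply(seq_along(peds), function(i) {
  f <- check_consistency(pedigree(peds[[i]]), profiles, kin_tab)
  if (nrow(f)) f$pedigree <- i
  f
}))
cat(sprintf("pedigree consistency: %d checks, %d violations\n",
            nrow(findings), sum(findings$status == "violation")))
if (any(findings$status == "violation"))
  print(findings[findings$status == "violation", ], row.names = FALSE)

ld <- lineage_diversity(profiles)
cat(sprintf("lineage diversity: %d mtDNA lineages, %d Y lineages\n",
            ld$n_mt_lineages, ld$n_y_lineages))

write.table(findings, "results/tables/pedigree_findings.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/tables/pedigree_findings.tsv\n")
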