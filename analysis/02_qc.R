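#!/usr/bin/env Rscript
# Stage 2: authenticity screening and genetic sex assignment from the
# read-count summaries written by stage 1.

library(paleokin)

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
rc <- read.delim("results/data/readcounts.tsv", stringsAsFactors = FALSE)
report <- run_qc(rc)

tally <- sex_tally(report)
cat(sprintf("QC: %d of %d individuals pass all evaluable criteria\n",
            sum(report$overall), nrow(report)))
cat(sprintf("genetic sex: %d F / %d M / %d U\n",
            tally[["F"]], tally[["M"]], tally[["U"]]))
if (any(!report$overall))
  cat("failing:", paste(report$individual_id[!report$overall], collapse = ", "), "\n")

write.table(report, "results/tables/qc_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/tables/qc_report.tsv\n")
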