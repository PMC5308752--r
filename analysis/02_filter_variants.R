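#!/usr/bin/env Rscript
# Step 2 — run the variant-filter cascade over the simulated call table.
#
# Applies the FFPE amplicon filter settings (phred > 30, coverage >= 100,
# VAF bands at 5% and 20%, primer proximity, overlap concordance, known
# SNPs, blacklist) and writes one decision row per call.

suppressPackageStartupMessages(library(oamlmut))

bundle <- read_bundle("results/bundle")
cfg <- filter_config()

decisions <- run_filter_cascade(bundle$variants, bundle$panel,
                                bundle$snp_db, cfg)
write_filter_decisions(decisions, "results/filter_decisions.tsv")

cat("Filter cascade over", nrow(decisions), "calls:\n")
print(table(decisions$verdict))
rej <- decisions$reasons[decisions$verdict == "reject"]
cat("rejection reasons (a call may carry several):\n")
print(sort(table(unlist(strsplit(rej, ";"))), decreasing = TRUE))
cat("decisions written to results/filter_decisions.tsv\n")
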