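#!/usr/bin/env Rscript
# Step 3 — annotate the surviving calls.
#
# Classifies variant type and protein effect against the coding model,
# applies the five-tool damaging consensus to missense calls, maps
# mutations onto protein domains, and exports a lollipop-ready table.

suppressPackageStartupMessages(library(oamlmut))

bundle <- read_bundle("results/bundle")
decisions <- utils::read.table("results/filter_decisions.tsv",
                               header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)

annotated <- annotate_mutations(decisions, bundle$verdicts)
utils::write.table(annotated, "results/annotated_mutations.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
lolli <- lollipop_table(annotated)
utils::write.table(lolli, "results/lollipop.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

nonsyn <- annotated[annotated$protein_effect != "synonymous", ]
cat("Annotated", nrow(annotated), "accepted calls (",
    nrow(nonsyn), "non-synonymous ):\n")
cat("variant types:\n"); print(table(nonsyn$variant_type))
cat("protein effects:\n"); print(table(nonsyn$protein_effect))
cat(sprintf("deleterious fraction (nonsense/frameshift/damaging): %.2f\n",
            mean(nonsyn$deleterious)))
dom <- nonsyn[!is.na(nonsyn$domain), c("gene", "protein_change", "domain")]
if (nrow(dom)) {
  cat("domain-resident mutations:\n")
  print(utils::head(dom, 10), row.names = FALSE)
}
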