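#!/usr/bin/env Rscript
# Step 4 — cohort mutation landscape.
#
# Builds the patients x genes matrix, per-gene and NF-kB pathway
# frequencies, summary statistics, per-gene VAF/clonality profile, and the
# mutual-exclusivity screen over the genes mutated in >= 12 patients.

suppressPackageStartupMessages(library(oamlmut))

bundle <- read_bundle("results/bundle")
annotated <- utils::read.table("results/annotated_mutations.tsv",
                               header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)

M <- build_matrix(annotated, bundle$clinical$patient_id)
print(M)

freqs <- gene_frequencies(M)
utils::write.table(freqs, "results/gene_frequencies.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(cbind(patient_id = rownames(M$indicator),
                         M$indicator * 1L),
                   "results/mutation_matrix.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("\nmost frequently mutated genes:\n")
print(utils::head(freqs[freqs$n_mutated > 0, ], 10), row.names = FALSE)

s <- summary_statistics(M)
cat(sprintf("\nmean mutated genes per patient: %.2f (range %d-%d)\n",
            s$mean_mutated_genes, s$range_mutated_genes[1],
            s$range_mutated_genes[2]))
cat(sprintf("mutation types: %.0f%% substitutions, %.0f%% deletions, %.0f%% insertions, %.0f%% complex\n",
            100 * s$type_breakdown["substitution"],
            100 * s$type_breakdown["deletion"],
            100 * s$type_breakdown["insertion"],
            100 * s$type_breakdown["complex"]))
cat(sprintf("deleterious fraction: %.0f%%\n",
            100 * s$deleterious_fraction))

nfkb <- pathway_frequency(M, gene_set("NF-kB"))
cat(sprintf("patients with >= 1 mutated NF-kB component: %d/%d (%.0f%%)\n",
            nfkb$n_mutated, nfkb$n_patients, 100 * nfkb$frequency))

vbg <- vaf_by_gene(M)
utils::write.table(vbg, "results/vaf_by_gene.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("\nper-gene VAF profile (top of the clonality spectrum):\n")
print(utils::head(vbg, 6), row.names = FALSE)

clon <- classify_clonality(M$detail$vaf)
utils::write.table(cbind(M$detail[c("patient_id", "gene", "chrom", "pos",
                                    "ref", "alt")], clon),
                   "results/clonality.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

scr <- cooccurrence_screen(M, min_cases = 12)
utils::write.table(scr, "results/cooccurrence.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("\nmutual-exclusivity screen (genes mutated in >= 12 cases):\n")
if (nrow(scr)) print(scr, row.names = FALSE) else
  cat("  fewer than two eligible genes in this cohort\n")
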