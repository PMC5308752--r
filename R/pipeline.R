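## End-to-end pipeline assembly and the run manifest. Each stage is a plain
## function over data.frames and writes inspectable TSV contracts, so stages
## can equally be run separately on intermediate files (the numbered scripts
## under analysis/ do exactly that).

#' Run the full cohort pipeline on an input bundle
#'
#' Chains the stages over an input bundle (as produced by
#' [simulate_cohort()] or assembled from files): filter cascade,
#' annotation, cohort matrix and landscape statistics, clonality and VAF
#' summaries, mutual-exclusivity screen, and mutation-stratified
#' disease-free survival. When `out_dir` is given, every stage output is
#' written as TSV together with a JSON run manifest.
#'
#' @param bundle List with `variants`, `panel`, `snp_db`, `verdicts`,
#'   `clinical` (and optionally `truth`).
#' @param cfg A [filter_config()].
#' @param survival_genes Genes to stratify DFS by (default: genes mutated
#'   in at least 12 patients).
#' @param out_dir Optional output directory.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic given the bundle).
#' @return List with `decisions`, `annotated`, `matrix`, `frequencies`,
#'   `summary`, `vaf_by_gene`, `cooccurrence`, `pathway_nfkb`, `dfs`,
#'   `manifest`.
#' @export
run_pipeline <- function(bundle, cfg = filter_config(),
                         survival_genes = NULL, out_dir = NULL,
                         seed = NA_integer_) {
  decisions <- run_filter_cascade(bundle$variants, bundle$panel,
                                  bundle$snp_db, cfg)
  annotated <- annotate_mutations(decisions, bundle$verdicts)
  M <- build_matrix(annotated, bundle$clinical$patient_id)
  freqs <- gene_frequencies(M)
  summ <- summary_statistics(M)
  vbg <- vaf_by_gene(M)
  cooc <- cooccurrence_screen(M)
  nfkb <- pathway_frequency(M, gene_set("NF-kB"))
  if (is.null(survival_genes))
    survival_genes <- freqs$gene[freqs$n_mutated >= 12]
  dfs <- lapply(stats::setNames(survival_genes, survival_genes),
                function(g) suppressMessages(
                  dfs_by_mutation(M, bundle$clinical, g)))
  manifest <- list(
    package_version = as.character(utils::packageVersion("oamlmut")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    filter_config = cfg[setdiff(names(cfg), "blacklist")],
    counts = list(
      n_variants_in = nrow(bundle$variants),
      n_accepted = sum(decisions$verdict == "accept"),
      n_review_accepted = sum(decisions$verdict == "review_accept"),
      n_rejected = sum(decisions$verdict == "reject"),
      n_nonsynonymous = nrow(M$detail),
      n_patients = length(M$patients)))
  out <- list(decisions = decisions, annotated = annotated, matrix = M,
              frequencies = freqs, summary = summ, vaf_by_gene = vbg,
              cooccurrence = cooc, pathway_nfkb = nfkb, dfs = dfs,
              manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(out, bundle, out_dir)
  out
}

#' Write all pipeline stage outputs as TSV plus the JSON manifest
#'
#' @param result A [run_pipeline()] result.
#' @param bundle The input bundle (for checksums in the manifest; may be
#'   `NULL`).
#' @param out_dir Output directory (created if needed).
#' @export
write_pipeline_outputs <- function(result, bundle = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_filter_decisions(result$decisions, p("filter_decisions.tsv"))
  utils::write.table(result$annotated, p("annotated_mutations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ind <- result$matrix$indicator
  utils::write.table(cbind(patient_id = rownames(ind), ind * 1L),
                     p("mutation_matrix.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(result$frequencies, p("gene_frequencies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$vaf_by_gene, p("vaf_by_gene.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$cooccurrence, p("cooccurrence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  clon <- classify_clonality(result$matrix$detail$vaf)
  utils::write.table(cbind(result$matrix$detail[c("patient_id", "gene",
                                                  "chrom", "pos", "ref",
                                                  "alt")], clon),
                     p("clonality.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lolli <- lollipop_table(result$annotated)
  utils::write.table(lolli, p("lollipop.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (g in names(result$dfs))
    write_dfs_tables(result$dfs[[g]],
                     p(sprintf("dfs_km_%s.tsv", g)),
                     p(sprintf("dfs_test_%s.tsv", g)))
  manifest <- result$manifest
  if (!is.null(bundle)) {
    tmp <- tempfile()
    checks <- list()
    for (nm in intersect(c("variants", "snp_db", "verdicts", "clinical"),
                         names(bundle))) {
      utils::write.table(bundle[[nm]], tmp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      checks[[nm]] <- unname(tools::md5sum(tmp))
    }
    unlink(tmp)
    manifest$input_checksums <- checks
  }
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Write the simulated input bundle to a directory
#'
#' Emits the full bundle in the package's file dialects (variant TSV,
#' extended-BED panel, SNP TSV, verdict TSV, clinical CSV, truth TSV), so
#' each pipeline stage can be run independently on files.
#'
#' @param bundle A [simulate_cohort()] result.
#' @param dir Output directory.
#' @return Named list of paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    variants = file.path(dir, "variants.tsv"),
    panel = file.path(dir, "panel.bed"),
    snp_db = file.path(dir, "snp_db.tsv"),
    verdicts = file.path(dir, "verdicts.tsv"),
    clinical = file.path(dir, "clinical.csv"),
    truth = file.path(dir, "truth.tsv"))
  write_variant_table(bundle$variants, paths$variants)
  write_amplicon_panel(bundle$panel, paths$panel)
  write_snp_table(bundle$snp_db, paths$snp_db)
  write_predictor_verdicts(bundle$verdicts, paths$verdicts)
  write_clinical_table(bundle$clinical, paths$clinical)
  utils::write.table(bundle$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}

#' Read an input bundle from a directory written by [write_bundle()]
#' @param dir Bundle directory.
#' @return List with `variants`, `panel`, `snp_db`, `verdicts`, `clinical`.
#' @export
read_bundle <- function(dir) {
  list(variants = read_variant_table(file.path(dir, "variants.tsv")),
       panel = read_amplicon_panel(file.path(dir, "panel.bed")),
       snp_db = read_snp_table(file.path(dir, "snp_db.tsv")),
       verdicts = read_predictor_verdicts(file.path(dir, "verdicts.tsv")),
       clinical = read_clinical_table(file.path(dir, "clinical.csv")))
}
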