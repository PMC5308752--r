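## Synthetic FFPE-amplicon cohort generator. Emulates the data shapes of a
## 63-patient targeted-amplicon study of ocular adnexal MALT lymphoma with
## known ground truth: purity-scaled clonal/subclonal VAFs, amplicon
## coverage with mean ~160 clamped to [20, 204], sub-5% FFPE-style artifact
## noise with a C:G>T:A bias, germline SNP calls, a recurrent blacklisted
## artifact site, mutation-linked relapse hazards, and a clinical table with
## the study's field structure. Every emitted variant row is attributable to
## exactly one origin class.

#' Default per-gene clonal mutation probabilities
#'
#' Per-gene probability that a cohort patient carries at least one
#' non-synonymous mutation, mirroring the published OAML mutation
#' landscape: TNFAIP3 27%, KMT2D 22%, MYD88 19%, NOTCH1/NOTCH2/TP53 8%,
#' BCL10 6%, rarer members at 2-5%, and zero for the eight genes in which
#' no non-synonymous mutation was observed.
#'
#' @return Named numeric vector over the 24 panel genes.
#' @export
default_gene_probs <- function() {
  p <- stats::setNames(rep(0, nrow(panel_genes())), panel_genes()$gene)
  p[c("TNFAIP3", "KMT2D", "MYD88", "NOTCH1", "NOTCH2", "TP53", "BCL10",
      "TNIP1", "NFKBIA")] <- c(0.27, 0.22, 0.19, 0.08, 0.08, 0.08, 0.06,
                               0.05, 0.03)
  p[c("BIRC3", "CARD11", "CD79B", "CYLD", "MAP3K7", "MAP3K14", "TRAF6")] <- 0.02
  p
}

#' Default per-gene subclonal probabilities
#'
#' Probability that a given mutation is subclonal rather than clonal.
#' Genes observed to carry mostly subclonal mutations (NOTCH1, TNIP1,
#' MAP3K7, BCL10, NFKBIA) default high; TNFAIP3, whose mutations are
#' mostly clonal with the highest average VAF, defaults low.
#'
#' @return Named numeric vector over the 24 panel genes.
#' @export
default_subclonal_probs <- function() {
  p <- stats::setNames(rep(0.25, nrow(panel_genes())), panel_genes()$gene)
  p[c("NOTCH1", "TNIP1", "MAP3K7", "BCL10", "NFKBIA")] <- 0.7
  p["TNFAIP3"] <- 0.15
  p["MYD88"] <- 0.20
  p
}

#' Default per-gene LOH/UPD probabilities
#'
#' Probability that a clonal mutation has lost its wild-type allele
#' (deletion of the second allele or uniparental disomy), which lifts the
#' expected VAF above 50%: under the single-copy model the expected VAF at
#' purity p is p / (2 - p). TNFAIP3, whose mutations show the highest
#' average VAF with several cases above 50%, defaults high; other genes
#' low.
#'
#' @return Named numeric vector over the 24 panel genes.
#' @export
default_loh_probs <- function() {
  p <- stats::setNames(rep(0.05, nrow(panel_genes())), panel_genes()$gene)
  p["TNFAIP3"] <- 0.5
  p
}

#' Simulation configuration
#'
#' Assembles the generator's parameters with defaults encoding the study
#' conditions the cohort emulates. See the methods vignette for the
#' rationale behind each default.
#'
#' @param n_patients Cohort size.
#' @param gene_probs Named per-gene mutation probabilities.
#' @param subclonal_probs Named per-gene subclonal probabilities.
#' @param loh_probs Named per-gene probabilities that a clonal mutation has
#'   allelic imbalance (LOH/UPD) lifting its expected VAF to
#'   `purity / (2 - purity)`.
#' @param second_mutation_prob Probability of a second mutation in the same
#'   gene, applied to KMT2D and TNFAIP3.
#' @param ccf_range Uniform range of subclonal cancer-cell fractions.
#' @param purity_range Uniform range of biopsy tumor-cell content.
#' @param coverage_mean,coverage_dispersion,coverage_bounds Negative
#'   binomial coverage model (mean, size) clamped to the bounds.
#' @param artifact_rate Expected artifacts per amplicon per patient sample.
#' @param artifact_vaf_shape Beta shape parameters of the artifact VAF,
#'   concentrated below the 5% calling threshold.
#' @param artifact_ct_bias Fraction of artifacts that are C:G>T:A
#'   (FFPE-deamination convention).
#' @param blacklist_artifact_rate Per-patient probability of the recurrent
#'   blacklisted 1-bp deletion call.
#' @param snp_plant_frac Fraction of true mutations also planted into the
#'   known-SNP list (exercises the cost of SNP filtering).
#' @param n_decoy_snps Known-SNP records never emitted as calls.
#' @param n_germline_sites,germline_het_prob Cohort-wide germline SNP sites
#'   and the per-patient heterozygosity probability; het sites are emitted
#'   as ~50% VAF calls and carry known-SNP records.
#' @param synonymous_rate Expected synonymous calls per patient (classified
#'   but excluded from landscape statistics).
#' @param type_probs Mutation-type mix over non-synonymous truth
#'   (substitution/deletion/insertion/complex).
#' @param substitution_effect_probs Missense/nonsense split of truth
#'   substitutions.
#' @param indel_len_probs Length mix (1/2/3 bp) of indels.
#' @param p_missense_damaging,p_missense_tolerated Probability that a truth
#'   missense variant draws a damaging (resp. tolerated) five-tool
#'   consensus profile; the remainder draw an undetermined profile.
#' @param myd88_hotspot_frac Fraction of MYD88 mutations that are the
#'   canonical Leu265Pro hotspot.
#' @param notch_intracellular_frac Fraction of NOTCH1/NOTCH2 mutations
#'   biased into the intracellular (TAD/PEST-side) portion of the protein.
#' @param exclusive_pair,exclusivity Gene pair with injected mutual
#'   exclusivity and its strength in [0, 1] (0 = independence; the joint
#'   probability is scaled by `1 - exclusivity` with marginals preserved).
#' @param baseline_hazard Monthly exponential DFS hazard of wild-type
#'   patients.
#' @param hazard_gene,hazard_ratio Gene whose mutated group has a
#'   proportionally increased hazard.
#' @param censor_range Uniform range (months) of administrative censoring.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_patients = 63L,
                       gene_probs = default_gene_probs(),
                       subclonal_probs = default_subclonal_probs(),
                       loh_probs = default_loh_probs(),
                       second_mutation_prob = 0.15,
                       ccf_range = c(0.10, 0.45),
                       purity_range = c(0.70, 0.95),
                       coverage_mean = 160,
                       coverage_dispersion = 60,
                       coverage_bounds = c(20L, 204L),
                       artifact_rate = 5e-4,
                       artifact_vaf_shape = c(1.2, 80),
                       artifact_ct_bias = 0.8,
                       blacklist_artifact_rate = 0.08,
                       snp_plant_frac = 0.02,
                       n_decoy_snps = 200L,
                       n_germline_sites = 40L,
                       germline_het_prob = 0.10,
                       synonymous_rate = 0.3,
                       type_probs = c(substitution = 0.70, deletion = 0.20,
                                      insertion = 0.09, complex = 0.01),
                       substitution_effect_probs = c(missense = 0.89,
                                                     nonsense = 0.11),
                       indel_len_probs = c(0.60, 0.25, 0.15),
                       p_missense_damaging = 0.51,
                       p_missense_tolerated = 0.34,
                       myd88_hotspot_frac = 0.67,
                       notch_intracellular_frac = 0.7,
                       exclusive_pair = c("TNFAIP3", "MYD88"),
                       exclusivity = 0.8,
                       baseline_hazard = 0.005,
                       hazard_gene = "MYD88",
                       hazard_ratio = 3.5,
                       censor_range = c(19, 194)) {
  stopifnot(all(gene_probs >= 0 & gene_probs <= 1),
            all(subclonal_probs >= 0 & subclonal_probs <= 1),
            all(loh_probs >= 0 & loh_probs <= 1),
            exclusivity >= 0, exclusivity <= 1,
            coverage_bounds[1] <= coverage_bounds[2],
            abs(sum(type_probs) - 1) < 1e-8,
            baseline_hazard > 0, hazard_ratio > 0)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Synthetic amplicon panel tiling the 24-gene coding models
#'
#' Tiles each gene's coding region with fixed-length inserts at a step
#' below the insert length, so adjacent amplicons overlap and interior
#' positions are covered by one or two amplicons — the geometry that makes
#' overlap-concordance checks possible. Deterministic (no random state).
#'
#' @param insert_len Insert length in bp.
#' @param step Tiling step in bp (`< insert_len` gives overlaps).
#' @param primer_len Primer length on each side.
#' @param ambiguous_amplicons Amplicon ids to flag as `mapping_ambiguous`.
#' @return Panel data.frame in the [read_amplicon_panel()] layout.
#' @export
synthetic_panel <- function(insert_len = 150L, step = 120L,
                            primer_len = 20L,
                            ambiguous_amplicons = character()) {
  key <- paste("panel", insert_len, step, primer_len, sep = "_")
  cached <- .oamlmut_cache[[key]]
  if (is.null(cached)) {
    pg <- panel_genes()
    rows <- lapply(seq_len(nrow(pg)), function(i) {
      len <- pg$protein_length[i] * 3L
      anchor <- pg$cds_anchor[i]
      starts <- seq(anchor, anchor + len - 1L, by = step)
      ends <- pmin(starts + insert_len - 1L, anchor + len - 1L)
      keep <- ends - starts + 1L >= 40L  # drop degenerate tail inserts
      starts <- starts[keep]; ends <- ends[keep]
      ## pad the terminal inserts beyond the target, as real panel designs
      ## do, so no target base is primer-proximal in every covering amplicon
      starts[1] <- starts[1] - 10L
      ends[length(ends)] <- ends[length(ends)] + 10L
      data.frame(
        amplicon_id = sprintf("%s_amp%03d", pg$gene[i], seq_along(starts)),
        chrom = pg$chrom[i],
        insert_start = starts, insert_end = ends,
        primer_len_5p = primer_len, primer_len_3p = primer_len,
        gene = pg$gene[i], mapping_ambiguous = FALSE, strand = "+",
        stringsAsFactors = FALSE)
    })
    cached <- do.call(rbind, rows)
    ## same ordering contract as read_amplicon_panel()
    cached <- cached[order(cached$chrom, cached$insert_start), , drop = FALSE]
    rownames(cached) <- NULL
    .oamlmut_cache[[key]] <- cached
  }
  panel <- cached
  panel$mapping_ambiguous <- panel$amplicon_id %in% ambiguous_amplicons
  panel
}

## clamped negative-binomial position coverage
rcoverage <- function(n, cfg) {
  x <- stats::rnbinom(n, mu = cfg$coverage_mean,
                      size = cfg$coverage_dispersion)
  pmin(pmax(x, cfg$coverage_bounds[1]), cfg$coverage_bounds[2])
}

## draw one truth mutation for `gene`; returns pos/ref/alt/designed effect
draw_mutation <- function(gene, cfg, force_effect = NULL) {
  pg <- panel_genes()
  i <- match(gene, pg$gene)
  L <- pg$protein_length[i]
  anchor <- pg$cds_anchor[i]
  seq <- synthetic_cds(gene)
  if (gene == "MYD88" && is.null(force_effect) &&
      stats::runif(1) < cfg$myd88_hotspot_frac) {
    return(list(pos = anchor + 794L - 1L, ref = "T", alt = "C",
                designed_effect = "missense"))
  }
  type <- if (!is.null(force_effect) && force_effect == "synonymous")
    "substitution"
  else sample(names(cfg$type_probs), 1, prob = cfg$type_probs)
  draw_aa <- function() {
    if (gene %in% c("NOTCH1", "NOTCH2") &&
        stats::runif(1) < cfg$notch_intracellular_frac)
      sample(seq(floor(0.78 * L), L - 1L), 1)
    else sample(2:(L - 1L), 1)
  }
  if (type == "substitution") {
    target <- if (!is.null(force_effect)) force_effect
    else sample(names(cfg$substitution_effect_probs), 1,
                prob = cfg$substitution_effect_probs)
    for (try in 1:40) {
      aa <- draw_aa()
      codon <- substr(seq, (aa - 1L) * 3L + 1L, aa * 3L)
      cands <- list()
      for (frame in 0:2) {
        ref_b <- substr(codon, frame + 1L, frame + 1L)
        for (alt_b in setdiff(c("A", "C", "G", "T"), ref_b)) {
          alt_codon <- codon
          substr(alt_codon, frame + 1L, frame + 1L) <- alt_b
          aa_ref <- translate_codon(codon)
          aa_alt <- translate_codon(alt_codon)
          eff <- if (aa_alt == "*") "nonsense"
          else if (aa_alt == aa_ref) "synonymous" else "missense"
          if (eff == target)
            cands[[length(cands) + 1L]] <-
              list(cds = (aa - 1L) * 3L + frame + 1L, ref = ref_b,
                   alt = alt_b)
        }
      }
      if (length(cands)) {
        pick <- cands[[sample.int(length(cands), 1)]]
        return(list(pos = anchor + pick$cds - 1L, ref = pick$ref,
                    alt = pick$alt, designed_effect = target))
      }
    }
    ## target unreachable from sampled codons; fall back to any exchange
    aa <- draw_aa()
    cds <- (aa - 1L) * 3L + 1L
    ref_b <- substr(seq, cds, cds)
    alt_b <- sample(setdiff(c("A", "C", "G", "T"), ref_b), 1)
    return(list(pos = anchor + cds - 1L, ref = ref_b, alt = alt_b,
                designed_effect = "missense"))
  }
  if (type %in% c("deletion", "insertion")) {
    k <- sample(1:3, 1, prob = cfg$indel_len_probs)
    d0 <- sample(2:(3L * L - k - 1L), 1)
    if (type == "deletion") {
      ref <- substr(seq, d0, d0 + k)
      alt <- substr(seq, d0, d0)
    } else {
      ref <- substr(seq, d0, d0)
      alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"), k,
                                      replace = TRUE), collapse = ""))
    }
    return(list(pos = anchor + d0 - 1L, ref = ref, alt = alt,
                designed_effect = if (k %% 3L) "frameshift" else "inframe_indel"))
  }
  ## complex: multi-base exchange
  repeat {
    d0 <- sample(2:(3L * L - 2L), 1)
    ref <- substr(seq, d0, d0 + 1L)
    alt <- paste(sample(c("A", "C", "G", "T"), 2, replace = TRUE),
                 collapse = "")
    if (alt != ref && substr(alt, 1, 1) != substr(ref, 1, 1)) break
  }
  list(pos = anchor + d0 - 1L, ref = ref, alt = alt,
       designed_effect = "other")
}

## read counts at a position: total coverage split over covering amplicons,
## per-amplicon variant reads binomial at the true VAF
draw_reads <- function(gene, chrom, pos, vaf, panel, cfg) {
  cov <- covering_amplicons(panel, chrom, pos)
  n_amp <- nrow(cov)
  total <- rcoverage(1, cfg)
  if (n_amp >= 2) {
    t1 <- stats::rbinom(1, total, 0.5)
    totals <- c(t1, total - t1)
    cov <- cov[1:2, , drop = FALSE]
  } else if (n_amp == 1) {
    totals <- total
  } else {
    return(NULL)  # outside panel; should not happen for coding positions
  }
  variants <- stats::rbinom(length(totals), totals, vaf)
  list(amplicon_ids = cov$amplicon_id, totals = totals, variants = variants,
       reads_total = sum(totals), reads_variant = sum(variants))
}

## five-tool verdict profile for one variant
draw_verdicts <- function(profile) {
  tools <- PREDICTOR_TOOLS
  v <- stats::setNames(rep("missing", 5), tools)
  if (profile == "damaging") {
    k <- sample(3:5, 1)
    v[sample(tools, k)] <- "damaging"
    v[v == "missing"] <- sample(c("tolerated", "missing"), sum(v == "missing"),
                                replace = TRUE)
  } else if (profile == "tolerated") {
    k <- sample(3:5, 1)
    v[sample(tools, k)] <- "tolerated"
    v[v == "missing"] <- sample(c("damaging", "missing"), sum(v == "missing"),
                                replace = TRUE)
  } else {
    v[sample(tools, 2)] <- "damaging"
    v[sample(names(v)[v == "missing"], 2)] <- "tolerated"
  }
  v
}

#' Simulate a synthetic OAML-like cohort
#'
#' Generates the full input bundle of a targeted-amplicon cohort study —
#' variant call table, amplicon panel, known-SNP list, predictor verdicts,
#' clinical table — together with the ground truth behind it. Read counts
#' of true mutations are binomial at the purity- and CCF-scaled expected
#' VAF; artifacts are sub-threshold FFPE-style noise (a draw whose observed
#' VAF would reach the 5% calling band at >= 100x coverage is resampled:
#' the artifact class is defined as sub-threshold); germline SNP calls sit
#' near 50% VAF and carry known-SNP records; a recurrent blacklisted 1-bp
#' deletion is injected at its fixed site. Seeded runs are
#' bit-reproducible.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed for all randomness.
#' @return List with `variants`, `panel`, `snp_db`, `verdicts`, `clinical`,
#'   `truth`.
#' @export
simulate_cohort <- function(cfg = sim_config(), seed = 1L) {
  set.seed(seed)
  panel <- synthetic_panel()
  pg <- panel_genes()
  genes <- pg$gene
  n <- cfg$n_patients
  patients <- sprintf("P%03d", seq_len(n))
  purity <- round(stats::runif(n, cfg$purity_range[1], cfg$purity_range[2]), 3)

  ## --- mutation indicators with injected exclusivity ------------------------
  probs <- cfg$gene_probs[genes]
  ind <- matrix(stats::runif(n * length(genes)) < rep(probs, each = n),
                nrow = n, dimnames = list(patients, genes))
  ex <- cfg$exclusive_pair
  if (length(ex) == 2 && all(ex %in% genes) && cfg$exclusivity > 0) {
    pa <- probs[ex[1]]; pb <- probs[ex[2]]
    p_b_given_a <- pb * (1 - cfg$exclusivity)
    p_b_given_nota <- (pb - pa * p_b_given_a) / (1 - pa)
    a <- stats::runif(n) < pa
    b <- stats::runif(n) < ifelse(a, p_b_given_a, p_b_given_nota)
    ind[, ex[1]] <- a
    ind[, ex[2]] <- b
  }

  truth_rows <- list()
  add_truth <- function(patient, gene, chrom, pos, ref, alt, origin,
                        clonal, ccf, pur, designed_effect, reads,
                        loh = FALSE, expected_vaf = NA_real_) {
    emitted <- !is.null(reads) && reads$reads_variant >= 1L
    if (is.na(expected_vaf) && !is.na(ccf)) expected_vaf <- pur * ccf / 2
    truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
      patient_id = patient, gene = gene, chrom = chrom, pos = pos,
      ref = ref, alt = alt, origin = origin, clonal = clonal, ccf = ccf,
      loh = loh, purity = pur, expected_vaf = expected_vaf,
      designed_effect = designed_effect, planted_snp = FALSE,
      emitted = emitted,
      reads_total = if (emitted) reads$reads_total else NA_integer_,
      reads_variant = if (emitted) reads$reads_variant else NA_integer_,
      amplicons = if (emitted) paste(reads$amplicon_ids, collapse = ";") else "",
      amplicon_counts = if (emitted)
        encode_amplicon_counts(reads$amplicon_ids, reads$totals,
                               reads$variants) else ".",
      phred = NA_real_, stringsAsFactors = FALSE)
    emitted
  }

  ## --- true somatic mutations ----------------------------------------------
  for (p in seq_len(n)) {
    for (g in genes[ind[p, ]]) {
      n_mut <- 1L + (g %in% c("KMT2D", "TNFAIP3") &&
                       stats::runif(1) < cfg$second_mutation_prob)
      for (m in seq_len(n_mut)) {
        mut <- draw_mutation(g, cfg)
        clonal <- stats::runif(1) >= cfg$subclonal_probs[g]
        loh <- clonal && stats::runif(1) < cfg$loh_probs[g]
        ccf <- if (clonal) 1 else stats::runif(1, cfg$ccf_range[1],
                                               cfg$ccf_range[2])
        vaf <- if (loh) purity[p] / (2 - purity[p]) else purity[p] * ccf / 2
        chrom <- pg$chrom[match(g, pg$gene)]
        reads <- draw_reads(g, chrom, mut$pos, vaf, panel, cfg)
        if (add_truth(patients[p], g, chrom, mut$pos, mut$ref, mut$alt,
                      "truth", clonal, ccf, purity[p],
                      mut$designed_effect, reads, loh = loh,
                      expected_vaf = vaf)) {
          i <- length(truth_rows)
          truth_rows[[i]]$phred <- stats::runif(1, 33, 45)
        }
      }
    }
    ## synonymous passengers (classified, excluded from statistics)
    for (s in seq_len(stats::rpois(1, cfg$synonymous_rate))) {
      g <- sample(genes, 1)
      mut <- draw_mutation(g, cfg, force_effect = "synonymous")
      chrom <- pg$chrom[match(g, pg$gene)]
      vaf <- purity[p] / 2
      reads <- draw_reads(g, chrom, mut$pos, vaf, panel, cfg)
      if (add_truth(patients[p], g, chrom, mut$pos, mut$ref, mut$alt,
                    "synonymous", TRUE, 1, purity[p], "synonymous", reads)) {
        truth_rows[[length(truth_rows)]]$phred <- stats::runif(1, 33, 45)
      }
    }
  }

  ## --- FFPE-style artifacts (sub-threshold noise) ---------------------------
  n_amp <- nrow(panel)
  for (p in seq_len(n)) {
    for (a in seq_len(stats::rpois(1, cfg$artifact_rate * n_amp))) {
      amp <- panel[sample.int(n_amp, 1), ]
      g <- amp$gene
      want_ct <- stats::runif(1) < cfg$artifact_ct_bias
      pos <- NA
      for (try in 1:30) {
        cand <- sample(amp$insert_start:amp$insert_end, 1)
        ref_b <- synthetic_ref(g, cand)
        if (is.na(ref_b)) next
        if (!want_ct || ref_b %in% c("C", "G")) { pos <- cand; break }
      }
      if (is.na(pos)) next
      ref_b <- synthetic_ref(g, pos)
      alt_b <- if (want_ct && ref_b == "C") "T"
      else if (want_ct && ref_b == "G") "A"
      else sample(setdiff(c("A", "C", "G", "T"), ref_b), 1)
      vaf <- min(stats::rbeta(1, cfg$artifact_vaf_shape[1],
                              cfg$artifact_vaf_shape[2]), 0.045)
      reads <- draw_reads(g, amp$chrom, pos, vaf, panel, cfg)
      if (is.null(reads)) next
      ## sub-threshold by construction: resample counts that would reach the
      ## calling band at evaluable coverage
      tries <- 0
      while (reads$reads_total >= 100 &&
             reads$reads_variant / reads$reads_total >= 0.05 && tries < 50) {
        reads$variants <- stats::rbinom(length(reads$totals), reads$totals,
                                        vaf)
        reads$reads_variant <- sum(reads$variants)
        tries <- tries + 1
      }
      if (reads$reads_total >= 100 &&
          reads$reads_variant / reads$reads_total >= 0.05) {
        reads$variants[1] <- max(0L, reads$variants[1] -
                                   (reads$reads_variant -
                                      (ceiling(0.05 * reads$reads_total) - 1L)))
        reads$reads_variant <- sum(reads$variants)
      }
      if (add_truth(patients[p], g, amp$chrom, pos, ref_b, alt_b, "artifact",
                    NA, NA_real_, purity[p], "artifact", reads)) {
        truth_rows[[length(truth_rows)]]$phred <- stats::runif(1, 26, 42)
      }
    }
    ## recurrent blacklisted deletion
    if (stats::runif(1) < cfg$blacklist_artifact_rate) {
      bl <- default_blacklist()[1, ]
      vaf <- stats::runif(1, 0.08, 0.30)
      reads <- draw_reads("NOTCH1", bl$chrom, bl$pos, vaf, panel, cfg)
      if (add_truth(patients[p], "NOTCH1", bl$chrom, bl$pos, bl$ref, bl$alt,
                    "blacklist_artifact", NA, NA_real_, purity[p],
                    "frameshift", reads)) {
        truth_rows[[length(truth_rows)]]$phred <- stats::runif(1, 33, 45)
      }
    }
  }

  ## --- germline SNP sites ---------------------------------------------------
  germ <- data.frame(gene = sample(genes, cfg$n_germline_sites,
                                   replace = TRUE))
  germ$chrom <- pg$chrom[match(germ$gene, pg$gene)]
  germ$cds <- vapply(germ$gene, function(g)
    sample.int(3L * pg$protein_length[match(g, pg$gene)] - 3L, 1) + 1L, 1L)
  germ$pos <- pg$cds_anchor[match(germ$gene, pg$gene)] + germ$cds - 1L
  germ$ref <- vapply(seq_len(nrow(germ)), function(i)
    synthetic_ref(germ$gene[i], germ$pos[i]), "")
  germ$alt <- vapply(germ$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  germ <- germ[!duplicated(variant_key(germ$chrom, germ$pos, germ$ref,
                                       germ$alt)), , drop = FALSE]
  for (p in seq_len(n)) {
    het <- which(stats::runif(nrow(germ)) < cfg$germline_het_prob)
    for (i in het) {
      reads <- draw_reads(germ$gene[i], germ$chrom[i], germ$pos[i], 0.5,
                          panel, cfg)
      if (add_truth(patients[p], germ$gene[i], germ$chrom[i], germ$pos[i],
                    germ$ref[i], germ$alt[i], "germline_snp", NA, NA_real_,
                    purity[p], "germline", reads)) {
        truth_rows[[length(truth_rows)]]$phred <- stats::runif(1, 33, 45)
      }
    }
  }

  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    stop("empty truth set")

  ## --- known-SNP list: germline sites, decoys, planted truth ----------------
  truth_keys <- variant_key(truth$chrom, truth$pos, truth$ref, truth$alt)
  ## well-known recurrent somatic hotspots are never polymorphism entries
  hotspot_key <- variant_key("chr3",
                             panel_genes()$cds_anchor[
                               match("MYD88", panel_genes()$gene)] + 793L,
                             "T", "C")
  somatic <- which(truth$origin == "truth" & truth_keys != hotspot_key)
  planted <- somatic[stats::runif(length(somatic)) < cfg$snp_plant_frac]
  truth$planted_snp[truth_keys %in% truth_keys[planted]] <- TRUE
  decoys <- data.frame(gene = sample(genes, cfg$n_decoy_snps, replace = TRUE))
  decoys$chrom <- pg$chrom[match(decoys$gene, pg$gene)]
  decoys$cds <- vapply(decoys$gene, function(g)
    sample.int(3L * pg$protein_length[match(g, pg$gene)] - 3L, 1) + 1L, 1L)
  decoys$pos <- pg$cds_anchor[match(decoys$gene, pg$gene)] + decoys$cds - 1L
  decoys$ref <- vapply(seq_len(nrow(decoys)), function(i)
    synthetic_ref(decoys$gene[i], decoys$pos[i]), "")
  decoys$alt <- vapply(decoys$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  snp_db <- rbind(
    data.frame(chrom = germ$chrom, pos = germ$pos, ref = germ$ref,
               alt = germ$alt, source = "db137", stringsAsFactors = FALSE),
    data.frame(chrom = truth$chrom[planted], pos = truth$pos[planted],
               ref = truth$ref[planted], alt = truth$alt[planted],
               source = rep("db137", length(planted)),
               stringsAsFactors = FALSE),
    data.frame(chrom = decoys$chrom, pos = decoys$pos, ref = decoys$ref,
               alt = decoys$alt, source = "db137", stringsAsFactors = FALSE))
  snp_db <- snp_db[!duplicated(variant_key(snp_db$chrom, snp_db$pos,
                                           snp_db$ref, snp_db$alt)), ,
                   drop = FALSE]
  ## decoys must not collide with emitted calls
  emitted_keys <- truth_keys[truth$emitted]
  snp_key <- variant_key(snp_db$chrom, snp_db$pos, snp_db$ref, snp_db$alt)
  planted_keys <- unique(truth_keys[planted])
  germ_keys <- variant_key(germ$chrom, germ$pos, germ$ref, germ$alt)
  drop <- snp_key %in% setdiff(emitted_keys, c(planted_keys, germ_keys))
  snp_db <- snp_db[!drop, , drop = FALSE]
  rownames(snp_db) <- NULL

  ## --- variant call table ---------------------------------------------------
  em <- truth[truth$emitted, , drop = FALSE]
  variants <- data.frame(
    patient_id = em$patient_id, chrom = em$chrom, pos = em$pos,
    ref = em$ref, alt = em$alt, gene = em$gene,
    reads_total = em$reads_total, reads_variant = em$reads_variant,
    phred = round(em$phred, 1), amplicons = em$amplicons,
    amplicon_counts = em$amplicon_counts, stringsAsFactors = FALSE)
  dup <- duplicated(paste(variants$patient_id,
                          variant_key(variants$chrom, variants$pos,
                                      variants$ref, variants$alt)))
  variants <- variants[!dup, , drop = FALSE]
  variants <- variants[order(variants$patient_id, variants$chrom,
                             variants$pos, variants$alt), , drop = FALSE]
  rownames(variants) <- NULL
  variants$vaf <- variants$reads_variant / variants$reads_total

  ## --- predictor verdicts ---------------------------------------------------
  subs <- variants[classify_variant_type(variants$ref, variants$alt) ==
                     "substitution", , drop = FALSE]
  subs <- subs[!duplicated(variant_key(subs$chrom, subs$pos, subs$ref,
                                       subs$alt)), , drop = FALSE]
  verdict_rows <- lapply(seq_len(nrow(subs)), function(i) {
    k <- variant_key(subs$chrom[i], subs$pos[i], subs$ref[i], subs$alt[i])
    is_truth <- any(truth_keys == k & truth$origin == "truth")
    profile <- if (is_truth)
      sample(c("damaging", "tolerated", "undetermined"), 1,
             prob = c(cfg$p_missense_damaging, cfg$p_missense_tolerated,
                      1 - cfg$p_missense_damaging - cfg$p_missense_tolerated))
    else sample(c("damaging", "tolerated", "undetermined"), 1,
                prob = c(0.15, 0.55, 0.30))
    v <- draw_verdicts(profile)
    data.frame(chrom = subs$chrom[i], pos = subs$pos[i], ref = subs$ref[i],
               alt = subs$alt[i], t(v), stringsAsFactors = FALSE)
  })
  verdicts <- if (length(verdict_rows)) do.call(rbind, verdict_rows)
  else data.frame(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), sift = character(),
                  polyphen2_hdiv = character(), polyphen2_hvar = character(),
                  lrt = character(), mutationtaster = character(),
                  stringsAsFactors = FALSE)
  names(verdicts)[5:9] <- PREDICTOR_TOOLS

  ## --- clinical table with mutation-linked DFS hazard -----------------------
  mutated_hazard_gene <- patients %in%
    truth$patient_id[truth$origin == "truth" & truth$gene == cfg$hazard_gene]
  hazard <- cfg$baseline_hazard *
    ifelse(mutated_hazard_gene, cfg$hazard_ratio, 1)
  t_event <- stats::rexp(n, hazard)
  t_censor <- stats::runif(n, cfg$censor_range[1], cfg$censor_range[2])
  event <- t_event <= t_censor
  followup <- pmax(round(pmin(t_event, t_censor), 1), 0.5)
  death <- event & stats::runif(n) < 0.15
  clinical <- data.frame(
    patient_id = patients,
    age_years = pmin(pmax(round(stats::rnorm(n, 67, 12)), 29), 87),
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.63, 0.37)),
    ann_arbor_stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                             prob = c(0.80, 0.09, 0.05, 0.06)),
    localization = sample(c("orbita", "conjunctiva", "lacrimal gland"), n,
                          replace = TRUE, prob = c(0.43, 0.46, 0.11)),
    treatment = sample(c("radiotherapy", "immunochemotherapy", "anti-CD20",
                         "none"), n, replace = TRUE,
                       prob = c(0.80, 0.13, 0.03, 0.04)),
    relapse = event,
    death = death,
    followup_months = followup,
    tumor_content_fraction = purity,
    stringsAsFactors = FALSE)

  rownames(truth) <- NULL
  list(variants = variants, panel = panel, snp_db = snp_db,
       verdicts = verdicts, clinical = clinical, truth = truth)
}

#' Recovery report: pipeline output against ground truth
#'
#' Measures how well the filter cascade recovers the simulated truth:
#' sensitivity per clonality class (true somatic mutations that survive the
#' cascade, excluding those deliberately planted into the known-SNP list,
#' which the cascade is supposed to remove), false-discovery count
#' (accepted calls of artifact, germline or blacklist origin), and per-gene
#' frequency recovery against the configured probabilities with binomial
#' standard errors.
#'
#' @param truth Truth table from [simulate_cohort()].
#' @param decisions Output of [run_filter_cascade()] on the simulated
#'   variants.
#' @param M Optional [build_matrix()] result for frequency recovery (else
#'   frequencies are taken from accepted truth calls).
#' @param cfg The [sim_config()] used.
#' @return List with `sensitivity_clonal`, `sensitivity_subclonal`,
#'   `n_false_discoveries`, `per_gene` (data.frame).
#' @export
recovery_report <- function(truth, decisions, M = NULL, cfg = sim_config()) {
  dec_key <- paste(decisions$patient_id,
                   variant_key(decisions$chrom, decisions$pos, decisions$ref,
                               decisions$alt))
  acc_key <- dec_key[decisions$verdict != "reject"]
  truth$call_key <- paste(truth$patient_id,
                          variant_key(truth$chrom, truth$pos, truth$ref,
                                      truth$alt))
  som <- truth[truth$origin == "truth" & !truth$planted_snp, , drop = FALSE]
  detected <- som$call_key %in% acc_key
  sens <- function(sel) if (any(sel)) mean(detected[sel]) else NA_real_
  bad <- truth[truth$origin %in% c("artifact", "germline_snp",
                                   "blacklist_artifact"), , drop = FALSE]
  n_fd <- sum(acc_key %in% bad$call_key) +
    sum(!acc_key %in% truth$call_key)
  n_pat <- cfg$n_patients
  observed <- if (!is.null(M)) {
    colSums(M$indicator)[names(cfg$gene_probs)] / length(M$patients)
  } else {
    acc_som <- som[detected, , drop = FALSE]
    vapply(names(cfg$gene_probs), function(g)
      length(unique(acc_som$patient_id[acc_som$gene == g])) / n_pat,
      numeric(1))
  }
  per_gene <- data.frame(
    gene = names(cfg$gene_probs),
    configured = as.numeric(cfg$gene_probs),
    observed = as.numeric(observed),
    stringsAsFactors = FALSE)
  per_gene$deviation <- per_gene$observed - per_gene$configured
  per_gene$se_binomial <- sqrt(per_gene$configured *
                                 (1 - per_gene$configured) / n_pat)
  list(sensitivity_clonal = sens(som$clonal),
       sensitivity_subclonal = sens(!som$clonal),
       n_false_discoveries = n_fd,
       per_gene = per_gene)
}
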