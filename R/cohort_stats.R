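## Cohort-level mutation landscape: the patients-by-genes indicator matrix,
## per-gene and pathway frequencies, VAF-based clonality calls, and the
## mutual-exclusivity screen built on an exact two-sided Fisher test
## implemented from first principles.

#' Build the patients-by-genes mutation matrix
#'
#' Indicator matrix over the full patient list and gene panel: a cell is
#' `TRUE` iff the patient carries at least one accepted non-synonymous
#' mutation in the gene. Patients with no mutations are retained as
#' all-`FALSE` rows; a patient may contribute several mutations to one gene
#' (one indicator cell, several detail rows).
#'
#' @param annotated Output of [annotate_mutations()].
#' @param patients Character vector of all cohort patient ids.
#' @param genes Gene panel (defaults to the 24 panel genes).
#' @return List of class `cohort_matrix` with `indicator` (logical matrix),
#'   `patients`, `genes`, and `detail` (the non-synonymous annotated
#'   mutations).
#' @export
build_matrix <- function(annotated, patients, genes = panel_genes()$gene) {
  detail <- annotated[annotated$verdict != "reject" &
                        !annotated$protein_effect %in% "synonymous", ,
                      drop = FALSE]
  unknown <- setdiff(detail$patient_id, patients)
  if (length(unknown))
    stop("mutation(s) for patient(s) absent from the cohort list: ",
         paste(unknown, collapse = ", "))
  off_panel <- setdiff(detail$gene, genes)
  if (length(off_panel))
    stop("mutation(s) in gene(s) outside the panel: ",
         paste(off_panel, collapse = ", "))
  ind <- matrix(FALSE, nrow = length(patients), ncol = length(genes),
                dimnames = list(patients, genes))
  if (nrow(detail))
    ind[cbind(match(detail$patient_id, patients),
              match(detail$gene, genes))] <- TRUE
  structure(list(indicator = ind, patients = patients, genes = genes,
                 detail = detail),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat("cohort_matrix:", length(x$patients), "patients x", length(x$genes),
      "genes;", nrow(x$detail), "non-synonymous mutations;",
      sum(rowSums(x$indicator) == 0), "patients without mutations\n")
  invisible(x)
}

#' Per-gene mutation frequencies
#'
#' Fraction of cohort patients with at least one accepted non-synonymous
#' mutation per gene (patients counted once per gene regardless of
#' mutation multiplicity), reported with counts alongside the unrounded
#' fraction.
#'
#' @param M A [build_matrix()] result.
#' @return data.frame with `gene`, `n_mutated`, `n_patients`, `frequency`,
#'   sorted by decreasing frequency.
#' @export
gene_frequencies <- function(M) {
  n <- length(M$patients)
  if (n == 0) stop("empty cohort")
  cnt <- colSums(M$indicator)
  out <- data.frame(gene = M$genes, n_mutated = as.integer(cnt),
                    n_patients = n, frequency = cnt / n,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$frequency, out$gene), , drop = FALSE]
}

#' Fraction of patients mutated in a gene set
#'
#' Union-based pathway frequency: the fraction of patients with at least
#' one mutated member of the set (each patient counted once).
#'
#' @param M A [build_matrix()] result.
#' @param genes Character vector of member genes (must be in the matrix),
#'   e.g. `gene_set("NF-kB")`.
#' @return List with `n_mutated`, `n_patients`, `frequency`.
#' @export
pathway_frequency <- function(M, genes) {
  if (!length(genes)) stop("empty gene set")
  missing_genes <- setdiff(genes, M$genes)
  if (length(missing_genes))
    stop("gene set members absent from matrix: ",
         paste(missing_genes, collapse = ", "))
  hit <- rowSums(M$indicator[, genes, drop = FALSE]) > 0
  list(n_mutated = sum(hit), n_patients = length(M$patients),
       frequency = mean(hit))
}

#' Cohort summary statistics
#'
#' Mean and range of mutated genes per patient (zero rows included), the
#' mutation-type breakdown over mutations (not patients), and the fraction
#' of non-synonymous mutations that are deleterious (nonsense, frameshift,
#' or damaging-consensus missense).
#'
#' @param M A [build_matrix()] result.
#' @return List with `mean_mutated_genes`, `range_mutated_genes`,
#'   `n_mutations`, `type_breakdown` (named fractions over
#'   substitution/deletion/insertion/complex), `deleterious_fraction`.
#' @export
summary_statistics <- function(M) {
  per_patient <- rowSums(M$indicator)
  types <- factor(M$detail$variant_type, levels = VARIANT_TYPES)
  n_mut <- nrow(M$detail)
  breakdown <- if (n_mut) as.numeric(table(types)) / n_mut else rep(0, 4)
  names(breakdown) <- VARIANT_TYPES
  list(mean_mutated_genes = mean(per_patient),
       range_mutated_genes = range(per_patient),
       n_mutations = n_mut,
       type_breakdown = breakdown,
       deleterious_fraction = if (n_mut) mean(M$detail$deleterious) else NA_real_)
}

#' Classify a mutation as clonal or subclonal from its VAF
#'
#' A heterozygous clonal mutation in a biopsy of purity `p` is expected at
#' VAF `p/2`. Calls below 20% VAF are very likely subclonal; calls above
#' 50% are clonal with likely loss of the second allele or uniparental
#' disomy. Boundaries: exactly 20% is clonal; the LOH/UPD flag requires
#' strictly more than 50%.
#'
#' @param vaf Variant allele frequency in `[0, 1]` (vectorized).
#' @param purity Tumor-cell content of the biopsy in `[0, 1]`, or `NA`.
#' @return data.frame with `vaf`, `label` (`subclonal` / `clonal` /
#'   `clonal_possible_LOH_or_UPD`) and `expected_clonal_vaf` (`purity / 2`,
#'   `NA` when purity is unknown).
#' @export
classify_clonality <- function(vaf, purity = NA_real_) {
  label <- ifelse(vaf < 0.20, "subclonal",
                  ifelse(vaf > 0.50, "clonal_possible_LOH_or_UPD", "clonal"))
  data.frame(vaf = vaf, label = label,
             expected_clonal_vaf = rep_len(purity / 2, length(vaf)),
             stringsAsFactors = FALSE)
}

#' Exact two-sided Fisher test for a 2x2 table
#'
#' Exact p-value by full hypergeometric enumeration with fixed margins,
#' summing the point probabilities of all tables no more probable than the
#' observed one (minimum-likelihood two-sided convention, with a relative
#' tie tolerance of 1e-7). Probabilities are accumulated on the
#' log-factorial scale, numerically stable up to table totals of order
#' 1e4. Any zero margin makes every table equally compatible and returns
#' p = 1.
#'
#' @param a,b,c,d Non-negative integer cell counts (`a` and `b` share the
#'   first row; `a` and `c` the first column).
#' @return Two-sided p-value.
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1.0)
  lo <- max(0L, r1 + c1 - n)
  hi <- min(r1, c1)
  support <- lo:hi
  ## log point probability of each achievable table with these margins
  logp <- lfactorial(r1) + lfactorial(n - r1) + lfactorial(c1) +
    lfactorial(n - c1) - lfactorial(n) -
    (lfactorial(support) + lfactorial(r1 - support) +
       lfactorial(c1 - support) + lfactorial(n - r1 - c1 + support))
  logp_obs <- logp[match(a, support)]
  keep <- logp <= logp_obs + 1e-7
  min(1, sum(exp(logp[keep])))
}

#' Mutual-exclusivity / co-occurrence screen
#'
#' Pairwise contingency analysis over the genes mutated in at least
#' `min_cases` patients. For each eligible pair the 2x2 table (both /
#' first only / second only / neither) is tested with
#' [fisher_exact_two_sided()]; the direction is negative (mutual
#' exclusivity) iff the observed co-occurrence count falls below its
#' expectation under independence. No multiple-testing correction is
#' applied by default; `adjust = "BH"` adds Benjamini-Hochberg adjusted
#' values.
#'
#' @param M A [build_matrix()] result.
#' @param min_cases Minimum number of mutated patients for a gene to enter
#'   the screen.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with one row per tested pair: counts, direction
#'   (`"+"`/`"-"`), `p_value` (and `p_adjusted` if requested); zero rows
#'   when fewer than two genes are eligible.
#' @export
cooccurrence_screen <- function(M, min_cases = 12L,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(min_cases >= 1)
  cnt <- colSums(M$indicator)
  eligible <- M$genes[cnt >= min_cases]
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      n_both = integer(), n_a_only = integer(),
                      n_b_only = integer(), n_neither = integer(),
                      direction = character(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  if (length(eligible) < 2) return(empty)
  pairs <- utils::combn(eligible, 2)
  n <- length(M$patients)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    ga <- pairs[1, k]; gb <- pairs[2, k]
    va <- M$indicator[, ga]; vb <- M$indicator[, gb]
    both <- sum(va & vb)
    expected_both <- sum(va) * sum(vb) / n
    data.frame(gene_a = ga, gene_b = gb,
               n_both = both, n_a_only = sum(va & !vb),
               n_b_only = sum(!va & vb), n_neither = sum(!va & !vb),
               direction = if (both < expected_both) "-" else "+",
               p_value = fisher_exact_two_sided(both, sum(va & !vb),
                                                sum(!va & vb),
                                                sum(!va & !vb)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out[order(out$p_value), , drop = FALSE]
}

#' Per-gene VAF summary
#'
#' Mean and standard deviation of the VAF of accepted non-synonymous
#' mutations per gene, with clonality label counts — the per-gene VAF
#' profile used to judge which genes carry mostly clonal versus mostly
#' subclonal mutations.
#'
#' @param M A [build_matrix()] result.
#' @return data.frame with `gene`, `n`, `mean_vaf`, `sd_vaf`,
#'   `n_subclonal`, `n_clonal`, `n_clonal_loh_upd`.
#' @export
vaf_by_gene <- function(M) {
  d <- M$detail
  if (!nrow(d))
    return(data.frame(gene = character(), n = integer(),
                      mean_vaf = numeric(), sd_vaf = numeric(),
                      n_subclonal = integer(), n_clonal = integer(),
                      n_clonal_loh_upd = integer(), stringsAsFactors = FALSE))
  lab <- classify_clonality(d$vaf)$label
  out <- do.call(rbind, lapply(split(seq_len(nrow(d)), d$gene), function(i) {
    data.frame(gene = d$gene[i[1]], n = length(i),
               mean_vaf = mean(d$vaf[i]), sd_vaf = stats::sd(d$vaf[i]),
               n_subclonal = sum(lab[i] == "subclonal"),
               n_clonal = sum(lab[i] == "clonal"),
               n_clonal_loh_upd = sum(lab[i] == "clonal_possible_LOH_or_UPD"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(-out$mean_vaf), , drop = FALSE]
}
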