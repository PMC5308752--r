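## Consequence classification of accepted variants, the five-tool damaging
## consensus, and protein-domain mapping. Coding context comes from the
## package's synthetic coding model (see synthetic_cds()); positions outside
## any coding model classify as "other" with a warning.

VARIANT_TYPES <- c("substitution", "deletion", "insertion", "complex")
PROTEIN_EFFECTS <- c("missense", "nonsense", "frameshift", "inframe_indel",
                     "synonymous", "other")

#' Classify a variant by allele shape
#'
#' Single-base 1:1 exchanges are substitutions; left-anchored allele pairs
#' where the shorter allele is a prefix of the longer are deletions (ref
#' longer) or insertions (alt longer); anything else — including multi-base
#' exchanges — is complex.
#'
#' @param ref,alt Non-empty allele strings, `ref != alt`.
#' @return One of `"substitution"`, `"deletion"`, `"insertion"`,
#'   `"complex"` (vectorized).
#' @export
classify_variant_type <- function(ref, alt) {
  if (any(!nzchar(ref)) || any(!nzchar(alt))) stop("empty allele")
  if (any(ref == alt)) stop("ref equals alt")
  nr <- nchar(ref); na <- nchar(alt)
  out <- rep("complex", length(ref))
  out[nr == 1L & na == 1L] <- "substitution"
  del <- nr > na & substr(ref, 1L, na) == alt
  out[del] <- "deletion"
  ins <- na > nr & substr(alt, 1L, nr) == ref
  out[ins] <- "insertion"
  out
}

#' Classify the protein-level effect of a coding variant
#'
#' Indels whose length is not a multiple of three shift the reading frame;
#' in-frame indels are length-preserving at the protein level.
#' Substitutions are evaluated on the reference codon: a stop gain is
#' nonsense, an amino-acid exchange missense, identity synonymous. Variants
#' without coding context (`cds_context = NULL`) classify as `"other"` with
#' a warning. Protein changes are reported as three-letter HGVS-like
#' strings (e.g. `"Leu265Pro"`, `"Pro2500fs"`).
#'
#' @param ref,alt Allele strings (reference strand).
#' @param variant_type From [classify_variant_type()].
#' @param cds_context List with `cds_pos`, `codon_number`, `frame`,
#'   `ref_codon`, `strand` (see [cds_context()]), or `NULL`.
#' @param warn Warn when context is missing.
#' @return List with `protein_effect`, `protein_change`, `protein_pos`.
#' @export
classify_protein_effect <- function(ref, alt, variant_type,
                                    cds_context = NULL, warn = TRUE) {
  none <- list(protein_effect = "other", protein_change = NA_character_,
               protein_pos = NA_integer_)
  if (is.null(cds_context)) {
    if (warn) warning("position outside supplied CDS; classified as 'other'")
    return(none)
  }
  pos_aa <- cds_context$codon_number
  if (variant_type %in% c("deletion", "insertion")) {
    indel_len <- abs(nchar(ref) - nchar(alt))
    aa_ref <- .AA3[translate_codon(cds_context$ref_codon)]
    if (indel_len %% 3L != 0L) {
      list(protein_effect = "frameshift",
           protein_change = paste0(aa_ref, pos_aa, "fs"),
           protein_pos = pos_aa)
    } else {
      list(protein_effect = "inframe_indel",
           protein_change = paste0(aa_ref, pos_aa,
                                   if (variant_type == "deletion") "del" else "ins"),
           protein_pos = pos_aa)
    }
  } else if (variant_type == "substitution") {
    b_ref <- toupper(ref); b_alt <- toupper(alt)
    if (identical(cds_context$strand, "-")) {
      b_ref <- .COMPLEMENT[b_ref]; b_alt <- .COMPLEMENT[b_alt]
    }
    codon <- cds_context$ref_codon
    if (substr(codon, cds_context$frame + 1L, cds_context$frame + 1L) != b_ref)
      warning("reference allele does not match coding model at codon ",
              pos_aa)
    alt_codon <- codon
    substr(alt_codon, cds_context$frame + 1L, cds_context$frame + 1L) <- b_alt
    aa_ref <- translate_codon(codon)
    aa_alt <- translate_codon(alt_codon)
    change <- paste0(.AA3[aa_ref], pos_aa, .AA3[aa_alt])
    if (aa_alt == "*") {
      list(protein_effect = "nonsense", protein_change = change,
           protein_pos = pos_aa)
    } else if (aa_alt == aa_ref) {
      list(protein_effect = "synonymous", protein_change = change,
           protein_pos = pos_aa)
    } else {
      list(protein_effect = "missense", protein_change = change,
           protein_pos = pos_aa)
    }
  } else {
    ## complex events are not resolved at protein level
    list(protein_effect = "other", protein_change = NA_character_,
         protein_pos = pos_aa)
  }
}

#' Five-tool damaging consensus
#'
#' A substitution is scored damaging when at least three of the five
#' prediction tools (SIFT, PolyPhen2 HDIV, PolyPhen2 HVAR, LRT,
#' MutationTaster) agree on `damaging`; symmetrically, tolerated when at
#' least three agree on `tolerated`; otherwise — including ties and
#' unreachable quorums from missing verdicts — `undetermined`.
#'
#' @param verdicts Character vector of five verdicts, each one of
#'   `"damaging"`, `"tolerated"`, `"missing"`.
#' @return `"yes"`, `"no"` or `"undetermined"`.
#' @export
damaging_consensus <- function(verdicts) {
  stopifnot(length(verdicts) == 5)
  if (!all(verdicts %in% c("damaging", "tolerated", "missing")))
    stop("verdicts must be 'damaging', 'tolerated' or 'missing'")
  if (sum(verdicts == "damaging") >= 3) "yes"
  else if (sum(verdicts == "tolerated") >= 3) "no"
  else "undetermined"
}

#' Map a protein position to its domain
#'
#' Returns the unique domain interval containing the position, or `NA` for
#' inter-domain positions; unknown genes return `NA` with a warning.
#'
#' @param gene Gene symbol.
#' @param protein_pos 1-based amino-acid position.
#' @param domain_map From [read_domain_map()].
#' @return Domain name or `NA_character_`.
#' @export
map_to_domain <- function(gene, protein_pos, domain_map = read_domain_map()) {
  if (is.na(protein_pos) || protein_pos < 1) return(NA_character_)
  d <- domain_map[domain_map$gene == gene, , drop = FALSE]
  if (nrow(d) == 0) {
    warning("no domain annotation for gene ", gene)
    return(NA_character_)
  }
  hit <- d$aa_start <= protein_pos & d$aa_end >= protein_pos
  if (any(hit)) d$domain[which(hit)[1]] else NA_character_
}

#' Deleterious flag for an annotated mutation
#'
#' Non-synonymous mutations count as deleterious when they are nonsense or
#' frameshift, or when they are replacement mutations with a damaging
#' consensus vote; missense calls with an undetermined vote are
#' conservatively not flagged.
#'
#' @param protein_effect One of the protein effect classes.
#' @param damaging Consensus vote (`"yes"`/`"no"`/`"undetermined"`).
#' @return Logical (vectorized).
#' @export
deleterious_flag <- function(protein_effect, damaging) {
  protein_effect %in% c("nonsense", "frameshift") |
    (protein_effect == "missense" & damaging == "yes")
}

#' Annotate filter-accepted variants
#'
#' Joins accepted and review-accepted filter decisions with the coding
#' model, predictor verdicts and domain map, producing one annotated
#' mutation per surviving call: variant type, protein effect and change,
#' damaging consensus (defined only for missense calls with at least three
#' non-missing verdicts), deleterious flag, and protein domain.
#'
#' @param decisions Output of [run_filter_cascade()].
#' @param verdicts Predictor verdict table (from
#'   [read_predictor_verdicts()]), or `NULL`.
#' @param domain_map From [read_domain_map()].
#' @return data.frame of annotated mutations (accepted calls only), with
#'   `synonymous` calls retained and flagged so downstream statistics can
#'   exclude them.
#' @export
annotate_mutations <- function(decisions, verdicts = NULL,
                               domain_map = read_domain_map()) {
  acc <- decisions[decisions$verdict != "reject", , drop = FALSE]
  n <- nrow(acc)
  variant_type <- if (n) classify_variant_type(acc$ref, acc$alt) else character()
  protein_effect <- character(n); protein_change <- character(n)
  protein_pos <- integer(n); damaging <- character(n); domain <- character(n)
  vkeys <- if (!is.null(verdicts) && nrow(verdicts))
    variant_key(verdicts$chrom, verdicts$pos, verdicts$ref, verdicts$alt)
  else character()
  for (i in seq_len(n)) {
    ctx <- cds_context(acc$gene[i], effective_cds_query_pos(acc$pos[i],
                                                            variant_type[i]))
    eff <- classify_protein_effect(acc$ref[i], acc$alt[i], variant_type[i],
                                   ctx, warn = FALSE)
    protein_effect[i] <- eff$protein_effect
    protein_change[i] <- eff$protein_change
    protein_pos[i] <- if (is.na(eff$protein_pos)) NA_integer_ else eff$protein_pos
    dmg <- "undetermined"
    if (protein_effect[i] == "missense" && length(vkeys)) {
      j <- match(variant_key(acc$chrom[i], acc$pos[i], acc$ref[i],
                             acc$alt[i]), vkeys)
      if (!is.na(j)) {
        vv <- unlist(verdicts[j, PREDICTOR_TOOLS], use.names = FALSE)
        if (sum(vv != "missing") >= 3) dmg <- damaging_consensus(vv)
        else dmg <- "undetermined"
      }
    }
    damaging[i] <- if (protein_effect[i] == "missense") dmg else "undetermined"
    domain[i] <- if (acc$gene[i] %in% domain_map$gene && !is.na(protein_pos[i]))
      map_to_domain(acc$gene[i], protein_pos[i], domain_map)
    else NA_character_
  }
  out <- acc
  out$variant_type <- variant_type
  out$protein_effect <- protein_effect
  out$protein_change <- protein_change
  out$protein_pos <- protein_pos
  out$damaging <- damaging
  out$deleterious <- deleterious_flag(protein_effect, damaging)
  out$domain <- domain
  rownames(out) <- NULL
  out
}

## indels are left-anchored at the base before the event; the affected codon
## is the one holding the first changed base
effective_cds_query_pos <- function(pos, variant_type) {
  if (variant_type %in% c("deletion", "insertion")) pos + 1L else pos
}

#' Lollipop export of mutation positions
#'
#' Per-gene protein-position summary suitable for external lollipop
#' plotting: one row per (gene, protein position, effect) with its
#' recurrence count and domain.
#'
#' @param annotated Output of [annotate_mutations()].
#' @param domain_map From [read_domain_map()].
#' @return data.frame with `gene`, `protein_pos`, `protein_effect`,
#'   `count`, `domain`.
#' @export
lollipop_table <- function(annotated, domain_map = read_domain_map()) {
  x <- annotated[!is.na(annotated$protein_pos) &
                   annotated$protein_effect != "synonymous", , drop = FALSE]
  if (!nrow(x))
    return(data.frame(gene = character(), protein_pos = integer(),
                      protein_effect = character(), count = integer(),
                      domain = character(), stringsAsFactors = FALSE))
  agg <- stats::aggregate(list(count = rep(1L, nrow(x))),
                          by = list(gene = x$gene,
                                    protein_pos = x$protein_pos,
                                    protein_effect = x$protein_effect),
                          FUN = sum)
  agg$domain <- vapply(seq_len(nrow(agg)), function(i) {
    if (agg$gene[i] %in% domain_map$gene)
      map_to_domain(agg$gene[i], agg$protein_pos[i], domain_map)
    else NA_character_
  }, "")
  agg[order(agg$gene, agg$protein_pos), , drop = FALSE]
}
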