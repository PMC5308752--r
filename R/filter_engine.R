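## The variant-filter cascade for FFPE amplicon call tables. Each rule maps
## to one reason code; a variant is rejected iff at least one code fires.
## Calls in the 5-20% VAF band that survive every automatic rule are kept
## with the distinct verdict "review_accept", a reproducible codification of
## the study's manual inspection of that band.

FILTER_REASONS <- c("LOW_PHRED", "LOW_COVERAGE", "VAF_BELOW_MIN",
                    "PRIMER_PROXIMAL", "SINGLE_AMPLICON_ONLY",
                    "AMBIGUOUS_MAPPING", "KNOWN_SNP", "BLACKLISTED")

#' Filter cascade configuration
#'
#' Thresholds of the variant-filter cascade. Defaults encode the published
#' filter settings for FFPE amplicon data: variant phred quality strictly
#' above 30; positions with coverage below 100 reads not considered (100
#' passes); variants supported by fewer than 5% of reads rejected as likely
#' FFPE/PCR noise; variants at 20% or more auto-accepted; the 5-20% band
#' flagged for review. `primer_proximity_bp` is the insert-edge window
#' within which a call is considered primer-proximal (the published rule
#' names no distance; 5 bp is a conventional choice).
#' `min_overlap_coverage` is the minimum read depth an overlapping amplicon
#' needs before absence of variant reads there counts as discordance.
#'
#' @param min_phred Exclusive phred threshold (reject at or below).
#' @param min_coverage Inclusive minimum coverage.
#' @param vaf_reject_below Reject below this VAF.
#' @param vaf_auto_accept_at Auto-accept at or above this VAF.
#' @param primer_proximity_bp Insert-edge window in bp.
#' @param min_overlap_support_reads Minimum variant reads expected in a
#'   well-covered overlapping amplicon.
#' @param min_overlap_coverage Minimum total reads for an amplicon to enter
#'   the overlap-concordance comparison.
#' @param blacklist data.frame of recurrent-artifact sites keyed by
#'   (chrom, pos, ref, alt); defaults to [default_blacklist()].
#' @return List of class `filter_config`.
#' @export
filter_config <- function(min_phred = 30,
                          min_coverage = 100L,
                          vaf_reject_below = 0.05,
                          vaf_auto_accept_at = 0.20,
                          primer_proximity_bp = 5L,
                          min_overlap_support_reads = 1L,
                          min_overlap_coverage = 20L,
                          blacklist = default_blacklist()) {
  stopifnot(vaf_reject_below >= 0, vaf_reject_below <= vaf_auto_accept_at,
            vaf_auto_accept_at <= 1, min_phred > 0, min_coverage > 0,
            primer_proximity_bp >= 0, min_overlap_support_reads >= 0,
            min_overlap_coverage >= 0)
  structure(list(min_phred = min_phred,
                 min_coverage = as.integer(min_coverage),
                 vaf_reject_below = vaf_reject_below,
                 vaf_auto_accept_at = vaf_auto_accept_at,
                 primer_proximity_bp = as.integer(primer_proximity_bp),
                 min_overlap_support_reads = as.integer(min_overlap_support_reads),
                 min_overlap_coverage = as.integer(min_overlap_coverage),
                 blacklist = blacklist),
            class = "filter_config")
}

#' Read a filter configuration from YAML
#'
#' YAML keys mirror the [filter_config()] arguments; `blacklist` may name a
#' TSV path. Missing keys take the defaults.
#'
#' @param path YAML file.
#' @return `filter_config` object.
#' @export
read_filter_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$blacklist) && is.character(y$blacklist))
    y$blacklist <- default_blacklist(y$blacklist)
  do.call(filter_config, y)
}

#' Quality and coverage gate
#'
#' `LOW_PHRED` fires iff the variant quality is at or below the (strict)
#' phred threshold; `LOW_COVERAGE` iff total reads fall below the minimum
#' coverage (the boundary value passes).
#'
#' @param phred Variant phred quality.
#' @param reads_total Total coverage at the position.
#' @param cfg A [filter_config()].
#' @return Character vector of reason codes (possibly empty).
#' @export
quality_coverage_gate <- function(phred, reads_total, cfg = filter_config()) {
  codes <- character()
  if (is.na(phred) || phred <= cfg$min_phred) codes <- c(codes, "LOW_PHRED")
  if (is.na(reads_total) || reads_total < cfg$min_coverage)
    codes <- c(codes, "LOW_COVERAGE")
  codes
}

#' VAF band classification
#'
#' Below `vaf_reject_below`: reject. In `[vaf_reject_below,
#' vaf_auto_accept_at)`: review. At or above `vaf_auto_accept_at`: accept.
#' Both lower boundaries are inclusive ("at least").
#'
#' @param reads_variant,reads_total Read counts; `reads_total` must be
#'   positive (VAF undefined otherwise).
#' @param cfg A [filter_config()].
#' @return One of `"reject"`, `"review"`, `"accept"`.
#' @export
vaf_band <- function(reads_variant, reads_total, cfg = filter_config()) {
  if (is.na(reads_total) || reads_total <= 0)
    stop("VAF undefined: reads_total must be positive")
  vaf <- reads_variant / reads_total
  if (vaf < cfg$vaf_reject_below) "reject"
  else if (vaf < cfg$vaf_auto_accept_at) "review"
  else "accept"
}

## amplicons of `panel` whose insert contains (chrom, pos); restricted to
## `ids` when the call names its covering amplicons
covering_amplicons <- function(panel, chrom, pos, ids = NULL) {
  p <- panel[panel$chrom == chrom & panel$insert_start <= pos &
               panel$insert_end >= pos, , drop = FALSE]
  if (!is.null(ids) && length(ids))
    p <- p[p$amplicon_id %in% ids, , drop = FALSE]
  p
}

#' Primer proximity check
#'
#' A call is primer-proximal iff, in every amplicon covering the position,
#' the distance from the position to the nearer insert edge is below
#' `primer_proximity_bp`; a call interior to at least one covering amplicon
#' passes. Positions outside all panel inserts cannot be assessed and fall
#' back to `AMBIGUOUS_MAPPING`.
#'
#' @param chrom,pos Variant position.
#' @param panel Amplicon panel (from [read_amplicon_panel()]).
#' @param cfg A [filter_config()].
#' @param amplicon_ids Optional restriction to the call's covering
#'   amplicons.
#' @return `"PRIMER_PROXIMAL"`, `"AMBIGUOUS_MAPPING"` or `character(0)`.
#' @export
primer_proximity_check <- function(chrom, pos, panel, cfg = filter_config(),
                                   amplicon_ids = NULL) {
  cov <- covering_amplicons(panel, chrom, pos, amplicon_ids)
  if (nrow(cov) == 0) return("AMBIGUOUS_MAPPING")
  edge_dist <- pmin(pos - cov$insert_start, cov$insert_end - pos)
  if (all(edge_dist < cfg$primer_proximity_bp)) "PRIMER_PROXIMAL"
  else character()
}

#' Overlap concordance check
#'
#' When a position is covered by overlapping amplicons, a real variant is
#' expected in the reads of each sufficiently covered amplicon.
#' `SINGLE_AMPLICON_ONLY` fires iff some covering amplicon with at least
#' `min_overlap_coverage` total reads has fewer than
#' `min_overlap_support_reads` variant reads while another has at least
#' that many. With per-amplicon counts for fewer than two well-covered
#' amplicons the rule is not evaluable and returns no code.
#'
#' @param amplicon_counts data.frame with `amplicon_id`, `total`, `variant`
#'   for the call (e.g. from [parse_amplicon_counts()]).
#' @param cfg A [filter_config()].
#' @return `"SINGLE_AMPLICON_ONLY"` or `character(0)`.
#' @export
overlap_concordance_check <- function(amplicon_counts,
                                      cfg = filter_config()) {
  if (is.null(amplicon_counts) || nrow(amplicon_counts) < 2)
    return(character())
  ok <- amplicon_counts$total >= cfg$min_overlap_coverage
  if (sum(ok) < 2) return(character())
  v <- amplicon_counts$variant[ok]
  if (any(v < cfg$min_overlap_support_reads) &&
      any(v >= cfg$min_overlap_support_reads)) "SINGLE_AMPLICON_ONLY"
  else character()
}

#' Known-SNP and blacklist check
#'
#' `KNOWN_SNP` fires iff the full allele key (chrom, pos, ref, alt) matches
#' a known-polymorphism record; `BLACKLISTED` iff it matches a configured
#' recurrent-artifact site. Matching is on the full key: a different alt at
#' the same position does not fire.
#'
#' @param chrom,pos,ref,alt Variant key.
#' @param snp_db Known-SNP data.frame (from [read_snp_table()]), or `NULL`.
#' @param cfg A [filter_config()].
#' @return Character vector of reason codes.
#' @export
snp_and_blacklist_check <- function(chrom, pos, ref, alt, snp_db = NULL,
                                    cfg = filter_config()) {
  key <- variant_key(chrom, pos, ref, alt)
  codes <- character()
  if (!is.null(snp_db) && nrow(snp_db) &&
      key %in% variant_key(snp_db$chrom, snp_db$pos, snp_db$ref, snp_db$alt))
    codes <- c(codes, "KNOWN_SNP")
  bl <- cfg$blacklist
  if (!is.null(bl) && nrow(bl) &&
      key %in% variant_key(bl$chrom, bl$pos, bl$ref, bl$alt))
    codes <- c(codes, "BLACKLISTED")
  codes
}

#' Run the full filter cascade
#'
#' Applies, per variant and in order: the quality/coverage gate, the VAF
#' band, mapping-ambiguity (any covering amplicon flagged
#' `mapping_ambiguous`, or position outside all panel inserts), primer
#' proximity, overlap concordance, and the known-SNP/blacklist check.
#' Verdicts: `reject` iff any reason code fired; otherwise `accept` for
#' calls at or above the auto-accept VAF and `review_accept` for calls in
#' the review band (all automatic checks passed). Decisions are
#' deterministic given inputs and configuration and independent of input
#' order.
#'
#' @param variants Variant table (from [read_variant_table()] or
#'   [simulate_cohort()]).
#' @param panel Amplicon panel.
#' @param snp_db Known-SNP table or `NULL`.
#' @param cfg A [filter_config()].
#' @return data.frame with the variant keys, `vaf`, `verdict`
#'   (`accept`/`review_accept`/`reject`) and `reasons`
#'   (`;`-joined codes, `""` when accepted).
#' @export
run_filter_cascade <- function(variants, panel, snp_db = NULL,
                               cfg = filter_config()) {
  n <- nrow(variants)
  empty <- data.frame(patient_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      gene = character(), vaf = numeric(),
                      verdict = character(), reasons = character(),
                      stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  verdict <- character(n)
  reasons <- character(n)
  vaf <- ifelse(variants$reads_total > 0,
                variants$reads_variant / variants$reads_total, NA_real_)
  ## precompute key lookups
  snp_keys <- if (!is.null(snp_db) && nrow(snp_db))
    variant_key(snp_db$chrom, snp_db$pos, snp_db$ref, snp_db$alt) else character()
  bl <- cfg$blacklist
  bl_keys <- if (!is.null(bl) && nrow(bl))
    variant_key(bl$chrom, bl$pos, bl$ref, bl$alt) else character()
  keys <- variant_key(variants$chrom, variants$pos, variants$ref,
                      variants$alt)
  counts_long <- parse_amplicon_counts(variants$amplicon_counts)
  counts_by_row <- if (nrow(counts_long))
    split(counts_long, counts_long$row) else list()
  amp_ids <- strsplit(ifelse(is.na(variants$amplicons), "",
                             variants$amplicons), ";", fixed = TRUE)
  for (i in seq_len(n)) {
    codes <- quality_coverage_gate(variants$phred[i], variants$reads_total[i],
                                   cfg)
    band <- if (!is.na(variants$reads_total[i]) && variants$reads_total[i] > 0)
      vaf_band(variants$reads_variant[i], variants$reads_total[i], cfg)
    else "reject"
    if (band == "reject") codes <- c(codes, "VAF_BELOW_MIN")
    cov <- covering_amplicons(panel, variants$chrom[i], variants$pos[i],
                              amp_ids[[i]])
    if (nrow(cov) == 0) {
      codes <- c(codes, "AMBIGUOUS_MAPPING")
    } else {
      if (any(cov$mapping_ambiguous)) codes <- c(codes, "AMBIGUOUS_MAPPING")
      edge_dist <- pmin(variants$pos[i] - cov$insert_start,
                        cov$insert_end - variants$pos[i])
      if (all(edge_dist < cfg$primer_proximity_bp))
        codes <- c(codes, "PRIMER_PROXIMAL")
    }
    cb <- counts_by_row[[as.character(i)]]
    codes <- c(codes, overlap_concordance_check(cb, cfg))
    key <- keys[i]
    if (key %in% snp_keys) codes <- c(codes, "KNOWN_SNP")
    if (key %in% bl_keys) codes <- c(codes, "BLACKLISTED")
    codes <- intersect(FILTER_REASONS, codes)  # canonical order, unique
    verdict[i] <- if (length(codes)) "reject"
    else if (band == "accept") "accept" else "review_accept"
    reasons[i] <- paste(codes, collapse = ";")
  }
  out <- data.frame(patient_id = variants$patient_id,
                    chrom = variants$chrom, pos = variants$pos,
                    ref = variants$ref, alt = variants$alt,
                    gene = variants$gene, vaf = vaf,
                    verdict = verdict, reasons = reasons,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write filter decisions as TSV
#' @param decisions Output of [run_filter_cascade()].
#' @param path Output file.
#' @export
write_filter_decisions <- function(decisions, path) {
  utils::write.table(decisions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
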