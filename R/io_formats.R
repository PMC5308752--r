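## Readers and writers for the external table dialects: variant call tables
## (TSV stand-in for the caller output, plus VCF 4.x), the amplicon panel
## (extended BED), known-SNP lists, damaging-predictor verdicts, and the
## clinical table. All internal coordinates are 1-based inclusive (GRCh37
## convention); BED input is converted on read.

VARIANT_COLUMNS <- c("patient_id", "chrom", "pos", "ref", "alt", "gene",
                     "reads_total", "reads_variant", "phred",
                     "amplicons", "amplicon_counts")

#' Read a variant call table
#'
#' Reads per-position candidate variant calls for one or more patient
#' samples. Two dialects are supported:
#'
#' * `"tsv"` — the package's documented tab-separated dialect with header
#'   columns `patient_id, chrom, pos, ref, alt, gene, reads_total,
#'   reads_variant, phred, amplicons, amplicon_counts`. `amplicons` is a
#'   `;`-joined list of panel amplicon ids covering the position;
#'   `amplicon_counts` encodes per-amplicon read support as
#'   `id:total:variant;...` or `.` when unavailable. This dialect stands in
#'   for the upstream caller's export, whose schema is not standardised.
#' * `"vcf"` — VCF 4.x (single sample per file) read via the vcfR package;
#'   coverage from FORMAT `DP` and variant support from FORMAT `AD`
#'   (ref,alt), quality from `QUAL`, gene symbol from INFO `GENE`, covering
#'   amplicons from INFO `AMP` and per-amplicon counts from INFO `AMPC`.
#'
#' The variant allele frequency is always recomputed as
#' `reads_variant / reads_total` and never taken from the file.
#'
#' @param path Input file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param strict If `TRUE` (default) invalid rows abort with row-numbered
#'   messages; if `FALSE` they are dropped with a warning.
#' @return data.frame of variant calls with a computed `vaf` column.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf"),
                               strict = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  x <- if (dialect == "tsv") .read_variant_tsv(path) else .read_variant_vcf(path)
  validate_variant_table(x, strict = strict)
}

.read_variant_tsv <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "",
                         colClasses = "character")
  missing_cols <- setdiff(VARIANT_COLUMNS, names(x))
  if (length(missing_cols))
    stop("variant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  x <- x[VARIANT_COLUMNS]
  for (col in c("pos", "reads_total", "reads_variant")) {
    v <- suppressWarnings(as.integer(x[[col]]))
    bad <- which(is.na(v) & !is.na(x[[col]]))
    if (length(bad))
      stop("non-numeric '", col, "' in row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    x[[col]] <- v
  }
  x$phred <- suppressWarnings(as.numeric(x$phred))
  x
}

.read_variant_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading the VCF dialect requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  if (nrow(fix) == 0)
    return(stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(VARIANT_COLUMNS))),
      VARIANT_COLUMNS))
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2) stop("missing coverage: VCF has no sample genotype columns")
  sample_id <- colnames(gt)[2]
  fmt <- strsplit(as.character(gt[, "FORMAT"]), ":", fixed = TRUE)
  val <- strsplit(as.character(gt[, 2]), ":", fixed = TRUE)
  pick <- function(i, key) {
    if (i > length(fmt) || i > length(val)) return(NA_character_)
    j <- match(key, fmt[[i]])
    if (is.na(j) || j > length(val[[i]])) NA_character_ else val[[i]][j]
  }
  n <- nrow(fix)
  dp <- vapply(seq_len(n), pick, "", key = "DP")
  ad <- vapply(seq_len(n), pick, "", key = "AD")
  if (all(is.na(dp)) || all(is.na(ad)))
    stop("missing coverage: VCF records lack DP/AD depth fields")
  info_get <- function(key) {
    out <- rep(NA_character_, n)
    hit <- grepl(paste0(key, "="), fix$INFO)
    out[hit] <- sub(paste0(".*", key, "="), "",
                    regmatches(fix$INFO, regexpr(paste0(key, "=[^;]*"),
                                                 fix$INFO)))
    out
  }
  data.frame(
    patient_id = sample_id,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    gene = info_get("GENE"),
    reads_total = as.integer(dp),
    reads_variant = as.integer(vapply(strsplit(ad, ","), function(z)
      if (length(z) >= 2) z[2] else NA_character_, "")),
    phred = as.numeric(fix$QUAL),
    amplicons = gsub(",", ";", info_get("AMP"), fixed = TRUE),
    amplicon_counts = gsub(",", ";", info_get("AMPC"), fixed = TRUE),
    stringsAsFactors = FALSE)
}

#' Validate a variant call table
#'
#' Checks the structural invariants of a variant table: positive 1-based
#' positions, `ref != alt`, non-negative counts with
#' `reads_variant <= reads_total`, and per-amplicon totals (when present)
#' summing to `reads_total`. Adds the computed `vaf` column.
#'
#' @inheritParams read_variant_table
#' @param x data.frame with the variant TSV dialect columns.
#' @return The validated data.frame with `vaf`.
#' @export
validate_variant_table <- function(x, strict = TRUE) {
  x$amplicons[is.na(x$amplicons) | x$amplicons == "."] <- ""
  x$amplicon_counts[is.na(x$amplicon_counts)] <- "."
  problems <- character(nrow(x))
  flag <- function(cond, msg) {
    i <- which(cond)
    problems[i] <<- ifelse(problems[i] == "", msg, paste(problems[i], msg,
                                                         sep = "; "))
  }
  flag(is.na(x$pos) | x$pos < 1, "pos must be >= 1")
  flag(is.na(x$ref) | is.na(x$alt) | x$ref == "" | x$alt == "", "empty allele")
  flag(!is.na(x$ref) & !is.na(x$alt) & x$ref == x$alt, "ref equals alt")
  flag(is.na(x$reads_total) | is.na(x$reads_variant) |
         x$reads_total < 0 | x$reads_variant < 0, "non-numeric or negative counts")
  flag(!is.na(x$reads_total) & !is.na(x$reads_variant) &
         x$reads_variant > x$reads_total, "reads_variant > reads_total")
  pc <- parse_amplicon_counts(x$amplicon_counts)
  if (nrow(pc)) {
    tot <- tapply(pc$total, pc$row, sum)
    rows <- as.integer(names(tot))
    mism <- rows[!is.na(x$reads_total[rows]) & tot != x$reads_total[rows]]
    flag(seq_len(nrow(x)) %in% mism, "per-amplicon totals != reads_total")
  }
  bad <- which(problems != "")
  if (length(bad)) {
    msg <- paste0("row ", bad, ": ", problems[bad], collapse = "\n  ")
    if (strict) stop("invalid variant row(s):\n  ", msg)
    warning("dropping invalid variant row(s):\n  ", msg)
    x <- x[-bad, , drop = FALSE]
  }
  x$vaf <- ifelse(x$reads_total > 0, x$reads_variant / x$reads_total, NA_real_)
  rownames(x) <- NULL
  x
}

#' Parse per-amplicon count strings
#'
#' Expands `id:total:variant;...` encodings into a long table. `"."` or
#' empty strings yield no rows (per-amplicon support is then not evaluable).
#'
#' @param s Character vector of encoded counts.
#' @return data.frame with `row` (index into `s`), `amplicon_id`, `total`,
#'   `variant`.
#' @export
parse_amplicon_counts <- function(s) {
  s[is.na(s)] <- "."
  keep <- which(s != "." & s != "")
  if (!length(keep))
    return(data.frame(row = integer(), amplicon_id = character(),
                      total = integer(), variant = integer(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(s[keep], ";", fixed = TRUE)
  row <- rep(keep, lengths(parts))
  triplet <- strsplit(unlist(parts), ":", fixed = TRUE)
  ok <- lengths(triplet) == 3
  if (!all(ok)) stop("malformed amplicon_counts entry: ",
                     paste(unlist(parts)[!ok][1]))
  m <- matrix(unlist(triplet), ncol = 3, byrow = TRUE)
  data.frame(row = row, amplicon_id = m[, 1],
             total = as.integer(m[, 2]), variant = as.integer(m[, 3]),
             stringsAsFactors = FALSE)
}

encode_amplicon_counts <- function(ids, totals, variants) {
  if (!length(ids)) return(".")
  paste(paste(ids, totals, variants, sep = ":"), collapse = ";")
}

#' Write a variant call table (TSV dialect)
#' @param x Variant table (as from [read_variant_table()]).
#' @param path Output file.
#' @export
write_variant_table <- function(x, path) {
  utils::write.table(x[VARIANT_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a variant call table as single-sample VCF 4.2
#'
#' Emits one minimal VCF per patient sample: `QUAL` carries the phred
#' score, FORMAT `DP`/`AD` the read counts, INFO `GENE`/`AMP`/`AMPC` the
#' gene symbol, covering amplicons and per-amplicon counts.
#'
#' @param x Variant table for a single patient.
#' @param path Output file.
#' @export
write_variant_vcf <- function(x, path) {
  if (length(unique(x$patient_id)) > 1)
    stop("VCF output is single-sample; split by patient_id first")
  sample_id <- if (nrow(x)) x$patient_id[1] else "SAMPLE"
  hdr <- c("##fileformat=VCFv4.2",
           "##source=oamlmut",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
           "##INFO=<ID=AMP,Number=.,Type=String,Description=\"Covering amplicon ids\">",
           "##INFO=<ID=AMPC,Number=.,Type=String,Description=\"Per-amplicon id:total:variant counts\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample_id, sep = "\t"))
  info <- paste0("GENE=", x$gene,
                 ifelse(x$amplicons == "", "",
                        paste0(";AMP=", gsub(";", ",", x$amplicons))),
                 ifelse(x$amplicon_counts == ".", "",
                        paste0(";AMPC=", gsub(";", ",", x$amplicon_counts))))
  body <- paste(x$chrom, x$pos, ".", x$ref, x$alt, format(x$phred), "PASS",
                info, "DP:AD",
                paste0(x$reads_total, ":",
                       x$reads_total - x$reads_variant, ",", x$reads_variant),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

## --- amplicon panel ---------------------------------------------------------

#' Read an amplicon panel (extended BED)
#'
#' The panel dialect is 8-10 column BED: `chrom, start, end` (0-based
#' half-open, spanning the full amplicon including primers), `amplicon_id`,
#' `score`, `strand`, `primer_len_5p`, `primer_len_3p`, and optionally
#' `gene` and `mapping_ambiguous` (0/1, flagging amplicons with homologous
#' off-target loci). Coordinates are converted to the 1-based inclusive
#' insert (primer-trimmed) interval; strand is parsed but ignored by all
#' computations.
#'
#' @param path Panel BED file.
#' @return data.frame sorted by (chrom, insert_start) with columns
#'   `amplicon_id`, `chrom`, `insert_start`, `insert_end`, `primer_len_5p`,
#'   `primer_len_3p`, `gene`, `mapping_ambiguous`, `strand`.
#' @export
read_amplicon_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  empty <- data.frame(amplicon_id = character(), chrom = character(),
                      insert_start = integer(), insert_end = integer(),
                      primer_len_5p = integer(), primer_len_3p = integer(),
                      gene = character(), mapping_ambiguous = logical(),
                      strand = character(), stringsAsFactors = FALSE)
  first <- readLines(path, n = 1)
  if (!length(first) || !nzchar(first)) {
    warning("empty panel file: ", path)
    return(empty)
  }
  x <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "")
  if (ncol(x) < 8) stop("panel BED needs >= 8 columns, got ", ncol(x))
  names(x)[1:8] <- c("chrom", "start", "end", "amplicon_id", "score",
                     "strand", "primer_len_5p", "primer_len_3p")
  gene <- if (ncol(x) >= 9) as.character(x[[9]]) else NA_character_
  ambig <- if (ncol(x) >= 10) as.integer(x[[10]]) != 0 else FALSE
  if (any(x$start >= x$end))
    stop("panel interval with start >= end: ",
         x$amplicon_id[which(x$start >= x$end)[1]])
  if (anyDuplicated(x$amplicon_id))
    stop("duplicate amplicon_id: ",
         x$amplicon_id[duplicated(x$amplicon_id)][1])
  if (any(x$primer_len_5p < 0 | x$primer_len_3p < 0))
    stop("negative primer length")
  out <- data.frame(
    amplicon_id = x$amplicon_id,
    chrom = x$chrom,
    insert_start = x$start + 1L + x$primer_len_5p,
    insert_end = x$end - x$primer_len_3p,
    primer_len_5p = x$primer_len_5p,
    primer_len_3p = x$primer_len_3p,
    gene = gene,
    mapping_ambiguous = ambig,
    strand = x$strand,
    stringsAsFactors = FALSE)
  if (any(out$insert_start > out$insert_end))
    stop("primer lengths exceed amplicon: ",
         out$amplicon_id[which(out$insert_start > out$insert_end)[1]])
  out[order(out$chrom, out$insert_start), , drop = FALSE]
}

#' Write an amplicon panel as extended BED
#' @param panel Panel data.frame (as from [read_amplicon_panel()]).
#' @param path Output file.
#' @export
write_amplicon_panel <- function(panel, path) {
  bed <- data.frame(
    chrom = panel$chrom,
    start = panel$insert_start - 1L - panel$primer_len_5p,
    end = panel$insert_end + panel$primer_len_3p,
    amplicon_id = panel$amplicon_id,
    score = 0L,
    strand = panel$strand,
    primer_len_5p = panel$primer_len_5p,
    primer_len_3p = panel$primer_len_3p,
    gene = panel$gene,
    mapping_ambiguous = as.integer(panel$mapping_ambiguous))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Overlapping amplicon pairs
#'
#' All pairs of panel amplicons whose primer-trimmed inserts share at least
#' one base on the same chromosome.
#'
#' @param panel Panel data.frame.
#' @return data.frame with columns `amplicon_a`, `amplicon_b`,
#'   `overlap_bp`.
#' @export
overlapping_pairs <- function(panel) {
  out <- list()
  for (chr in unique(panel$chrom)) {
    p <- panel[panel$chrom == chr, , drop = FALSE]
    p <- p[order(p$insert_start), , drop = FALSE]
    n <- nrow(p)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      j <- i + 1
      while (j <= n && p$insert_start[j] <= p$insert_end[i]) {
        ov <- min(p$insert_end[i], p$insert_end[j]) - p$insert_start[j] + 1L
        out[[length(out) + 1L]] <- data.frame(
          amplicon_a = p$amplicon_id[i], amplicon_b = p$amplicon_id[j],
          overlap_bp = ov, stringsAsFactors = FALSE)
        j <- j + 1
      }
    }
  }
  if (!length(out))
    return(data.frame(amplicon_a = character(), amplicon_b = character(),
                      overlap_bp = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

## --- SNP list and predictor verdicts ---------------------------------------

#' Read a known-SNP list
#'
#' Tab-separated table of known polymorphisms (dbSNP-build style) keyed by
#' (chrom, pos, ref, alt), with an optional `source` tag column.
#'
#' @param path SNP TSV file.
#' @return data.frame keyed uniquely by (chrom, pos, ref, alt).
#' @export
read_snp_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "")
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(x)))
    stop("SNP table needs columns: ", paste(need, collapse = ", "))
  if (!"source" %in% names(x)) x$source <- "unknown"
  x$pos <- as.integer(x$pos)
  key <- variant_key(x$chrom, x$pos, x$ref, x$alt)
  x[!duplicated(key), c(need, "source"), drop = FALSE]
}

#' Write a known-SNP list
#' @param x SNP data.frame.
#' @param path Output file.
#' @export
write_snp_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

PREDICTOR_TOOLS <- c("sift", "polyphen2_hdiv", "polyphen2_hvar", "lrt",
                     "mutationtaster")

#' Read precomputed damaging-predictor verdicts
#'
#' One row per variant key with the verdicts of the five substitution-impact
#' tools (SIFT, PolyPhen2 HDIV, PolyPhen2 HVAR, LRT, MutationTaster), each
#' one of `damaging`, `tolerated`, `missing`.
#'
#' @param path Verdict TSV with columns `chrom, pos, ref, alt` plus the five
#'   tool columns.
#' @return data.frame with validated verdict values.
#' @export
read_predictor_verdicts <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "")
  need <- c("chrom", "pos", "ref", "alt", PREDICTOR_TOOLS)
  if (!all(need %in% names(x)))
    stop("verdict table needs columns: ", paste(need, collapse = ", "))
  x$pos <- as.integer(x$pos)
  for (tool in PREDICTOR_TOOLS) {
    bad <- !x[[tool]] %in% c("damaging", "tolerated", "missing")
    if (any(bad))
      stop("invalid verdict '", x[[tool]][bad][1], "' in column ", tool)
  }
  x[need]
}

#' Write predictor verdicts
#' @param x Verdict data.frame.
#' @param path Output file.
#' @export
write_predictor_verdicts <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## --- clinical table ---------------------------------------------------------

STAGE_LEVELS <- c("I", "II", "III", "IV", "unknown")
LOCALIZATION_LEVELS <- c("orbita", "conjunctiva", "lacrimal gland", "unknown")
TREATMENT_LEVELS <- c("radiotherapy", "immunochemotherapy", "anti-CD20",
                      "none", "unknown")

#' Read the clinical table
#'
#' Comma-separated table of per-patient clinical characteristics: age, sex,
#' Ann Arbor stage at diagnosis, localization, treatment, relapse and death
#' flags, follow-up in months, and the histopathological tumor-cell content
#' of the biopsy. Categorical fields are normalized to fixed vocabularies;
#' unknown values are preserved as `"unknown"`, never dropped. Stage
#' modifiers (e.g. `IEA` for localized extranodal disease) are normalized to
#' the bare numeral with the raw value kept in `ann_arbor_stage_raw`.
#' Cohorts are expected to contain biopsies with at least 70% tumor cells;
#' lower values warn but do not error, since the cutoff is an inclusion
#' guideline rather than a structural invariant.
#'
#' @param path Clinical CSV with header `patient_id, age_years, sex,
#'   ann_arbor_stage, localization, treatment, relapse, death,
#'   followup_months[, tumor_content_fraction]`.
#' @return Normalized data.frame.
#' @export
read_clinical_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "age_years", "sex", "ann_arbor_stage",
            "localization", "treatment", "relapse", "death",
            "followup_months")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stop("clinical table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  x$ann_arbor_stage_raw <- as.character(x$ann_arbor_stage)
  x$ann_arbor_stage <- normalize_stage(x$ann_arbor_stage_raw)
  x$localization <- normalize_level(x$localization, LOCALIZATION_LEVELS)
  x$treatment <- normalize_level(x$treatment, TREATMENT_LEVELS,
                                 synonyms = c("anti-cd20" = "anti-CD20",
                                              "anti-cd20 antibody" = "anti-CD20",
                                              "no therapy" = "none"))
  x$relapse <- parse_flag(x$relapse, "relapse")
  x$death <- parse_flag(x$death, "death")
  x$followup_months <- as.numeric(x$followup_months)
  if (any(is.na(x$followup_months) | x$followup_months <= 0))
    stop("followup_months must be positive for every patient; offending row(s): ",
         paste(which(is.na(x$followup_months) | x$followup_months <= 0),
               collapse = ", "))
  if (!"tumor_content_fraction" %in% names(x)) {
    x$tumor_content_fraction <- NA_real_
  } else {
    x$tumor_content_fraction <- as.numeric(x$tumor_content_fraction)
    low <- which(!is.na(x$tumor_content_fraction) &
                   x$tumor_content_fraction < 0.7)
    if (length(low))
      warning("tumor content below the 70% inclusion guideline for patient(s): ",
              paste(x$patient_id[low], collapse = ", "))
  }
  x
}

normalize_stage <- function(s) {
  s <- toupper(trimws(as.character(s)))
  core <- sub("^(IV|III|II|I).*$", "\\1", s)
  ok <- core %in% c("I", "II", "III", "IV")
  out <- ifelse(ok, core, "unknown")
  bad <- !ok & !(s %in% c("", "NA", "UNKNOWN", "?", "."))
  if (any(bad)) stop("unparseable Ann Arbor stage: ", s[bad][1])
  out
}

normalize_level <- function(v, levels, synonyms = character()) {
  v <- trimws(as.character(v))
  lv <- tolower(v)
  mapped <- ifelse(lv %in% names(synonyms), synonyms[lv], v)
  hit <- match(tolower(mapped), tolower(levels))
  out <- ifelse(is.na(hit), "unknown", levels[ifelse(is.na(hit), 1L, hit)])
  out
}

parse_flag <- function(v, what) {
  lv <- tolower(trimws(as.character(v)))
  out <- rep(NA, length(v))
  out[lv %in% c("yes", "true", "1", "y")] <- TRUE
  out[lv %in% c("no", "false", "0", "n")] <- FALSE
  if (anyNA(out))
    stop("unparseable ", what, " flag: ", v[is.na(out)][1])
  out
}

#' Write the clinical table
#' @param x Clinical data.frame.
#' @param path Output CSV.
#' @export
write_clinical_table <- function(x, path) {
  cols <- c("patient_id", "age_years", "sex", "ann_arbor_stage",
            "localization", "treatment", "relapse", "death",
            "followup_months", "tumor_content_fraction")
  y <- x[intersect(cols, names(x))]
  y$relapse <- ifelse(y$relapse, "yes", "no")
  y$death <- ifelse(y$death, "yes", "no")
  utils::write.csv(y, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
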