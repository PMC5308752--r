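# Fixtures built in code: a three-amplicon toy panel on chr9 around the
# blacklisted NOTCH1 site, and a ten-variant table designed by hand so that
# exactly four calls survive the cascade and each reject carries one known
# reason code.

toy_panel <- function() {
  data.frame(
    amplicon_id = c("ampA", "ampB", "ampC"),
    chrom = "chr9",
    insert_start = c(139390900L, 139391020L, 139391140L),
    insert_end = c(139391049L, 139391169L, 139391289L),
    primer_len_5p = 20L, primer_len_3p = 20L,
    gene = "NOTCH1", mapping_ambiguous = FALSE, strand = "+",
    stringsAsFactors = FALSE)
}

toy_snp_db <- function() {
  data.frame(chrom = "chr9", pos = 139390980L, ref = "A", alt = "G",
             source = "db137", stringsAsFactors = FALSE)
}

# expected verdict/reason per row is recorded alongside; reasons were
# derived by applying each published rule by hand to the counts below
toy_variants <- function() {
  v <- data.frame(
    patient_id = "T01",
    chrom = "chr9",
    pos = c(139390960L, 139390970L, 139391030L, 139391200L,  # survivors
            139390955L, 139390965L, 139390980L, 139391035L,  # rejects
            139390944L, 139390902L),
    # ref alleles match the synthetic NOTCH1 coding model at each position
    # (the last amplicon reaches past the coding model: effect "other")
    ref = c("G", "T", "A", "A", "G", "G", "A", "A", "GC", "A"),
    alt = c("C", "C", "G", "G", "A", "A", "G", "T", "G", "G"),
    gene = "NOTCH1",
    reads_total = c(150L, 150L, 150L, 120L, 99L, 150L, 150L, 130L, 150L, 150L),
    reads_variant = c(60L, 18L, 58L, 50L, 40L, 6L, 70L, 12L, 45L, 60L),
    phred = 40,
    amplicons = c("ampA", "ampA", "ampA;ampB", "ampC", "ampA", "ampA",
                  "ampA", "ampA;ampB", "ampA", "ampA"),
    amplicon_counts = c("ampA:150:60", "ampA:150:18",
                        "ampA:80:30;ampB:70:28", "ampC:120:50",
                        "ampA:99:40", "ampA:150:6", "ampA:150:70",
                        "ampA:80:12;ampB:50:0", "ampA:150:45",
                        "ampA:150:60"),
    stringsAsFactors = FALSE)
  v$expected_verdict <- c("accept", "review_accept", "accept", "accept",
                          "reject", "reject", "reject", "reject",
                          "reject", "reject")
  v$expected_reason <- c("", "", "", "",
                         "LOW_COVERAGE", "VAF_BELOW_MIN", "KNOWN_SNP",
                         "SINGLE_AMPLICON_ONLY", "BLACKLISTED",
                         "PRIMER_PROXIMAL")
  v
}

# random valid variant rows for round-trip and property tests
random_variants <- function(n, seed = 1) {
  set.seed(seed)
  pg <- panel_genes()
  i <- sample(nrow(pg), n, replace = TRUE)
  total <- sample(20:204, n, replace = TRUE)
  vr <- rbinom(n, total, runif(n, 0.02, 0.6))
  offs <- sample(30:200, n, replace = TRUE)
  data.frame(
    patient_id = sprintf("P%03d", sample(1:20, n, replace = TRUE)),
    chrom = pg$chrom[i],
    pos = pg$cds_anchor[i] + offs,
    ref = vapply(seq_len(n), function(k) synthetic_ref(pg$gene[i[k]],
                                                       pg$cds_anchor[i[k]] + offs[k]), ""),
    alt = "X",  # replaced below to differ from ref
    gene = pg$gene[i],
    reads_total = total,
    reads_variant = vr,
    phred = round(runif(n, 20, 45), 1),
    amplicons = "",
    amplicon_counts = ".",
    stringsAsFactors = FALSE) -> v
  v$alt <- vapply(v$ref, function(r) sample(setdiff(c("A", "C", "G", "T"),
                                                    r), 1), "")
  v$amplicons <- vapply(seq_len(n), function(k) {
    cov <- covering_amplicons(synthetic_panel(), v$chrom[k], v$pos[k])
    paste(cov$amplicon_id, collapse = ";")
  }, "")
  v$amplicon_counts <- vapply(seq_len(n), function(k) {
    ids <- strsplit(v$amplicons[k], ";")[[1]]
    if (length(ids) == 0) return(".")
    if (length(ids) == 1)
      return(paste(ids, v$reads_total[k], v$reads_variant[k], sep = ":"))
    t1 <- v$reads_total[k] %/% 2
    v1 <- min(v$reads_variant[k], t1)
    paste(paste(ids[1], t1, v1, sep = ":"),
          paste(ids[2], v$reads_total[k] - t1, v$reads_variant[k] - v1,
                sep = ":"), sep = ";")
  }, "")
  v
}
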