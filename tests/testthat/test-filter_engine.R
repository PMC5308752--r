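# The filter cascade: threshold boundary semantics, the per-rule checks
# against hand-derived outcomes on the toy panel, and the cascade's
# order-independence / monotonicity / completeness properties.

test_that("quality and coverage gate uses the published boundary semantics", {
  cfg <- filter_config()
  # below-100 coverage is out; exactly 100 passes
  expect_equal(quality_coverage_gate(40, 99, cfg), "LOW_COVERAGE")
  expect_equal(quality_coverage_gate(31, 100, cfg), character(0))
  # phred strictly above 30: 30.0 itself fails
  expect_equal(quality_coverage_gate(30.0, 150, cfg), "LOW_PHRED")
  expect_setequal(quality_coverage_gate(29, 50, cfg),
                  c("LOW_PHRED", "LOW_COVERAGE"))
})

test_that("VAF bands: <5% reject, 5-20% review, >=20% accept", {
  cfg <- filter_config()
  expect_equal(vaf_band(6, 150, cfg), "reject")    # 4%
  expect_equal(vaf_band(18, 150, cfg), "review")   # 12%
  expect_equal(vaf_band(60, 150, cfg), "accept")   # 40%
  # boundaries are inclusive ("at least")
  expect_equal(vaf_band(5, 100, cfg), "review")
  expect_equal(vaf_band(20, 100, cfg), "accept")
  expect_error(vaf_band(0, 0, cfg), "VAF undefined")
})

test_that("primer proximity: proximal only when near the edge of every covering amplicon", {
  panel <- toy_panel()
  cfg <- filter_config()
  # 2 bp from the edge of the only covering amplicon
  expect_equal(primer_proximity_check("chr9", 139390902, panel, cfg),
               "PRIMER_PROXIMAL")
  # interior position passes
  expect_equal(primer_proximity_check("chr9", 139390975, panel, cfg),
               character(0))
  # edge-proximal in ampA (dist 2) but interior in overlapping ampB
  expect_equal(primer_proximity_check("chr9", 139391047, panel, cfg),
               character(0))
  # outside every insert: cannot assess
  expect_equal(primer_proximity_check("chr9", 139380000, panel, cfg),
               "AMBIGUOUS_MAPPING")
})

test_that("primer proximity agrees with brute-force enumeration over the toy panel", {
  panel <- toy_panel()
  cfg <- filter_config()
  oracle <- function(pos) {
    covering <- which(panel$insert_start <= pos & panel$insert_end >= pos)
    if (!length(covering)) return("AMBIGUOUS_MAPPING")
    prox <- vapply(covering, function(i)
      min(pos - panel$insert_start[i], panel$insert_end[i] - pos) <
        cfg$primer_proximity_bp, NA)
    if (all(prox)) "PRIMER_PROXIMAL" else "none"
  }
  for (pos in seq(139390895L, 139391295L, by = 1L)) {
    got <- primer_proximity_check("chr9", pos, panel, cfg)
    expect_equal(if (length(got)) got else "none", oracle(pos),
                 info = paste("pos", pos))
  }
})

test_that("overlap concordance requires support in every well-covered amplicon", {
  cfg <- filter_config()
  counts <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(amplicon_id = paste0("a", seq_len(nrow(m))),
               total = m[, 1], variant = m[, 2])
  }
  expect_equal(overlap_concordance_check(counts(80, 12, 50, 0), cfg),
               "SINGLE_AMPLICON_ONLY")
  expect_equal(overlap_concordance_check(counts(80, 12, 50, 7), cfg),
               character(0))
  # single amplicon: not evaluable
  expect_equal(overlap_concordance_check(counts(80, 12), cfg), character(0))
  # second amplicon below the coverage floor: not evaluable
  expect_equal(overlap_concordance_check(counts(80, 12, 15, 0), cfg),
               character(0))
})

test_that("SNP and blacklist checks match on the full allele key", {
  cfg <- filter_config()
  snp <- toy_snp_db()
  expect_equal(snp_and_blacklist_check("chr9", 139390980, "A", "G", snp, cfg),
               "KNOWN_SNP")
  # same position, different alt: no hit
  expect_equal(snp_and_blacklist_check("chr9", 139390980, "A", "T", snp, cfg),
               character(0))
  # shipped default blacklist carries the recurrent 1-bp deletion
  expect_equal(snp_and_blacklist_check("chr9", 139390944, "GC", "G", snp, cfg),
               "BLACKLISTED")
})

test_that("cascade on the designed ten-variant fixture keeps exactly four calls", {
  v <- toy_variants()
  dec <- run_filter_cascade(v, toy_panel(), toy_snp_db())
  expect_equal(dec$verdict, v$expected_verdict)
  expect_equal(dec$reasons, v$expected_reason)
  expect_equal(sum(dec$verdict != "reject"), 4)
})

test_that("cascade decisions are invariant under input permutation", {
  v <- toy_variants()
  dec <- run_filter_cascade(v, toy_panel(), toy_snp_db())
  set.seed(5)
  perm <- sample(nrow(v))
  dec_p <- run_filter_cascade(v[perm, ], toy_panel(), toy_snp_db())
  reorder <- order(perm)
  expect_equal(dec_p$verdict[reorder], dec$verdict)
  expect_equal(dec_p$reasons[reorder], dec$reasons)
})

test_that("reasons accumulate and rejection is complete", {
  v <- toy_variants()[1, ]
  v$reads_total <- 90L; v$reads_variant <- 3L  # low coverage AND VAF 3.3%
  v$amplicon_counts <- "ampA:90:3"
  dec <- run_filter_cascade(v, toy_panel(), toy_snp_db())
  expect_equal(dec$verdict, "reject")
  expect_setequal(strsplit(dec$reasons, ";")[[1]],
                  c("LOW_COVERAGE", "VAF_BELOW_MIN"))
  # every reject carries >= 1 code from the enumerated set, accepts none
  b <- simulate_cohort(sim_config(), seed = 3)
  dec <- run_filter_cascade(b$variants, b$panel, b$snp_db)
  rej <- dec$verdict == "reject"
  expect_true(all(nzchar(dec$reasons[rej])))
  expect_true(all(dec$reasons[!rej] == ""))
  codes <- unique(unlist(strsplit(dec$reasons[rej], ";")))
  expect_true(all(codes %in% FILTER_REASONS))
  # review_accept only in the 5-20% band
  ra <- dec$verdict == "review_accept"
  expect_true(all(dec$vaf[ra] >= 0.05 & dec$vaf[ra] < 0.20))
})

test_that("empty input yields an empty decision table", {
  v <- toy_variants()[0, ]
  dec <- run_filter_cascade(v, toy_panel(), toy_snp_db())
  expect_equal(nrow(dec), 0)
})

test_that("tightening coverage or VAF thresholds never grows the accepted set", {
  b <- simulate_cohort(sim_config(), seed = 9)
  key <- function(dec) paste(dec$patient_id, dec$chrom, dec$pos, dec$alt)
  accepted <- function(cfg) {
    dec <- run_filter_cascade(b$variants, b$panel, b$snp_db, cfg)
    key(dec)[dec$verdict != "reject"]
  }
  prev <- accepted(filter_config(min_coverage = 50))
  for (mc in c(100, 150, 200)) {
    cur <- accepted(filter_config(min_coverage = mc))
    expect_true(all(cur %in% prev), info = paste("min_coverage", mc))
    prev <- cur
  }
  prev <- accepted(filter_config(vaf_reject_below = 0.01))
  for (vb in c(0.05, 0.10, 0.20)) {
    cur <- accepted(filter_config(vaf_reject_below = vb,
                                  vaf_auto_accept_at = max(vb, 0.20)))
    expect_true(all(cur %in% prev), info = paste("vaf_reject_below", vb))
    prev <- cur
  }
})

test_that("mapping-ambiguous amplicons poison the calls they cover", {
  v <- toy_variants()[1, ]  # interior ampA position, otherwise accepted
  panel <- toy_panel()
  panel$mapping_ambiguous[panel$amplicon_id == "ampA"] <- TRUE
  dec <- run_filter_cascade(v, panel, toy_snp_db())
  expect_equal(dec$verdict, "reject")
  expect_match(dec$reasons, "AMBIGUOUS_MAPPING")
})

test_that("filter configuration round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("min_phred: 25", "min_coverage: 80",
               "vaf_reject_below: 0.03", "vaf_auto_accept_at: 0.25"), path)
  cfg <- read_filter_config(path)
  expect_s3_class(cfg, "filter_config")
  expect_equal(cfg$min_phred, 25)
  expect_equal(cfg$min_coverage, 80L)
  expect_equal(cfg$vaf_auto_accept_at, 0.25)
})
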