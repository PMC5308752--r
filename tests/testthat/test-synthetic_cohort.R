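# The cohort generator: determinism, conservation, VAF and coverage models,
# and round-tripping of every emitted table through the io layer.

test_that("seeded simulation is bit-reproducible", {
  b1 <- simulate_cohort(sim_config(), seed = 5)
  b2 <- simulate_cohort(sim_config(), seed = 5)
  expect_identical(b1, b2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_bundle(b1, d1); write_bundle(b2, d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  b3 <- simulate_cohort(sim_config(), seed = 6)
  expect_false(identical(b1$variants, b3$variants))
})

test_that("every emitted call is attributable to exactly one origin class", {
  b <- simulate_cohort(sim_config(), seed = 13)
  vkey <- paste(b$variants$patient_id,
                variant_key(b$variants$chrom, b$variants$pos,
                            b$variants$ref, b$variants$alt))
  tr <- b$truth[b$truth$emitted, ]
  tkey <- paste(tr$patient_id, variant_key(tr$chrom, tr$pos, tr$ref, tr$alt))
  expect_true(all(vkey %in% tkey))
  origin_per_call <- tapply(tr$origin, tkey, function(o)
    length(unique(o)))
  expect_true(all(origin_per_call == 1))
  expect_true(all(tr$origin %in% c("truth", "synonymous", "artifact",
                                   "blacklist_artifact", "germline_snp")))
})

test_that("clonal heterozygous truth has expected VAF purity/2", {
  cfg <- sim_config(purity_range = c(0.8, 0.8))
  b <- simulate_cohort(cfg, seed = 31)
  clonal <- b$truth[b$truth$origin == "truth" & b$truth$clonal &
                      !b$truth$loh, ]
  expect_true(all(abs(clonal$expected_vaf - 0.4) < 1e-12))
  # allelic-imbalance cases sit above 50%: purity / (2 - purity)
  loh <- b$truth[b$truth$origin == "truth" & b$truth$loh, ]
  if (nrow(loh))
    expect_true(all(abs(loh$expected_vaf - 0.8 / 1.2) < 1e-12))
  # observed VAF of emitted clonal heterozygous truth centres on purity/2
  em <- clonal[clonal$emitted, ]
  vaf <- em$reads_variant / em$reads_total
  se <- sd(vaf) / sqrt(nrow(em))
  expect_lt(abs(mean(vaf) - 0.4), 3 * se)
})

test_that("coverage matches its clamped negative-binomial model", {
  cfg <- sim_config()
  # positions where emission is essentially unconditional (high true VAF),
  # so observed coverage is an unbiased draw from the model
  high_vaf_cov <- function(b) {
    tr <- b$truth[b$truth$emitted, ]
    tr$reads_total[tr$origin == "germline_snp" |
                     (tr$origin == "truth" & tr$clonal)]
  }
  b <- simulate_cohort(cfg, seed = 41)
  cov <- high_vaf_cov(b)
  expect_gte(length(cov), 200)
  expect_true(all(cov >= cfg$coverage_bounds[1] &
                    cov <= cfg$coverage_bounds[2]))
  # oracle: exact mean of the clamped NB by summation over its support
  x <- 0:2000
  px <- dnbinom(x, mu = cfg$coverage_mean, size = cfg$coverage_dispersion)
  xc <- pmin(pmax(x, cfg$coverage_bounds[1]), cfg$coverage_bounds[2])
  mu_clamped <- sum(xc * px)
  sd_clamped <- sqrt(sum((xc - mu_clamped)^2 * px))
  # pool several seeds to pass the 1000-position mark
  for (s in 42:44)
    cov <- c(cov, high_vaf_cov(simulate_cohort(cfg, seed = s)))
  expect_gte(length(cov), 1000)
  expect_lt(abs(mean(cov) - mu_clamped), 2 * sd_clamped / sqrt(length(cov)))
})

test_that("artifact calls are sub-threshold at evaluable coverage", {
  b <- simulate_cohort(sim_config(), seed = 51)
  art <- b$truth[b$truth$origin == "artifact" & b$truth$emitted, ]
  vaf <- art$reads_variant / art$reads_total
  expect_true(all(vaf[art$reads_total >= 100] < 0.05))
  # deamination bias: most artifact substitutions are C>T or G>A
  ct <- (art$ref == "C" & art$alt == "T") | (art$ref == "G" & art$alt == "A")
  expect_gt(mean(ct), 0.5)
})

test_that("an artifact-only cohort yields zero accepted calls at coverage >= 100", {
  cfg <- sim_config(gene_probs = setNames(rep(0, 24), panel_genes()$gene),
                    synonymous_rate = 0, germline_het_prob = 0,
                    blacklist_artifact_rate = 0, artifact_rate = 5e-3)
  b <- simulate_cohort(cfg, seed = 61)
  expect_gt(nrow(b$variants), 50)  # plenty of artifact calls to test
  dec <- run_filter_cascade(b$variants, b$panel, b$snp_db)
  accepted <- dec[dec$verdict != "reject", ]
  expect_equal(nrow(accepted), 0)
})

test_that("the simulated bundle round-trips through the io layer", {
  b <- simulate_cohort(sim_config(), seed = 71)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  b2 <- read_bundle(dir)
  expect_equal(b2$variants[VARIANT_COLUMNS], b$variants[VARIANT_COLUMNS],
               ignore_attr = TRUE)
  expect_equal(b2$panel, b$panel, ignore_attr = TRUE)
  expect_equal(b2$snp_db, b$snp_db, ignore_attr = TRUE)
  expect_equal(b2$verdicts, b$verdicts, ignore_attr = TRUE)
  for (col in c("patient_id", "relapse", "death", "followup_months",
                "tumor_content_fraction"))
    expect_equal(b2$clinical[[col]], b$clinical[[col]], info = col)
})

test_that("subclonal truth classifies as subclonal when detected", {
  cfg <- sim_config(purity_range = c(0.8, 0.8))
  b <- simulate_cohort(cfg, seed = 81)
  sub <- b$truth[b$truth$origin == "truth" & !b$truth$clonal &
                   b$truth$emitted, ]
  # ccf ~ U(0.10, 0.45) at purity 0.8: expected VAF in [0.04, 0.18] < 0.20
  expect_true(all(sub$expected_vaf < 0.20))
  vaf <- sub$reads_variant / sub$reads_total
  lab <- classify_clonality(vaf)$label
  expect_gt(mean(lab == "subclonal"), 0.9)
})

test_that("recovery report separates clonality classes and counts false discoveries", {
  cfg <- sim_config(artifact_rate = 0, blacklist_artifact_rate = 0,
                    germline_het_prob = 0, snp_plant_frac = 0,
                    subclonal_probs = setNames(rep(0, 24),
                                               panel_genes()$gene),
                    coverage_bounds = c(120L, 204L))
  b <- simulate_cohort(cfg, seed = 91)
  dec <- run_filter_cascade(b$variants, b$panel, b$snp_db)
  ann <- annotate_mutations(dec, b$verdicts)
  M <- build_matrix(ann, b$clinical$patient_id)
  rep <- recovery_report(b$truth, dec, M, cfg)
  expect_equal(rep$sensitivity_clonal, 1.0)
  expect_equal(rep$n_false_discoveries, 0)
  expect_true(all(c("configured", "observed", "se_binomial") %in%
                    names(rep$per_gene)))
})
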