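# Consequence classification, damaging consensus, domain mapping.

test_that("variant-type classification matches the exhaustive length-comparison oracle", {
  # alignment-free oracle over every allele pair with lengths <= 4
  oracle <- function(ref, alt) {
    if (nchar(ref) == 1 && nchar(alt) == 1) return("substitution")
    if (nchar(ref) > nchar(alt) &&
        substr(ref, 1, nchar(alt)) == alt) return("deletion")
    if (nchar(alt) > nchar(ref) &&
        substr(alt, 1, nchar(ref)) == ref) return("insertion")
    "complex"
  }
  bases <- c("A", "C", "G", "T")
  alleles <- unlist(lapply(1:4, function(k)
    apply(expand.grid(rep(list(bases), k)), 1, paste, collapse = "")))
  set.seed(1)
  pairs <- expand.grid(ref = alleles, alt = alleles,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  got <- classify_variant_type(pairs$ref, pairs$alt)
  want <- mapply(oracle, pairs$ref, pairs$alt)
  expect_equal(got, unname(want))
})

test_that("variant-type examples: SNV, left-anchored deletion, multi-base exchange", {
  expect_equal(classify_variant_type("T", "C"), "substitution")
  expect_equal(classify_variant_type("CAG", "C"), "deletion")
  expect_equal(classify_variant_type("C", "CAG"), "insertion")
  expect_equal(classify_variant_type("AT", "GC"), "complex")
  expect_error(classify_variant_type("", "A"), "empty allele")
})

test_that("the canonical MYD88 hotspot annotates as Leu265Pro", {
  ctx <- cds_context("MYD88", 38182641)
  expect_equal(ctx$codon_number, 265)
  expect_equal(ctx$ref_codon, "CTG")
  eff <- classify_protein_effect("T", "C", "substitution", ctx)
  expect_equal(eff$protein_effect, "missense")
  expect_equal(eff$protein_change, "Leu265Pro")
  expect_equal(eff$protein_pos, 265)
})

test_that("indel frame arithmetic: 1-2 bp shift the frame, 3 bp are in-frame", {
  ctx <- cds_context("NOTCH1", 139390945)
  eff <- classify_protein_effect("GC", "G", "deletion", ctx)
  expect_equal(eff$protein_effect, "frameshift")
  expect_match(eff$protein_change, "fs$")
  eff3 <- classify_protein_effect("GCAT", "G", "deletion", ctx)
  expect_equal(eff3$protein_effect, "inframe_indel")
  effi <- classify_protein_effect("G", "GAT", "insertion", ctx)
  expect_equal(effi$protein_effect, "frameshift")
})

test_that("stop-gain substitutions classify as nonsense", {
  # find a codon in TP53's synthetic model one exchange away from a stop
  seq <- synthetic_cds("TP53")
  found <- FALSE
  for (aa in 2:392) {
    codon <- substr(seq, (aa - 1) * 3 + 1, aa * 3)
    for (frame in 0:2) for (b in setdiff(c("A", "C", "G", "T"),
                                         substr(codon, frame + 1, frame + 1))) {
      alt_codon <- codon
      substr(alt_codon, frame + 1, frame + 1) <- b
      if (alt_codon %in% c("TAA", "TAG", "TGA")) {
        anchor <- panel_genes()$cds_anchor[panel_genes()$gene == "TP53"]
        pos <- anchor + (aa - 1) * 3 + frame
        eff <- classify_protein_effect(substr(codon, frame + 1, frame + 1),
                                       b, "substitution",
                                       cds_context("TP53", pos))
        expect_equal(eff$protein_effect, "nonsense")
        expect_match(eff$protein_change, "Ter$")
        found <- TRUE
        break
      }
    }
    if (found) break
  }
  expect_true(found)
})

test_that("positions without coding context classify as other, with warning", {
  expect_warning(
    eff <- classify_protein_effect("A", "G", "substitution", NULL),
    "outside supplied CDS")
  expect_equal(eff$protein_effect, "other")
})

test_that("damaging consensus needs three agreeing tools; ties are undetermined", {
  D <- "damaging"; T_ <- "tolerated"; M <- "missing"
  expect_equal(damaging_consensus(c(D, D, D, T_, T_)), "yes")
  expect_equal(damaging_consensus(c(D, D, T_, T_, T_)), "no")
  expect_equal(damaging_consensus(c(D, D, M, M, M)), "undetermined")
  expect_equal(damaging_consensus(c(D, D, T_, T_, M)), "undetermined")
  expect_error(damaging_consensus(c(D, D, D, T_)), "length")
})

test_that("domain lookup returns the unique containing interval", {
  dm <- read_domain_map()
  expect_equal(map_to_domain("KMT2D", 5450, dm), "SET")
  expect_equal(map_to_domain("NOTCH2", 2400, dm), "PEST")
  expect_equal(map_to_domain("NOTCH1", 2500, dm), "PEST")
  # before the first domain: inter-domain
  expect_true(is.na(map_to_domain("NOTCH1", 1, dm)))
  expect_warning(res <- map_to_domain("NOSUCHGENE", 10, dm),
                 "no domain annotation")
  expect_true(is.na(res))
})

test_that("domain mapping is a partition query over each protein", {
  dm <- read_domain_map()
  for (g in unique(dm$gene)) {
    d <- dm[dm$gene == g, ]
    for (pos in seq(1, max(d$aa_end), by = 37)) {
      hits <- sum(d$aa_start <= pos & d$aa_end >= pos)
      expect_lte(hits, 1)
    }
  }
})

test_that("deleterious definition: truncating events or damaging-consensus missense", {
  expect_true(deleterious_flag("frameshift", "undetermined"))
  expect_true(deleterious_flag("nonsense", "no"))
  expect_true(deleterious_flag("missense", "yes"))
  expect_false(deleterious_flag("missense", "undetermined"))
  expect_false(deleterious_flag("missense", "no"))
  expect_false(deleterious_flag("synonymous", "undetermined"))
})

test_that("annotation assigns exactly one type and one effect to each accepted call", {
  b <- simulate_cohort(sim_config(), seed = 17)
  dec <- run_filter_cascade(b$variants, b$panel, b$snp_db)
  ann <- annotate_mutations(dec, b$verdicts)
  expect_equal(nrow(ann), sum(dec$verdict != "reject"))
  expect_true(all(ann$variant_type %in% VARIANT_TYPES))
  expect_true(all(ann$protein_effect %in% PROTEIN_EFFECTS))
  # the generator's designed effects are recovered for truth calls
  tr <- b$truth[b$truth$origin == "truth" & b$truth$emitted, ]
  key <- function(d) paste(d$patient_id, d$chrom, d$pos, d$ref, d$alt)
  m <- match(key(ann), key(tr))
  hit <- !is.na(m)
  designed <- tr$designed_effect[m[hit]]
  comparable <- designed %in% c("missense", "nonsense", "frameshift",
                                "inframe_indel", "synonymous")
  expect_true(all(ann$protein_effect[hit][comparable] ==
                    designed[comparable]))
})
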