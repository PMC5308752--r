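# Cohort matrix, frequencies, clonality, and the exact Fisher test.

# minimal annotated-mutation rows for matrix construction
ann_rows <- function(patient, gene, vaf = 0.4, effect = "missense") {
  data.frame(patient_id = patient, gene = gene, chrom = "chr1",
             pos = seq_along(patient), ref = "A", alt = "G", vaf = vaf,
             verdict = "accept", reasons = "", variant_type = "substitution",
             protein_effect = effect, protein_change = NA, protein_pos = NA,
             damaging = "undetermined", deleterious = FALSE, domain = NA,
             stringsAsFactors = FALSE)
}

test_that("matrix keeps zero-mutation patients and collapses multiplicity", {
  ann <- ann_rows(c("P1", "P1", "P3", "P3"),
                  c("MYD88", "KMT2D", "MYD88", "MYD88"))
  M <- build_matrix(ann, c("P1", "P2", "P3"))
  expect_equal(dim(M$indicator), c(3, 24))
  expect_true(M$indicator["P1", "MYD88"])
  expect_true(M$indicator["P1", "KMT2D"])
  expect_false(any(M$indicator["P2", ]))
  # two MYD88 rows in P3: one indicator cell, two detail rows
  expect_true(M$indicator["P3", "MYD88"])
  expect_equal(sum(M$detail$patient_id == "P3"), 2)
  # empty mutation list: all-false matrix
  M0 <- build_matrix(ann[0, ], c("P1", "P2"))
  expect_false(any(M0$indicator))
  # unknown patient errors
  expect_error(build_matrix(ann, c("P1", "P2")), "absent from the cohort")
})

test_that("synonymous calls are excluded from the landscape matrix", {
  ann <- rbind(ann_rows("P1", "MYD88"),
               ann_rows("P2", "MYD88", effect = "synonymous"))
  M <- build_matrix(ann, c("P1", "P2"))
  expect_true(M$indicator["P1", "MYD88"])
  expect_false(M$indicator["P2", "MYD88"])
})

test_that("gene frequencies are column means with counts alongside", {
  ann <- ann_rows(sprintf("P%02d", 1:12), rep("MYD88", 12))
  M <- build_matrix(ann, sprintf("P%02d", 1:63))
  f <- gene_frequencies(M)
  expect_equal(f$frequency[f$gene == "MYD88"], 12 / 63)
  expect_equal(f$n_mutated[f$gene == "MYD88"], 12L)
  expect_true(all(f$frequency[!f$gene %in% "MYD88"] == 0))
  expect_equal(colSums(M$indicator)[f$gene], setNames(f$n_mutated, f$gene))
})

test_that("pathway frequency is a union count over member genes", {
  ann <- rbind(ann_rows("P1", "KMT2D"),        # not an NF-kB member
               ann_rows("P2", "TNFAIP3"),
               ann_rows("P2", "MYD88"))        # counted once
  M <- build_matrix(ann, c("P1", "P2", "P3"))
  nfkb <- pathway_frequency(M, gene_set("NF-kB"))
  expect_equal(nfkb$n_mutated, 1)
  expect_equal(nfkb$frequency, 1 / 3)
  expect_error(pathway_frequency(M, character()), "empty gene set")
  expect_error(pathway_frequency(M, "NOSUCH"), "absent from matrix")
})

test_that("the NF-kB set is the 19 pathway members, excluding the other panel genes", {
  s <- gene_set("NF-kB")
  expect_length(s, 19)
  expect_false(any(c("KMT2D", "NOTCH1", "NOTCH2", "TP53", "FAS") %in% s))
  expect_true(all(c("MYD88", "TNFAIP3", "BCL10", "TNIP1", "TRAF3",
                    "MAP3K14") %in% s))
})

test_that("empirical pathway union matches the independence product oracle", {
  # Monte-Carlo oracle: with independent per-gene Bernoulli mutation
  # indicators the union frequency is 1 - prod(1 - p_g) over the set
  probs <- default_gene_probs()
  nfkb <- gene_set("NF-kB")
  expected <- 1 - prod(1 - probs[nfkb])
  set.seed(123)
  reps <- 60; n <- 63
  hits <- 0L
  for (r in seq_len(reps)) {
    ind <- matrix(runif(n * length(probs)) < rep(probs, each = n), nrow = n)
    colnames(ind) <- names(probs)
    mutated <- which(ind, arr.ind = TRUE)
    ann <- ann_rows(sprintf("P%03d", mutated[, 1]),
                    names(probs)[mutated[, 2]])
    M <- build_matrix(ann, sprintf("P%03d", 1:n))
    hits <- hits + pathway_frequency(M, nfkb)$n_mutated
  }
  u <- hits / (reps * n)
  se <- sqrt(expected * (1 - expected) / (reps * n))
  expect_lt(abs(u - expected), 3 * se)
})

test_that("summary statistics: per-patient mean/range and per-mutation breakdown", {
  ann <- rbind(
    ann_rows(c("P2"), "MYD88"),
    ann_rows(c("P3", "P3"), c("MYD88", "KMT2D")),
    ann_rows(c("P4", "P4"), c("TNFAIP3", "BCL10")))
  ann$variant_type <- c("substitution", "substitution", "deletion",
                        "substitution", "insertion")
  M <- build_matrix(ann, c("P1", "P2", "P3", "P4"))
  s <- summary_statistics(M)
  expect_equal(s$mean_mutated_genes, 1.25)
  expect_equal(s$range_mutated_genes, c(0, 2))
  expect_equal(unname(s$type_breakdown),
               c(3 / 5, 1 / 5, 1 / 5, 0))
})

test_that("clonality labels: <20% subclonal, >50% flags possible LOH/UPD", {
  cl <- classify_clonality(c(0.19, 0.20, 0.48, 0.50, 0.55), purity = 0.8)
  expect_equal(cl$label, c("subclonal", "clonal", "clonal", "clonal",
                           "clonal_possible_LOH_or_UPD"))
  expect_equal(unique(cl$expected_clonal_vaf), 0.4)
  # labels partition all calls
  set.seed(2)
  v <- runif(500)
  expect_false(anyNA(classify_clonality(v)$label))
})

test_that("Fisher p-values match direct enumeration on hand-checked tables", {
  # modal table: every table is at least as probable as the observed one
  expect_equal(fisher_exact_two_sided(5, 5, 5, 5), 1.0)
  # perfectly concordant 10/10: only the two extreme tables qualify
  expect_equal(fisher_exact_two_sided(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  # zero-margin tables are uninformative
  expect_equal(fisher_exact_two_sided(0, 0, 5, 7), 1.0)
  expect_equal(fisher_exact_two_sided(0, 5, 0, 7), 1.0)
  # mutual-exclusivity-shaped table vs independent brute force over a=0..12
  oracle <- function(a, b, c, d) {
    r1 <- a + b; c1 <- a + c; n <- a + b + c + d
    ks <- max(0, r1 + c1 - n):min(r1, c1)
    p <- choose(r1, ks) * choose(n - r1, c1 - ks) / choose(n, c1)
    sum(p[p <= p[match(a, ks)] * (1 + 1e-7)])
  }
  expect_equal(fisher_exact_two_sided(0, 12, 17, 34), oracle(0, 12, 17, 34),
               tolerance = 1e-10)
  expect_equal(fisher_exact_two_sided(0, 12, 17, 34),
               stats::fisher.test(matrix(c(0, 12, 17, 34), 2,
                                         byrow = TRUE))$p.value,
               tolerance = 1e-7)
  expect_error(fisher_exact_two_sided(-1, 2, 3, 4), "non-negative")
})

test_that("Fisher p is symmetric under row and column swaps", {
  set.seed(4)
  for (i in 1:25) {
    t <- rmultinom(1, sample(5:40, 1), runif(4, 0.05, 1))
    p <- fisher_exact_two_sided(t[1], t[2], t[3], t[4])
    expect_equal(fisher_exact_two_sided(t[3], t[4], t[1], t[2]), p)
    expect_equal(fisher_exact_two_sided(t[2], t[1], t[4], t[3]), p)
    expect_equal(fisher_exact_two_sided(t[1], t[3], t[2], t[4]), p)
  }
})

test_that("co-occurrence screen tests all pairs of genes above the case floor", {
  n <- 63
  pats <- sprintf("P%03d", 1:n)
  ann <- rbind(ann_rows(pats[1:17], rep("TNFAIP3", 17)),
               ann_rows(pats[30:41], rep("MYD88", 12)),
               ann_rows(pats[18:31], rep("KMT2D", 14)),
               ann_rows(pats[1:5], rep("TP53", 5)))
  M <- build_matrix(ann, pats)
  scr <- cooccurrence_screen(M, min_cases = 12)
  expect_equal(nrow(scr), 3)  # TP53 (5 cases) excluded
  expect_false("TP53" %in% c(scr$gene_a, scr$gene_b))
  # disjoint pair: negative direction, small p
  row <- scr[(scr$gene_a == "TNFAIP3" & scr$gene_b == "MYD88") |
               (scr$gene_a == "MYD88" & scr$gene_b == "TNFAIP3"), ]
  expect_equal(row$direction, "-")
  expect_lt(row$p_value, 0.05)
  expect_equal(row$n_both, 0)
})

test_that("identical mutation patterns screen as co-occurring", {
  pats <- sprintf("P%03d", 1:40)
  ann <- rbind(ann_rows(pats[1:15], rep("TNFAIP3", 15)),
               ann_rows(pats[1:15], rep("MYD88", 15)))
  M <- build_matrix(ann, pats)
  scr <- cooccurrence_screen(M, min_cases = 12)
  expect_equal(scr$direction, "+")
  expect_lt(scr$p_value, 1e-6)
  # fewer than two eligible genes: empty result
  expect_equal(nrow(cooccurrence_screen(M, min_cases = 20)), 0)
})
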