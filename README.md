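# oamlmut

Targeted-amplicon mutation analysis of ocular adnexal MALT lymphoma
(OAML) cohorts, from per-position variant call tables to cohort-level
conclusions.

OAML studies sequence panels of candidate genes (NF-κB regulators,
KMT2D, NOTCH1/2, TP53, FAS) by multiplex PCR amplicon sequencing of
FFPE biopsies. This package implements the post-alignment analysis such a
study needs, as a tested R package plus a numbered analysis workflow:

* **Filter cascade** for FFPE amplicon calls: phred > 30, coverage ≥ 100,
  VAF bands at 5% (reject below) and 20% (auto-accept at or above, with a
  flagged review band between), primer-proximity and amplicon
  overlap-concordance rules, known-SNP (dbSNP-style) and
  recurrent-artifact blacklist exclusion. Every rejection carries
  machine-readable reason codes.
* **Annotation**: variant type and protein effect by codon arithmetic
  (missense / nonsense / frameshift / in-frame / synonymous, HGVS-like
  `Leu265Pro` strings), a five-tool damaging consensus (≥ 3 of SIFT,
  PolyPhen2 HDIV/HVAR, LRT, MutationTaster), protein-domain mapping for
  NOTCH1/2, KMT2D, TNFAIP3, and a deleterious flag (truncating or
  damaging-consensus missense).
* **Cohort statistics**: patients × genes matrix, per-gene and NF-κB
  pathway frequencies, VAF-based clonality calls — subclonal < 20%,
  clonal, possible LOH/UPD > 50%, expected clonal heterozygous VAF
  purity/2 — and a mutual-exclusivity screen over genes mutated in ≥ 12
  cases using a from-first-principles exact two-sided Fisher test
  (hypergeometric enumeration, minimum-likelihood convention).
* **Survival**: Kaplan–Meier disease-free survival stratified by mutation
  status with log-rank comparison and subgroup restriction.
* **Synthetic cohort generator** with ground truth: purity-scaled
  clonal/subclonal VAFs, negative-binomial coverage (mean 160, clamped to
  [20, 204]), sub-5% FFPE artifact noise with C:G→T:A bias, germline SNP
  calls, SNP-list contamination, injected TNFAIP3/MYD88 exclusivity, and
  a mutation-linked relapse hazard — so the whole pipeline is testable
  without access to patient data.

The core statistic behind the exclusivity screen is the exact two-sided
Fisher p for a 2×2 table with fixed margins: with support
k ∈ [max(0, r₁+c₁−N), min(r₁, c₁)] and hypergeometric point probabilities
p(k), the reported p is Σ p(k) over all k with p(k) ≤ p(k_obs),
accumulated on the log-factorial scale. It is verified exhaustively
against independent enumeration on every table with N ≤ 40.

## Worked example

The numbered scripts under `analysis/` run the full workflow on a
simulated cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_filter_variants.R
Rscript analysis/03_annotate_mutations.R
Rscript analysis/04_cohort_landscape.R
Rscript analysis/05_survival_analysis.R
Rscript analysis/06_recovery_benchmark.R
```

Step 2 prints, for the seed-1 cohort of 365 calls:

```
       accept        reject review_accept
           72           271            22
rejection reasons (a call may carry several):
           KNOWN_SNP        VAF_BELOW_MIN            LOW_PHRED
                 250                   17                    7
SINGLE_AMPLICON_ONLY          BLACKLISTED         LOW_COVERAGE
                   5                    3                    1
```

i.e. the cascade removes the ~250 germline SNP calls, the sub-5% FFPE
artifacts, and the planted recurrent NOTCH1 deletion, keeping 94 calls
(22 from the flagged 5–20% review band). Step 4 summarises the landscape:

```
mean mutated genes per patient: 1.05 (range 0-3)
mutation types: 65% substitutions, 26% deletions, 8% insertions, 0% complex
deleterious fraction: 69%
patients with >= 1 mutated NF-kB component: 39/63 (62%)

    gene  n  mean_vaf    sd_vaf n_subclonal n_clonal n_clonal_loh_upd
 TNFAIP3 23 0.5237472 0.2140805           2       10               11
```

TNFAIP3 shows the highest mean VAF with eleven calls above 50%
(possible LOH/UPD), while the per-gene table further down shows the
subclonal-dominant genes. Step 5 stratifies DFS by MYD88:

```
MYD88: 11 mutated vs 52 wild-type patients
log-rank chi-square 6.03, p = 0.0141
  mutated    5-year DFS: 0.61
  wild_type  5-year DFS: 0.82
stage-I subgroup (n=57): log-rank p = 0.0381
```

MYD88-mutated patients relapse earlier, also within the stage-I
radiotherapy subgroup. Step 6 closes the loop against ground truth
(clonal sensitivity 1.00, 0 false discoveries for this cohort; per-gene
recovery within its binomial band). Single 63-patient cohorts are noisy
by design — e.g. in this cohort only one gene reaches the 12-case floor,
so step 4's exclusivity screen reports no eligible pair; aggregated
replicates (below) recover the configured landscape tightly.

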