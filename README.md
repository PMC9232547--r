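# apobecscope

Characterising the APOBEC mutational process in somatic SNV catalogs.

APOBEC3 cytidine deaminases attack single-stranded DNA at tCw motifs
(a cytosine preceded by T and followed by A or T, read on the pyrimidine
strand) and leave two genomic footprints: a genome-wide excess of C>X
substitutions in tCw context, and *kataegis* — localised showers of
clustered mutations with short intermutational distances. `apobecscope`
implements the full analysis chain used to quantify these footprints in
tumour cohorts (the motivating setting is pancreatic ductal
adenocarcinoma, where APOBEC3C expression stratifies survival):

* **Trinucleotide spectra** — 96-channel pyrimidine-collapsed mutation
  spectra from MAF catalogs and a FASTA reference.
* **Signature deconstruction** — non-negative exposures
  `w_k` to reference SBS signatures, minimising
  `SSE = || s − Σ_k w_k P[,k] ||²` on the proportion spectrum `s` by
  forward selection with golden-section weight refinement and
  small-weight pruning (default threshold 0.06), with cosine-similarity
  diagnostics and an aetiology lookup.
* **Motif enrichment** — the fold-enrichment score
  `E = (mut_motif × ctx_C) / (mut_C × ctx_motif)` per sample, where the
  context counts are taken over ±20 bp windows around each mutated
  cytosine; samples with `E > 2` are classified APOBEC-enriched, and
  enriched vs non-enriched groups are compared (per-gene Fisher exact
  tests with BH correction, rank-sum burden tests).
* **Kataegis** — detection of regions with ≥ 6 consecutive mutations at
  mean intermutational distance ≤ 1000 bp (exactly equivalent to
  exhaustive window enumeration), classification into C>X-enriched
  (> 5 C>X per kb of span) and strict TpC→TpX regions, gene annotation,
  rainfall tables, expression correlation and expression-extreme
  subgroup comparison.
* **Paired-catalog subtraction** — newly occurring SNVs of an
  overexpressing cell line relative to its control, keyed on
  (chrom, pos, ref, alt) presence.
* **Survival stratification** — Kaplan–Meier curves, log-rank
  (Mantel–Cox) tests, Mantel–Haenszel hazard ratios and maximally
  selected expression cutpoints (with a permutation-adjusted p-value
  alongside the naive one, since the maximised statistic is
  anti-conservative).
* **Synthetic cohorts** — a first-class generator producing a random
  reference, signature-mixture catalogs with injected kataegis showers,
  paired control/overexpression catalogs, and expression/survival tables
  with a known hazard ratio — every downstream stage is testable against
  ground truth without downloads.

## Worked example

```r
library(apobecscope)

cfg <- sim_config(seed = 11, n_samples = 40, background_snvs_per_sample = 150,
                  ref_length_per_contig = 5e5)
cohort <- simulate_cohort(cfg)   # truth: 70% APOBEC-like / 30% CpG-deamination mixture

spec <- build_spectrum(cohort$catalog, cohort$ref)
fit  <- fit_exposures(spec, cohort$signatures)
fit
#> exposure_fit on 6072 SNVs
#>   SBS_APOBEC 0.6920
#>   SBS_AGE  0.3019
#>   unexplained 0.0061 | SSE 1.077e-04 | cosine 0.9996
```

The fit recovers the generating 0.70/0.30 mixture to within 0.01. The
tCw enrichment score is far above the E > 2 classification line for
every sample, as expected for catalogs dominated by an APOBEC-like
process:

```r
enr <- motif_enrichment(cohort$catalog, cohort$ref, motif = "TCW")
head(enr[, c("sample_id", "mut_motif", "mut_C", "E")], 3)
#>    sample_id mut_motif mut_C        E
#> 1:       S01       106   157 3.477070
#> 2:       S02       115   157 3.579281
#> 3:       S03       108   158 3.188608
```

Kataegis detection finds the injected showers plus chance background
runs; only tight showers pass the strict C>X-density class, mirroring
the small enriched fraction seen in real cohorts:

```r
regions <- classify_regions(detect_kataegis(cohort$catalog),
                            cohort$catalog, cohort$ref)
nrow(regions); sum(regions$is_ctox_enriched); sum(regions$is_strict_tpc)
#> [1] 14
#> [1] 1
#> [1] 3
```

Survival stratification by a maximally selected expression cutoff, on a
cohort simulated with a true hazard ratio of 3 between expression
groups (group medians 100 and 1000, geometric midpoint 316):

```r
tabs <- simulate_cohort_tables(n_samples = 160, true_hr = 3,
                               censoring_rate = 0.2, seed = 19)
optimal_cutpoint(tabs$expression, tabs$survival, n_perm = 1000, seed = 20)
#> optimal cutpoint 172.1: high n=75, low n=85
#>   log-rank chi2 = 45.780, naive p = 1.323e-11, permutation p = 0.000999
#>   HR (high vs low) = 2.868 [1.900, 4.328]
#>   note: the naive p at a maximally selected cutoff is anti-conservative
```

The Mantel–Haenszel estimate (2.87, CI 1.90–4.33) covers the true
hazard ratio of 3.

`run_pipeline(pipeline_config(...))` chains all stages over a directory
of inputs (MAF + FASTA + signature TSV + BED + expression/survival
TSVs), writing TSV/JSON outputs and a manifest with parameters, seed and
input checksums; `write_simulated_cohort()` produces a matching input
directory from a `sim_config()`.

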