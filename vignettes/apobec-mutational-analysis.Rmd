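---
title: "Methods: quantifying the APOBEC mutational process in somatic SNV catalogs"
author: "apobecscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the APOBEC mutational process}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apobecscope)
```

# Scope and data model

`apobecscope` analyses somatic single-nucleotide variant (SNV) catalogs
for the footprints of APOBEC3 cytidine-deaminase activity: skew of the
trinucleotide mutation spectrum toward C>X at tCw motifs, localised
hypermutation showers (kataegis), the emergence of new SNVs in
overexpression experiments, and survival differences between
expression-defined patient groups.

All modules speak a small set of plain containers: a mutation catalog is
a `data.table` with one row per variant (sample, chromosome, 1-based
position, ref/alt alleles, variant type and classification), a reference
is a named list of uppercase contig strings (`ref_seq`), signature
catalogs are 96 × K probability matrices, and expression/survival tables
are two- and three-column `data.table`s. Readers for MAF, FASTA,
COSMIC-layout signature TSVs, BED4+ and TSV tables normalise external
conventions at the boundary: chromosome names are canonicalised to the
prefix-less dialect, BED's 0-based half-open intervals become 1-based
inclusive, catalogs are sorted and deduplicated on the
(sample, chrom, pos, ref, alt) 5-tuple, and the GDC allele convention
(`Tumor_Seq_Allele2`, falling back to `Tumor_Seq_Allele1` when it equals
the reference) picks the alternate allele.

# Trinucleotide spectra

Each SNV is assigned one of 96 channels: six pyrimidine-collapsed
substitution classes (C>A, C>G, C>T, T>A, T>C, T>G) by 16 flank pairs,
with the 5' flank varying slowest, each flank in A, C, G, T order — the
COSMIC channel order, asserted to match the signature catalog at fit
time. Purine-centred mutations are reverse-complemented onto the
pyrimidine strand, which makes every channel invariant under
reverse-complementing the reference and mirroring coordinates (a
property test in the suite). A record whose reference allele disagrees
with the reference sequence is an error carrying its locus; records
whose flank contains N or falls off a contig end are skipped with a
warning by default (real exome MAFs hit scaffold edges), with a strict
mode available.

# Signature deconstruction

The fit minimises the sum of squared channel errors (SSE) between the
proportion spectrum and a convex combination of reference signatures,
subject to non-negative weights summing to at most 1. The objective is
SSE on proportion vectors, not a likelihood, which keeps the fit
scale-invariant (multiplying all counts by a constant changes nothing —
a tested invariant).

The algorithm is greedy forward selection: start from the single
signature with the lowest SSE; at each step, optimise each candidate's
weight by golden-section search on [0, 1] (tolerance 1e-4 on the
weight), rescaling the whole weight vector back onto the simplex if it
overflows, and accept the best candidate while the relative SSE
improvement exceeds 1e-3. After convergence, signatures with weight
below the prune threshold (default 0.06) are dropped and the surviving
weights re-refined by golden-section coordinate descent; pruning and
refinement repeat until every retained weight clears the threshold, so
reported exposures are never below it. A `max_signatures` cap (default
10) bounds runtime on large catalogs and is reported when it binds.

On two-signature problems the fit agrees with an exhaustive 0.01-step
simplex grid search to within ±0.02 per weight (tested on random
spectra, and re-measured by the acceptance script), and recovers a
0.70/0.30 mixture from 2000 sampled SNVs within ±0.05. No trinucleotide
abundance renormalisation is applied by default; a positive 96-vector
pre-multiplier is accepted for exome/genome rescaling when the user has
one, because published analyses differ in this choice and it materially
changes exposures.

Retained signatures are joined against a bundled aetiology table
(ageing, APOBEC, mismatch-repair deficiency, POLE, artefact classes);
signatures commonly regarded as sequencing artefacts are flagged rather
than hidden.

# Motif enrichment score

For a sample, with motif M containing the mutated cytosine (the last C
of the IUPAC string, so `TCW` mutates the middle base and `CC` the 3'
one):

E = (mut_motif × ctx_C) / (mut_C × ctx_motif)

where `mut_C` counts the sample's C>X mutations on the collapsed strand,
`mut_motif` those whose neighbourhood matches M, and `ctx_motif`/`ctx_C`
count motif occurrences and cytosines (both strands) in ±`flank` bp
windows around each mutated site (default 20 bp; the value is a
convention, not printed in most publications, so it is a logged
parameter). Windows are not deduplicated when they overlap — each
mutation contributes its own window.

Two counting details matter for calibration and were chosen
deliberately:

* motifs are matched against a window slice extended by the motif
  length, so an occurrence whose flanking bases straddle the window edge
  still counts (counting its centre only if the centre lies in the
  window);
* window positions closer than the motif length to the mutated base are
  excluded from **both** context counts. Such positions can never be
  motif centres — their motif span covers the mutated site, whose base
  is fixed — and counting them toward `ctx_C` but never toward
  `ctx_motif` biases E upward by several percent even under uniformly
  placed mutations.

With these rules the trivial motif `C` gives E = 1 identically, and
under mutations placed uniformly over the cytosines of a sparse random
reference E is 1 within binomial error (both re-measured by the
acceptance script). Samples with no C>X mutations are flagged
not-evaluable instead of erroring; `ctx_motif = 0` with motif mutations
present yields E = +Inf, flagged. Classification uses a strict
`E > threshold` rule (default 2), and group comparisons report per-gene
two-sided Fisher exact tests with Benjamini–Hochberg correction plus
rank-sum burden tests; the test choices are recorded in the output
because source analyses often leave them unnamed.

# Kataegis

A rainfall table orders one sample's SNVs per chromosome and attaches
each mutation's distance to its predecessor; chains never cross samples
or chromosomes. Putative kataegis is any window of at least `k_min = 6`
consecutive mutations whose mean intermutational gap is at most
`d_max = 1000` bp (boundary inclusive). The detector reports the union
of all qualifying windows, merged when they share a mutation; because a
merged run can itself violate the mean-gap bound (two tight showers
bridged by sparse mutations), merged regions are re-checked and
recursively split at their largest gap until every reported region
satisfies the bound. This windowed-then-merge reading is one consistent
interpretation of the usual prose definition; the suite pins it to a
brute-force enumerator over all contiguous subsequences, and raising
`d_max` or lowering `k_min` never removes regions (a tested
monotonicity).

Regions are classified from their member records: C>X counts are
pyrimidine-collapsed (matching the spectrum convention — analyses that
count only +-strand C would halve the density); the C>X density uses the
first-to-last member span inclusive (a single-position span counts as
1 bp), and the enriched class applies the strict rule
density > 5 per 1000 bp. The strict TpC class requires every member to
be a C>X whose collapsed 5' neighbour is T, which implies the region's
C>X count equals its mutation count (a tested implication). Note that
the mean-IMD definition lets a tight shower absorb nearby background
mutations, stretching the span and diluting the density — so only a
minority of detected regions reach the enriched class, as in real
cohorts.

Gene annotation attaches every interval overlapping a region span by at
least 1 bp. Per-sample counts (total, enriched, strict, enriched
proportion) feed a Spearman correlation against expression (Pearson
optional; constant inputs are flagged degenerate rather than erroring)
and a comparison of the `top_n` highest- versus `bottom_n`
lowest-expression samples (defaults 25/25), with per-gene counts and
per-sample means per subgroup.

# Paired-catalog subtraction

Newly occurring variants of a treated line are the records whose
(chrom, pos, ref, alt) key is absent from the paired control — presence
only, with no VAF or depth matching, because the upstream question is
whether the variant exists. A position present in both catalogs with a
different alternate allele is therefore retained. Multi-sample catalogs
require an explicit pairing map; ambiguity is an error.

# Survival stratification

Kaplan–Meier estimation, the log-rank (Mantel–Cox) test and its O/E/V
decomposition are delegated to the `survival` package (events precede
censorings at tied times); the suite checks them against hand
product-limit computations and a textbook risk-set loop. The
Mantel–Haenszel hazard ratio is `(O_A/E_A)/(O_B/E_B)` with a 95% CI of
`exp(log HR ± 1.96/sqrt(V))` from the log-rank hypergeometric variance;
when one group has no events the ratio is degenerate and a 0.5
continuity correction is applied and flagged.

The optimal cutpoint scans midpoints between consecutive distinct
expression values whose split leaves each group at least `minprop`
(default 0.1) of the cohort, maximising the log-rank chi-square; ties
break toward the smaller cutoff, making the result deterministic. The
naive p-value at a maximally selected cutoff is anti-conservative —
the statistic was chosen to be extreme — so the result carries a
permutation-adjusted p (default 1000 seeded permutations of expression
against survival, re-running the full scan each time) next to the naive
one, and the printed output says so explicitly.

# Synthetic cohorts: what they emulate and what they do not

The generator is a pure function of its configuration and seed, used
both as the test bed and as a user-facing module:

* **Reference**: i.i.d. bases at a configurable GC fraction (default
  0.41, genome-like). No repeats, isochores or chromatin structure.
* **Background SNVs**: each mutation samples a 96-channel from the
  configured signature mixture, then a uniformly chosen reference
  position with the matching collapsed trinucleotide (without
  replacement per sample), written on the + strand. Empirical channel
  frequencies converge to the mixture (checked by chi-square
  goodness-of-fit and binomial-error bounds).
* **Kataegis showers**: anchors are uniform; successive gaps are
  geometric with configurable mean — memoryless gaps reproduce the
  rainfall appearance and no published generative model exists to
  prefer. Proposed positions snap to the nearest unused TpC site with
  probability `tpc_fraction`; snapped sites mutate to C>T with
  probability `c_to_t_fraction`, otherwise C>A/C>G. The default shower
  (size 8, mean gap 100 bp, 90% TpC, 80% C>T) is a tight
  APOBEC-flavoured cluster whose C>X density comfortably exceeds the
  5/kb class rule before background absorption.
* **Paired lines**: the treated catalog is the control plus fresh
  background from an APOBEC-skewed mixture and optional new showers;
  the truth table lists exactly the added records, giving
  `subtract_catalog()` a set-difference oracle.
* **Cohort tables**: expression is log-normal per group (medians 100
  and 1000 on a TPM-like scale, so the true cutoff is their geometric
  midpoint ~316); survival is exponential with the configured hazard
  ratio between groups under independent exponential censoring tuned to
  the expected censored fraction. A censoring rate of 1 yields the
  degenerate all-censored table that downstream tests must reject.

Passing tests on these cohorts establish that the detectors and
estimators recover known structure under idealised noise. They do not
establish performance on real tumour data: the generator has no
sequencing error, no variant-allele-frequency structure, no copy-number
or purity effects, no replication-timing or strand-asymmetry covariates,
and an unrealistic i.i.d. genome. Conclusions about real cohorts rest on
the correctness of the published definitions implemented here, not on
simulation fidelity.

# Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately desk-scale
sizes: 20 random catalogs of ~500 SNVs for detector/oracle equivalence,
20 replicate megabase cohorts (background 1 SNV/10 kb, showers of 8 at
mean gap 200 bp) for recovery, 2000–5000 sampled SNVs for signature and
enrichment checks, 500 null replicates at n = 100 for log-rank size and
200 replicates at n = 400 for hazard-ratio recovery. Golden-section
tolerance is 1e-4, the outer-loop stop is a relative SSE improvement of
1e-3, signature columns must sum to 1 within 1e-4 (renormalised) and
mixture weights to 1 within 1e-9. Ties in the cutpoint scan go to the
smaller cutoff; ties in kataegis splitting go to the first largest gap.
Degenerate inputs (empty spectra, constant expression, all-censored
tables, zero-event groups) raise typed errors or carry explicit flags
rather than propagating NaN.
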