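---
title: "Methods: placental genomic instability from expressed somatic variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: placental genomic instability from expressed somatic variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgin)
```

# Scope and model

`pgin` quantifies genomic instability in placental tissue from RNA-seq
derived somatic variant calls and relates it, together with a
transcriptional hypoxia score, to adverse pregnancy outcomes:
preeclampsia (PE), maternal vascular malperfusion (MVM) and
small-for-gestational-age (SGA) neonates. The package starts *after*
alignment, variant calling and annotation: its inputs are an annotated
MAF-like variant table (or minimal VCF), per-sample depth histograms as
produced by `bedtools genomecov`, a genes-by-samples expression matrix,
and cohort metadata.

The analysis has five stages.

1. **Filter cascade.** Calls are kept only if every *present* quality
   metric satisfies its strict inequality (DP > 10, GQ > 20, QD > 5,
   MQ > 40, ReadPosRankSum > −3, MQRankSum > −10, FS < 200, QUAL > 50);
   flagged RNA-editing sites, low-complexity calls and common variants
   are removed; rarity requires depth strictly above the assay
   threshold (50 for placental RNA, 10 for circulating RNA, 30 for WGS
   cell lines) and a population maximum allele frequency strictly below
   0.01; cohort-recurrence filters drop variants seen in more than 70%
   of samples (33% for the WGS preset) and whole genes mutated in more
   than 50% of samples. A rare variant is *damaging* if PolyPhen calls
   it damaging or SIFT deleterious or it is nonsense/nonstop, unless
   ClinVar asserts "benign" (the veto always wins). An `intersection`
   rule requiring PolyPhen and SIFT to agree is available because the
   source wording is ambiguous; `union` is the default.

2. **Genomic instability.** For each sample the *capture region* is the
   set of positions covered at or above the depth threshold, measured
   from the sample's own coverage histogram (RNA-seq has no panel, so
   the empirical covered region is the only meaningful denominator).
   The score is rare variants per megabase of capture region:
   `burden = n_rare / (covered_bases / 1e6)`. Indels count by default;
   `snv_only` restricts to SNVs. We deliberately use "≥ threshold" for
   the denominator and the strict "> threshold" for the per-variant
   depth filter, mirroring the two different phrasings each rule comes
   from; users who need a single convention can set the thresholds one
   apart.

3. **Mutational signatures.** Context-complete SNVs are mapped to the
   96 pyrimidine-centric trinucleotide channels in standard COSMIC
   order (purine-reference calls are reverse-complemented; the channel
   order is written into every catalog file because silent order
   mismatch is the classic failure mode when matching references).
   Signatures are extracted by non-negative matrix factorization
   minimizing Frobenius error with multiplicative updates: relative
   tolerance 1e-6, at most 5000 iterations, best of 10 seeded random
   restarts. Extracted signatures are normalized to probability vectors,
   labelled SBSA, SBSB, ..., and matched to a reference catalog by
   maximum cosine similarity (ties broken by reference order). The rank
   K is user-chosen; reconstruction error is non-increasing in K, so an
   error-vs-K scan plus the stability of reference matches is the
   intended selection aid. The packaged reference
   (`inst/extdata/synthetic_sbs_reference.tsv`) contains four
   *synthetic* profiles whose shapes mimic well-known families
   (CpG-deamination clock-like, flat endogenous, C>A oxidative-damage,
   T>A slippage); real analyses should supply the published catalog
   they target via `read_reference_signatures()`.

4. **Hypoxia score.** For every signature gene present in the matrix,
   samples strictly above the per-gene cohort median score +1,
   otherwise −1 (ties at the median score −1 under the strict ">"
   reading; `tie_score = 0` is available because the equal case is not
   specified by the upstream scoring method). Per-signature scores are
   sums over genes; the `combined` score sums the per-signature scores
   and is the default downstream feature, with both emitted so either
   reading can be used. Because only ranks relative to the median
   matter, the score is invariant to strictly increasing per-gene
   transforms; cross-sample normalization of the expression matrix
   remains the caller's responsibility.

5. **Outcome statistics and prediction.** Group comparisons use
   Mann-Whitney U tests (two-sided by default; one-sided on an explicit
   direction) with Benjamini-Hochberg correction applied across the
   pairs of one call — cross-call families are the caller's
   responsibility. Enrichment uses Fisher's exact test; both the
   conditional-MLE odds ratio (with exact CI) and the cross-product
   sample odds ratio are reported because the convention behind
   published OR values is often unstated. The gestational-age-to-event
   model is a Cox proportional-hazards fit with gestational age at
   delivery as the time axis, Breslow ties, and a ridge penalizer
   chosen from {0, 0.01, 0.1, 1} by 5-fold cross-validated partial
   log-likelihood (Verweij–van Houwelingen). Proportional-hazards
   assumptions are checked per feature with the scaled-Schoenfeld score
   test (`survival::cox.zph`) at p = 0.05 on the unpenalized companion
   fit; failing features are squared and the model refit exactly once.
   `ph_check = FALSE` keeps the plain proportional fit, which is what
   simulation studies of the estimator itself should use. Partial-effect
   curves evaluate the Breslow baseline cumulative hazard at covariate
   vectors holding the feature of interest at its 10th and 90th
   percentiles and the remaining features at their means.
   Classification uses k-nearest neighbors (k = 5, Euclidean distance,
   uniform weights, no standardization by default because the reference
   workflow reports default parameters with no scaling step; a
   `standardize` flag exists). Cross-validation is stratified 5-fold
   with seeded fold assignment; out-of-fold probabilities are pooled
   into a single ROC whose AUC is the trapezoid area, equal to the
   tie-adjusted pair-counting U statistic scaled by n_pos·n_neg.
   Distance ties break by training-set order and fetal sex is encoded
   0/1 — both choices exist so that results are exactly reproducible.

# The synthetic cohort generator

Every stage is tested against cohorts with planted, known parameters
(`simulation_spec()` / `simulate_cohort()`). Defaults are the study
conditions the pipeline targets: 112 samples in four clinical groups
(23 EP-N, 30 NTT-N, 20 EP-PE, 39 NTT-PE, with early preterm defined by
gestational age < 34 weeks), a doubled rare-variant rate in EP-PE,
group-specific signature mixtures (EP-PE dominated by the
oxidative-damage-like profile with a minor T>A component, EP-N by the
flat endogenous profile), hypoxia signature genes shifted up by 1.5
log2 units in every group except NTT-N, and a planted log hazard ratio
of ln(1.7) per unit burden on the gestational-age axis. Where the
source material gives no value we fixed one realistic choice once: a
Poisson mean of 150 called variants per sample, 35% of them rare, 25%
of rare variants damaging, 15% planted quality failures, 10% artefact
flags, capture regions of 30–60 Mb, and a Beta(2,2) variant allele
fraction (the generator makes no claim of matching any published VAF
range).

Two generation modes exist because the cohort design and the hazard
model cannot both be held exactly:

* **fixed-groups** (default): group sizes are exact, gestational ages
  are drawn inside each group's window, and PE flags follow the group.
  This is the mode for design-shaped demonstrations and group tests.
* **hazard** (`group_scheme = NULL`): gestational age at delivery and
  the PE event are drawn from an exponential baseline hazard (0.08 per
  week past week 20, censoring at week 42) multiplied by
  `exp(beta_burden * burden + beta_hypoxia * hypoxia)` using the
  *realized* planted covariates, and groups are derived afterwards.
  Because the hazard uses the same covariate values the Cox model later
  sees, parameter-recovery tests measure the estimator, not attenuation
  from simulation noise.

One master seed fans out to fixed per-component substreams (metadata,
coverage, variants, expression, survival), so regenerating one
component does not disturb the others and written bundles are
byte-identical across runs.

What the generator does *not* emulate: alignment artefacts, true
RNA-editing biology (flags are drawn labels), linkage between variants,
transcript-level expression structure, or informative censoring.
Passing recovery tests therefore demonstrate correctness of the
*computations* under the planted model, not fidelity of any biological
claim about real placentas.

# Numerical choices and degenerate inputs

* Missing quality metrics satisfy their predicate vacuously (RNA-seq
  callers omit rank-sum statistics at homozygous sites; discarding on
  missingness would silently empty real data); `strict_missing_quality`
  flips this. Missing MAX_AF counts as rare by default
  (`missing_af_is_rare`), reading absence from population catalogs as
  evidence of rarity.
* Recurrence denominators are the number of samples in the analysis
  set, not the number of samples bearing variants; variant identity is
  (chrom, pos, ref, alt).
* All thresholds are strict inequalities exactly as printed; boundary
  values (DP = 10, MAX_AF = 0.01, FS = 200, 34.0 weeks) fail.
* Zero covered bases raises an explicit undefined-score error (a
  coverage-QC failure), never a silent 0 or Inf.
* An all-zero catalog refuses factorization; samples with zero total
  exposure are excluded from group contributions with a log message.
* Cox fits require ≥ 20 samples, no missing features, and non-degenerate
  event times; Breslow ties make the estimate invariant under
  duplicating every row.
* `fisher.test`'s two-sided convention (summing all tables with
  probability ≤ observed) is used for enrichment because it matches the
  dominant implementations.

# Problem sizes used by the test suite

The packaged checks run, per criterion: 50 random 50–500-variant
fixtures against a brute-force predicate oracle across all three
presets and both damaging rules; 200 random histograms for
covered-region monotonicity; signature recovery on 50 samples × 2000
mutations at K = 3 plus a 10000-mutation single-signature catalog;
exhaustive Fisher enumeration over every 2×2 table with all margins
≤ 15, Mann-Whitney enumeration up to 8 + 8, and 25 random BH vectors;
Cox recovery on one 500-sample hazard-mode cohort with 400 null
replicates and 100 coverage replicates at n = 300 per replicate (the
Wald test's finite-sample type-I rate is mildly inflated below n ≈ 200,
so calibration is assessed at a size where its nominal behaviour is
expected to hold); 50 label-permutation replicates for the classifier;
and a byte-identity rerun of the full pipeline on a 36-sample cohort.

# Known limitations

* The NMF solver is a plain Frobenius multiplicative-update scheme;
  it is adequate for the catalog sizes here but offers no sparsity
  penalties or automatic rank selection.
* The square-and-refit response to a proportional-hazards failure is a
  single pass by design; genuinely time-varying effects need a
  different model.
* The hypoxia score treats genes symmetrically; signatures mixing up-
  and down-regulated genes would need signed gene lists, which the
  two-column input format does not carry.
* Only single-base-substitution signature classes are supported — no
  indel or doublet channels and no strand-bias decomposition.
* The KNN classifier is deliberately minimal (fixed k, no calibration);
  it is a biomarker sanity check, not a production risk model.
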