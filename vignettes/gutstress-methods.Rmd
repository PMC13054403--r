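---
title: "Methods: linking gut microbiome composition to acute stress reactivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking gut microbiome composition to acute stress reactivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutstress)
```

## The design being modeled

A cohort of healthy adults is randomized to an acute-stress induction or a
non-stressful control condition. Salivary cortisol and subjective stress
ratings are collected at seven timepoints: a day-1 baseline (T0) and six
day-2 samples at −57, 0, +23, +40, +59 and +84 minutes relative to stress
induction (T1–T6; T2 = 0 is the immediate pre-stress baseline). Each
participant contributes one baseline stool sample profiled by 16S amplicon
sequencing into an ASV count table with SILVA-style taxonomy. The analysis
asks whether between-person variation in gut microbial alpha diversity and
in taxonomy-inferred SCFA production capacity predicts cortisol and
subjective stress reactivity, post-stress recovery, and AUC summaries.

## Microbiome processing

The canonical order is rarefy → filter → summarize, with diversity taken
from the processed table:

1. **Rarefaction** subsamples each sample's reads without replacement
   (multivariate hypergeometric, one draw per sample, via
   `vegan::rrarefy()` under a fixed seed) to the minimum library size by
   default; a fixed depth can be pinned. Samples below the target depth
   are a hard error — nothing is dropped silently.
2. **Rare-ASV filtering** zeroes, within each sample, ASVs whose
   within-sample relative abundance is strictly below 0.1% (an ASV at
   exactly 0.1% is retained). Counts are not renormalized afterwards;
   downstream relative abundances are recomputed from the filtered counts,
   which keeps the table integer and makes filtering idempotent.
3. **Summaries**: Shannon entropy in natural-log units (nats), inverse
   Simpson, observed richness; genus-level aggregation pools ASVs with a
   missing genus into an explicit "unassigned" taxon (which is never
   SCFA-annotated); the Firmicutes/Bacteroidetes ratio is computed on
   relative abundances, with a missing value — never infinity — when a
   sample has no Bacteroidetes reads.

Whether diversity is computed on the filtered or the merely rarefied table
is exposed as `diversity_on`; the default is `"filtered"`, the same table
used for capacity scoring, so all microbiome covariates describe one
consistent community snapshot.

## SCFA production capacity

Capacity is a taxonomy-based proxy, not a metabolite measurement: the
summed relative abundance of genera annotated as butyrate or propionate
producers, one value per SCFA per sample. Production is a binary genus
phenotype — a genus with several biosynthesis pathways for the same SCFA
counts once. Acetate is excluded by design because its pathway is
near-ubiquitous in gut bacteria and carries no discriminating signal.
Genus matching is exact and case-sensitive after whitespace trimming;
fuzzy matching was rejected because silent mis-joins across taxonomies are
worse than missed coverage.

## Stress statistics

Cortisol is log-transformed (natural log; the base only rescales
coefficients) and a missing day-1 baseline (T0) may be filled by linear
extrapolation from the T1–T2 pair — the only imputation the design admits.
Reactivity is the rise from T2 to the post-stress peak (the larger of T3
and T4; ties resolve to the earlier T3), divided by the elapsed minutes;
recovery is the analogous decline from the peak to T5. Normalizing by
elapsed time makes the statistics comparable across participants whose
sampling times drifted. The recovery window ends at T5 exactly as designed
even though a brief stress reminder precedes it — the statistic mirrors
the protocol rather than correcting it. AUCg is the trapezoidal area over
a configurable window (default T2..T5, the reactivity-plus-recovery
span); AUCi subtracts the rectangle at the window's first value.
Subjective ratings go through the identical slope operations on the raw
1–7 Likert scale, untransformed.

## Robust regression

The modeling engine is Huber M-estimation fitted by iteratively reweighted
least squares, written in-package:

- initialize at OLS; each iteration recomputes residuals, the robust scale
  `s = median(|r|)/0.6745` (MAD about zero, consistent for the Gaussian
  sigma and re-estimated every iteration), Huber weights
  `w = min(1, k/|r/s|)`, and a weighted least-squares update;
- convergence is the maximum absolute coefficient change below 1e-8
  (default cap 200 iterations; non-convergence returns the fit flagged
  `converged = FALSE` with a warning — common and acceptable for
  very small stratified fits);
- `k = 1.345` by default, the conventional constant giving 95% Gaussian
  efficiency;
- standard errors use the standard M-estimator asymptotic covariance with
  the usual small-sample correction, and coefficient tests use the normal
  reference (z statistics), matching the reporting convention for
  `rlm`-style fits;
- model fit is the variance-based R² = 1 − SSres/SStot with SStot about
  the mean of the observed response (so robust and OLS fits are
  comparable on the same scale), and the adjusted form multiplies the
  residual ratio by (n−1)/(n−p−1) with p excluding the intercept.

An interpolating fit drives the robust scale to numerical noise; scale
below 1e-10 of the response spread is treated as exactly zero, giving zero
standard errors and undefined (NA) tests rather than astronomically
inflated z values.

Every robust fit is paired with an OLS companion for stability checks:
classical R², leverage, and Cook's distance flagged at the conventional
4/n threshold. The tests verify Cook's distance against a leave-one-out
refit oracle, and verify that under contamination the robust model's
winsorized residual account (weight-scaled residuals, bounded by the psi
function) is more symmetric than the OLS residuals while the weighted
fit's maximum Cook's distance shrinks.

## Model families and reduction

The maximal model per outcome is
`outcome ~ sex + trait anxiety + perceived stress (+ baseline cortisol) +
microbiota term (* group)`, with baseline cortisol entering only the
cortisol outcomes. Three families are fitted: across groups with the
microbiota × group interaction, stress-only, and control-only. Group is
coded control = 0 / stress = 1 and sex female = 0 / male = 1; continuous
predictors are z-scored within the modeled set, so coefficients are per
standardized unit — exact reproduction of raw-scale coefficients from any
particular dataset is deliberately not attempted, since the original
scaling of such coefficients is generally unknowable.

`backward_eliminate()` operationalizes iterative model reduction: refit,
remove the unprotected term with the largest p above alpha, stop when all
unprotected terms are significant *or when removal would reduce the
adjusted variance-based R²* (the "maximum explained variance" rule). The
microbiota term, group, their interaction, and any main effect inside a
retained interaction are protected; which terms an analyst protects is
genuinely open, and this hierarchy-preserving rule is the package's
declared choice. The pipeline fits maximal models by default
(`eliminate = FALSE`) so coefficient tables are directly comparable across
terms and families.

No cross-family multiplicity correction is applied; Holm correction is
reserved for the per-timepoint post-hoc family, mirroring the analysis
design.

## Group-level statistics

The stress-induction check is a mixed between-within ANOVA (group ×
timepoint) on log cortisol. Sums of squares are computed by the direct
balanced-design decomposition (verified in the tests against `aov()`
error strata); within-subject effects carry the Greenhouse–Geisser epsilon
computed from the pooled within-group covariance via orthonormal
contrasts, multiplying both degrees of freedom. Effect sizes are
generalized eta-squared (effect SS over effect SS plus all error SS) —
whether a given report's eta-squares are partial or generalized is often
unstated, and generalized is the declared choice here. Post-hoc
per-timepoint comparisons are Student t-tests by default (Welch optional;
the choice is rarely reported and is exposed as a flag) with Holm
correction across the timepoint family and pooled-SD Cohen's d.
Comparability checks use the Yates-corrected chi-square (2×2) and Fisher's
exact test for small 2×k tables.

## The synthetic cohort generator

The generator exists so the whole pipeline is testable end to end with
known ground truth. What it emulates, and its defaults:

- **Cohort**: 35 stress / 39 control participants, the study group sizes.
- **Microbiome**: genus base abundances follow a log-normal rank-abundance
  curve (60 genera, 240 ASVs nested within them); per-sample counts are
  Dirichlet-multinomial around the base composition (total concentration
  300 — sample-to-sample compositional variability of a realistic
  magnitude) with library sizes uniform on 6,000–20,000 reads, so the
  default rarefaction depth lands near the minimum library size of a real
  run. No generative model for the compositional process is prescribed by
  the design; Dirichlet-multinomial is the field's standard choice and the
  concentration is exposed in the configuration.
- **Producer calibration**: genera are flagged as producers greedily from
  the most abundant down, taking each genus only when it moves the
  cumulative expected producer abundance closer to the target (butyrate
  0.29, propionate 0.89 — the observed cohort means at two digits). The
  greedy nearest-step rule guarantees the calibration is reachable
  regardless of the rank-abundance curve's skew.
- **Covariates**: GAD-7 integers bounded 0–21 around 6 ± 4, PSS bounded
  0–40 around 17 ± 7 (instrument ranges; the exact population
  distributions are not published, so these are stated choices, not
  inferences), afternoon baseline cortisol log-normal around 7 nmol/L,
  ~60% female, plus BMI, diet, birth mode and early nutrition at
  plausible population frequencies.
- **Planted effects**: the latent reactivity slope is generated from
  exactly the linear model the pipeline fits, with default coefficients on
  the scale of the published tables (interaction 0.003 log-nmol/L per
  minute per SD of diversity; residual SD 0.004). The Shannon index
  entering the latent model is computed through the same
  rarefy-and-filter chain the profiling module applies, seeded with the
  configuration seed, so an analysis run with the same seed sees the
  identical predictor and parameter recovery is not attenuated by
  rarefaction noise.
- **Trajectories**: noise enters at the latent level only. Rendering
  inverts the slope definitions deterministically — peak at T3 or T4
  (Bernoulli 1/2 per participant; both peaks occur in practice), rise
  equal to reactivity × elapsed minutes, fall equal to recovery × elapsed
  minutes — so slope extraction is an exact round trip (the tests demand
  1e-9; the achieved error is at machine precision). Latent recovery is a
  partial return toward baseline (uniform 50–90% of the rise recovered by
  T5). Subjective ratings peak mostly at T3 (appraisal precedes the
  hormonal peak) and are kept continuous rather than integer so their
  round trip is exact too.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: sequencing noise and contamination,
compositional artefacts beyond multinomial sampling, microbiota dynamics
over time, circadian structure in cortisol, integer-valued ratings, and
real covariate correlation structure (covariates are drawn independently).
Parameter-recovery results certify the estimation machinery, not the
biology.

## Numerical choices and degenerate inputs

- Rarefaction, covariate draws and model fits are deterministic under the
  configuration seed; repeated runs are byte-identical including written
  CSVs.
- T3/T4 peak ties resolve to T3; the tie rule matters only on a
  measure-zero set but is fixed for determinism.
- All-zero samples, samples below rarefaction depth, missing non-T0
  values, non-positive cortisol, rank-deficient designs, zero response
  variance and zero-margin contingency tables are hard errors naming the
  offending unit; undefined statistics (F/B with no Bacteroidetes, t with
  zero variance, Cook's distance at leverage 1) are reported as missing
  values, never infinities.
- The problem sizes used by the test harnesses are chosen to make the
  statistical assertions sharp at desk scale: 1,000 participants for
  round-trip and recovery checks, 200 samples for capacity calibration,
  50 seeds for interaction recovery, 200 seeds for the null rejection
  rate.

## Known limitations

- Capacity scores depend entirely on the producer annotation supplied;
  the package ships no curated map and makes no attempt to reconcile
  divergent taxonomy-to-pathway mappings (a real analysis at ~89%
  propionate prevalence should treat that figure as
  classification-dependent).
- Only Huber's psi is implemented (no Tukey bisquare or sandwich
  covariance variants), and only Greenhouse–Geisser correction (no
  Huynh–Feldt or Mauchly reporting).
- The exact covariance formula behind any given report's robust standard
  errors is generally unverifiable; the standard M-estimator form used
  here matches `MASS::rlm` to high precision in the cross-checks.
- Beta diversity, phylogenetic metrics, per-timepoint mixed models and
  power analysis are out of scope.
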