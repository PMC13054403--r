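# gutstress

Links gut-microbiome composition to the acute stress response in healthy
adults. The package implements, as a tested and reusable pipeline, an
analysis design in which participants undergo a standardized acute-stress
induction (or a non-stressful control condition), salivary cortisol and
subjective stress are sampled repeatedly around the stressor, and each
participant's baseline stool sample is profiled by 16S amplicon sequencing.
The question it answers: do alpha diversity and the inferred capacity to
produce the short-chain fatty acids (SCFAs) butyrate and propionate predict
how strongly a person reacts to — and recovers from — acute stress?

It is written for microbiome/psychobiology researchers who want the whole
chain in one place: ASV-table processing, taxonomy-based SCFA capacity
scoring, cortisol slope statistics, and a robust-regression framework —
plus a synthetic-cohort generator with planted effects so every stage is
testable without sequencing data.

## The statistics at the core

**Stress statistics.** With cortisol log-transformed and T2 the
pre-stress baseline,

    reactivity = (max(v_T3, v_T4) − v_T2) / (t_peak − t_T2)
    recovery   = (v_T5 − v_peak) / (t_T5 − t_peak)

in log-nmol/L per minute, normalizing for between-participant differences in
sampling times. AUCg/AUCi (trapezoidal area with respect to ground and
increase) summarize the same window. Subjective stress ratings use the same
slope formulas on the raw Likert scale.

**Microbiome summaries.** Counts are rarefied to a common depth
(multivariate hypergeometric subsampling), ASVs under 0.1% within-sample
relative abundance are zeroed, and Shannon (nats), inverse Simpson and
observed richness are computed from the processed table. SCFA production
capacity is the summed genus-level relative abundance of annotated butyrate
or propionate producers — a binary genus phenotype, acetate excluded.

**Robust models.** Each outcome is regressed on a microbiota measure plus
biological sex, trait anxiety (GAD-7), perceived stress (PSS) and baseline
cortisol using Huber M-estimation fitted by IRLS (scale = MAD/0.6745
re-estimated per iteration, k = 1.345), with `z = b/SE` tests against the
normal reference and model fit reported as the variance-based
R² = 1 − SSres/SStot and its adjusted form
1 − (SSres/SStot)·(n−1)/(n−p−1). Every robust fit has an OLS companion
with Cook's-distance diagnostics (4/n threshold). Three model families are
fitted: across groups (with a microbiota × group interaction), stress-only,
and control-only.

## Worked example

```r
library(gutstress)

cfg     <- simulation_config(seed = 42)          # 35 stress / 39 control
cohort  <- render_trajectories(simulate_cohort(cfg))
results <- run_pipeline(cohort, seed = 42)
results
#> <gutstress_results>
#>   74 participants modeled, 90 fitted models
#>   sex comparability: chi2 = 0.000, p = 1.000
#>   group x time ANOVA: F(1.14, 81.94) = 10.696, p = 0.001004

mt <- results$model_table
mt[mt$outcome == "reactivity" & mt$term == "shannon" &
     mt$family == "across_groups", c("predictor", "b", "se", "z", "p")]
#>               predictor         b       se      z        p
#> 1           (Intercept) -0.004858 0.000639 -7.598 3.02e-14
#> 2                   sex  0.002152 0.000856  2.513 1.20e-02
#> 3                  gad7  0.003248 0.000412  7.889 3.05e-15
#> 4                   pss -0.001549 0.000397 -3.900 9.61e-05
#> 5 baseline_log_cortisol -0.001318 0.000401 -3.289 1.00e-03
#> 6               shannon  0.000144 0.000573  0.251 8.02e-01
#> 7                 group  0.005214 0.000820  6.362 1.99e-10
#> 8         shannon:group  0.002285 0.000804  2.841 4.50e-03
```

Reading the table: the cohort was simulated with a positive
diversity-by-group interaction of 0.003 on the latent reactivity slope, and
the fitted `shannon:group` coefficient (0.0023, p = 0.0045) recovers it —
higher Shannon diversity predicts higher cortisol reactivity in the stress
group but not in controls (`shannon` main effect ~ 0). Units are
log-nmol/L per minute per standardized predictor. The group-by-timepoint
ANOVA line confirms the stress induction separated the cortisol
trajectories.

`tidy()` and `glance()` work on every fit, `autoplot()` shows the
IRLS-weighted residuals, and `plot_trajectories()` reproduces the classic
group-mean cortisol time course. `write_fixtures()` /
`run_pipeline("dir/")` round-trip everything through plain-text files, and
`inst/cli/gutstress.R` exposes `simulate` and `run` subcommands for shell
use.

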