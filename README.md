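# methmod

Moderation analysis of smoking-associated DNA methylation.

`methmod` asks a specific epigenomic question: given a panel of CpG loci
whose methylation responds to cigarette smoking, does a subject-level
moderator — a composite methylation index such as promoter methylation at
*MTHFR* (mMTHFR) — amplify or blunt those responses? The package is aimed at
EWAS analysts working with Illumina 450K-style beta values (methylation
fractions in \[0,1\]) and a phenotype table of exposure, demographics and
leukocyte composition.

## The model

Per locus, methylation is modeled by **beta regression** with a logit mean
link and constant precision: `y_i ~ Beta(mu_i * phi, (1 - mu_i) * phi)` with

```
logit(mu_i) = b0 + bS·S_i + bM·M_i + bSM·S_i·M_i + b_male·male_i + b_age·age_i
```

where `S` is smoking status (or average consumption on a 0–6 scale) and `M`
the moderator index (the per-sample mean of z-scored beta values at its
probes). Model 1 omits the interaction `bSM`; Model 2 adds it. The fit is
maximum likelihood (quasi-Newton with analytic score, Newton polishing,
observed-information standard errors, two-sided Wald tests).

A locus's *direction class* is the sign of the Model 1 smoking coefficient
(hyper-methylating if smokers are more methylated, hypo otherwise); its
*interaction sign* is the sign of `bSM`. Cross-classifying significant loci
gives a 2×2 direction-by-sign table whose **uncorrected Pearson chi-square**
tests sign consistency — the headline statistic for the claim that the
moderator shifts hyper- and hypo-methylating responses in systematically
opposite directions. Sign-concordant loci (hypo direction with positive
interaction; hyper with negative) are then standardized and averaged into
hypo/hyper **outcome indices**, which are regressed on smoking, the
moderator, their interaction, sex, age, diet and five cell-type fractions by
OLS, with simple slopes at moderator values ±1 SD explicating the
interaction.

Supporting machinery: detection-p/beadcount QC filters, design-type-stratified
quantile normalization, a boundary "squeeze" transform into (0,1),
reference-based cell-type deconvolution by constrained projection
(`min ||y − Rw||²` s.t. `w ≥ 0`, `Σw ≤ 1`), and a synthetic cohort
generator with recorded ground truth for every locus.

## Worked example

```r
library(methmod)

cfg    <- generator_config(seed = 42)   # 180 samples, 300 loci + background
cohort <- simulate_cohort(cfg)
report <- run_pipeline(cohort)
print(report)
#> Moderation pipeline report (status, tier nominal, alpha 0.05)
#> Scanned 300 loci; 108 classified (hyper-:27 hyper+:3 hypo+:74 hypo-:4)
#> Sign-consistency chi-square(1) = 76.263, log10 p = -17.61; concordant fraction 0.935
```

108 of the 300 scanned loci show a nominally significant smoking ×
moderator interaction; 93.5% of them fall in the sign-concordant cells
(hyper-direction loci with negative interactions, hypo with positive), and
the chi-square rejects independence of direction and sign emphatically —
the generator's built-in moderation pattern, recovered end to end.

```r
report$simple_slopes$hypo
#> # A tibble: 2 × 4
#>   moderator_level moderator_value  slope intercept
#> 1 -1 SD                    -0.965 -1.65      0.327
#> 2 +1 SD                     0.965  0.409     0.286
```

The smoking effect on the hypo-methylation index is strongly negative for
subjects one SD below the moderator mean and near zero one SD above it: low
moderator values exaggerate the hypo-methylating response, high values blunt
it. `autoplot()` draws the corresponding crossing lines;
`tidy()`/`glance()` give broom-style tables for every fitted model.

The sign-consistency statistics can also be computed directly from counts:

```r
tab <- contingency_table(hyper_pos = 7, hyper_neg = 66,
                         hypo_pos = 205, hypo_neg = 14)
pearson_chi2(tab)
#> # A tibble: 1 × 4
#>   statistic    df  p_value log10_p
#> 1      194.     1 3.66e-44   -43.4
row_proportions(tab)
#> # A tibble: 2 × 3
#>   direction positive_pct negative_pct
#> 1 hyper              9.6         90.4
#> 2 hypo              93.6          6.4
```

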