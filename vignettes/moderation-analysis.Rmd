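---
title: "Moderated EWAS analysis with methmod: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moderated EWAS analysis with methmod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`methmod` implements a moderated epigenome-wide analysis: per-locus beta
regressions testing whether a subject-level methylation index (the canonical
example is promoter methylation at *MTHFR*, "mMTHFR") moderates
smoking-associated methylation change, a sign-consistency chi-square over
the resulting interaction pattern, composite outcome indices, and
covariate-adjusted index-level regressions. This vignette explains the
models and their assumptions, the tunable parameters, what the synthetic
cohort generator does and does not emulate, and the numerical choices made
where the design was genuinely open.

## The per-locus model

Methylation beta values live on \[0,1\] and are typically skewed and
heteroscedastic, so per-locus inference uses beta regression rather than
OLS. In the mean–precision parameterization the response is
$y \sim \mathrm{Beta}(\mu\phi, (1-\mu)\phi)$, giving
$\mathbb{E}[y] = \mu$ and $\mathrm{Var}[y] = \mu(1-\mu)/(1+\phi)$. The mean
is linked through the logit:

$$
\operatorname{logit}(\mu_i) = b_0 + b_S S_i + b_M M_i + b_{SM} S_i M_i
  + b_{male}\,\mathrm{male}_i + b_{age}\,\mathrm{age}_i ,
$$

with $S$ binary smoking status (or continuous 0–6 consumption in the
sensitivity variant) and $M$ the moderator index. Model 1 drops the
interaction term; Model 2 includes it. Assumptions worth stating:

* **Constant precision.** $\phi$ is a single scalar with a log link — no
  precision submodel. Per-locus tables in this literature report only
  mean-model terms, and a precision submodel would add parameters the
  180-sample design cannot support.
* **Wald inference.** Two-sided p-values from $z = \hat b/\widehat{SE}$
  against the standard normal, matching single-coefficient p-values as
  reported in the field. No likelihood-ratio or robust-variance options.
* **Covariate set.** The per-locus models adjust for age and sex only.
  Diet and cell-type fractions enter the index-level OLS models instead.
  This split follows the analysis design this package operationalizes; its
  statistical consequence is quantified below.

Fitting is maximum likelihood: BFGS on the negative log-likelihood with the
analytic score, started from an OLS fit of $\operatorname{logit}(y)$ (for
$b$) and a method-of-moments precision, then polished with damped Newton
steps until the score's largest component is below $10^{-9}$. Standard
errors come from the inverse observed information, evaluated by central
finite differences of the analytic score with step
$10^{-5}\max(1,|\theta_j|)$. A fit is flagged non-converged when the final
gradient norm exceeds $10^{-5}$ or the information matrix is not positive
definite; the scan records such loci but never classifies them.

Because the beta likelihood is undefined at 0 and 1, observed values are
first mapped into the open interval by the usual compression
$y' = (y(n-1) + 0.5)/n$ with $n$ the number of samples. The transform is
affine, so it preserves order, fixes 0.5, and leaves z-scored indices
unchanged.

## Scan, classification, and the sign-consistency statistic

`scan_loci()` fits both models at every locus of the panel (input order,
one record per locus). Interaction p-values receive Bonferroni
($\min(1, mp)$, $m$ = number of loci scanned) and Benjamini–Hochberg
step-up adjustment. `classify_interactions()` keeps loci whose interaction
p at the chosen tier falls below $\alpha$ (default 0.05, two-sided) and
cross-classifies them by direction class — the *sign of the current
sample's Model 1 smoking coefficient*, not an external catalogue — and
interaction sign.

The 2×2 direction-by-sign table is tested with the **uncorrected** Pearson
chi-square (1 df). No Yates correction is applied: the uncorrected statistic
is the convention this analysis reproduces. The upper-tail p-value is
evaluated in log space (`pchisq(..., log.p = TRUE)`), so the astronomically
small values a strongly consistent pattern produces (order $10^{-44}$ for
the motivating table) remain representable; `pearson_chi2()` reports both
`p_value` and `log10_p`.

## Indices and index-level models

A composite index is the per-sample mean of per-probe z-scores (sample SD,
$n-1$ denominator), computed on the full post-QC analysis sample — smokers
and non-smokers together — so every index has mean zero by construction.
The moderator index defaults to the probes annotated to *MTHFR*; an
alternative wider probe set is just a different `probes` argument to
`build_index()`. Outcome indices are built from the *sign-concordant*
classified loci only: hypo-direction loci with positive interactions, and
hyper-direction loci with negative interactions.

Index-level inference is OLS with classical standard errors and
t-distribution p-values: outcome regressed on smoking, moderator, sex, age,
diet, and the five cell-type fractions (Model 1), plus the
smoking × moderator product (Model 2). Simple slopes
$b_S + b_{SM} m$ at $m = \pm 1$ SD of the moderator explicate the fitted
interaction; plot-ready intercepts evaluate the remaining covariates at
their sample means. The Bonferroni-restricted index analysis is the same
code path with classification tier `"bonferroni"`.

## Preprocessing

* **Sample filter:** drop a sample when *strictly more than* 1% of its
  probes have detection p > 0.05. **Probe filters:** drop a probe when its
  beadcount is below 3 in *at least* 5% of samples, or detection p exceeds
  0.05 in *at least* 1% of samples. The strict/attained asymmetry follows
  the wording conventions of the protocol being reproduced; both thresholds
  are arguments.
* **Quantile normalization** forces every sample in a stratum to the mean
  order-statistic reference, ties receiving the mean of their tied
  reference quantiles (deterministic). When a probe annotation provides
  design types, normalization is stratified by design type. This is a
  beta-value-level analogue of intensity-level Type-I/II-aware
  normalization: the full intensity pipeline needs raw channel data this
  package does not model, and the operative property — between-sample
  distribution alignment within design strata — is preserved at the data
  level the pipeline owns. Idempotence and within-stratum distribution
  equality are tested invariants.
* **Deconvolution.** Cell fractions are estimated per sample by constrained
  projection onto reference profiles: minimize $\|y - R\omega\|^2$ subject
  to $\omega \ge 0$ and $\sum\omega \le 1$. The inequality (rather than
  equality) sum constraint reflects a mononuclear-cell reference panel that
  does not span granulocytes, so fractions legitimately sum below 1. The
  QP is solved exactly by enumerating KKT active sets — at most
  $2^{k+1}$ tiny equality-constrained solves for $k$ cell types, exact and
  deterministic for the small panels used here ($k \le 15$ enforced). All
  reference probes are used; discriminating-probe selection is a property
  of reference construction, which is synthetic in this package.

## The synthetic cohort generator

The generator is the package's test bed: it draws cohorts with recorded
ground truth whose statistical structure mirrors the study design this
analysis targets.

**Phenotypes.** Smoking is Bernoulli(0.483); age Normal(48.861, 8.586²)
years; sex Bernoulli(0.372) male; diet uniform on {1..4}; consumption a
noisy monotone function of smoking truncated into \[0,6\] (non-smokers
near 0, smokers centered near 2.7), supporting the consumption-based
sensitivity models without a longitudinal simulator. The latent moderator
is standard normal with correlation 0.412 with the male indicator. Cell
fractions are Dirichlet with means (0.137, 0.284, 0.071, 0.165, 0.144) and
concentration 50 — realistic between-subject variability around the target
means — with per-sample Dirichlet means tilted on the log scale by the
latent moderator. The tilt vector was calibrated once so the simulated
moderator/cell-fraction correlations reproduce the observed cohort pattern
(about −0.20, −0.30, +0.08, +0.18, +0.19 for CD8T, CD4T, NK, B, Mono);
because fractions are compositional, the small positive correlations
cannot be pushed lower without distorting the large negative ones.

**Loci.** Default panel: 300 scanned loci — 24 hyper-methylating
($b_S > 0$, $b_{SM} < 0$), 73 hypo-methylating ($b_S < 0$, $b_{SM} > 0$),
203 interaction-null ($b_{SM} = 0$, random-signed $b_S$) — mirroring, at
desk scale, a smoking-associated panel in which roughly a third of loci
carry genuine moderation with the dominant opposite-sign pattern. Effect
magnitudes default to 0.4 (smoking) and 0.6 (interaction) on the logit
scale, mid-range of the per-locus coefficient tables this design
reproduces, jittered ±30% per locus; locus baselines are uniform on
logit(0.2)–logit(0.8); precision $\phi = 50$ gives per-locus SDs of
0.05–0.07, typical of 450K betas. Each locus also receives small
moderator, sex and age main effects and a cell-composition term
$\gamma^\top(w - \bar w)$ with $\gamma \sim N(0, 1)$ per cell type, making
the deconvolution covariates genuinely confounding (they are correlated
with the moderator through the tilt), exactly the situation the
cell-adjusted index models exist for.

**Background probes.** Besides the scanned panel and the seven moderator
probes, the generator emits 2,000 effect-free background probes
(`n_background`). They exist because between-sample quantile normalization
is only well behaved when systematically exposure-responsive probes are a
small minority of what it sees — on the real platform the scanned panel is
a few hundred of ~485,000 probes. Normalizing a panel composed almost
entirely of responsive loci lets their systematic shifts leak into the
reference quantiles and manufactures spurious interactions at null loci;
with the background complement the leakage is negligible.

**Moderator probes** are logit-linear in the latent moderator (slope 0.4,
precision 300), chosen so the standardized 7-probe mean correlates above
0.9 with the latent value — index validity is a tested property, not an
assumption. The generator standardizes the latent moderator and does not
attempt to match any particular raw-scale SD of a real index.

**What the generator does not emulate:** longitudinal smoking
trajectories across waves; batch/plate structure; realistic genome
annotation or probe-type chemistry; missing values. Passing end-to-end
tests therefore demonstrates that the machinery recovers a known moderation
structure under realistic noise, confounding and normalization — not that
it is robust to batch artifacts or array chemistry, which real analyses
must still address upstream.

## Calibration of the interaction test

Two facts, both computed by the test suite and the acceptance script at
2,000 null loci with 180 samples:

* When null loci are generated under the model family the per-locus
  regression fits (moderator, sex, age effects present; no omitted
  structure), the interaction Wald p-value is uniform: rejection fraction
  0.05 within 3 binomial SE, Kolmogorov–Smirnov uniformity not rejected.
* When null loci additionally carry the cohort's designed cell-composition
  term — which the per-locus models deliberately omit, and which is
  correlated with the moderator — the test becomes mildly anticonservative
  (rejection fractions around 0.06–0.07). This is not a defect of the
  optimizer; it is the price of leaving cell composition out of per-locus
  models when composition tracks the moderator, and it is precisely why
  the index-level models adjust for the five fractions.

Analysts applying the per-locus scan to real data should read nominal
interaction p-values near the threshold with this in mind, or verify
robustness by adding estimated fractions to the per-locus design.

## Problem sizes and other numerical choices

The shipped tests and the acceptance script use sizes chosen to make every
property measurable with comfortable statistical margins on a laptop-class
single core: 2,000 null loci for size, 200 replicates at $n = 500$ for
parameter-recovery coverage, a 180 × 300 cohort for the end-to-end
pattern, grid oracles at step $10^{-3}$ (beta MLE) and $10^{-2}$
(deconvolution simplex). Tie-breaks and degenerate inputs are handled
deterministically throughout: constant loci are flagged non-convergent and
excluded from classification (never silently dropped from totals);
zero-variance probes raise errors naming the probe; empty sign-concordant
classes raise errors for that index while the other is still built; strata
with fewer than two probes pass through normalization unchanged with a
warning. All generator draws derive from a single integer seed, and
identical seed plus configuration reproduces byte-identical pipelines.

## Known limitations

* Constant-precision beta regression cannot represent loci whose dispersion
  itself depends on smoking or the moderator; such dispersion effects would
  surface as mild miscalibration.
* The moderator index is treated as fixed in both per-locus and index
  models; its measurement error (small by construction here, with
  index–latent correlation > 0.9) attenuates interaction estimates
  slightly.
* Direction classes are estimated from the same sample used to test
  interactions; with weak main effects, direction misclassification would
  blur the contingency table. At the default effect sizes this is
  negligible (all effect loci classify correctly in the shipped runs).
* The deconvolution active-set enumeration is exponential in the number of
  cell types; it is instantaneous for realistic panels (5–6 types) but not
  intended for large signature matrices.
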