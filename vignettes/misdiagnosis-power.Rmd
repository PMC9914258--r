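---
title: "Power of case-control association studies under case misdiagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power of case-control association studies under case misdiagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(misdiagpower)
```

## The problem

Case-control association studies of diseases without a diagnostic
biomarker recruit "cases" by clinical criteria.  For a heterogeneous
condition such as ME/CFS, a fraction of those cases are genuine
patients of some other disease — *apparent* cases.  If the candidate
causal factor (a risk allele, a persistent infection, an autoantibody)
is associated only with genuine disease, apparent cases dilute the
signal, and the dilution is invisible in the data: the analyst sees one
case column.  This package quantifies the resulting loss of power and
the largest misdiagnosis rate a given design can tolerate.

## Model and assumptions

Let θ₀ be the probability that the factor is present in healthy
controls, θ₁\* the same probability in genuine cases, and γ the
misdiagnosis rate.  The model rests on a small set of simplifying
assumptions: diagnosed cases are a two-component mixture; the factor is
associated only with genuine cases; apparent cases carry the control
prevalence θ₀; misdiagnosis is independent of confounders and of
disease course; controls are truly healthy.  Under these, the marginal
prevalence in diagnosed cases is the convex combination

$$\theta_1 = \gamma\,\theta_0 + (1-\gamma)\,\theta_1^{*}.$$

The effect size is parameterised by the true odds ratio
$\Delta_T = \mathrm{odds}(\theta_1^{*})/\mathrm{odds}(\theta_0)$ in
genuine cases, so
$\theta_1^{*} = \Delta_T\theta_0 / (1-\theta_0+\Delta_T\theta_0)$
(`invert_odds_ratio()`).  The inversion is equally valid for protective
factors ($\Delta_T<1$), which simply yield $\theta_1^{*}<\theta_0$.

When the factor itself cannot be measured perfectly — the typical
serological situation, where seropositivity comes from a cut-off with
sensitivity π_se and specificity π_sp assumed common to all subjects —
each of the four latent strata (apparent/genuine × truly
exposed/unexposed) contributes observed positives, giving

$$\theta_1 = \pi_{se}\gamma\theta_0 + (1-\pi_{sp})\gamma(1-\theta_0)
  + \pi_{se}(1-\gamma)\theta_1^{*}
  + (1-\pi_{sp})(1-\gamma)(1-\theta_1^{*}),$$

and, in controls, $\pi_{se}\theta_0 + (1-\pi_{sp})(1-\theta_0)$.  At
π_se = π_sp = 1 the serology formula reduces exactly to the mixture
above; this reduction is enforced by a property test.

## What the simulator emulates — and what it does not

Each replicate study is drawn from the product-binomial sampling model
of a fixed-margin case-control design: the observed-positive counts are
independent `Binomial(n0, p0)` and `Binomial(n1, p1)` draws with the
group sizes as design constants.  Two samplers are provided:
`sample_table()` draws the observed table directly from the marginal
probabilities, and `sample_latent_table()` draws the full latent
hierarchy (case status, then true exposure per stratum, then the
per-individual classification).  The two are distributionally
identical — a property test compares their empirical distributions at
20,000 replicates — and the marginal route is what the power loops use,
since its cost does not grow with the group size.

The generator inherits the model's idealisations: no confounding, no
covariates, a single homogeneous genuine-case stratum, perfectly
healthy controls, and classification errors that are independent and
identically distributed across subjects.  Passing tests therefore show
that the *method* is implemented correctly under these conditions, not
that any real study satisfies them; contaminated control groups or
several genuine-case subtypes with different effect sizes would lower
power further and are outside the package's scope.

## The test, and a deliberate choice about the correction

An association is "detected" when Pearson's χ² test on the 2×2 table
rejects at level α (0.05 by default).  `pearson_chi2()` implements the
classical, *uncorrected* statistic; a `yates` switch provides the
continuity-corrected variant.  The uncorrected default is a considered
decision: the package's reference threshold tables are reproduced
cell-for-cell by the uncorrected statistic, while the Yates variant
shifts thresholds downward by 0.01–0.08 at n = 100.  Tables with an
empty row margin (likely when θ is near 0 or 1 and n is small) leave
the statistic undefined; they are scored as "no association detected"
(p = 1), since a margin-empty table carries no evidence against the
null — this keeps every replicate's contribution to power defined.

## Power curves, thresholds, and numerical choices

`power_curve()` estimates power on a γ grid (default 0 to 1 in steps of
0.01, the resolution at which thresholds are reported) with a default
of 10,000 replicates per point, giving a binomial Monte-Carlo standard
error of at most 0.005.  `max_gamma_for_power()` extracts γ_max, the
largest grid value whose power meets the target (default 80%).  Because
the raw estimates fluctuate around a curve that is non-increasing in γ
by construction, the default first applies antitonic regression
(`isoreg` on the negated curve); this makes the threshold stable at
reduced replicate counts, while `smooth = FALSE` reproduces naive
thresholding of the raw curve.  The full curve is always retained, so
threshold searches double as plot-ready output.  Ties and plateaus
resolve in favour of the *largest* qualifying γ; when even γ = 0 fails
the target, γ_max is `NA`.

Reproducibility is by substreams: every unit of work (a grid point, a
grid cell, a study factor) derives its own `set.seed()` value by
hashing the root seed with the unit's identifying parameter values.
Results are therefore independent of execution order, and a subsetted
run reproduces the matching cells of a full run bit-for-bit.

The two grid runners mirror the package's reference analyses:
`run_table2_grid()` crosses Δ_T ∈ {1.25, 1.5, 2, 3, 5, 10} with
θ₀ ∈ {0.05, 0.1, 0.25, 0.5} and per-group sizes
{100, 250, 500, 1000, 2500, 5000} under perfect classification;
`run_table3_grid()` fixes Δ_T = 3, θ₀ = 0.25 and crosses
π_se, π_sp ∈ {0.8, 0.9, 0.925, 0.975, 1}.  The π_se = π_sp = 1 column
of the second grid must agree with the (Δ_T = 3, θ₀ = 0.25) column of
the first within grid resolution — an internal cross-check in the test
suite.

## The bundled study re-analyses

Two published ME/CFS studies are shipped as parameter fixtures
(`inst/extdata/*.csv`, loaded by `load_study_fixtures()`), carrying the
reported control prevalences, odds ratios, confidence intervals and
p-values; only the prevalences, odds ratios, group sizes and
classification accuracies enter the simulation.

**Candidate-gene study** (five SNPs; 201 controls, 305 cases).  The
reported θ̂₀ are *allele* frequencies and the Δ̂_T are allele-based odds
ratios, so each subject contributes two independent allele copies: the
binomial denominators are 402 and 610 (`copies_per_subject = 2`).
This choice is forced by the arithmetic — with subject-level
denominators the strongest association (rs3087243, θ̂₀ = 0.56,
Δ̂_T = 1.54) would have power ≈ 0.65 even at γ = 0 and could never
reach the 80% target, whereas allele counts give ≈ 0.91 at γ = 0 and a
threshold in the low teens, consistent with the study-level results the
fixtures summarise.  Genotyping error is neglected (π_se = π_sp = 1),
as in genetic association practice.

**Serology study** (six herpesviruses; 107 controls, 251 severely
affected cases).  Seropositivity cut-offs followed the 2σ rule — the
mean plus two standard deviations of a seronegative population — whose
expected specificity under normality is approximately 0.975; with no
reported accuracy figures, π_se = π_sp = 0.975 is adopted for both, and
both are exposed as overrides in the CLI (`apps --pi-se --pi-sp`).
Here one observation per subject is simulated (`copies_per_subject =
1`).

At 5,000 replicates per grid point, only rs3087243 among the SNPs ever
reaches 80% power (and only for small γ), and no antibody does at any
misdiagnosis rate — the qualitative pattern the acceptance tests
assert.

## Problem sizes and defaults

Default replicate counts are 10,000 per power estimate (the package's
reference precision) with 2,000–5,000 used in the test suite, where the
stated tolerances (±0.03 on thresholds, ±0.05 on powers) include both
Monte-Carlo noise and the 0.01 grid step.  Because each replicate
reduces to two binomial draws, runtime is independent of group size; a
full 101-point curve at 10,000 replicates takes well under a second.

## Known limitations

* The model is mathematically equivalent to a two-subtype case mixture
  with the association confined to one subtype; more than two subtypes,
  graded associations, or contaminated controls are not modelled.
* γ_max is reported at the 0.01 grid resolution; no interpolation
  between grid points is attempted.
* The Woolf interval in `odds_ratio_with_ci()` (with Haldane–Anscombe
  correction for zero cells) is a transcription-checking utility, not
  an inferential endpoint of the package.
* Power is defined against the two-sided χ² test only; exact or
  one-sided tests would give different thresholds.
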