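---
title: "Measuring metacognitive sensitivity: model, pipeline, and simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring metacognitive sensitivity: model, pipeline, and simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(7)
```

```{r setup}
library(metacogsim)
```

## The measurement problem

Metacognitive sensitivity is the degree to which a subject's trial-by-trial
confidence distinguishes their own correct from incorrect decisions. It is
confounded with first-order performance: a subject who is simply better at
the task has better-separated evidence distributions and, for free, more
informative confidence. The design this package analyses removes that
confound at the source. Perceptual accuracy is clamped near 71% by adaptive
staircases on the stimulus (the mean orientation of a moving dot cloud), so
between-subject differences in type-II measures cannot be explained by
type-I performance, and a battery of perceptual-control tests verifies the
clamp after the fact.

## Type-II ROC analysis

Each subject's continuous confidence ratings are discretised into six
equal-count bins *within subject* (empirical sextiles, linear-interpolation
quantiles, ties assigned to the lower bin). Binning within subject makes
the measure invariant to how each individual uses the slider: any strictly
increasing transform of a subject's ratings leaves their bins, and hence
their AUROC2, unchanged.

Sweeping a criterion from the most to the least confident bin gives
cumulative rates $h_k = P(\mathrm{conf} \ge k \mid \mathrm{correct})$ and
$f_k = P(\mathrm{conf} \ge k \mid \mathrm{error})$. AUROC2 is the
trapezoidal area under the $(f, h)$ polyline with endpoints $(0,0)$ and
$(1,1)$. This area is algebraically identical to the tie-corrected
Mann–Whitney statistic
$P(\mathrm{conf}_{c} > \mathrm{conf}_{e}) + \tfrac12 P(\mathrm{tie})$,
and the test suite pins the implementation to an exhaustive pairwise
enumeration of that statistic on a thousand random instances. We chose the
trapezoid-plus-identity formulation deliberately: published closed-form
renderings of the binned formula are easy to typeset incorrectly, whereas
the rank identity is exact and implementation-independent.

Subjects with no error trials (or none correct) after exclusion have no
defined type-II ROC; they are reported and dropped from AUROC2 analyses,
never imputed.

Type-I sensitivity and bias use the left-motion class as "signal":
$d' = (z(H) - z(FA))/\sqrt{2}$ — the $\sqrt 2$ is the standard correction
for two-alternative forced choice — and $c = -\tfrac12(z(H) + z(FA))$. A
`strict_printed_c` switch reproduces the alternative sign convention
$-\tfrac12(z(H)-z(FA))$ found in some reports; we do not use it by default
because that expression is a rescaling of $d'$ and cannot serve as an
independent bias covariate. Rates of exactly 0 or 1 are moved to
$1/(2N)$ or $1 - 1/(2N)$ of the relevant class before the z-transform
(configurable; `correction = "none"` disables it).

## Exclusion rules

Applied in order, once, before any metric is computed:

1. all block-1 trials (staircase burn-in; 36 of 144 trials);
2. trials with anticipatory (< 100 ms), late (> 1500 ms) or missing
   responses, or missing confidence — leaving 108 trials for a clean
   session;
3. subjects whose accuracy falls below the lower Tukey fence
   Q1 − 1.5·IQR (the standard boxplot whisker; only the lower fence,
   because the exclusion targets poor performers — a subject *above* the
   upper fence is never removed).

The exclusion report keeps exact arithmetic
(`n_in = n_out + removals`) and the filter is idempotent.

## Group inference

All tests are classical and two-sided. ANOVAs report
$\eta^2 = SS_{\mathrm{effect}}/SS_{\mathrm{total}}$; t-tests are
pooled-variance (df $= n_1 + n_2 - 2$) with Cohen's
$d = \Delta\bar x / s_{\mathrm{pooled}}$. The ANCOVA reports the partial F
for the group factor — full linear model versus the model with covariates
only — which, with no group-by-covariate interactions in the model, is the
Type-III test for the factor. The 2×2 mixed ANOVA (group between,
correctness within) is computed from the sums-of-squares decomposition,
testing the group effect against subjects-within-groups and the within
effects against the correctness-by-subject residual; the test suite checks
it against `aov()` error strata.

The Bayes-factor t-test quantifies evidence *for* the null of no group
difference (BF01). The effect-size prior is the JZS Cauchy with scale
`r_scale` (default 1, the classical unit-information choice; a normal
unit-information prior is available via `prior = "normal"`). The marginal
likelihood is evaluated by adaptive quadrature of the t-statistic integral
over the variance-scaling mixture after the substitution $g = r^2 q$,
which keeps the integrand's mass near $q \approx 1$ for any prior scale
(relative tolerance 1e-10); an independent fixed-grid Simpson quadrature
serves as the oracle in the tests. BF01 depends on the data only through
$(t, n_1, n_2)$, so published values are exactly reproducible from printed
t statistics.

## The synthetic cohort generator

The simulator exists so that every stage of the pipeline — and design
questions such as statistical power for a selective metacognitive effect —
can be studied without experimental data. It emulates the task's
statistical structure, not its optics: dot clouds are represented by their
generative parameters (per-dot direction = ±mean orientation + N(0, SD),
1100 dots, 250 ms; `sample_dot_directions()` draws them for stimulus-level
checks), and no frames, dot lifetimes or apertures are rendered.

**Observer.** First-order evidence
$x \sim N(\pm k \cdot \theta \cdot \rho_v,\ \sigma_{\mathrm{perc}})$,
where $\theta$ is the staircased orientation and $\rho_v$ a per-variance
attenuation (1 at 20° SD, 0.75 at 30°); the choice is the sign of $x$. The
confidence stage reads $x_2 = x + N(0, \sigma_{\mathrm{meta}})$ and reports
$\mathrm{plogis}(\mathrm{gain}\cdot|x_2|)$, which is 0.5 (the squashing
midpoint) when the gain is zero and saturates at 1. Metacognitive noise
$\sigma_{\mathrm{meta}}$ is the single group-difference dial: it degrades
confidence-accuracy coupling without touching choices. Response times are
shifted lognormal (100 ms + lognormal with median `rt_location_ms` = 550
and log-SD 0.35 — strictly positive and right-skewed); misses (p = 0.02)
and anticipatory guesses with RT < 100 ms (p = 0.01) occur at fixed rates.
A jittered slider start position (±12%) is carried in the output for
realism but never analysed.

**Staircase.** Two consecutive correct responses lower the orientation by
one step, one error raises it (step 0.5°, floor 0.1°, ceiling 45°). The
fixed point of this rule is the accuracy $p$ with $p^2 = 0.5$, i.e.
70.7%. Step size and bounds are not constrained by published task
descriptions, so they are configurable; the defaults pair a small step
with a starting level of 10°, standing in for a threshold carried over
from a training phase. The signal gain default $k = 0.055$ per degree was
set so the staircase equilibrium ($z(0.707)/k \approx 10°$ in the 20°
condition) coincides with that starting level — a session then sits at
its asymptotic regime from the first block, which is precisely what
starting at a trained threshold achieves, and session accuracy lands near
0.71 as the design requires. Each variance condition runs its own
staircase; conditions are interleaved in seeded shuffled order with equal
counts per block (36 trials × 4 blocks, 18 per condition per block).

**Seeding.** Per-subject seeds derive from the master seed by a
deterministic counter, so cohorts are byte-reproducible and adding
subjects never perturbs earlier subjects' data.

**Group defaults and a known ceiling.** Within this observer class, at an
accuracy clamped to 70.7%, confidence can never be more informative than
$|x|$ itself; the resulting ceiling on binned AUROC2 is about 0.67
(Monte-Carlo measured). Empirical studies of this task report placebo-group
means around 0.70 — real observers evidently exploit information beyond
the decision variable (e.g. post-decisional evidence), which this
deliberately minimal two-stage model does not represent. The defaults
therefore target the *standardized* group effect rather than the absolute
level: placebo and amisulpride observers share
$\sigma_{\mathrm{meta}} = 0.5$ (mean AUROC2 ≈ 0.60–0.63) and the
propranolol observer has $\sigma_{\mathrm{meta}} = 0.1$ (≈ 0.67), giving
Cohen's d around 0.8–1.3 at 20 subjects per group, the magnitude reported
for real noradrenergic blockade. Passing the pipeline's tests on such
cohorts demonstrates correct recovery of a confidence-specific
manipulation under realistic trial counts and noise; it does not certify
absolute AUROC2 levels, post-decisional confidence dynamics, or serial
dependencies present in real data.

```{r recovery, fig.width = 6, fig.height = 5}
trials <- simulate_cohort(cohort_spec(n_per_group = 10, seed = 7))
fit <- metacog(trials)
summary(fit)
plot(fit)
```

## Numerical choices and degenerate inputs

* Quantile definition: linear interpolation between order statistics
  everywhere (bins, Tukey fences), so results are reproducible across
  implementations.
* Bin-boundary ties share the lower bin; a subject whose ratings are all
  identical gets a single bin, flagged `degenerate`, and an AUROC2 of 0.5.
* Zero/one SDT rate cells: 1/(2N) nudge, configurable.
* Bayes-factor quadrature: relative tolerance 1e-10; agreement with the
  independent Simpson oracle to better than 4 significant figures over a
  grid of (t, n, r).
* Rank-deficient ANCOVA designs fail with the offending columns named;
  groups with fewer than two subjects, single-class SDT inputs, and
  subjects with fewer ratings than bins all raise validation errors rather
  than returning silent NAs.

## Problem sizes used in validation

The test suite exercises the staircase fixed point over 12,000 trials
(2,000 burn-in), the AUROC2/rank identity over 1,000 random instances at
machine precision, and the parameter-recovery and type-I-error properties
over 100 replicate two-group cohorts of 20 subjects each — sizes chosen to
put Monte-Carlo error well inside each test's tolerance while keeping the
full suite in the low minutes on one core.

## Limitations

The simulator's confidence model is static within a trial; it produces no
confidence drift, learning, or fatigue across blocks, no response-time /
confidence coupling, and no metacognitive bias differences between groups
beyond what the gain parameter implies. The analysis side applies no
multiple-comparison correction across the test battery, mirroring standard
practice for this design, and estimates no process-model quantities
(e.g. meta-d′): AUROC2 is the sole type-II measure.
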