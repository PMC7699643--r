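---
title: "Methods: an environment-wide association scan of dietary exposures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an environment-wide association scan of dietary exposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

coxewas screens many dietary exposures — food items in servings/day and
composition-derived nutrients — against an incident disease endpoint with
a single, uniform modelling protocol, then controls multiple testing with
a permutation-based false discovery rate whose null preserves the
confounding structure of the cohort. This vignette explains the model,
the design decisions behind each stage, what the synthetic cohort does
and does not emulate, and the numerical choices that matter.

## The association model

For each exposure $i$ the package fits an extended Cox proportional
hazards model on counting-process data,

$$ \lambda(t \mid x_i, C) \;=\; \lambda_0(t)\,
   \exp\{\beta_i\, z_i(t) + \gamma^\top C(t)\}, $$

where $t$ is time on study, $z_i(t)$ is the standardized, variance-
stabilized cumulative-average intake of exposure $i$ up to the start of
the current 2-year follow-up interval, and $C(t)$ are the adjustment
covariates (age updated on the grid; BMI, physical activity, smoking,
ethnicity, medication and supplement use, blood pressure, cholesterol and
family-history indicators at baseline; total caloric intake as the
time-updated cumulative-average derived energy). The partial likelihood
uses Efron tie handling, the right default for interval-gridded cohort
data. Effect sizes are per 1 SD of the transformed exposure so that
hazard ratios are comparable across hundreds of regressions.

Each fitted exposure is reported with its effect size, SE, hazard ratio
with a two-sided 95% Wald interval ($\mathrm{HR} = e^{\beta}$,
$\mathrm{CI} = e^{\beta \mp 1.959964\,\mathrm{se}}$; rounding happens
only at report time), a proportional-hazards p-value (score test of zero
slope of the scaled Schoenfeld residuals of the exposure term against
Kaplan–Meier-transformed time — one number per exposure), and a variance
inflation factor ($1/(1-R^2)$ of the exposure column regressed on the
rest of the design; perfect collinearity is reported as `Inf`, not an
error).

## Exposure processing

FFQ responses are ordinal with nine levels, from "almost never" to "six
or more times per day". The instrument fixes two anchors (never = 0,
once per day = 1); the intermediate categories use the standard midpoint
convention, `r 'ffq_servings_map()'`, and the whole table is overridable
from YAML because no single convention is canonical. Nutrient intakes
are the servings-weighted sums over the composition table and are
therefore linear in servings; energy (kcal/day) is itself a derived
nutrient and is the single source of truth for both the plausibility
exclusion and the calorie-adjustment covariate.

Baseline exclusions mirror standard cohort hygiene: prevalent disease
(CVD, diabetes, cancer), missing demographics, reported energy strictly
below 600 or strictly above 3500 kcal/day, and more than 70 unanswered
FFQ items. Blanks take precedence over the energy rule in the exclusion
log because a mostly-blank questionnaire yields a meaningless energy
total; item-level blanks inside a returned questionnaire count as zero
intake (keeping energy computable) while a wholly blank wave is a missing
wave. Exclusions are applied at baseline only.

The time-varying exposure is the cumulative average of all waves
observed at or before the interval start — the long-term habitual intake,
damping within-person variation. After an intermediate (non-case)
diagnosis the dietary record freezes: later waves are ignored and the
last pre-freeze average is carried forward, while the subject stays at
risk. Cases stop contributing risk time at the event, so the freeze rule
only matters for non-cases.

Box–Cox transformation is applied to the pooled subject-interval
distribution of each cumulative-average exposure, with $\lambda$ chosen
by profile maximum likelihood on the grid $-2, -1.95, \dots, 2$. Intakes
are often exactly zero, so a shift equal to half the smallest positive
observed value is applied when zeros are present. The transform is
monotone, so ranks are preserved; a constant exposure is a hard error
("degenerate exposure").

## The permutation FDR and its biased pool

The multiple-testing protocol estimates, at a level $\alpha$, the ratio
of the null proportion of p-values at or below $\alpha$ (averaged over
permutations) to the observed proportion, capped at 1. The significance
threshold $\alpha^\*$ is the largest observed p-value with estimated FDR
at most $q = 0.05$, and per-exposure q-values are the monotone step-up
minima $\min_{\alpha \ge p_i} \widehat{\mathrm{FDR}}(\alpha)$.

The null is built by re-drawing the case set, not by uniform shuffling.
A covariates-only Cox fit gives each subject a baseline linear predictor;
its exponential serves as a sampling weight (scale-free by the usual Cox
invariance), and exactly the observed number of cases is drawn without
replacement by exponential keys ($\mathrm{key}_j = \mathrm{Exp}(1) /
w_j$; the smallest keys win). Permuted cases fail at their own observed
exit time; follow-up lengths, exposures and covariates are untouched, so
the person-time structure and the covariate–outcome coupling survive the
permutation while every exposure–outcome association is destroyed. The
Box–Cox/z transform depends only on the exposures, which are never
permuted, so the observed transform is reused inside the null scan.

Two properties of this construction deserve emphasis.

First, the null p-values of different exposures within one permutation
share a case set and are correlated. A Kolmogorov–Smirnov uniformity
test on the fully pooled matrix therefore runs at an invalid nominal
level and rejects spuriously as the pool grows; the package's acceptance
checks thin the pool to one randomly chosen exposure p-value per
permutation, which gives near-independent draws at the test's stated
level. The permutation null is also *conditional* on the realized
exposure and exit-time structure: marginal uniformity requires the
chance correlation between an exposure and the exit-time process to be
small, which holds in the cohort regime this method targets (event
fractions around 10%, administratively capped follow-up) but not, for
example, at extreme event fractions with heavy-tailed follow-up.

Second, the reason for the biased pool is visible only when adjustment
is imperfect. When every confounder is measured and enters the hazard
linearly, a naive uniform shuffle and the biased pool produce
indistinguishable, uniform nulls. Under residual confounding — modelled
in the generator as an unmeasured healthy-behaviour factor
(`latent_hazard_effect`) that shapes both diet and risk — the observed
scan of truly null exposures is anticonservative, and the biased-pool
null reproduces that inflation (its p-values shift downward with the
observed ones) while the naive null stays uniform. An FDR computed
against the naive null would therefore underestimate the number of
expected false discoveries. The package's checks assert exactly this
contrast: the biased-pool null sits stochastically below the naive null
under residual confounding.

## The food–nutrient network

Significant nutrients are linked to the significant foods that carry
them. For nutrient $i$ the weight of the link to food $k$ is the
per-serving composition amount normalized over the significant source
foods, $w'_k = a_{ik} / \sum_{k'} a_{ik'}$; an optional
consumption-weighted variant multiplies amounts by mean servings/day
before normalizing (both phrasings of "contribution to the food supply"
occur in practice; per-serving is the default). The food-implied
nutrient hazard ratio is the weighted geometric mean

$$ \langle \mathrm{HR}_i \rangle
   = e^{\sum_k w'_k \beta^F_k}
   = \prod_k (\mathrm{HR}^F_k)^{w'_k}, $$

an algebraic identity the test suite checks to $10^{-12}$ in both forms.
If every significant source food is protective the expected HR is below
one (a weighted geometric mean bound). Nutrients whose only sources are
non-significant foods are dropped from the network and logged. The
comparison table flags, per nutrient, whether the actual and the
food-implied HR fall on the same side of 1; the network exports as
GraphML plus a flat edge list for any layout tool.

## The synthetic cohort

The generator exists so every downstream stage is testable with known
truth. It emulates the *structural* assumptions of a longitudinal
nutritional cohort — not the marginal distributions of any real food:

* baseline covariates with realistic ranges (age 40–65, BMI ~ N(25.5,
  4.5), log-normal activity, smoking and medication indicators);
* a latent healthy-diet propensity confounded with those covariates
  (`confounding_strength` scales the covariate loadings), plus an
  optional direct hazard effect of that latent factor
  (`latent_hazard_effect`) for residual-confounding scenarios;
* repeated FFQ waves every 4 years with a subject–food random effect
  (within-subject autocorrelation) and wave-to-wave noise
  (`within_person_sd`, a free parameter because real within-person
  dietary variance is not identified from the published material);
* a sparse composition table with each nutrient concentrated in 2–6
  source foods, so the network decomposition has signal; energy is dense
  across all foods;
* piecewise-exponential event times on the 2-year interval grid —
  exactly the hazard the counting-process Cox likelihood assumes — with
  independent censoring and an administrative end of follow-up;
* intermediate non-case diagnoses as an independent Poisson process that
  freezes dietary records without ending follow-up;
* seeded fractions of subjects violating each baseline exclusion rule
  (including >70 blank items and out-of-range energy, bisected into the
  target window per subject).

True exposure effects are specified per 1 SD of the variance-stabilized
(Box–Cox) cumulative-average intake — the same scale on which the scan
reports effect sizes — so recovery is unbiased by construction. The
default baseline hazard (0.004 per person-year) yields roughly 10%
cumulative incidence over the default 10-year follow-up under the
default confounder effects; hazard effects are dominated by age, as in
any CHD cohort. Identical configurations reproduce byte-identical
studies: the generator snapshots and restores the caller's RNG state.

What passing tests on this generator do *not* show: robustness to
differential measurement error, to informative censoring, to secular
dietary trends, or to the brand- and preparation-level resolution of a
real FFQ (brand-level detail is representable only as per-food
composition overrides). Conclusions about real cohort data still require
the usual sensitivity analyses.

## Numerical choices and problem sizes

* Cox fitting: `survival::coxph` (Efron ties) for user-facing fits and
  diagnostics. The permutation engine refits the same design tens of
  thousands of times with only the event vector changing, so it uses a
  package-internal Newton solver (C++) with precomputed sort orders and
  warm starts from the observed fit; it is validated against `coxph` to
  numerical precision in the test suite, and against a brute-force grid
  maximization of the explicitly written Efron partial likelihood on
  small instances.
* Permutations are seeded independently (`seed + b` for permutation
  `b`), so results do not depend on execution order.
* FDR conventions: 0/0 is defined as 0; a nonzero null proportion with
  zero observed discoveries caps at 1 with a warning.
* Quintile analyses cut the pooled subject-interval distribution of the
  cumulative-average exposure; correlations among significant exposures
  are Spearman, computed across subjects on each subject's
  interval-averaged exposure.
* Replication validation: discovery q-value < 0.05, replication
  two-sided p < 0.05, and agreeing effect signs; exposures missing from
  the replication scan are flagged and never validated.
* Test problem sizes: the calibration suite uses 20 replicates of a
  3000-subject cohort with 40 exposures and 100 permutations (all true
  effects zero, active confounding); parameter recovery uses 50
  replicates at 3000 subjects with a true log-hazard of 0.15 per SD —
  the scale of the strongest published diet–CHD effects; the
  residual-confounding contrast uses 4 replicates with
  `latent_hazard_effect = -0.3`. These sizes were chosen as the smallest
  at which the binomial tolerances of the checks are meaningful.

## Limitations

The scan is associational: with residual confounding the FDR controls
the rate of *statistical* false discoveries against the preserved-
confounding null, not causal error. One exposure is tested at a time, so
jointly acting nutrients are seen only through their marginal (and
mutually correlated) associations — the network decomposition is an
interpretation aid, not a joint model. Statistical power estimation for
the scan is not implemented. Left truncation by late entry and competing
risks are out of scope; follow-up starts at the baseline questionnaire
for everyone.
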