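---
title: "Methods: personal network metrics, outcome models, and the permutation omnibus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: personal network metrics, outcome models, and the permutation omnibus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(persnet)
```

## The scientific setting

People with multiple sclerosis (pwMS) are especially vulnerable to social
isolation, and features of a person's *personal (egocentric) social
network* — its size, how interconnected its members are, the health
behaviors of those members — are candidate modifiable contributors to
neurological outcomes.  This package implements the full quantitative
pipeline for that question on PERSNET-style survey exports: per-network
structural and compositional metrics, univariate covariate screening,
covariate-adjusted regressions of three patient-reported outcomes (PROs)
on each network feature, an MS-diagnosis moderation analysis, and a
longitudinal within-subject analysis of pandemic-era network contraction
with a permutation-calibrated Fisher omnibus.

Because the underlying survey data are not publicly distributable, the
package carries a first-class synthetic-cohort generator whose defaults
encode the descriptive moments of the published pwMS and control cohorts.
Every analysis stage is exercised and tested against that generator, with
known ground truth.

## Ego networks and the 18 features

An ego network here is the respondent (ego) plus the alters they named,
with a symmetric binary alter–alter tie matrix.  By elicitation the ego
knows every alter, so the ego's own ties are uninformative and are
excluded wherever the definitions call for it.

**Structural features (6).**

* *Size* — number of alters.
* *Density* — alter–alter ties over `n(n-1)/2`; undefined (`NA`) below
  two alters, never coerced to zero.
* *Constraint* (Burt) — `C = sum_j (p_ij + sum_q p_iq p_qj)^2` over the
  ego's alters, with proportional weights on the ego-included graph; the
  ego's weights are `1/n`, an alter's weights spread over its ego tie
  plus its alter–alter ties.  Reported ×100 so that cohort means land in
  the 50–60 range typical of dense personal networks.  A star gives
  `100/n`, an ego–alter dyad 100.
* *Effective size* (Burt) — non-redundant alters; for binary symmetric
  ties this reduces to `n - 2t/n` with `t` the alter–alter tie count.
* *Maximum / mean degree* — computed in the alter–alter graph with the
  ego excluded.  The alternative convention (counting the ego tie) adds
  exactly 1 to every degree; we exclude it, matching the density
  convention of "excluding the index person's ties".

The test suite proves `burt_constraint()` and `effective_size()` equal to
independent brute-force implementations of the definitions on *every*
binary symmetric tie matrix with up to 5 alters (1,024 matrices at
n = 5), and cross-checks constraint against `igraph::constraint()` on
random networks.

**Compositional features (12).**  Percent kin, SD of alter age, sex and
race diversity, and the percentages contacted weekly or less, known
under 6 years, living over 15 miles away, drinking, smoking,
non-exercising, eating badly, and perceived as a negative health
influence.  Conventions that the survey leaves open:

* Percentages use alters with a *non-missing* value of the attribute as
  the denominator; "unknown" responses count in neither numerator nor
  denominator.  An attribute missing for every alter yields `NA`.
* "Contacted weekly or less" counts contact at weekly frequency or rarer
  (everything less often than daily) — the literal reading of the label.
* Diversity is normalized Blau heterogeneity
  `(1 - sum p_k^2) / (1 - 1/K)` ×100, with `K = 2` for sex (alters of
  other/unknown sex excluded) and `K` = the number of codebook race
  levels for race.  The normalization for race is configurable
  (`diversity_race_k = "codebook"` or `"observed"`) because the original
  choice is not documented; codebook-`K` is the default.
* Which relationship codes are *kin* is codebook-defined (the survey
  does not fix it); the default set is spouse/partner, parent, child,
  sibling, in-law, other family.

**Two scales.**  Descriptive tables use 0–100 percentages; regressions
consume 0–1 proportions (`features_regression_scale()`), so a
coefficient is the outcome shift for a full 0-to-1 sweep of the feature.
Size, degrees, density (already 0–1) and constraint (0–100) keep their
native scales in both contexts.

## Outcomes, covariates, and screening

The three PROs are PDDS (ordinal gait disability, 0–8), MSRS-R (symptom
burden, 0–32, higher = worse) and PROMIS Physical Function (T-score,
population mean 50, higher = better).  PDDS and MSRS-R are defined for
pwMS only.  All three are modeled by ordinary least squares — including
ordinal PDDS, mirroring the single linear-regression framework of the
source analyses; an ordinal model is an explicit non-goal.

Candidate covariates are encoded to single monotone numeric scores so
that the screening rule's "a Pearson correlation" is well defined:
income as the ordinal bracket 1–9, employment as a binary employed (for
wages or self-employed) indicator, education as ordinal 1–6, race and
ethnicity dichotomized to non-Hispanic White vs otherwise ("not sure"
counts as *other*, since it cannot confirm either condition).  The
screening rule retains a covariate iff it is present in more than 70% of
pwMS records, and has `|r| >= 0.1` with `p < .05` against **all three**
PROs.  "Presence" is the fraction of non-missing values.  Constant
candidates (undefined correlation) are excluded and flagged.

Analyses use complete cases per analysis cell (feature + outcome + all
covariates), so each regression reports its own `n`.

## Cross-sectional analyses

* **Group comparison** — Welch two-sample t tests of each feature
  between pwMS and controls, with a Bonferroni family of m = 18.  The
  source Methods say "paired" t tests for this comparison, but the two
  groups are independent samples with no pairing key; we treat that as a
  wording slip, use Welch's test here, and reserve paired t tests for
  the longitudinal within-subject comparisons where pairing is defined.
* **Regression battery** — 18 features × 3 PROs = 54 pwMS models
  adjusting age, disease duration, employment, income (m = 54, per-test
  threshold 0.00092); 18 control models for PROMIS only, dropping
  disease duration.
* **Moderation** — joint pwMS + control PROMIS model with a
  feature × diagnosis interaction, covariates age, employment, income
  (disease duration is undefined for controls).  Simple slopes per group
  come from the coefficients (`slope_pwms = b_feature + b_interaction`)
  with delta-method intervals, and the feature quartiles are reported as
  plotting anchors.

CIs are normal-theory 95% Wald intervals throughout.

## Longitudinal analysis and the permutation omnibus

Participants with a prepandemic assessment are paired to it — the most
proximal baseline strictly before the pandemic assessment — and
`elapsed_years` (days/365.25, 2 decimals; design window 1–4 years) plus
the study cohort enter as additional covariates.

Within-subject change in each feature is tested by a paired t test
(α = .05 per feature).  Change–outcome regressions relate each
feature's pandemic-minus-baseline change to the pandemic PRO.

The 18 change regressions per outcome are combined by Fisher's method,
`X² = -2 Σ log p` on 2k df.  Fisher's analytic reference assumes
independent tests, which the feature changes violate (size, density,
constraint and effective size are mutually dependent), so the statistic
is calibrated against its *empirical* permutation distribution: the
outcome vector is permuted across participants while the feature-change
and covariate block stays intact, preserving the inter-feature
correlation; `empirical_p = (1 + #{X²_perm >= X²_obs}) / (B + 1)` with
B = 10,000 by default.  Rows are canonicalized by participant identifier
before permuting, so results are row-order invariant under a fixed seed.
Permuting outcomes (rather than features or residuals) is the simplest
scheme that leaves the feature–covariate joint distribution untouched;
a covariate-preserving residual-permutation variant was considered and
left out of scope as the covariates here are weakly related to the
changes.  The permuted p-value matrix also yields the Q-Q envelope: per
order statistic, the 2.5th–97.5th percentiles of the sorted −log10 p
across permutations, against expected quantiles `-log10(i/(k+1))`.

The omnibus machinery evaluates each regression's focal p-value through
a QR/Frisch–Waugh projection that is algebraically identical to `lm()`
(tested to 1e-10) but fast enough to make 10,000 permutations routine;
an `exact = TRUE` mode enumerates all `n!` permutations for cohorts of
up to 8 participants and is tested against an `lm()`-per-permutation
oracle for exact agreement of counts.

## The synthetic-cohort generator

The generator is the package's stand-in for the non-distributable survey
data; its defaults *are* the study conditions and were fixed once from
the published descriptive moments, not tuned afterwards.

* **Network size** — negative binomial truncated to 1–25 alters, with
  the raw mean solved by root finding so the *truncated* mean hits the
  target exactly: pwMS pandemic 6.79 (SD 4.24), controls 6.78 (3.90);
  the longitudinal preset uses the prepandemic baselines 8.02 (5.70) and
  8.18 (4.05).
* **Ties** — per-participant density drawn from a Beta matched to the
  published mean/SD (pwMS 0.76/0.25), then i.i.d. Bernoulli ties, giving
  the dense, kin-heavy networks typical of these cohorts.
* **Alters** — kin flags (pwMS 0.56, longitudinal baseline 0.46),
  contact frequency with daily dominating (weekly-or-less ≈ 16%
  cross-sectionally, ≈ 23.5% at the longitudinal baseline), behavior
  flags at the published percentages, ages around a per-network center,
  and a *negative health influence* flag drawn from a logistic model on
  the alter's four behavior flags (intercept −1.341, each flag +0.9,
  population rate ≈ 0.36).  The logistic link makes the
  negative-influence percentage correlate with, but not duplicate, the
  behavior percentages — matching the observation that the specific
  behaviors did not individually reach significance.
* **Covariates** — age normal (pwMS 50.7/12.1, controls 44.4/12.1),
  income over the published nine-bracket distribution, employment
  Bernoulli (0.537/0.779), disease duration Gamma with mean 15 years
  (shape 2.25, scale 6.67; the publication reports no duration moments,
  so a typical mid-disease cohort was chosen), plus sex, race/ethnicity,
  education, marital and cohabitation status at the published rates.
* **Outcomes** — MSRS-R and PROMIS are linear in the configured feature
  effects and covariates with Gaussian residuals; intercepts are solved
  so the population means hit the published values (7.55, 46.4, 56.3).
  Default effects are the published estimates: negative influence
  +2.181 on MSRS-R and −0.650 on PROMIS in pwMS, −5.707 on PROMIS in
  controls; `effects = "null"` zeroes everything for calibration runs.
  PDDS is a thresholded latent score cut at fixed right-skewed
  probabilities (mean ≈ 1.9, 35% at step 0).  MSRS-R and PROMIS are
  left on the continuous latent scale rather than censored to the
  instrument ranges: censoring at 0 would attenuate coefficient
  recovery by roughly 7% and break the linear generative contract that
  the recovery tests verify.  `read_cohort(strict = FALSE)` exists for
  round-tripping such synthetic cohorts through the CSV dialect.

**The contraction operator** turns a prepandemic cohort into a paired
pandemic timepoint the way distancing pruned personal networks: *weak*
alters (contacted less than weekly *and* non-kin) are dropped with
probability 0.80; everyone else faces a background dropout of 0.165,
halved for kin (`kin_boost = 0.5`); surviving alter–alter ties can be
removed with probability `tie_removal` (default 0, preserving the
"tighter-knit" signature of the published pandemic networks).  The
background rate exists because the published size reduction
(8.02 → 6.63, −17.3%) is larger than the total weak-alter mass implied
by the published contact-frequency margins (≈ 6–7% of alters), so
weak-tie pruning alone cannot produce it; with the defaults the expected
retention is 0.8267, i.e. an expected pandemic mean of 6.63 exactly.
Pandemic outcomes are regenerated from the configured models on the
contracted networks; kin protection makes the percent kin rise, as
observed.

What the generator does **not** emulate: real joint dependence between
alter attributes (they are conditionally independent given the
network), informative missingness (optional-question missingness must be
configured or injected by the caller), cohort-site differences beyond a
categorical label, or any direct network→outcome causality beyond the
configured linear effects.  Passing tests therefore demonstrate that the
*machinery* is correct and calibrated under the assumed data-generating
process, not that the published substantive findings replicate.

## Numerical and design choices

* Problem sizes: recovery tests use 200 replicate cohorts at the
  published analysis-cell sizes (713 pwMS complete cases; 1,250
  controls); omnibus calibration uses 100 seeded null runs at the
  longitudinal n = 230 with B = 999 permutations; package examples and
  unit tests use smaller cohorts chosen to keep the suite quick while
  leaving Monte-Carlo error well below the tested tolerances.
* Degenerate inputs are explicit: density/constraint/effective size are
  `NA` below their minimum sizes; all-zero paired differences give
  t = 0, p = 1, and zero-variance nonzero differences an infinite
  statistic with a flag; constant screening candidates are excluded and
  flagged; `fisher_omnibus()` rejects p = 0 and points to the
  permutation floor `1/(B+1)`.
* Ties are binary and symmetric; any tie-strength coding must be
  thresholded upstream.  Networks above 25 alters trigger a warning
  (the survey caps elicitation in practice; the reader does not refuse
  them).
* Seeds: every stochastic entry point takes one integer seed;
  `simulate_cohort()`, `apply_contraction()`, `permutation_omnibus()`
  and `run_pipeline()` are bit-reproducible given it.

## Known limitations

* OLS on ordinal PDDS is a deliberate simplification inherited from the
  analysis framework being reimplemented.
* The moderation and control-arm analyses cannot adjust for disease
  duration by construction; estimates for pwMS differ accordingly from
  the duration-adjusted battery.
* The analytic Fisher p-value is reported but should not be interpreted
  when feature changes are correlated — only the empirical p is
  calibrated (this asymmetry is itself tested).
* Real-data coefficients are not reproducible here (no deposited data);
  all quantitative claims in the package are about synthetic recovery
  and internal consistency.
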