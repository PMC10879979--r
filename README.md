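# persnet

Personal (egocentric) social network analysis for patient-reported
outcomes in people with multiple sclerosis (pwMS) and controls.

Social connections are a candidate modifiable environmental factor in
neurological disease. PERSNET-style surveys elicit each respondent's
personal network — the alters they discuss personal matters with, the
ties among those alters, and the alters' demographics and health
behaviors — alongside three patient-reported outcomes (PROs): PDDS
(gait disability, ordinal 0–8), MSRS-R (symptom burden, 0–32) and
PROMIS Physical Function (T-score). `persnet` implements the complete
analysis pipeline for such data, for epidemiologists and clinical
researchers working with ego-network surveys.

## What it computes

**Network features (per ego network).** Six structural features — size
*n*; density `t / (n(n−1)/2)` over alter–alter ties *t* (ego excluded);
Burt constraint `C = Σ_j (p_ij + Σ_q p_iq p_qj)² × 100` on the
ego-included graph; Burt effective size (`n − 2t/n` for binary
symmetric ties); maximum and mean alter degree — and twelve
compositional features: percent kin, SD of alter age, normalized Blau
diversity of sex and race `(1 − Σ p_k²)/(1 − 1/K) × 100`, and the
percentages of alters contacted weekly or less, known < 6 years, living
> 15 miles away, drinking, smoking, non-exercising, eating badly, and
perceived as a negative health influence.

**Analyses.**

* Covariate screening (presence > 70%, |r| ≥ 0.1 and p < .05 against
  all three PROs);
* Welch t comparisons of all 18 features between groups (Bonferroni
  m = 18);
* the 18 × 3 covariate-adjusted OLS battery for pwMS (age, disease
  duration, employment, income; m = 54) and the control-arm PROMIS
  battery;
* MS-diagnosis moderation models with simple slopes and quartile
  anchors;
* longitudinal within-subject paired t tests, change→outcome
  regressions, and a Fisher combined-probability omnibus
  (`χ² = −2 Σ log p`, 2k df) calibrated by outcome permutation
  (`empirical p = (1 + #{χ²_perm ≥ χ²_obs})/(B + 1)`, B = 10,000
  default) with a permutation Q-Q confidence envelope.

**Synthetic cohorts.** A generator calibrated to the published cohort
moments (network size, density, kin share, behavior rates, covariate
distributions, outcome means) with configurable feature→outcome
effects, plus a pandemic-style *contraction operator* that prunes weak
ties (non-kin, contacted less than weekly) with kin protection. Every
stage of the pipeline is tested against it with known ground truth; see
`vignette("persnet-methods")`.

## Worked example

```r
library(persnet)

cfg <- generator_config(n_pwms = 1130, n_controls = 1250, seed = 2026)
cohort <- simulate_cohort(cfg)
cohort
#> <persnet_cohort> 2380 records (2380 participants)
#>           pandemic
#>   control     1250
#>   pwms        1130

frame <- analysis_frame(cohort)   # 18 features (0-1 scale) + covariates + PROs

# covariate-adjusted association: negative-influence proportion vs MSRS-R
feature_outcome_regression(frame[frame$group == "pwms", ],
                           "pct_negative_influence", "msrs_r")
#>   feature                outcome    n  beta ci_low ci_high      p
#> 1 pct_negative_influence  msrs_r 1130  1.96  0.655    3.27 0.0033
```

The generating coefficient was 2.181 (the default configuration): a
0→1 sweep of the negative-influence proportion raises MSRS-R symptom
burden by about 2 points, and the fitted estimate 1.96 (95% CI
0.66–3.27) recovers it within sampling error at this cohort size.

```r
moderation_analysis(frame, "pct_negative_influence")
#> <moderation_result> pct_negative_influence -> promis_pf (n=2380)
#>   interaction beta 6.418 [3.042, 9.794], p=0.000198
#>   slope (pwms) 1.253 [-1.160, 3.665], p=0.309
#>   slope (control) -5.165 [-7.527, -2.803], p=1.87e-05
#>   feature quartile anchors: 0.25 / 0.333 / 0.5
```

Here the diagnosis moderates the *strength* of the association: the
control slope recovers the generating −5.707 (a higher share of
negative-influence alters predicts markedly worse physical function),
while the pwMS slope is generated near zero — so the interaction is
large and positive.

An end-to-end run (`run_pipeline()`) writes the report tables —
features, group comparisons, the 54-model association battery,
moderation estimates, paired change tests, omnibus JSON and Q-Q
coordinates — into an output directory, deterministically for a given
seed.

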