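# ergogwas

Desk-scale analysis pipeline for **cardiorespiratory fitness (CRF) and
physical activity (PA) phenotypes with sex-stratified genetic association**,
exercised end to end on a fully synthetic cohort with known ground truth.

Large biobank studies estimate fitness from *submaximal* cycle ramp tests:
heart rate is recorded while workload increases, and fitness is the workload
extrapolated to the age-predicted maximum heart rate, scaled by body weight.
The raw traces are noisy and need careful QC and filtering before the two
fitness phenotypes can be derived and taken into a GWAS. This package
implements that whole chain for researchers who want a tested, reproducible
reference implementation of the method — without access to restricted cohort
data — plus the downstream statistics: covariate residualization, per-variant
association by sex stratum, LD clumping, two-stratum heterogeneity
meta-analysis and disease-frequency decile profiles.

## The model

For each eligible ramp-test session (risk categories *minimal*, *small*,
*medium*; bicycle method only), observations are restricted to the workload
ramp (minimal/small) or the full constant-load exercise phase (medium), rows
with cadence outside 35–125 RPM are dropped, and sessions with fewer than 20
surviving observations are excluded. The heart-rate series is smoothed with a
zero-phase low-pass Butterworth filter (order 4, cutoff 0.1 × Nyquist by
default), then:

- **CRF-vo2max** (relative power, W/kg): fit the least-squares line of
  workload on filtered heart rate, evaluate it at the age-predicted maximum
  heart rate `HRmax = 208 − 0.7·age`, and divide the extrapolated workload by
  body weight:

  `CRF-vo2max = WL(HRmax) / weight`

- **CRF-slope** (bpm per trend unit): the slope β₁ of `HR ~ β₀ + β₁·trend`
  over the same filtered window; sessions with β₁ < 0 are excluded from the
  slope phenotype (β₁ = 0 is retained).

Accelerometer-based PA records pass QC when wear-time and calibration flags
are good, no problem indicators are present, and the 7-day average is
≤ 100 milligravities.

Association uses simple linear regression of covariate-residualized traits on
allele dosage (the unrelated-sample stand-in for a mixed model), p-value
informed greedy LD clumping (r² ≥ 0.2 within ±500 kb), and for sex-specific
hits an inverse-variance fixed-effect meta-analysis of the male/female pair
with Cochran's Q, I² = 100·max(0, (Q−df)/Q), and the Higgins–Thompson
test-based 95% CI for I².

## Worked example

```r
library(ergogwas)

cfg    <- sim_config(hr_noise_sd = 3)                  # AR(1) noise, sd 3 bpm
sim    <- simulate_cohort(200, seed = 7, cfg)          # demographics + truth
traces <- simulate_traces(sim$cohort, sim$truth, seed = 7, cfg)
crf    <- derive_crf_phenotypes(traces, sim$cohort)

head(crf$records[, c("participant_id", "crf_vo2max", "crf_slope",
                     "n_trend", "qc_flags")], 3)
#>   participant_id crf_vo2max  crf_slope n_trend                           qc_flags
#> 1        P000001  0.4466710         NA      88 degenerate_workload,negative_slope
#> 2        P000002  2.6697234 0.47621488      59
#> 3        P000003  0.3542909 0.02911539      90                degenerate_workload
crf$exclusions
#>       reason n
#> 1 bad_method 2
#> 2   bad_risk 9
```

Participant 2 cycled a minimal-risk ramp: 59 observations survived QC, the
extrapolated relative power is 2.67 W/kg and heart rate rose 0.48 bpm per
trend step. Participant 1's medium-risk constant-load session cannot be
extrapolated (flag `degenerate_workload`: the constant workload is used) and
its negative heart-rate slope voids the slope phenotype only. Eleven of the
200 sessions were excluded outright (wrong method or high-risk protocol).

A male/female effect pair is meta-analysed in one call:

```r
meta_two_groups(beta_m = 0.040, se_m = 0.007, beta_f = 0.0163, se_f = 0.0060)
#>   beta_pooled      Q    p_Q      i2   i2_lo   i2_hi
#> 1      0.0263 6.6081 0.0102 84.8671 38.3666 96.2844
```

Q ≈ 6.6 (p ≈ 0.01) with I² ≈ 85% (95% CI ≈ 38–96%): strong evidence the male
and female effects differ. `run_pipeline(pipeline_config(seed = 1))` drives
the full chain — simulation, CRF/PA derivation, residualization, stratified
association, clumping, heterogeneity and disease deciles — in a few seconds
at the default scale (2000 participants, 500 variants in 50 LD blocks).

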