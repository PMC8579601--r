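---
title: "Deriving fitness phenotypes and sex-stratified genetic associations from synthetic ramp-test cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving fitness phenotypes and sex-stratified genetic associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ergogwas)
```

## Scope and rationale

Biobank-scale fitness genetics works from *submaximal* cycle ramp tests:
participants pedal against an increasing workload while a chest ECG records
heart rate, and fitness is estimated by extrapolating the workload–heart-rate
relation to the age-predicted maximum heart rate. The raw traces are noisy,
the protocol differs by clinical risk category, and the derived phenotypes
feed a GWAS whose most interesting signals may differ between the sexes.
ergogwas implements this chain as a small set of composable stages, and —
because the cohorts such analyses are built on are access-restricted — ships
a synthetic cohort generator with known ground truth so that every stage is
testable end to end.

## The phenotype model

For one session the observation series is `(trend, heart_rate, workload,
cadence)` within pre-test, exercise and recovery phases; `trend` is the
ordinal index of repeated measurements within a phase. The derivation is:

1. **Window selection.** Minimal- and small-risk protocols hold a steady
   load for ~2 minutes, then ramp for ~4 minutes; only the ramp is modelled.
   The ramp is identified as the longest contiguous non-decreasing workload
   run with an overall strict increase, with the leading constant-load
   segment (a repeated initial workload value) removed; a session whose
   initial workload never repeats is treated as ramping from its first
   observation. Medium-risk sessions are constant-load throughout and the
   whole exercise phase is used. High-risk and non-bicycle sessions are
   excluded (`bad_risk`, `bad_method`).
2. **QC.** Observations with cadence outside 35–125 RPM (the ergometer's
   guaranteed accuracy band; both boundaries inclusive) are removed; fewer
   than 20 survivors excludes the session (`low_cadence_n`).
3. **Filtering.** The heart-rate series is smoothed by a zero-phase (applied
   forward and backward) low-pass Butterworth filter so the trend is not
   lagged. Defaults: order 4, cutoff 0.1 × Nyquist.
4. **CRF-vo2max** (W/kg). The least-squares line of workload on filtered
   heart rate is evaluated at `HRmax = 208 − 0.7·age` (bpm) and divided by
   body weight. An alternative `endpoints` mode draws the line through the
   first and last filtered observation instead; the two modes coincide on
   exactly linear data and `regression` is the default because it uses the
   whole window. A constant-workload window (the medium protocol) has no
   slope to extrapolate: the constant workload itself is emitted and flagged
   `degenerate_workload` rather than excluding the participant.
5. **CRF-slope** (bpm per trend unit). β₁ from OLS of filtered heart rate on
   trend. A negative slope voids the slope phenotype only (`negative_slope`,
   the vo2max value is kept); a zero slope is retained — the exclusion rule
   is strictly `β₁ < 0`. `trend` is used as recorded (an ordinal index, not
   seconds), so β₁'s scale is per observation step.

Every exclusion carries a reason and the per-reason counts partition the
input: `n_input = n_records + n_excluded` always holds.

Activity records pass QC when both quality flags are good, no problem
indicator is present, and the wear-time-adjusted 7-day mean acceleration is
at most 100 milligravities — exactly 100 mg is retained; the exclusion is
strictly "> 100".

## Filter implementation

A naive forward–backward IIR pass has large boundary transients (zero
initial conditions) which would corrupt exactly the endpoints the phenotype
depends on. The filter here therefore:

- removes the least-squares line first and restores it afterwards, making
  the filter *exact* on affine signals (a constant or straight trend passes
  through bit-for-bit, so noiseless sessions reproduce the analytic truth);
- pads the detrended residual by mirror reflection (length `min(n−1,
  ⌈6/cutoff⌉)`), which is continuous at the joints and injects no spurious
  offset when the residual oscillates;
- starts each pass from steady-state initial conditions scaled to the first
  padded sample (the standard step-response construction).

Sequences shorter than `max(20, 3·order)` are returned unfiltered with a
degraded-mode flag rather than erroring. The forward–backward application
squares the magnitude response, so a Nyquist-frequency artefact is
attenuated by ~8 orders of magnitude at the default settings while the ramp
trend (bandwidth well below 0.05 × Nyquist at a 4-s sampling interval) is
untouched.

## Covariates, association and downstream statistics

Two covariate presets mirror common practice: the **gwas** spec (age, age²,
sex for sex-combined analyses only, genotyping array, assessment centre,
10 principal components; plus risk category and the trend-entry count for
CRF traits, since protocol and series length affect the derived values) and
the **decile** spec (age and socioeconomic status only) used before ranking
participants for disease-frequency profiles. Smoking and drinking are
deliberately not defaults — adjusting for heritable covariates can bias
genetic estimates — but can be added. Designs must be full rank;
collinearity is an error naming the offending columns rather than a silent
drop.

Association is per-variant OLS of the residualized trait on dosage with
t-reference p-values (n − 2 df). On unrelated samples with the trait
pre-residualized this coincides in expectation with mixed-model association,
which is why the package does not carry a GRM: the synthetic cohorts are
unrelated by construction. Monomorphic variants are emitted with missing
statistics and a flag, never dropped silently. Clumping is p-value informed
and greedy: ascending p (ties broken by chromosome, position, variant id for
determinism), each index absorbing unassigned variants with r² ≥ 0.2 within
±500 kb — "500 kb" is read as a half-window around the index, the common
convention; no secondary member p-threshold is applied. Variants absent from
the LD reference are listed separately rather than clumped.

For sex-specific hits, the male/female effect pair is pooled by
inverse-variance fixed-effect meta-analysis with Cochran's Q (df = 1),
I² = 100·max(0, (Q − 1)/Q), and a test-based 95% CI for I² built on
`H = √(Q/df)` with `se(ln H) = ln Q / (2(√(2Q) − 1))`. That standard error
is a large-sample form valid when Q exceeds the number of strata, so for two
strata the CI is reported only when Q > 2 and the lower bound is truncated
at 0 — matching how such intervals are conventionally printed (no CI for
small Q, "0.0" lower bounds). The package bundles twelve published
two-stratum worked examples (`het_worked_examples()`); recomputing p, I² and
the CI from each published Q reproduces every printed value to about one
unit in the last printed digit, the residual slack coming from the examples'
own rounding of Q to two decimals. Opposite-sex follow-up uses a Bonferroni
threshold `0.05 / n_snps_tested` within each trait family.

Disease-frequency deciles rank participants by the age+SES-residualized
phenotype separately within each sex, split them into ten groups whose sizes
differ by at most one (the lower deciles take the remainder; ties broken by
participant id, so any input order gives the same assignment), and report
the proportion with at least one diagnosis per disease group — each
participant counts once per group however many admissions they have, and
undiagnosed participants stay in the denominators. The default ICD-10 map
covers the ten leading causes of death in high-income countries
(CAD = I20–I25, STR = I60–I69, ALZ = F01/F03/G30, LCX = C33–C34,
COPD = J40–J44/J47, LRTI = J09–J18/J20–J22, CCX = C18–C21, DIA = E10–E14,
KID = N00–N19, BCX = C50) and is overridable. Prevalent and incident disease
are not distinguished, and non-ICD-10 coding systems are out of scope.

## What the generator emulates — and what it does not

`simulate_cohort()` and friends produce a cohort of 40–69-year-olds with
sex, weight, a Townsend-like deprivation score, 22 assessment centres, two
genotyping arrays, ten standard-normal principal components and the four
risk categories (defaults 35/35/25/5%). Each participant carries a resting
heart rate (Normal(65, 8) bpm) and a heart-rate response slope
(Normal(0.40, 0.08) bpm/W, truncated positive); the analytic true fitness is
`((208 − 0.7·age) − hr_rest) / hr_per_watt / weight`, which the derivation
pipeline must recover. Sessions are sampled every 4 s (the ~90
exercise-phase observations comfortably clear the 20-observation rule);
minimal/small ramps run 40→115 W and 30→95 W after a 2-minute steady
segment, medium holds 30 W. Heart-rate noise is AR(1) (marginal sd 3 bpm,
ρ = 0.6 by default) with salt-and-pepper spike artefacts (probability 0.01,
20–40 bpm) — linear response plus autocorrelated noise and spikes is exactly
the structure the filtering stage is designed for. Cadence is Normal(60, 4)
RPM with a 2% chance of an out-of-band excursion.

Genotypes are LD-blocked dosages from a haplotype-copying process: within a
block each variant copies its neighbour's allele with probability
`copy_prob` (1 → perfect LD, 0 → independence), blocks are separated by
~1 Mb so they are unlinked at clumping scale. A planted quantitative trait
adds sex-specific causal effects, and disease indicators follow
`Bernoulli(logistic(α_g + slope·z))` in the standardized trait with
per-group baselines chosen to give realistic prevalences (~0.5–8%).

Deliberate non-goals: no heart-rate lag or on-kinetics (real heart rate
trails workload by tens of seconds; here the response is instantaneous, so
derived slopes are optimistic relative to real traces), no recovery-phase
modelling, no realistic LD from reference panels, no imputation uncertainty,
no relatedness, and summary-level activity only (no raw accelerometry).
Passing tests therefore demonstrate correctness of the *computations* under
a faithful noise model, not robustness to every pathology of real traces.

Genetic effects are planted on a dedicated simulated trait rather than
threaded through the ramp-test generator, so the trace-derived CRF
phenotypes have no genetic signal at default scale; the planted trait is the
vehicle for association, clumping and heterogeneity demonstrations, and the
disease liability is driven by it.

## Numerical choices and problem sizes

All randomness flows from one root seed through named per-stage sub-streams,
so identical configurations give byte-identical results and single stages
can be re-run in isolation. Configurations round-trip losslessly through
YAML; every written table is stamped with its producing stage and a
configuration hash.

The test suite runs the derivation at these scales, chosen as the smallest
sizes at which each property is statistically sharp: noiseless recovery on
100 sessions (exact to 10⁻⁶, in practice ~10⁻¹⁵), noisy recovery on 500
sessions, association calibration on 10,000 null variants × 500 samples,
clumping against a brute-force reference on 100 random 50-variant
instances, disease-gradient recovery over 100 seeds of 5,000 participants,
and the full pipeline at 2,000 participants × 500 variants (a few seconds on
one core).

Two quantitative caveats surfaced by the suite are worth knowing. First,
under the default AR(1) noise the median relative error of recovered
CRF-vo2max sits *around* five percent (seed-to-seed range roughly 4–6%):
the ρ = 0.6 autocorrelation puts noise power below any cutoff that
preserves the ramp trend, and the extrapolation to the age-predicted
maximum heart rate amplifies slope error about five-fold (the leverage
`(HRmax − mean HR)` is several times the observed heart-rate span). Lowering
the filter cutoff does not help — the error is variance from in-band noise,
not bias — and the signed bias is under two percent. Second, published
heterogeneity statistics are reproduced from Q exactly, but recomputing Q
from *rounded* published effect estimates moves it in the second decimal, so
checks anchor on Q, not on the rounded betas.

## Known limitations

- The association stand-in is OLS; with related samples or strong
  stratification a mixed model would be required.
- The I² CI is undefined (suppressed) for Q ≤ 2 with two strata; no
  random-effects pooling or >2-strata meta-analysis is provided.
- `trend` is treated as an ordinal index; if real devices sample unevenly,
  slopes are per observation, not per second.
- The endpoints mode is sensitive to boundary noise even after filtering;
  it exists for comparability, not as the recommended estimator.
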