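---
title: "Models and methods behind chronocope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chronocope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronocope)
```

`chronocope` studies the coupling between circadian rhythmicity and animal
personality in zebrafish cohorts. This vignette is the package's own
account of its generative model, its estimators, the calibration choices
behind the defaults, and what the passing test suite does and does not
demonstrate about real data.

## 1. The generative model

Each fish `i` carries a latent boldness `b_i ~ Uniform(0, 1)`
(1 = maximally proactive). Boldness drives three families of observables.

**Emergence latency.** One session in context `c` (group or single test)
yields

$$L_{i,c,s} = s_0 \exp\{\beta\,(1 - b_i) + u_i + e_{i,c,s}\},$$

with scale $s_0$ (`latency_scale`, seconds), boldness slope $\beta$, a
stable individual deviation $u_i \sim N(0, \sigma_u^2)$ shared across all
sessions, and fresh session noise $e \sim N(0, \sigma_e^2)$, all on the log
scale. Ranking ascending latencies within a group of 10 gives the
emergence rank (1 = EE, 10 = LE); fish not emerging within 10 min are
excluded from ranking.

**Mirror-image stimulation.** Freezing grows with shyness and is capped at
the 10-min trial; the count of aggressive acts is Poisson with a rate
increasing in boldness over the time actually spent facing the mirror.
Fish freezing for the whole trial are non-responders and are excluded.

**Rhythmic channels.** Gene expression (relative units), hormone
concentration and binned swimming velocity follow a fixed-period cosinor

$$x_i(t) = M(b_i) + A(b_i)\cos\!\big(2\pi\,(t-\varphi)/24\big)\,D(t)
           + \varepsilon,\qquad
  \varepsilon \sim N\!\big(0, (\mathrm{cv}\cdot M(b_i))^2\big),$$

where mesor `M` and amplitude `A` interpolate linearly in boldness between
a shy and a bold extreme, `φ` is the acrophase (time of peak, hCT) and
`D(t) = 1` under light–dark cycling. Under constant light the oscillation
damps as $D(t) = 2^{-t_{LL}/h}$ with `h = ll_damping_halflife` (20 h):
bold fish gradually lose their rhythm, shy fish have none to lose.
Concentrations and velocities are floored at zero after noise. A cosine
parameterisation (acrophase = time of peak) is used throughout because the
acrophase is directly interpretable; it is equivalent to a sine up to a
phase shift.

The locomotor channel has two extra ingredients:

* a per-fish multiplicative scale $S_i = e^{N(0,\,0.6^2)}$ applied to
  mesor and amplitude alike, representing stable individual differences in
  overall activity that are unrelated to personality. Its consequence is
  deliberate: amplitude and AUC are contaminated by scale variation while
  rhythm strength, a *relative* measure, is not — which is exactly why the
  model-selection step singles out rhythm strength;
* a few escape bursts per day whose magnitude approaches the fish's
  physiological ceiling (`vmax_ceiling` × $S_i$, 20 mm s⁻¹ by default).
  The ceiling does not depend on boldness, so the daily maximum velocity
  (Vmax) is personality-independent by construction and serves as a null
  predictor. An absolute, cohort-wide ceiling was rejected: to dominate
  the largest fish's rhythmic peak it would have to sit an order of
  magnitude above a small fish's mesor, and the resulting spikes would
  drown the small fish's 24-h component.

All randomness derives from the cohort seed through keyed substreams
(`substream_seed()`): draws for one fish and session are a function of the
fish id and session label only, so enlarging a cohort or adding a session
never perturbs existing draws, and every pipeline stage is a pure function
of its configuration.

## 2. Default calibration

Defaults (in `cohort_config()` and `default_channel_params()`) encode the
study conditions: groups of 10 sampled at 1, 7, 13, 15, 19, 23 hCT under a
14:10 LD cycle; a 6-day activity recording in 30-min bins starting at
7 hCT (3 days LD, then 3 days LL); 9 groups with 2 fish per group randomly
eliminated, giving 72 analysed fish; 24 groups for the behavioural
validation test.

* **Latency model**: $\beta = 4$, $\sigma_u = \sigma_e = 0.1$,
  $s_0 = 30$ s, so the median group-test latency is ≈ 220 s and roughly a
  fifth of the fish miss the 10-min cutoff. These values were fixed by a
  design-stage Monte-Carlo so that the pooled correlation between group
  rank and single-test latency reaches the published magnitude. Two
  structural facts constrain them hard: ranking within groups of 10
  destroys the between-group share of the boldness variance, and the
  10-min exclusion truncates the shy tail — together they cap the pooled
  Spearman ρ at ≈ 0.83 *even with zero noise*. Reproducing a published
  ρ of 0.82 therefore forces a nearly noise-free latent coupling, which in
  turn makes the test–retest repeatability of the generator higher than
  emergence tests typically show. With one number for both quantities the
  model cannot match them simultaneously; the rank correlation is the
  primary target and wins.
* **Genes** (*bmal1a*, *clock1a*, *per1a*, *cry1a*, *cipca*):
  noise cv 0.12, shy amplitude = 10% of the bold amplitude, acrophases
  spread over the cycle (dawn-peaking *per1a*/*cry1a*, evening-peaking
  *bmal1a*/*clock1a*, midday *cipca*). *bmal1a* and *cipca* carry the
  steepest mesor declines towards shy fish, so their net output (AUC)
  shows the clearest rank trend while amplitude falls with rank for all
  five.
* **Hormones**: cortisol 10 → 25 ng g⁻¹ mesor from bold to shy with the
  rhythm (amplitude 8, dawn peak) only in bold fish — "constantly high"
  cortisol in shy fish; melatonin 100 → 130 pg g⁻¹ with a dark-phase peak
  (amplitude 80) in bold fish and an intermediate flat level in shy fish.
  Net output (AUC over the sampling window) therefore *rises* with rank
  for both hormones while amplitude falls.
* **Activity**: mesor 4 → 5 mm s⁻¹, relative amplitude 5% → 70% of the
  mesor from shy to bold, acrophase 1 hCT (activity peaks in the first
  hours of the light phase), bin noise cv 0.5, scale sd 0.6 (log).

The between-individual variance components are not published anywhere;
they are calibration choices, made once, and the calibration target was
that every recovered rank–metric correlation meets or exceeds the
published magnitude (the acceptance suite checks exactly this).

## 3. Rhythm quantification

Given a tidy series (`time_hct`, `value`):

* `lowess_smooth()` — locally weighted linear regression with tricube
  weights, a 5-point window (span `min(1, 5/n)`) and **zero** robustness
  iterations, evaluated at the input times. The implementation delegates
  to `stats::lowess`; the test suite verifies it point-by-point against a
  direct hand-written tricube regression.
* `fit_sine24()` — closed-form OLS on {1, cos(2πt/24), sin(2πt/24)}.
  The period is fixed at exactly 24 h: free-period fitting is out of
  scope, and on diurnal designs with six samples per cycle a free period
  is barely identifiable anyway. Times are used unfolded; multi-day series
  rely on the basis' own periodicity. Conventions: amplitude ≥ 0,
  acrophase in [0, 24); a constant series returns amplitude 0 and, by
  convention, R² = 0.
* `compute_auc()` — trapezoidal integral of the *LOWESS curve* over the
  observed window. Integrating the fitted sinusoid instead would collapse
  to 24 × mesor over a full period and discard the curve's shape, losing
  the "net output" meaning on the unevenly sampled 6-point design.
* `rhythm_strength_24h()` — the R² of the fixed-24-h harmonic regression
  on the raw series. The literature offers several "rhythm strength"
  statistics (χ²-periodogram peak height, spectral ratios); the R² was
  chosen because it is dimensionless, bounded in [0, 1], invariant under
  affine rescaling of the values (so fish with different overall activity
  levels compare fairly) and exactly the variance fraction of the 24-h
  component. It requires ≥ 8 points spanning ≥ 48 h. Its white-noise
  expectation is 2/(n−1) (two harmonic regressors), which the test suite
  confirms by simulation.
* `vmax()` — mean of the per-24-h-window maxima over the first three LD
  days.

Numerical edge cases: series must be strictly increasing in time; fits
need ≥ 4 points and ≥ 3 distinct times modulo 24 (otherwise a
singular-design error); zero-variance series raise an explicit
undefined-strength error rather than returning NaN.

## 4. qPCR quantification

Technical triplicates are averaged on the Ct scale before any subtraction
(standard practice; the Ct scale is where the noise is approximately
Gaussian). `delta_ct()` subtracts the *ippA* housekeeping Ct within each
(fish, timepoint); `fold_change_ee_vs_le()` is the classic
$2^{\Delta\Delta Ct}$ contrast of early versus late emergers. For time
courses the pairwise ΔΔCt generalises to per-sample relative expression
$2^{-\Delta Ct}$, normalised to the series mean so genes are comparable —
an interpretation, since the pairwise definition does not directly apply
to a 6-point series. For rank-level curves, Ct values are averaged within
(gene, rank, timepoint) *before* the housekeeping subtraction. Global Ct
shifts (e.g. input-amount differences hitting targets and housekeeping
alike) cancel identically at every stage.

## 5. The inferential layer

Spearman correlations use mid-ranks; the p-value is exact by full
enumeration for n < 10 (the n! permutation distribution is computed, not
approximated) and the t approximation otherwise. The strain test is a
Pearson goodness-of-fit of the AB/TL split per rank against 50/50 with one
degree of freedom per rank. Two-way ANOVA uses type-II sums of squares
(`car::Anova`) so unbalanced layouts remain well defined; Bonferroni
(α/m) and Šidák (1−(1−α)^{1/m}) helpers adjust post hoc levels.

`select_rhythm_model()` reproduces the selection chain that identifies
rhythm strength: (1) iterative VIF pruning at threshold 5, highest first;
(2) Cook's distance flags at 4/n — *reported, never auto-removed*, keeping
the analyst in the loop; (3) backward elimination by AIC; (4) a
likelihood-ratio confirmation that iteratively drops retained predictors
not significant at α = 0.05. The VIF and Cook thresholds are the common
textbook defaults (neither is dictated by the scientific question) and are
exposed as arguments. Emergence rank is treated as numeric in the linear
model, matching regression-on-rank usage. One caveat is intrinsic to the
procedure: with two effectively null candidate predictors surviving to the
confirmation stage, the chance that the retained set is *exactly*
{rhythm strength} is about (1−α)² ≈ 0.90 per cohort — the test suite's
90%-of-100-cohorts check operates at the procedure's own theoretical
operating point.

## 6. Problem sizes and runtime choices

The test and acceptance runs use the study-design sizes directly: 72
analysed fish for physiology (9 × 10 with two eliminated per group), 240
fish for the behavioural validation (24 × 10), 288 activity bins per fish,
and 20-seed averages for the headline correlations; the selection
consistency and the Vmax null are checked over 100 seeded cohorts. These
sizes keep the full suite in the low minutes on a single core while
leaving Monte-Carlo error well below the decision margins.

## 7. What the synthetic cohorts do and do not show

The generator reproduces the *structure* the analyses assume — monotone
amplitude decline along the proactive–reactive axis, elevated flat
cortisol in shy fish, damping under constant light, null body-weight and
Vmax controls, exclusion rules — with effect sizes calibrated so the
printed correlation magnitudes are attainable. It does not emulate several
features of real data:

* biological waveforms are not pure cosines (skewed activity onsets,
  pulsatile hormone release); the cosinor amplitude of a non-sinusoidal
  rhythm underestimates its peak-to-trough range;
* measurement error is Gaussian and independent across timepoints; real
  qPCR and ELISA errors are heteroscedastic and batch-correlated;
* each synthetic fish is measured at all six timepoints, whereas real
  expression/hormone sampling is terminal — the real design measures each
  *rank* (different fish per timepoint), so per-fish AUC here corresponds
  to per-rank AUC there;
* the latency calibration needed to reach the published rank correlation
  implies near-perfect test–retest repeatability (section 2), higher than
  real emergence tests show;
* the weak positive rank trend of activity AUC in the generator does not
  reproduce the published negative LD correlation of total activity with
  rank; making it strongly negative would require coupling overall
  activity level to boldness, which would erode the Vmax null and the
  selection result. The published pattern suggests the real coupling is
  between boldness and *rhythmic* (not total) output, which is what the
  generator encodes.

Passing tests therefore demonstrate the correctness and stability of the
estimators and of the inference chain under a faithful stylised model —
not that real cohorts would yield these effect sizes.
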