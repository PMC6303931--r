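# chronocope

Chronobiology of animal personality: does a robust circadian clock go with a
proactive coping style? In zebrafish (*Danio rerio*), individuals span a
proactive–reactive continuum — bold, risk-taking, aggressive fish at one end
and shy, risk-avoiding fish at the other — that can be scored with an
emergence test (rank 1 = early emerger, EE; rank 10 = late emerger, LE).
`chronocope` provides a tested, fully reproducible pipeline for studying how
diurnal rhythmicity of clock-gene expression, cortisol and melatonin
secretion, and locomotor activity co-varies with emergence rank:

* a **seeded synthetic-cohort generator** in which each fish carries a latent
  boldness `b ∈ [0, 1]` driving its emergence latency, mirror-test
  aggression, and the mesor/amplitude of every rhythmic channel;
* **rhythm quantification** exactly as in the classic analysis chain:
  LOWESS smoothing (5-point window), a fixed-period 24-h sinusoid fit,
  area under the curve (AUC), amplitude, rhythm strength and maximum
  swimming velocity (Vmax);
* **qPCR quantification** by ΔΔCt (housekeeping gene *ippA*, technical
  triplicates averaged on the Ct scale);
* **behavioural scoring** of group/single emergence (10-min exclusion rule)
  and mirror-image stimulation (AGR frequency over non-freezing time);
* an **inferential layer**: Spearman rank correlations (exact permutation
  p for small n), chi-square strain tests, two-way ANOVA with
  Bonferroni/Šidák corrections, and the VIF → Cook's distance → backward-AIC
  → likelihood-ratio model-selection procedure that identifies rhythm
  strength as the predictor of emergence rank.

## The model

Every rhythmic channel (gene expression, hormone concentration, binned
swimming velocity) is a single-component cosinor with the period fixed at
24 h:

```
x(t) = M + A · cos( 2π (t − φ) / 24 ) · D(t) + ε
```

with mesor `M`, amplitude `A`, acrophase `φ` (clock time of the peak, hCT;
0 hCT = lights-on in the 14:10 LD cycle) and noise `ε`. Under cycling light
`D(t) = 1`; under constant light the oscillation damps as
`D(t) = 2^(−t_LL / h)` with half-life `h` (20 h by default). Fitting is
closed-form least squares on the harmonic basis {1, cos, sin}; amplitude is
`√(a² + b²)` and rhythm strength is the regression R² — the fraction of
variance carried by the 24-h component, a dimensionless quantity in [0, 1].

In the generator, mesor and amplitude interpolate linearly in boldness
between a shy and a bold extreme: amplitudes collapse towards zero in shy
fish for every channel, cortisol is constantly high in shy fish (mesor
2.5× the bold mesor), melatonin sits at an intermediate flat level, and
clock-gene expression falls. Body weight and the per-fish activity scale
are independent of boldness, giving built-in null controls (weight, Vmax).

## Worked example

```r
library(chronocope)

cfg   <- cohort_config(n_groups = 9, seed = 1)   # 9 groups of 10 fish
study <- run_full_study(cfg)                     # rank, sample, quantify, correlate

subset(study$correlations,
       metric %in% c("amplitude", "auc", "rhythm_strength") &
       channel %in% c("bmal1a", "cortisol", "melatonin", "activity"))
#>    channel   regime metric              rho  p_value     n
#>  1 activity  LD     auc              0.0580 6.28e- 1    72
#>  2 activity  LD     amplitude       -0.530  1.71e- 6    72
#>  3 activity  LD     rhythm_strength -0.794  9.41e-17    72
#>  4 activity  LL     auc              0.0736 5.39e- 1    72
#>  5 activity  LL     amplitude       -0.337  3.80e- 3    72
#>  6 activity  LL     rhythm_strength -0.566  2.26e- 7    72
#>  7 bmal1a    LD     auc             -0.903  2.36e-27    72
#>  8 bmal1a    LD     amplitude       -0.829  2.53e-19    72
#>  9 cortisol  LD     auc              0.938  6.96e-34    72
#> 10 cortisol  LD     amplitude       -0.856  1.06e-21    72
#> 11 melatonin LD     auc              0.691  1.92e-11    72
#> 12 melatonin LD     amplitude       -0.901  4.43e-27    72
```

Reading the table: amplitude falls with emergence rank in every channel
(shy fish are arrhythmic), cortisol/melatonin net output (AUC) *rises* with
rank (constantly elevated hormones in shy fish), clock-gene output falls,
and under constant light the activity correlations weaken as the bold
fish's rhythms damp out. The model-selection step recovers rhythm strength
as the sole predictor of rank:

```r
study$selection
#> <chrono_selection> retained: rhythm_strength
#>   dropped by VIF: auc, amplitude
#>   flagged points (Cook's D > 0.0556 ): 4
```

Individual series work the same way with data-frame-first verbs:

```r
ts <- simulate_channel_timeseries(generate_cohort(cfg)[1, ], cfg, "cortisol")
fit_sine24(ts[c("time_hct", "value")])
#> <sine_fit> 24-h cosinor: mesor 15.38, amplitude 5.539, acrophase 2.35 hCT, R^2 0.879 (n = 6)
compute_auc(ts[c("time_hct", "value")])
#> [1] 332.4707
```

`tidy()`, `glance()` and `autoplot()` methods are available for fitted
sinusoids, correlation results, selection results and whole studies; a thin
command-line front end lives in `inst/scripts/chronocope.R`
(`simulate`, `score-emergence`, `score-mirror`, `rhythm`, `run-all`).

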