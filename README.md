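# fnirsinc

Quantifying how hair and skin characteristics affect fNIRS signal
quality — and what that means for inclusivity.

Functional near-infrared spectroscopy (fNIRS) measures cortical
haemodynamics by shining near-infrared light through the scalp.
Hair density, shaft thickness, curl type, hair colour and skin
pigmentation all absorb or scatter that light, so signal quality varies
systematically across participants. Left unaddressed, this biases who
can be measured well, and therefore who is represented in fNIRS
research. `fnirsinc` is an R package for researchers and hardware
developers who want to quantify these effects: it implements
channel-level signal-quality metrics, a combined hair-skin difficulty
metric, the statistical battery relating participant factors to signal
quality, a detector-sensitivity (noise-equivalent-power) analysis of
channel pruning, and a task GLM — plus a synthetic-data generator that
emulates the structure of a 115-participant inclusion study so the
whole pipeline runs end-to-end without any acquisition hardware.

## What it computes

**Signal-quality metrics** (per channel, two wavelengths at 760/850 nm):

- *Uncorrected Signal Mean* — the raw intensity time-course mean,
  averaged across wavelengths.
- *Corrected Signal Mean* — the mean divided by the LED source-power
  percentage, times 100, then log10-transformed:
  `CSM = log10(mean(I) / power% * 100)`.
- *Scalp Coupling Index* — both wavelength traces are band-passed to
  the cardiac band (0.5–2.5 Hz), normalised to unit SD, and correlated
  at zero lag; `SCI ≈ 1` means both wavelengths carry the same cardiac
  pulsation, i.e. good optode-scalp coupling. A Fisher z-transform
  (`z = atanh(SCI)`) stabilises the variance for analysis.

**Combined hair-skin metric** — the equal-weight mean of four
normalised factors, each scaled to [0, 1] over its observed range:
shaft thickness (42–88 µm), hair type (0–4), hair colour (0–4) and
skin pigmentation (melanin index 4.7–90). Values bin into five groups,
[0.15, 0.30) up to [0.75, 1].

**Statistics** — equal-width binning with Mann-Whitney U tests
(Benjamini-Hochberg corrected, α = 0.01); Spearman correlation with a
robust linear fit (IRLS, bisquare ψ, c = 4.685) and the signed fold
change between the 1st/99th factor percentiles,
`FC = U/L if U ≥ L, −L/U otherwise` (on the unlogged scale);
multicollinearity screening at |r| > 0.5 with variance inflation
factors `VIF = 1/(1−R²)`; robust multiple regression with Cohen's
`f² = (R²_full − R²_−j)/(1 − R²_full)`.

**NEP inclusivity** — the device's raw-unit noise floor (6.8·10⁻⁶)
maps to its noise-equivalent power (52 fW/√Hz); channels are pruned
when their equivalent optical power falls below `NEP · 10^(20 dB/10)`,
i.e. two orders of magnitude above the noise floor. Sweeping the NEP
shows what fraction of each hair-skin group a less sensitive system
would lose.

**Task GLM** — intensity → optical density (−ln I/Ī) → SNR < 5
pruning → zero-phase 6th-order Butterworth low-pass at 0.5 Hz →
modified Beer-Lambert inversion (no pathlength correction) → OLS GLM
with a modified-gamma HRF, `h(t) = e·u²·e^(−u²)`, `u = (t−τ)/σ`
(τ, σ, duration = 0.1, 3, 5 s for HbO₂; 1.8, 3, 5 s for HbR), a
per-channel short-separation nuisance regressor (the most correlated
~8 mm channel), and baseline correction over −2..0 s.

## Worked example

```r
library(fnirsinc)

cfg    <- sim_config(seed = 1)
probe  <- generate_probe()                     # 44 channels, 2 hemispheres
cohort <- participant_metrics(generate_participants(30, cfg))
qc     <- cohort_quality(cohort, probe, cfg, duration_s = 180)

# Did thorough capping improve coupling on the (hairy) side of the head?
compare_runs(qc$run1, qc$run2, "sci", roi = "side")
#>   metric roi       n mean1   sd1 mean2    sd2 percent_increase p_paired_t
#> 1 sci    side    720 0.767 0.135 0.874 0.0993             14.0  2.55e-306
```

Mean SCI rises from 0.77 after hasty capping to 0.87 after thorough
hair adjustment — a 14% improvement, overwhelmingly significant in a
paired test over the 720 side-of-head channels.

```r
# Which participant factors predict the corrected signal mean there?
quality_regression_table(qc$run2, cohort, "side")
#>             predictor  estimate       se tstat   pvalue      f2  vif
#> 3   skin_pigmentation -0.003461 0.001275 -2.71 6.85e-03 0.01454 1.81
#> 4          hair_color -0.107740 0.022316 -4.83 1.76e-06 0.05518 1.94
#> 5        hair_texture -0.049365 0.018149 -2.72 6.72e-03 0.01642 1.22
#> ...
```

Darker hair and higher skin pigmentation significantly reduce the
log-scale signal mean (negative estimates, p < 0.01); all VIFs are
below 2, so the screened predictors are not collinear.

```r
# How inclusive is the detector? Pass rates per hair-skin group:
groups <- cohort$metric_group[match(qc$run2$participant, cohort$id)]
group_pass_percentages(qc$run2, groups)
#>   group     n pass_pct        suboptimal: 0.7%
#> 1     1    44    100
#> 3     3   836     99.3
#> 4     4   220     98.6
```

At the study device's own sensitivity almost every channel clears the
20 dB criterion; `sensitivity_sweep()` shows how a higher-NEP system
loses the high-metric groups first. `run_study()` chains all stages
(cohort → recordings → QC → metrics → statistics → NEP → GLM) and
writes every table as CSV; `study_report()` renders a markdown summary
with violin, effect-size and NEP figures.

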