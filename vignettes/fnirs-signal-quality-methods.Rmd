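---
title: "Methods: signal quality, participant factors and inclusivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal quality, participant factors and inclusivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsinc)
```

# Scope and model overview

`fnirsinc` analyses how participant-level factors — hair colour, type,
texture, density and shaft thickness, skin pigmentation, head size, sex
and age — relate to the signal quality of continuous-wave fNIRS
recordings. The package has two halves that share one set of contracts:

* an **analysis half**: channel-quality metrics, the combined
  hair-skin metric, association and robust-regression statistics, the
  noise-equivalent-power (NEP) pruning analysis, and the task GLM;
* a **synthetic half**: a cohort and forward-signal generator that
  reproduces the statistical structure those analyses assume, so that
  every stage is testable end-to-end without instrument data.

# Signal-quality metrics

For a channel with intensity time courses $I_\lambda(t)$ at
$\lambda \in \{760, 850\}$ nm:

* **Uncorrected signal mean**: $\tfrac12\sum_\lambda \overline{I_\lambda}$,
  in raw instrument units. Used for the NEP analysis and the capping
  comparison, because it reflects the light level the detector actually
  sees.
* **Corrected signal mean**:
  $\log_{10}\!\big(\tfrac12\sum_\lambda \overline{I_\lambda}\,/\,p_\lambda \times 100\big)$
  with $p_\lambda$ the LED source-power percentage. The power
  correction makes channels comparable across participants after the
  instrument's automatic source modulation; the log approximately
  linearises the relationship with attenuating factors. The wording of
  the metric leaves open whether the two wavelengths are averaged
  before or after the log; the default averages the power-corrected
  means first and then takes the log, and
  `corrected_signal_mean(order = "log-then-average")` provides the
  alternative. The two differ by at most the spread between wavelength
  means and move all channels coherently.
* **Scalp coupling index (SCI)**: both wavelength traces are band-pass
  filtered to the cardiac band (0.5–2.5 Hz), normalised to unit SD,
  and correlated at lag zero. The band is fixed by the definition; the
  filter inside it is a design choice — a 3rd-order Butterworth applied
  forward-backward, because zero-phase filtering preserves the zero-lag
  correlation. The DC level is removed before filtering: `filtfilt`
  starts from zero state, and an edge transient proportional to the
  baseline (typically 100x the cardiac amplitude) would otherwise be
  shared between the wavelengths and bias the SCI towards 1. Fisher's
  $z = \operatorname{atanh}(r)$ is applied for analysis, with $|r|$
  clipped at $1 - 10^{-12}$ so degenerate perfect correlations stay
  finite.
* **SNR** is mean/SD of the raw, unfiltered intensity (averaged across
  wavelengths); channels below 5 are excluded from the task GLM. A
  constant (noiseless) trace has infinite SNR and is retained — a
  synthetic channel without noise should not be pruned.

# Combined hair-skin metric and groups

The combined metric is the equal-weight mean of four normalised
factors: average shaft thickness (normalisation range 42–88 µm), hair
type (0–4), hair colour (0–4) and skin pigmentation (melanin index,
range 4.7–90). The ranges are the observed extremes of the study
population the package emulates; values outside them are clipped to
[0, 1] with a warning, since new data may exceed them. The thickness
entering the metric averages the side- and back-of-head trichoscopy
readings — the metric is defined from both regions and no aggregation
rule is prescribed, so the symmetric choice is used. Group bins are
half-open on the right except the last ([0.15, 0.30) … [0.75, 1]),
and values below 0.15 fold into group 1 so the assignment is total on
[0, 1].

# Statistical battery

* **Binning** is for visualisation only: violin plots use four
  equal-width bins over the factor's range, while correlations and
  regressions use the continuous values. The pipeline reuses one
  binning implementation in both places to enforce that separation.
* **Mann-Whitney U** compares the response between the lowest and
  highest bins, two-sided; exact p-values for groups of at most 20
  without ties, the tie-corrected normal approximation otherwise.
* **Benjamini-Hochberg** adjustment is applied within each region's
  family of factors, with significance declared at 0.01.
* **Spearman's rho** uses average ranks for ties and the
  $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ approximation for p-values.
* **Robust fits** use iteratively reweighted least squares with Tukey
  bisquare weights, tuning constant 4.685 (95% Gaussian efficiency),
  scale re-estimated each iteration as $\mathrm{median}|r|/0.6745$,
  convergence at $10^{-8}$ relative coefficient change or 50
  iterations (non-convergence is flagged, the last iterate returned).
  Standard errors come from the standard M-estimator asymptotic
  covariance $\big[\sum\psi^2/(n-p)\big]/\big[\overline{\psi'}\big]^2 (X'X)^{-1}$;
  p-values use $n-p-1$ degrees of freedom. Type-I error at nominal
  0.05 is verified by permutation in the test suite.
* **Fold change** evaluates the robust line at the 1st and 99th factor
  percentiles (linear interpolation between order statistics, the
  default quantile definition), unlogs both endpoints, and applies the
  sign rule $U/L$ if $U \ge L$, else $-L/U$, so the magnitude is
  always at least 1 and the sign tracks the direction.
* **Multicollinearity screening** drops one member of every predictor
  pair with $|r| > 0.5$, keeping the more objective, interpretable
  metric (melanin index over Fitzpatrick type, trichoscopy over visual
  codes). Pairs are processed in descending $|r|$ with re-checking
  after each drop, which makes correlation chains deterministic.
* **Cohen's $f^2$** uses the robust fit's weighted $R^2$ analogue
  ($1 - \sum w r^2 / \sum w (y-\bar y_w)^2$ at the converged weights)
  in the partial formula; the pairing of $f^2$ with a robust fit has
  no canonical definition, so this one is fixed and tested for
  internal consistency. Note that the weighted $R^2$ runs slightly
  higher than the OLS $R^2$ on clean Gaussian data (bisquare weights
  suppress tail residuals), so robust $f^2$ values are not numerically
  interchangeable with OLS ones.
* **Unit of analysis**: responses are channel-wise within a region by
  default (the association analyses are defined channel-wise); a
  per-participant-mean switch exists because pooling channels inflates
  the nominal sample size for inference.

# NEP inclusivity analysis

The measured raw noise floor of the reference device ($6.8\times10^{-6}$
raw units) is paired with its detector sensitivity (NEP =
52 fW/$\sqrt{\mathrm{Hz}}$, detector area 9.6 mm²), which defines a
linear raw-to-power equivalence; the $\sqrt{\mathrm{Hz}}$ bandwidth
normalisation is absorbed into that measured pair. A channel passes
when its equivalent optical power is at least the pruning threshold
$\mathrm{NEP}\times10^{\mathrm{margin}/10}$ — with the default 20 dB
margin, two orders of magnitude in power (1 pW maps to 100 pW), with
the boundary passing ("at least"). In a sensitivity sweep, the
*measured* powers keep the device equivalence while the *threshold*
follows the hypothetical system's NEP; consequently each group's pass
curve is non-increasing in NEP by construction.

# Task GLM

The task chain converts intensity to optical density
($OD = -\ln I/\bar I$; natural log, fixed by contract), prunes
SNR < 5 channels, low-passes at 0.5 Hz with a 6th-order Butterworth
applied forward-backward (zero phase; the effective attenuation order
doubles, which is the documented convention), and inverts the
modified Beer-Lambert law per channel with the source-detector
separation as the only distance scaling — no differential pathlength
factor, so concentrations carry effective (pathlength-free) molar
units. Extinction coefficients at 760/850 nm come from the standard
Gratzer/Prahl compilation used across fNIRS toolboxes
(`extinction_coefficients()`).

The HRF kernel is the modified gamma
$h(t) = e\,u^2 e^{-u^2}$, $u = (t-\tau)/\sigma$ for $t \ge \tau$,
sampled over −2..12 s; it peaks with value 1 at $\tau+\sigma$ (3.1 s
for HbO₂, 4.8 s for HbR with the default parameters). The third
parameter ("duration" = 5 s) is interpreted as the boxcar length the
kernel is convolved with, matching the 5 s stimuli. Condition
regressors are normalised so a single trial peaks at 1, making the
fitted beta the peak single-trial concentration change. The design
adds an intercept, a linear drift (a deliberately minimal drift
model), and one short-separation regressor per long channel — the
short channel whose HbO₂ trace correlates best with the long channel,
ties broken by label order. The estimated HRF is baseline-corrected by
subtracting its mean over −2..0 s, and the t statistic of the HbO₂
condition beta is reported.

**Calibration caveat.** OLS standard errors assume white residuals.
The 0.5 Hz low-pass leaves the residuals autocorrelated, so nominal
p-values from the filtered pipeline are anticonservative (in the
synthetic null, $|t| > 1.96$ occurs for roughly 13% of fits rather
than 5%). The test suite therefore verifies the estimator's nominal
calibration on unfiltered white-residual data, and verifies
sign-symmetry of the null t under the full pipeline. Downstream, GLM
outputs are used as response variables in the factor regressions, not
as inferential endpoints, which is robust to this caveat. Prewhitened
or AR-corrected GLM solvers are out of scope.

# The synthetic-data generator

The generator's defaults encode the emulated study conditions:

* **Montage**: per hemisphere, forehead 4 long + 1 short channel,
  side 10 long + 2 short, back 4 long + 1 short; ~30 mm and ~8 mm
  nominal separations; wavelengths 760/850 nm; sampling rate 10.2 Hz.
  Optode positions are schematic identifiers, not head geometry.
* **Cohort**: continuous factors are truncated normals with the
  reported cohort means/SDs (e.g. side hair density 160.7 ± 41.3 /cm²,
  shaft thickness 62.2 ± 8.0 µm truncated to 42–88, pigmentation
  25.3 ± 18.1 truncated to 4.7–90, age 26.4 ± 10.3 truncated to
  18–89); truncation elsewhere is mean ± 3 SD floored at 0.
  Categorical priors are chosen so the implied means/SDs match the
  reported scale summaries (colour 3.2 ± 1.0, type 1.8 ± 1.1,
  texture 1.7 ± 0.8, regrouped skin type 2.0 ± 0.9, 55/45
  female/male). Pigmentation, skin type and hair colour share a latent
  Gaussian copula; the dependence parameter targets the *realised*
  Pearson correlation (default 0.4), with the latent correlation
  de-attenuated for the marginal transforms on a deterministic
  quantile grid. Skin type is modelled as a coarse visual reading of
  pigmentation (latent correlation 0.85), which is what makes the
  multicollinearity screen drop it in favour of the melanin index.
  Percentage triples are renormalised to sum to 100; cumulative
  thickness is derived exactly as density × thickness × 10⁻³. The
  default cohort contains no "no hair" participants (the trichoscopy
  moments describe haired scalps); the coding is fully supported and a
  prevalence can be configured.
* **Forward model**: per-channel intensity is
  $B \cdot 10^{-A_c}\,(1 + \text{cardiac}) \cdot e^{-OD_{phys}} + \varepsilon$.
  The attenuation exponent $A_c$ is linear in the [0, 1]-normalised
  factors on the log10 scale — chosen so the corrected signal mean is
  linear in the factors, matching the linear analyses — times a
  per-channel log-normal multiplier (hair sits under specific
  optodes). The forehead uses pigmentation only. The weights are the
  package's own calibration: no attenuation-per-factor constants are
  published, so they were set a priori to reproduce the reported
  directions of effect and the coarse regional scale of the resting
  runs (uncorrected means near 0.33/0.17/0.11 and SCI near
  0.95/0.90/0.76 on forehead/side/back after thorough capping), and
  they are not fitted to any reported regression coefficients.
* **Cardiac term**: a 1.1 Hz sinusoid plus one harmonic at 1% relative
  amplitude — inside the SCI band — shared across wavelengths with
  coupling $\in [0,1]$ equal to 1 minus a weighted hair-factor sum
  (clipped); the uncoupled remainder is independent cardiac-band noise
  per wavelength, so hair degrades SCI without changing the mean.
* **Noise**: additive Gaussian at the device-equivalent floor
  $6.8\times10^{-6}$ raw units.
* **Superficial physiology**: a shared 0.05–0.4 Hz process injected in
  OD space into every channel (including short channels) through the
  same Beer-Lambert forward relation the analysis inverts, giving the
  short-separation regressor something real to remove.
* **Task responses**: evoked HbO₂/HbR concentration changes (defaults
  1 µM and −0.3 µM peak) convolved with the same HRF kernels, injected
  into side-region long channels; 15 trials per hand, 5 s stimuli,
  5–15 s uniform inter-stimulus intervals, fully randomised order.
* **Capping pair**: a "fast capping" run multiplies the attenuation
  exponent and reduces coupling on the hairy regions relative to the
  "proper capping" run, sharing the same per-channel pattern so the
  contrast isolates the capping effect; the forehead is untouched.
* **Source power**: fixed at 100% by default; an auto-scaled mode
  emulates the instrument raising LED power on attenuated channels
  (drive reference 25%, capped at 100%), which divorces the
  uncorrected from the corrected mean.

**What the generator does not emulate**: photon transport in realistic
head geometry, motion artifacts, hair styles (braids, locs, etc. —
excluded from the emulated analysis as well), instrument drift and
wavelength-dependent attenuation differences. Passing tests therefore
demonstrate that the analysis chain recovers the structure this
forward model encodes — directions and detectability of factor
effects, coupling-driven SCI differences, NEP-dependent pruning — not
that it reproduces any particular device's absolute numbers on real
scalps.

# Numerical choices and degenerate inputs

* Quantiles: linear interpolation between order statistics throughout.
* Bins and groups: half-open on the right, closed last bin.
* Paired comparisons with numerically constant differences report
  p = 1 (zero difference) or p = 0 (constant non-zero shift) instead
  of an undefined t.
* Zero-variance traces: SCI undefined (`NA`, flagged); SNR infinite
  (retained); constant factors are skipped in association tables and
  dropped from regressions with a message.
* IRLS guards: if bisquare rejects all but ≤ p points, weights are
  floored to keep the system full rank; an exactly-interpolating fit
  short-circuits with unit weights.
* Fisher z clipping at $|r| = 1 - 10^{-12}$.
* Rank-deficient VIF designs report `Inf` for the affected predictors.

# Problem sizes in the test suite

The test suite exercises the full chain at sizes chosen to make the
statistical claims sharp while staying desk-scale: SCI oracle and null
checks on 3-minute traces (200 draws each); Mann-Whitney against full
enumeration for all group sizes up to 8; robust-regression type-I
calibration with 500 permutations at n = 115; sign recovery of the
pigmentation and hair-colour effects over 100 independent cohorts of
115 participants (10 s resting segments, which fix the mean-based
metrics to well under a percent); GLM amplitude recovery over 100
simulated task runs on the motor-area montage; and NEP monotonicity on
a 400-participant cohort. Resting-state demonstrations use the full
3-minute runs.

# Known limitations

* The attenuation and coupling weights are directionally calibrated,
  not fitted; absolute regression coefficients from synthetic cohorts
  are not comparable to any specific device or population.
* The GLM's nominal p-values are anticonservative under the 0.5 Hz
  low-pass (see the calibration caveat above).
* Channel-wise association analyses treat channels within a
  participant as independent rows; a per-participant switch is
  provided, and mixed-effects modelling is deliberately out of scope.
* The SNIRF reader targets standard continuous-wave files only (no
  frequency- or time-domain variants); unknown optional groups are
  ignored with a message.
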