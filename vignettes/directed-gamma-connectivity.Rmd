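---
title: "Directed gamma-band connectivity between auditory cortices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed gamma-band connectivity between auditory cortices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dichotr)
```

## The scientific problem

During dichotic listening — two different consonant–vowel syllables presented
simultaneously, one per ear — most listeners report the right-ear syllable
more often (the right-ear advantage, REA). The callosal relay account holds
that a left-ear stimulus, arriving first in the right hemisphere, must cross
the corpus callosum to reach left-hemisphere speech areas, which predicts a
*directed* right-to-left flow of information between auditory cortices when
the left-ear syllable is perceived. Testing that prediction needs more than
undirected coupling: it needs a measure of directed (Granger-sense) influence
between the source-level time series of left and right primary (PAC) and
secondary (SAC) auditory cortex, evaluated in the gamma band (30–100 Hz)
where auditory cortical interaction is expressed.

`dichotr` implements the two connectivity statistics that address this, the
multi-trial autoregressive machinery underneath the directed one, a synthetic
data generator with exactly known directed coupling, and the group pipeline
(windowing, band averaging, laterality index, within-subject statistics)
that turns per-trial source signals into group-level inference.

## Functional connectivity: lagged phase synchronization

For ROI signals $x$ and $y$, each trial's discrete Fourier transform is
normalized coefficient-wise to unit modulus (only phase is retained), outer
products are averaged over trials and scaled to coherency form, giving the
complex coherency $f_{x,y}(\omega)$. Lagged phase synchronization is

$$\varphi^2_{x \rightleftarrows y}(\omega) =
  \frac{\{\mathrm{Im}\, f_{x,y}(\omega)\}^2}{1 - \{\mathrm{Re}\, f_{x,y}(\omega)\}^2}.$$

The real part of coherency carries the instantaneous (zero-lag) dependence;
in EEG source space that component is dominated by volume conduction and by
inverse-solution leakage rather than physiology. Dividing the squared
imaginary part by $1-\mathrm{Re}^2$ partials the instantaneous component
out, so an invertible zero-lag mixing of independent signals does not create
spurious $\varphi^2$. The measure is symmetric and lies in $[0,1]$.

Estimator details (all exposed as arguments of `coherency()`):

* single-taper DFT over the full analysis window, no Hann taper by default
  (`hann = FALSE`); unit-modulus normalization is applied per coefficient
  *before* trial averaging, the most literal reading of a
  "normalized Fourier transform" estimator;
* the frequency grid is the native DFT grid of the window — about 5 Hz
  spacing for a 200 ms window at 256 Hz;
* per-trial demeaning on by default; a zero DFT coefficient (undefined
  phase) contributes zero rather than `NaN`.

## Effective connectivity: isolated effective coherence

The directed measure is computed on a multivariate autoregressive (MVAR)
model
$$x(t) = \sum_{k=1}^{p} A_k\, x(t-k) + \varepsilon(t), \qquad
  \mathrm{Cov}(\varepsilon) = S_\varepsilon,$$
fitted jointly across trials. In the frequency domain the coupling structure
is carried by
$$\bar A(\omega) = I - \sum_{k=1}^{p} A_k e^{-i 2\pi \omega k / f_s}.$$

To isolate the influence of ROI $j$ on ROI $i$, every cross-ROI lag
coefficient except the $j \to i$ entries is set to zero, all
self-connections (diagonal lag coefficients) are kept — the source's own
autoregressive dynamics enter through $\bar A_{jj}$ — and the innovation
covariance is reduced to its diagonal. On that isolated model the isolated
effective coherence is

$$\kappa_{i \leftarrow j}(\omega) =
  \frac{s_{ii}^{-1}\,\lvert \bar A_{ij}(\omega)\rvert^2}
       {s_{ii}^{-1}\,\lvert \bar A_{ij}(\omega)\rvert^2 +
        s_{jj}^{-1}\,\lvert \bar A_{jj}(\omega)\rvert^2} \in [0, 1],$$

a partial-directed-coherence-style quantity whose construction makes the
Granger-sense direction explicit: all other pathways are removed before the
ratio is formed. Because only the $(i,j)$ and $(j,j)$ entries of the
isolated $\bar A$ are nonzero off the remaining diagonal, the statistic has
the closed form implemented in `isolated_effective_coherence()`; the test
suite checks it against an independently coded naive implementation (full
isolated model, explicit loops) to $10^{-10}$.

Two conventions were genuinely open and are resolved as follows:

* **Noise variances.** $s_{ii}, s_{jj}$ are the *full* model's innovation
  variances carried into the isolated model, rather than variances refitted
  under the constraint; this matches the description of isolation as
  "setting connections to zero" and keeps the statistic a deterministic
  function of one fitted model.
* **One fit vs per-trial fits.** The default fits one MVAR per subject and
  condition across all trials ("joint"); `pipeline_config(icoh_fit =
  "per_trial")` instead fits each trial separately and averages the iCoh
  spectra. The joint fit is the default because the short 200 ms window
  leaves a single trial's 43 regression rows barely above the 32
  coefficients per equation of an order-8, 4-ROI model.

## MVAR fitting

`fit_mvar()` estimates the $A_k$ by ordinary least squares on the stacked
per-trial lagged design; regression rows never straddle trial boundaries,
so stimulus-locked epochs are treated as independent realizations of one
stationary process. The innovation covariance is the pooled-residual
covariance with a degrees-of-freedom correction. Numerical behaviour:

* a rank-deficient design (e.g. a duplicated ROI) raises an error naming
  the collinear ROI/lag columns;
* fewer than $10 \times (\text{ROIs} \times p)$ pooled rows warns but does
  not fail; an unstable *fitted* model warns (it may still be summarized),
  while requesting a simulation from an unstable model is a hard error;
* stability is assessed by the spectral radius of the
  $(\text{ROIs} \cdot p)$-dimensional companion matrix.

The default order is $p = 8$: with 1 Hz evaluation of the AR spectrum, a
high order gives the spectral resolution that a 200 ms window cannot
provide nonparametrically. Order is a configuration value, not a constant.

**Known bias.** Per-trial demeaning (default, and appropriate for band-passed
signals with residual offsets) introduces the classic $O(1/T)$
autoregressive shrinkage bias for short trials — about 0.03 in absolute
coefficient terms at $T = 51$ samples. It is immaterial for the
connectivity contrasts (both conditions are equally affected) but visible
in raw coefficient recovery; the consistency property in the test suite
therefore fits with `demean = FALSE`, and recovery at the study's trial
counts stays within $\pm 0.05$ either way.

## The synthetic-data generator

No raw data accompany the study design this package targets, so the
generator stands in for it with a model whose ground truth is exact:

* each ROI is a stochastically driven damped AR(2) oscillator with poles at
  modulus 0.95 and center frequency 40 Hz (inside the gamma band) at
  $f_s = 256$ Hz — keeping the generator *inside* the MVAR family means the
  generating coefficients are the truth that fitting must recover, with no
  approximation gap;
* directed coupling is injected as lag-1 cross coefficients
  (`coupling` tibble: source, target, strength, condition); the default
  scheme has weak (0.05) bidirectional homotopic PAC–PAC and SAC–SAC
  coupling in both conditions plus an LE-only rSAC → lSAC boost of 0.08 —
  the callosal-relay pattern;
* conditions are `LE` and `RE` (left-/right-ear report), 82 trials each,
  200 ms epochs beginning 500 ms post-stimulus (the generator produces the
  analysis window directly; longer epochs can be configured and windowed);
* optional instantaneous mixing emulates volume conduction;
* every output is a pure function of `(config, seed)`; trials are drawn
  independently with a burn-in of $40 p$ samples, safely past transients
  for pole moduli up to about 0.97.

Per-subject heterogeneity draws each edge strength from a normal with the
configured mean and `coupling_sd` (default 0.05); draws are rejected and
redrawn (deterministically) until both condition models are stable, i.e.
the subject-level distribution is truncated to the stable region.
Behavioral counts are one multinomial draw per subject over 240 trials with
RE/LE/error probabilities proportional to mean counts of
134.81/80.00/25.69 — a clear right-ear advantage.

**Calibration of the default effect.** The LE-only boost of 0.08 was chosen
so that the group pipeline detects the built-in condition × direction
interaction with power well above 0.8 at $n = 33$ subjects while remaining
a small coefficient relative to the oscillator dynamics; the boost, the
baseline strength and `coupling_sd` are all configuration values, not
claims about any real effect size.

**What the generator does not emulate:** lead fields and inverse-solution
leakage (mixing is a free matrix, not a head model), 1/f broadband
background, evoked (phase-locked) components, non-stationarity within the
window, and any genuine neural-behavioral coupling — behavioral counts and
coupling strengths are independent by design. Passing tests therefore
validate the estimators and the pipeline logic under known ground truth;
they do not certify performance on real source-localized EEG.

## The group pipeline

`run_study()` reproduces the full analysis:

1. subjects missing a condition are excluded (fewer than 3 remaining
   aborts); per subject, trial counts are balanced across conditions by
   seeded random subsampling to the smaller count;
2. the 500–700 ms window is taken half-open with sample index
   $\mathrm{round}((t - t_0) f_s)$;
3. per subject × condition: LPS for the homotopic SAC and PAC pairs from
   the unit-modulus coherency; iCoh from the fitted MVAR for all homotopic
   directed pairs and (by default) the crossed heterotopic pairs
   (e.g. rPAC → lSAC); everything averaged over 30–100 Hz, both band edges
   inclusive;
4. group statistics: paired Wilcoxon signed-rank (LE vs RE) per LPS pair;
   per homotopic pair a 2 × 2 repeated-measures ANOVA with Condition and
   Direction as within-subject factors; four post-hoc Wilcoxon contrasts
   (LE: R→L vs L→R; RE: R→L vs L→R; R→L: LE vs RE; L→R: LE vs RE) with
   Holm correction over exactly that family of four; the behavioral
   laterality index $LI = 100\,(RE-LE)/(RE+LE)$ with a paired RE-vs-LE
   Wilcoxon as the REA test.

Statistical conventions:

* the Wilcoxon uses the normal approximation with the standard tie
  correction, zero differences dropped; effect size $r = |Z|/\sqrt{n}$
  with $n$ the number of pairs entering the test; at least 5 pairs are
  required, smaller groups report `NA` rather than aborting;
* the ANOVA is fitted with `stats::aov` and an
  `Error(subject/(condition*direction))` stratum structure; with two levels
  per factor sphericity holds trivially (Greenhouse–Geisser $\varepsilon =
  1$, so the correction machinery is inert by design) and each $F$ equals
  the squared paired $t$ of the corresponding contrast — an identity the
  test suite verifies against an independent paired-$t$ computation;
  effect sizes are partial $\eta^2 = SS_{\text{eff}} / (SS_{\text{eff}} +
  SS_{\text{err}})$; a zero-variance error stratum is reported as an
  infinite-$F$ flag with a warning rather than a crash;
* Holm adjustment is `stats::p.adjust(method = "holm")`.

## Numerical choices

* Denominator floors of $10^{-12}$ guard both statistics; entries with
  $\mathrm{Re}^2 f \ge 1 - 10^{-10}$ (perfect instantaneous coherence) set
  $\varphi^2 = 0$ with a warning instead of exploding.
* iCoh is evaluated on a 1 Hz grid from 1 Hz to Nyquist by default; LPS on
  the window's native DFT grid. The two grids are intentionally different —
  the AR spectrum interpolates smoothly, the DFT does not.
* Band averaging is the arithmetic mean over grid frequencies $f$ with
  $30 \le f \le 100$, inclusive on both edges.
* Epoch files are Apache Arrow/Feather tables (one float64 column per ROI,
  `fs`, `t0` and ROI labels in the file metadata): a language-neutral
  container with bit-exact float64 round-trip, readable from Python/Julia
  via Arrow. Behavioral counts are TSV; manifests and group results are
  JSON; per-subject scalars are TSV.

## Known limitations

* **Residual LPS null inflation under strong mixing.** With 82 trials,
  mixing two independent signals with $[[1, 0.5], [0.5, 1]]$ raises mean
  band-averaged null LPS slightly (about $+0.0007$ on a null mean of
  $0.006$): the large real coherency deflates the $1-\mathrm{Re}^2$
  denominator and inflates the *sampling noise* of the numerator. The
  elevation vanishes as trial count grows and is far inside the
  Monte-Carlo null band (null sd $\approx 0.002$), but a strict
  "identical to null" reading does not hold at finite trial counts.
* **Sensitivity asymmetry.** A lag-1 coupling boost moves iCoh much more
  than LPS, so at the default calibrated effect the directed contrasts are
  reliably significant while the undirected LPS contrast is directionally
  consistent but lower-powered.
* **Demeaning bias** as described above.
* The pipeline starts from ROI time series: acquisition, preprocessing and
  source localization are out of scope, as are order selection criteria,
  time-varying MVAR models and other connectivity measures.

## Problem sizes used by the test suite

The suite validates properties at the study's own scale where that matters
(82 trials × 51 samples, $n = 33$ subjects) and at reduced scale where only
the logic is at stake: the 200-replicate direction-recovery, mixing and
power checks and the 500-replicate type-I calibration run at full study
scale (the type-I and power runs use a two-ROI SAC-only configuration,
since only the SAC pair enters the interaction test being calibrated);
plumbing tests use small toy studies. The type-I calibration exploits the
fact that under the null with no between-subject variability all
subject × condition datasets are i.i.d., drawing them in one batched
simulation before splitting — distributionally exact and much faster than
per-subject simulation.
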