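# dichotr

Directed gamma-band connectivity analysis between auditory cortices for
dichotic-listening EEG studies, starting from source-level region-of-interest
(ROI) time series.

During dichotic listening, most listeners preferentially report the
right-ear syllable (the right-ear advantage). The callosal relay account
predicts that perceiving the *left*-ear syllable requires directed
right-to-left information flow between the secondary auditory cortices.
`dichotr` provides the two connectivity statistics used to test this, for
researchers analysing epoched, stimulus-locked ROI signals:

* **Lagged phase synchronization (LPS)** — undirected functional
  connectivity from the complex coherency `f` of unit-modulus-normalized
  Fourier coefficients,

  ```
  φ²(ω) = Im[f(ω)]² / (1 − Re[f(ω)]²),
  ```

  which partials out the instantaneous (zero-lag) component that volume
  conduction produces in EEG source space.

* **Isolated effective coherence (iCoh)** — directed (Granger-sense)
  connectivity from a multivariate autoregressive (MVAR) model
  `x(t) = Σₖ Aₖ x(t−k) + ε(t)`. With `Ā(ω) = I − Σₖ Aₖ e^(−i2πωk/fs)` and
  all pathways other than j→i (and all self-connections) set to zero,

  ```
  κ_{i←j}(ω) = s_ii⁻¹ |Ā_ij(ω)|² / ( s_ii⁻¹ |Ā_ij(ω)|² + s_jj⁻¹ |Ā_jj(ω)|² ) ∈ [0, 1].
  ```

Around these, the package supplies multi-trial MVAR least-squares fitting
with stability diagnostics, a synthetic-data generator with exactly known
directed coupling (coupled damped AR(2) gamma oscillators inside the MVAR
family), and the full group pipeline: 500–700 ms windowing, 30–100 Hz band
averaging, behavioral laterality index `LI = 100 (RE − LE)/(RE + LE)`,
paired Wilcoxon signed-rank tests, 2 × 2 repeated-measures
Condition × Direction ANOVAs with partial η², and Holm-corrected post-hoc
contrasts. All results are tibbles; fitted objects have `tidy()`,
`glance()` and `autoplot()` methods.

## Worked example

A unidirectional unit-strength coupling with unit noise and no self-lags
has the closed-form iCoh κ = 1/(1+1) = 0.5 toward the target and 0 in the
reverse direction:

```r
library(dichotr)
m  <- mvar_model(list(matrix(c(0, 1, 0, 0), 2, 2)), diag(2), fs = 256,
                 roi_labels = c("rSAC", "lSAC"))
band_average(isolated_effective_coherence(m), 30, 100)
#> # A tibble: 2 × 3
#>   source target value
#>   <chr>  <chr>  <dbl>
#> 1 rSAC   lSAC     0.5
#> 2 lSAC   rSAC     0
```

A full synthetic study — 33 subjects, two conditions (left-/right-ear
report), 82 trials each, with the generator's built-in LE-only
rSAC → lSAC coupling boost — analysed end to end:

```r
study  <- simulate_study(n_subjects = 33, seed = 42)
result <- run_study(study, pipeline_config(), seed = 42)
result
#> <study_result> 33 subjects, conditions LE/RE
#>   LI: mean 25.79 (sd 6.26), REA test z = 5.01, p = 5.37e-07
#>   PAC Condition x Direction: F(1,32) = 1.469, p = 0.234, eta2p = 0.04
#>   SAC Condition x Direction: F(1,32) = 76.715, p = 5.23e-10, eta2p = 0.71

result$posthoc[result$posthoc$pair == "SAC", c("contrast", "z", "p", "p_holm", "r")]
#> # A tibble: 4 × 5
#>   contrast              z           p     p_holm     r
#>   <chr>             <dbl>       <dbl>      <dbl> <dbl>
#> 1 LE: R->L vs L->R  3.85  0.000118    0.000354   0.670
#> 2 RE: R->L vs L->R -1.05  0.296       0.592      0.182
#> 3 R->L: LE vs RE    4.90  0.000000936 0.00000374 0.854
#> 4 L->R: LE vs RE   -0.992 0.321       0.592      0.173
```

Reading the output: the positive mean laterality index (25.79) is the
behavioral right-ear advantage; the SAC Condition × Direction interaction
(F(1,32) = 76.7) says the direction imbalance of SAC–SAC coupling depends
on which ear is reported; the post-hocs localize it — during left-ear
reports the right→left SAC flow exceeds left→right (z = 3.85), and
right→left flow is stronger during left-ear than right-ear reports
(z = 4.90), while the two control contrasts stay non-significant. That is
exactly the callosal-relay pattern the generator builds in, recovered by
the pipeline. `tidy(result)` returns every test as one long tibble;
`glance(result)` a one-row summary; `autoplot(result)` the per-subject
distributions.

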