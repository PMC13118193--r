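# dkiupgrade

Quantitative diffusion-weighted MRI analysis of prostate cancer **Grade Group
upgrading** — the situation where the ISUP Grade Group found at radical
prostatectomy exceeds the one assigned from TRUS biopsy cores. Because biopsy
undergrading can push men with clinically significant cancer toward active
surveillance, non-invasive markers of upgrading risk are of direct clinical
interest. This package provides, for radiologists and imaging scientists, the
full quantitative chain from multi-b-value DWI signal to cohort-level
biomarker evaluation:

1. **Signal models.** The monoexponential model
   `S(b) = S0 · exp(−b·ADC)` and the diffusion-kurtosis representation
   `S(b) = S0 · exp(−b·Dapp + b²·Dapp²·K/6)`,
   with b in s/mm² and diffusivities on the conventional 10⁻³ mm²/s scale.
   Kurtosis K captures non-Gaussian diffusion at high b (b ≥ ~1000 s/mm²),
   where dense, heterogeneous tumour tissue deviates from monoexponential
   decay.
2. **Voxelwise fitting and maps.** `adc_fit()` (log-linear LS, b ≤ 1200
   s/mm²) and `dki_fit()` (exact closed-form log-quadratic LS over all b:
   `Dapp = −c1`, `K = 6·c2/c1²`, with optional bounded nonlinear refinement),
   assembled into ADC/Dapp/K/S0 maps with validity masks by `fit_maps()`, and
   ROI-mean extraction with ROI propagation across maps.
3. **Simulation.** Multi-b DWI phantoms with known ground truth and Rician
   noise (`generate_phantom()`), and lesion-level cohorts with prescribed
   per-stratum group moments (`generate_cohort()`); the packaged defaults are
   the six-b prostate protocol (0, 100, 500, 800, 1200, 2000 s/mm², five
   averages) and the reference cohort's group moments.
4. **Cohort statistics.** Upgrade-vs-no-upgrade comparisons per biopsy-GG
   stratum (Shapiro–Wilk gated Welch t / Mann–Whitney U, pooled-SD Cohen's d,
   Holm adjustment within each five-variable family) and single-predictor
   diagnostic performance by logistic regression with 5×5-fold
   cross-validation, empirical ROC/AUC, DeLong 95% CIs and Youden-index
   operating points.

## Worked example

```r
library(dkiupgrade)

# fit the kurtosis model to a noiseless tumour-like decay curve
b <- c(0, 100, 500, 800, 1200, 2000)
dki_fit(dki_signal(b, S0 = 1000, Dapp = 0.914, K = 1.311), b)
#> Diffusion-kurtosis model fit (log-quadratic LS )
#>   S0 = 1000, Dapp = 0.914 x 1e-3 mm2/s, K = 1.311
#>   6 points used, 0 dropped (non-positive signal)

# simulate a 142-lesion cohort at the packaged group moments and analyse it
coh <- generate_cohort(seed = 20)
summarize_upgrades(coh)
#>  stratum   n n_upgraded pct_upgraded
#>      GG1  27         20        74.07
#>      GG2  67         36        53.73
#>      GG3  35          8        22.86
#>      GG4  13          4        30.77
#>  overall 142         68        47.89

compare_groups(coh, stratum = 2, variable = "ADC")
#>   variable stratum n_no_upgrade mean_no_upgrade ... test        p cohens_d
#> 1      ADC       2           31           0.864 ...    t 5.39e-05    -1.04

cv_logistic_roc(coh, stratum = 2, predictor = "ADC", seed = 20)
#> ROC analysis of ADC (GG2 stratum, lower-positive), 36 upgrade / 31 no-upgrade
#>   cross-validated AUC (5 x 5-fold): 0.768  [95% CI 0.650 - 0.884]
#>   full-sample AUC: 0.776
#>   Youden threshold 0.774: sensitivity 0.694, specificity 0.871
```

The fitted Grade Group 2 cohort shows the expected biology: upgraded lesions
have lower ADC (0.732 vs 0.864 ×10⁻³ mm²/s, Welch p ≈ 5×10⁻⁵, d ≈ −1.0) and
the ADC threshold ≈0.77×10⁻³ mm²/s separates them with AUC ≈ 0.77 — values
that fluctuate with the cohort seed around the population AUC of ≈0.81
implied by the group moments.

An end-to-end run (phantom → maps → ROI table, cohort → comparison and ROC
tables → upgrade summary) is available through `run_pipeline()` or the thin
CLI at `inst/cli/dki-pipeline.R`, driven by a YAML config and a master seed;
all outputs are listed in a `manifest.json` with MD5 hashes and are
byte-identical under a fixed seed.

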