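# osaconnect

Band-specific EEG brain-connectivity contrast between obstructive sleep
apnea (OSA) and healthy sleepers.

Obstructive sleep apnea leaves a signature in the spatial organisation of
sleep EEG: slow-wave (delta) activity is more strongly coupled across
scalp regions in OSA than in healthy sleep. `osaconnect` is an R package
for sleep researchers and biosignal engineers that turns that observation
into a reproducible pipeline over 4-channel polysomnography EEG
(F4-A1, F3-A2, O1-A2, O2-A1 at 200 Hz):

1. **Preprocessing** — 50 Hz IIR notch (Q = 30) and 0.5-35 Hz
   4th-order Butterworth band-pass, both zero-phase.
2. **Wavelet packet decomposition** — orthonormal db4 filter bank, level
   5 (32 leaves of 3.125 Hz), Gray-code frequency ordering, leaves
   assigned to the clinical bands δ (0.5-4), θ (4-8), α (8-13),
   β (13-30), γ (30-35 Hz) by centre-frequency containment.
3. **Connectivity** — per band and 30 s epoch, the channel-by-channel
   Pearson matrix of absolute wavelet coefficients
   `r_ij = corr(|w_i|, |w_j|)`, averaged over epochs; positive-edge
   graphs (`r_ij > 0`), node degrees, group min/max positive
   correlation, BrainNet Viewer `.node`/`.edge` export.
4. **Statistics** — per-band Mann-Whitney-Wilcoxon U test between
   groups (exact null distribution for small tie-free samples, tie- and
   continuity-corrected normal approximation otherwise), per-node Welch
   t-maps of degree, and Pearson correlation of t-maps with network
   maps.
5. **Synthetic cohorts** — two-group 4-channel generators whose
   inter-channel coupling is prescribed per band (Cholesky mixing of
   band-limited noise over a pink 1/f floor), so the whole pipeline is
   testable without clinical data. The `osa_contrast` preset gives the
   OSA-like group strong delta coupling (0.75-0.90) against a weaker
   healthy-like group (0.45-0.65).

Everything is tidyverse-native: readers and the generator return light
recording objects, every analysis result is a tibble, fitted objects
have `tidy()`/`glance()` methods, and result types have `autoplot()`
methods.

## Worked example

A full synthetic study — generate a 10 + 10 cohort (120 s per subject),
run the pipeline, and test the per-band group contrast on each
subject's mean positive correlation:

```r
library(osaconnect)

spec   <- cohort_spec(n_osa = 10, n_healthy = 10, duration_s = 120, seed = 42)
config <- run_config(input = "synth", synth_spec = spec, summary = "mean_pos_r")
report <- run_pipeline(config)
report
#> <osa_report> 20 subjects (HEALTHY: 10, OSA: 10)
#>
#> Group positive-correlation extremes:
#>   band   group   min_pos_r max_pos_r n_subjects empty
#>  delta     OSA 0.260831188 0.5039801         10 FALSE
#>  delta HEALTHY 0.019536169 0.2726921         10 FALSE
#>  theta     OSA 0.140259078 0.2686416         10 FALSE
#>  theta HEALTHY 0.042048148 0.2080206         10 FALSE
#>  alpha     OSA 0.031020397 0.1777481         10 FALSE
#>  alpha HEALTHY 0.004589321 0.1972965         10 FALSE
#>   beta     OSA 0.084024114 0.1689817         10 FALSE
#>   beta HEALTHY 0.074958759 0.1793617         10 FALSE
#>
#> Per-band Mann-Whitney-Wilcoxon:
#>   band statistic_U statistic_z      p_value n1 n2 method significant
#>  alpha          47  -0.2267787 8.534283e-01 10 10  exact       FALSE
#>   beta          52   0.1511858 9.117972e-01 10 10  exact       FALSE
#>  delta           0  -3.7796447 1.082509e-05 10 10  exact        TRUE
#>  theta           0  -3.7796447 1.082509e-05 10 10  exact        TRUE
```

Reading the output: the OSA-like group's delta-band positive
correlations (0.26-0.50 across subjects) sit clearly above the
healthy-like group's (0.02-0.27) — note these are correlations of
*absolute wavelet coefficients*, a strongly attenuated but monotone
proxy of the generated band-signal coupling — and the delta contrast is
overwhelming (`U = 0`: complete group separation, exact
`p = 1.1e-05`), while alpha, whose coupling does not differ between
groups, stays null. Theta inherits part of the delta contrast through
spectral leakage of the 8-tap db4 filters (quantified in the methods
vignette). `glance(report)` condenses this to one row;
`autoplot(report)` draws the group-mean connectivity heatmaps, and
`tidy(report$group_mean_connectivity$OSA$delta)` gives the edge list:

```r
tidy(report$group_mean_connectivity$OSA$delta)
#> # A tibble: 6 × 4
#>   band  from  to        r
#>   <chr> <chr> <chr> <dbl>
#> 1 delta F4-A1 F3-A2 0.353
#> 2 delta F4-A1 O1-A2 0.382
#> 3 delta F3-A2 O1-A2 0.377
#> 4 delta F4-A1 O2-A1 0.382
#> 5 delta F3-A2 O2-A1 0.358
#> 6 delta O1-A2 O2-A1 0.383
```

Real recordings enter through `read_edf()` (channel selection, mixed-rate
rejection) or the columnar text format (`read_columnar()`), with group
membership supplied as configuration (`run_config(input = "edf",
path = ..., channels = ..., group_map = ...)`). A thin CLI wrapper with
`run` and `synth` subcommands ships in `inst/cli/osaconnect`.

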