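---
title: "Methods: band-specific EEG connectivity contrast of OSA and healthy sleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band-specific EEG connectivity contrast of OSA and healthy sleep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osaconnect)
```

## The analysis in one paragraph

Obstructive sleep apnea (OSA) reshapes the spatial organisation of sleep
EEG: slow-wave (delta) activity becomes more strongly coupled across
scalp regions than in healthy sleepers. `osaconnect` operationalises
that contrast as a pipeline over 4-channel polysomnography EEG
(F4-A1, F3-A2, O1-A2, O2-A1 at 200 Hz): power-line notch and 0.5-35 Hz
band-pass filtering, level-5 Daubechies-4 wavelet-packet decomposition
(WPD) into the five clinical bands (delta, theta, alpha, beta, gamma),
per-band channel-by-channel Pearson correlation of the *absolute*
wavelet coefficients, positive-edge graphs with node degrees, and a
per-band Mann-Whitney-Wilcoxon contrast between groups. A synthetic
cohort generator with prescribed band-specific coupling makes every
stage verifiable without clinical recordings.

## Preprocessing

Two cascaded filters are applied channel-wise before decomposition:

* a second-order IIR notch at 50 Hz (RBJ biquad). The quality factor is
  not dictated by the analysis; we fix Q = 30, i.e. a -3 dB width of
  ~1.7 Hz, which removes mains interference without touching the 35 Hz
  band edge.
* a 4th-order Butterworth band-pass, 0.5-35 Hz, which bounds the
  analysis to the sleep-EEG range and removes DC.

Both are applied forward-backward (zero phase) so band features are not
time-shifted relative to each other; the effective magnitude response is
the squared single-pass response, which is what `filter_response()`
reports and what the tests compare measured RMS gains against. Edge
transients are handled by odd-reflective padding of three filter lengths
at each end; measurement-style checks additionally discard a 2 s margin.
The filter designs themselves (biquad + Butterworth, these orders) are
our choice: the analysis only requires "a 50 Hz notch" and "0.5-35 Hz
band-pass", and any standard design meeting the attenuation contracts
in the test suite is equivalent for what follows.

## Wavelet packet decomposition

Each channel (or 30 s epoch of it) is decomposed with an orthonormal
db4 filter bank in which *both* branches are split at every level, to
depth 5, giving `2^5 = 32` leaves of width `fs/64 = 3.125` Hz at
200 Hz. We implement the periodized transform: it is exactly orthogonal
(Parseval holds to ~1e-12 in the tests), coefficient counts match the
signal length, and the inverse reproduces the input to ~1e-12 relative
error. Signals whose length is not a multiple of 32 are extended by
repeating the last sample and truncated after inversion. Symmetric or
zero-padded variants would only change boundary coefficients while
losing exact orthogonality, so they are not offered.

Leaves indexed by filter path are **not** in spectral order: every
high-pass-plus-decimate stage mirrors the spectrum, and the ascending
frequency order is the binary Gray code (`frequency_order()`). This is
validated in the tests by a brute-force oracle: for each of the 32 leaf
centre frequencies, a pure sine must put its maximal leaf energy in the
mapped leaf — which it does, at every leaf and every level 1-5.

Band edges follow conventional clinical definitions — delta 0.5-4,
theta 4-8, alpha 8-13, beta 13-30, gamma 30-35 Hz (gamma capped at the
band-pass edge) — and a leaf belongs to the band containing its centre
frequency (half-open containment). At 200 Hz / level 5 that yields
delta = {0}, theta = {1, 2}, alpha = {3}, beta = {4..9}, gamma = {10}.
Alpha and gamma being single leaves is a direct consequence of the
stated level and is documented rather than "fixed".

**Spectral leakage is real and quantified.** db4's 8-tap filters have
transition bands wider than a 3.125 Hz leaf, and the high-pass cascade
aliases energy into non-adjacent leaves. A sine at a leaf's centre
frequency concentrates between ~55% and ~100% of its coefficient energy
in that leaf (worst mid-band; best at the spectrum edges); at band
level, a sine at the band centre puts ~99% of its energy into theta or
beta (multi-leaf bands) but only ~71% into alpha and ~66% into gamma.
The *argmax* assignment is nevertheless always correct, which is the
property the band mapping relies on. Consequences for the analysis:
band features are contaminated by neighbouring-band activity at the
tens-of-percent level, which inflates cross-band similarity of derived
quantities but affects both groups identically.

The per-band, per-channel feature is the concatenation of absolute
coefficient values over the band's leaves in frequency order; the
band-limited time series (inverse transform with out-of-band leaves
zeroed) is also available and is what parameter-recovery checks use.

## Connectivity

For each band, each epoch contributes a 4x4 matrix of Pearson
correlations between channels' absolute-coefficient vectors; subject
matrices are the plain mean over epochs (Fisher-z averaging is available
but off by default — with 4-10 epochs and |r| mostly < 0.95 the
difference is far below sampling noise). Correlating absolute values
rather than signed signals measures co-modulation of band amplitude; for
jointly Gaussian band signals with correlation rho, the correlation of
absolute values is a known strictly increasing function of rho that is
substantially attenuated (e.g. ~0.41 at rho = 0.67). The pipeline
therefore treats the abs-coefficient correlation as a monotone proxy for
the underlying coupling, and states exact-recovery claims on band-signal
correlation only.

Graphs retain strictly positive correlations (threshold 0 by default,
configurable), never self-loops; node degree is the count of incident
retained edges, and the handshake identity is asserted on every exported
graph. Group summaries report the minimum and maximum positive
off-diagonal correlation across all subjects of a group per band.
BrainNet Viewer `.node`/`.edge` text files are written with degree in
the size column; default electrode coordinates are approximate MNI
positions of the 10-20 sites F3/F4/O1/O2 and are purely presentational.

## Statistics

Band-level group differences use the Mann-Whitney-Wilcoxon test built
from the U statistic on midranks. For tie-free samples with
`n1*n2 <= 400` the two-sided p is exact, computed from the full null
distribution via the standard counting recursion (verified against
exhaustive enumeration for all `n1, n2 <= 6`); otherwise the normal
approximation with tie-corrected variance and continuity correction is
used (simulated type-I error at nominal 0.05: ~0.052 with 50 + 50).
Degree maps are compared per node with Welch's t (the one place a
t statistic is appropriate here, degrees being approximately interval
scaled within groups), and t-maps are correlated with a reference
network map — by default the OSA group's mean degree map — using the
same Pearson routine. No multiple-testing correction is applied by
default, matching common practice in small-montage sleep studies; a
Benjamini-Hochberg switch exists and its absence is flagged in the
report's documentation rather than hidden.

The tested per-subject summary is configurable: `mean_abs_coeff` (mean
absolute wavelet coefficient per band) or `mean_pos_r` (mean positive
inter-channel correlation per band). They answer different questions —
amplitude vs coupling. Under a contrast that changes only coupling (as
the synthetic preset does), `mean_abs_coeff` has *no* power by
construction, so coupling-oriented checks use `mean_pos_r`.

## Synthetic cohorts

`cohort_spec()` describes a two-group cohort; the defaults are the
study conditions the pipeline is exercised under: 40 OSA-like and 10
healthy-like subjects, 200 Hz, 300 s each, four ISRUC-style channels.
Per band, four independent band-limited unit-variance noises (white
noise with out-of-band Fourier coefficients zeroed) are mixed by the
Cholesky factor of an equicorrelation target matrix; each subject's
coupling is drawn uniformly from the group's range. The
`osa_contrast` preset encodes the delta contrast — OSA-like coupling
in [0.75, 0.90], healthy-like in [0.45, 0.65], all other bands
identical across groups — so delta should separate and alpha should
not. Band relative powers (delta .40, theta .20, alpha .15, beta .15,
gamma .10 of the structured variance) follow the usual slow-wave-sleep
dominance of delta; an independent pink noise floor (PSD proportional
to 1/f above 0.5 Hz) carries 20% of each channel's variance so the
filters and decomposition have realistic broadband input to reject.
Per-subject RNG streams are derived by stable integer hashing of
(seed, group, index): cohorts are bit-reproducible and extensible
without regenerating earlier subjects.

What the generator does *not* emulate: sleep-stage dynamics, apnea
event waveforms, artifacts, non-stationarity, volume-conduction
structure. Passing tests therefore demonstrate the pipeline's
correctness and sensitivity under its stated noise model, not clinical
performance on real polysomnography.

Two calibration facts matter when interpreting recovery checks. First,
the pink floor is independent across channels, so its in-band share
attenuates estimated correlations multiplicatively; exact-recovery
checks therefore run with a zero floor and delta-only content (matching
the generator's own contract), where the WPD extraction is a fixed
linear operator applied identically per channel and preserves the mixed
correlation exactly. Measured recovery at couplings {0.2, 0.5, 0.8}
over 300 s is within ±0.05. Second, the abs-coefficient estimate is
attenuated (see above) but strictly monotone in the true coupling,
which is what group contrasts need.

## Problem sizes used in the checks

Verification runs are sized for a laptop-class single core: perfect
reconstruction on 100 signals of 32-4096 samples; swept-sine ordering
at all 32 leaves (32 s of signal each); group-contrast replication with
50 cohorts of 10 + 10 subjects at 60 s per subject (two 30 s epochs,
delta and alpha bands); exact-test enumeration to `n1 = n2 = 6`; 2000
null replicates for type-I calibration. The full suite runs in a few
minutes; the cohort analysis itself takes seconds for 20 subjects at
120 s.

## Numerical choices and degenerate inputs

* Constant vectors make Pearson r undefined: `pearson()` errors rather
  than returning 0/NA; epochs with a constant channel feature are
  excluded with a warning, and an all-excluded band errors.
* Welch t with zero standard error is reported as missing, never
  infinite; t-map correlation requires >= 3 defined nodes.
* EDF signals are quantized to the 16-bit digital range of a physical
  range rounded *up* to two significant digits, so header ASCII and
  scaling agree exactly and no sample can wrap; round-trip error is
  bounded by one digital step.
* Correlation matrices are clamped to [-1, 1]; Cholesky mixing adds a
  1e-12 ridge to tolerate exactly singular PSD targets.
* Ties in group labels/bands: report tables are sorted
  deterministically, and the whole pipeline is byte-reproducible given
  a config (no timestamps in the report).

## Known limitations

* Four channels give 4x4 matrices and at most 6 distinct edges: graph
  metrics beyond degree are meaningless at this montage and are not
  offered.
* Alpha (one leaf, ~71% isolation) and gamma (one leaf, band truncated
  by the 35 Hz band-pass) are the weakest bands of the level-5 db4
  decomposition; conclusions about them lean on the argmax property,
  not on clean isolation.
* The Mann-Whitney exact path requires tie-free data; heavily
  discretized features fall back to the (tie-corrected) approximation
  even for small samples.
* Group assignment for file-based cohorts is user configuration; the
  package does not infer diagnosis from data.
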