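---
title: "Methods: basal ganglia beta oscillations and REM-sleep atonia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: basal ganglia beta oscillations and REM-sleep atonia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

In REM sleep behaviour disorder (RBD), the muscle atonia that normally
accompanies REM sleep fails intermittently, and patients enact their dreams.
In Parkinson's disease (PD), exaggerated beta-band (13--30 Hz) oscillations
in the basal ganglia are a hallmark of the dopamine-depleted motor circuit.
`rembeta` implements an analysis pipeline that connects the two: it scores
REM sleep without atonia (RSWA) from the chin EMG of polysomnography (PSG)
recordings, extracts beta-band features from basal ganglia local field
potentials (LFPs) recorded through DBS electrodes, and quantifies the
coupling between the LFP beta power envelope and the EMG power envelope --
its strength, its significance against block-shuffled surrogates, the lag at
which it peaks, and its Granger-causal direction.

Because raw patient recordings of this kind are not publicly available, the
package ships a synthetic PSG generator with fully known ground truth.  The
generator is first-class, tested code: every downstream stage of the
pipeline is validated by recovering parameters the generator planted.

## Pipeline stages

1. **Hypnogram preparation** (`prepare_hypnogram()`): 30-s epochs carry one
   stage label from {W, N1, N2, N3, R}.  With two scorers, only epochs with
   consistent labels remain eligible.  *Isolated* epochs -- a label differing
   from both neighbours, e.g. a single N2 between two REM epochs -- are
   dropped as unstable; a boundary epoch is dropped when it differs from its
   single neighbour.  Each eligible REM epoch is then matched to a distinct
   eligible NREM epoch so that the total epoch-index distance is minimal.
   The assignment is computed exactly by a non-crossing dynamic programme
   (for absolute-difference costs on a line an optimal monotone assignment
   always exists); ties resolve to the earlier NREM epoch.  NREM substages
   are pooled, with a `substage` switch for sensitivity analyses.

2. **RSWA detection** (`rswa_analysis()`): the chin EMG is bandpassed
   80--160 Hz (zero-phase Butterworth), its power envelope taken as the
   squared analytic-signal magnitude (a rectify-and-smooth alternative sits
   behind `method = "rectified"`), and the area under the envelope
   integrated per 3-s segment (ten segments tile each 30-s epoch).  The
   individualized threshold is twice the 5th percentile of the subject's
   NREM segment values, with the linear-interpolation percentile convention
   (R type 7) fixed so tests can assert exact values; at least 20 NREM
   segments are required.  A REM segment strictly above threshold is loss of
   atonia; ties count as atonia, a conservative choice with measure zero on
   real signals.  RSWA% is the fraction of REM segments above threshold.
   EMG variance over the same band is available as an alternative statistic.

3. **Spectral features** (`welch_psd()`, `band_power()`,
   `select_channel()`, `band_coherence()`, `beta_bursts()`): Welch spectra
   use a 1024-sample Hann window with 50% overlap, restricted to 2--60 Hz
   and normalized to percent of sum power (the normalization is exact to
   1e-9 by construction).  Band power is the *mean* of normalized bins in
   the closed band, which makes it invariant to frequency resolution and
   hence comparable between 1000 and 2000 Hz recordings.  Of the three
   bipolar LFP channels per hemisphere, the one with the highest wake beta
   power is selected, ties to the lowest index.  LFP--EEG magnitude-squared
   coherence uses the same Welch parameters against the ipsilateral central
   channel.  Beta bursts are supra-threshold excursions of the smoothed
   (200 ms) beta amplitude envelope, thresholded at the 75th percentile of
   the state-pooled envelope with a 100-ms minimum duration -- the fixed,
   config-overridable convention of the basal-ganglia burst literature.  A
   near-constant envelope makes a percentile threshold meaningless; the
   detector flags this degenerate case instead of reporting a record-long
   burst.

4. **Connectivity** (`beta_emg_coupling()`): signals are decimated to
   200 Hz (zero-phase spectral lowpass with a raised-cosine rolloff from 95
   to 100 Hz so the 60--90 Hz EMG band survives), and instantaneous power is
   extracted with 10-cycle Morlet wavelets at 1-Hz steps, averaged over
   13--30 Hz (LFP) and 60--90 Hz (EMG).  Each REM epoch's envelopes are
   whitened with an AR(2) model fitted by least squares -- wavelet power
   envelopes are heavily autocorrelated, and rank correlations between
   unwhitened envelopes would be wildly anticonservative.  Spearman
   correlations are averaged over epochs, then hemispheres, giving one
   subject-level coefficient.  Significance comes from 200 surrogates that
   permute the order of contiguous 1-s blocks of the whitened EMG envelope
   within each epoch, preserving its autocorrelation while destroying
   cross-coupling; the two-tailed p uses the +1 correction, so the smallest
   attainable p is 1/201.  The lagged cross-correlation is evaluated at
   every 5-ms envelope sample in ±1000 ms, with negative lags meaning the
   LFP beta envelope leads the EMG; time-domain Granger causality is
   computed on the whitened envelopes decimated to 20 Hz with model order 4,
   so the 200-ms horizon is an integral number of lags, as
   log(restricted/full residual variance) in each direction.

5. **Group statistics** (`paired_test()`, `unpaired_test()`,
   `group_kruskal()`, `clinical_correlation()`): nonparametric throughout.
   The signed-rank test drops zero differences and uses an exact null for up
   to 25 effective pairs, computed by convolving the rank generating
   function (doubling tied mid-ranks onto an integer lattice), so exactness
   survives ties; larger samples fall back to the corrected normal
   approximation.  The Mann-Whitney test uses the exact null when feasible.
   No multiple-testing correction is applied in primary reporting;
   `adjust_results_bh()` offers Benjamini-Hochberg for sensitivity analyses.

## The synthetic generator

`generate_recording()` builds, per subject: bipolar LFP channels as
unit-variance 1/f^1.2 background plus transient beta bursts -- Hann-windowed
20-Hz sinusoids with gamma-distributed inter-burst intervals and durations
(mean 200 ms, in the range typically reported for subthalamic beta bursts);
a chin EMG as 60--160 Hz bandlimited noise under a stage-dependent amplitude
envelope; and central EEG channels as plain 1/f noise for coherence
plumbing.  Loss-of-atonia episodes arrive as a Poisson process (1.6/min of
REM by default) with exponential durations of mean 10 s, clipped to their
REM run.

The coupled (parkinsonian) regime ties the two modalities together in three
ways, all scaled by a single `coupling_strength` in [0, 1]:

* the EMG envelope during an episode gains a *phasic* component that follows
  the selected channel's beta burst envelope, lightly smoothed (50 ms) and
  delayed by `coupling_delay_ms` (default 200 ms -- beta leads);
* a *tonic* component (30% of the excess) sustains the elevated tone across
  the episode, which is what makes the 3-s threshold detector recover the
  episode boundaries reliably;
* beta bursting itself is elevated inside the (delay-shifted) episodes, so
  coupled subjects genuinely show more beta during atonia loss -- the
  within-subject contrast the spectral stage is designed to detect.  The
  strongest channel's burst train is shared between hemispheres, emulating
  the bilateral beta synchrony of the parkinsonian basal ganglia and letting
  a midline muscle couple coherently to both recorded sides.

At `coupling_strength = 0` (the dystonia-like regime) the EMG excess is
driven entirely by independent slow noise and bursting is homogeneous, so
the EMG is statistically independent of the LFP by construction -- the
regime used to verify the surrogate test's type-I error.

NREM/wake chin tone sits at four times the REM atonia level with slow
lognormal variability (log-sd 0.6, 5-s correlation time); real NREM chin
EMG fluctuates strongly, and this variability is what separates the 5th
percentile from the median and makes the doubled-percentile threshold
discriminative.  Cohort profiles draw subject-level parameters: PD profiles
draw coupling 0.45--0.9 and 1.2--2.2 episodes/min; the dystonia profile has
zero coupling and 0.25--0.65 episodes/min.  Clinical scores are generated as
noisy monotone functions of coupling strength (RBDSQ ≈ 2 + 10·coupling +
noise, clipped to 0--13), so score-connectivity correlations are recoverable
by design.

**What the generator does not emulate**: sleep micro-architecture (spindles,
slow waves, arousals), apnoea, movement or electrode artefacts, non-white
EMG carriers, volume conduction between channels, drug or stimulation
effects, and night-to-night variability.  Passing tests therefore show that
the pipeline's inference machinery is correct and calibrated on signals with
the asserted envelope structure -- not that real recordings satisfy that
structure.

## Numerical choices and conventions

* All intervals are half-open `[start, end)` in seconds; epoch indices are
  0-based; 3-s segments tile epochs exactly.
* Lag sign: `rho(L) = cor(beta[t], emg[t - L])`, so a negative peak lag
  means beta leads the EMG.
* The surrogate engine trims each epoch to a whole number of 1-s blocks
  (discarding under one second per 30-s epoch).  With equal blocks, a
  permutation leaves block positions aligned and the shuffled correlation
  reduces to a permuted trace of the block-level cross-product matrix,
  making hundreds of surrogates cheap; the empirical coefficient entering
  the test is computed on the same trimmed samples for exchangeability.
* The lag profile ranks each epoch once and computes Pearson correlations
  of the rank vectors over each lag's overlap with exact per-overlap
  moments; for 30-s epochs the difference from re-ranking every overlap is
  negligible, and constructed shifts are still recovered exactly.  The
  per-lag 97.5th-percentile surrogate band is estimated from the same
  block-shuffle engine with 20 rank-based surrogate profiles per epoch,
  pooled over epochs and subjects -- a band for plotting, not the primary
  test, which always uses 200 scalar surrogates.
* AR(2) whitening refuses near-constant input; Granger fits raise an error
  naming the singular design instead of returning spurious zeros.
* EDF output quantizes each channel to 16 bits over its own symmetric
  physical range; the round-trip error is below one quantization step.

## Problem sizes in the tests

The shipped study conditions are desk-scale by design: default recordings
are 56 epochs (28 min, 20 REM) -- a condensed night preserving the
NREM/REM alternation -- and the statistical checks use 400 independent
subjects for surrogate-test calibration, 20-subject cohorts for lag and
direction recovery, and 20-seed simulation sets for ordering and
sign-test properties.  These sizes keep the full suite within tens of
minutes on one CPU while leaving the binomial confidence intervals of the
calibration checks meaningful.

## Known limitations

* The measured peak lag is unbiased when burst durations are near or below
  the transmission delay; for bursts much longer than ~300 ms the
  interaction of the two series' different AR(2) whitening filters with the
  broad envelope autocorrelation biases the estimated lead by a few tens of
  milliseconds beyond the true delay.  The default burst duration (200 ms)
  sits in the physiological range where the estimate is accurate.
* The tonic component of atonia-loss episodes carries episode-state
  information in both directions; with very strong burst-rate elevation the
  reverse (EMG-to-beta) Granger channel grows, which is why the boost
  defaults to a modest 0.8 of the baseline rate per unit coupling.
* The greedy nearest-pair matching heuristic is not optimal on adversarial
  epoch layouts; the package therefore solves the assignment exactly (the
  dynamic programme is O(REM × NREM) and never slower in practice).
* Percentile conventions matter at these sample sizes: a different
  percentile type changes the RSWA threshold of small NREM pools by a few
  percent.  Type 7 is fixed and documented.
* Surrogate block length (1 s) is a convention: long enough to preserve
  envelope autocorrelation within blocks, short enough to give many
  distinguishable permutations per 30-s epoch.  It is configurable, and the
  type-I-error calibration test pins its adequacy under the default.
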