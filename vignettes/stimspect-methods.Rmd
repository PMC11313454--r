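---
title: "Spectral and phase analysis of stimulation-evoked intracranial EEG"
author: "stimspect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral and phase analysis of stimulation-evoked intracranial EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

Single pulses of transcranial magnetic stimulation (TMS) delivered during
intracranial EEG (iEEG) monitoring allow the spectral consequences of
cortical stimulation to be measured directly inside the human brain. The
analytic challenge is threefold:

1. **Power.** Does a pulse change band-limited power (theta 3–8 Hz, gamma
   30–50 Hz, high-frequency activity 70–110 Hz) relative to a sham pulse
   that preserves the auditory click and expectancy cues?
2. **Phase.** Are post-pulse rhythms *evoked* (phase-locked to the pulse)
   or *induced* (amplitude-modulated with trial-varying phase)?
3. **Oscillation vs broadband.** Are theta-power increases genuine
   narrowband oscillations, or the low-frequency tail of a broadband
   evoked transient?

`stimspect` implements the complete chain — preprocessing, windowed
multitaper band power with pre-stimulus baseline correction, Morlet
time-frequency maps, inter-trial phase locking (IPL), per-trial spectral
parameterization, and hierarchical group statistics — together with a
multi-subject synthetic-data generator so every stage can be validated
against known injected effects.

## Preprocessing

Stages run in a fixed order per subject (`preprocess_subject()`):

* **Re-referencing.** Depth (stereo-EEG) contacts are re-referenced to a
  bipolar montage: contacts adjacent on a shaft are differenced, turning
  $n$ contacts into $n-1$ derived channels and cancelling far-field
  reference noise. Grid/strip contacts are re-referenced to their common
  average. Contacts flagged as excluded (seizure involvement, amplifier
  saturation, non-neural noise) are omitted from the common average and
  from bipolar pairing before anything downstream sees them. A shaft left
  with a single usable contact is dropped with a warning.
* **Artifact interpolation.** The ~15 ms stimulation artifact is scrubbed
  by replacing the interval from 25 ms before to 25 ms after each pulse
  with the weighted sum of the reversed 50 ms flanks:
  $y(j) = \mathrm{rev}(\text{pre})_j\,w_\downarrow(j) +
  \mathrm{rev}(\text{post})_j\,(1 - w_\downarrow(j))$, where
  $w_\downarrow$ ramps linearly from 1 to 0 across the window. The ramp
  endpoints are chosen so the first and last replaced samples equal the
  adjacent unreplaced samples (continuity at the joins); the weights sum
  to one pointwise, so a constant trace is unchanged, and the operation is
  idempotent because it reads only samples outside the replaced window.
  Interpolation runs on the continuous record, before epoching, so the
  replacement introduces no epoch-edge effects. It is applied at every
  event in both conditions so the two conditions receive identical
  treatment.
* **Line noise.** At 60 Hz and each harmonic below Nyquist, a sinusoid is
  tested with the Thomson multitaper harmonic F-test (time-bandwidth 4) on
  a centred window of at most 2048 samples; harmonics significant at
  Bonferroni-corrected p < 0.05 are removed by exact least-squares
  sinusoid subtraction over the full trace. Non-significant frequencies
  are left untouched.
* **Downsampling** to 500 Hz with a windowed-sinc (Hamming) FIR whose
  cutoff sits at 0.8× the target Nyquist; the filter's integer group delay
  is compensated exactly, and its stopband (≥50 dB) guarantees ≥40 dB
  attenuation above the target Nyquist. The filter is normalized to unit
  DC gain.
* **Epoching** into 2.5 s trials spanning 500 ms before to 2 s after each
  pulse. Conventions used everywhere: times in seconds, 0-based sample
  indexing in the time-to-index maps, half-open windows $[t_0, t_1)$.

## Band power and baseline correction

Power spectral density is estimated with DPSS (Slepian) multitapers,
time-bandwidth product 4, dropping tapers with spectral concentration
below 0.9 (at NW = 4 all $2NW-1 = 7$ tapers pass). Band power is computed
by log-transforming the PSD per frequency bin (natural log) and averaging
the logs across in-band bins — log first, then average.

Post-stimulation windows start 50 ms after the pulse (clear of the
interpolated artifact) and advance in 100 ms steps to a last start of
850 ms; theta and gamma use 500 ms windows, HFA 250 ms windows (HFA
fluctuates on faster timescales). The window grid is start-indexed: the
"until 850 ms" endpoint is read as the last window *start*, consistent
with a first post-stimulation window of 0.05–0.55 s.

Each trial's **baseline** — the same estimator applied to the 450 ms
window $[-0.5, -0.05)$ s, buffered 50 ms from the artifact — is
subtracted from every post-stimulation window of that trial. Because the
values are log powers, the corrected values are log power ratios and are
exactly invariant to channel gain.

The Morlet time-frequency representation uses 3-cycle complex wavelets at
25 log-spaced frequencies from 3 to 110 Hz; power is log-transformed and
baseline-corrected per frequency with the same baseline window. Wavelets
are made exactly zero-mean (the standard Morlet correction term) so
constant offsets cannot leak into low-frequency power, and epochs are
mirror-padded before convolution to suppress edge artifacts. For
subcortical-style timecourses, `windowed_tfr_power()` averages the TFR
into non-overlapping 100 ms windows over the first second.

## Group statistics

Per contact, band and window, baseline-corrected power is contrasted
between TMS and sham trials with a classic pooled-variance two-sample t
(Welch would also be defensible, but pooled variance is the default
reading of an unqualified "two-sample t-test"). Contact
t-statistics are then modelled per region of interest with an
intercept-only linear mixed model, `t ~ 1 + (1 | subject)`, fitted by
REML; the Wald z (intercept / SE) tests whether the population response
differs from zero. Regions sampled in fewer than five subjects are not
analyzed. If the mixed model fails to converge the code falls back to a
one-sample t over subject means and flags the row (`method` column).
P-values are Benjamini–Hochberg corrected over the nine windows within
each (region × band) family — over timepoints, not regions or bands; the
pixelwise time-frequency test corrects over the full grid instead.
One-sample `subregion_ttest()` (contacts pooled across subjects) serves
the small-sample subregion analyses where mixed models rarely converge;
zero-variance inputs return a flagged degenerate result rather than an
error.

The session-adaptation contrast splits each contact's active trials into
the first and last 25 (sham split the same way), forms the TMS-vs-sham t
separately for the early and late subsets, and tests the late-minus-early
difference against zero across contacts.

## Inter-trial phase locking

IPL (the phase-locking value) at time $t$ and frequency $f$ is the mean
resultant vector length $\left|\tfrac1n\sum_k e^{i\varphi_k(t,f)}\right|$
of the per-trial phases. Phase is extracted with DPSS-tapered complex
wavelets, time-bandwidth 4, two cycles long; "two cycles" is read as a
frequency-dependent window of $2/f$ seconds, the convention of the
standard multitaper TFR implementations. IPL is computed per taper from
the normalized coefficients and averaged across tapers. Analysis
frequencies are 3–8 Hz in 1 Hz steps, averaged after the IPL computation.

Because the statistic is biased upward at small trial counts (null
expectation $\approx \tfrac{\sqrt{\pi}}{2}n^{-1/2}$), trial counts are
matched by randomly subsampling both conditions to the smaller count
(one seeded draw per subject). Each trial is mirror-buffered by 450 ms
before convolution — the leading and trailing edges are reversed and
prepended/appended, then clipped from the output — so edge artifacts
cannot masquerade as phase locking. Each condition's mean IPL over the
baseline window $[-0.5, -0.05)$ s is subtracted (the baseline is computed
on the same matched subsets), and ΔIPL = corrected TMS − corrected sham.
Group inference averages ΔIPL into 500 ms windows starting 0.1–0.9 s in
100 ms steps and reuses the mixed-model/FDR machinery.

## Oscillation detection

To separate narrowband oscillations from broadband evoked responses, each
trial's 1 s post-stimulation window (50–1050 ms, giving 1 Hz resolution)
is parameterized into periodic and aperiodic components over 3–50 Hz:

* the aperiodic component is a line in log10 power vs log10 frequency
  (offset and exponent; no knee — a 3–50 Hz range rarely needs one);
* Gaussian peaks are added largest-residual-first while the maximum
  residual exceeds 3 residual standard deviations, with peak widths
  (2 × Gaussian SD) constrained to 0.5–12 Hz; "standard deviation of the
  aperiodic baseline" is read as the SD of the fit residuals;
* the aperiodic line is refit on the peak-removed spectrum.

The per-trial theta statistic is the largest-amplitude detected peak with
centre in 3–8 Hz. Trials without a detected theta peak contribute
amplitude 0 to the per-condition mean, so the contact statistic reflects
both oscillation prevalence and magnitude (`absent_as_zero = FALSE`
switches to peak-bearing trials only). The TMS-minus-sham difference is
tested against zero across a region's contacts with a one-sample t.
Trial counts are deliberately not matched here — the statistic is a mean,
not a resultant length, so it carries no trial-count bias.

The input PSD for the per-trial fits uses NW = 3 rather than the NW = 4
of the band-power estimator: on a 1 s single-trial window, 4 Hz of
half-bandwidth smears a three-cycle theta burst into the aperiodic
component and leaks sub-3 Hz background into the fit range, producing
spurious low-edge peaks; 3 Hz preserves peak structure at acceptable
estimator variance. This is the one estimator setting that differs from
the band-power chain, and it is exposed as an argument.

## The synthetic-data generator

`generate_dataset()` emulates the recording conditions the pipeline
targets: multi-subject recordings sampled at a configurable rate (8 kHz
acquisition band-passed 0.7–800 Hz by default; studies at 500 Hz directly
are supported and used in the tests), 0.5 Hz pulse trains with 2 s
inter-stimulation intervals and a randomized interleaving of active and
sham pulses, a 1/f² Gaussian background, common 60 Hz line noise, a
biphasic ±7.5 ms stimulation artifact (50× background SD, with
contact-specific coupling so bipolar derivations retain it), and
per-subject log-normal gain (σ = 0.2) to exercise the hierarchical model.

Each simulated region is one depth shaft whose regional effect amplitude
falls off geometrically (0.5× per contact, dipole-like), so bipolar
differencing retains a consistent-sign effect at about half the injected
amplitude. Three archetypal region profiles are the defaults:

* **Evoked** (`evoked_theta`): a deterministic broadband transient —
  a frozen 1/f-shaped waveform with *deterministic amplitude spectrum*
  (random phases drawn once per subject-region), amplitude 20 SD, decaying
  with τ = 0.3 s — plus a small 5 Hz damped cosine (4 SD). Identical
  across trials, it is perfectly phase-locked and spectrally smooth: it
  drives band power and IPL but presents no discrete spectral peak, the
  defining signature of an evoked potential. The deterministic spectrum
  matters: a single realization of ordinary shaped noise carries
  bin-to-bin spectral ripple that, frozen across trials, would imprint
  consistent pseudo-peaks on every trial's spectrum.
* **Induced** (`induced_theta`): a 6 Hz, 3-cycle Hanning-windowed burst,
  amplitude 12 SD, with uniform random phase per trial and onset latency
  0.1 s + U(0, 0.2) s. Detectable by power and by peak fitting, invisible
  to phase locking.
* **Suppression** (`hfa_suppression`): 80% of the 70–110 Hz band-passed
  background amplitude removed between 0.25 and 0.75 s after each active
  pulse.

Sham trials carry a small auditory-click evoked component (damped 5 Hz
transient, 2 SD) in every region — clicks are heard brain-wide. Besides
realism, this symmetrizes the oscillation detector's false-peak behaviour
between conditions: broadband spectral shifts modulate how often the
detector fires on noise, and an effect present in only one condition
would otherwise bias the TMS-minus-sham oscillation statistic.

Amplitudes are free parameters (reported in background-SD units; the
physical-unit scale is not identified). The defaults were fixed once, at
design time, to values giving clearly detectable single-contact effects
of the kind the pipeline is built to dissociate — strong evoked potentials
near a stimulation site can exceed the background by an order of
magnitude — and are exercised end-to-end in the recovery tests of the test suite at
6 subjects × 3 regions × 4 bipolar contacts × 100 + 100 trials at 500 Hz.
An optional per-trial linear amplitude drift models session adaptation.

Every injected trial parameter (induced phase and latency, drift gain,
subject gain) is returned as ground truth and written as a JSON sidecar
by `write_dataset()`, so tests can compare pipeline output against
oracle values — e.g. the resultant-vector length of the stored phases.

**What the generator does not emulate:** volume conduction and realistic
dipole geometry, epileptiform transients, non-stationary background
(state changes, drowsiness), heteroscedastic artifacts, or
between-region effect correlations. Passing the recovery tests therefore
demonstrates that the estimators and statistics behave correctly under
the stated signal model, not that the pipeline is robust to every
pathology of clinical recordings.

## Numerical choices and degenerate inputs

* Natural log for band power ("log-transformed" is not base-specified in
  common usage; the contrasts are base-invariant), log10 inside the
  spectral parameterization (the field convention there).
* Powers are floored at machine epsilon before log so constant or silent
  channels yield finite values; zero-variance t-tests return NaN with a
  warning (two-sample) or a flagged degenerate result (one-sample).
* DPSS tapers come from the symmetric tridiagonal eigenproblem with
  concentrations from the sinc-kernel quadratic form, cached per
  (length, NW, k); taper signs are fixed so sums are non-negative.
* The harmonic F-test uses df (2, 2K−2) and the fitted sinusoid is
  removed by exact least squares at the known line frequency, which is
  exact for stationary line noise and avoids notch-filter ringing.
* Ties and edge cases in the window maps follow the half-open convention;
  `round()` half-to-even applies to sample-index rounding, while reported
  percentages round half away from zero to one decimal.
* Mixed-model non-convergence (rare at the default scale) falls back to a
  flagged one-sample t over subject means.

## Problem sizes

The test-suite defaults are sized for a laptop-class single core: the
end-to-end recovery study uses 6 subjects × 3 regions × 5 contacts with
100 + 100 trials at 500 Hz (about four minutes); the null-calibration
property uses 200 seeded repetitions of a 5-subject, single-region,
15 + 15-trial study (about three minutes); spectral-model recovery uses
100 randomized spectra. These sizes are the package's validation design;
all of them scale up by changing the corresponding configuration fields.

## Known limitations

* The 2-cycle, NW = 4 phase-locking wavelets are very broadband at the
  top of the theta range (±16 Hz at 8 Hz); IPL values at neighbouring
  frequencies are accordingly correlated. This mirrors the estimator
  convention the pipeline standardizes on rather than improving on it.
* The LMM Wald test is anticonservative for very few subjects (normal
  approximation to what is effectively a t-statistic with
  subjects-minus-one degrees of freedom); with the five-subject minimum
  enforced, the BH step across windows keeps the realized null
  window-rejection fraction well under α in the package's own
  calibration check.
* `fit_spectral_model()` is a two-stage fit (aperiodic, then greedy
  peaks, then aperiodic refit) rather than a full joint optimization;
  for heavily overlapping peaks a joint refit would be more accurate.
* The adaptation contrast assumes sham stationarity when splitting sham
  trials into early/late subsets alongside the active trials.
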