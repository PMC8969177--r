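---
title: "Methods: spike, burst and connectivity analysis of multiwell MEA recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike, burst and connectivity analysis of multiwell MEA recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meapipe)
```

meapipe analyses extracellular recordings from multiwell microelectrode
arrays (MEAs) of in vitro neuronal networks — the kind of data used to follow
the functional maturation of human pluripotent stem cell (hPSC)-derived and
rodent cortical cultures. This vignette explains the models and procedures
behind each stage, the parameters that matter, and the design choices made
where the methods literature leaves options open.

## The data model

A recording is one plate: either 12 wells with 64 electrodes each, or 48
wells with 16 electrodes each, sampled at 12.5 kHz. On disk a plate is an
HDF5 file with two groups. `/Data` holds one subgroup per recorded well and
one dataset per electrode (`/Data/A3/22` is the voltage time series of
electrode 22 in well A3, in volts, stored as 32-bit float). `/DataInfo`
holds two datasets — `ExcludedWells` (wells not used in the experiment) and
`InactiveChannels` (single malfunctioning electrodes) — and five attributes:
`SamplingFrequencyInHz`, `DurationInSec`, `RecordingUnits` (always "Volts"),
`DIV` (days in vitro) and `Plate type` (12 or 48). Requesting a trace for an
excluded well or inactive channel is an error, exactly as reading the absent
dataset from the file would be. All dataset addresses use forward slashes.

Storage choices the dialect does not force: electrode datasets are written
as 32-bit floats (lossless at the dynamic range and noise floor of these
recordings, half the size of doubles); `InactiveChannels` entries are
stored as `"well/electrode"` strings; times are 0-based seconds from the
recording start and intervals are half-open.

## Spike detection

Detection is a hybrid of two classical methods, run per electrode:

1. **Prefilter.** A 4th-order elliptic band-pass (0.1 dB passband ripple,
   40 dB stopband attenuation) with a 200–3000 Hz passband, applied
   forward–backward so the net phase is zero and spike times are not
   shifted. Only the passband edges are canonical; ripple, order and
   attenuation are our choices, typical for extracellular work.
2. **Amplitude threshold.** The noise SD is estimated robustly as
   `median(|x|) / 0.6745` — the median of absolute values is nearly blind to
   the sparse spikes riding on the noise, and 0.6745 is the 75th percentile
   of the standard normal. Samples with `|x|` above **4.5×** this estimate
   become candidate events, each aligned to the local absolute extremum
   within 1 ms after the crossing; events closer than a 1 ms dead time
   collapse to the larger one. Both polarities are detected (absolute
   amplitude), and the threshold-to-sigma ratio is 4.5 exactly, for every
   input.
3. **SWTTEO cancellation.** The stationary (undecimated) wavelet transform
   of the filtered trace is taken to level 2 with a symlet (sym5 by
   default; sym4 available), the Teager energy operator
   `psi[d](n) = d(n)^2 - d(n-1) d(n+1)` is applied to each level's detail
   coefficients, the levels are summed, rectified, and smoothed with a
   0.5 ms Hamming window. If thresholding found N events, the N highest
   local maxima of this energy signal (separated by at least the dead time)
   are the wavelet detector's events, and only threshold events confirmed
   by a wavelet event within 1 ms survive. The cancellation stage can
   remove false positives but never add events.

The wavelet, level, smoothing and matching tolerance are configurable
because the SWTTEO literature itself varies them; the defaults here follow
common practice for biological data. An electrode is **active** when its
rate strictly exceeds 10 spikes per minute; only active electrodes enter
further analysis (10 spikes in 60 s is inactive, 11 is active).

## Burst detection (logISI)

Bursts are detected per electrode from the inter-spike-interval (ISI)
distribution. The histogram of `log10(ISI)` is built at 10 bins per decade,
padded with one empty bin on each side, and smoothed with a centred 3-bin
moving average. Peaks are strict local maxima. If a peak exists below the
100 ms intra-burst cap, the ISI threshold is the histogram minimum between
that peak and the next peak separated from it by a **void parameter**
`1 - h_min / sqrt(h_peak1 * h_peak2)` of at least 0.7; if no later peak
qualifies, the threshold falls back to 100 ms; if no sub-100 ms peak exists
the electrode is treated as burst-free. Maximal runs of consecutive ISIs
strictly below the threshold containing at least **5 spikes** become bursts,
and consecutive bursts whose inter-burst interval (last spike to first
spike) is strictly below **100 ms** are merged. Filtering on the 5-spike
minimum happens before merging (merging only grows counts, so the order
cannot remove a burst, but it is fixed for determinism).

Two numerical details: strict-< comparisons at the threshold and merge
boundaries carry a 1 ns guard, because timestamps quantized at the sampling
period can land exactly on a boundary that binary floating point cannot
represent; and a burst whose first and last spikes coincide has its
duration floored at one sample period so the in-burst frequency stays
finite.

Per electrode the statistics are: bursts per minute, mean burst duration,
mean in-burst spike frequency (spikes / burst duration), mean spikes per
burst, and the percentage of all spikes that fall inside bursts. Electrodes
without bursts report a zero burst rate and *missing* burst means — burst
statistics are defined only for electrodes exhibiting bursts, and missing
values propagate (never imputed as zero). Well-level aggregation counts the
active electrodes (`nae`), averages the firing rate over active electrodes
only, and averages burst statistics over the electrodes exhibiting bursts.
Noisy-listed electrodes are discarded before any of this; a well whose every
electrode is eliminated is omitted from the output tables.

## Network synchronization

**STTC** (spike time tiling coefficient) quantifies pairwise spike-train
correlation insensitively to firing rate:
`STTC = 1/2 [ (P_A - T_B)/(1 - P_A T_B) + (P_B - T_A)/(1 - P_B T_A) ]`,
where `T_X` is the fraction of the recording covered by ±dt windows around
X's spikes and `P_X` is the proportion of X's spikes within ±dt of any spike
of the other train. The default window is **dt = 50 ms**. The T terms are
computed exactly by sorted interval-union arithmetic with windows clipped at
the interval bounds — not by grid approximation (the dense-grid version
exists in the test suite as the independent oracle). Empty trains and
degenerate denominators give missing values. Well-level STTC averages all
defined pairs over active electrodes (configurable).

**CorSE** (correlated spectral entropy) works on the raw traces: each trace
is cut into 1 s Hann-tapered windows with 50 % overlap; per window the
periodogram is normalized into a probability distribution over its K
frequency bins and the normalized Shannon entropy `H = -sum p ln p / ln K`
is recorded; the CorSE of a pair is the Pearson correlation of their
entropy series, and its magnitude is the connectivity strength. Entropy is
scale-invariant, so CorSE responds to correlated changes in spectral
*content* (bursts concentrate power into the spike band and depress the
entropy) rather than shared amplitude. A constant (dead) channel has a
constant entropy series and yields missing pairs, which drop out of the
well mean. Window length, overlap and the spectrum estimator are
configurable; the well mean includes sub-threshold pairs, while the
connectivity *map* keeps only pairs with strength strictly above 0.7.

## Feature PCA

Each well/timepoint contributes a 7-feature vector: mean firing rate by
active electrodes, burst rate per minute, mean burst duration, mean in-burst
spike frequency, mean spikes per burst, percentage of spikes in bursts, and
the well-mean STTC. The number of active electrodes is deliberately not a
feature (it only serves to compute the others). Observations with any
missing feature are dropped with a logged count rather than imputed — the
classification targets timepoints where activity is well developed and all
features are defined. All observations entering one PCA are pooled into a
single standard-score normalization (sample SD, n−1), so different groups
share one embedding. The PCA itself is the SVD of the centred matrix; three
components are retained for 3-D classification plots, and each loading
column's sign is fixed so its largest-magnitude entry is positive,
preventing run-to-run mirror flips.

## The synthetic plate generator

Every stage is testable without raw recordings because the generator
produces ground-truthed plates with the same structure and statistics the
pipeline targets:

- **Spike trains**: stationary Poisson firing (`tonic_poisson`) or Poisson
  burst onsets with fixed-ISI intra-burst runs (`bursting`), matching the
  developmental progression from individual spiking to mature bursting.
  The emitted burst intervals are returned as ground truth.
- **Correlated channels**: a mother train thinned independently per channel
  and jittered with truncated zero-mean Gaussian noise; dependence decays
  with jitter and thinning, giving graded fixtures for STTC and CorSE.
- **Traces**: Gaussian background noise (default SD 3 µV) plus a 1.2 ms
  biphasic template (sharp negative peak, smaller positive rebound) scaled
  to per-electrode amplitudes drawn from 15–60 µV — the low-SNR regime
  typical of hPSC-derived networks, where hybrid detection earns its keep.
- **Plates**: full 12- or 48-well geometry at 12.5 kHz, default 600 s (the
  10-minute recordings the pipeline targets); a `ttx` flag multiplies all
  rates by 0.01, emulating tetrodotoxin silencing controls used to verify
  that detected activity is neuronal.

Generators are pure functions of (configuration, seed), with hierarchical
per-electrode seeding so any electrode is reproducible in isolation.

What the generator does *not* emulate: electrode-to-electrode gain
variation, non-Gaussian and non-stationary noise, movement/stimulus
artifacts, waveform diversity across units, volume-conducted crosstalk, and
developmental drift within a recording. Passing tests therefore demonstrate
algorithmic correctness under controlled conditions, not performance on
every real recording.

## Problem sizes and determinism

Unit and acceptance tests run on deliberately small instances — seconds of
signal, a handful of wells, up to a few hundred spikes per train — chosen so
the whole suite completes in well under a minute of compute while still
exercising every code path; estimator benchmarks (STTC vs its grid oracle,
burst detection vs run enumeration) use 100 randomized small cases under
fixed seeds. The pipeline itself has no size limits beyond memory. All
randomness flows from explicit integer seeds; rerunning any stage with the
same configuration and seed reproduces its outputs byte for byte, and the
run manifest records the configuration, seed and package version needed to
do so.

## Known limitations

- The HDF5 dialect is self-consistent but not guaranteed bit-compatible
  with any particular vendor export (dataset dtype and compression of
  third-party files vary); the reader checks structure, not provenance.
- The logISI variant here fixes histogram resolution, smoothing and
  void-parameter handling that the burst-detection literature leaves open;
  all are configurable, and other choices shift thresholds slightly.
- SWTTEO event selection enforces the dead time when picking the N highest
  energy maxima; implementations that skip this differ on pathological
  traces.
- CorSE on short recordings (few windows) has high variance; with 1 s
  windows and 50 % overlap, a 60 s trace yields 119 windows, which is about
  the practical minimum for stable correlations.
- Network-level (multi-electrode) burst detection, spike sorting and
  directed connectivity are out of scope.
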