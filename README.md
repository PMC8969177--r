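# meapipe

Spike, burst and network-synchronization analysis for multiwell
microelectrode array (MEA) recordings of in vitro neuronal networks.

MEAs record the extracellular activity of a population of cultured neurons —
for example hPSC-derived or rat embryonic cortical networks — across many
wells in parallel (12 wells × 64 electrodes, or 48 wells × 16 electrodes,
sampled at 12.5 kHz). As such cultures mature, individual spiking gives way
to spike trains, bursts and network-wide synchronized activity. meapipe is
an end-to-end pipeline for that data, for electrophysiologists and
computational neuroscientists who want the standard analyses in one tested,
scriptable package:

- **Plate I/O** — an HDF5 dialect with `/Data/<well>/<electrode>` voltage
  traces plus `/DataInfo` metadata (`ExcludedWells`, `InactiveChannels`,
  sampling frequency, duration, units, DIV, plate type), and the CSV side
  files (spike tables, noisy-electrode lists, experiment logs, per-feature
  well tables).
- **Spike detection** — 200–3000 Hz elliptic band-pass, absolute-amplitude
  thresholding at 4.5 × the robust noise estimate `median(|x|)/0.6745`,
  and false-positive cancellation by a stationary-wavelet-transform Teager
  energy operator (SWTTEO): if thresholding finds N events, only those
  confirmed by one of the N highest wavelet-energy maxima survive.
  Electrodes with strictly more than 10 spikes/min count as active.
- **Burst detection** — a logISI method: the ISI threshold is read off the
  smoothed log10(ISI) histogram at the minimum between the sub-100 ms peak
  and the next peak with void parameter ≥ 0.7; runs of sub-threshold ISIs
  with ≥ 5 spikes become bursts, merged when the inter-burst interval is
  < 100 ms; plus per-electrode and per-well burst statistics.
- **Synchronization** — the spike time tiling coefficient
  `STTC = ½[(P_A−T_B)/(1−P_A·T_B) + (P_B−T_A)/(1−P_B·T_A)]` with a 50 ms
  window (exact interval-union tiling terms), and CorSE, the Pearson
  correlation of sliding-window spectral-entropy series of two raw traces,
  with connectivity maps thresholded at strength > 0.7.
- **Classification** — a 7-feature vector per well (MFR by active
  electrodes, burst rate, mean burst duration, mean in-burst frequency,
  mean spikes/burst, % spikes in bursts, STTC), z-scored and embedded with
  a 3-component PCA.
- **Synthetic data** — a ground-truthed generator (Poisson/bursting trains,
  correlated channel groups, biphasic spike templates on Gaussian noise,
  full plate geometries, TTX-style silencing scenarios) so the whole
  pipeline is testable without any recordings.

## Worked example

```r
library(meapipe)

# simulate a 4-well recording on the 48-well geometry (16 electrodes/well)
scenario <- plate_scenario(
  plate_type = 48, duration_s = 5,
  included_wells = c("A1", "A2", "B1", "B2"),
  model = train_model("bursting", tonic_rate_hz = 2,
                      burst_rate_per_min = 60, spikes_per_burst = 8)
)
files <- run_pipeline(out_dir = "mea_out", config = pipeline_config(seed = 42),
                      scenario = scenario)

nrow(read_spike_csv(files$spikes))        # detected spikes
#> [1] 3157
nrow(read_spike_csv(files$truth_spikes))  # simulated ground truth
#> [1] 3256

read_feature_table(files$feature_bursts_per_min)
#>       DIV21
#> A1 62.00000
#> A2 46.28571
#> B1 44.40000
#> B2 52.00000
```

The detector recovers ~97 % of the simulated spikes at this SNR, and the
burst-rate table shows each well's mean rate (bursts per minute, averaged
over electrodes exhibiting bursts) at the recording's DIV. Independent
electrodes give near-zero well-mean STTC, as expected. Per electrode:

```r
spikes <- read_spike_csv(files$spikes)
a1_11  <- subset(spikes, well == "A1" & electrode == "11")
train  <- spike_train(a1_11$time_s, 5)
train
#> spike_train: 54 spikes in 5 s (10.80 Hz)
detect_bursts(train)
#> burst_list: 5 burst(s), ISI threshold 0.02239 s
#>   start_s   end_s n_spikes
#> 1 0.22744 0.29744        8
#> 2 0.43472 0.50472        8
#> 3 0.65432 0.72432        8
#> 4 2.09072 2.19152       11
#> 5 4.31408 4.38408        8
```

The detected bursts are the simulated 8-spike events (one pair merged into
an 11-spike burst where a background spike fell inside), with the logISI
threshold landing between the 10 ms intra-burst ISI and the background ISIs.

`run_pipeline()` writes the raw `.h5` plate, the spike CSV, the eight
per-feature well tables (`*_meanfiringrate_by_active_electrodes.csv`,
`*_nae.csv`, `*_STTC.csv`, `*_bursts_per_min.csv`, `*_mean_dur.csv`,
`*_mean_freq_in_burst.csv`, `*_per_spikes_in_burst.csv`,
`*_mean_spikes_in_burst.csv`), STTC/CorSE matrices and maps, PCA scores and
a JSON run manifest. A thin CLI over the same functions lives at
`inst/cli/mea-pipeline.R` (subcommands `simulate`, `detect-spikes`,
`analyze-bursts`, `sttc`, `corse`, `pca`, `run-all`).

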