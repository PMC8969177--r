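#' Default extracellular spike template
#'
#' A 1.2 ms biphasic waveform (sharp negative peak followed by a smaller,
#' slower positive rebound) resembling an extracellular action potential as
#' seen by a planar MEA electrode. The waveform is normalized to unit peak
#' absolute amplitude.
#'
#' @param fs_hz Sampling rate; the default matches the 12.5 kHz acquisition
#'   rate the generator emulates.
#' @param duration_ms Template duration, at most 4 ms.
#' @return List of class `spike_template` with elements `waveform` (numeric)
#'   and `peak_index` (sample offset of the absolute extremum, 1-based).
#' @export
spike_template <- function(fs_hz = 12500, duration_ms = 1.2) {
  if (duration_ms > 4) stop("template duration must be <= 4 ms")
  t <- seq(0, duration_ms / 1000, by = 1 / fs_hz)
  w <- -exp(-((t - 0.35e-3) / 0.12e-3)^2) + 0.35 * exp(-((t - 0.75e-3) / 0.25e-3)^2)
  w <- w / max(abs(w))
  structure(list(waveform = w, peak_index = which.max(abs(w))),
            class = "spike_template")
}

#' Spike-train generating model
#'
#' Two firing regimes cover the developmental repertoire the generator
#' emulates: `tonic_poisson` (stationary Poisson firing at `tonic_rate_hz`)
#' and `bursting` (burst onsets as a Poisson process at `burst_rate_per_min`,
#' each burst a fixed-ISI run of `spikes_per_burst` spikes, on top of an
#' optional tonic background).
#'
#' @param mode "tonic_poisson" or "bursting".
#' @param tonic_rate_hz Background firing rate (Hz).
#' @param burst_rate_per_min Burst onset rate (bursts per minute).
#' @param intra_burst_isi_s Fixed inter-spike interval within a burst.
#' @param spikes_per_burst Spikes per burst (>= 1).
#' @return List of class `train_model`.
#' @export
train_model <- function(mode = c("tonic_poisson", "bursting"),
                        tonic_rate_hz = 0,
                        burst_rate_per_min = 0,
                        intra_burst_isi_s = 0.01,
                        spikes_per_burst = 8L) {
  mode <- match.arg(mode)
  stopifnot(tonic_rate_hz >= 0, burst_rate_per_min >= 0,
            intra_burst_isi_s > 0, spikes_per_burst >= 1)
  structure(list(mode = mode, tonic_rate_hz = tonic_rate_hz,
                 burst_rate_per_min = burst_rate_per_min,
                 intra_burst_isi_s = intra_burst_isi_s,
                 spikes_per_burst = as.integer(spikes_per_burst)),
            class = "train_model")
}

#' Generate a spike train from a model
#'
#' Deterministic given `seed`. In bursting mode the burst intervals actually
#' emitted are returned as the `bursts` attribute (ground truth for burst
#' detection benchmarks).
#'
#' @param model A [train_model()].
#' @param duration_s Recording duration (s).
#' @param seed Integer RNG seed.
#' @return A [spike_train()] with sorted times in `[0, duration_s]`.
#' @export
generate_train <- function(model, duration_s, seed = 1L) {
  stopifnot(duration_s > 0)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  times <- numeric()
  bursts <- NULL
  if (model$tonic_rate_hz > 0) {
    n <- rpois(1, model$tonic_rate_hz * duration_s)
    times <- runif(n, 0, duration_s)
  }
  if (model$mode == "bursting" && model$burst_rate_per_min > 0) {
    n_b <- rpois(1, model$burst_rate_per_min / 60 * duration_s)
    onsets <- sort(runif(n_b, 0, duration_s))
    if (n_b > 0) {
      spk <- lapply(onsets, function(o) {
        o + (seq_len(model$spikes_per_burst) - 1) * model$intra_burst_isi_s
      })
      keep <- vapply(spk, function(s) all(s <= duration_s), TRUE)
      spk <- spk[keep]
      if (length(spk)) {
        bursts <- data.frame(
          start_s = vapply(spk, min, 0), end_s = vapply(spk, max, 0),
          n_spikes = lengths(spk)
        )
        times <- c(times, unlist(spk))
      }
    }
  }
  times <- sort(unique(times))
  tr <- spike_train(times, duration_s)
  attr(tr, "bursts") <- bursts
  tr
}

#' Generate correlated spike trains
#'
#' A mother train is drawn from `model`; each of `n_channels` child trains
#' keeps each mother spike independently with probability
#' `participation_prob` and jitters it with zero-mean Gaussian noise of SD
#' `jitter_s` (truncated so times stay inside the recording). Pairwise
#' dependence between children weakens as jitter grows or participation
#' drops.
#'
#' @inheritParams generate_train
#' @param n_channels Number of child trains (>= 2).
#' @param jitter_s Jitter SD in seconds (>= 0).
#' @param participation_prob Per-spike participation probability in `[0,1]`.
#' @return List of [spike_train()] objects; the mother train is attached as
#'   attribute `mother`.
#' @export
generate_correlated_trains <- function(model, duration_s, n_channels,
                                       jitter_s = 0, participation_prob = 1,
                                       seed = 1L) {
  if (n_channels < 2) stop("n_channels must be >= 2")
  stopifnot(jitter_s >= 0, participation_prob >= 0, participation_prob <= 1)
  mother <- generate_train(model, duration_s, seed = seed)
  old <- .Random.seed_guard(derive_seed(seed, 1L))
  on.exit(old(), add = TRUE)
  out <- lapply(seq_len(n_channels), function(i) {
    keep <- runif(length(mother$times_s)) < participation_prob
    t <- mother$times_s[keep]
    if (jitter_s > 0 && length(t)) {
      t <- t + rnorm(length(t), 0, jitter_s)
      t <- pmin(pmax(t, 0), duration_s)
    }
    spike_train(sort(unique(t)), duration_s)
  })
  attr(out, "mother") <- mother
  out
}

#' Synthesize a raw voltage trace from a spike train
#'
#' Gaussian background noise of SD `noise_sd_v` plus one template occurrence
#' per spike, scaled so its peak absolute amplitude equals `amplitude_v` and
#' aligned so the template extremum falls on the spike sample. Template
#' samples falling outside the trace are clipped.
#'
#' @param train A [spike_train()].
#' @param template A [spike_template()] (default template if `NULL`).
#' @param amplitude_v Peak spike amplitude in volts (scalar or per spike).
#' @param noise_sd_v Background noise SD in volts.
#' @param fs_hz Sampling rate.
#' @param duration_s Trace duration; spike times beyond it are an error.
#' @param seed Integer RNG seed.
#' @return Numeric voltage trace of `round(duration_s * fs_hz)` samples.
#' @export
synthesize_trace <- function(train, template = NULL, amplitude_v = 30e-6,
                             noise_sd_v = 3e-6, fs_hz = 12500,
                             duration_s = train$duration_s, seed = 1L) {
  stopifnot(all(amplitude_v >= 0), fs_hz > 0)
  if (any(train$times_s > duration_s)) {
    stop("spike time beyond trace duration")
  }
  if (is.null(template)) template <- spike_template(fs_hz)
  n <- round(duration_s * fs_hz)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  x <- rnorm(n, 0, noise_sd_v)
  nt <- length(train$times_s)
  amp <- rep_len(amplitude_v, nt)
  w <- template$waveform
  for (i in seq_len(nt)) {
    centre <- round(train$times_s[i] * fs_hz) + 1L
    idx <- centre + seq_along(w) - template$peak_index
    ok <- idx >= 1L & idx <= n
    x[idx[ok]] <- x[idx[ok]] + amp[i] * w[ok]
  }
  x
}

#' Scenario description for a synthetic plate
#'
#' Describes one full synthetic recording: plate geometry, recording length,
#' the firing model used for every electrode, amplitude/noise levels and an
#' optional sodium-channel-block ("ttx") flag that scales all firing rates by
#' `silencing_factor`, emulating a tetrodotoxin silencing control.
#'
#' @param plate_type 12 or 48.
#' @param duration_s Recording duration; defaults to the 10-minute
#'   recordings the generator emulates.
#' @param fs_hz Sampling rate (default 12.5 kHz).
#' @param div Days in vitro stamped into the metadata.
#' @param included_wells Wells to simulate (default: all wells of the plate);
#'   the rest are listed as excluded.
#' @param model A [train_model()] applied to every electrode.
#' @param amplitude_range_v Per-electrode peak spike amplitudes are drawn
#'   uniformly from this range (default 15-60 uV, the low-amplitude regime
#'   typical of hPSC-derived networks).
#' @param noise_sd_v Background noise SD (default 3 uV).
#' @param ttx If `TRUE`, all rates are multiplied by `silencing_factor`.
#' @param silencing_factor Rate multiplier for ttx scenarios (default 0.01).
#' @return List of class `plate_scenario`.
#' @export
plate_scenario <- function(plate_type = 12L, duration_s = 600, fs_hz = 12500,
                           div = 21L, included_wells = NULL,
                           model = train_model("bursting", tonic_rate_hz = 0.5,
                                               burst_rate_per_min = 10),
                           amplitude_range_v = c(15e-6, 60e-6),
                           noise_sd_v = 3e-6,
                           ttx = FALSE, silencing_factor = 0.01) {
  plate_type <- check_plate_type(plate_type)
  all_wells <- well_labels(plate_type)
  if (is.null(included_wells)) included_wells <- all_wells
  check_well_labels(included_wells, plate_type, "included well")
  structure(list(plate_type = plate_type, duration_s = duration_s,
                 fs_hz = fs_hz, div = as.integer(div),
                 included_wells = included_wells, model = model,
                 amplitude_range_v = amplitude_range_v,
                 noise_sd_v = noise_sd_v, ttx = isTRUE(ttx),
                 silencing_factor = silencing_factor),
            class = "plate_scenario")
}

#' Generate a ground-truthed synthetic plate recording
#'
#' Every electrode of every included well receives an independent spike train
#' from the scenario's model (hierarchically seeded, so each electrode is
#' reproducible in isolation) rendered into a noisy voltage trace. The
#' returned ground truth carries the true spike times and true burst
#' intervals per electrode.
#'
#' @param scenario A [plate_scenario()].
#' @param seed Integer RNG seed.
#' @return List with elements `plate` (an [mea_plate()]) and `truth` (list
#'   with `spikes`, a `spike_table`, and `bursts`, a data frame of true burst
#'   intervals).
#' @export
generate_plate <- function(scenario, seed = 1L) {
  sc <- scenario
  model <- sc$model
  if (sc$ttx) {
    model$tonic_rate_hz <- model$tonic_rate_hz * sc$silencing_factor
    model$burst_rate_per_min <- model$burst_rate_per_min * sc$silencing_factor
  }
  all_wells <- well_labels(sc$plate_type)
  electrodes <- electrode_labels(sc$plate_type)
  excluded <- setdiff(all_wells, sc$included_wells)
  template <- spike_template(sc$fs_hz)
  wells <- list()
  truth_rows <- list()
  burst_rows <- list()
  k <- 0L
  for (w in sort(sc$included_wells)) {
    traces <- list()
    for (e in electrodes) {
      k <- k + 1L
      s_e <- derive_seed(seed, k)
      tr <- generate_train(model, sc$duration_s, seed = s_e)
      old <- .Random.seed_guard(derive_seed(s_e, 1L))
      amp <- runif(1, sc$amplitude_range_v[1], sc$amplitude_range_v[2])
      old()
      traces[[e]] <- synthesize_trace(tr, template, amplitude_v = amp,
                                      noise_sd_v = sc$noise_sd_v,
                                      fs_hz = sc$fs_hz,
                                      duration_s = sc$duration_s,
                                      seed = derive_seed(s_e, 2L))
      if (length(tr$times_s)) {
        truth_rows[[k]] <- data.frame(well = w, electrode = e,
                                      time_s = tr$times_s,
                                      stringsAsFactors = FALSE)
      }
      b <- attr(tr, "bursts")
      if (!is.null(b) && nrow(b)) {
        burst_rows[[k]] <- cbind(data.frame(well = w, electrode = e,
                                            stringsAsFactors = FALSE), b)
      }
    }
    wells[[w]] <- traces
  }
  md <- recording_metadata(sampling_frequency_hz = sc$fs_hz,
                           duration_s = sc$duration_s, div = sc$div,
                           plate_type = sc$plate_type,
                           excluded_wells = excluded)
  spikes <- if (length(truth_rows)) {
    df <- do.call(rbind, truth_rows)
    spike_table(df$well, df$electrode, df$time_s, duration_s = sc$duration_s)
  } else spike_table(duration_s = sc$duration_s)
  bursts <- if (length(burst_rows)) do.call(rbind, burst_rows) else
    data.frame(well = character(), electrode = character(),
               start_s = numeric(), end_s = numeric(), n_spikes = integer())
  list(plate = mea_plate(wells, md),
       truth = list(spikes = spikes, bursts = bursts))
}

# Save/restore the global RNG state around a seeded section, so generators
# are pure functions of (config, seed) without clobbering the caller's RNG.
.Random.seed_guard <- function(seed) {
  prev <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(prev)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", prev, envir = globalenv())
    }
  }
}
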