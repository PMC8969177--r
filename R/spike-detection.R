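#' Spike train
#'
#' Ordered spike times (seconds from recording start) for one electrode,
#' together with the recording duration and optional provenance and
#' per-spike peak amplitudes.
#'
#' @param times_s Numeric vector of spike times (s); sorted internally.
#' @param duration_s Recording duration (s), > 0.
#' @param well,electrode Optional provenance labels.
#' @param amplitudes_v Optional per-spike peak amplitudes (volts).
#' @return Object of class `spike_train`.
#' @export
spike_train <- function(times_s, duration_s, well = NA_character_,
                        electrode = NA_character_, amplitudes_v = NULL) {
  stopifnot(duration_s > 0)
  o <- order(times_s)
  times_s <- as.numeric(times_s)[o]
  if (!is.null(amplitudes_v)) amplitudes_v <- as.numeric(amplitudes_v)[o]
  if (length(times_s) && (times_s[1] < 0 || times_s[length(times_s)] > duration_s)) {
    stop("spike times must lie in [0, duration_s]")
  }
  structure(list(times_s = times_s, duration_s = as.numeric(duration_s),
                 well = well, electrode = electrode,
                 amplitudes_v = amplitudes_v),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat("spike_train: ", length(x$times_s), " spikes in ", x$duration_s, " s (",
      sprintf("%.2f", length(x$times_s) / x$duration_s), " Hz)\n", sep = "")
  invisible(x)
}

#' Spike detection parameters
#'
#' Defaults implement the detection pipeline for multiwell MEA recordings:
#' elliptic band-pass prefilter with a 200-3000 Hz passband, absolute
#' amplitude threshold at 4.5 times the robust noise-SD estimate, SWTTEO
#' false-positive cancellation, and a strict >10 spikes/min active-electrode
#' rule.
#'
#' @param passband_low_hz,passband_high_hz Band-pass edges (Hz).
#' @param threshold_multiplier Threshold as a multiple of the noise SD.
#' @param dead_time_s Minimum separation between detected events (s).
#' @param match_tolerance_s Tolerance for matching threshold events against
#'   SWTTEO events.
#' @param swt_level Stationary wavelet decomposition depth.
#' @param swt_wavelet Symlet name, "sym4" or "sym5".
#' @param teo_smooth_window_s Hamming smoothing window for the Teager energy.
#' @param min_active_rate_spm Active-electrode rate threshold, spikes per
#'   minute, strict.
#' @param filter_order,filter_ripple_db,filter_stopband_db Elliptic filter
#'   design parameters (order per section, passband ripple dB, stopband
#'   attenuation dB).
#' @return List of class `detection_params`.
#' @export
detection_params <- function(passband_low_hz = 200, passband_high_hz = 3000,
                             threshold_multiplier = 4.5,
                             dead_time_s = 1e-3,
                             match_tolerance_s = 1e-3,
                             swt_level = 2L, swt_wavelet = "sym5",
                             teo_smooth_window_s = 0.5e-3,
                             min_active_rate_spm = 10,
                             filter_order = 4L, filter_ripple_db = 0.1,
                             filter_stopband_db = 40) {
  stopifnot(passband_low_hz > 0, passband_low_hz < passband_high_hz,
            threshold_multiplier > 0, dead_time_s > 0, swt_level >= 1)
  structure(list(passband_low_hz = passband_low_hz,
                 passband_high_hz = passband_high_hz,
                 threshold_multiplier = threshold_multiplier,
                 dead_time_s = dead_time_s,
                 match_tolerance_s = match_tolerance_s,
                 swt_level = as.integer(swt_level),
                 swt_wavelet = swt_wavelet,
                 teo_smooth_window_s = teo_smooth_window_s,
                 min_active_rate_spm = min_active_rate_spm,
                 filter_order = as.integer(filter_order),
                 filter_ripple_db = filter_ripple_db,
                 filter_stopband_db = filter_stopband_db),
            class = "detection_params")
}

#' Zero-phase elliptic band-pass filter
#'
#' Elliptic band-pass applied forward-backward (zero phase, squared
#' magnitude response), as prefiltering before spike detection.
#'
#' @param trace Numeric voltage trace.
#' @param fs_hz Sampling rate; must exceed twice the upper passband edge.
#' @param params A [detection_params()].
#' @return Filtered trace, same length as the input.
#' @export
bandpass_filter <- function(trace, fs_hz, params = detection_params()) {
  if (fs_hz <= 2 * params$passband_high_hz) {
    stop("sampling rate too low for a ", params$passband_high_hz, " Hz passband edge")
  }
  flt <- signal::ellip(params$filter_order, params$filter_ripple_db,
                       params$filter_stopband_db,
                       c(params$passband_low_hz, params$passband_high_hz) / (fs_hz / 2),
                       type = "pass")
  as.numeric(signal::filtfilt(flt, trace))
}

#' Robust noise standard deviation estimate
#'
#' `median(|x|) / 0.6745`, the standard robust estimator used for
#' amplitude-threshold spike detection: the median of absolute values is
#' insensitive to the (sparse) spikes riding on the noise floor, and 0.6745
#' is the 75th percentile of the standard normal.
#'
#' @param trace Filtered voltage trace (non-empty).
#' @return Estimated noise SD (volts).
#' @export
estimate_noise_sd <- function(trace) {
  if (!length(trace)) stop("cannot estimate noise from an empty trace")
  median(abs(trace)) / 0.6745
}

#' Absolute-amplitude threshold detection
#'
#' Flags samples with `|x| > k * sigma`, aligns each crossing to the local
#' absolute-amplitude extremum within 1 ms after the crossing, and collapses
#' events closer than the dead time to the larger one.
#'
#' @inheritParams bandpass_filter
#' @param sigma_v Noise SD; estimated from the trace when `NULL`.
#' @return List of class `threshold_events`: `times_s`, `amplitudes_v`,
#'   `threshold_v`, `sigma_v`. `threshold_v / sigma_v` equals the configured
#'   multiplier exactly.
#' @export
threshold_detect <- function(trace, fs_hz, params = detection_params(),
                             sigma_v = NULL) {
  if (is.null(sigma_v)) sigma_v <- estimate_noise_sd(trace)
  thr <- params$threshold_multiplier * sigma_v
  n <- length(trace)
  above <- abs(trace) > thr
  times <- numeric(); amps <- numeric()
  if (any(above)) {
    idx <- which(above)
    starts <- idx[c(TRUE, diff(idx) > 1L)]
    win <- max(1L, round(1e-3 * fs_hz))
    peaks <- vapply(starts, function(s) {
      j <- s:min(n, s + win)
      j[which.max(abs(trace[j]))]
    }, 0L)
    amp <- abs(trace[peaks])
    # dead-time collapse, keeping the larger event
    o <- order(peaks)
    peaks <- peaks[o]; amp <- amp[o]
    dead <- params$dead_time_s * fs_hz
    keep_i <- integer()
    for (i in seq_along(peaks)) {
      if (length(keep_i) && (peaks[i] - peaks[keep_i[length(keep_i)]]) < dead) {
        if (amp[i] > amp[keep_i[length(keep_i)]]) keep_i[length(keep_i)] <- i
      } else {
        keep_i <- c(keep_i, i)
      }
    }
    peaks <- peaks[keep_i]; amp <- amp[keep_i]
    dup <- !duplicated(peaks)
    times <- (peaks[dup] - 1) / fs_hz
    amps <- amp[dup]
  }
  structure(list(times_s = times, amplitudes_v = amps,
                 threshold_v = thr, sigma_v = sigma_v),
            class = "threshold_events")
}

#' Teager energy operator
#'
#' `psi[x](n) = x(n)^2 - x(n-1) * x(n+1)`, an instantaneous energy estimate
#' that emphasizes transients. End samples, where a neighbour is missing,
#' are set to zero.
#'
#' @param x Numeric vector.
#' @return Numeric vector, same length.
#' @export
teager_energy <- function(x) {
  n <- length(x)
  if (n < 3L) return(numeric(n))
  psi <- numeric(n)
  psi[2:(n - 1)] <- x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n]
  psi
}

# Symlet analysis low-pass filter banks (least-asymmetric Daubechies).
# The high-pass partner follows from the quadrature-mirror relation.
SYMLET_DEC_LO <- list(
  sym4 = c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
           0.8037387518059161, 0.29785779560527736, -0.09921954357684722,
           -0.012603967262037833, 0.0322231006040427),
  sym5 = c(0.027333068345077982, 0.029519490925774643, -0.039134249302383094,
           0.1993975339773936, 0.7234076904024206, 0.6339789634582119,
           0.01660210576452232, -0.17532808990845047, -0.021101834024758855,
           0.019538882735286728)
)

# One level of the undecimated (a trous) wavelet transform with periodic
# boundary handling; filters are upsampled by 2^(level-1). The output is
# advanced by half the (upsampled) filter length, matching the usual SWT
# phase convention.
swt_step <- function(x, h) {
  n <- length(x)
  L <- length(h)
  if (L > n) stop("trace too short for this SWT level")
  hp <- c(h, numeric(n - L))
  y <- Re(fft(fft(x) * fft(hp), inverse = TRUE)) / n
  s <- L %/% 2
  c(y[(s + 1):n], y[1:s])
}

#' Stationary wavelet transform detail coefficients
#'
#' Undecimated (a trous) symlet decomposition to `level`, periodic boundary
#' extension; returns one detail-coefficient vector per level, each the
#' length of the input.
#'
#' @param x Numeric trace (length >= `2^level`).
#' @param level Decomposition depth.
#' @param wavelet "sym4" or "sym5".
#' @return List of numeric vectors `d1 ... d<level>`.
#' @export
swt_details <- function(x, level = 2L, wavelet = "sym5") {
  lo <- SYMLET_DEC_LO[[wavelet]]
  if (is.null(lo)) stop("unknown wavelet: ", wavelet, " (available: ",
                        paste(names(SYMLET_DEC_LO), collapse = ", "), ")")
  if (length(x) < 2^level) stop("trace too short for SWT level ", level)
  hi <- rev(lo) * (-1)^seq_along(lo)
  a <- x
  out <- vector("list", level)
  for (j in seq_len(level)) {
    f <- 2^(j - 1L)
    lo_j <- hi_j <- numeric(length(lo) * f)
    lo_j[seq(1, length(lo_j), by = f)] <- lo
    hi_j[seq(1, length(hi_j), by = f)] <- hi
    out[[j]] <- swt_step(a, hi_j)
    a <- swt_step(a, lo_j)
  }
  names(out) <- paste0("d", seq_len(level))
  out
}

#' SWTTEO spike-emphasis energy signal
#'
#' The stationary wavelet transform is taken to `swt_level`, the Teager
#' energy operator is applied to the detail coefficients of each level, the
#' per-level energies are summed, rectified, and smoothed with a short
#' Hamming window. The result is a non-negative signal, the same length as
#' the trace, whose local maxima mark spike-like transients.
#'
#' @inheritParams bandpass_filter
#' @return Non-negative numeric energy signal.
#' @export
swtteo_energy <- function(trace, fs_hz, params = detection_params()) {
  det <- swt_details(trace, params$swt_level, params$swt_wavelet)
  e <- Reduce(`+`, lapply(det, teager_energy))
  e <- pmax(e, 0)
  wlen <- max(1L, round(params$teo_smooth_window_s * fs_hz))
  if (wlen > 1L) {
    w <- as.numeric(signal::hamming(wlen))
    w <- w / sum(w)
    e <- as.numeric(stats::filter(e, w, sides = 2))
    e[is.na(e)] <- 0
  }
  e
}

# n highest local maxima of an energy signal, greedily enforcing a minimum
# separation (in samples), returned as sample indices.
top_energy_peaks <- function(e, n_events, min_sep) {
  n <- length(e)
  if (n_events == 0L || n < 3L) return(integer())
  is_max <- c(FALSE, e[2:(n - 1)] > e[1:(n - 2)] & e[2:(n - 1)] >= e[3:n], FALSE)
  cand <- which(is_max & e > 0)
  if (!length(cand)) return(integer())
  cand <- cand[order(e[cand], decreasing = TRUE)]
  picked <- integer()
  for (i in cand) {
    if (!length(picked) || all(abs(picked - i) >= min_sep)) {
      picked <- c(picked, i)
      if (length(picked) == n_events) break
    }
  }
  sort(picked)
}

#' Detect spikes on one electrode
#'
#' Hybrid detector: the band-passed trace is thresholded at
#' `threshold_multiplier` times the noise SD; the number N of threshold
#' events fixes the number of candidate events taken from the SWTTEO energy
#' signal (its N highest local maxima, separated by at least the dead time);
#' only threshold events confirmed by an SWTTEO event within the match
#' tolerance are kept. The cancellation stage can only remove events, never
#' add them.
#'
#' @param trace Raw voltage trace (volts).
#' @param fs_hz Sampling rate (Hz).
#' @param params A [detection_params()].
#' @param prefilter Apply [bandpass_filter()] first (default TRUE).
#' @param well,electrode Provenance labels stored in the result.
#' @return A [spike_train()]; attributes `sigma_v` and `n_threshold` record
#'   the noise estimate and the pre-cancellation event count.
#' @export
detect_spikes <- function(trace, fs_hz, params = detection_params(),
                          prefilter = TRUE, well = NA_character_,
                          electrode = NA_character_) {
  x <- if (prefilter) bandpass_filter(trace, fs_hz, params) else trace
  dur <- length(trace) / fs_hz
  te <- threshold_detect(x, fs_hz, params)
  n_thr <- length(te$times_s)
  if (n_thr == 0L) {
    out <- spike_train(numeric(), dur, well, electrode)
  } else {
    e <- swtteo_energy(x, fs_hz, params)
    peaks <- top_energy_peaks(e, n_thr, round(params$dead_time_s * fs_hz))
    swt_times <- (peaks - 1) / fs_hz
    keep <- vapply(te$times_s, function(t) {
      length(swt_times) > 0 && min(abs(swt_times - t)) <= params$match_tolerance_s
    }, TRUE)
    out <- spike_train(te$times_s[keep], dur, well, electrode,
                       amplitudes_v = te$amplitudes_v[keep])
  }
  attr(out, "sigma_v") <- te$sigma_v
  attr(out, "n_threshold") <- n_thr
  out
}

#' Active-electrode classification
#'
#' An electrode is active when its firing rate strictly exceeds
#' `min_active_rate_spm` spikes per minute (default 10); only active
#' electrodes enter further analysis. Exactly 10 spikes in 60 s is inactive.
#'
#' @param train A [spike_train()].
#' @param params A [detection_params()].
#' @return Logical scalar.
#' @export
classify_active <- function(train, params = detection_params()) {
  stopifnot(train$duration_s > 0)
  60 * length(train$times_s) / train$duration_s > params$min_active_rate_spm
}

#' Extract spike waveform cutouts
#'
#' Fixed-length cutouts around each spike's alignment sample. Spikes whose
#' window would run past either end of the trace are dropped; the count of
#' dropped spikes is recorded in the `n_dropped` attribute.
#'
#' @param trace Voltage trace the spikes were detected on.
#' @param train A [spike_train()].
#' @param window_pre_ms,window_post_ms Window extent before/after the spike.
#' @param fs_hz Sampling rate.
#' @return Matrix (spikes x samples) of class `waveform_set` with attributes
#'   `window_pre_ms`, `window_post_ms`, `n_dropped`.
#' @export
extract_waveforms <- function(trace, train, window_pre_ms = 1,
                              window_post_ms = 2, fs_hz = 12500) {
  n_pre <- round(window_pre_ms / 1000 * fs_hz)
  n_post <- round(window_post_ms / 1000 * fs_hz)
  centres <- round(train$times_s * fs_hz) + 1L
  ok <- centres - n_pre >= 1L & centres + n_post <= length(trace)
  n_dropped <- sum(!ok)
  if (n_dropped) {
    message(n_dropped, " spike(s) dropped: waveform window outside the trace")
  }
  m <- t(vapply(centres[ok], function(c0) trace[(c0 - n_pre):(c0 + n_post)],
                numeric(n_pre + n_post + 1L)))
  if (!sum(ok)) m <- matrix(numeric(), 0L, n_pre + n_post + 1L)
  structure(m, class = c("waveform_set", class(m)),
            window_pre_ms = window_pre_ms, window_post_ms = window_post_ms,
            n_dropped = n_dropped)
}
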