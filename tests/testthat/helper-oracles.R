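# Independent brute-force oracles used to validate the exact implementations.

# STTC by dense-grid approximation of the tiling terms and exhaustive pair
# scan for the proportion terms (independent of the interval-union code).
sttc_grid_oracle <- function(a, b, dt, interval, grid = 1e-4) {
  n_g <- floor((interval[2] - interval[1]) / grid) + 1L
  cover_frac <- function(times) {
    covered <- logical(n_g)
    for (t in times) {
      lo <- max(1L, ceiling((t - dt - interval[1]) / grid) + 1L)
      hi <- min(n_g, floor((t + dt - interval[1]) / grid) + 1L)
      if (lo <= hi) covered[lo:hi] <- TRUE
    }
    mean(covered)
  }
  near_frac <- function(x, ref) {
    mean(vapply(x, function(t) any(abs(ref - t) <= dt), TRUE))
  }
  TA <- cover_frac(a); TB <- cover_frac(b)
  PA <- near_frac(a, b); PB <- near_frac(b, a)
  0.5 * ((PA - TB) / (1 - PA * TB) + (PB - TA) / (1 - PB * TA))
}

# Burst detection by direct enumeration of maximal sub-threshold runs and a
# from-scratch re-scanning merge loop.
burst_oracle <- function(times, isi_threshold, min_spikes, merge_ibi) {
  n <- length(times)
  bursts <- list()
  i <- 1L
  while (i < n) {
    j <- i
    while (j < n && times[j + 1L] - times[j] < isi_threshold - 1e-9) j <- j + 1L
    if (j - i + 1L >= min_spikes) {
      bursts[[length(bursts) + 1L]] <- c(times[i], times[j], j - i + 1L)
    }
    i <- max(j, i + 1L)
  }
  if (!length(bursts)) {
    return(data.frame(start_s = numeric(), end_s = numeric(), n_spikes = integer()))
  }
  b <- do.call(rbind, bursts)
  b <- data.frame(start_s = b[, 1], end_s = b[, 2], n_spikes = as.integer(b[, 3]))
  repeat {
    merged <- FALSE
    k <- 1L
    while (k < nrow(b)) {
      if (b$start_s[k + 1L] - b$end_s[k] < merge_ibi - 1e-9) {
        b$end_s[k] <- b$end_s[k + 1L]
        b$n_spikes[k] <- b$n_spikes[k] + b$n_spikes[k + 1L]
        b <- b[-(k + 1L), , drop = FALSE]
        merged <- TRUE
      } else {
        k <- k + 1L
      }
    }
    if (!merged) break
  }
  rownames(b) <- NULL
  b
}

# Small synthetic trace with spikes at known times, for detector fixtures.
fixture_trace <- function(times_s, duration_s, fs_hz = 12500,
                          amplitude_v = 40e-6, noise_sd_v = 3e-6, seed = 1L) {
  tr <- spike_train(times_s, duration_s)
  synthesize_trace(tr, spike_template(fs_hz), amplitude_v = amplitude_v,
                   noise_sd_v = noise_sd_v, fs_hz = fs_hz,
                   duration_s = duration_s, seed = seed)
}

match_counts <- function(detected, truth, tol = 1e-3) {
  n_match <- sum(vapply(truth, function(t)
    length(detected) > 0 && any(abs(detected - t) <= tol), TRUE))
  list(recall = if (length(truth)) n_match / length(truth) else NA_real_,
       precision = if (length(detected)) {
         sum(vapply(detected, function(t) any(abs(truth - t) <= tol), TRUE)) /
           length(detected)
       } else NA_real_)
}
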