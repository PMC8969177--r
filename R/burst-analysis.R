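#' Burst detection parameters
#'
#' Defaults implement a logISI burst detector tuned for in vitro MEA data:
#' at least 5 spikes per burst, bursts merged when the inter-burst interval
#' (last spike to first spike) is under 100 ms, and an intra-burst ISI cap of
#' 100 ms for the histogram peak search.
#'
#' @param min_spikes_in_burst Minimum spikes per burst.
#' @param merge_max_ibi_s Bursts closer than this gap are merged (strict <).
#' @param isi_max_s Intra-burst ISI cap for the logISI peak search.
#' @param bins_per_decade Log-ISI histogram resolution.
#' @param void_threshold Minimum void parameter for a valley to separate two
#'   histogram peaks.
#' @return List of class `burst_params`.
#' @export
burst_params <- function(min_spikes_in_burst = 5L, merge_max_ibi_s = 0.100,
                         isi_max_s = 0.100, bins_per_decade = 10L,
                         void_threshold = 0.7) {
  stopifnot(min_spikes_in_burst >= 2, merge_max_ibi_s > 0, isi_max_s > 0,
            bins_per_decade >= 2)
  structure(list(min_spikes_in_burst = as.integer(min_spikes_in_burst),
                 merge_max_ibi_s = merge_max_ibi_s, isi_max_s = isi_max_s,
                 bins_per_decade = as.integer(bins_per_decade),
                 void_threshold = void_threshold),
            class = "burst_params")
}

#' logISI inter-spike-interval threshold
#'
#' Builds a histogram of `log10(ISI)` (one bin per `1/bins_per_decade`
#' decade, padded with an empty bin on each side, smoothed with a centred
#' 3-bin moving average) and locates its peaks (strict local maxima). If a
#' peak exists at an ISI below `isi_max_s`, the threshold is the ISI at the
#' histogram minimum between that peak and the next peak separated from it
#' by a void parameter `1 - h_min / sqrt(h_peak1 * h_peak2)` of at least
#' `void_threshold`; when no later peak qualifies, the threshold falls back
#' to `isi_max_s`. When no peak lies below `isi_max_s` the train is treated
#' as burst-free and `NULL` is returned.
#'
#' @param train A [spike_train()] (>= 2 spikes for a defined result).
#' @param params A [burst_params()].
#' @return ISI threshold in seconds, or `NULL`.
#' @export
logisi_threshold <- function(train, params = burst_params()) {
  isi <- diff(train$times_s)
  if (length(isi) < 1L || length(train$times_s) < 2L) return(NULL)
  isi <- isi[isi > 0]
  if (!length(isi)) return(NULL)
  binw <- 1 / params$bins_per_decade
  l <- log10(isi)
  breaks <- seq(floor(min(l) / binw) * binw - binw,
                ceiling(max(l) / binw) * binw + binw, by = binw)
  if (length(breaks) < 4L) breaks <- c(breaks[1] - binw, breaks, breaks[length(breaks)] + binw)
  h <- graphics::hist(l, breaks = breaks, plot = FALSE)
  counts <- as.numeric(h$counts)
  centres <- h$mids
  sm <- as.numeric(stats::filter(counts, rep(1 / 3, 3), sides = 2))
  sm[1] <- mean(counts[1:2]); sm[length(sm)] <- mean(counts[(length(sm) - 1):length(sm)])
  n <- length(sm)
  peaks <- which(c(FALSE, sm[2:(n - 1)] > sm[1:(n - 2)] &
                     sm[2:(n - 1)] > sm[3:n], FALSE))
  if (!length(peaks)) {
    # all mass in one bin (or a flat plateau): treat the maximum as the peak
    peaks <- which.max(sm)
  }
  isi_at <- 10^centres
  first <- peaks[isi_at[peaks] < params$isi_max_s][1]
  if (is.na(first)) return(NULL)
  later <- peaks[peaks > first]
  for (p2 in later) {
    between <- (first + 1):(p2 - 1)
    if (!length(between) || first + 1 > p2 - 1) next
    h_min <- min(sm[between])
    void <- 1 - h_min / sqrt(sm[first] * sm[p2])
    if (is.finite(void) && void >= params$void_threshold) {
      at_min <- between[which.min(sm[between])]
      return(10^centres[at_min])
    }
  }
  params$isi_max_s
}

#' Detect bursts in a spike train
#'
#' Maximal runs of consecutive ISIs strictly below the (logISI-derived) ISI
#' threshold that contain at least `min_spikes_in_burst` spikes become
#' bursts; consecutive bursts whose inter-burst interval (next start minus
#' previous end) is strictly below `merge_max_ibi_s` are then merged. The
#' result is sorted and non-overlapping.
#'
#' @inheritParams logisi_threshold
#' @param isi_threshold_s Optional explicit ISI threshold; computed with
#'   [logisi_threshold()] when `NULL`.
#' @return Data frame of class `burst_list` with columns `start_s`, `end_s`,
#'   `n_spikes`; attribute `isi_threshold_s` records the threshold used.
#' @export
detect_bursts <- function(train, params = burst_params(), isi_threshold_s = NULL) {
  if (is.null(isi_threshold_s)) isi_threshold_s <- logisi_threshold(train, params)
  empty <- data.frame(start_s = numeric(), end_s = numeric(), n_spikes = integer())
  if (is.null(isi_threshold_s) || length(train$times_s) < params$min_spikes_in_burst) {
    return(as_burst_list(empty, train, NA_real_))
  }
  t <- train$times_s
  # strict <, with the same 1 ns guard as the merge pass for ISIs that land
  # exactly on the threshold up to floating-point representation
  below <- diff(t) < isi_threshold_s - 1e-9
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= params$min_spikes_in_burst - 1L)
  if (!length(runs)) return(as_burst_list(empty, train, isi_threshold_s))
  b <- data.frame(
    start_s = t[starts[runs]],
    end_s = t[ends[runs] + 1L],
    n_spikes = r$lengths[runs] + 1L
  )
  b <- merge_bursts(b, params$merge_max_ibi_s)
  as_burst_list(b, train, isi_threshold_s)
}

# One merging pass repeated to a fixed point: while two consecutive bursts
# have gap (next.start - prev.end) < max_ibi, merge them (spanning interval,
# summed spike counts). Idempotent by construction. The strict-< comparison
# uses a 1 ns guard so a gap of exactly the merge bound (reachable by
# timestamps quantized at the sampling period) lands on the not-merged side
# despite floating-point representation error.
merge_bursts <- function(b, max_ibi_s) {
  if (nrow(b) < 2L) return(b)
  b <- b[order(b$start_s), , drop = FALSE]
  out <- b[1, , drop = FALSE]
  for (i in 2:nrow(b)) {
    last <- nrow(out)
    if (b$start_s[i] - out$end_s[last] < max_ibi_s - 1e-9) {
      out$end_s[last] <- max(out$end_s[last], b$end_s[i])
      out$n_spikes[last] <- out$n_spikes[last] + b$n_spikes[i]
    } else {
      out <- rbind(out, b[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

as_burst_list <- function(df, train, isi_threshold_s) {
  rownames(df) <- NULL
  class(df) <- c("burst_list", "data.frame")
  attr(df, "isi_threshold_s") <- isi_threshold_s
  attr(df, "duration_s") <- train$duration_s
  attr(df, "n_spikes_total") <- length(train$times_s)
  df
}

#' @export
print.burst_list <- function(x, ...) {
  cat("burst_list: ", nrow(x), " burst(s), ISI threshold ",
      signif(attr(x, "isi_threshold_s"), 4), " s\n", sep = "")
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10))
  invisible(x)
}

#' Per-electrode burst statistics
#'
#' Burst rate, mean burst duration, mean intra-burst spike frequency
#' (spikes / burst duration), mean spikes per burst and the percentage of
#' all spikes participating in bursts. Electrodes without bursts yield
#' `bursts_per_min = 0` and missing (NA) burst means: burst statistics are
#' defined only for electrodes exhibiting bursts. A burst whose first and
#' last spikes coincide has its duration floored at one sample period to
#' keep the in-burst frequency finite.
#'
#' @param bursts A `burst_list` from [detect_bursts()].
#' @param train The [spike_train()] the bursts came from.
#' @param duration_s Recording duration (defaults to the train's).
#' @param fs_hz Sampling rate used for the duration floor.
#' @return List of class `electrode_burst_stats`.
#' @export
electrode_stats <- function(bursts, train, duration_s = train$duration_s,
                            fs_hz = 12500) {
  stopifnot(duration_s > 0)
  n_b <- nrow(bursts)
  n_spk <- length(train$times_s)
  if (n_b == 0L) {
    out <- list(bursts_per_min = 0, mean_dur_s = NA_real_,
                mean_freq_in_burst = NA_real_, mean_spikes_in_burst = NA_real_,
                per_spikes_in_burst = if (n_spk) 0 else NA_real_)
  } else {
    dur <- pmax(bursts$end_s - bursts$start_s, 1 / fs_hz)
    out <- list(
      bursts_per_min = 60 * n_b / duration_s,
      mean_dur_s = mean(dur),
      mean_freq_in_burst = mean(bursts$n_spikes / dur),
      mean_spikes_in_burst = mean(bursts$n_spikes),
      per_spikes_in_burst = 100 * sum(bursts$n_spikes) / n_spk
    )
  }
  structure(out, class = "electrode_burst_stats")
}

#' Per-well statistics
#'
#' Aggregates one well's electrodes: noisy electrodes are discarded first;
#' `nae` counts the active electrodes (strict >10 spikes/min rule); the mean
#' firing rate is averaged over active electrodes only; burst statistics are
#' averaged over the (active) electrodes that exhibit bursts. A well with no
#' active electrode yields `nae = 0` and missing feature values, and is
#' omitted from written feature tables.
#'
#' @param trains Named list (by electrode label) of [spike_train()] objects.
#' @param duration_s Recording duration.
#' @param params A [burst_params()].
#' @param detection A [detection_params()] (for the activity rule).
#' @param noisy Character vector of electrode labels to discard.
#' @param sttc Optional precomputed well-mean STTC to carry through.
#' @return List of class `well_stats` with the per-well features.
#' @export
well_stats <- function(trains, duration_s, params = burst_params(),
                       detection = detection_params(), noisy = character(),
                       sttc = NA_real_) {
  trains <- trains[setdiff(names(trains), noisy)]
  active <- vapply(trains, classify_active, TRUE, params = detection)
  nae <- sum(active)
  if (nae == 0L) {
    return(structure(list(nae = 0L, mfr_by_active_electrodes = NA_real_,
                          bursts_per_min = NA_real_, mean_dur_s = NA_real_,
                          mean_freq_in_burst = NA_real_,
                          mean_spikes_in_burst = NA_real_,
                          per_spikes_in_burst = NA_real_, sttc = sttc),
                     class = "well_stats"))
  }
  act <- trains[active]
  rates <- vapply(act, function(tr) length(tr$times_s) / duration_s, 0)
  st <- lapply(act, function(tr) {
    electrode_stats(detect_bursts(tr, params), tr, duration_s)
  })
  bursting <- vapply(st, function(s) s$bursts_per_min > 0, TRUE)
  mean_of <- function(field) {
    if (!any(bursting)) return(NA_real_)
    mean(vapply(st[bursting], function(s) s[[field]], 0))
  }
  structure(list(
    nae = as.integer(nae),
    mfr_by_active_electrodes = mean(rates),
    bursts_per_min = mean_of("bursts_per_min"),
    mean_dur_s = mean_of("mean_dur_s"),
    mean_freq_in_burst = mean_of("mean_freq_in_burst"),
    mean_spikes_in_burst = mean_of("mean_spikes_in_burst"),
    per_spikes_in_burst = mean_of("per_spikes_in_burst"),
    sttc = sttc
  ), class = "well_stats")
}
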