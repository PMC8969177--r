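#' STTC parameters
#'
#' @param dt_s Coincidence window (+- delta t) in seconds; default 50 ms.
#' @return List of class `sttc_params`.
#' @export
sttc_params <- function(dt_s = 0.050) {
  stopifnot(dt_s > 0)
  structure(list(dt_s = dt_s), class = "sttc_params")
}

#' Spike time tiling coefficient
#'
#' A firing-rate-insensitive pairwise spike-train correlation:
#' `STTC = 1/2 * ((P_A - T_B) / (1 - P_A * T_B) + (P_B - T_A) / (1 - P_B * T_A))`
#' where `T_X` is the fraction of the analysis interval covered by the union
#' of +-dt windows around the spikes of train X (windows clipped at the
#' interval bounds, computed exactly by interval-union arithmetic) and `P_X`
#' is the proportion of X's spikes falling within +-dt of any spike of the
#' other train. Undefined terms (an empty train, or a degenerate
#' denominator) make the value missing (NA), never zero.
#'
#' @param train_a,train_b [spike_train()] objects.
#' @param params An [sttc_params()].
#' @param interval_s Analysis interval `c(start, end)`; defaults to
#'   `[0, duration_s]` of train_a.
#' @return Value in `[-1, 1]`, or `NA`.
#' @export
sttc <- function(train_a, train_b, params = sttc_params(),
                 interval_s = c(0, train_a$duration_s)) {
  a <- train_a$times_s; b <- train_b$times_s
  if (!length(a) || !length(b)) return(NA_real_)
  dt <- params$dt_s
  ta <- tiled_fraction(a, dt, interval_s)
  tb <- tiled_fraction(b, dt, interval_s)
  pa <- prop_within(a, b, dt)
  pb <- prop_within(b, a, dt)
  d1 <- 1 - pa * tb
  d2 <- 1 - pb * ta
  t1 <- if (abs(d1) < .Machine$double.eps) NA_real_ else (pa - tb) / d1
  t2 <- if (abs(d2) < .Machine$double.eps) NA_real_ else (pb - ta) / d2
  if (is.na(t1) && is.na(t2)) return(NA_real_)
  if (is.na(t1)) return(t2)
  if (is.na(t2)) return(t1)
  (t1 + t2) / 2
}

# Fraction of [interval] covered by the union of [t - dt, t + dt] windows,
# exact sorted-union arithmetic (times assumed sorted).
tiled_fraction <- function(times, dt, interval_s) {
  lo <- pmax(times - dt, interval_s[1])
  hi <- pmin(times + dt, interval_s[2])
  keep <- hi > lo
  lo <- lo[keep]; hi <- hi[keep]
  if (!length(lo)) return(0)
  total <- 0
  cur_lo <- lo[1]; cur_hi <- hi[1]
  if (length(lo) > 1L) {
    for (i in 2:length(lo)) {
      if (lo[i] <= cur_hi) {
        cur_hi <- max(cur_hi, hi[i])
      } else {
        total <- total + (cur_hi - cur_lo)
        cur_lo <- lo[i]; cur_hi <- hi[i]
      }
    }
  }
  total <- total + (cur_hi - cur_lo)
  total / (interval_s[2] - interval_s[1])
}

# Proportion of spikes in `x` lying within +-dt of any spike of `ref`.
prop_within <- function(x, ref, dt) {
  i <- findInterval(x, ref)
  d_prev <- ifelse(i >= 1L, x - ref[pmax(i, 1L)], Inf)
  d_next <- ifelse(i < length(ref), ref[pmin(i + 1L, length(ref))] - x, Inf)
  mean(pmin(d_prev, d_next) <= dt)
}

#' Pairwise STTC matrix for one well
#'
#' Computes the STTC for every unordered electrode pair (by default over
#' active electrodes only, mirroring the activity filter of the rest of the
#' pipeline), plus the well mean over defined pairs.
#'
#' @param trains Named list of [spike_train()] objects (>= 2 electrodes).
#' @param params An [sttc_params()].
#' @param active_only Restrict to active electrodes (default TRUE).
#' @param detection A [detection_params()] for the activity rule.
#' @return A `connectivity_matrix` (see [connectivity_matrix()]); the well
#'   mean is in attribute `well_mean` (NA when < 2 usable electrodes).
#' @export
sttc_matrix <- function(trains, params = sttc_params(), active_only = TRUE,
                        detection = detection_params()) {
  if (active_only) {
    trains <- trains[vapply(trains, classify_active, TRUE, params = detection)]
  }
  labels <- names(trains)
  n <- length(labels)
  m <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  if (n >= 1L) diag(m) <- 1
  if (n >= 2L) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      v <- sttc(trains[[i]], trains[[j]], params)
      m[i, j] <- m[j, i] <- v
    }
  }
  connectivity_matrix(m, "STTC")
}

#' Connectivity matrix
#'
#' Symmetric matrix of pairwise synchronization values over a well's
#' electrodes; the attribute `well_mean` is the mean over the defined
#' off-diagonal pairs (NA when fewer than one defined pair).
#'
#' @param m Symmetric numeric matrix with electrode dimnames.
#' @param estimator Estimator name ("STTC" or "CorSE").
#' @return Object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(m, estimator) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  vals <- m[upper.tri(m)]
  wm <- if (any(!is.na(vals))) mean(vals, na.rm = TRUE) else NA_real_
  structure(m, class = c("connectivity_matrix", class(m)),
            estimator = estimator, well_mean = wm)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("connectivity_matrix (", attr(x, "estimator"), "): ", nrow(x),
      " electrodes, well mean ", signif(attr(x, "well_mean"), 4), "\n", sep = "")
  invisible(x)
}

#' CorSE parameters
#'
#' @param window_s Sliding spectral window length (s); default 1 s Hann.
#' @param overlap_fraction Window overlap in `(0, 1)`; default 0.5.
#' @param map_threshold Connectivity-map strength threshold (strict >);
#'   default 0.7.
#' @return List of class `corse_params`.
#' @export
corse_params <- function(window_s = 1, overlap_fraction = 0.5,
                         map_threshold = 0.7) {
  stopifnot(window_s > 0, overlap_fraction > 0, overlap_fraction < 1,
            map_threshold >= 0, map_threshold <= 1)
  structure(list(window_s = window_s, overlap_fraction = overlap_fraction,
                 map_threshold = map_threshold), class = "corse_params")
}

#' Sliding-window spectral entropy
#'
#' Splits the trace into Hann-tapered windows of `window_s` with
#' `overlap_fraction` overlap; per window the periodogram is normalized to a
#' probability distribution `p_k` over its K frequency bins and the
#' normalized Shannon entropy `H = -sum(p_k ln p_k) / ln K` is returned.
#' H is 1 for a flat spectrum (white noise) and near 0 for a line spectrum.
#' A zero-power (constant) window yields `H = 0`.
#'
#' @param trace Numeric voltage trace (at least one window long).
#' @param fs_hz Sampling rate.
#' @param params A [corse_params()].
#' @return Numeric vector of entropies in `[0, 1]`, one per window.
#' @export
spectral_entropy_series <- function(trace, fs_hz, params = corse_params()) {
  n_win <- round(params$window_s * fs_hz)
  if (n_win < 8L) stop("window too short: needs >= 8 samples")
  if (length(trace) < n_win) stop("trace shorter than one spectral window")
  hop <- max(1L, round(n_win * (1 - params$overlap_fraction)))
  starts <- seq(1L, length(trace) - n_win + 1L, by = hop)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, n_win - 1) / (n_win - 1))
  k_half <- floor(n_win / 2) + 1L
  vapply(starts, function(s) {
    seg <- trace[s:(s + n_win - 1L)]
    seg <- (seg - mean(seg)) * taper
    p <- Mod(fft(seg)[seq_len(k_half)])^2
    tot <- sum(p)
    if (tot <= 0) return(0)
    p <- p / tot
    p <- p[p > 0]
    -sum(p * log(p)) / log(k_half)
  }, 0)
}

#' Correlated spectral entropy (CorSE)
#'
#' Functional connectivity between two raw voltage traces: the Pearson
#' correlation of their sliding-window spectral entropy series. Correlated
#' changes in spectral content (e.g. a shared bursting envelope) drive the
#' value towards 1; the magnitude is the connectivity strength. A constant
#' entropy series (dead channel) makes the value missing.
#'
#' @param trace_a,trace_b Equal-length voltage traces.
#' @param fs_hz Sampling rate.
#' @param params A [corse_params()].
#' @return Signed correlation in `[-1, 1]`, or `NA`.
#' @export
corse <- function(trace_a, trace_b, fs_hz, params = corse_params()) {
  if (length(trace_a) != length(trace_b)) stop("traces must have equal length")
  ea <- spectral_entropy_series(trace_a, fs_hz, params)
  eb <- spectral_entropy_series(trace_b, fs_hz, params)
  corse_from_entropy(ea, eb)
}

corse_from_entropy <- function(ea, eb) {
  if (sd(ea) == 0 || sd(eb) == 0) return(NA_real_)
  cor(ea, eb)
}

#' Well-level CorSE
#'
#' Computes each electrode's entropy series once, correlates all unordered
#' pairs, and averages the defined pairwise values into the well's overall
#' connectivity strength.
#'
#' @param traces Named list of equal-length voltage traces (>= 2).
#' @param fs_hz Sampling rate.
#' @param params A [corse_params()].
#' @return A `connectivity_matrix` with estimator "CorSE"; well mean in
#'   attribute `well_mean`.
#' @export
well_corse <- function(traces, fs_hz, params = corse_params()) {
  labels <- names(traces)
  n <- length(labels)
  if (n < 2L) stop("well_corse needs at least 2 electrodes")
  ent <- lapply(traces, spectral_entropy_series, fs_hz = fs_hz, params = params)
  m <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  diag(m) <- 1
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- corse_from_entropy(ent[[i]], ent[[j]])
  }
  connectivity_matrix(m, "CorSE")
}

#' Connectivity map edge list
#'
#' Thresholds a connectivity matrix into the edge list of the most robust
#' network participants: unordered pairs whose connectivity strength
#' (absolute value) strictly exceeds `threshold`. Node positions follow the
#' electrode grid layout.
#'
#' @param m A `connectivity_matrix`.
#' @param threshold Strength threshold in `[0, 1]` (strict >); defaults to
#'   0.7 for CorSE maps.
#' @return Data frame with columns `from`, `to`, `strength`; attribute
#'   `nodes` holds the [electrode_positions()] layout.
#' @export
connectivity_map <- function(m, threshold = 0.7) {
  stopifnot(threshold >= 0, threshold <= 1)
  labels <- rownames(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  strength <- abs(m[idx])
  keep <- !is.na(strength) & strength > threshold
  edges <- data.frame(from = labels[idx[keep, 1]], to = labels[idx[keep, 2]],
                      strength = strength[keep], stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  attr(edges, "nodes") <- electrode_positions(labels)
  edges
}
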