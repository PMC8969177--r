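fs <- 12500

test_that("band-pass filter rejects out-of-band and passes in-band tones", {
  t <- seq(0, 1, by = 1 / fs)
  trim <- 2000:10000  # avoid filtfilt edge transients
  lo <- sin(2 * pi * 100 * t)
  hi <- sin(2 * pi * 1000 * t)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(bandpass_filter(lo, fs)[trim]), 0.05 * rms(lo[trim]))
  expect_lt(abs(rms(bandpass_filter(hi, fs)[trim]) / rms(hi[trim]) - 1), 0.05)
  expect_equal(bandpass_filter(numeric(100) , fs), numeric(100))
  expect_error(bandpass_filter(hi, 5000), "sampling rate too low")
})

test_that("robust noise estimator is consistent, zero-safe and equivariant", {
  set.seed(11)
  x <- rnorm(60 * fs, sd = 10e-6)
  expect_lt(abs(estimate_noise_sd(x) - 10e-6) / 10e-6, 0.02)
  expect_identical(estimate_noise_sd(numeric(10)), 0)
  expect_equal(estimate_noise_sd(2 * x), 2 * estimate_noise_sd(x))
  expect_error(estimate_noise_sd(numeric()), "empty")
})

test_that("threshold detection aligns events and enforces the 4.5 sigma rule", {
  # one 50 uV template on a silent trace, sigma forced to 10 uV
  tr <- fixture_trace(0.1, 0.3, amplitude_v = 50e-6, noise_sd_v = 0)
  ev <- threshold_detect(tr, fs, sigma_v = 10e-6)
  expect_length(ev$times_s, 1L)
  expect_lt(abs(ev$times_s - 0.1), 1e-3)
  expect_equal(ev$amplitudes_v, 50e-6)
  expect_equal(ev$threshold_v / ev$sigma_v, 4.5)
  # 3 sigma pulses stay below threshold
  lowtr <- fixture_trace(c(0.05, 0.15), 0.3, amplitude_v = 30e-6, noise_sd_v = 0)
  expect_length(threshold_detect(lowtr, fs, sigma_v = 10e-6)$times_s, 0L)
  # the ratio holds on arbitrary noisy input too
  set.seed(3)
  ev2 <- threshold_detect(rnorm(fs, sd = 5e-6), fs)
  expect_equal(ev2$threshold_v / ev2$sigma_v, 4.5)
})

test_that("Teager energy of a sinusoid is the analytic constant", {
  f0 <- 700
  x <- 2 * sin(2 * pi * f0 * (0:999) / fs)
  psi <- teager_energy(x)
  expect_equal(psi[3:998], rep(4 * sin(2 * pi * f0 / fs)^2, 996),
               tolerance = 1e-10)
  expect_equal(teager_energy(numeric(5)), numeric(5))
})

test_that("SWT detail coefficients match the reference decomposition", {
  # fixture values computed with an independent wavelet implementation
  x <- c(1.690526, -0.465937, 0.03282, 0.407516, -0.788923, 0.002066,
         -0.00089, -1.754724, 1.017658, 0.600499, -0.625429, -0.171548,
         0.505299, -0.261356, -0.242749, -1.453241)
  d <- swt_details(x, 2L, "sym4")
  d1_ref <- c(-2.1845346333, 1.2511396373, -0.0549243056, -0.6313247687,
              0.8630017007, -0.5911974911, -0.4616145512, 1.8458406393,
              -1.5886090839, -0.2294303277, 0.974762661, -0.0581896967,
              -0.6936157835, 0.2810223298, -0.167287437, 1.4449611106)
  d2_ref <- c(-0.5093048649, 0.1472019723, 0.0525051072, 0.1307118165,
              0.069425082, 0.6484543037, 0.681275522, -1.0344307159,
              -1.0022441573, 0.6989402182, 0.3413423399, -0.7421076617,
              0.105866683, 1.259368162, 0.2611342882, -1.1081380953)
  expect_equal(d$d1, d1_ref, tolerance = 1e-9)
  expect_equal(d$d2, d2_ref, tolerance = 1e-9)
  expect_error(swt_details(x[1:3], 2L), "too short")
  expect_error(swt_details(x, 2L, "haar"), "unknown wavelet")
})

test_that("SWTTEO energy is non-negative and peaks at embedded spikes", {
  expect_equal(swtteo_energy(numeric(4096), fs), numeric(4096))
  tr <- fixture_trace(0.2, 0.4, amplitude_v = 50e-6, noise_sd_v = 1e-6, seed = 6)
  e <- swtteo_energy(tr, fs)
  expect_length(e, length(tr))
  expect_true(all(e >= 0))
  expect_lt(abs((which.max(e) - 1) / fs - 0.2), 1e-3)
})

test_that("hybrid detector is accurate at high SNR and never adds events", {
  truth <- seq(0.25, 19.75, length.out = 100)
  tr <- fixture_trace(truth, 20, amplitude_v = 40e-6, noise_sd_v = 3e-6, seed = 8)
  st <- detect_spikes(tr, fs)
  m <- match_counts(st$times_s, truth)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
  # cancellation only removes: detected times are a subset of threshold times
  filt <- bandpass_filter(tr, fs)
  thr_times <- threshold_detect(filt, fs)$times_s
  expect_lte(length(st$times_s), length(thr_times))
  expect_true(all(vapply(st$times_s,
                         function(t) min(abs(thr_times - t)) < 1e-9, TRUE)))
  # silent trace -> empty train
  expect_length(detect_spikes(fixture_trace(numeric(), 1, seed = 2), fs)$times_s,
                0L)
})

test_that("detection is equivariant under time translation", {
  truth <- c(0.3, 0.7, 1.1)
  tr <- fixture_trace(truth, 2, amplitude_v = 50e-6, noise_sd_v = 2e-6, seed = 12)
  shift_s <- 0.2
  shifted <- c(numeric(round(shift_s * fs)), tr)[seq_along(tr)]
  t0 <- detect_spikes(tr, fs)$times_s
  t1 <- detect_spikes(shifted, fs)$times_s
  keep <- t0 + shift_s < 2 - 0.1
  expect_equal(t1[seq_len(sum(keep))], (t0 + shift_s)[keep], tolerance = 1e-3)
})

test_that("activity rule is a strict >10 spikes-per-minute cut", {
  mk <- function(n) spike_train(seq(1, 59, length.out = n), 60)
  expect_false(classify_active(mk(10)))
  expect_true(classify_active(mk(11)))
  expect_false(classify_active(spike_train(numeric(), 60)))
})

test_that("waveform cutouts have fixed extent and drop edge spikes", {
  truth <- c(0.0, 0.15)
  tr <- fixture_trace(truth[2], 0.3, amplitude_v = 50e-6, noise_sd_v = 0)
  tr[1:5] <- 1e-4  # fake event at t = 0
  st <- spike_train(truth, 0.3)
  expect_message(ws <- extract_waveforms(tr, st, 1.2, 2, fs), "dropped")
  expect_equal(dim(ws), c(1L, round(3.2e-3 * fs) + 1L))
  expect_equal(attr(ws, "n_dropped"), 1L)
  # noiseless cutout reproduces the scaled template around its peak
  tpl <- spike_template(fs)
  centre <- round(0.15 * fs) + 1L
  rel <- (centre - round(1.2e-3 * fs)):(centre + round(2e-3 * fs))
  expect_equal(as.numeric(ws[1, ]), tr[rel])
  expect_equal(min(ws[1, ]), -50e-6, tolerance = 1e-12)
})
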