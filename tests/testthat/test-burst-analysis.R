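burst_train <- function(times) spike_train(times, 60)

test_that("logISI threshold brackets the modes of a bimodal train", {
  # 12 bursts of 6 spikes at 10 ms ISI, 2 s apart
  starts <- seq(2, 46, by = 4)
  times <- as.vector(outer((0:5) * 0.01, starts, "+"))
  thr <- logisi_threshold(burst_train(sort(times)))
  expect_gt(thr, 0.01)
  expect_lt(thr, 2)
})

test_that("unimodal slow trains and tiny trains yield no threshold", {
  set.seed(31)
  pois <- generate_train(train_model("tonic_poisson", 0.2), 600, seed = 31)
  expect_null(logisi_threshold(pois))
  expect_null(logisi_threshold(burst_train(c(1, 2))))
  expect_null(logisi_threshold(burst_train(5)))
})

test_that("burst detection enforces the 5-spike minimum", {
  b5 <- detect_bursts(burst_train(10 + (0:4) * 0.01))
  expect_equal(nrow(b5), 1L)
  expect_equal(b5$n_spikes, 5L)
  expect_equal(b5$start_s, 10)
  expect_equal(b5$end_s, 10.04)
  b4 <- detect_bursts(burst_train(10 + (0:3) * 0.01))
  expect_equal(nrow(b4), 0L)
})

test_that("bursts merge below a 100 ms inter-burst interval, strict", {
  two_clusters <- function(gap_s) {
    c1 <- 10 + (0:7) * 0.005
    burst_train(c(c1, max(c1) + gap_s + (0:7) * 0.005))
  }
  merged <- detect_bursts(two_clusters(0.050))
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$n_spikes, 16L)
  apart <- detect_bursts(two_clusters(0.150))
  expect_equal(nrow(apart), 2L)
  expect_equal(apart$n_spikes, c(8L, 8L))
  boundary <- detect_bursts(two_clusters(0.100))
  expect_equal(nrow(boundary), 2L)
})

test_that("detection agrees with the brute-force run oracle on random trains", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    times <- sort(runif(n, 0, 20))
    thr <- runif(1, 0.02, 0.3)
    got <- detect_bursts(spike_train(times, 20), isi_threshold_s = thr)
    want <- burst_oracle(times, thr, 5L, 0.100)
    expect_equal(got$start_s, want$start_s)
    expect_equal(got$end_s, want$end_s)
    expect_equal(got$n_spikes, want$n_spikes)
  }
})

test_that("merging is idempotent and bursts never overlap", {
  set.seed(23)
  for (i in 1:25) {
    times <- sort(runif(80, 0, 30))
    b <- detect_bursts(spike_train(times, 30), isi_threshold_s = 0.2)
    if (nrow(b) >= 2L) {
      expect_true(all(b$start_s[-1] - b$end_s[-nrow(b)] >= 0.100 - 1e-9))
      again <- meapipe:::merge_bursts(as.data.frame(b), 0.100)
      expect_equal(again$start_s, b$start_s)
      expect_equal(again$n_spikes, b$n_spikes)
    }
    expect_true(all(b$end_s >= b$start_s))
  }
})

test_that("electrode statistics match hand arithmetic", {
  # 1 burst (5 spikes over 40 ms) among 10 spikes total in 60 s
  times <- c(10 + (0:4) * 0.01, 20, 25, 30, 35, 40)
  tr <- burst_train(sort(times))
  b <- detect_bursts(tr, isi_threshold_s = 0.05)
  st <- electrode_stats(b, tr)
  expect_equal(st$bursts_per_min, 1)
  expect_equal(st$mean_dur_s, 0.04)
  expect_equal(st$mean_spikes_in_burst, 5)
  expect_equal(st$mean_freq_in_burst, 125)
  expect_equal(st$per_spikes_in_burst, 50)
  # burst-less electrode: zero rate, undefined burst means
  none <- electrode_stats(detect_bursts(burst_train(c(1, 30))), burst_train(c(1, 30)))
  expect_equal(none$bursts_per_min, 0)
  expect_true(is.na(none$mean_dur_s))
  expect_equal(none$per_spikes_in_burst, 0)
  # all spikes in bursts -> 100 %
  all_in <- burst_train(10 + (0:9) * 0.01)
  st2 <- electrode_stats(detect_bursts(all_in, isi_threshold_s = 0.05), all_in)
  expect_equal(st2$per_spikes_in_burst, 100)
})

test_that("per-spike participation is always a percentage in [0, 100]", {
  set.seed(41)
  for (i in 1:20) {
    times <- sort(runif(sample(5:100, 1), 0, 60))
    tr <- burst_train(times)
    st <- electrode_stats(detect_bursts(tr, isi_threshold_s = 0.15), tr)
    expect_gte(st$per_spikes_in_burst, 0)
    expect_lte(st$per_spikes_in_burst, 100)
  }
})

test_that("well statistics honour activity, bursting and noisy filters", {
  burst_times <- 5 + (0:29) * 0.01
  active_bursty <- burst_train(c(burst_times, seq(10, 55, by = 2)))
  silent <- spike_train(numeric(), 60)
  trains <- list("11" = active_bursty, "12" = active_bursty, "13" = silent)
  ws <- well_stats(trains, 60)
  expect_equal(ws$nae, 2L)
  expect_equal(ws$mfr_by_active_electrodes, length(active_bursty$times_s) / 60)
  el <- electrode_stats(detect_bursts(active_bursty), active_bursty)
  expect_equal(ws$mean_spikes_in_burst, el$mean_spikes_in_burst)
  # noisy-listed electrode is excluded from nae and the means
  ws_noisy <- well_stats(trains, 60, noisy = "12")
  expect_equal(ws_noisy$nae, 1L)
  # no active electrodes -> nae 0 and missing features
  ws0 <- well_stats(list("11" = silent), 60)
  expect_equal(ws0$nae, 0L)
  expect_true(is.na(ws0$mfr_by_active_electrodes))
})
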