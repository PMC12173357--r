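## local clean PPG renderer with controllable onsets (uses the package's
## pulse kernel so the analytic onset/peak geometry matches the generator)
render_ppg <- function(onsets, duration, fs = 300, amps = rep(1, length(onsets))) {
  t <- (seq_len(duration * fs) - 1) / fs
  x <- numeric(length(t))
  for (i in seq_along(onsets))
    x <- x + amps[i] * respifuse:::ppg_kernel(t - onsets[i])
  x
}

test_that("clean 60 bpm ECG yields one R peak per second within 10 ms", {
  cfg <- clean_cfg(duration = 30, hr = 60)
  ecg <- generate_ecg(cfg)
  r <- pan_tompkins_rpeaks(ecg$samples, 300)
  expect_gte(length(r), 29)
  expect_lte(length(r), 31)
  m <- match_events((r - 1) / 300, ecg$truth$r_times, tol_s = 0.010)
  expect_equal(m$recall, 1)
  expect_lte(m$max_err, 0.010)
})

test_that("flat or too-short ECG raises the no-beat / short-window errors", {
  expect_error(pan_tompkins_rpeaks(rep(0, 9000), 300),
               class = "respifuse_no_beat_error")
  expect_error(pan_tompkins_rpeaks(rnorm(300), 300),
               class = "respifuse_short_window_error")
})

test_that("beat detection is exact on clean records across heart rates", {
  for (hr in c(50, 80, 120)) {
    cfg <- clean_cfg(duration = 30, hr = hr)
    ecg <- generate_ecg(cfg)
    r <- pan_tompkins_rpeaks(ecg$samples, 300)
    m <- match_events((r - 1) / 300, ecg$truth$r_times, tol_s = 0.05)
    f1 <- 2 * m$recall * m$precision / (m$recall + m$precision)
    expect_equal(f1, 1, info = paste("hr", hr))
    ib <- diff((r - 1) / 300)
    expect_true(all(ib >= 0.3 & ib <= 2.0))
  }
})

test_that("R detection stays >= 99% sensitive and precise at 20 dB SNR", {
  cfg <- noisy_cfg(duration = 60, hr = 80, snr = 20)
  ecg <- generate_ecg(cfg)
  r <- pan_tompkins_rpeaks(ecg$samples, 300)
  m <- match_events((r - 1) / 300, ecg$truth$r_times, tol_s = 0.05)
  expect_gte(m$recall, 0.99)
  expect_gte(m$precision, 0.99)
})

test_that("Q wave is the minimum of the 200 ms interval before R", {
  fs <- 300
  ## V-shaped dip 80 ms before each R on an otherwise flat signal
  ecg <- rep(0, 10 * fs)
  r <- as.integer(seq(2, 9, by = 1) * fs)
  for (ri in r) {
    dip <- ri - round(0.080 * fs)
    ecg[(dip - 6):(dip + 6)] <- -c(0:6, 5:0) / 6   # V with minimum at dip
    ecg[ri] <- 1
  }
  q <- locate_q_waves(ecg, r, fs)
  expect_equal(as.integer(q), r - round(0.080 * fs))
  expect_identical(attr(q, "r_retained"), r)

  ## monotonically increasing ramp before R: argmin at the left edge
  ramp <- as.numeric(seq_len(10 * fs))
  q2 <- locate_q_waves(ramp, r[1], fs)
  expect_equal(as.integer(q2), r[1] - round(0.2 * fs) + 1L)
})

test_that("beats too close to the window start are dropped with a message", {
  ecg <- rnorm(900)
  expect_message(q <- locate_q_waves(ecg, c(10L, 400L), 300), "dropped")
  expect_length(q, 1)
  expect_identical(attr(q, "r_retained"), 400L)
})

test_that("clean 75 bpm PPG pulse train yields one trough per pulse within 20 ms", {
  cfg <- clean_cfg(duration = 30, hr = 75)
  ppg <- generate_ppg(cfg)
  tr <- detect_ppg_troughs(ppg$samples, 300)
  expect_gte(length(tr), 36)
  expect_lte(length(tr), 38)
  m <- match_events((tr - 1) / 300, ppg$truth$onset_times, tol_s = 0.020)
  expect_gte(m$recall, (length(ppg$truth$onset_times) - 1) /
                        length(ppg$truth$onset_times))
  expect_lte(m$max_err, 0.020)
})

test_that("constant PPG raises a no-beat error", {
  expect_error(detect_ppg_troughs(rep(1, 9000), 300),
               class = "respifuse_no_beat_error")
})

test_that("a missing pulse reduces the trough count by exactly one", {
  onsets <- seq(0.5, 19, by = 0.75)
  full <- render_ppg(onsets, 20)
  gap <- render_ppg(onsets[-10], 20)
  n_full <- length(detect_ppg_troughs(full, 300))
  n_gap <- length(detect_ppg_troughs(gap, 300))
  expect_equal(n_full - n_gap, 1L)
})

test_that("systolic peak is the maximum within 125 ms after the trough", {
  fs <- 300
  onsets <- seq(0.5, 9, by = 0.8)
  x <- render_ppg(onsets, 10)
  tr <- detect_ppg_troughs(x, fs)
  pk <- locate_systolic_peaks(x, tr, fs)
  ## analytic apex of the pulse kernel
  tp <- 0.030 * log(1 + 0.250 / 0.030)
  errs <- abs((pk - 1) / fs - ((attr(pk, "troughs_retained") - 1) / fs + tp))
  expect_lte(max(errs), 0.015)
  expect_true(all(pk - attr(pk, "troughs_retained") <= round(0.125 * fs)))

  ## monotonically decreasing after the trough: first sample is the peak
  y <- c(5, 4, 10, rev(seq_len(60)) / 10)
  pk2 <- locate_systolic_peaks(y, 2L, fs)
  expect_equal(as.integer(pk2), 3L)

  ## trough at the last sample: pair dropped
  expect_message(pk3 <- locate_systolic_peaks(y, c(2L, length(y)), fs), "dropped")
  expect_length(pk3, 1)
})

test_that("detect_fiducials returns a consistent paired set", {
  cfg <- clean_cfg(duration = 30)
  rec <- generate_record(cfg)
  fid <- suppressMessages(
    detect_fiducials(rec$channels$ecg$samples, rec$channels$ppg$samples, 300))
  expect_s3_class(fid, "fiducial_set")
  expect_length(fid$q_waves, length(fid$r_peaks))
  expect_length(fid$ppg_peaks, length(fid$ppg_troughs))
  expect_true(all(diff(fid$r_peaks) > 0))
  expect_true(all(fid$r_peaks - fid$q_waves <= 0.2 * 300))
  expect_true(all(fid$ppg_peaks - fid$ppg_troughs <= round(0.125 * 300)))
})
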