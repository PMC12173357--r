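make_tone_record <- function(duration, fs = 300) {
  t <- (seq_len(duration * fs) - 1) / fs
  waveform_record(list(
    ecg = list(samples = sin(2 * pi * 1.2 * t), fs = fs),
    ppg = list(samples = cos(2 * pi * 1.2 * t), fs = fs)
  ), subject_id = "tone")
}

test_that("CSV record round-trip is sample-identical", {
  rec <- generate_record(clean_cfg(duration = 40, seed = 5))
  dir <- withr::local_tempdir()
  write_record_csv(rec, dir)
  rec2 <- load_record(dir, format = "csv")
  expect_equal(rec2$channels$ecg$samples, rec$channels$ecg$samples)
  expect_equal(rec2$channels$ppg$samples, rec$channels$ppg$samples)
  expect_equal(rec2$channels$ecg$fs, 300)
  expect_true(all(c("resp", "rr_ref") %in% names(rec2$channels)))
})

test_that("non-finite samples and missing channels are data errors", {
  dir <- withr::local_tempdir()
  write.csv(data.frame(time = 0:9 / 125, value = c(1:9, NA)),
            file.path(dir, "ecg.csv"), row.names = FALSE)
  write.csv(data.frame(time = 0:9 / 125, value = 1:10),
            file.path(dir, "ppg.csv"), row.names = FALSE)
  expect_error(load_record(dir), class = "respifuse_data_error")

  dir2 <- withr::local_tempdir()
  write.csv(data.frame(time = 0:9 / 125, value = 1:10),
            file.path(dir2, "ecg.csv"), row.names = FALSE)
  expect_error(load_record(dir2), class = "respifuse_channel_error")
})

test_that("CSV sampling rate is inferred from the time column", {
  dir <- withr::local_tempdir()
  n <- 250
  for (ch in c("ecg", "ppg"))
    write.csv(data.frame(time = (0:(n - 1)) / 125, value = rnorm(n)),
              file.path(dir, paste0(ch, ".csv")), row.names = FALSE)
  rec <- load_record(dir)
  expect_equal(rec$channels$ecg$fs, 125)
})

test_that("minimal WFDB reader recovers format-16 signals", {
  dir <- withr::local_tempdir()
  n <- 600
  ecg <- round(sin(2 * pi * 1.2 * (0:(n - 1)) / 300) * 1000)
  ppg <- round(cos(2 * pi * 1.0 * (0:(n - 1)) / 300) * 1000)
  inter <- as.integer(rbind(ecg, ppg))
  writeBin(inter, file.path(dir, "rec.dat"), size = 2, endian = "little")
  writeLines(c("rec 2 300 600",
               "rec.dat 16 200 12 0 0 0 0 ECG",
               "rec.dat 16 200 12 0 0 0 0 PLETH"),
             file.path(dir, "rec.hea"))
  rec <- load_record(file.path(dir, "rec"), format = "wfdb")
  expect_equal(rec$channels$ecg$samples, ecg / 200)
  expect_equal(rec$channels$ppg$samples, ppg / 200)
  expect_equal(rec$channels$ecg$fs, 300)
})

test_that("window counts follow the sliding-step arithmetic", {
  rec <- make_tone_record(480)
  expect_length(segment_windows(rec, pipeline_config(step_fraction = 1)), 16)
  # starts 15k with 15k + 30 <= 480  =>  k = 0..30
  w <- segment_windows(rec, pipeline_config(step_fraction = 0.5))
  expect_length(w, 31)
  starts <- vapply(w, `[[`, 0, "start_time")
  expect_equal(starts, seq(0, 450, by = 15))
  expect_warning(out <- segment_windows(make_tone_record(20), pipeline_config()),
                 "shorter")
  expect_length(out, 0)
})

test_that("windows are resampled to the target rate", {
  t <- (seq_len(60 * 125) - 1) / 125
  rec <- waveform_record(list(
    ecg = list(samples = sin(2 * pi * 5 * t), fs = 125),
    ppg = list(samples = cos(2 * pi * 5 * t), fs = 125)
  ))
  w <- segment_windows(rec, pipeline_config())[[1]]
  expect_length(w$ecg, 9000)
  t300 <- (seq_len(9000) - 1) / 300
  i <- 200:8800   # interior, away from interpolation edges
  relerr <- sqrt(sum((w$ecg[i] - sin(2 * pi * 5 * t300[i]))^2) /
                 sum(sin(2 * pi * 5 * t300[i])^2))
  expect_lt(relerr, 0.01)
})

test_that("resampling an in-band tone up and back is near-lossless", {
  fs <- 125
  t <- (seq_len(30 * fs) - 1) / fs
  x <- sin(2 * pi * 5 * t)
  y <- resample_uniform(resample_uniform(x, 125, 300), 300, 125)
  i <- 50:(length(y) - 50)
  expect_lt(sqrt(sum((y[i] - x[i])^2) / sum(x[i]^2)), 0.01)
})

test_that("preprocessing kills DC and passes zero through", {
  cfg <- pipeline_config()
  expect_equal(preprocess(rep(0, 9000), 300, cfg), rep(0, 9000))
  y <- preprocess(rep(2.5, 9000), 300, cfg)
  expect_lt(max(abs(y[1000:8000])), 2.5e-3)
})

test_that("0.01 Hz drift is attenuated per the squared Butterworth response", {
  cfg <- pipeline_config()
  fs <- 300
  t <- (seq_len(200 * fs) - 1) / fs
  y <- preprocess(sin(2 * pi * 0.01 * t), fs, cfg)
  mid <- y[20000:40000]
  ## analytic zero-phase magnitude at f/fc = 0.2: ((0.2^3)/sqrt(1+0.2^6))^2
  h2 <- (0.2^3 / sqrt(1 + 0.2^6))^2
  expect_lt(max(abs(mid)), 0.01)          # >= 40 dB
  expect_lt(max(abs(mid)), 3 * h2)
  expect_gt(max(abs(mid)), h2 / 3)
})

test_that("preprocessing is linear", {
  cfg <- pipeline_config()
  set.seed(11)
  x <- rnorm(6000); y <- rnorm(6000)
  lhs <- preprocess(2 * x + 3 * y, 300, cfg)
  rhs <- 2 * preprocess(x, 300, cfg) + 3 * preprocess(y, 300, cfg)
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-6)
})

test_that("too-short windows raise a short-window error", {
  expect_error(preprocess(rnorm(50), 300, pipeline_config()),
               class = "respifuse_short_window_error")
})
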