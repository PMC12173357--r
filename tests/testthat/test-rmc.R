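## hand-built window: spikes of known amplitude at known times
toy_ecg_fiducials <- function(r_times, r_amp, q_amp, fs = 300, duration = 12) {
  x <- rep(0, duration * fs)
  r <- as.integer(round(r_times * fs)) + 1L
  q <- r - as.integer(round(0.05 * fs))
  x[r] <- r_amp
  x[q] <- q_amp
  list(x = x, fid = fiducial_set(r, q, integer(0), integer(0), fs))
}

test_that("ECG components follow their defining arithmetic", {
  tw <- toy_ecg_fiducials(c(1.0, 1.8, 2.6, 3.4), r_amp = 1.0, q_amp = -0.2)
  rm <- extract_ecg_rmcs(tw$x, tw$fid, 300)
  expect_equal(rm$EAM$values, rep(1.2, 4))
  expect_equal(rm$EBW$values, rep(0.4, 4))
  expect_equal(rm$EFM$values, rep(0.8, 3), tolerance = 1e-9)
  expect_equal(rm$EFM$times, c(1.4, 2.2, 3.0), tolerance = 1e-9)
  expect_equal(rm$EAM$times, c(1.0, 1.8, 2.6, 3.4), tolerance = 1e-9)
})

test_that("PPG components follow their defining arithmetic", {
  fs <- 300
  x <- rep(0, 4 * fs)
  tr <- as.integer(round(c(0.5, 1.3, 2.1, 2.9) * fs)) + 1L
  pk <- tr + as.integer(round(0.1 * fs))
  x[tr] <- 0.1
  x[pk] <- 0.9
  fid <- fiducial_set(integer(0), integer(0), tr, pk, fs)
  rm <- extract_ppg_rmcs(x, fid, fs)
  expect_equal(rm$PAM$values, rep(0.8, 4))
  expect_equal(rm$PBW$values, rep(0.5, 4))
  expect_equal(rm$PFM$values, rep(0.8, 3), tolerance = 1e-9)
})

test_that("fewer than four beats is an insufficient-beats error", {
  tw <- toy_ecg_fiducials(c(1.0, 1.8, 2.6), r_amp = 1, q_amp = 0)
  expect_error(extract_ecg_rmcs(tw$x, tw$fid, 300),
               class = "respifuse_insufficient_beats_error")
})

test_that("AM series are invariant to a constant raw-signal offset", {
  tw <- toy_ecg_fiducials(seq(1, 8, by = 0.8), r_amp = 1, q_amp = -0.3)
  rm1 <- extract_ecg_rmcs(tw$x, tw$fid, 300)
  rm2 <- extract_ecg_rmcs(tw$x + 5, tw$fid, 300)
  expect_equal(rm2$EAM$values, rm1$EAM$values)
  expect_equal(rm2$EBW$values, rm1$EBW$values + 5)
  ## after the centering built into resampling both are offset-invariant
  cfg <- pipeline_config()
  expect_equal(resample_beat_series(rm2$EBW, cfg)$values,
               resample_beat_series(rm1$EBW, cfg)$values, tolerance = 1e-9)
})

test_that("uniform resampling centers constants and reproduces polynomials", {
  cfg <- pipeline_config()
  bs <- beat_series("EAM", seq(0.5, 25, by = 0.8), rep(3.7, 31))
  expect_equal(resample_beat_series(bs, cfg)$values,
               rep(0, length(resample_beat_series(bs, cfg)$values)))

  tt <- seq(0.4, 28, by = 0.75)
  line <- beat_series("PBW", tt, 0.3 * tt - 1.1)
  us <- resample_beat_series(line, cfg)
  grid <- us$t0 + (seq_along(us$values) - 1) / cfg$beat_series_fs
  truth <- 0.3 * grid - 1.1
  expect_equal(us$values, truth - mean(truth), tolerance = 1e-9)
})

test_that("a respiratory tone sampled at beat times keeps its frequency", {
  set.seed(4)
  tt <- cumsum(runif(40, 0.75, 0.95))       # ~70 bpm irregular beats
  bs <- beat_series("PAM", tt, sin(2 * pi * 0.25 * tt))
  us <- resample_beat_series(bs, pipeline_config())
  pk <- spectral_peak(us$values, us$fs, n_pad = 2^14)
  expect_equal(pk$freq, 0.25, tolerance = 0.02)
})

test_that("interval series stay within physiologic bounds on synthetic records", {
  rec <- generate_record(clean_cfg(duration = 40))
  fid <- suppressMessages(
    detect_fiducials(rec$channels$ecg$samples, rec$channels$ppg$samples, 300))
  rm <- extract_ecg_rmcs(rec$channels$ecg$samples, fid, 300)
  pm <- extract_ppg_rmcs(rec$channels$ppg$samples, fid, 300)
  expect_true(all(rm$EFM$values >= 0.3 & rm$EFM$values <= 2.0))
  expect_true(all(pm$PFM$values >= 0.3 & pm$PFM$values <= 2.0))
})

test_that("each modulation mechanism drives its component family and not the decoupled ones", {
  ## Enable one mechanism at a time. `hot` families must show a dominant
  ## in-band peak (peak-to-median ratio > 5) at the respiratory frequency;
  ## `cold` families -- those with no physical pathway from the mechanism --
  ## must not. Families coupled by construction are left unasserted: QRS
  ## scaling moves EAM and EBW together (shared mechanism), and interval
  ## modulation leaks weakly into PAM/PBW through the overlap of diastolic
  ## tails at varying beat spacing.
  base <- list(duration = 90, hr_bpm = 80, rr_bpm = 15, am_depth = 0,
               fm_depth = 0, bw_amp = 0, ppg_am_depth = 0, ppg_fm_depth = 0,
               ppg_bw_amp = 0, noise_snr_db = Inf, seed = 2)
  cases <- list(
    list(set = c(am_depth = 0.2), hot = c("EAM", "EBW"),
         cold = c("EFM", "PAM", "PFM", "PBW")),
    list(set = c(fm_depth = 0.05), hot = c("EFM", "PFM"),
         cold = c("EAM", "EBW")),
    list(set = c(ppg_am_depth = 0.3), hot = c("PAM", "PBW"),
         cold = c("EAM", "EFM", "EBW", "PFM"))
  )
  cfg <- pipeline_config()
  for (cs in cases) {
    args <- modifyList(base, as.list(cs$set))
    rec <- generate_record(do.call(synth_config, args))
    fid <- suppressMessages(
      detect_fiducials(preprocess(rec$channels$ecg$samples, 300, cfg),
                       preprocess(rec$channels$ppg$samples, 300, cfg), 300))
    rms <- c(extract_ecg_rmcs(preprocess(rec$channels$ecg$samples, 300, cfg), fid, 300),
             extract_ppg_rmcs(preprocess(rec$channels$ppg$samples, 300, cfg), fid, 300))
    for (tag in names(rms)) {
      us <- resample_beat_series(rms[[tag]], cfg)
      pk <- spectral_peak(us$values, us$fs)
      ratio <- pk$power / stats::median(pk$spec)
      at_fr <- abs(pk$freq - 0.25) < 0.03
      if (tag %in% cs$hot) {
        expect_gt(ratio, 5)
        expect_true(at_fr, info = paste(tag, "peak at", round(pk$freq, 3)))
      } else if (tag %in% cs$cold) {
        expect_false(ratio > 5 && at_fr,
                     info = paste(tag, "unexpectedly modulated"))
      }
    }
  }
})
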