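#' Synthetic cardiorespiratory record configuration
#'
#' Parameters of the simulator that produces paired ECG/PPG records with
#' known respiratory modulation and exact fiducial ground truth. One
#' shared beat-time process (integral pulse frequency modulation with
#' sinusoidal respiratory sinus arrhythmia) drives both channels, as in
#' physiology, so cross-signal fusion is exercised. Respiration is
#' sinusoidal at `rr_bpm`; setting `rr_end_bpm` turns it into a linear
#' chirp from `rr_bpm` to `rr_end_bpm` over the record for tracking
#' studies.
#'
#' The respiratory tone must stay below the beat-domain Nyquist rate
#' (`rr_bpm/60 < hr_bpm/120`): beat-by-beat sampling cannot carry a faster
#' modulation, so configurations violating this are rejected.
#'
#' @param duration Record length in seconds.
#' @param fs Sampling rate in Hz.
#' @param hr_bpm Mean heart rate, 40--180 beats/min.
#' @param rr_bpm Respiratory rate, 3--45 breaths/min.
#' @param am_depth ECG beat-amplitude modulation depth (fraction).
#' @param fm_depth Respiratory sinus arrhythmia depth: peak deviation of
#'   the beat period, seconds.
#' @param bw_amp ECG baseline-wander amplitude (signal units).
#' @param ppg_am_depth PPG pulse-amplitude modulation depth (fraction).
#' @param ppg_fm_depth Additional pulse-transit-time modulation depth,
#'   seconds (adds pulse-interval modulation beyond the shared RSA).
#' @param ppg_bw_amp PPG baseline-wander amplitude.
#' @param noise_snr_db Additive white noise level, dB relative to the
#'   clean channel power; `Inf` disables noise.
#' @param rr_end_bpm Optional end rate for a linear chirp.
#' @param seed Integer seed; records are bit-reproducible given the seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(duration = 480, fs = 300, hr_bpm = 80, rr_bpm = 15,
                         am_depth = 0.1, fm_depth = 0.05, bw_amp = 0.05,
                         ppg_am_depth = 0.2, ppg_fm_depth = 0,
                         ppg_bw_amp = 0.1, noise_snr_db = 20,
                         rr_end_bpm = NULL, seed = 1L) {
  cfg <- list(duration = duration, fs = fs, hr_bpm = hr_bpm, rr_bpm = rr_bpm,
              am_depth = am_depth, fm_depth = fm_depth, bw_amp = bw_amp,
              ppg_am_depth = ppg_am_depth, ppg_fm_depth = ppg_fm_depth,
              ppg_bw_amp = ppg_bw_amp, noise_snr_db = noise_snr_db,
              rr_end_bpm = rr_end_bpm, seed = as.integer(seed))
  if (rr_bpm < 3 || rr_bpm > 45)
    rf_config_error("rr_bpm must lie in [3, 45], got %g", rr_bpm)
  if (hr_bpm < 40 || hr_bpm > 180)
    rf_config_error("hr_bpm must lie in [40, 180], got %g", hr_bpm)
  rr_hi <- max(rr_bpm, if (is.null(rr_end_bpm)) rr_bpm else rr_end_bpm)
  if (rr_hi / 60 >= hr_bpm / 120)
    rf_config_error(paste0(
      "respiratory tone (%g bpm = %g Hz) must stay below the beat-domain ",
      "Nyquist rate hr/120 = %g Hz"), rr_hi, rr_hi / 60, hr_bpm / 120)
  if (duration <= 0 || fs <= 0) rf_config_error("duration and fs must be positive")
  class(cfg) <- "synth_config"
  cfg
}

## Respiratory phase (radians) at time t: constant rate or linear chirp.
resp_phase <- function(cfg, t) {
  f0 <- cfg$rr_bpm / 60
  if (is.null(cfg$rr_end_bpm)) return(2 * pi * f0 * t)
  f1 <- cfg$rr_end_bpm / 60
  2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * cfg$duration))
}

#' Generate modulated beat times
#'
#' Beats are laid down sequentially with instantaneous period
#' `60/hr_bpm + fm_depth * sin(resp phase)`: with `fm_depth = 0` and a
#' 60 bpm heart rate, beats fall exactly at 0, 1, 2, ... seconds.
#'
#' @param cfg A [synth_config()].
#' @return Numeric vector of beat times in seconds, all `< duration`.
#' @export
generate_beat_times <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  t <- 0
  beats <- numeric(0)
  base <- 60 / cfg$hr_bpm
  while (t < cfg$duration) {
    beats <- c(beats, t)
    t <- t + base + cfg$fm_depth * sin(resp_phase(cfg, t))
  }
  beats
}

## Gaussian wave atlas: one cardiac cycle as P-QRS-T bumps relative to the
## R apex. QRS amplitudes are scaled per beat by the amplitude modulation.
.ecg_waves <- data.frame(
  wave  = c("P", "Q", "R", "S", "T"),
  amp   = c(0.08, -0.15, 1.00, -0.20, 0.30),
  mu    = c(-0.200, -0.025, 0.000, 0.030, 0.250),
  sigma = c(0.025, 0.010, 0.010, 0.012, 0.045)
)

#' Generate a synthetic ECG channel
#'
#' Each beat renders a fixed Gaussian P-QRS-T template at the beat time,
#' with the QRS amplitudes scaled by `1 + am_depth * sin(resp phase)`,
#' plus a respiratory baseline `bw_amp * sin(resp phase)` and white noise
#' at `noise_snr_db`. Fiducial ground truth is exact by construction: the
#' R apex sits at the beat time and the Q trough 25 ms before it.
#'
#' @param cfg A [synth_config()].
#' @param beat_times Optional precomputed [generate_beat_times()] output
#'   (shared with the PPG channel).
#' @return List with `samples`, `fs`, and `truth` (list with `r_times`,
#'   `q_times`).
#' @export
generate_ecg <- function(cfg, beat_times = generate_beat_times(cfg)) {
  n <- round(cfg$duration * cfg$fs)
  t <- (seq_len(n) - 1) / cfg$fs
  x <- numeric(n)
  for (tb in beat_times) {
    scale_qrs <- 1 + cfg$am_depth * sin(resp_phase(cfg, tb))
    i0 <- max(1, floor((tb - 0.35) * cfg$fs) + 1)
    i1 <- min(n, ceiling((tb + 0.45) * cfg$fs) + 1)
    tt <- t[i0:i1] - tb
    seg <- numeric(length(tt))
    for (w in seq_len(nrow(.ecg_waves))) {
      a <- .ecg_waves$amp[w]
      if (.ecg_waves$wave[w] %in% c("Q", "R", "S")) a <- a * scale_qrs
      seg <- seg + a * exp(-((tt - .ecg_waves$mu[w])^2) / (2 * .ecg_waves$sigma[w]^2))
    }
    x[i0:i1] <- x[i0:i1] + seg
  }
  x <- x + cfg$bw_amp * sin(resp_phase(cfg, t))
  x <- add_noise(x, cfg$noise_snr_db, cfg$seed + 101L)
  list(samples = x, fs = cfg$fs,
       truth = list(r_times = beat_times, q_times = beat_times - 0.025))
}

## PPG pulse kernel: (1 - exp(-s/tau_r)) * exp(-s/tau_d), zero at the
## onset, sharp upstroke, slow diastolic decay into the next onset so the
## inter-pulse minimum is a clean V exactly at the onset. Normalized to
## unit peak; the analytic peak lies at tau_r*log(1 + tau_d/tau_r).
.ppg_tau_r <- 0.030
.ppg_tau_d <- 0.250

ppg_kernel <- function(s) {
  tp <- .ppg_tau_r * log(1 + .ppg_tau_d / .ppg_tau_r)
  pk <- (1 - exp(-tp / .ppg_tau_r)) * exp(-tp / .ppg_tau_d)
  ifelse(s <= 0, 0, (1 - exp(-s / .ppg_tau_r)) * exp(-s / .ppg_tau_d) / pk)
}

#' Generate a synthetic PPG channel
#'
#' Pulses start `0.2 + ppg_fm_depth * sin(resp phase)` seconds after each
#' (shared) beat time, with amplitude `1 + ppg_am_depth * sin(resp phase)`,
#' a respiratory baseline and white noise. The pulse shape is zero at the
#' onset with a fast upstroke and slow diastolic decay, so the waveform's
#' minimum falls exactly on the onset. Ground-truth systolic peak times
#' are located on the rendered noise-free waveform, making them exact for
#' the composite (overlapping-pulse) signal.
#'
#' @inheritParams generate_ecg
#' @return List with `samples`, `fs`, and `truth` (list with
#'   `onset_times`, `peak_times`).
#' @export
generate_ppg <- function(cfg, beat_times = generate_beat_times(cfg)) {
  n <- round(cfg$duration * cfg$fs)
  t <- (seq_len(n) - 1) / cfg$fs
  onsets <- beat_times + 0.2 +
    cfg$ppg_fm_depth * sin(resp_phase(cfg, beat_times))
  onsets <- onsets[onsets < cfg$duration - 0.2]
  x <- numeric(n)
  for (ob in onsets) {
    amp <- 1 + cfg$ppg_am_depth * sin(resp_phase(cfg, ob))
    i0 <- max(1, floor(ob * cfg$fs) + 1)
    i1 <- min(n, ceiling((ob + 1.6) * cfg$fs) + 1)
    x[i0:i1] <- x[i0:i1] + amp * ppg_kernel(t[i0:i1] - ob)
  }
  ## exact peak truth from the clean composite waveform
  peak_times <- vapply(onsets, function(ob) {
    i0 <- floor(ob * cfg$fs) + 1
    i1 <- min(n, i0 + round(0.125 * cfg$fs))
    t[i0 + which.max(x[i0:i1]) - 1]
  }, 0)
  x <- x + cfg$ppg_bw_amp * sin(resp_phase(cfg, t))
  x <- add_noise(x, cfg$noise_snr_db, cfg$seed + 202L)
  list(samples = x, fs = cfg$fs,
       truth = list(onset_times = onsets, peak_times = peak_times))
}

add_noise <- function(x, snr_db, seed) {
  if (!is.finite(snr_db)) return(x)
  set.seed(seed)
  sigma <- sqrt(stats::var(x) / 10^(snr_db / 10))
  x + stats::rnorm(length(x), sd = sigma)
}

#' Generate a full synthetic cardiorespiratory record
#'
#' Bundles a shared-beat ECG and PPG, a reference respiration trace
#' (`sin` of the respiratory phase at `fs`), and an `rr_ref` channel with
#' the instantaneous respiratory rate at 1 Hz. The exact fiducial and
#' beat-time ground truth is attached as attribute `"ground_truth"`.
#'
#' @param cfg A [synth_config()].
#' @param subject_id Identifier for the record.
#' @return A [waveform_record()] with channels `ecg`, `ppg`, `resp`,
#'   `rr_ref` and attribute `ground_truth` (list with `beat_times`,
#'   `r_times`, `q_times`, `onset_times`, `peak_times`).
#' @examples
#' rec <- generate_record(synth_config(duration = 60, rr_bpm = 15, seed = 7))
#' rec
#' @export
generate_record <- function(cfg, subject_id = sprintf("synth-%04d", cfg$seed)) {
  stopifnot(inherits(cfg, "synth_config"))
  beats <- generate_beat_times(cfg)
  ecg <- generate_ecg(cfg, beats)
  ppg <- generate_ppg(cfg, beats)
  n <- round(cfg$duration * cfg$fs)
  t <- (seq_len(n) - 1) / cfg$fs
  resp <- sin(resp_phase(cfg, t))
  t1 <- seq(0, cfg$duration - 1)
  rr_inst <- if (is.null(cfg$rr_end_bpm)) rep(cfg$rr_bpm, length(t1)) else
    cfg$rr_bpm + (cfg$rr_end_bpm - cfg$rr_bpm) * t1 / cfg$duration
  rec <- waveform_record(list(
    ecg = list(samples = ecg$samples, fs = cfg$fs, units = "mV"),
    ppg = list(samples = ppg$samples, fs = cfg$fs, units = "a.u."),
    resp = list(samples = resp, fs = cfg$fs, units = "a.u."),
    rr_ref = list(samples = rr_inst, fs = 1, units = "breaths/min")
  ), subject_id = subject_id)
  attr(rec, "ground_truth") <- list(
    beat_times = beats,
    r_times = ecg$truth$r_times, q_times = ecg$truth$q_times,
    onset_times = ppg$truth$onset_times, peak_times = ppg$truth$peak_times
  )
  rec
}
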