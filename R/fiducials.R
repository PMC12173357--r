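#' Pan-Tompkins QRS detection
#'
#' Classical real-time QRS detector: 5--15 Hz band-pass, five-point
#' derivative, squaring, 150 ms moving-window integration, then adaptive
#' signal/noise thresholds with a 200 ms refractory period and a
#' half-threshold search-back when a beat appears to be missed. Detected
#' integrator peaks are mapped back to the raw ECG maximum within
#' +/- 50 ms so the returned indices sit on the R apex.
#'
#' @param ecg Numeric vector (preprocessed ECG).
#' @param fs Sampling rate in Hz (>= 100).
#' @return Strictly increasing integer sample indices of R peaks.
#' @export
pan_tompkins_rpeaks <- function(ecg, fs) {
  n <- length(ecg)
  if (n / fs < 2) rf_short_window("need at least 2 s of ECG")
  if (fs < 100) rf_config_error("pan_tompkins_rpeaks requires fs >= 100 Hz")
  if (stats::sd(ecg) == 0) rf_no_beat("flat ECG, no beats detectable")

  bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  bp <- filtfilt_ss(bf$b, bf$a, ecg)
  ## five-point derivative (zero-phase alignment by centered stencil)
  d <- c(0, 0, (-bp[1:(n - 4)] - 2 * bp[2:(n - 3)] +
                2 * bp[4:(n - 1)] + bp[5:n]) / 8, 0, 0)
  sq <- d^2
  mwi <- moving_average(sq, max(3, round(0.150 * fs)))

  refr <- round(0.200 * fs)
  ## candidate peaks of the integrated signal: local maxima, collapsed so
  ## that only the tallest survives within any refractory span (the
  ## integrator ripples; its per-beat maximum is what tracks the QRS)
  loc <- which(diff(sign(diff(mwi))) < 0) + 1
  if (length(loc) == 0) rf_no_beat("no candidate peaks in integrated signal")
  ord <- loc[order(mwi[loc], decreasing = TRUE)]
  kept <- integer(0)
  for (p in ord)
    if (length(kept) == 0 || min(abs(kept - p)) >= refr) kept <- c(kept, p)
  loc <- sort(kept)

  ## adaptive thresholding (signal level SPKI, noise level NPKI)
  init <- mwi[seq_len(min(n, 2 * fs))]
  spki <- max(init) * 0.6
  npki <- mean(init) * 0.5
  thr <- function() npki + 0.25 * (spki - npki)
  peaks <- integer(0)
  last <- -Inf
  rr_avg <- NA_real_
  for (p in loc) {
    if (p - last < refr) next
    if (mwi[p] >= thr()) {
      ## search-back not needed when beat accepted directly
      peaks <- c(peaks, p)
      spki <- 0.125 * mwi[p] + 0.875 * spki
      if (length(peaks) >= 2) {
        ib <- diff(utils::tail(peaks, 9)) / fs
        rr_avg <- mean(ib)
      }
      last <- p
    } else {
      npki <- 0.125 * mwi[p] + 0.875 * npki
      ## search-back: if the expected beat is overdue, retry at half threshold
      if (!is.na(rr_avg) && (p - last) / fs > 1.66 * rr_avg &&
          mwi[p] >= 0.5 * thr()) {
        peaks <- c(peaks, p)
        spki <- 0.25 * mwi[p] + 0.75 * spki
        last <- p
      }
    }
  }
  if (length(peaks) == 0) rf_no_beat("no beats above adaptive threshold")

  ## map to the raw-ECG local maximum within +/- 50 ms
  w <- as.integer(round(0.050 * fs))
  rp <- vapply(peaks, function(p) {
    i0 <- max(1L, as.integer(p) - w); i1 <- min(n, as.integer(p) + w)
    i0 + which.max(ecg[i0:i1]) - 1L
  }, 0L)
  rp <- sort(unique(rp))

  ## physiologic inter-beat bounds [0.3, 2.0] s: drop the smaller-amplitude
  ## peak of any pair closer than 0.3 s
  if (length(rp) >= 2) {
    keep <- rep(TRUE, length(rp))
    for (i in 2:length(rp)) {
      prev <- max(which(keep[1:(i - 1)]))
      if ((rp[i] - rp[prev]) / fs < 0.3) {
        if (ecg[rp[i]] >= ecg[rp[prev]]) keep[prev] <- FALSE else keep[i] <- FALSE
      }
    }
    rp <- rp[keep]
  }
  if (length(rp) == 0) rf_no_beat("all detected beats rejected")
  rp
}

#' Locate Q waves preceding detected R peaks
#'
#' The Q wave is the minimum of the ECG over the 200 ms interval strictly
#' preceding each R peak. Beats whose interval would extend before the
#' window start are dropped (with a message); the retained R peaks are
#' attached as attribute `"r_retained"`.
#'
#' @param ecg Numeric vector.
#' @param r_peaks Integer R-peak sample indices.
#' @param fs Sampling rate in Hz.
#' @return Integer Q indices, one per retained R peak, with attribute
#'   `r_retained`.
#' @export
locate_q_waves <- function(ecg, r_peaks, fs) {
  span <- as.integer(round(0.2 * fs))
  ok <- r_peaks - span >= 1
  if (any(!ok))
    message(sum(!ok), " beat(s) dropped: Q search interval precedes window start")
  r <- r_peaks[ok]
  q <- vapply(r, function(ri) {
    i0 <- ri - span + 1L
    i0 + which.min(ecg[i0:(ri - 1L)]) - 1L
  }, 0L)
  attr(q, "r_retained") <- r
  q
}

#' Detect PPG pulse onsets (troughs)
#'
#' Adaptive-threshold slope-sum onset detector. The systolic upstroke is
#' located first: a slope-sum function (windowed sum of positive slopes of
#' the lightly smoothed waveform, 128 ms window) is thresholded against a
#' running fraction of its 90th percentile over a 2 s context, with a
#' 300 ms refractory period keeping the strongest upstroke per cycle. The
#' onset is then the waveform minimum in the 150 ms preceding each
#' upstroke (latest index on ties, so a flat diastolic baseline resolves
#' to the foot of the rise), refined to the raw-signal minimum within
#' +/- 20 ms.
#'
#' @param ppg Numeric vector (preprocessed PPG).
#' @param fs Sampling rate in Hz.
#' @return Strictly increasing integer trough indices.
#' @export
detect_ppg_troughs <- function(ppg, fs) {
  n <- length(ppg)
  if (n / fs < 2) rf_short_window("need at least 2 s of PPG")
  if (stats::sd(ppg) == 0) rf_no_beat("flat PPG, no pulses detectable")
  y <- moving_average(ppg, max(3, round(0.030 * fs)))
  d <- pmax(diff(y), 0)
  w <- max(3, round(0.128 * fs))
  ssf <- c(0, moving_average(d, w) * w)
  ## strongest slope-sum peak per cycle
  loc <- which(diff(sign(diff(ssf))) < 0) + 1L
  if (length(loc) == 0) rf_no_beat("no upstrokes in PPG")
  refr <- round(0.3 * fs)
  ord <- loc[order(ssf[loc], decreasing = TRUE)]
  kept <- integer(0)
  for (p in ord)
    if (length(kept) == 0 || min(abs(kept - p)) >= refr) kept <- c(kept, p)
  loc <- sort(kept)
  ## adaptive threshold: fraction of the running 90th percentile
  ctx <- round(2 * fs)
  keep <- vapply(loc, function(i) {
    i0 <- max(1, i - ctx); i1 <- min(n, i + ctx)
    ssf[i] >= 0.3 * stats::quantile(ssf[i0:i1], 0.9, names = FALSE)
  }, TRUE)
  loc <- loc[keep]
  if (length(loc) == 0) rf_no_beat("no upstrokes above adaptive threshold")
  ## onset: foot of the upstroke. The smoothed slope jumps from the slow
  ## diastolic/baseline drift to the steep systolic rise at the onset, so
  ## the last pre-upstroke sample whose slope is below 5% of the cycle's
  ## maximum slope marks the foot, independent of baseline slope.
  back <- as.integer(round(0.150 * fs))
  sl <- c(0, diff(y))
  tro <- vapply(loc, function(c0) {
    i0 <- max(1L, as.integer(c0) - back)
    win <- i0:c0
    mpos <- win[which.max(sl[win])]
    smax <- sl[mpos]
    below <- win[win < mpos & sl[win] <= 0.05 * smax]
    if (length(below) == 0) i0 else max(below)
  }, 0L)
  tro <- sort(unique(tro))
  ## one onset per cycle: enforce the refractory on the onsets themselves
  if (length(tro) >= 2) {
    keep <- rep(TRUE, length(tro))
    for (i in 2:length(tro)) {
      prev <- max(which(keep[1:(i - 1)]))
      if (tro[i] - tro[prev] < refr) {
        if (ppg[tro[i]] < ppg[tro[prev]]) keep[prev] <- FALSE else keep[i] <- FALSE
      }
    }
    tro <- tro[keep]
  }
  tro
}

#' Locate systolic peaks after PPG troughs
#'
#' The systolic peak is the maximum of the PPG within the 125 ms window
#' following each trough (exclusive of the trough itself). Troughs too
#' close to the window end to fit a search interval are dropped (with a
#' message); retained troughs are attached as attribute
#' `"troughs_retained"`.
#'
#' @param ppg Numeric vector.
#' @param troughs Integer trough indices.
#' @param fs Sampling rate in Hz.
#' @return Integer peak indices with attribute `troughs_retained`.
#' @export
locate_systolic_peaks <- function(ppg, troughs, fs) {
  n <- length(ppg)
  span <- as.integer(round(0.125 * fs))
  ok <- troughs + 1 <= n
  if (any(!ok))
    message(sum(!ok), " trough(s) dropped: no samples after trough")
  tr <- troughs[ok]
  pk <- vapply(tr, function(ti) {
    i1 <- min(n, ti + span)
    (ti + 1L) + which.max(ppg[(ti + 1L):i1]) - 1L
  }, 0L)
  attr(pk, "troughs_retained") <- tr
  pk
}

#' Detect all fiducials of one analysis window
#'
#' Convenience wrapper running [pan_tompkins_rpeaks()] +
#' [locate_q_waves()] on the ECG and [detect_ppg_troughs()] +
#' [locate_systolic_peaks()] on the PPG, returning a paired, validated
#' `fiducial_set`.
#'
#' @param ecg,ppg Preprocessed window signals at `fs`.
#' @param fs Sampling rate in Hz.
#' @return A `fiducial_set`: list with `r_peaks`, `q_waves`,
#'   `ppg_troughs`, `ppg_peaks`, `fs`.
#' @export
detect_fiducials <- function(ecg, ppg, fs) {
  r <- pan_tompkins_rpeaks(ecg, fs)
  q <- locate_q_waves(ecg, r, fs)
  tr <- detect_ppg_troughs(ppg, fs)
  pk <- locate_systolic_peaks(ppg, tr, fs)
  fiducial_set(r_peaks = attr(q, "r_retained"), q_waves = as.integer(q),
               ppg_troughs = attr(pk, "troughs_retained"),
               ppg_peaks = as.integer(pk), fs = fs)
}

#' @rdname detect_fiducials
#' @param r_peaks,q_waves,ppg_troughs,ppg_peaks Paired index vectors.
#' @export
fiducial_set <- function(r_peaks, q_waves, ppg_troughs, ppg_peaks, fs) {
  stopifnot(length(r_peaks) == length(q_waves),
            length(ppg_troughs) == length(ppg_peaks))
  if (length(r_peaks) > 1 && any(diff(r_peaks) <= 0))
    rf_data_error("r_peaks not strictly increasing")
  if (length(ppg_troughs) > 1 && any(diff(ppg_troughs) <= 0))
    rf_data_error("ppg_troughs not strictly increasing")
  if (any(r_peaks - q_waves <= 0) || any((r_peaks - q_waves) / fs > 0.2))
    rf_data_error("each Q must precede its R by at most 0.2 s")
  if (any(ppg_peaks - ppg_troughs <= 0) ||
      any((ppg_peaks - ppg_troughs) / fs > 0.125 + 1 / fs))
    rf_data_error("each systolic peak must follow its trough by at most 125 ms")
  structure(list(r_peaks = as.integer(r_peaks), q_waves = as.integer(q_waves),
                 ppg_troughs = as.integer(ppg_troughs),
                 ppg_peaks = as.integer(ppg_peaks), fs = fs),
            class = "fiducial_set")
}
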