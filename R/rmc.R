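#' Beat-domain respiratory modulated component series
#'
#' A `beat_series` holds irregularly sampled (time, value) measurements of
#' one respiratory modulated component. AM/BW values are in the signal's
#' amplitude units, FM values in seconds.
#'
#' @param component One of `"EAM"`, `"EFM"`, `"EBW"`, `"PAM"`, `"PFM"`,
#'   `"PBW"`.
#' @param times Strictly increasing times in seconds.
#' @param values Numeric values, same length as `times`.
#' @return An object of class `beat_series`.
#' @export
beat_series <- function(component, times, values) {
  component <- match.arg(component, c("EAM", "EFM", "EBW", "PAM", "PFM", "PBW"))
  stopifnot(length(times) == length(values))
  if (length(times) > 1 && any(diff(times) <= 0))
    rf_data_error("beat times must be strictly increasing")
  structure(list(component = component, times = as.numeric(times),
                 values = as.numeric(values)),
            class = "beat_series")
}

#' Extract the three ECG respiratory modulated components
#'
#' Per cardiac cycle `i` with R peak at `r_i` and Q wave at `q_i`:
#' * EAM (amplitude modulation): `ecg[r_i] - ecg[q_i]`, stamped at the R time;
#' * EBW (baseline wander): `(ecg[r_i] + ecg[q_i]) / 2`, stamped at the R time;
#' * EFM (frequency modulation): the R-R interval `t(r_{i+1}) - t(r_i)`,
#'   stamped at the interval midpoint (one fewer element than R peaks).
#'
#' @param ecg Numeric window signal.
#' @param fid A `fiducial_set` for this window.
#' @param fs Sampling rate in Hz.
#' @return Named list of three [beat_series()]: `EAM`, `EFM`, `EBW`.
#' @export
extract_ecg_rmcs <- function(ecg, fid, fs) {
  r <- fid$r_peaks; q <- fid$q_waves
  if (length(r) < 4) rf_insufficient("only %d usable beats (need >= 4)", length(r))
  tr <- (r - 1) / fs
  eam <- beat_series("EAM", tr, ecg[r] - ecg[q])
  ebw <- beat_series("EBW", tr, (ecg[r] + ecg[q]) / 2)
  ib <- diff(tr)
  efm <- beat_series("EFM", (tr[-length(tr)] + tr[-1]) / 2, ib)
  list(EAM = eam, EFM = efm, EBW = ebw)
}

#' Extract the three PPG respiratory modulated components
#'
#' Per pulse `i` with onset (trough) at `o_i` and systolic peak at `p_i`:
#' * PAM: `ppg[p_i] - ppg[o_i]`, stamped at the peak time;
#' * PBW: `(ppg[p_i] + ppg[o_i]) / 2`, stamped at the peak time;
#' * PFM: the peak-to-peak interval, stamped at the interval midpoint.
#'
#' @param ppg Numeric window signal.
#' @param fid A `fiducial_set` for this window.
#' @param fs Sampling rate in Hz.
#' @return Named list of three [beat_series()]: `PAM`, `PFM`, `PBW`.
#' @export
extract_ppg_rmcs <- function(ppg, fid, fs) {
  tr <- fid$ppg_troughs; pk <- fid$ppg_peaks
  if (length(pk) < 4) rf_insufficient("only %d usable pulses (need >= 4)", length(pk))
  tp <- (pk - 1) / fs
  pam <- beat_series("PAM", tp, ppg[pk] - ppg[tr])
  pbw <- beat_series("PBW", tp, (ppg[pk] + ppg[tr]) / 2)
  ib <- diff(tp)
  pfm <- beat_series("PFM", (tp[-length(tp)] + tp[-1]) / 2, ib)
  list(PAM = pam, PFM = pfm, PBW = pbw)
}

#' Resample a beat series onto a uniform grid
#'
#' Cubic-spline interpolation of the irregular (time, value) pairs onto
#' the absolute lattice `k / cfg$beat_series_fs`, restricted to the span
#' of observed beats (no extrapolation), followed by mean subtraction so
#' downstream spectral stages see a zero-mean series. Because every
#' component of a window is interpolated onto the same absolute lattice,
#' resampled components can be aligned sample-by-sample for fusion.
#'
#' @param bs A [beat_series()] with at least 4 points.
#' @param cfg A [pipeline_config()]; only `beat_series_fs` is used.
#' @return A `uniform_series`: list with `component`, `fs`, `t0` (time of
#'   the first grid sample) and zero-mean `values`.
#' @export
resample_beat_series <- function(bs, cfg = pipeline_config()) {
  stopifnot(inherits(bs, "beat_series"))
  if (length(bs$times) < 4)
    rf_insufficient("beat series '%s' has %d points (need >= 4)",
                    bs$component, length(bs$times))
  fsb <- cfg$beat_series_fs
  k0 <- ceiling(bs$times[1] * fsb - 1e-9)
  k1 <- floor(bs$times[length(bs$times)] * fsb + 1e-9)
  if (k1 < k0) rf_insufficient("no grid points inside beat span of '%s'", bs$component)
  grid <- (k0:k1) / fsb
  f <- stats::splinefun(bs$times, bs$values, method = "fmm")
  v <- f(grid)
  uniform_series(bs$component, fsb, v - mean(v), t0 = k0 / fsb)
}

#' @rdname resample_beat_series
#' @param component Component tag.
#' @param fs Sampling rate of the uniform grid in Hz.
#' @param values Zero-mean numeric values.
#' @param t0 Time of the first sample in seconds.
#' @export
uniform_series <- function(component, fs, values, t0 = 0) {
  if (!all(is.finite(values))) rf_data_error("non-finite values in uniform series")
  structure(list(component = component, fs = fs, values = values, t0 = t0),
            class = "uniform_series")
}
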