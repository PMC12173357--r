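#' Respiratory rate from a fused waveform
#'
#' The fused waveform's Hann-windowed periodogram, zero-padded to
#' `n_pad` bins, is searched for its maximum inside the closed respiratory
#' band; the rate is 60 times that peak frequency. With the default
#' 2^14-bin padding the rate grid is about 0.04 breaths/min at a 10 Hz
#' series rate, far below the windowing-induced uncertainty, so no
#' interpolation around the peak is performed. Ties go to the lower
#' frequency.
#'
#' @param fused A `fused_waveform` (or any object with `values`), length
#'   >= 32.
#' @param fs Sampling rate of the fused series in Hz.
#' @param band Respiratory band `c(low, high)` in Hz (closed interval).
#' @param n_pad Periodogram FFT length.
#' @return List with `f_rr` (Hz) and `rr` (breaths/min).
#' @export
estimate_rr <- function(fused, fs, band = c(0.05, 0.75), n_pad = 2^14) {
  v <- if (is.list(fused)) fused$values else fused
  if (length(v) < 32) rf_short_window("fused series of %d samples too short", length(v))
  pk <- spectral_peak(v, fs, n_pad = n_pad, band = band)
  list(f_rr = pk$freq, rr = 60 * pk$freq)
}

## Run the ECG side of one window; NULL components on failure.
window_ecg_components <- function(ecg, fs, cfg, flags) {
  out <- list(EAM = NULL, EFM = NULL, EBW = NULL)
  tryCatch({
    r <- pan_tompkins_rpeaks(ecg, fs)
    q <- locate_q_waves(ecg, r, fs)
    fid <- fiducial_set(attr(q, "r_retained"), as.integer(q),
                        ppg_troughs = integer(0), ppg_peaks = integer(0), fs = fs)
    out <- extract_ecg_rmcs(ecg, fid, fs)
  },
  respifuse_no_beat_error = function(e) flags$add("no_beat_ecg"),
  respifuse_insufficient_beats_error = function(e) flags$add("insufficient_beats_ecg"),
  respifuse_data_error = function(e) flags$add("insufficient_beats_ecg"))
  out
}

window_ppg_components <- function(ppg, fs, cfg, flags) {
  out <- list(PAM = NULL, PFM = NULL, PBW = NULL)
  tryCatch({
    tr <- detect_ppg_troughs(ppg, fs)
    pk <- locate_systolic_peaks(ppg, tr, fs)
    fid <- fiducial_set(integer(0), integer(0),
                        ppg_troughs = attr(pk, "troughs_retained"),
                        ppg_peaks = as.integer(pk), fs = fs)
    out <- extract_ppg_rmcs(ppg, fid, fs)
  },
  respifuse_no_beat_error = function(e) flags$add("no_beat_ppg"),
  respifuse_insufficient_beats_error = function(e) flags$add("insufficient_beats_ppg"),
  respifuse_data_error = function(e) flags$add("insufficient_beats_ppg"))
  out
}

flag_bag <- function() {
  fl <- character(0)
  list(add = function(f) fl <<- union(fl, f),
       get = function() fl)
}

#' Run the full estimation pipeline on a record
#'
#' For every analysis window: preprocess both channels, detect fiducials,
#' extract the six beat-domain components, resample each to the uniform
#' beat-series grid, denoise each with VMD and keep its respiratory mode,
#' screen the filtered components with the adaptive mean-RQI threshold,
#' fuse the survivors through their first principal component, and read
#' the rate off the fused spectrum. A stage failure on one channel (e.g. a
#' flat ECG) removes that channel's components and the window proceeds on
#' the rest; a window with no usable components yields an `NA` rate with
#' its quality flags set. Windows are never silently dropped, so coverage
#' is visible downstream.
#'
#' @param record A [waveform_record()] with `ecg` and `ppg` channels.
#' @param cfg A [pipeline_config()].
#' @return A data frame of class `rr_estimates`, one row per window:
#'   `subject`, `window_start_s`, `rr_est_bpm`, `f_rr_hz`, `m_used`,
#'   `rqi_eam` ... `rqi_pbw`, `threshold_T`, `ref_rr_bpm`, `flags`
#'   (comma-separated quality flags, empty when clean).
#' @export
run_pipeline <- function(record, cfg = pipeline_config()) {
  stopifnot(inherits(record, "waveform_record"))
  set.seed(cfg$seed)
  windows <- segment_windows(record, cfg)
  tags <- c("EAM", "EFM", "EBW", "PAM", "PFM", "PBW")
  rows <- lapply(windows, function(w) {
    flags <- flag_bag()
    row <- data.frame(subject = record$subject_id,
                      window_start_s = w$start_time,
                      rr_est_bpm = NA_real_, f_rr_hz = NA_real_,
                      m_used = 0L,
                      rqi_eam = NA_real_, rqi_efm = NA_real_, rqi_ebw = NA_real_,
                      rqi_pam = NA_real_, rqi_pfm = NA_real_, rqi_pbw = NA_real_,
                      threshold_T = NA_real_,
                      ref_rr_bpm = w$ref_rr, flags = "",
                      stringsAsFactors = FALSE)
    ecg <- tryCatch(preprocess(w$ecg, w$fs, cfg),
                    respifuse_error = function(e) { flags$add("short_window"); NULL })
    ppg <- tryCatch(preprocess(w$ppg, w$fs, cfg),
                    respifuse_error = function(e) { flags$add("short_window"); NULL })
    comps <- c(
      if (is.null(ecg)) list(EAM = NULL, EFM = NULL, EBW = NULL)
      else window_ecg_components(ecg, w$fs, cfg, flags),
      if (is.null(ppg)) list(PAM = NULL, PFM = NULL, PBW = NULL)
      else window_ppg_components(ppg, w$fs, cfg, flags)
    )
    ## uniform resampling + VMD denoising per component
    filtered <- stats::setNames(vector("list", 6), tags)
    grid_meta <- list()
    for (tag in tags) {
      bs <- comps[[tag]]
      if (is.null(bs)) next
      f <- tryCatch({
        us <- resample_beat_series(bs, cfg)
        res <- vmd_decompose(us$values, cfg$beat_series_fs, cfg$vmd_K,
                             alpha = cfg$vmd_alpha, tau = cfg$vmd_tau,
                             tol = cfg$vmd_tol)
        if (!res$converged) flags$add("vmd_unconverged")
        fr <- select_respiratory_imf(res, us$values, cfg$beat_series_fs,
                                     component = tag)
        fr$t0 <- us$t0; fr$fs <- us$fs
        fr
      },
      respifuse_insufficient_beats_error = function(e) {
        flags$add("insufficient_beats"); NULL },
      respifuse_short_window_error = function(e) {
        flags$add("insufficient_beats"); NULL },
      respifuse_degenerate_error = function(e) {
        flags$add("degenerate"); NULL })
      filtered[[tag]] <- f
    }
    if (all(vapply(filtered, is.null, TRUE))) {
      flags$add("degenerate")
      row$flags <- paste(flags$get(), collapse = ",")
      return(row)
    }
    report <- screen_components(filtered, cfg$beat_series_fs, cfg$resp_band_hz)
    row[paste0("rqi_", tolower(tags))] <- as.list(report$rqi_values)
    row$threshold_T <- report$threshold_T

    sel <- filtered[report$selected]
    aligned <- align_common_grid(sel, cfg$beat_series_fs)
    if (is.null(aligned)) {
      flags$add("degenerate")
      row$flags <- paste(flags$get(), collapse = ",")
      return(row)
    }
    est <- tryCatch({
      fw <- fuse_components(aligned, normalize = cfg$normalize_rmcs)
      estimate_rr(fw, cfg$beat_series_fs, cfg$resp_band_hz)
    }, respifuse_error = function(e) { flags$add("degenerate"); NULL })
    if (!is.null(est)) {
      row$rr_est_bpm <- est$rr
      row$f_rr_hz <- est$f_rr
      row$m_used <- report$m
    }
    row$flags <- paste(flags$get(), collapse = ",")
    row
  })
  out <- if (length(rows) == 0)
    data.frame(subject = character(0), window_start_s = numeric(0),
               rr_est_bpm = numeric(0), f_rr_hz = numeric(0),
               m_used = integer(0), flags = character(0))
  else do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("rr_estimates", class(out))
  out
}

## Restrict a set of uniform series (with t0/fs on the same absolute
## lattice) to their common overlap; NULL if the overlap is too short.
align_common_grid <- function(series, fs) {
  if (length(series) == 0) return(NULL)
  k0 <- max(vapply(series, function(s) round(s$t0 * fs), 0))
  k1 <- min(vapply(series, function(s) round(s$t0 * fs) + length(s$values) - 1, 0))
  if (k1 - k0 + 1 < 32) return(NULL)
  lapply(series, function(s) {
    ks <- round(s$t0 * fs)
    s$values <- s$values[(k0 - ks + 1):(k1 - ks + 1)]
    s$t0 <- k0 / fs
    s
  })
}
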