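#' Pipeline configuration
#'
#' Collects every tunable of the estimation pipeline in one validated
#' object. Defaults reproduce the reference analysis settings: 30 s
#' non-overlapping windows at 300 Hz, a 10-point smoother followed by a
#' third-order 0.05 Hz zero-phase Butterworth high-pass, 5-mode VMD
#' denoising, the 0.05--0.75 Hz respiratory band (3--45 breaths/min), and
#' beat series resampled to 10 Hz before decomposition.
#'
#' @param window_length_s Analysis window length in seconds, in \[30, 60\].
#' @param step_fraction Sliding-step size as a fraction of the window
#'   length, in (0, 1\]. 1 gives non-overlapping windows.
#' @param target_fs Common working sampling rate in Hz; both channels are
#'   resampled to this rate inside each window.
#' @param smoothing_points Length of the moving-average smoother (samples
#'   at `target_fs`).
#' @param highpass_cutoff_hz High-pass cutoff in Hz.
#' @param highpass_order Butterworth order of the high-pass.
#' @param vmd_K Number of VMD modes.
#' @param vmd_alpha VMD bandwidth penalty.
#' @param vmd_tau VMD dual-ascent step (0 disables the Lagrangian update,
#'   tolerating additive noise).
#' @param vmd_tol VMD convergence tolerance on the relative mode change.
#' @param resp_band_hz Two-element numeric, the respiratory band in Hz.
#' @param beat_series_fs Uniform resampling rate for beat-domain series, Hz.
#' @param normalize_rmcs Scale each component to unit variance before PCA
#'   fusion so that seconds-valued and amplitude-valued components weigh
#'   equally. Set `FALSE` for covariance (centering-only) PCA.
#' @param seed Integer seed forwarded to any randomized stage.
#'
#' @return An object of class `pipeline_config` (a validated named list).
#' @examples
#' cfg <- pipeline_config(window_length_s = 30, step_fraction = 0.5)
#' cfg$resp_band_hz
#' @export
pipeline_config <- function(window_length_s = 30,
                            step_fraction = 1,
                            target_fs = 300,
                            smoothing_points = 10,
                            highpass_cutoff_hz = 0.05,
                            highpass_order = 3,
                            vmd_K = 5,
                            vmd_alpha = 2000,
                            vmd_tau = 0,
                            vmd_tol = 1e-7,
                            resp_band_hz = c(0.05, 0.75),
                            beat_series_fs = 10,
                            normalize_rmcs = TRUE,
                            seed = 1L) {
  cfg <- list(
    window_length_s = as.numeric(window_length_s),
    step_fraction = as.numeric(step_fraction),
    target_fs = as.numeric(target_fs),
    smoothing_points = as.integer(smoothing_points),
    highpass_cutoff_hz = as.numeric(highpass_cutoff_hz),
    highpass_order = as.integer(highpass_order),
    vmd_K = as.integer(vmd_K),
    vmd_alpha = as.numeric(vmd_alpha),
    vmd_tau = as.numeric(vmd_tau),
    vmd_tol = as.numeric(vmd_tol),
    resp_band_hz = as.numeric(resp_band_hz),
    beat_series_fs = as.numeric(beat_series_fs),
    normalize_rmcs = isTRUE(normalize_rmcs),
    seed = as.integer(seed)
  )
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  with(cfg, {
    if (window_length_s < 30 || window_length_s > 60)
      rf_config_error("window_length_s must lie in [30, 60], got %g", window_length_s)
    if (step_fraction <= 0 || step_fraction > 1)
      rf_config_error("step_fraction must lie in (0, 1], got %g", step_fraction)
    if (target_fs <= 0) rf_config_error("target_fs must be positive")
    if (length(resp_band_hz) != 2 ||
        resp_band_hz[1] <= 0 || resp_band_hz[1] >= resp_band_hz[2] ||
        resp_band_hz[2] >= target_fs / 2)
      rf_config_error("resp_band_hz must satisfy 0 < low < high < target_fs/2")
    if (resp_band_hz[2] >= beat_series_fs / 2)
      rf_config_error("resp_band_hz upper edge must be below beat_series_fs/2")
    if (step_fraction * window_length_s < 1 / beat_series_fs)
      rf_config_error("step must be at least one beat-series sample")
    if (vmd_K < 1) rf_config_error("vmd_K must be >= 1")
    if (smoothing_points < 1) rf_config_error("smoothing_points must be >= 1")
  })
  cfg
}

#' Read or write a pipeline configuration as YAML
#'
#' The YAML keys mirror the [pipeline_config()] argument names exactly;
#' keys not present fall back to the defaults, unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) rf_config_error("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    rf_config_error("unknown config keys: %s", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param cfg A `pipeline_config` object.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x))
    cat(sprintf("  %-20s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}
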