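#' Respiratory quality index
#'
#' Fraction of a zero-mean series' spectral power that falls inside the
#' physiological respiratory band: the discrete Fourier transform of `x`
#' is taken as-is (no taper, no zero padding), and the ratio of
#' magnitude-squared coefficients summed over in-band positive-frequency
#' bins to the sum over all positive-frequency bins (DC excluded) is
#' returned. The index is scale invariant and lies in \[0, 1\]; 1 means
#' all oscillatory energy is respiratory-band energy.
#'
#' @param x Numeric vector, length >= 32, zero-mean (a nonzero mean only
#'   affects the excluded DC bin).
#' @param fs Sampling rate in Hz.
#' @param band `c(low, high)` in Hz; default 0.05--0.75 Hz
#'   (3--45 breaths/min).
#' @return A value in \[0, 1\]; 0 if the series has no spectral power.
#' @examples
#' t <- seq(0, 30, by = 0.1)[-1]
#' compute_rqi(sin(2 * pi * 0.3 * t), fs = 10)   # 1: pure in-band tone
#' @export
compute_rqi <- function(x, fs, band = c(0.05, 0.75)) {
  n <- length(x)
  if (n < 32) rf_short_window("compute_rqi needs >= 32 samples, got %d", n)
  X <- stats::fft(x)
  kmax <- floor(n / 2)
  p <- Mod(X[2:(kmax + 1)])^2
  freqs <- (1:kmax) * fs / n
  p_all <- sum(p)
  if (p_all == 0) return(0)
  sum(p[freqs >= band[1] & freqs <= band[2]]) / p_all
}

#' Screen filtered components with the adaptive mean-RQI threshold
#'
#' Computes the RQI of each available filtered component, sets the
#' adaptive threshold `T` to the arithmetic mean of the available RQIs,
#' and selects the components with RQI >= T for fusion. Since the maximum
#' is never below the mean, at least one component is always selected.
#' Components missing from `filtered` (e.g. failed fiducial extraction on
#' one channel) are excluded from both the mean and the selection rather
#' than scored zero, so a missing channel does not bias `T` downward.
#'
#' @param filtered Named list of `filtered_rmc` objects (or objects with a
#'   `values` field); `NULL` entries allowed.
#' @param fs Sampling rate of the component series in Hz.
#' @param band Respiratory band in Hz.
#' @return An `rqi_report`: list with `rqi_values` (named, `NA` where
#'   missing), `threshold_T`, `selected` (logical mask, `FALSE` where
#'   missing), `m` (number selected).
#' @export
screen_components <- function(filtered, fs, band = c(0.05, 0.75)) {
  tags <- names(filtered)
  if (is.null(tags) || length(filtered) == 0)
    rf_degenerate("no components available for screening")
  avail <- !vapply(filtered, is.null, TRUE)
  if (!any(avail)) rf_degenerate("no components available for screening")
  rqi <- rep(NA_real_, length(filtered))
  names(rqi) <- tags
  for (i in which(avail))
    rqi[i] <- compute_rqi(filtered[[i]]$values, fs, band)
  thr <- mean(rqi[avail])
  sel <- !is.na(rqi) & rqi >= thr
  structure(list(rqi_values = rqi, threshold_T = thr,
                 selected = sel, m = sum(sel)),
            class = "rqi_report")
}

#' @export
print.rqi_report <- function(x, ...) {
  cat("<rqi_report> T =", format(x$threshold_T, digits = 4), "\n")
  for (nm in names(x$rqi_values))
    cat(sprintf("  %-4s RQI %s %s\n", nm,
                format(x$rqi_values[[nm]], digits = 4),
                if (isTRUE(x$selected[[nm]])) "*" else ""))
  invisible(x)
}
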