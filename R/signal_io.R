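#' Construct a multichannel waveform record
#'
#' A `waveform_record` bundles one or more uniformly sampled channels with
#' possibly different sampling rates. Channel labels are normalized to the
#' set `ecg`, `ppg`, `resp`, `rr_ref`.
#'
#' @param channels Named list; each element a list with fields `samples`
#'   (finite numeric vector), `fs` (Hz, > 0) and optionally `units`.
#' @param subject_id Identifier string.
#' @return An object of class `waveform_record`.
#' @export
waveform_record <- function(channels, subject_id = "unknown") {
  if (length(channels) == 0 || is.null(names(channels)))
    rf_channel_error("channels must be a non-empty named list")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (is.null(ch$fs) || ch$fs <= 0)
      rf_data_error("channel '%s': fs must be positive", nm)
    if (!all(is.finite(ch$samples)))
      rf_data_error("channel '%s': non-finite samples", nm)
    if (is.null(ch$units)) channels[[nm]]$units <- "a.u."
  }
  durations <- vapply(channels, function(ch) length(ch$samples) / ch$fs, 0)
  rec <- list(
    channels = channels,
    duration = max(durations),
    subject_id = subject_id
  )
  class(rec) <- "waveform_record"
  rec
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record> subject %s, %.1f s\n", x$subject_id, x$duration))
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    cat(sprintf("  %-7s %7d samples @ %g Hz [%s]\n",
                nm, length(ch$samples), ch$fs, ch$units))
  }
  invisible(x)
}

## Label normalization: map free-form channel names onto the canonical set.
.default_label_map <- list(
  ecg    = c("ecg", "ekg", "ii", "lead_ii", "v", "mlii"),
  ppg    = c("ppg", "pleth", "pulse", "spo2_wave"),
  resp   = c("resp", "respiration", "co2", "capnogram", "imp", "airflow"),
  rr_ref = c("rr_ref", "rr", "resp_rate", "reference_rr")
)

normalize_label <- function(label, label_map = .default_label_map) {
  key <- tolower(gsub("[^a-z0-9_]", "", tolower(label)))
  for (canon in names(label_map))
    if (key %in% label_map[[canon]] || key == canon) return(canon)
  NA_character_
}

#' Load a waveform record from disk
#'
#' Two formats are supported. `csv`: `path` is a directory holding one
#' two-column CSV per channel (header `time,value`, '.' decimal, UTF-8);
#' the file stem names the channel and the sampling rate is inferred from
#' the time column. `wfdb`: `path` is the record name (path to the `.hea`
#' header without extension); a minimal reader for WFDB signal formats 16
#' and 212 is included since no installed package reads WFDB in R.
#'
#' At least one ECG-like and one PPG-like channel must be identifiable
#' through `label_map`; unrecognized files/signals are skipped with a
#' message.
#'
#' @param path Directory of CSVs, or WFDB record name.
#' @param format `"csv"` or `"wfdb"`.
#' @param subject_id Optional identifier; defaults to the basename of `path`.
#' @param label_map Named list mapping canonical labels (`ecg`, `ppg`,
#'   `resp`, `rr_ref`) to accepted lower-case aliases.
#' @return A [waveform_record()].
#' @export
load_record <- function(path, format = c("csv", "wfdb"),
                        subject_id = NULL,
                        label_map = .default_label_map) {
  format <- match.arg(format)
  if (is.null(subject_id)) subject_id <- basename(path)
  channels <- switch(format,
    csv  = load_record_csv(path, label_map),
    wfdb = load_record_wfdb(path, label_map)
  )
  if (!("ecg" %in% names(channels)) || !("ppg" %in% names(channels)))
    rf_channel_error("record must contain identifiable ecg and ppg channels (found: %s)",
                     paste(names(channels), collapse = ", "))
  waveform_record(channels, subject_id = subject_id)
}

load_record_csv <- function(path, label_map) {
  if (!dir.exists(path)) rf_data_error("record directory not found: %s", path)
  files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
  if (length(files) == 0) rf_data_error("no CSV channel files in %s", path)
  channels <- list()
  for (f in files) {
    canon <- normalize_label(sub("\\.csv$", "", basename(f)), label_map)
    if (is.na(canon)) {
      message("skipping unrecognized channel file: ", basename(f))
      next
    }
    if (canon %in% names(channels))
      rf_channel_error("ambiguous channel label '%s' (multiple files map to it)", canon)
    d <- utils::read.csv(f)
    if (!all(c("time", "value") %in% names(d)))
      rf_data_error("%s: expected columns 'time,value'", basename(f))
    if (!all(is.finite(d$value)) || !all(is.finite(d$time)))
      rf_data_error("%s: non-finite samples", basename(f))
    dt <- diff(d$time)
    if (any(dt <= 0)) rf_data_error("%s: time column not strictly increasing", basename(f))
    fs <- 1 / stats::median(dt)
    ## snap to an integer rate when the time stamps are consistent with one
    if (abs(fs - round(fs)) < 1e-6 * fs) fs <- round(fs)
    channels[[canon]] <- list(samples = d$value, fs = fs, units = "a.u.")
  }
  channels
}

## Minimal WFDB reader: text header plus formats 16 (16-bit LE) and
## 212 (packed 12-bit pairs). Enough for the common open ECG/PPG records.
load_record_wfdb <- function(record, label_map) {
  hea <- paste0(record, ".hea")
  if (!file.exists(hea)) rf_data_error("WFDB header not found: %s", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(sub("/.*", "", top[3])) else 250
  sigs <- lines[2:(1 + nsig)]
  specs <- lapply(sigs, function(l) {
    p <- strsplit(trimws(l), "\\s+")[[1]]
    fmt <- as.integer(sub("x.*|:.*|\\+.*", "", p[2]))
    gain <- if (length(p) >= 3) as.numeric(sub("\\(.*", "", sub("/.*", "", p[3]))) else 200
    if (!is.finite(gain) || gain == 0) gain <- 200
    baseline <- if (length(p) >= 3 && grepl("\\(", p[3]))
      as.numeric(sub(".*\\((-?[0-9]+)\\).*", "\\1", p[3])) else 0
    desc <- if (length(p) >= 9) paste(p[9:length(p)], collapse = "_") else paste0("sig", seq_along(sigs))
    list(file = p[1], fmt = fmt, gain = gain, baseline = baseline, desc = desc)
  })
  channels <- list()
  for (fname in unique(vapply(specs, `[[`, "", "file"))) {
    idx <- which(vapply(specs, `[[`, "", "file") == fname)
    fmt <- specs[[idx[1]]]$fmt
    datpath <- file.path(dirname(hea), fname)
    if (!file.exists(datpath)) rf_data_error("WFDB signal file not found: %s", datpath)
    raw <- readBin(datpath, "raw", n = file.info(datpath)$size)
    vals <- switch(as.character(fmt),
      "16" = readBin(raw, "integer", n = length(raw) / 2, size = 2,
                     signed = TRUE, endian = "little"),
      "212" = read_fmt212(raw),
      rf_data_error("unsupported WFDB format %d (formats 16 and 212 supported)", fmt)
    )
    ns <- length(idx)
    vals <- vals[seq_len((length(vals) %/% ns) * ns)]
    mat <- matrix(vals, ncol = ns, byrow = TRUE)
    for (j in seq_along(idx)) {
      sp <- specs[[idx[j]]]
      canon <- normalize_label(sp$desc, label_map)
      if (is.na(canon)) {
        message("skipping unrecognized WFDB signal: ", sp$desc)
        next
      }
      if (canon %in% names(channels)) next
      x <- (mat[, j] - sp$baseline) / sp$gain
      if (!all(is.finite(x))) rf_data_error("WFDB signal '%s': non-finite samples", sp$desc)
      channels[[canon]] <- list(samples = x, fs = fs, units = "physical")
    }
  }
  channels
}

read_fmt212 <- function(raw) {
  n <- (length(raw) %/% 3) * 3
  b <- as.integer(raw[seq_len(n)])
  b1 <- b[seq(1, n, 3)]; b2 <- b[seq(2, n, 3)]; b3 <- b[seq(3, n, 3)]
  s1 <- b1 + bitwAnd(b2, 15L) * 256L
  s2 <- b3 + bitwAnd(bitwShiftR(b2, 4L), 15L) * 256L
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  as.vector(rbind(s1, s2))
}

#' Write a record as per-channel CSV files
#'
#' Inverse of [load_record()]'s CSV format: one `<label>.csv` with columns
#' `time,value` per channel.
#'
#' @param record A [waveform_record()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_record_csv <- function(record, dir) {
  stopifnot(inherits(record, "waveform_record"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(record$channels)) {
    ch <- record$channels[[nm]]
    d <- data.frame(time = (seq_along(ch$samples) - 1) / ch$fs,
                    value = ch$samples)
    utils::write.csv(d, file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  invisible(dir)
}

#' Band-limited resampling of a uniformly sampled signal
#'
#' Windowed-sinc (Hann-windowed) polyphase interpolation with odd
#' (point-symmetric) edge extension; the kernel cutoff is lowered when
#' downsampling so the result stays alias-free.
#'
#' @param x Numeric vector.
#' @param fs_in,fs_out Input and output sampling rates in Hz.
#' @param half_width Kernel half-width in output-band zero crossings.
#' @return Numeric vector of length `floor((length(x)-1)*fs_out/fs_in)+1`.
#' @export
resample_uniform <- function(x, fs_in, fs_out, half_width = 16) {
  if (fs_in == fs_out) return(x)
  n <- length(x)
  ratio <- fs_out / fs_in
  cutoff <- min(1, ratio)
  m <- floor((n - 1) * ratio) + 1
  tout <- (seq_len(m) - 1) / ratio
  reach <- ceiling(half_width / cutoff) + 1
  if (n < reach + 2) rf_short_window("signal too short to resample (%d samples)", n)
  pad <- reach + 1
  xe <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- numeric(m)
  for (k in seq_len(m)) {
    c0 <- tout[k]
    i <- (floor(c0) - reach):(ceiling(c0) + reach)
    s <- (i - c0) * cutoff
    snc <- ifelse(s == 0, 1, sin(pi * s) / (pi * s))
    w <- cutoff * snc * ifelse(abs(s) <= half_width,
                               0.5 + 0.5 * cos(pi * s / half_width), 0)
    y[k] <- sum(xe[i + pad + 1] * w)
  }
  y
}

## Zero-phase IIR filtering. Forward and backward passes are each started
## from the filter's steady state for the edge-local signal level (mean of
## `init_span` leading samples), so a constant input maps exactly to its
## (DC-gain scaled) constant output and a high-pass annihilates DC to
## machine precision. The local-mean initialization keeps a fast excursion
## at the window edge (e.g. a QRS complex on the first sample) from being
## mistaken for the slow level, which would otherwise inject a long
## decaying baseline transient. Short odd extension absorbs the remainder.
filtfilt_ss <- function(b, a, x, init_span = 1L) {
  nn <- max(length(a), length(b))
  pad <- 3 * (nn - 1)
  n <- length(x)
  if (n <= pad + 1) rf_short_window("signal too short for zero-phase filtering")
  xe <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  g <- sum(b) / sum(a)
  ff <- function(u) {
    c0 <- mean(u[seq_len(min(length(u), init_span))])
    as.numeric(signal::filter(b, a, u,
                              init.x = rep(c0, length(b) - 1),
                              init.y = rep(g * c0, length(a) - 1)))
  }
  y <- rev(ff(xe))
  y <- rev(ff(y))
  y[(pad + 1):(pad + n)]
}

## Centered moving average with reflective edge padding. An even length is
## applied with a half-sample asymmetry (floor(n/2) left, the rest right);
## at 300 Hz the residual delay of a 10-point smoother is 1.7 ms.
moving_average <- function(x, n_points) {
  if (n_points <= 1) return(x)
  n <- length(x)
  lpad <- floor((n_points - 1) / 2)
  rpad <- n_points - 1 - lpad
  xe <- c(rev(x[seq_len(lpad) + 1]), x, rev(x[(n - rpad):(n - 1)]))
  cs <- c(0, cumsum(xe))
  (cs[(n_points + 1):(n_points + n)] - cs[1:n]) / n_points
}

#' Preprocess a window of ECG or PPG
#'
#' The denoising chain applied to every analysis window: a
#' `cfg$smoothing_points`-sample centered moving average to attenuate
#' high-frequency noise, then a zero-phase (forward-backward) Butterworth
#' high-pass of order `cfg$highpass_order` at `cfg$highpass_cutoff_hz` to
#' remove slow drift. The effective attenuation is the squared magnitude
#' response of the analog prototype; fiducial timing is preserved because
#' the chain has zero phase.
#'
#' @param x Numeric vector sampled at `fs`.
#' @param fs Sampling rate in Hz (the window's working rate).
#' @param cfg A [pipeline_config()].
#' @return Numeric vector, same length as `x`.
#' @export
preprocess <- function(x, fs, cfg = pipeline_config()) {
  if (length(x) < 12 * max(3 * cfg$highpass_order, cfg$smoothing_points))
    rf_short_window("window of %d samples too short for stable filtering", length(x))
  sm <- moving_average(x, cfg$smoothing_points)
  bf <- signal::butter(cfg$highpass_order, cfg$highpass_cutoff_hz / (fs / 2),
                       type = "high")
  ## initialize the high-pass from ~0.25/fc s of edge-local mean so that a
  ## beat landing on the window edge does not masquerade as baseline
  span <- max(1L, min(length(sm), round(0.25 * fs / cfg$highpass_cutoff_hz)))
  filtfilt_ss(bf$b, bf$a, sm, init_span = span)
}

#' Cut a record into analysis windows
#'
#' Windows are half-open intervals `[k*step, k*step + L)` with
#' `step = L * cfg$step_fraction`; only fully contained windows are
#' produced (trailing partial windows are dropped). Within each window the
#' ECG and PPG channels are resampled to `cfg$target_fs`. When the record
#' carries an `rr_ref` channel its median over the window is attached as
#' the reference rate.
#'
#' @param record A [waveform_record()] with `ecg` and `ppg` channels.
#' @param cfg A [pipeline_config()].
#' @return A list of `analysis_window` objects (fields `start_time`,
#'   `length_s`, `fs`, `ecg`, `ppg`, `ref_rr`). A record shorter than one
#'   window yields an empty list with a warning.
#' @export
segment_windows <- function(record, cfg = pipeline_config()) {
  stopifnot(inherits(record, "waveform_record"))
  L <- cfg$window_length_s
  if (record$duration < L) {
    warning("record shorter than one window; no windows produced")
    return(list())
  }
  step <- L * cfg$step_fraction
  starts <- seq(0, record$duration - L, by = step)
  nsamp <- round(L * cfg$target_fs)
  lapply(starts, function(s0) {
    chans <- lapply(c("ecg", "ppg"), function(nm) {
      ch <- record$channels[[nm]]
      i0 <- floor(s0 * ch$fs) + 1
      i1 <- min(i0 + round(L * ch$fs) - 1, length(ch$samples))
      seg <- ch$samples[i0:i1]
      if (ch$fs != cfg$target_fs)
        seg <- resample_uniform(seg, ch$fs, cfg$target_fs)
      length(seg) <- nsamp            # pad/trim the off-by-one sample
      seg[is.na(seg)] <- seg[max(which(!is.na(seg)))]
      seg
    })
    ref_rr <- NA_real_
    if ("rr_ref" %in% names(record$channels)) {
      ch <- record$channels$rr_ref
      i0 <- floor(s0 * ch$fs) + 1
      i1 <- min(max(i0, floor((s0 + L) * ch$fs)), length(ch$samples))
      ref_rr <- stats::median(ch$samples[i0:i1])
    }
    w <- list(start_time = s0, length_s = L, fs = cfg$target_fs,
              ecg = chans[[1]], ppg = chans[[2]], ref_rr = ref_rr)
    class(w) <- "analysis_window"
    w
  })
}
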