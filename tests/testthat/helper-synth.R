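## Shared fixture builders. Records are generated in code at test time;
## short durations keep the suite fast while leaving >= 1 full window.

clean_cfg <- function(duration = 60, hr = 80, rr = 15, seed = 1) {
  synth_config(duration = duration, hr_bpm = hr, rr_bpm = rr,
               noise_snr_db = Inf, seed = seed)
}

noisy_cfg <- function(duration = 60, hr = 80, rr = 15, seed = 1, snr = 20) {
  synth_config(duration = duration, hr_bpm = hr, rr_bpm = rr,
               noise_snr_db = snr, seed = seed)
}

## beat-matching: recall / precision / timing of detected vs true event times
match_events <- function(detected_s, truth_s, tol_s) {
  used <- rep(FALSE, length(truth_s))
  hits <- 0L
  errs <- c()
  for (d in detected_s) {
    j <- which(!used & abs(truth_s - d) <= tol_s)
    if (length(j) > 0) {
      j <- j[which.min(abs(truth_s[j] - d))]
      used[j] <- TRUE
      hits <- hits + 1L
      errs <- c(errs, abs(truth_s[j] - d))
    }
  }
  list(recall = hits / length(truth_s),
       precision = hits / length(detected_s),
       max_err = if (length(errs)) max(errs) else Inf)
}
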