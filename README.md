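# respifuse

Continuous respiratory-rate (RR) estimation from simultaneous single-channel
ECG and PPG, for anyone who needs breaths-per-minute out of wearable or
bedside cardiovascular waveforms without a dedicated respiration sensor:
physiological-signal researchers, monitoring-algorithm developers, and
clinical data scientists working with datasets that pair ECG/PPG with a
reference respiration channel.

## The method

Respiration modulates both waveforms through three mechanisms, giving six
beat-domain *respiratory modulated components* (RMCs):

| ECG | PPG | mechanism |
|-----|-----|-----------|
| EAM = R − Q amplitude | PAM = systolic peak − onset | amplitude modulation |
| EFM = R–R interval | PFM = peak-to-peak interval | respiratory sinus arrhythmia |
| EBW = (R + Q)/2 | PBW = (peak + onset)/2 | baseline wander |

Per 30 s analysis window the pipeline:

1. resamples to 300 Hz, applies a 10-point smoother and a zero-phase
   third-order 0.05 Hz Butterworth high-pass;
2. detects R peaks (Pan–Tompkins), Q waves (minimum in the 200 ms before
   R), PPG onsets (slope-sum upstroke + foot marking) and systolic peaks
   (maximum within 125 ms after the onset);
3. builds the six beat series above and spline-resamples each to a uniform
   10 Hz grid;
4. denoises each series with variational mode decomposition (K = 5) and
   keeps the mode whose spectral peak is closest to the input's;
5. scores each filtered component with the respiratory quality index
   RQI = P_band / P_total — the fraction of (non-DC) spectral power inside
   the respiratory band 0.05–0.75 Hz (3–45 breaths/min) — and keeps the m
   components with RQI ≥ T, where T is the mean RQI of the window;
6. fuses the m survivors through their first principal component
   (RW = X q₁, loadings unit-norm) and reads the rate off the fused
   waveform's spectral peak: RR = 60 · f_peak.

Agreement against a reference rate is summarized by ME, STD (n−1), MAE,
RMSE and Bland–Altman bias with ±1.96 SD limits of agreement.

A synthetic cardiorespiratory generator (`generate_record()`) produces
paired ECG/PPG with a shared modulated beat process, known modulation
depths, additive noise, and exact fiducial ground truth, so every stage is
testable without external data.

## Worked example

```r
library(respifuse)

cfg <- synth_config(duration = 120, hr_bpm = 80, rr_bpm = 15,
                    noise_snr_db = 20, seed = 42)
rec <- generate_record(cfg)
rec
#> <waveform_record> subject synth-0042, 120.0 s
#>   ecg       36000 samples @ 300 Hz [mV]
#>   ppg       36000 samples @ 300 Hz [a.u.]
#>   resp      36000 samples @ 300 Hz [a.u.]
#>   rr_ref      120 samples @ 1 Hz [breaths/min]

est <- run_pipeline(rec, pipeline_config())
est[, c("window_start_s", "rr_est_bpm", "m_used", "threshold_T", "flags")]
#>   window_start_s rr_est_bpm m_used threshold_T flags
#> 1              0   14.72168      5   0.9956908
#> 2             30   14.57520      5   0.9992474
#> 3             60   14.53857      5   0.9954589
#> 4             90   14.57520      5   0.9992090

error_metrics(est$rr_est_bpm, est$ref_rr_bpm)
#> <error_summary> n = 4 (0 excluded)
#>   ME -0.397  STD  0.081  MAE  0.397  RMSE  0.404 breaths/min
#>   Bland-Altman bias -0.397, LoA [-0.556, -0.238]
```

Each row is one 30 s window: the estimated rate, how many of the six
components survived quality screening (`m_used`), the adaptive RQI
threshold, and quality flags (empty when every stage succeeded). Here the
true rate is 15 breaths/min and every window recovers it within 0.5.

A command-line front end covers the same workflow from a shell:

```sh
Rscript exec/respifuse simulate --out-dir data --duration 120 --rr 15 --seed 42
Rscript exec/respifuse estimate --input data/synth-0042 --out est.csv
Rscript exec/respifuse evaluate --pred est.csv
Rscript exec/respifuse batch --input-dir data
```

`load_record()` also reads records in CSV (`time,value` per channel) or
WFDB form (signal formats 16/212), so the same harness runs on public
ECG+PPG datasets that ship a reference respiratory annotation.

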