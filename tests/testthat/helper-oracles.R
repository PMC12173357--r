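## Independent oracles, deliberately written without reference to the
## package internals so they can cross-check them.

## Reference VMD: direct transcription of the published ADMM iteration --
## sequential mode sweeps (each Wiener update sees the modes already
## refreshed this sweep, each center frequency follows its mode
## immediately), on the unshifted [0, 1) frequency grid with symmetric
## signal extension as the algorithm prescribes. Independently written;
## shares no code or conventions with the package implementation.
## Returns center frequencies in Hz, ascending.
reference_vmd_omegas <- function(x, fs, K, alpha = 2000, n_iter = 300) {
  h <- length(x) %/% 2
  x <- c(x[h:1], x, x[length(x):(length(x) - h + 1)])
  N <- length(x)
  Xf <- fft(x)
  f <- (seq_len(N) - 1) / N          # normalized frequency grid [0, 1)
  posk <- which(f <= 0.5)            # one-sided half
  omega <- (seq_len(K) - 0.5) / (2 * K)
  U <- matrix(0 + 0i, N, K)
  for (it in seq_len(n_iter)) {
    for (k in seq_len(K)) {
      others <- rowSums(U) - U[, k]
      U[, k] <- (Xf - others) / (1 + 2 * alpha * (f - omega[k])^2)
      p <- Mod(U[posk, k])^2
      omega[k] <- sum(f[posk] * p) / max(sum(p), .Machine$double.xmin)
    }
  }
  sort(omega) * fs
}

## Brute-force first principal component: covariance assembled by explicit
## sums, dominant eigenvector by power iteration. Independent of eigen().
reference_pc1 <- function(X, n_iter = 2000) {
  n <- nrow(X); m <- ncol(X)
  Xc <- X
  for (j in seq_len(m)) Xc[, j] <- X[, j] - sum(X[, j]) / n
  P <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m))
    P[i, j] <- sum(Xc[, i] * Xc[, j]) / (n - 1)
  v <- rep(1 / sqrt(m), m)
  for (it in seq_len(n_iter)) {
    w <- P %*% v
    v <- as.numeric(w) / sqrt(sum(w^2))
  }
  lambda1 <- as.numeric(t(v) %*% P %*% v)
  if (v[which.max(abs(v))] < 0) v <- -v
  list(loadings = v, scores = as.numeric(Xc %*% v),
       lambda1 = lambda1, total_var = sum(diag(P)))
}

## Simple independent periodogram peak (rectangular window, heavy padding).
naive_peak_freq <- function(x, fs, n_pad = 2^14) {
  xc <- x - mean(x)
  X <- fft(c(xc, rep(0, n_pad - length(xc))))
  kmax <- floor(n_pad / 2)
  p <- Mod(X[2:(kmax + 1)])^2
  ((which.max(p)) * fs) / n_pad
}

## Band-limited random test signal: a few tones inside [f_lo, f_hi].
## Tones are kept at least `min_sep` Hz apart so the decomposition is
## well-posed: below the mode bandwidth (~ fs/sqrt(2*alpha)) the split of
## a tone cluster between modes is arbitrary.
random_bandlimited <- function(n, fs, f_lo, f_hi, n_tones = 3, min_sep = 0.2) {
  t <- (seq_len(n) - 1) / fs
  repeat {
    freqs <- runif(n_tones, f_lo, f_hi)
    if (n_tones < 2 || min(diff(sort(freqs))) >= min_sep) break
  }
  amps <- runif(n_tones, 0.5, 1.5)
  phis <- runif(n_tones, 0, 2 * pi)
  x <- numeric(n)
  for (i in seq_len(n_tones)) x <- x + amps[i] * sin(2 * pi * freqs[i] * t + phis[i])
  list(x = x - mean(x), freqs = sort(freqs))
}
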