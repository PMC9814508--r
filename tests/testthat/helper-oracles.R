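# Independent brute-force oracles, written directly from the published
# definitions. They are deliberately naive (O(N^2) loops) and share no code
# with the implementation.

# direct DFT power spectrum of one frame, zero-padded to n_fft
oracle_power_row <- function(frame, n_fft) {
  x <- c(frame, rep(0, n_fft - length(frame)))
  k_max <- n_fft %/% 2
  sapply(0:k_max, function(k) {
    re <- 0
    im <- 0
    for (n in 0:(n_fft - 1)) {
      re <- re + x[n + 1] * cos(2 * pi * n * k / n_fft)
      im <- im - x[n + 1] * sin(2 * pi * n * k / n_fft)
    }
    (re^2 + im^2) / n_fft
  })
}

# direct log mel band energies for one power row
oracle_logmel_row <- function(p_row, weights, log_floor) {
  sapply(seq_len(nrow(weights)), function(m) {
    acc <- 0
    for (k in seq_along(p_row)) acc <- acc + p_row[k] * weights[m, k]
    log(max(acc, log_floor))
  })
}

# direct DCT (0th coefficient excluded) for one log-energy row
oracle_dct_row <- function(s_row, L) {
  M <- length(s_row)
  sapply(seq_len(L), function(n) {
    acc <- 0
    for (m in seq_len(M)) acc <- acc + s_row[m] * cos(pi * n * (m - 0.5) / M)
    acc
  })
}

# direct delta with edge replication
oracle_delta <- function(C, k) {
  Tn <- nrow(C)
  denom <- sum((-k:k)^2)
  D <- matrix(0, Tn, ncol(C))
  for (t in seq_len(Tn)) {
    for (i in -k:k) {
      ti <- min(max(t + i, 1), Tn)
      D[t, ] <- D[t, ] + i * C[ti, ]
    }
  }
  D / denom
}

# steady-state amplitude of a tone in a signal (via peak of the DFT
# magnitude over an interior window)
tone_amplitude <- function(x, sr, freq, from_s, to_s) {
  seg <- x[round(from_s * sr):round(to_s * sr)]
  n <- length(seg)
  sp <- Mod(stats::fft(seg))
  k <- round(freq * n / sr)
  2 * max(sp[(k - 1):(k + 3)]) / n
}

# fraction of one-sided spectral power below a cutoff
low_band_fraction <- function(x, sr, cutoff) {
  n <- length(x)
  p <- Mod(stats::fft(x))[1:(n %/% 2 + 1)]^2
  f <- (0:(n %/% 2)) * sr / n
  sum(p[f <= cutoff]) / sum(p)
}

# band power of a signal restricted to [f1, f2]
band_power <- function(x, sr, f1, f2) {
  n <- length(x)
  p <- Mod(stats::fft(x))[1:(n %/% 2 + 1)]^2
  f <- (0:(n %/% 2)) * sr / n
  sum(p[f >= f1 & f <= f2]) / n
}

# build a tiny labelled feature table for model tests without the full
# synthesis pipeline (fast, deterministic)
tiny_feature_set <- function(n_per_class = 4, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  labs <- rep(c("normal", "abnormal", "noise"), each = n_per_class)
  feats <- lapply(seq_along(labs), function(i) {
    base <- match(labs[i], c("normal", "abnormal", "noise"))
    matrix(rnorm(199 * 39, mean = base), 199, 39)
  })
  list(features = feats, labels = labs)
}
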