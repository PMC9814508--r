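#' Feature-extraction configuration
#'
#' Bundles every tunable of the improved-MFCC extractor. The defaults are the
#' package's defining convention for 2-s segments at 2000 Hz: 20 ms frames
#' (40 samples) hopped by 10 ms (20 samples) with no centring give exactly
#' 199 frames, each zero-padded to a 256-point FFT; 13 triangular mel filters
#' span 0 Hz to Nyquist; 13 cepstra are kept; difference coefficients use a
#' +/-2 frame regression window.
#'
#' @param preemph_alpha Pre-emphasis coefficient (0 <= alpha < 1).
#' @param hamming_alpha Hamming window alpha (0.46).
#' @param frame_len_samples Frame length in samples.
#' @param hop_samples Hop between frame starts in samples.
#' @param n_fft FFT length (frames are zero-padded up to it).
#' @param n_mels Number of mel filters M.
#' @param n_ceps Number of cepstral coefficients L (<= M).
#' @param delta_k Half-width k of the delta regression window.
#' @param fmin_hz,fmax_hz Filter-bank frequency range; `fmax_hz = NULL` means
#'   the Nyquist frequency of the signal being analysed.
#' @param log_floor Floor inside the log for silent bands.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(preemph_alpha = 0.97, hamming_alpha = 0.46,
                           frame_len_samples = 40L, hop_samples = 20L,
                           n_fft = 256L, n_mels = 13L, n_ceps = 13L,
                           delta_k = 2L, fmin_hz = 0, fmax_hz = NULL,
                           log_floor = 1e-10) {
  stopifnot(preemph_alpha >= 0, preemph_alpha < 1,
            frame_len_samples >= 1, hop_samples >= 1,
            frame_len_samples <= n_fft, n_ceps <= n_mels, n_mels >= 2,
            delta_k >= 1, log_floor > 0)
  structure(
    list(preemph_alpha = preemph_alpha, hamming_alpha = hamming_alpha,
         frame_len_samples = as.integer(frame_len_samples),
         hop_samples = as.integer(hop_samples), n_fft = as.integer(n_fft),
         n_mels = as.integer(n_mels), n_ceps = as.integer(n_ceps),
         delta_k = as.integer(delta_k), fmin_hz = fmin_hz, fmax_hz = fmax_hz,
         log_floor = log_floor),
    class = "feature_config")
}

#' Mel scale conversions
#'
#' `hz_to_mel()` implements the standard perceptual mapping
#' \eqn{\mathrm{mel}(f) = 2595 \log_{10}(1 + f/700)}; `mel_to_hz()` is its
#' exact inverse. Both are strictly increasing bijections on `[0, Inf)`.
#'
#' @param f Frequency in Hz (non-negative).
#' @param m Mel value (non-negative).
#' @return Numeric vector of mels (resp. Hz).
#' @export
hz_to_mel <- function(f) {
  if (any(f < 0)) stop("invalid parameter: negative frequency", call. = FALSE)
  2595 * log10(1 + f / 700)
}

#' @rdname hz_to_mel
#' @export
mel_to_hz <- function(m) {
  if (any(m < 0)) stop("invalid parameter: negative mel value", call. = FALSE)
  700 * (10^(m / 2595) - 1)
}

#' Pre-emphasis high-pass
#'
#' `y[n] = x[n] - alpha * x[n-1]` with the boundary convention `y[1] = x[1]`,
#' boosting the weak high-frequency content of heart sounds before framing.
#'
#' @param x Numeric signal.
#' @param alpha Pre-emphasis coefficient in `[0, 1)` (values near 1 are
#'   typical); `alpha = 1` is allowed for a pure first difference.
#' @return Signal of the same length.
#' @export
pre_emphasize <- function(x, alpha = 0.97) {
  if (alpha < 0 || alpha > 1) {
    stop("invalid parameter: alpha must be in [0, 1]", call. = FALSE)
  }
  n <- length(x)
  if (n <= 1) return(x)
  c(x[1], x[2:n] - alpha * x[1:(n - 1)])
}

# Hamming window of length n with the given alpha (0.46):
# w(i) = 1 - alpha - alpha * cos(2*pi*i/(n-1)), i = 0..n-1.
hamming_window <- function(n, alpha = 0.46) {
  i <- seq_len(n) - 1
  (1 - alpha) - alpha * cos(2 * pi * i / (n - 1))
}

#' Frame a signal and apply the Hamming window
#'
#' Frame `t` (0-based) covers samples `[t*hop, t*hop + frame_len)`; there is
#' no centring and no padding, so the frame count is
#' `floor((length(x) - frame_len) / hop) + 1`. Each frame is multiplied by
#' the Hamming window `1 - alpha - alpha*cos(2*pi*n/(N-1))` with alpha 0.46.
#'
#' @param x Numeric signal (at least one frame long).
#' @param cfg A [feature_config()].
#' @return A `T x frame_len` matrix of windowed frames.
#' @export
frame_and_window <- function(x, cfg = feature_config()) {
  n <- length(x)
  fl <- cfg$frame_len_samples
  hp <- cfg$hop_samples
  if (n < fl) {
    stop("invalid input: signal (", n, " samples) shorter than one frame (",
         fl, ")", call. = FALSE)
  }
  n_frames <- (n - fl) %/% hp + 1L
  starts <- (seq_len(n_frames) - 1L) * hp
  idx <- outer(starts, seq_len(fl), `+`) # T x fl sample indices
  frames <- matrix(x[idx], nrow = n_frames, ncol = fl)
  w <- hamming_window(fl, cfg$hamming_alpha)
  frames * matrix(w, nrow = n_frames, ncol = fl, byrow = TRUE)
}

#' One-sided power spectrum of windowed frames
#'
#' Each frame is zero-padded to `n_fft` and transformed; the power spectrum is
#' `P(k) = |X(k)|^2 / n_fft` for the one-sided bins `k = 0 .. n_fft/2`.
#'
#' @param frames `T x frame_len` matrix from [frame_and_window()].
#' @param cfg A [feature_config()].
#' @return A `T x (n_fft/2 + 1)` non-negative matrix.
#' @export
power_spectrum <- function(frames, cfg = feature_config()) {
  nf <- cfg$n_fft
  stopifnot(ncol(frames) <= nf)
  padded <- matrix(0, nrow = nf, ncol = nrow(frames))
  padded[seq_len(ncol(frames)), ] <- t(frames)
  X <- stats::mvfft(padded)
  k <- nf %/% 2 + 1L
  t(Mod(X[seq_len(k), , drop = FALSE])^2) / nf
}

#' Build the triangular mel filter bank
#'
#' `n_mels + 2` edge frequencies are placed uniformly on the mel scale
#' between `fmin_hz` and `fmax_hz`, converted back to Hz and quantised to
#' one-sided FFT bins. Filter m rises linearly from bin `f(m-1)` to a unit
#' peak at `f(m)` and falls to zero at `f(m+1)`. With unit peaks and shared
#' edges, the filter responses of adjacent triangles sum to exactly 1 at
#' every interior bin — the bank's defining normalisation property.
#'
#' @param cfg A [feature_config()].
#' @param sample_rate_hz Sampling rate of the analysed signal.
#' @return A list of class `mel_filter_bank` with `weights`
#'   (`n_mels x (n_fft/2 + 1)`), `center_bins` and `edge_bins`.
#' @export
build_mel_filter_bank <- function(cfg = feature_config(),
                                  sample_rate_hz = 2000L) {
  nyq <- sample_rate_hz / 2
  fmax <- if (is.null(cfg$fmax_hz)) nyq else cfg$fmax_hz
  if (fmax > nyq) {
    stop("invalid parameter: fmax_hz above Nyquist", call. = FALSE)
  }
  m_edges <- seq(hz_to_mel(cfg$fmin_hz), hz_to_mel(fmax),
                 length.out = cfg$n_mels + 2L)
  hz_edges <- mel_to_hz(m_edges)
  bins <- floor((cfg$n_fft + 1) * hz_edges / sample_rate_hz)
  n_bins <- cfg$n_fft %/% 2 + 1L
  bins <- pmin(bins, n_bins - 1L)
  if (any(diff(bins) < 1)) {
    stop("configuration error: mel filter with coincident edge bins; ",
         "increase n_fft or reduce n_mels", call. = FALSE)
  }
  W <- matrix(0, nrow = cfg$n_mels, ncol = n_bins)
  k <- seq(0, n_bins - 1L)
  for (m in seq_len(cfg$n_mels)) {
    lo <- bins[m]; ce <- bins[m + 1]; hi <- bins[m + 2]
    rise <- k >= lo & k <= ce
    fall <- k > ce & k <= hi
    W[m, rise] <- (k[rise] - lo) / (ce - lo)
    W[m, fall] <- (hi - k[fall]) / (hi - ce)
  }
  structure(list(weights = W, center_bins = bins[2:(cfg$n_mels + 1L)],
                 edge_bins = bins, sample_rate_hz = sample_rate_hz),
            class = "mel_filter_bank")
}

#' Log mel band energies
#'
#' `S(m) = ln( max( sum_k P(k) H_m(k), log_floor) )` per frame; the floor
#' keeps silent frames finite.
#'
#' @param P `T x K` power-spectrum matrix.
#' @param bank A [build_mel_filter_bank()] result.
#' @param cfg A [feature_config()].
#' @return A `T x n_mels` matrix of natural-log band energies.
#' @export
log_mel_energies <- function(P, bank, cfg = feature_config()) {
  stopifnot(ncol(P) == ncol(bank$weights))
  E <- P %*% t(bank$weights)
  log(pmax(E, cfg$log_floor))
}

#' Cepstra by discrete cosine transform
#'
#' `C(n) = sum_{m=1..M} S(m) cos(pi * n * (m - 0.5) / M)` for `n = 1..L`
#' (DCT-II family with the 0th, pure-energy coefficient excluded).
#'
#' @param S `T x M` log-energy matrix.
#' @param cfg A [feature_config()].
#' @return A `T x n_ceps` cepstral matrix.
#' @export
dct_cepstra <- function(S, cfg = feature_config()) {
  M <- ncol(S)
  L <- cfg$n_ceps
  stopifnot(L <= M)
  m <- seq_len(M) - 0.5
  D <- cos(pi * outer(m, seq_len(L)) / M) # M x L
  S %*% D
}

#' Temporal difference (delta) coefficients
#'
#' The regression-style derivative over time,
#' `D(t) = sum_{i=-k..k} i * C(t+i) / sum_{i=-k..k} i^2`, applied per
#' cepstral coefficient; frames past either edge are replicated, which
#' preserves the frame count and yields exact zeros on time-constant input.
#' Applying it twice gives the second-order (delta-delta) coefficients.
#'
#' @param C `T x L` matrix (frames in rows).
#' @param k Regression half-width (default 2; denominator is then 10).
#' @return A `T x L` matrix of the same shape.
#' @export
delta_coefficients <- function(C, k = 2L) {
  if (k < 1) stop("invalid parameter: k must be >= 1", call. = FALSE)
  Tn <- nrow(C)
  denom <- 2 * sum(seq_len(k)^2)
  D <- matrix(0, nrow = Tn, ncol = ncol(C))
  for (i in seq_len(k)) {
    fwd <- pmin(seq_len(Tn) + i, Tn) # edge replication
    bwd <- pmax(seq_len(Tn) - i, 1L)
    D <- D + i * (C[fwd, , drop = FALSE] - C[bwd, , drop = FALSE])
  }
  D / denom
}

#' Improved MFCC feature matrix of a segment
#'
#' Runs the full chain — pre-emphasis, framing + Hamming window, one-sided
#' power spectrum, mel filter bank, natural log, DCT, then first- and
#' second-order difference coefficients — and stacks the three `T x 13`
#' blocks column-wise into the `T x 39` network input (199 x 39 for a
#' standard 2-s, 2000 Hz segment).
#'
#' @param samples Numeric vector (a segment; 4000 samples for the default
#'   configuration) or one row of a segment tibble via `samples[[i]]`.
#' @param sample_rate_hz Sampling rate of the segment (default 2000).
#' @param cfg A [feature_config()].
#' @return An object of class `feature_matrix`: list with `mfcc`, `delta`,
#'   `delta2` (each `T x n_ceps`) and `stacked` (`T x 3*n_ceps`).
#' @export
improved_mfcc <- function(samples, sample_rate_hz = 2000L,
                          cfg = feature_config()) {
  y <- pre_emphasize(samples, cfg$preemph_alpha)
  frames <- frame_and_window(y, cfg)
  P <- power_spectrum(frames, cfg)
  bank <- build_mel_filter_bank(cfg, sample_rate_hz)
  S <- log_mel_energies(P, bank, cfg)
  C <- dct_cepstra(S, cfg)
  D <- delta_coefficients(C, cfg$delta_k)
  D2 <- delta_coefficients(D, cfg$delta_k)
  structure(list(mfcc = C, delta = D, delta2 = D2,
                 stacked = cbind(C, D, D2), config = cfg),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d frames x %d coefficients (static|d|d2)\n",
              nrow(x$stacked), ncol(x$stacked)))
  invisible(x)
}

#' Extract features for every segment in a segment tibble
#'
#' @param segments Segment tibble from [segment_audio()] /
#'   [preprocess_manifest()].
#' @param cfg A [feature_config()].
#' @param block Which block to keep: `"improved_mfcc"` (the stacked T x 39
#'   matrix), `"mfcc"`, `"delta"` or `"delta2"`.
#' @return The input tibble with a `features` list-column of matrices.
#' @export
extract_features <- function(segments, cfg = feature_config(),
                             block = c("improved_mfcc", "mfcc", "delta",
                                       "delta2")) {
  block <- match.arg(block)
  field <- if (block == "improved_mfcc") "stacked" else block
  segments$features <- lapply(segments$samples, function(s) {
    improved_mfcc(s, sample_rate_hz = 2000L, cfg = cfg)[[field]]
  })
  segments
}

#' Persist a feature matrix with its configuration
#'
#' Writes the stacked matrix as a plain CSV next to a JSON sidecar holding
#' the full [feature_config()], so a run can be reloaded or audited.
#'
#' @param fm A `feature_matrix`.
#' @param path Output CSV path (`<path>.json` records the configuration).
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  utils::write.table(fm$stacked, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(unclass(fm$config), paste0(path, ".json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}
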