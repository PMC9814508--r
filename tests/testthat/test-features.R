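cfg <- feature_config()

test_that("mel scale is the standard bijection", {
  expect_equal(hz_to_mel(0), 0)
  expect_equal(hz_to_mel(700), 2595 * log10(2))
  set.seed(1)
  f <- stats::runif(50, 0, 1000)
  expect_equal(mel_to_hz(hz_to_mel(f)), f, tolerance = 1e-9)
  expect_true(all(diff(hz_to_mel(seq(0, 1000, by = 10))) > 0))
  expect_error(hz_to_mel(-1), "negative")
})

test_that("pre-emphasis implements y[n] = x[n] - alpha x[n-1]", {
  x <- rnorm(100)
  expect_identical(pre_emphasize(x, 0), x)
  const <- pre_emphasize(rep(3, 10), 0.97)
  expect_equal(const, c(3, rep(0.03 * 3, 9)))
  ramp <- pre_emphasize(0:9, 1)
  expect_equal(ramp[-1], rep(1, 9))
  expect_error(pre_emphasize(x, 1.5), "alpha")
})

test_that("framing yields 199 frames for a 2-s segment and windows correctly", {
  frames <- frame_and_window(rnorm(4000), cfg)
  expect_equal(dim(frames), c(199L, 40L))

  # window values from the definition: centre 1, endpoints 1 - 2*0.46
  w <- cardiomel:::hamming_window(41, 0.46) # odd length has an exact centre
  expect_equal(w[21], 1.0)
  expect_equal(w[1], 0.08)
  expect_equal(w[41], 0.08)

  # recover the window by framing a constant signal
  ones <- frame_and_window(rep(1, 4000), cfg)
  expect_equal(ones[1, ], cardiomel:::hamming_window(40, 0.46))

  expect_error(frame_and_window(rnorm(10), cfg), "shorter than one frame")
})

test_that("frame count formula holds for random signal lengths", {
  set.seed(2)
  for (n in sample(40:5000, 25)) {
    frames <- frame_and_window(rnorm(n), cfg)
    expect_equal(nrow(frames), (n - 40) %/% 20 + 1)
  }
})

test_that("power spectrum matches the direct DFT oracle", {
  zero <- power_spectrum(matrix(0, 1, 40), cfg)
  expect_equal(as.numeric(zero), rep(0, 129))

  impulse <- matrix(c(1, rep(0, 39)), 1, 40)
  p <- power_spectrum(impulse, cfg)
  expect_equal(as.numeric(p), rep(1 / 256, 129))

  set.seed(3)
  small_cfg <- feature_config(frame_len_samples = 12L, hop_samples = 6L,
                              n_fft = 16L, n_mels = 4L, n_ceps = 3L)
  for (rep in 1:10) {
    frames <- matrix(rnorm(5 * 12), 5, 12)
    p <- power_spectrum(frames, small_cfg)
    for (t in 1:5) {
      expect_equal(p[t, ], oracle_power_row(frames[t, ], 16),
                   tolerance = 1e-9)
    }
  }
})

test_that("mel filter bank has unit peaks and interior columns summing to 1", {
  bank <- build_mel_filter_bank(cfg, 2000L)
  expect_equal(dim(bank$weights), c(13L, 129L))

  # unit peak at each centre bin
  for (m in 1:13) {
    expect_equal(bank$weights[m, bank$center_bins[m] + 1], 1)
    expect_equal(max(bank$weights[m, ]), 1)
  }
  # support confined to [f(m-1), f(m+1)]
  for (m in 1:13) {
    outside <- setdiff(0:128, bank$edge_bins[m]:bank$edge_bins[m + 2])
    expect_true(all(bank$weights[m, outside + 1] == 0))
  }
  # interior column sums are exactly 1
  interior <- (bank$center_bins[1]):(bank$center_bins[13])
  expect_equal(colSums(bank$weights)[interior + 1], rep(1, length(interior)),
               tolerance = 1e-6, ignore_attr = TRUE)

  # midpoint of the rising edge sits at 0.5 up to one-bin quantisation
  m <- 7
  lo <- bank$edge_bins[m]; ce <- bank$edge_bins[m + 1]
  mid <- (lo + ce) / 2
  expect_lt(abs(bank$weights[m, floor(mid) + 1] - 0.5), 1 / (ce - lo))

  expect_error(build_mel_filter_bank(feature_config(n_fft = 16L,
                                                    n_mels = 13L,
                                                    frame_len_samples = 16L),
                                     2000L),
               "coincident")
  expect_error(build_mel_filter_bank(feature_config(fmax_hz = 1500), 2000L),
               "Nyquist")
})

test_that("column sums stay normalised across FFT sizes and rates", {
  for (sr in c(2000L, 4000L)) {
    for (nf in c(256L, 512L)) {
      b <- build_mel_filter_bank(feature_config(n_fft = nf), sr)
      interior <- (b$center_bins[1]):(b$center_bins[13])
      expect_equal(colSums(b$weights)[interior + 1],
                   rep(1, length(interior)), tolerance = 1e-6,
                   ignore_attr = TRUE)
    }
  }
})

test_that("log mel energies floor silence and match the direct oracle", {
  bank <- build_mel_filter_bank(cfg, 2000L)
  zero <- log_mel_energies(matrix(0, 1, 129), bank, cfg)
  expect_equal(as.numeric(zero), rep(log(1e-10), 13))

  set.seed(4)
  p <- matrix(abs(rnorm(3 * 129)), 3, 129)
  s <- log_mel_energies(p, bank, cfg)
  a <- 7.3
  s_scaled <- log_mel_energies(a * p, bank, cfg)
  expect_equal(s_scaled, s + log(a), tolerance = 1e-12)
  for (t in 1:3) {
    expect_equal(s[t, ], oracle_logmel_row(p[t, ], bank$weights, 1e-10),
                 tolerance = 1e-9)
  }
})

test_that("cepstral DCT obeys cosine orthogonality and the direct oracle", {
  const <- dct_cepstra(matrix(5.5, 2, 13), cfg)
  expect_equal(as.numeric(const), rep(0, 2 * 13), tolerance = 1e-12)

  M <- 13
  # orthogonality holds for j <= M - 1 (the j = M basis vector is identically
  # zero at the half-sample points)
  for (j in c(1, 4, 12)) {
    s <- matrix(cos(pi * j * ((1:M) - 0.5) / M), 1, M)
    cj <- dct_cepstra(s, cfg)
    expected <- numeric(13); expected[j] <- M / 2
    expect_lt(max(abs(as.numeric(cj) - expected)), 1e-9)
  }

  set.seed(5)
  s <- matrix(rnorm(4 * 13), 4, 13)
  C <- dct_cepstra(s, cfg)
  for (t in 1:4) {
    expect_equal(C[t, ], oracle_dct_row(s[t, ], 13), tolerance = 1e-9)
  }
})

test_that("delta operator differentiates ramps exactly and matches its oracle", {
  const <- delta_coefficients(matrix(2.5, 9, 3))
  expect_equal(as.numeric(const), rep(0, 27))

  ramp <- matrix(rep(1:20, 3), 20, 3)
  d <- delta_coefficients(ramp)
  expect_equal(as.numeric(d[3:18, ]), rep(1, 16 * 3))

  # second difference of a quadratic is constant away from the edges
  quad <- matrix(rep((1:20)^2, 2), 20, 2)
  d2 <- delta_coefficients(delta_coefficients(quad))
  expect_equal(as.numeric(d2[5:16, ]), rep(2, 12 * 2), tolerance = 1e-9)

  set.seed(6)
  C <- matrix(rnorm(8 * 5), 8, 5)
  expect_equal(delta_coefficients(C, 2), oracle_delta(C, 2),
               tolerance = 1e-12)
  expect_equal(delta_coefficients(C, 3), oracle_delta(C, 3),
               tolerance = 1e-12)
  expect_error(delta_coefficients(C, 0), "k must be")
})

test_that("improved MFCC stacks three 199x13 blocks deterministically", {
  rec <- synth_recording("abnormal", 2, synth_config(seed = 21))
  fm <- improved_mfcc(rec$samples)
  expect_equal(dim(fm$mfcc), c(199L, 13L))
  expect_equal(dim(fm$stacked), c(199L, 39L))
  expect_identical(fm$stacked, cbind(fm$mfcc, fm$delta, fm$delta2))

  fm2 <- improved_mfcc(rec$samples)
  expect_identical(fm$stacked, fm2$stacked)
})

test_that("amplitude scaling cancels out of the cepstra (log/DCT identity)", {
  # a gain a scales the power spectrum by a^2, shifting every log band
  # energy by the same constant; the DCT without the 0th coefficient kills
  # constant shifts, so all three blocks are invariant to gain
  rec <- synth_recording("normal", 2, synth_config(seed = 22))
  f1 <- improved_mfcc(rec$samples)
  f2 <- improved_mfcc(0.5 * rec$samples)
  expect_equal(f2$mfcc, f1$mfcc, tolerance = 1e-9)
  expect_equal(f2$delta, f1$delta, tolerance = 1e-9)
  expect_equal(f2$delta2, f1$delta2, tolerance = 1e-9)
})

test_that("static cepstra agree with an independent implementation", {
  # reference written from the same published definitions in numpy (different
  # language and FFT); correlation per coefficient > 0.999. Scaling
  # conventions are matched deliberately (documented tolerance).
  py <- Sys.which("python")
  expect_true(nzchar(py))
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys, numpy as np",
    "x = np.loadtxt(sys.argv[1])",
    "y = np.concatenate(([x[0]], x[1:] - 0.97 * x[:-1]))",
    "n = np.arange(40)",
    "w = 0.54 - 0.46 * np.cos(2 * np.pi * n / 39)",
    "frames = np.stack([y[s:s+40] * w for s in range(0, 3961, 20)])",
    "P = np.abs(np.fft.rfft(frames, 256, axis=1)) ** 2 / 256",
    "mel = lambda f: 2595 * np.log10(1 + f / 700)",
    "imel = lambda m: 700 * (10 ** (m / 2595) - 1)",
    "edges = np.floor(257 * imel(np.linspace(0, mel(1000), 15)) / 2000).astype(int)",
    "W = np.zeros((13, 129))",
    "for m in range(13):",
    "    lo, ce, hi = edges[m], edges[m+1], edges[m+2]",
    "    k = np.arange(129)",
    "    W[m][(k >= lo) & (k <= ce)] = (k[(k >= lo) & (k <= ce)] - lo) / (ce - lo)",
    "    W[m][(k > ce) & (k <= hi)] = (hi - k[(k > ce) & (k <= hi)]) / (hi - ce)",
    "S = np.log(np.maximum(P @ W.T, 1e-10))",
    "m_idx = np.arange(1, 14) - 0.5",
    "D = np.cos(np.pi * np.outer(m_idx, np.arange(1, 14)) / 13)",
    "np.savetxt(sys.argv[2], S @ D)"
  ), script)
  rec <- synth_recording("abnormal", 2, synth_config(seed = 23))
  fin <- withr::local_tempfile(); fout <- withr::local_tempfile()
  writeLines(format(rec$samples, digits = 17), fin)
  status <- system2(py, c(script, fin, fout))
  expect_equal(status, 0L)
  ref <- as.matrix(utils::read.table(fout))
  ours <- improved_mfcc(rec$samples)$mfcc
  for (j in 1:13) {
    expect_gt(stats::cor(ours[, j], ref[, j]), 0.999)
  }
})
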