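#' Synthetic phonocardiogram configuration
#'
#' The generator is a stylised signal model of 2-s heart-sound units at
#' 2000 Hz, not a physiological simulator: S1 and S2 are exponentially damped
#' tones placed on a jittered cardiac grid; murmurs are band-limited noise
#' confined to systole; the artifact class has no periodic structure. The
#' defaults describe a resting adult heart (~75 bpm, 0.3 s systole) with S1
#' near 60 Hz and the shorter, higher S2 near 90 Hz.
#'
#' @param sample_rate_hz Sampling rate (2000).
#' @param cycle_s Cardiac cycle length in seconds (0.8 = 75 bpm).
#' @param systole_s S1-to-S2 interval in seconds.
#' @param s1_freq_hz,s2_freq_hz Centre frequencies of the damped S1/S2 tones.
#' @param tone_decay_s Exponential decay time constant of the tones.
#' @param murmur_band_hz Two-vector, the murmur noise band in Hz.
#' @param murmur_snr_db Heart-tone-to-murmur power ratio in dB (smaller is a
#'   louder murmur, i.e. a harder class boundary).
#' @param noise_kind `"broadband"` or `"spikes"` for the artifact class.
#' @param seed Integer seed; together with the label it fully determines the
#'   signal.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(sample_rate_hz = 2000L, cycle_s = 0.8,
                         systole_s = 0.3, s1_freq_hz = 60, s2_freq_hz = 90,
                         tone_decay_s = 0.04,
                         murmur_band_hz = c(150, 400), murmur_snr_db = 5,
                         noise_kind = c("broadband", "spikes"), seed = 1L) {
  noise_kind <- match.arg(noise_kind)
  nyq <- sample_rate_hz / 2
  stopifnot(s1_freq_hz < nyq, s2_freq_hz < nyq, max(murmur_band_hz) < nyq,
            systole_s < cycle_s, tone_decay_s > 0)
  structure(
    list(sample_rate_hz = as.integer(sample_rate_hz), cycle_s = cycle_s,
         systole_s = systole_s, s1_freq_hz = s1_freq_hz,
         s2_freq_hz = s2_freq_hz, tone_decay_s = tone_decay_s,
         murmur_band_hz = murmur_band_hz, murmur_snr_db = murmur_snr_db,
         noise_kind = noise_kind, seed = as.integer(seed)),
    class = "synth_config")
}

# damped tone of given length placed at `at` (sample index, 1-based)
place_tone <- function(x, at, freq, decay_s, amp, sr) {
  len <- min(round(3 * decay_s * sr * 2), length(x) - at + 1)
  if (len <= 0) return(x)
  t <- seq(0, len - 1) / sr
  tone <- amp * sin(2 * pi * freq * t) * exp(-t / decay_s)
  x[at:(at + len - 1)] <- x[at:(at + len - 1)] + tone
  x
}

# white noise restricted to a frequency band via spectral masking
band_noise <- function(n, band, sr) {
  w <- stats::rnorm(n)
  f <- seq(0, n - 1) / n * sr
  f <- pmin(f, sr - f)
  mask <- as.numeric(f >= band[1] & f <= band[2])
  Re(stats::fft(stats::fft(w) * mask, inverse = TRUE)) / n
}

#' Generate one synthetic heart-sound recording
#'
#' `normal`: damped S1/S2 tone pairs on a jittered ~`cycle_s` grid over a
#' faint broadband floor. `abnormal`: the same signal plus band-limited
#' murmur noise confined to each systolic interval at `murmur_snr_db`.
#' `noise`: broadband noise or a random spike train with no periodic
#' structure. The peak amplitude is normalised to 0.9, and the output is a
#' deterministic function of `(label, cfg$seed)`.
#'
#' @param label `"normal"`, `"abnormal"` or `"noise"`.
#' @param duration_s Duration in seconds (>= 2 for downstream use).
#' @param cfg A [synth_config()].
#' @param id Recording id.
#' @return An [audio_recording()] with `source = "synthetic"`.
#' @export
synth_recording <- function(label, duration_s = 2, cfg = synth_config(),
                            id = paste0("syn_", label)) {
  if (!label %in% c("normal", "abnormal", "noise")) {
    stop("invalid label '", label, "'; must be normal, abnormal or noise",
         call. = FALSE)
  }
  sr <- cfg$sample_rate_hz
  n <- round(duration_s * sr)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  # label folded into the stream so classes are not correlated copies
  set.seed(cfg$seed + match(label, c("normal", "abnormal", "noise")) * 7919L)

  if (label == "noise") {
    x <- if (cfg$noise_kind == "broadband") {
      stats::rnorm(n)
    } else {
      sp <- numeric(n)
      at <- sort(sample.int(n, max(3, round(duration_s * 8))))
      sp[at] <- stats::runif(length(at), -1, 1) * 5
      stats::filter(sp, exp(-seq(0, 40) / 8), sides = 1) |>
        as.numeric() |>
        (\(v) ifelse(is.na(v), 0, v))() + stats::rnorm(n, sd = 0.05)
    }
  } else {
    x <- stats::rnorm(n, sd = 0.01) # faint sensor floor
    onset <- round(stats::runif(1, 0, 0.1) * sr) + 1
    starts <- c()
    at <- onset
    while (at < n) {
      starts <- c(starts, at)
      at <- at + round((cfg$cycle_s + stats::rnorm(1, sd = 0.02)) * sr)
    }
    sys_len <- round(cfg$systole_s * sr)
    for (s1 in starts) {
      a1 <- stats::runif(1, 0.85, 1)
      a2 <- stats::runif(1, 0.5, 0.7)
      x <- place_tone(x, s1, cfg$s1_freq_hz * stats::runif(1, 0.95, 1.05),
                      cfg$tone_decay_s, a1, sr)
      s2 <- s1 + sys_len
      if (s2 <= n) {
        x <- place_tone(x, s2, cfg$s2_freq_hz * stats::runif(1, 0.95, 1.05),
                        cfg$tone_decay_s * 0.75, a2, sr)
      }
    }
    if (label == "abnormal") {
      mur <- band_noise(n, cfg$murmur_band_hz, sr)
      gate <- numeric(n)
      s1_len <- round(0.1 * sr)
      for (s1 in starts) { # murmur occupies systole, between S1 and S2
        from <- min(s1 + s1_len, n)
        to <- min(s1 + sys_len, n)
        if (to > from) gate[from:to] <- 1
      }
      tone_p <- mean(x^2)
      mur_gated <- mur * gate
      mp <- mean(mur_gated^2)
      if (mp > 0) {
        target <- tone_p / 10^(cfg$murmur_snr_db / 10)
        x <- x + mur_gated * sqrt(target / mp)
      }
    }
  }
  x <- 0.9 * x / max(abs(x))
  audio_recording(x, sr, raw_label = label, source = "synthetic", id = id)
}

# save/restore the global RNG state so generation is a pure function of seed
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# per-file seed derived from (master seed, index); kept inside 32-bit range
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 1000003 + 7919 * as.numeric(index)) %%
               2147483647)
}

#' Generate a labelled synthetic dataset on disk
#'
#' Writes `3 * n_per_class` WAV files plus a manifest CSV in the preprocess
#' module's schema (`id,path,source,raw_label`). Per-file seeds are derived
#' from the master seed, so regeneration is bit-identical.
#'
#' @param n_per_class Recordings per class (>= 1).
#' @param dir Output directory (created if missing).
#' @param duration_s Per-recording duration in seconds.
#' @param cfg A [synth_config()]; its `seed` is the master seed.
#' @return The manifest tibble (invisibly also written to
#'   `file.path(dir, "manifest.csv")`).
#' @export
make_dataset <- function(n_per_class, dir, duration_s = 2,
                         cfg = synth_config()) {
  stopifnot(n_per_class >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  classes <- c("normal", "abnormal", "noise")
  grid <- tidyr::expand_grid(label = classes, i = seq_len(n_per_class))
  rows <- purrr::pmap(list(grid$label, grid$i, seq_len(nrow(grid))),
                      function(label, i, idx) {
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(cfg$seed, idx)
    id <- sprintf("syn_%s_%03d", label, i)
    rec <- synth_recording(label, duration_s, cfg_i, id = id)
    path <- file.path(dir, paste0(id, ".wav"))
    write_wav(rec$samples, rec$sample_rate_hz, path)
    tibble::tibble(id = id, path = path, source = "synthetic",
                   raw_label = label)
  })
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  manifest
}

#' Generate an in-memory synthetic segment table
#'
#' Convenience wrapper used by the tests, examples and the evaluation
#' protocol: generates recordings, runs the full preprocessing chain and
#' returns the segment tibble directly, with no disk round-trip.
#'
#' @inheritParams make_dataset
#' @return A segment tibble (see [segment_audio()]).
#' @export
make_segment_table <- function(n_per_class, duration_s = 2,
                               cfg = synth_config()) {
  classes <- c("normal", "abnormal", "noise")
  grid <- tidyr::expand_grid(label = classes, i = seq_len(n_per_class))
  segs <- purrr::pmap(list(grid$label, grid$i, seq_len(nrow(grid))),
                      function(label, i, idx) {
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(cfg$seed, idx)
    rec <- synth_recording(label, duration_s, cfg_i,
                           id = sprintf("syn_%s_%03d", label, i))
    preprocess_recording(rec, label = label)
  })
  dplyr::bind_rows(segs)
}
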