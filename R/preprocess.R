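#' Construct a labelled audio recording
#'
#' The unit of raw input: a mono amplitude sequence with its sampling rate,
#' the label printed by the source corpus, and provenance.
#'
#' @param samples Numeric vector of amplitudes (finite, non-empty).
#' @param sample_rate_hz Positive integer sampling rate.
#' @param raw_label Label string as published by the source corpus.
#' @param source One of `"physionet"`, `"pascal"`, `"yaseen"`, `"synthetic"`,
#'   `"other"`.
#' @param id Recording identifier.
#' @return An object of class `audio_recording`.
#' @export
audio_recording <- function(samples, sample_rate_hz, raw_label = NA_character_,
                            source = "other", id = "rec") {
  if (length(samples) == 0) stop("samples must be non-empty", call. = FALSE)
  if (!all(is.finite(samples))) {
    stop("invalid input: samples contain non-finite values", call. = FALSE)
  }
  sample_rate_hz <- as.integer(sample_rate_hz)
  if (is.na(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("sample_rate_hz must be a positive integer", call. = FALSE)
  }
  source <- match.arg(source,
                      c("physionet", "pascal", "yaseen", "synthetic", "other"))
  structure(
    list(samples = as.numeric(samples), sample_rate_hz = sample_rate_hz,
         raw_label = raw_label, source = source, id = id),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording '%s'> %d samples @ %d Hz (%.2f s), %s/%s\n",
              x$id, length(x$samples), x$sample_rate_hz,
              length(x$samples) / x$sample_rate_hz, x$source, x$raw_label))
  invisible(x)
}

# Zero-phase low-pass of a numeric vector: even (mirror) extension makes the
# signal circularly continuous, then the real spectrum is weighted by the
# squared analog Butterworth magnitude 1 / (1 + (f/fc)^(2*order)).
lowpass_core <- function(x, sr, cutoff_hz, order) {
  n <- length(x)
  x2 <- c(x, rev(x))
  n2 <- length(x2)
  f <- seq(0, n2 - 1) / n2 * sr
  f <- pmin(f, sr - f) # fold to [0, sr/2]
  h <- 1 / (1 + (f / cutoff_hz)^(2 * order))
  y2 <- Re(stats::fft(stats::fft(x2) * h, inverse = TRUE)) / n2
  y2[seq_len(n)]
}

#' Zero-phase Butterworth low-pass filter
#'
#' Removes high-frequency content from a recording while preserving S1/S2
#' timing. The filter is applied with zero phase, so the effective magnitude
#' response is the squared Butterworth magnitude
#' \eqn{|H(f)|^2 = 1 / (1 + (f/f_c)^{2n})}: a tone at the cutoff is passed at
#' amplitude 1/2, and DC at gain 1.
#'
#' @param rec An [audio_recording()].
#' @param cutoff_hz Cutoff frequency in Hz (default 400).
#' @param order Filter order (default 5).
#' @return A filtered `audio_recording` of identical length and rate.
#' @export
lowpass_filter <- function(rec, cutoff_hz = 400, order = 5L) {
  stopifnot(inherits(rec, "audio_recording"))
  if (cutoff_hz >= rec$sample_rate_hz / 2) {
    stop("invalid parameter: cutoff_hz (", cutoff_hz,
         ") must be below the Nyquist frequency (",
         rec$sample_rate_hz / 2, ")", call. = FALSE)
  }
  if (!all(is.finite(rec$samples))) {
    stop("invalid input: samples contain non-finite values", call. = FALSE)
  }
  rec$samples <- lowpass_core(rec$samples, rec$sample_rate_hz,
                              cutoff_hz, order)
  rec
}

#' Down-sample a recording
#'
#' Fourier-method rational resampling: the even-extended signal's spectrum is
#' truncated at the target Nyquist frequency, which preserves the amplitude
#' and frequency of all tonal content below it. Up-sampling is deliberately
#' unsupported (the pipeline only ever reduces the rate, to 2000 Hz).
#'
#' @param rec An [audio_recording()].
#' @param target_hz Target sampling rate (default 2000).
#' @return An `audio_recording` with `round(n * target_hz / sample_rate_hz)`
#'   samples at `target_hz`.
#' @export
resample_to <- function(rec, target_hz = 2000L) {
  stopifnot(inherits(rec, "audio_recording"))
  target_hz <- as.integer(target_hz)
  if (target_hz > rec$sample_rate_hz) {
    stop("unsupported parameter: up-sampling (", rec$sample_rate_hz,
         " -> ", target_hz, " Hz) is not supported", call. = FALSE)
  }
  if (target_hz == rec$sample_rate_hz) return(rec)

  n <- length(rec$samples)
  m <- round(n * target_hz / rec$sample_rate_hz)
  if (m < 1) stop("recording too short to resample", call. = FALSE)
  x2 <- c(rec$samples, rev(rec$samples))
  n2 <- 2L * n
  m2 <- 2L * m
  X <- stats::fft(x2)
  Y <- complex(m2)
  half <- m2 %/% 2
  Y[1:(half + 1)] <- X[1:(half + 1)]
  if (half > 1) Y[(m2 - half + 2):m2] <- X[(n2 - half + 2):n2]
  # the (unpaired) Nyquist bin of the shortened spectrum must stay real
  Y[half + 1] <- Re(Y[half + 1])
  y2 <- Re(stats::fft(Y, inverse = TRUE)) / n2
  rec$samples <- y2[seq_len(m)]
  rec$sample_rate_hz <- target_hz
  rec
}

#' Cut a recording into fixed-length segments
#'
#' Consecutive non-overlapping windows of `duration_s`; a trailing remainder
#' shorter than one window is discarded, and recordings shorter than one
#' window yield zero segments (with a warning). A recording of exactly
#' `duration_s` yields one segment.
#'
#' @param rec An [audio_recording()], already at the target rate.
#' @param duration_s Segment duration in seconds (default 2).
#' @param label Unified class label to attach (`"normal"`, `"abnormal"`,
#'   `"noise"`), or `NA` to carry `rec$raw_label` through unchanged.
#' @return A tibble with columns `segment_id`, `parent_id`, `offset_s`,
#'   `label` and a list-column `samples` (each of exactly
#'   `duration_s * sample_rate_hz` values).
#' @export
segment_audio <- function(rec, duration_s = 2, label = NA_character_) {
  stopifnot(inherits(rec, "audio_recording"))
  seg_len <- as.integer(round(duration_s * rec$sample_rate_hz))
  n_seg <- length(rec$samples) %/% seg_len
  if (n_seg == 0) {
    warning("recording '", rec$id, "' is shorter than ", duration_s,
            " s and was discarded", call. = FALSE)
    return(tibble::tibble(segment_id = character(), parent_id = character(),
                          offset_s = numeric(), label = character(),
                          samples = list()))
  }
  lab <- if (is.na(label)) rec$raw_label else label
  tibble::tibble(
    segment_id = sprintf("%s_seg%03d", rec$id, seq_len(n_seg)),
    parent_id = rec$id,
    offset_s = (seq_len(n_seg) - 1) * duration_s,
    label = lab,
    samples = lapply(seq_len(n_seg), function(i) {
      rec$samples[((i - 1) * seg_len + 1):(i * seg_len)]
    })
  )
}

#' Default label map for the supported corpora
#'
#' Maps each (source, raw label) pair of the PhysioNet/CinC 2016, Pascal
#' (Kaggle) and Yaseen corpora — plus the synthetic generator — onto the
#' unified three-class scheme \{normal, abnormal, noise\}. Pascal's
#' artifact class becomes `noise`; its murmur and extra-heart-sound classes
#' and Yaseen's four pathological classes become `abnormal`. The map is
#' shipped as a CSV (`extdata/default_label_map.csv`) so users can override
#' any row.
#'
#' @param path Optional path to a CSV with columns `source,raw_label,label`
#'   replacing the shipped default.
#' @return A tibble with columns `source`, `raw_label`, `label`.
#' @export
default_label_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_label_map.csv",
                        package = "cardiomel", mustWork = TRUE)
  }
  map <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  stopifnot(all(c("source", "raw_label", "label") %in% names(map)))
  bad <- setdiff(unique(map$label), c("normal", "abnormal", "noise"))
  if (length(bad) > 0) {
    stop("label map contains non-unified labels: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(map)
}

#' Unify a source-specific label into the three-class scheme
#'
#' @param map A label-map tibble as returned by [default_label_map()].
#' @param source Corpus name(s).
#' @param raw_label Raw label(s) as published by the corpus.
#' @return Character vector of unified labels (`normal`/`abnormal`/`noise`).
#' @export
unify_labels <- function(map, source, raw_label) {
  key <- paste(tolower(source), tolower(raw_label), sep = "\r")
  map_key <- paste(tolower(map$source), tolower(map$raw_label), sep = "\r")
  idx <- match(key, map_key)
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1]
    stop("unmapped label: (source = '", source[miss], "', raw_label = '",
         raw_label[miss], "') is not in the label map", call. = FALSE)
  }
  map$label[idx]
}

#' Read a recording manifest
#'
#' The manifest is the package's interface to any corpus: a CSV with header
#' `id,path,source,raw_label`, one row per WAV file.
#'
#' @param path Manifest CSV path.
#' @return A tibble with those four character columns.
#' @export
read_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  need <- c("id", "path", "source", "raw_label")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(m[need])
}

#' Preprocess one recording into labelled 2-s segments
#'
#' The cleaning chain: zero-phase Butterworth low-pass (default 400 Hz,
#' order 5), down-sampling to `target_hz`, fixed-length cutting.
#'
#' @param rec An [audio_recording()].
#' @param label Unified label for the resulting segments.
#' @param cutoff_hz,filter_order,target_hz,segment_seconds Chain parameters.
#' @return A segment tibble (see [segment_audio()]).
#' @export
preprocess_recording <- function(rec, label = NA_character_, cutoff_hz = 400,
                                 filter_order = 5L, target_hz = 2000L,
                                 segment_seconds = 2) {
  rec |>
    lowpass_filter(cutoff_hz = cutoff_hz, order = filter_order) |>
    resample_to(target_hz = target_hz) |>
    segment_audio(duration_s = segment_seconds, label = label)
}

#' Preprocess every recording in a manifest
#'
#' Reads each WAV, unifies its label through the label map, runs the cleaning
#' chain and row-binds the resulting segment tibbles.
#'
#' @param manifest Tibble from [read_manifest()] (paths must be resolvable).
#' @param label_map Label-map tibble; defaults to [default_label_map()].
#' @inheritParams preprocess_recording
#' @return A segment tibble covering the whole manifest.
#' @export
preprocess_manifest <- function(manifest, label_map = default_label_map(),
                                cutoff_hz = 400, filter_order = 5L,
                                target_hz = 2000L, segment_seconds = 2) {
  labels <- unify_labels(label_map, manifest$source, manifest$raw_label)
  segs <- purrr::pmap(
    list(manifest$id, manifest$path, manifest$source, labels),
    function(id, path, source, label) {
      wav <- read_wav(path)
      rec <- audio_recording(wav$samples, wav$sample_rate_hz,
                             raw_label = label, source = source, id = id)
      preprocess_recording(rec, label = label, cutoff_hz = cutoff_hz,
                           filter_order = filter_order, target_hz = target_hz,
                           segment_seconds = segment_seconds)
    }
  )
  dplyr::bind_rows(segs)
}

#' Write a segment manifest CSV
#'
#' @param segments Segment tibble.
#' @param path Output CSV path (columns
#'   `segment_id,parent_id,offset_s,label`).
#' @return `path`, invisibly.
#' @export
write_segment_manifest <- function(segments, path) {
  readr::write_csv(
    segments[c("segment_id", "parent_id", "offset_s", "label")], path)
  invisible(path)
}
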