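#' PCG recording container
#'
#' Bundles a vector of audio samples with its sampling rate, an optional
#' class label and a source identifier. All pipeline stages consume and
#' return this container.
#'
#' @param samples Numeric vector of (dimensionless) amplitudes.
#' @param fs Sampling rate in Hz.
#' @param label Optional integer class code in 1..5 (see [class_codes()]),
#'   or `NA`.
#' @param source_id Opaque string identifying the origin of the recording.
#' @return An object of class `pcg_recording`.
#' @export
pcg_recording <- function(samples, fs, label = NA_integer_, source_id = "") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("recording has no samples")
  if (!all(is.finite(samples))) stop("recording contains non-finite samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("invalid sampling rate")
  if (!is.na(label)) {
    label <- as.integer(label)
    if (!label %in% 1:5) stop("label must be a class code in 1..5")
  }
  structure(
    list(samples = samples, fs = as.numeric(fs), label = label,
         source_id = as.character(source_id)),
    class = "pcg_recording"
  )
}

#' @export
print.pcg_recording <- function(x, ...) {
  lab <- if (is.na(x$label)) "unlabelled" else class_codes()[x$label]
  cat(sprintf("<pcg_recording> %d samples @ %g Hz (%.2f s), %s%s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, lab,
              if (nzchar(x$source_id)) paste0(", ", x$source_id) else ""))
  invisible(x)
}

#' @export
length.pcg_recording <- function(x) length(x$samples)

#' Class code table
#'
#' The five diagnostic classes and their integer codes: 1 = N (normal),
#' 2 = MVP (mitral valve prolapse), 3 = AS (aortic stenosis),
#' 4 = MR (mitral regurgitation), 5 = MS (mitral stenosis).
#'
#' @return Named character vector mapping code to class abbreviation.
#' @export
class_codes <- function() {
  c(`1` = "N", `2` = "MVP", `3` = "AS", `4` = "MR", `5` = "MS")
}

#' Map class abbreviations to codes
#' @param x Character vector of labels in `N, MVP, AS, MR, MS` (case
#'   insensitive) or integer codes.
#' @return Integer vector of codes 1..5.
#' @export
label_to_code <- function(x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (!all(x %in% 1:5)) stop("numeric labels must be codes in 1..5")
    return(x)
  }
  x <- trimws(as.character(x))
  num <- suppressWarnings(as.integer(x))
  if (all(!is.na(num))) return(label_to_code(num))
  tbl <- c(stats::setNames(1:5, class_codes()),
           stats::setNames(1:5, as.character(1:5)))
  code <- tbl[toupper(x)]
  if (anyNA(code)) {
    stop("unknown class label(s): ",
         paste(unique(x[is.na(code)]), collapse = ", "))
  }
  unname(code)
}

# ---- WAV I/O ----------------------------------------------------------------
# Minimal RIFF/WAVE reader/writer (PCM 8/16/24/32-bit and IEEE float32).
# Samples are exchanged as doubles in [-1, 1] for PCM.

#' Read a WAV file into a PCG recording
#'
#' Reads PCM (8/16/24/32-bit) or IEEE float32 WAV. Multi-channel files are
#' reduced to channel 0 with a warning; stethoscope recordings are mono.
#'
#' @param path Path to a `.wav` file.
#' @param label Optional class code or abbreviation attached to the recording.
#' @return A [pcg_recording()] with the file's native sampling rate. PCM
#'   samples are scaled to `[-1, 1]` by the format's full scale.
#' @export
load_wav <- function(path, label = NA) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt_found <- FALSE
  audio_format <- n_channels <- fs <- bits <- NA_integer_
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(sz) == 0L) break
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "raw", sz)
      audio_format <- readBin(fmt[1:2], "integer", 1, size = 2,
                              endian = "little", signed = FALSE)
      n_channels <- readBin(fmt[3:4], "integer", 1, size = 2,
                            endian = "little", signed = FALSE)
      fs <- readBin(fmt[5:8], "integer", 1, size = 4, endian = "little")
      bits <- readBin(fmt[15:16], "integer", 1, size = 2,
                      endian = "little", signed = FALSE)
      fmt_found <- TRUE
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
    if (fmt_found && !is.null(data_raw)) break
  }
  if (!fmt_found || is.null(data_raw)) stop("malformed WAV (missing fmt/data chunk): ", path)
  # 0xFFFE = WAVE_FORMAT_EXTENSIBLE; sub-format assumed to match `bits`
  if (!audio_format %in% c(1L, 3L, 65534L)) {
    stop("unsupported WAV encoding (format tag ", audio_format, ")")
  }

  x <- if (audio_format == 3L || (audio_format == 65534L && bits == 32L)) {
    readBin(data_raw, "double", length(data_raw) %/% 4L, size = 4,
            endian = "little")
  } else if (bits == 16L) {
    readBin(data_raw, "integer", length(data_raw) %/% 2L, size = 2,
            endian = "little") / 32768
  } else if (bits == 8L) {
    (readBin(data_raw, "integer", length(data_raw), size = 1,
             endian = "little", signed = FALSE) - 128) / 128
  } else if (bits == 32L) {
    readBin(data_raw, "integer", length(data_raw) %/% 4L, size = 4,
            endian = "little") / 2147483648
  } else if (bits == 24L) {
    n <- length(data_raw) %/% 3L
    b <- matrix(as.integer(data_raw[seq_len(3L * n)]), nrow = 3L)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    ifelse(v >= 8388608, v - 16777216, v) / 8388608
  } else {
    stop("unsupported PCM bit depth: ", bits)
  }

  if (n_channels > 1L) {
    warning("multi-channel WAV: keeping channel 0 of ", n_channels)
    x <- x[seq(1L, length(x), by = n_channels)]
  }
  if (length(x) == 0L) stop("WAV contains no audio samples: ", path)
  if (!is.na(label) && !identical(label, NA)) label <- label_to_code(label)
  pcg_recording(x, fs = fs, label = if (identical(label, NA)) NA_integer_ else label,
                source_id = basename(path))
}

#' Write a PCG recording to a WAV file
#'
#' @param rec A [pcg_recording()].
#' @param path Output path.
#' @param bits 16 for PCM16, 32 for IEEE float32.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, bits = 16L) {
  stopifnot(inherits(rec, "pcg_recording"), bits %in% c(16L, 32L))
  x <- rec$samples
  float_fmt <- bits == 32L
  bytes_per <- bits %/% 8L
  data_size <- length(x) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(if (float_fmt) 3L else 1L, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(rec$fs), con, size = 4, endian = "little")
  writeBin(as.integer(rec$fs * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (float_fmt) {
    writeBin(x, con, size = 4, endian = "little")
  } else {
    q <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
    writeBin(q, con, size = 2, endian = "little")
  }
  invisible(path)
}

# ---- preprocessing ----------------------------------------------------------

#' Resample a recording to the working rate
#'
#' Downsamples to the 4 kHz analysis rate with anti-aliasing (polyphase
#' resampling). Upsampling is refused: the pipeline only ever reduces rate.
#'
#' @param rec A [pcg_recording()].
#' @param target_fs Target sampling rate in Hz (default 4000).
#' @return The recording at `target_fs`.
#' @export
resample_to_working_rate <- function(rec, target_fs = 4000) {
  stopifnot(inherits(rec, "pcg_recording"))
  if (rec$fs < target_fs) {
    stop("refusing to upsample: recording at ", rec$fs, " Hz < target ",
         target_fs, " Hz")
  }
  if (rec$fs == target_fs) return(rec)
  # rational rate ratio p/q in lowest terms
  r <- target_fs / rec$fs
  fr <- .as_fraction(r)
  y <- signal::resample(rec$samples, p = fr[1], q = fr[2])
  n_expected <- round(length(rec$samples) * r)
  y <- y[seq_len(min(length(y), n_expected))]
  pcg_recording(y, fs = target_fs, label = rec$label, source_id = rec$source_id)
}

# continued-fraction rationalization of a rate ratio
.as_fraction <- function(x, tol = 1e-9, max_den = 10^6) {
  a <- floor(x); p0 <- 1L; q0 <- 0L; p1 <- a; q1 <- 1L; frac <- x - a
  while (abs(p1 / q1 - x) > tol && q1 < max_den && frac > 0) {
    x2 <- 1 / frac; a <- floor(x2); frac <- x2 - a
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
  }
  c(as.integer(p1), as.integer(q1))
}

#' Bandpass filter a recording
#'
#' Zero-phase Butterworth bandpass (applied forward and backward with
#' `signal::filtfilt`), passing the 25--900 Hz band where heart sounds and
#' murmurs carry their energy.
#'
#' @param rec A [pcg_recording()].
#' @param low,high Cutoff frequencies in Hz.
#' @param order Butterworth order of the underlying one-pass design.
#' @return Filtered recording, same length and rate.
#' @export
bandpass_filter <- function(rec, low = 25, high = 900, order = 4L) {
  stopifnot(inherits(rec, "pcg_recording"))
  nyq <- rec$fs / 2
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (high >= nyq) stop("high cutoff ", high, " Hz must be below Nyquist (",
                        nyq, " Hz)")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  y <- signal::filtfilt(bf, rec$samples)
  pcg_recording(y, fs = rec$fs, label = rec$label, source_id = rec$source_id)
}

#' Amplitude-normalize a recording
#'
#' Divides every sample by the maximum absolute amplitude so the output peaks
#' at exactly 1. Removes recording-gain differences between devices.
#'
#' @param rec A [pcg_recording()].
#' @return Normalized recording (max absolute amplitude 1).
#' @export
normalize_amplitude <- function(rec) {
  stopifnot(inherits(rec, "pcg_recording"))
  m <- max(abs(rec$samples))
  if (m == 0) stop("cannot normalize an all-zero recording")
  pcg_recording(rec$samples / m, fs = rec$fs, label = rec$label,
                source_id = rec$source_id)
}

#' Full preprocessing chain
#'
#' Resample to the working rate, bandpass filter, and amplitude-normalize.
#'
#' @param rec A [pcg_recording()] at any rate `>=` `target_fs`.
#' @param target_fs Working rate in Hz.
#' @param low,high,order Bandpass parameters, see [bandpass_filter()].
#' @return Preprocessed recording at `target_fs` with peak amplitude 1.
#' @export
preprocess_recording <- function(rec, target_fs = 4000, low = 25, high = 900,
                                 order = 4L) {
  rec <- resample_to_working_rate(rec, target_fs)
  rec <- bandpass_filter(rec, low = low, high = high, order = order)
  normalize_amplitude(rec)
}

#' Read a label manifest
#'
#' CSV with header `path,label`; labels are `N, MVP, AS, MR, MS` or codes
#' 1..5. Relative paths are resolved against the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @return Data frame with columns `path` (absolute) and `label` (code 1..5).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(df))) {
    stop("manifest must have columns `path` and `label`")
  }
  base <- dirname(normalizePath(path))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", df$path), df$path,
                file.path(base, df$path))
  data.frame(path = abs, label = label_to_code(df$label),
             stringsAsFactors = FALSE)
}
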