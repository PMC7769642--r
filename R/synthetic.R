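# Five-class synthetic phonocardiogram generator.
#
# Emulates the phenomenology of auscultation recordings: S1/S2 valve-closure
# transients as Gaussian-enveloped tone bursts at the cardiac-cycle cadence
# (energy 25-300 Hz), plus class-specific murmurs as enveloped band-limited
# noise. Murmur timing/band per class:
#   AS  systolic crescendo-decrescendo, 100-600 Hz, loud
#   MR  holosystolic,                   100-500 Hz
#   MS  diastolic decrescendo,           50-300 Hz
#   MVP mid-to-late systolic,           150-500 Hz
#   N   no murmur
# White noise is added at a configurable SNR.

#' Synthetic PCG configuration
#'
#' @param fs Sampling rate in Hz.
#' @param duration_s Recording duration in seconds.
#' @param heart_rate_bpm Heart rate, 40--180 beats/min.
#' @param class_code Class code 1..5 (see [class_codes()]).
#' @param snr_db Signal-to-noise ratio of the added white noise, in dB.
#' @param seed Integer RNG seed; identical `(config, seed)` gives identical
#'   samples.
#' @param murmur_gain Multiplier on the class's murmur amplitude (used for
#'   per-recording jitter in [generate_dataset()]).
#' @return A `synth_config` list.
#' @export
synth_config <- function(fs = 4000, duration_s = 2.5, heart_rate_bpm = 72,
                         class_code = 1L, snr_db = 25, seed = 1L,
                         murmur_gain = 1) {
  if (duration_s <= 0) stop("duration_s must be positive")
  if (heart_rate_bpm < 40 || heart_rate_bpm > 180) {
    stop("heart_rate_bpm must be in [40, 180]")
  }
  class_code <- as.integer(class_code)
  if (!class_code %in% 1:5) stop("class_code must be in 1..5")
  structure(list(fs = fs, duration_s = duration_s,
                 heart_rate_bpm = heart_rate_bpm, class_code = class_code,
                 snr_db = snr_db, seed = as.integer(seed),
                 murmur_gain = murmur_gain),
            class = "synth_config")
}

# run `expr` under a private RNG state so generation never disturbs the
# caller's random stream
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Gaussian-enveloped tone burst added in place
.tone_burst <- function(x, t, center_s, freq_hz, sigma_s, amp) {
  env <- amp * exp(-(t - center_s)^2 / (2 * sigma_s^2))
  x + env * sin(2 * pi * freq_hz * (t - center_s))
}

# class murmur descriptors: band (Hz), timing window as fractions of the
# systolic/diastolic interval, base amplitude, envelope shape
.murmur_spec <- function(class_code) {
  switch(class_code,
    NULL,                                                          # N
    list(band = c(150, 500), phase = "systole", win = c(0.45, 1),  # MVP
         amp = 0.45, shape = "flat"),
    list(band = c(100, 600), phase = "systole", win = c(0, 1),     # AS
         amp = 0.75, shape = "diamond"),
    list(band = c(100, 500), phase = "systole", win = c(0, 1),     # MR
         amp = 0.45, shape = "flat"),
    list(band = c(50, 300), phase = "diastole", win = c(0, 0.7),   # MS
         amp = 0.45, shape = "decrescendo")
  )
}

#' Generate one synthetic PCG recording
#'
#' @param cfg A [synth_config()].
#' @return A labelled [pcg_recording()] at `cfg$fs`.
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  .with_seed(cfg$seed, {
    fs <- cfg$fs
    n <- round(cfg$duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    x <- numeric(n)

    cycle_s <- 60 / cfg$heart_rate_bpm
    systole_s <- 0.37 * cycle_s          # systole is the shorter interval
    s1_off <- 0.05 * cycle_s             # S1 shortly after cycle onset
    cycle_starts <- seq(0, cfg$duration_s, by = cycle_s)

    # per-recording tonal character of the valve sounds
    f_s1 <- stats::runif(1, 70, 110)
    f_s2 <- stats::runif(1, 100, 150)

    for (cs in cycle_starts) {
      s1_c <- cs + s1_off
      s2_c <- s1_c + systole_s
      if (s1_c < cfg$duration_s) {
        x <- .tone_burst(x, t, s1_c, f_s1 * stats::runif(1, 0.95, 1.05),
                         sigma_s = 0.018, amp = 1.0)
      }
      if (s2_c < cfg$duration_s) {
        x <- .tone_burst(x, t, s2_c, f_s2 * stats::runif(1, 0.95, 1.05),
                         sigma_s = 0.013, amp = 0.8)
      }
    }

    mur <- .murmur_spec(cfg$class_code)
    if (!is.null(mur)) {
      bf <- signal::butter(4, mur$band / (fs / 2), type = "pass")
      noise <- signal::filtfilt(bf, stats::rnorm(n))
      noise <- noise / stats::sd(noise)
      env <- numeric(n)
      for (cs in cycle_starts) {
        s1_c <- cs + s1_off
        s2_c <- s1_c + systole_s
        if (mur$phase == "systole") {
          a <- s1_c + 0.03 + mur$win[1] * (systole_s - 0.06)
          b <- s1_c + 0.03 + mur$win[2] * (systole_s - 0.06)
        } else {
          dia <- cycle_s - systole_s
          a <- s2_c + 0.04 + mur$win[1] * (dia - 0.08)
          b <- s2_c + 0.04 + mur$win[2] * (dia - 0.08)
        }
        idx <- t >= a & t <= b
        if (!any(idx)) next
        u <- (t[idx] - a) / (b - a)
        env[idx] <- pmax(env[idx], switch(mur$shape,
          flat = rep(1, sum(idx)),
          diamond = 1 - abs(2 * u - 1),
          decrescendo = 1 - u))
      }
      # smooth envelope edges slightly (10 ms) to avoid clicks
      k <- max(1L, round(0.01 * fs))
      env <- stats::filter(env, rep(1 / k, k), sides = 2)
      env[is.na(env)] <- 0
      x <- x + cfg$murmur_gain * mur$amp * as.numeric(env) * noise
    }

    sig_pow <- mean(x^2)
    noise_sd <- sqrt(sig_pow / 10^(cfg$snr_db / 10))
    x <- x + stats::rnorm(n, sd = noise_sd)
    pcg_recording(x, fs = fs, label = cfg$class_code,
                  source_id = sprintf("synth_c%d_seed%d", cfg$class_code,
                                      cfg$seed))
  })
}

#' Generate a balanced labelled synthetic dataset
#'
#' Produces `5 * n_per_class` recordings with per-recording jitter of heart
#' rate (+/- 10 bpm), murmur amplitude (+/- 20\%) and duration (+/- 15\%).
#' Content is a pure function of `(n_per_class, cfg_base)`.
#'
#' @param n_per_class Recordings per class.
#' @param cfg_base A [synth_config()] providing the base parameters; its
#'   `class_code` is ignored.
#' @return List of [pcg_recording()], classes interleaved 1..5.
#' @export
generate_dataset <- function(n_per_class, cfg_base = synth_config()) {
  stopifnot(inherits(cfg_base, "synth_config"), n_per_class >= 1)
  n_tot <- 5L * n_per_class
  draws <- .with_seed(cfg_base$seed, {
    list(seeds = sample.int(.Machine$integer.max - 1L, n_tot),
         hr = stats::runif(n_tot, -10, 10),
         gain = stats::runif(n_tot, 0.8, 1.2),
         dur = stats::runif(n_tot, 0.85, 1.15))
  })
  recs <- vector("list", n_tot)
  i <- 0L
  for (rep_idx in seq_len(n_per_class)) {
    for (cls in 1:5) {
      i <- i + 1L
      hr <- min(180, max(40, cfg_base$heart_rate_bpm + draws$hr[i]))
      cfg <- synth_config(
        fs = cfg_base$fs,
        duration_s = cfg_base$duration_s * draws$dur[i],
        heart_rate_bpm = hr,
        class_code = cls,
        snr_db = cfg_base$snr_db,
        seed = draws$seeds[i],
        murmur_gain = cfg_base$murmur_gain * draws$gain[i])
      recs[[i]] <- generate_recording(cfg)
    }
  }
  recs
}

#' Write a dataset as WAV files plus a labels.csv manifest
#'
#' @param recordings List of labelled [pcg_recording()].
#' @param dir Output directory (created if needed).
#' @param bits WAV sample format, see [write_wav()].
#' @return Path to the written `labels.csv`, invisibly.
#' @export
write_dataset <- function(recordings, dir, bits = 16L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(recordings), function(i) {
    rec <- recordings[[i]]
    fn <- sprintf("pcg_%04d_%s.wav", i, class_codes()[rec$label])
    # peak-scale so PCM quantization doesn't clip
    scaled <- pcg_recording(rec$samples / max(abs(rec$samples)), rec$fs,
                            rec$label, rec$source_id)
    write_wav(scaled, file.path(dir, fn), bits = bits)
    data.frame(path = fn, label = class_codes()[rec$label],
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  out <- file.path(dir, "labels.csv")
  utils::write.csv(manifest, out, row.names = FALSE, quote = FALSE)
  invisible(out)
}
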