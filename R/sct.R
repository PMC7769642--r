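# Spline-kernel Chirplet transform (SCT).
#
# The transform demodulates the signal along a piecewise-polynomial
# instantaneous-frequency (IF) law before Gaussian-windowed Fourier analysis.
# For analysis time nt falling in spline piece i (breakpoints n_i), the
# demodulated signal is
#
#   xbar(n) = x(n) * PsiR(n, Q) * PsiS(n, nt, Q)
#
# with the frequency-rotate operator
#   PsiR(n, Q) = exp(-j 2 pi [ sum_l q_l^i (n - n_i)^l + gamma_i ])
# and the frequency-shift operator
#   PsiS(n, nt, Q) = exp(+j 2 pi [ sum_l c_l q_l^i (nt - n_i)^(l-1) ] n).
#
# Q(i, l) = q_l^i are phase-polynomial coefficients in cycles/sample^l, so
# the kernel's IF law is nu(n) = sum_l l q_l^i (n - n_i)^(l-1) cycles/sample.
# With c_l = l the shift frequency is exactly nu(nt) (the derivative of the
# rotate phase), which re-centres the ridge at the true frequency; c_l = 1
# reproduces the shift operator as sometimes printed without the derivative
# factor (`convention = "printed"`). The phase offsets gamma_i (in cycles)
# chain the pieces continuously, gamma_1 = 0.

#' Gaussian analysis window
#'
#' `w(n) = exp(-n^2 / (2 sigma^2)) / (sqrt(2 pi) sigma)` evaluated on the
#' symmetric support `n = -half_width .. half_width`.
#'
#' @param sigma Window width in samples (> 0).
#' @param half_width Half support in samples.
#' @return Numeric vector of length `2 * half_width + 1`.
#' @export
gaussian_window <- function(sigma, half_width = ceiling(3 * sigma)) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  n <- seq(-half_width, half_width)
  exp(-n^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
}

#' Spline kernel for the Chirplet transform
#'
#' @param coeffs `I x L` matrix `Q`; `Q[i, l]` is the order-`l`
#'   phase-polynomial coefficient of piece `i`, in cycles/sample^l.
#' @param breakpoints Integer vector of `I + 1` strictly increasing sample
#'   indices (0-based) covering the signal support `[0, N)`.
#' @param order Spline order `L` (defaults to `ncol(coeffs)`).
#' @return A `spline_kernel` with phase-continuity offsets `gamma` (cycles),
#'   `gamma[1] == 0`.
#' @export
spline_kernel <- function(coeffs, breakpoints, order = ncol(coeffs)) {
  coeffs <- as.matrix(coeffs)
  if (nrow(coeffs) < 1L || ncol(coeffs) < 1L) stop("need I >= 1 and L >= 1")
  if (length(breakpoints) != nrow(coeffs) + 1L) {
    stop("breakpoints must have one more entry than kernel pieces")
  }
  if (any(diff(breakpoints) <= 0)) stop("breakpoints must be strictly increasing")
  if (order != ncol(coeffs)) stop("order must equal ncol(coeffs)")
  I <- nrow(coeffs); L <- ncol(coeffs)
  gamma <- numeric(I)
  if (I > 1L) {
    for (i in seq_len(I - 1L)) {
      d <- breakpoints[i + 1L] - breakpoints[i]
      gamma[i + 1L] <- gamma[i] + sum(coeffs[i, ] * d^seq_len(L))
    }
  }
  structure(list(coeffs = coeffs, breakpoints = as.numeric(breakpoints),
                 offsets = gamma, order = L, n_pieces = I),
            class = "spline_kernel")
}

#' Zero (identity) spline kernel
#'
#' All coefficients zero: both Chirplet operators collapse to 1 and the SCT
#' reduces to the Gaussian-windowed STFT.
#'
#' @param n_samples Signal length the kernel covers.
#' @param n_pieces,order Kernel geometry.
#' @return A [spline_kernel()].
#' @export
zero_spline_kernel <- function(n_samples, n_pieces = 1L, order = 1L) {
  bp <- round(seq(0, n_samples, length.out = n_pieces + 1L))
  spline_kernel(matrix(0, n_pieces, order), bp)
}

# kernel IF law in cycles/sample at (0-based) sample positions
.kernel_if <- function(kernel, pos) {
  i <- pmin(pmax(findInterval(pos, kernel$breakpoints), 1L), kernel$n_pieces)
  L <- kernel$order
  out <- numeric(length(pos))
  for (l in seq_len(L)) {
    out <- out + l * kernel$coeffs[cbind(i, l)] *
      (pos - kernel$breakpoints[i])^(l - 1L)
  }
  out
}

#' Estimate the instantaneous-frequency ridge of a recording
#'
#' Maximum-magnitude frequency per Gaussian-STFT time bin, median-filtered to
#' suppress bin-to-bin jumps. This drives the spline-kernel fit: the
#' transform needs an IF law, and the ridge of the plain spectrogram is the
#' natural estimate.
#'
#' @param rec Preprocessed [pcg_recording()].
#' @param n_fft FFT length.
#' @param sigma Gaussian window width in samples.
#' @param hop Hop size in samples.
#' @param min_freq Lowest frequency (Hz) considered for the ridge; bins below
#'   it (DC drift) are ignored.
#' @param median_k Odd window length of the median filter.
#' @return Numeric vector of ridge frequencies in Hz, one per time bin, with
#'   attributes `sample_pos` (0-based frame centres), `n_samples`, and
#'   `low_confidence` (TRUE when all frame magnitudes are negligible, e.g.
#'   silence).
#' @export
estimate_if_ridge <- function(rec, n_fft = 1600L, sigma = 200, hop = 80L,
                              min_freq = 25, median_k = 5L) {
  stopifnot(inherits(rec, "pcg_recording"))
  tfr <- sct_transform(rec, zero_spline_kernel(length(rec$samples)),
                       sigma = sigma, n_fft = n_fft, hop = hop)
  mag <- abs(tfr$values)
  keep <- which(tfr$freq_axis >= min_freq)
  sub <- mag[, keep, drop = FALSE]
  idx <- max.col(sub, ties.method = "first")
  ridge <- tfr$freq_axis[keep[idx]]
  maxmag <- sub[cbind(seq_len(nrow(sub)), idx)]
  if (length(ridge) >= median_k) {
    ridge <- as.numeric(stats::runmed(ridge, median_k))
  }
  structure(ridge,
            sample_pos = round(tfr$time_axis * rec$fs),
            n_samples = length(rec$samples),
            fs = rec$fs,
            low_confidence = all(maxmag <= 1e-12))
}

#' Fit a spline kernel to an instantaneous-frequency track
#'
#' Least-squares piecewise-polynomial fit of the IF law on `n_pieces`
#' equal-width pieces. Within piece `i` the IF (cycles/sample) is modelled as
#' a polynomial of degree `order - 1` in `(n - n_i)`; its antiderivative
#' gives the phase coefficients `q_l = c_(l-1) / l`. Offsets `gamma_i` chain
#' the pieces so the rotate phase is continuous at breakpoints (`gamma_1 = 0`).
#'
#' @param if_track Ridge frequencies in Hz (e.g. from [estimate_if_ridge()]).
#' @param n_pieces Number of spline pieces `I`.
#' @param order Spline order `L`.
#' @param fs Sampling rate in Hz (defaults to the track's attribute).
#' @param sample_pos 0-based sample positions of the track values.
#' @param n_samples Signal length the kernel must cover.
#' @return A [spline_kernel()].
#' @export
fit_spline_kernel <- function(if_track, n_pieces = 10L, order = 3L,
                              fs = attr(if_track, "fs"),
                              sample_pos = attr(if_track, "sample_pos"),
                              n_samples = attr(if_track, "n_samples")) {
  if (is.null(fs)) stop("fs is required")
  if (!all(is.finite(if_track))) stop("if_track must be finite")
  if (n_pieces < 1L || order < 1L) stop("need n_pieces >= 1 and order >= 1")
  if (n_pieces > length(if_track)) {
    stop("n_pieces (", n_pieces, ") exceeds number of time bins (",
         length(if_track), ")")
  }
  if (is.null(sample_pos)) {
    sample_pos <- seq(0, length.out = length(if_track))
    n_samples <- length(if_track)
  }
  if (is.null(n_samples)) n_samples <- max(sample_pos) + 1
  nu <- as.numeric(if_track) / fs            # cycles/sample
  bp <- round(seq(0, n_samples, length.out = n_pieces + 1L))
  Q <- matrix(0, n_pieces, order)
  for (i in seq_len(n_pieces)) {
    if (i < n_pieces) sel <- sample_pos >= bp[i] & sample_pos < bp[i + 1L]
    else sel <- sample_pos >= bp[i]
    if (!any(sel)) next
    u <- sample_pos[sel] - bp[i]
    deg <- min(order - 1L, sum(sel) - 1L)
    X <- outer(u, 0:deg, `^`)
    cf <- qr.coef(qr(X), nu[sel])
    cf[is.na(cf)] <- 0
    Q[i, seq_len(deg + 1L)] <- cf / seq_len(deg + 1L)   # q_l = c_(l-1) / l
  }
  spline_kernel(Q, bp)
}

#' Spline-kernel Chirplet transform
#'
#' Computes the complex time-frequency matrix of a recording: at each hop the
#' signal is demodulated by the kernel's frequency-rotate and frequency-shift
#' operators (piece selected by the analysis time), Gaussian-windowed, and
#' Fourier transformed. With a zero kernel this is exactly the
#' Gaussian-windowed STFT.
#'
#' @param rec Preprocessed [pcg_recording()].
#' @param kernel A [spline_kernel()] covering the recording's support.
#' @param sigma Gaussian window width in samples.
#' @param n_fft FFT length; frequency bin spacing is `fs / n_fft`.
#' @param hop Hop between analysis times in samples.
#' @param half_width Window half support; capped so the windowed segment fits
#'   in `n_fft`.
#' @param convention `"consistent"` (shift frequency is the derivative of the
#'   rotate phase) or `"printed"` (no derivative factor).
#' @return A `tfr_matrix`: complex `values` (time bins x frequency bins,
#'   frequencies 0..fs/2), `freq_axis` (Hz), `time_axis` (s), `fs`, `sigma`.
#' @export
sct_transform <- function(rec, kernel, sigma = 200, n_fft = 1600L, hop = 80L,
                          half_width = NULL,
                          convention = c("consistent", "printed")) {
  stopifnot(inherits(rec, "pcg_recording"), inherits(kernel, "spline_kernel"))
  convention <- match.arg(convention)
  x <- rec$samples
  N <- length(x)
  bp <- kernel$breakpoints
  if (bp[1] > 0 || bp[length(bp)] < N) {
    stop("kernel breakpoints (", bp[1], "..", bp[length(bp)],
         ") do not cover the signal support [0, ", N, ")")
  }
  if (is.null(half_width)) half_width <- ceiling(3 * sigma)
  half_width <- min(half_width, (n_fft - 1L) %/% 2L)
  w <- gaussian_window(sigma, half_width)
  L <- kernel$order
  lfac <- if (convention == "consistent") seq_len(L) else rep(1, L)

  centers <- seq(0, N - 1, by = hop)              # 0-based analysis times
  n_freq <- n_fft %/% 2L + 1L
  vals <- matrix(0 + 0i, nrow = length(centers), ncol = n_freq)
  d <- seq(-half_width, half_width)
  zero_kernel <- all(kernel$coeffs == 0)

  for (fi in seq_along(centers)) {
    nt <- centers[fi]
    n_idx <- nt + d
    ok <- n_idx >= 0 & n_idx <= N - 1
    if (!any(ok)) next
    nn <- n_idx[ok]
    seg <- x[nn + 1]
    if (!zero_kernel) {
      i <- min(max(findInterval(nt, bp), 1L), kernel$n_pieces)
      q <- kernel$coeffs[i, ]
      u <- nn - bp[i]
      rot_phase <- kernel$offsets[i]
      for (l in seq_len(L)) rot_phase <- rot_phase + q[l] * u^l
      f_shift <- sum(lfac * q * (nt - bp[i])^(seq_len(L) - 1L))
      seg <- seg * exp(-2i * pi * rot_phase) * exp(2i * pi * f_shift * nn)
    }
    buf <- complex(n_fft)
    buf[which(ok)] <- seg * w[ok]
    sp <- stats::fft(buf)
    vals[fi, ] <- sp[seq_len(n_freq)]
  }

  structure(list(values = vals,
                 fs = rec$fs,
                 freq_axis = (seq_len(n_freq) - 1) * rec$fs / n_fft,
                 time_axis = centers / rec$fs,
                 sigma = sigma, n_fft = as.integer(n_fft),
                 hop = as.integer(hop), half_width = as.integer(half_width)),
            class = "tfr_matrix")
}

#' Chirplet transform (single global linear chirp kernel)
#'
#' Convenience wrapper: a one-piece kernel whose IF law is a straight line of
#' slope `chirp_rate`. Equivalent to [sct_transform()] with `I = 1` and a
#' quadratic phase piece (`q_2 = chirp_rate / (2 fs^2)` cycles/sample^2).
#'
#' @param rec Preprocessed [pcg_recording()].
#' @param chirp_rate Chirp rate in Hz/s; 0 gives the plain Gaussian STFT.
#' @inheritParams sct_transform
#' @return A `tfr_matrix`.
#' @export
ct_transform <- function(rec, chirp_rate = 0, sigma = 200, n_fft = 1600L,
                         hop = 80L, half_width = NULL,
                         convention = c("consistent", "printed")) {
  N <- length(rec$samples)
  q2 <- chirp_rate / (2 * rec$fs^2)       # Hz/s -> cycles/sample^2, phase coeff
  kern <- spline_kernel(matrix(c(0, q2), 1, 2), c(0, N))
  sct_transform(rec, kern, sigma = sigma, n_fft = n_fft, hop = hop,
                half_width = half_width, convention = convention)
}

#' @export
print.tfr_matrix <- function(x, ...) {
  cat(sprintf(
    "<tfr_matrix> %d time bins x %d frequency bins, fs %g Hz, df %.3g Hz, sigma %g samples\n",
    nrow(x$values), ncol(x$values), x$fs, x$fs / x$n_fft, x$sigma))
  invisible(x)
}

#' Export a TFR to delimited text
#'
#' Tab-separated magnitude matrix with explicit axis headers: first row the
#' frequency axis (Hz), first column the time axis (s).
#'
#' @param tfr A `tfr_matrix`.
#' @param path Output path.
#' @param magnitude Write `|T|` (default) or the real part.
#' @return `path`, invisibly.
#' @export
export_tfr <- function(tfr, path, magnitude = TRUE) {
  stopifnot(inherits(tfr, "tfr_matrix"))
  m <- if (magnitude) abs(tfr$values) else Re(tfr$values)
  out <- cbind(time_s = tfr$time_axis, m)
  colnames(out) <- c("time_s", sprintf("%.6g", tfr$freq_axis))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Contour/image plot of a TFR
#'
#' @param tfr A `tfr_matrix`.
#' @param file Optional PNG path; when given the plot is written there.
#' @param max_freq Upper frequency limit of the display in Hz.
#' @param ... Passed to [graphics::image()].
#' @return `NULL`, invisibly.
#' @export
plot_tfr <- function(tfr, file = NULL, max_freq = 1000, ...) {
  stopifnot(inherits(tfr, "tfr_matrix"))
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off())
  }
  keep <- tfr$freq_axis <= max_freq
  graphics::image(x = tfr$time_axis, y = tfr$freq_axis[keep],
                  z = abs(tfr$values[, keep, drop = FALSE]),
                  xlab = "Time (s)", ylab = "Frequency (Hz)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(NULL)
}
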