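test_that("gaussian window matches its closed form and is symmetric", {
  w <- gaussian_window(10, 30)
  expect_length(w, 61)
  expect_equal(w[31], 1 / (sqrt(2 * pi) * 10))
  expect_equal(w, rev(w))
  expect_equal(w[41] / w[31], exp(-1 / 2))    # n = sigma
  expect_error(gaussian_window(0), "positive")
})

test_that("spline kernel validates geometry and chains phase offsets", {
  Q <- matrix(c(1e-3, 2e-3, 1e-7, -1e-7), 2, 2)
  k <- spline_kernel(Q, c(0, 500, 1000))
  expect_equal(k$offsets[1], 0)
  # continuity: piece-1 phase at the shared breakpoint equals gamma_2
  d <- 500
  expect_equal(k$offsets[2], sum(Q[1, ] * d^(1:2)))
  expect_error(spline_kernel(Q, c(0, 500)), "one more")
  expect_error(spline_kernel(Q, c(0, 500, 500)), "increasing")
})

test_that("rotate/shift phase is continuous at breakpoints for fitted kernels", {
  pos <- seq(0, 4000, by = 40)
  if_hz <- 150 + 80 * sin(2 * pi * pos / 4000)
  k <- fit_spline_kernel(if_hz, n_pieces = 8, order = 3, fs = 4000,
                         sample_pos = pos, n_samples = 4001)
  phase <- function(i, n) {
    u <- n - k$breakpoints[i]
    sum(k$coeffs[i, ] * u^(1:3)) + k$offsets[i]
  }
  for (i in 1:7) {
    bp <- k$breakpoints[i + 1]
    expect_equal(phase(i, bp), phase(i + 1, bp), tolerance = 1e-10)
  }
})

test_that("IF ridge tracks a stationary tone and a linear chirp", {
  tone <- make_tone(200, dur = 1)
  r <- estimate_if_ridge(tone)
  expect_true(all(abs(r - 200) <= 2.5))       # within one 2.5 Hz bin
  expect_false(attr(r, "low_confidence"))

  ch <- make_chirp(100, 300, dur = 1)
  rr <- estimate_if_ridge(ch)
  pos <- attr(rr, "sample_pos")
  true_if <- 100 + 200 * (pos / 4000)
  # interior frames (full window support): within 2 bins of the analytic IF
  interior <- pos > 600 & pos < 4000 - 600
  expect_true(all(abs(rr[interior] - true_if[interior]) <= 5))

  silent <- pcg_recording(rep(0, 4000), 4000)
  rs <- estimate_if_ridge(silent)
  expect_true(attr(rs, "low_confidence"))
  expect_true(all(is.finite(rs)))
})

test_that("spline fit recovers constant and polynomial IF laws", {
  pos <- seq(0, 3999, by = 80)
  const <- rep(180, length(pos))
  k <- fit_spline_kernel(const, n_pieces = 4, order = 3, fs = 4000,
                         sample_pos = pos, n_samples = 4000)
  expect_equal(max(abs(k$coeffs[, 2:3])), 0, tolerance = 1e-12)
  expect_equal(k$coeffs[, 1], rep(180 / 4000, 4), tolerance = 1e-10)

  # degree-2 IF polynomial, single piece, order 3: exact recovery of the
  # IF coefficients c_(l-1) = l * q_l
  cf <- c(100, 0.05, 1e-5)                    # Hz per sample^deg
  ifp <- cf[1] + cf[2] * pos + cf[3] * pos^2
  k1 <- fit_spline_kernel(ifp, n_pieces = 1, order = 3, fs = 4000,
                          sample_pos = pos, n_samples = 4000)
  rec_cf <- k1$coeffs[1, ] * (1:3) * 4000
  expect_equal(rec_cf, cf, tolerance = 1e-6)

  # piecewise-linear IF with the break at a piece boundary, L = 2, I = 2
  brk <- 2000
  slopes <- c(0.04, -0.02)
  ifpw <- ifelse(pos < brk, 100 + slopes[1] * pos,
                 100 + slopes[1] * brk + slopes[2] * (pos - brk))
  k2 <- fit_spline_kernel(ifpw, n_pieces = 2, order = 2, fs = 4000,
                          sample_pos = pos, n_samples = 4000)
  rec_slopes <- k2$coeffs[, 2] * 2 * 4000
  expect_equal(rec_slopes, slopes, tolerance = 1e-6)

  expect_error(fit_spline_kernel(const, n_pieces = 200, order = 3, fs = 4000,
                                 sample_pos = pos, n_samples = 4000),
               "exceeds")
})

test_that("zero-kernel SCT equals the directly computed Gaussian STFT", {
  rec <- make_tone(200, dur = 1)
  tfr <- sct_transform(rec, zero_spline_kernel(length(rec$samples)))
  oracle <- stft_oracle(rec$samples, 200, 1600, 80, tfr$half_width)
  expect_lt(max(abs(tfr$values - oracle)), 1e-9)
  expect_equal(tfr$freq_axis, (0:800) * 2.5)
  expect_true(all(tfr$freq_axis <= 2000))
})

test_that("Chirplet operators are pure phase factors: energy is conserved", {
  set.seed(5)
  x <- rnorm(2000)
  rec <- pcg_recording(x, 4000)
  kern <- spline_kernel(matrix(c(2e-2, 1e-6, 1e-10,
                                 -1e-2, 2e-6, -1e-10), 2, 3, byrow = TRUE),
                        c(0, 1000, 2000))
  # demodulate exactly as the transform does at one analysis time and check
  # |xbar| == |x|
  nt <- 700
  i <- findInterval(nt, kern$breakpoints)
  u <- (0:1999) - kern$breakpoints[i]
  rot <- exp(-2i * pi * (kern$coeffs[i, 1] * u + kern$coeffs[i, 2] * u^2 +
                           kern$coeffs[i, 3] * u^3 + kern$offsets[i]))
  fsh <- sum((1:3) * kern$coeffs[i, ] * (nt - kern$breakpoints[i])^(0:2))
  shift <- exp(2i * pi * fsh * (0:1999))
  xbar <- x * rot * shift
  expect_equal(abs(xbar), abs(x), tolerance = 1e-12)
  expect_equal(sum(abs(xbar)^2), sum(x^2), tolerance = 1e-10)
})

test_that("zero signal transforms to an identically zero TFR", {
  rec <- pcg_recording(rep(0, 2000), 4000)
  tfr <- sct_transform(rec, zero_spline_kernel(2000))
  expect_true(all(tfr$values == 0))
})

test_that("fitted kernel sharpens a chirp ridge relative to plain STFT", {
  ch <- make_chirp(100, 300, dur = 1)
  ridge <- estimate_if_ridge(ch)
  kern <- fit_spline_kernel(ridge, n_pieces = 10, order = 3)
  tsct <- sct_transform(ch, kern)
  tstft <- sct_transform(ch, zero_spline_kernel(length(ch$samples)))
  bandwidth <- function(tfr) {
    m <- abs(tfr$values); f <- tfr$freq_axis
    per_frame <- apply(m, 1, function(p) {
      p <- p^2
      if (sum(p) == 0) return(NA_real_)
      p <- p / sum(p)
      mu <- sum(p * f)
      sqrt(sum(p * (f - mu)^2))
    })
    mean(per_frame, na.rm = TRUE)
  }
  expect_lt(bandwidth(tsct), bandwidth(tstft))
})

test_that("a tone's energy peaks at its own frequency bin under any matched kernel", {
  rec <- make_tone(250, dur = 1)
  # kernel whose IF law is the constant 250 Hz
  kern <- spline_kernel(matrix(250 / 4000, 1, 1), c(0, 4000))
  tfr <- sct_transform(rec, kern)
  interior <- 10:40
  peak_bins <- apply(abs(tfr$values[interior, ]), 1, which.max)
  expect_true(all(abs(tfr$freq_axis[peak_bins] - 250) <= 2.5))
})

test_that("CT wrapper collapses to STFT at zero rate and matches its SCT kernel", {
  rec <- make_tone(200, dur = 0.5)
  t0 <- ct_transform(rec, chirp_rate = 0)
  tz <- sct_transform(rec, zero_spline_kernel(length(rec$samples)))
  expect_identical(t0$values, tz$values)

  rate <- 200
  tct <- ct_transform(rec, chirp_rate = rate)
  kern <- spline_kernel(matrix(c(0, rate / (2 * 4000^2)), 1, 2),
                        c(0, length(rec$samples)))
  tsk <- sct_transform(rec, kern)
  expect_identical(tct$values, tsk$values)
})

test_that("CT at the matched rate concentrates a chirp more than STFT", {
  ch <- make_chirp(100, 300, dur = 1)
  bw <- function(tfr) {
    m <- abs(tfr$values); f <- tfr$freq_axis
    mean(apply(m, 1, function(p) {
      p <- p^2; if (sum(p) == 0) return(NA_real_)
      p <- p / sum(p); mu <- sum(p * f); sqrt(sum(p * (f - mu)^2))
    }), na.rm = TRUE)
  }
  tct <- ct_transform(ch, chirp_rate = 200)
  tstft <- ct_transform(ch, chirp_rate = 0)
  expect_lt(bw(tct), bw(tstft))
})

test_that("kernel/signal coverage mismatch is rejected", {
  rec <- make_tone(100, dur = 1)
  expect_error(sct_transform(rec, zero_spline_kernel(2000)), "cover")
})

test_that("TFR export writes a parseable matrix with axis headers", {
  rec <- make_tone(200, dur = 0.25)
  tfr <- sct_transform(rec, zero_spline_kernel(length(rec$samples)))
  f <- withr::local_tempfile(fileext = ".tsv")
  export_tfr(tfr, f)
  back <- utils::read.delim(f, check.names = FALSE)
  expect_equal(nrow(back), nrow(tfr$values))
  expect_equal(back$time_s, tfr$time_axis)
  expect_equal(as.numeric(back[3, -1]), abs(tfr$values[3, ]), tolerance = 1e-6)
})
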