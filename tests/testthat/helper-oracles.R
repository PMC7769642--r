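# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (double loops, direct definitions) so they check the
# optimized implementations from a different route.

# O(N^2) sample entropy by explicit template-pair counting
sampen_bruteforce <- function(x, m, r) {
  n <- length(x)
  cheb <- function(i, j, len) {
    d <- 0
    for (t in 0:(len - 1L)) d <- max(d, abs(x[i + t] - x[j + t]))
    d
  }
  count_pairs <- function(len) {
    cnt <- 0L
    for (i in seq_len(n - m - 1L)) {
      for (j in (i + 1L):(n - m)) {
        if (cheb(i, j, len) <= r) cnt <- cnt + 1L
      }
    }
    cnt
  }
  B <- count_pairs(m)
  A <- count_pairs(m + 1L)
  if (A == 0L || B == 0L) {
    bp <- max(B, 2L)
    return(log(bp * (bp - 1)) + 1)
  }
  -log(A / B)
}

# permutation entropy by direct histogram over ordinal patterns
pen_bruteforce <- function(x, ord, delay = 1L, normalized = TRUE) {
  n_w <- length(x) - (ord - 1L) * delay
  pats <- character(n_w)
  for (i in seq_len(n_w)) {
    w <- x[i + (0:(ord - 1L)) * delay]
    pats[i] <- paste(rank(w, ties.method = "first"), collapse = "-")
  }
  p <- table(pats) / n_w
  h <- -sum(p * log(p))
  if (normalized) h / log(factorial(ord)) else h
}

# direct Gaussian-windowed STFT with the same framing convention as the
# transform under test (zero-padded n_fft buffer per hop)
stft_oracle <- function(x, sigma, n_fft, hop, hw) {
  N <- length(x)
  centers <- seq(0, N - 1, by = hop)
  n <- seq(-hw, hw)
  w <- exp(-n^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  out <- matrix(0 + 0i, length(centers), n_fft / 2 + 1)
  for (fi in seq_along(centers)) {
    idx <- centers[fi] + n
    ok <- idx >= 0 & idx <= N - 1
    buf <- complex(n_fft)
    buf[which(ok)] <- x[idx[ok] + 1] * w[ok]
    out[fi, ] <- stats::fft(buf)[1:(n_fft / 2 + 1)]
  }
  out
}

# exhaustive L1 solver over supports of size <= 2: per support, per sign
# pattern, the stationary candidate is (As'As)^-1 (As'b - lambda s); keep it
# if the signs agree, and take the best objective over all candidates
lasso_bruteforce <- function(A, b, lambda) {
  obj <- function(g) 0.5 * sum((b - A %*% g)^2) + lambda * sum(abs(g))
  m <- ncol(A)
  best <- obj(numeric(m))
  for (i in seq_len(m)) {
    a <- A[, i]
    g1 <- sign(sum(a * b)) * max(abs(sum(a * b)) - lambda, 0) / sum(a * a)
    g <- numeric(m); g[i] <- g1
    best <- min(best, obj(g))
  }
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    As <- A[, c(i, j)]
    G <- crossprod(As)
    for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) {
      gs <- try(solve(G, crossprod(As, b) - lambda * c(s1, s2)), silent = TRUE)
      if (inherits(gs, "try-error")) next
      if (all(sign(gs) == c(s1, s2)) || all(gs == 0)) {
        g <- numeric(m); g[c(i, j)] <- gs
        best <- min(best, obj(g))
      }
    }
  }
  best
}

# independent per-class metric recomputation straight from TP/TN/FP/FN
metrics_bruteforce <- function(conf) {
  C <- nrow(conf); total <- sum(conf)
  out <- data.frame(precision = numeric(C), sensitivity = numeric(C),
                    specificity = numeric(C), f_score = numeric(C))
  for (c in seq_len(C)) {
    tp <- conf[c, c]
    fn <- sum(conf[c, ]) - tp
    fp <- sum(conf[, c]) - tp
    tn <- total - tp - fn - fp
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    sens <- if (tp + fn > 0) tp / (tp + fn) else 0
    spec <- if (tn + fp > 0) tn / (tn + fp) else 0
    f <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
    out[c, ] <- 100 * c(prec, sens, spec, f)
  }
  out$oa <- 100 * sum(diag(conf)) / total
  out
}

# fake TFR container with arbitrary complex values
make_tfr <- function(values, fs = 4000, n_fft = 2 * (ncol(values) - 1L)) {
  structure(list(values = values, fs = fs,
                 freq_axis = (seq_len(ncol(values)) - 1) * fs / n_fft,
                 time_axis = (seq_len(nrow(values)) - 1) * 0.02,
                 sigma = 200, n_fft = as.integer(n_fft), hop = 80L,
                 half_width = 600L),
            class = "tfr_matrix")
}

make_tone <- function(freq, dur = 1, fs = 4000, amp = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  pcg_recording(amp * sin(2 * pi * freq * t), fs)
}

make_chirp <- function(f0, f1, dur = 1, fs = 4000) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  rate <- (f1 - f0) / dur
  pcg_recording(sin(2 * pi * (f0 * t + rate * t^2 / 2)), fs)
}

# well-separated 5-class toy dictionary in feature space: `per_class` atoms
# clustered tightly around 5 distant centroids
toy_dictionary <- function(per_class = 5L, dim = 10L, spread = 0.05,
                           gap = 10, seed = 303) {
  set.seed(seed)
  centroids <- matrix(stats::rnorm(5 * dim), 5, dim) * gap
  Z <- do.call(rbind, lapply(1:5, function(c) {
    centroids[rep(c, per_class), , drop = FALSE] +
      matrix(stats::rnorm(per_class * dim, sd = spread), per_class, dim)
  }))
  list(Z = Z, labels = rep(1:5, each = per_class))
}

# memoized small synthetic feature sets shared across tests in one session
.fixture_cache <- new.env(parent = emptyenv())

tiny_features <- function(n_per_class = 3L, snr_db = 25, seed = 404,
                          duration_s = 1.6) {
  key <- paste("feat", n_per_class, snr_db, seed, duration_s, sep = "_")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  recs <- generate_dataset(n_per_class,
                           synth_config(snr_db = snr_db, seed = seed,
                                        duration_s = duration_s))
  feats <- pcg_feature_matrix(recs, dlksrn_config(seed = seed))
  out <- list(recordings = recs, features = feats)
  .fixture_cache[[key]] <- out
  out
}
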