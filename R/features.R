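# Per-frequency-atom nonlinear features of the time-frequency magnitude
# matrix. A frequency "atom" is one DFT bin of the TFR grid, skipping DC:
# atom k sits at k * fs / n_fft Hz. Each recording is summarized by 400
# L1-norms, 400 sample entropies and 400 permutation entropies, concatenated
# blockwise into a 1200-dimensional vector.

#' Magnitude series of one frequency atom
#'
#' @param tfr A `tfr_matrix`.
#' @param k Atom index (1-based, DC excluded): atom `k` is the DFT bin at
#'   `k * fs / n_fft` Hz.
#' @return Numeric vector `|T(., k)|` over time bins.
#' @export
atom_series <- function(tfr, k) {
  stopifnot(inherits(tfr, "tfr_matrix"))
  n_atoms <- ncol(tfr$values) - 1L
  if (k < 1L || k > n_atoms) {
    stop("atom index k = ", k, " out of range 1..", n_atoms)
  }
  abs(tfr$values[, k + 1L])
}

#' L1-norm feature of a frequency atom
#'
#' Sum of the magnitudes down the atom's column of the time-frequency
#' matrix: total energy-like mass of that frequency over the recording.
#'
#' @inheritParams atom_series
#' @return Nonnegative scalar.
#' @export
l1_norm_feature <- function(tfr, k) {
  sum(atom_series(tfr, k))
}

#' Sample entropy
#'
#' `SampEn(m, r) = -ln(A / B)` where `B` counts pairs of length-`m` templates
#' within Chebyshev distance `r` (self-matches excluded) and `A` the same for
#' length `m + 1`. Counting follows the convention that both template sets
#' start at positions `1 .. N - m`.
#'
#' @param series Numeric vector, length `>= m + 2`.
#' @param m Embedding dimension.
#' @param r Tolerance. `NULL` (default) uses `r_factor * sd(series)` with an
#'   absolute floor of `1e-12`, so constant series count as fully regular
#'   (SampEn 0) rather than undefined.
#' @param r_factor Multiplier on the series SD when `r` is `NULL`.
#' @param cap Value returned when no matches exist at length `m + 1` (or
#'   `m`). `NULL` uses `log(B' (B' - 1)) + 1` with `B' = max(B, 2)`, finite
#'   and larger than any attainable value.
#' @return Nonnegative scalar.
#' @export
sample_entropy <- function(series, m = 2L, r = NULL, r_factor = 0.2,
                           cap = NULL) {
  x <- as.numeric(series)
  n <- length(x)
  if (n < m + 2L) stop("series must have at least m + 2 = ", m + 2L, " points")
  if (!all(is.finite(x))) stop("series must be finite")
  if (is.null(r)) r <- max(r_factor * stats::sd(x), 1e-12)
  if (r <= 0) stop("tolerance r must be positive")

  D <- abs(outer(x, x, `-`))
  M <- D
  if (m > 1L) {
    for (k in seq_len(m - 1L)) {
      nk <- n - k
      M <- pmax(M[seq_len(nk), seq_len(nk), drop = FALSE],
                D[(k + 1L):n, (k + 1L):n, drop = FALSE])
    }
  }
  nm <- n - m                               # templates 1 .. n - m
  Mm <- M[seq_len(nm), seq_len(nm), drop = FALSE]
  B <- sum(Mm[upper.tri(Mm)] <= r)
  Mm1 <- pmax(Mm, D[(m + 1L):n, (m + 1L):n, drop = FALSE])
  A <- sum(Mm1[upper.tri(Mm1)] <= r)
  if (A == 0L || B == 0L) {
    if (!is.null(cap)) return(cap)
    bp <- max(B, 2L)
    return(log(bp * (bp - 1)) + 1)
  }
  -log(A / B)
}

#' Permutation entropy
#'
#' Shannon entropy of the ordinal-pattern distribution of delay-embedded
#' windows; ties are ranked by order of occurrence (stable ranking). When
#' `normalized`, divided by `log(order!)` so the value lies in `[0, 1]`.
#'
#' @param series Numeric vector, length `>= (order - 1) * delay + 2`.
#' @param order Pattern length (embedding dimension).
#' @param delay Embedding delay in samples.
#' @param normalized Divide by `log(order!)`?
#' @return Scalar in `[0, 1]` when normalized.
#' @export
permutation_entropy <- function(series, order = 3L, delay = 1L,
                                normalized = TRUE) {
  x <- as.numeric(series)
  n <- length(x)
  n_w <- n - (order - 1L) * delay
  if (n_w < 2L) {
    stop("series too short: need length >= (order - 1) * delay + 2 = ",
         (order - 1L) * delay + 2L)
  }
  if (!all(is.finite(x))) stop("series must be finite")
  W <- vapply(seq_len(order),
              function(k) x[seq_len(n_w) + (k - 1L) * delay],
              numeric(n_w))
  if (n_w == 1L) W <- matrix(W, nrow = 1L)
  # stable rank of column j within each row: strictly-smaller count plus
  # earlier-equal count
  pat <- integer(n_w)
  for (j in seq_len(order)) {
    rj <- integer(n_w)
    for (k in seq_len(order)) {
      if (k == j) next
      rj <- rj + (W[, k] < W[, j]) + (k < j) * (W[, k] == W[, j])
    }
    pat <- pat + rj * order^(j - 1L)
  }
  p <- tabulate(match(pat, unique(pat)))
  p <- p / n_w
  h <- -sum(p * log(p))
  if (normalized) h / log(factorial(order)) else h
}

#' Extract the full per-recording feature vector
#'
#' For atoms `k = 1 .. n_atoms` of the TFR magnitude matrix, computes the
#' L1-norm, sample entropy and permutation entropy of `|T(., k)|` and
#' concatenates them blockwise `[LN | SEN | PEN]` into a `3 * n_atoms`
#' vector (1200 under defaults).
#'
#' @param tfr A `tfr_matrix` with at least `n_atoms + 1` frequency bins.
#' @param n_atoms Number of leading frequency atoms.
#' @param sen_m,sen_r_factor Sample-entropy parameters.
#' @param pen_order,pen_delay Permutation-entropy parameters.
#' @return Named numeric vector (`LN_001 .. PEN_400`) with attribute `label`
#'   copied from nothing here; attach labels at the dataset level.
#' @export
extract_feature_vector <- function(tfr, n_atoms = 400L, sen_m = 2L,
                                   sen_r_factor = 0.2, pen_order = 3L,
                                   pen_delay = 1L) {
  stopifnot(inherits(tfr, "tfr_matrix"))
  if (ncol(tfr$values) - 1L < n_atoms) {
    stop("TFR has only ", ncol(tfr$values) - 1L, " atoms; need ", n_atoms)
  }
  mag <- abs(tfr$values[, 1L + seq_len(n_atoms), drop = FALSE])
  ln <- colSums(mag)
  sen <- apply(mag, 2L, sample_entropy, m = sen_m, r_factor = sen_r_factor)
  pen <- apply(mag, 2L, permutation_entropy, order = pen_order,
               delay = pen_delay)
  out <- c(ln, sen, pen)
  names(out) <- c(sprintf("LN_%03d", seq_len(n_atoms)),
                  sprintf("SEN_%03d", seq_len(n_atoms)),
                  sprintf("PEN_%03d", seq_len(n_atoms)))
  out
}

#' Fit a min-max feature scaler on training data
#'
#' Per-dimension min-max scaling fitted on the training set only; constant
#' dimensions map to 0. Values outside the training range map outside
#' `[0, 1]` (affine, not clipped).
#'
#' @param train Numeric matrix, instances in rows.
#' @return A `feature_scaler`.
#' @export
fit_feature_scaler <- function(train) {
  train <- as.matrix(train)
  if (nrow(train) < 1L) stop("training set is empty")
  mins <- apply(train, 2L, min)
  rng <- apply(train, 2L, max) - mins
  structure(list(mins = mins, ranges = rng), class = "feature_scaler")
}

#' Apply a fitted min-max scaler
#'
#' @param scaler A `feature_scaler` from [fit_feature_scaler()].
#' @param X Matrix (instances x dimensions) or a single feature vector.
#' @return Scaled matrix/vector of the same shape.
#' @export
apply_feature_scaler <- function(scaler, X) {
  stopifnot(inherits(scaler, "feature_scaler"))
  vec <- is.null(dim(X))
  X <- if (vec) matrix(X, nrow = 1L) else as.matrix(X)
  if (ncol(X) != length(scaler$mins)) stop("dimension mismatch with scaler")
  denom <- ifelse(scaler$ranges == 0, 1, scaler$ranges)
  out <- sweep(sweep(X, 2L, scaler$mins), 2L, denom, `/`)
  out[, scaler$ranges == 0] <- 0
  if (vec) drop(out) else out
}

#' Min-max scale train/other feature sets together
#'
#' @param train,others Feature matrices (instances x dimensions); `others`
#'   may be `NULL`.
#' @return List `train`, `others`, `scaler`.
#' @export
scale_features <- function(train, others = NULL) {
  scaler <- fit_feature_scaler(train)
  list(train = apply_feature_scaler(scaler, train),
       others = if (!is.null(others)) apply_feature_scaler(scaler, others),
       scaler = scaler)
}

#' Write a labelled feature matrix to CSV
#'
#' Header names each dimension (`LN_001 .. PEN_400`) plus `label`.
#'
#' @param X Feature matrix (instances x dimensions, named columns).
#' @param labels Integer class codes, one per row.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
save_features <- function(X, labels, path) {
  X <- as.matrix(X)
  stopifnot(length(labels) == nrow(X))
  df <- as.data.frame(X)
  df$label <- as.integer(labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a labelled feature matrix written by [save_features()]
#'
#' @param path CSV path.
#' @return List `X` (matrix) and `labels` (integer vector).
#' @export
load_features <- function(path) {
  df <- utils::read.csv(path)
  if (!"label" %in% names(df)) stop("feature file lacks a `label` column")
  lab <- as.integer(df$label)
  df$label <- NULL
  list(X = as.matrix(df), labels = lab)
}
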