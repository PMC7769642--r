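test_that("L1-norm feature sums magnitudes down the atom's column", {
  vals <- matrix(0 + 0i, 3, 5)          # 3 time bins, bins 0..4 (4 atoms)
  vals[, 2] <- c(0.5, 0.25, 0.25)       # atom 1
  vals[, 3] <- c(3i, -4, 0)             # atom 2: magnitudes 3, 4
  tfr <- make_tfr(vals)
  expect_equal(l1_norm_feature(tfr, 1), 1.0)
  expect_equal(l1_norm_feature(tfr, 2), 7)
  expect_equal(l1_norm_feature(tfr, 4), 0)
  expect_error(l1_norm_feature(tfr, 5), "out of range")
  expect_error(l1_norm_feature(tfr, 0), "out of range")
})

test_that("L1-norm equals brute-force accumulation on a random matrix", {
  set.seed(42)
  vals <- matrix(complex(real = rnorm(25), imaginary = rnorm(25)), 5, 5)
  tfr <- make_tfr(vals)
  for (k in 1:4) {
    acc <- 0
    for (i in 1:5) acc <- acc + abs(vals[i, k + 1])
    expect_equal(l1_norm_feature(tfr, k), acc)
  }
})

test_that("sample entropy handles canonical hand cases", {
  expect_equal(sample_entropy(rep(3, 30), m = 2, r = 0.1), 0)   # A/B = 1
  x <- rep(c(1, 2, 3), 4)
  expect_equal(sample_entropy(x, m = 2, r = 0.5),
               sampen_bruteforce(x, 2, 0.5))
  expect_error(sample_entropy(c(1, 2, 3), m = 2), "at least")
})

test_that("sample entropy equals the O(N^2) oracle on random sequences", {
  set.seed(7)
  for (case in 1:60) {
    n <- sample(10:200, 1)
    x <- switch(1 + case %% 3,
                rnorm(n),
                cumsum(rnorm(n)),
                round(runif(n), 1))        # many ties
    m <- sample(1:3, 1)
    r <- 0.2 * stats::sd(x)
    if (r == 0) r <- 0.1
    expect_equal(sample_entropy(x, m = m, r = r),
                 sampen_bruteforce(x, m, r), tolerance = 1e-12)
  }
})

test_that("no-match sample entropy returns the finite cap", {
  # the (0, 1) template recurs three times (B = 3) but every length-3
  # extension differs wildly, so A = 0 and -ln(A/B) is undefined
  x <- c(0, 1, 100, 0, 1, 200, 0, 1, 300, 9)
  v <- sample_entropy(x, m = 2, r = 0.5)
  expect_equal(v, log(3 * 2) + 1)               # ln(B(B-1)) + 1
  expect_gt(v, log(3))                          # above the attainable ln(B)
  expect_equal(v, sampen_bruteforce(x, 2, 0.5))
  expect_equal(sample_entropy(x, m = 2, r = 0.5, cap = 99), 99)
})

test_that("permutation entropy spans its degenerate and maximal cases", {
  expect_equal(permutation_entropy(1:50, order = 3), 0)
  # all 6 order-3 patterns exactly once: windows at stride 3 with separators
  # would break embedding, so craft a sequence whose 6 consecutive windows
  # realize each pattern once is fiddly; instead check uniformity on the
  # canonical construction below and via the oracle on random data
  x <- c(1, 2, 3, 1, 0, 2, 0, 3, 1)
  expect_equal(permutation_entropy(x, order = 3),
               pen_bruteforce(x, 3))
  expect_error(permutation_entropy(c(1, 2), order = 3), "too short")
})

test_that("permutation entropy is 1 for an exactly uniform pattern histogram", {
  # order 2: windows alternate up/down, two of each
  expect_equal(permutation_entropy(c(1, 2, 1, 2, 1), order = 2), 1)
  # order 3: the 6 consecutive windows of this sequence realize each of the
  # 3! ordinal patterns exactly once (verified by the oracle)
  x <- c(7, 6, 1, 8, 3, 4, 5, 2)
  expect_equal(pen_bruteforce(x, 3), 1)
  expect_equal(permutation_entropy(x, order = 3), 1)
})

test_that("permutation entropy matches the histogram oracle on random data", {
  set.seed(13)
  for (case in 1:60) {
    n <- sample(8:200, 1)
    x <- if (case %% 2) rnorm(n) else sample(0:3, n, replace = TRUE)
    ord <- sample(2:4, 1)
    delay <- sample(1:2, 1)
    if (n < (ord - 1) * delay + 2) next
    expect_equal(permutation_entropy(x, order = ord, delay = delay),
                 pen_bruteforce(x, ord, delay), tolerance = 1e-12)
  }
})

test_that("normalized PEN stays in [0,1] and LN stays nonnegative", {
  set.seed(3)
  for (i in 1:40) {
    x <- rnorm(sample(10:100, 1))
    p <- permutation_entropy(x, order = 3)
    expect_gte(p, 0); expect_lte(p, 1)
  }
})

test_that("feature vector has blockwise layout and exact length 1200", {
  rec <- generate_recording(synth_config(duration_s = 1.2, seed = 8))
  rec <- preprocess_recording(rec)
  tfr <- sct_transform(rec, zero_spline_kernel(length(rec$samples)))
  fv <- extract_feature_vector(tfr)
  expect_length(fv, 1200L)
  expect_identical(names(fv)[1], "LN_001")
  expect_identical(names(fv)[401], "SEN_001")
  expect_identical(names(fv)[801], "PEN_001")
  expect_true(all(fv[1:400] >= 0))
  expect_true(all(fv[801:1200] >= 0 & fv[801:1200] <= 1))
  expect_true(all(is.finite(fv)))
  # blockwise agreement with the single-atom functions
  expect_equal(unname(fv[7]), l1_norm_feature(tfr, 7))
  expect_equal(unname(fv[400 + 7]), sample_entropy(atom_series(tfr, 7)))
  expect_equal(unname(fv[800 + 7]), permutation_entropy(atom_series(tfr, 7)))
})

test_that("zero TFR yields finite features under the zero-variance policy", {
  tfr <- make_tfr(matrix(0 + 0i, 10, 401))
  fv <- extract_feature_vector(tfr, n_atoms = 400)
  expect_true(all(is.finite(fv)))
  expect_true(all(fv[1:400] == 0))
  expect_true(all(fv[401:800] == 0))    # constant series: fully regular
  expect_true(all(fv[801:1200] == 0))   # single tie-pattern
})

test_that("feature extraction is deterministic and validates atom count", {
  rec <- preprocess_recording(
    generate_recording(synth_config(duration_s = 1.2, seed = 9)))
  tfr <- sct_transform(rec, zero_spline_kernel(length(rec$samples)))
  expect_identical(extract_feature_vector(tfr), extract_feature_vector(tfr))
  small <- make_tfr(matrix(0 + 0i, 10, 41))
  expect_error(extract_feature_vector(small, n_atoms = 400), "atoms")
})

test_that("min-max scaling follows the train-only affine map", {
  train <- matrix(c(2, 6, 4,   1, 1, 1), ncol = 2)  # dim 2 is constant
  sc <- fit_feature_scaler(train)
  out <- apply_feature_scaler(sc, train)
  expect_true(all(out >= 0 & out <= 1))
  expect_equal(apply_feature_scaler(sc, c(4, 1))[1], 0.5)
  expect_equal(apply_feature_scaler(sc, c(4, 1))[2], 0)     # constant dim -> 0
  expect_equal(apply_feature_scaler(sc, c(10, 1))[1], 2)    # outside, not clipped
  both <- scale_features(train, matrix(c(0, 1), 1, 2))
  expect_equal(unname(both$others[1, 1]), -0.5)
})

test_that("AS murmur-band L1 mass exceeds normal at matched SNR", {
  cfg <- dlksrn_config()
  band_mean_ln <- function(class_code) {
    rec <- generate_recording(synth_config(class_code = class_code,
                                           snr_db = 25, seed = 55,
                                           duration_s = 2))
    fv <- pcg_features(rec, cfg)
    # atoms at 300-780 Hz on the 2.5 Hz grid: indices 120..312
    mean(fv[120:312])
  }
  expect_gt(band_mean_ln(3L), band_mean_ln(1L))
})

test_that("feature CSV round-trips matrix, names and labels", {
  X <- matrix(runif(12), 3, 4,
              dimnames = list(NULL, c("LN_001", "LN_002", "SEN_001", "PEN_001")))
  f <- withr::local_tempfile(fileext = ".csv")
  save_features(X, c(1L, 3L, 5L), f)
  back <- load_features(f)
  expect_equal(unname(back$X), unname(X), tolerance = 1e-12)
  expect_equal(colnames(back$X), colnames(X))
  expect_equal(back$labels, c(1L, 3L, 5L))
})
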