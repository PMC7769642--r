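# End-to-end model: preprocessing -> SCT -> 1200-dim features -> min-max
# scaling -> two ELM-autoencoder layers (800, 600) -> KSRC dictionary.

#' Pipeline configuration
#'
#' Collects every tunable of the chain with the package defaults: 4 kHz
#' working rate, 25--900 Hz band, Gaussian window sigma 200 samples (50 ms),
#' 1600-point FFT (2.5 Hz bins, atoms 1..400 span 2.5--1000 Hz), 80-sample
#' hop, order-3 spline kernel on 10 pieces, hidden layers 800/600,
#' ELM ridge 1e3, RBF kernel with median-heuristic bandwidth, KPCA reduction,
#' L1 weight 1e-3.
#'
#' @param target_fs,bp_low,bp_high,bp_order Preprocessing parameters.
#' @param sigma,n_fft,hop SCT analysis parameters (samples / bins / samples).
#' @param n_pieces,spline_order Spline-kernel fit.
#' @param n_atoms Frequency atoms per feature block.
#' @param sen_m,sen_r_factor,pen_order,pen_delay Entropy parameters.
#' @param hidden1,hidden2 ELM-autoencoder layer sizes.
#' @param elm_reg Ridge parameter of both layers.
#' @param activation Layer activation.
#' @param kernel [kernel_config()] for KSRC.
#' @param reduce_method,reduce_dim Pseudotransformation method/dimension
#'   (`NULL` dim means `min(m - 1, 300)`).
#' @param lambda KSRC L1 weight.
#' @param seed Master seed: layer and projection seeds derive from it.
#' @return A `dlksrn_config`.
#' @export
dlksrn_config <- function(target_fs = 4000, bp_low = 25, bp_high = 900,
                          bp_order = 4L, sigma = 200, n_fft = 1600L,
                          hop = 80L, n_pieces = 10L, spline_order = 3L,
                          n_atoms = 400L, sen_m = 2L, sen_r_factor = 0.2,
                          pen_order = 3L, pen_delay = 1L, hidden1 = 800L,
                          hidden2 = 600L, elm_reg = 1e3,
                          activation = "sigmoid", kernel = kernel_config(),
                          reduce_method = "kpca", reduce_dim = NULL,
                          lambda = 1e-3, seed = 1L) {
  structure(as.list(environment()), class = "dlksrn_config")
}

#' Compute the feature vector of one recording
#'
#' Full per-recording chain: preprocess, ridge estimate, spline-kernel fit,
#' SCT, blockwise feature extraction.
#'
#' @param rec A [pcg_recording()] (any rate `>=` the working rate).
#' @param config A [dlksrn_config()].
#' @param preprocessed Set TRUE if `rec` is already filtered/normalized at
#'   the working rate.
#' @return Named feature vector of length `3 * n_atoms`.
#' @export
pcg_features <- function(rec, config = dlksrn_config(), preprocessed = FALSE) {
  stopifnot(inherits(rec, "pcg_recording"))
  if (!preprocessed) {
    rec <- preprocess_recording(rec, target_fs = config$target_fs,
                                low = config$bp_low, high = config$bp_high,
                                order = config$bp_order)
  }
  n_bins <- length(seq(0, length(rec$samples) - 1, by = config$hop))
  min_bins <- max(config$sen_m + 2L,
                  (config$pen_order - 1L) * config$pen_delay + 2L)
  if (n_bins < min_bins) {
    stop("recording too short: ", n_bins, " analysis frames, need >= ",
         min_bins)
  }
  ridge <- estimate_if_ridge(rec, n_fft = config$n_fft, sigma = config$sigma,
                             hop = config$hop)
  kern <- fit_spline_kernel(ridge, n_pieces = min(config$n_pieces, n_bins),
                            order = config$spline_order)
  tfr <- sct_transform(rec, kern, sigma = config$sigma, n_fft = config$n_fft,
                       hop = config$hop)
  extract_feature_vector(tfr, n_atoms = config$n_atoms, sen_m = config$sen_m,
                         sen_r_factor = config$sen_r_factor,
                         pen_order = config$pen_order,
                         pen_delay = config$pen_delay)
}

#' Feature matrix for a set of recordings
#'
#' @param recordings List of [pcg_recording()].
#' @param config A [dlksrn_config()].
#' @param progress Print a progress line every 25 recordings?
#' @return List `X` (instances x features) and `labels` (may contain `NA`).
#' @export
pcg_feature_matrix <- function(recordings, config = dlksrn_config(),
                               progress = FALSE) {
  feats <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    feats[[i]] <- pcg_features(recordings[[i]], config)
    if (progress && i %% 25L == 0L) {
      message("featurized ", i, "/", length(recordings))
    }
  }
  X <- do.call(rbind, feats)
  labels <- vapply(recordings, function(r) as.integer(r$label), integer(1))
  list(X = X, labels = labels)
}

# classifier head on precomputed features: scaler + 2 ELM-AE layers + KSRC
.fit_head <- function(X, labels, config) {
  scaler <- fit_feature_scaler(X)
  Xs <- apply_feature_scaler(scaler, X)
  layer1 <- fit_elm_ae_layer(Xs, config$hidden1, reg = config$elm_reg,
                             seed = config$seed + 1L,
                             activation = config$activation)
  Z1 <- elm_transform(layer1, Xs)
  layer2 <- fit_elm_ae_layer(Z1, config$hidden2, reg = config$elm_reg,
                             seed = config$seed + 2L,
                             activation = config$activation)
  Zstar <- elm_transform(layer2, Z1)
  ksrc <- ksrc_fit(Zstar, labels, kernel = config$kernel,
                   method = config$reduce_method, d = config$reduce_dim,
                   lambda = config$lambda, seed = config$seed + 3L)
  list(scaler = scaler, layer1 = layer1, layer2 = layer2, ksrc = ksrc)
}

.predict_head <- function(head, X) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
  Xs <- apply_feature_scaler(head$scaler, X)
  Zstar <- stack_transform(Xs, head$layer1, head$layer2)
  out <- vector("list", nrow(Zstar))
  for (i in seq_len(nrow(Zstar))) {
    out[[i]] <- ksrc_classify(head$ksrc, Zstar[i, ])
  }
  out
}

#' Train the full classifier on labelled recordings
#'
#' @param recordings List of labelled [pcg_recording()] (at least 2 classes,
#'   at least 2 instances per class).
#' @param config A [dlksrn_config()].
#' @param features Optional precomputed feature list (`X`, `labels`) from
#'   [pcg_feature_matrix()]; skips re-featurizing.
#' @return A `dlksrn_model`.
#' @export
dlksrn_train <- function(recordings, config = dlksrn_config(),
                         features = NULL) {
  if (is.null(features)) features <- pcg_feature_matrix(recordings, config)
  labels <- features$labels
  if (anyNA(labels)) stop("all training recordings must be labelled")
  tab <- table(labels)
  if (length(tab) < 2L) stop("training needs at least 2 classes")
  if (any(tab < 2L)) {
    stop("every class needs at least 2 instances; short: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  }
  head <- .fit_head(features$X, labels, config)
  structure(list(config = config, scaler = head$scaler,
                 layer1 = head$layer1, layer2 = head$layer2,
                 ksrc = head$ksrc,
                 class_names = class_codes()[sort(unique(labels))],
                 version = "dlksrn-model-1"),
            class = "dlksrn_model")
}

#' @export
print.dlksrn_model <- function(x, ...) {
  cat(sprintf(
    "<dlksrn_model> %s | %d-dim features -> %d -> %d -> KSRC (%d atoms, %d classes)\n",
    x$version, ncol(x$layer1$W), nrow(x$layer1$W), nrow(x$layer2$W),
    nrow(x$ksrc$dictionary), length(x$ksrc$classes)))
  invisible(x)
}

#' Predict the class of one recording
#'
#' @param model A trained `dlksrn_model`.
#' @param rec A [pcg_recording()].
#' @param preprocessed See [pcg_features()].
#' @return List `label` (code), `class` (abbreviation), `residuals`.
#' @export
dlksrn_predict <- function(model, rec, preprocessed = FALSE) {
  stopifnot(inherits(model, "dlksrn_model"))
  x <- pcg_features(rec, model$config, preprocessed = preprocessed)
  sc <- .predict_head(model, x)[[1L]]
  list(label = sc$predicted, class = unname(class_codes()[sc$predicted]),
       residuals = sc$residuals)
}

#' Save / load a trained model
#'
#' Single-file archive (RDS) holding every sub-state: scaler, both layer
#' weight sets, KSRC dictionary and kernel, config, and a version tag.
#'
#' @param model A `dlksrn_model`.
#' @param path File path.
#' @return `path` / the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dlksrn_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "dlksrn_model")) stop("not a dlksrn model archive")
  model
}

# ---- evaluation -------------------------------------------------------------

#' Confusion-matrix metrics
#'
#' One-vs-rest per class: `TP = conf[c, c]`, `FN` = rest of row `c`, `FP` =
#' rest of column `c`, `TN` = remainder. Rows are true classes, columns
#' predictions. Undefined ratios (0/0) are reported as 0 and flagged.
#'
#' @param confusion Square nonnegative count matrix.
#' @return List: `per_class` data frame (`precision`, `sensitivity`,
#'   `specificity`, `f_score`, in percent, plus TP/TN/FP/FN counts), `oa`
#'   (percent), `undefined` (logical flag), `confusion`.
#' @export
compute_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) {
    stop("confusion matrix must be square")
  }
  if (any(confusion < 0) || any(confusion != round(confusion))) {
    stop("confusion matrix must hold nonnegative integer counts")
  }
  total <- sum(confusion)
  C <- nrow(confusion)
  undefined <- FALSE
  ratio <- function(num, den) {
    if (den == 0) { undefined <<- TRUE; 0 } else num / den
  }
  rows <- lapply(seq_len(C), function(c) {
    tp <- confusion[c, c]
    fn <- sum(confusion[c, ]) - tp
    fp <- sum(confusion[, c]) - tp
    tn <- total - tp - fn - fp
    prec <- ratio(tp, tp + fp)
    sens <- ratio(tp, tp + fn)
    spec <- ratio(tn, tn + fp)
    f <- if (prec + sens == 0) { undefined <<- TRUE; 0 } else {
      2 * prec * sens / (prec + sens)
    }
    data.frame(TP = tp, TN = tn, FP = fp, FN = fn,
               precision = 100 * prec, sensitivity = 100 * sens,
               specificity = 100 * spec, f_score = 100 * f)
  })
  per_class <- do.call(rbind, rows)
  rownames(per_class) <- rownames(confusion) %||% as.character(seq_len(C))
  oa <- if (total == 0) { undefined <- TRUE; 0 } else {
    100 * sum(diag(confusion)) / total
  }
  list(per_class = per_class, oa = oa, undefined = undefined,
       confusion = confusion)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.confusion_from <- function(truth, predicted, classes) {
  tab <- table(factor(truth, levels = classes),
               factor(predicted, levels = classes))
  m <- matrix(as.integer(tab), nrow = length(classes),
              dimnames = list(true = as.character(classes),
                              predicted = as.character(classes)))
  m
}

# stratified index split; fractions sum to 1; per-class counts rounded so
# class ratios are preserved within one instance
.split_stratified <- function(labels, fractions, seed) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  .with_seed(seed, {
    parts <- vector("list", length(fractions))
    for (cls in sort(unique(labels))) {
      idx <- sample(which(labels == cls))
      n <- length(idx)
      counts <- floor(fractions * n)
      rem <- n - sum(counts)
      if (rem > 0) {
        extra <- order(fractions * n - counts, decreasing = TRUE)[seq_len(rem)]
        counts[extra] <- counts[extra] + 1L
      }
      at <- cumsum(c(0L, counts))
      for (p in seq_along(fractions)) {
        parts[[p]] <- c(parts[[p]], idx[seq.int(at[p] + 1L,
                                                length.out = counts[p])])
      }
    }
    parts
  })
}

.eval_report <- function(truth, predicted, classes, split, seed) {
  conf <- .confusion_from(truth, predicted, classes)
  met <- compute_metrics(conf)
  structure(list(confusion = conf, per_class = met$per_class, oa = met$oa,
                 undefined = met$undefined, split = split, seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s (seed %s): OA %.2f%%\n", x$split,
              as.character(x$seed), x$oa))
  print(round(x$per_class[, c("precision", "sensitivity", "specificity",
                              "f_score")], 2))
  invisible(x)
}

#' Mean and SD summary across evaluation reports
#'
#' @param reports List of `eval_report`.
#' @return List with `oa_mean`, `oa_sd`, and a `per_class` data frame of
#'   mean and SD for each metric.
#' @export
summarize_reports <- function(reports) {
  oas <- vapply(reports, function(r) r$oa, numeric(1))
  mets <- c("precision", "sensitivity", "specificity", "f_score")
  per <- lapply(mets, function(mname) {
    vals <- sapply(reports, function(r) r$per_class[[mname]])
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
    data.frame(metric = mname,
               class = rownames(reports[[1L]]$per_class),
               mean = rowMeans(vals),
               sd = apply(vals, 1L, stats::sd))
  })
  list(oa_mean = mean(oas), oa_sd = stats::sd(oas),
       per_class = do.call(rbind, per))
}

#' Hold-out evaluation with repeated stratified trials
#'
#' For each trial: stratified train/validation/test split, fit the head on
#' the training portion, predict the test portion. Features are computed
#' once for the whole dataset; the validation portion is held out of fitting
#' (reserved for hyperparameter tuning).
#'
#' @param recordings Labelled recordings.
#' @param fractions Train/validation/test fractions, summing to 1.
#' @param n_trials Number of random trials.
#' @param seed Base seed; trial `t` splits with `seed + t`.
#' @param config A [dlksrn_config()].
#' @param features Optional precomputed feature list.
#' @return List `reports` (per trial), `summary` (mean +/- SD).
#' @export
holdout_evaluate <- function(recordings, fractions = c(0.60, 0.10, 0.30),
                             n_trials = 5L, seed = 1L,
                             config = dlksrn_config(), features = NULL) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (is.null(features)) features <- pcg_feature_matrix(recordings, config)
  labels <- features$labels
  tab <- table(labels)
  if (any(tab < sum(fractions > 0))) {
    stop("class sizes too small to stratify at the given fractions")
  }
  classes <- sort(unique(labels))
  reports <- vector("list", n_trials)
  for (trial in seq_len(n_trials)) {
    sp <- .split_stratified(labels, fractions, seed = seed + trial)
    if (length(unique(labels[sp[[1L]]])) < length(classes)) {
      stop("training portion lost a class; class sizes too small to ",
           "stratify at the given fractions")
    }
    tr <- sp[[1L]]; te <- sp[[3L]]
    head <- .fit_head(features$X[tr, , drop = FALSE], labels[tr], config)
    preds <- .predict_head(head, features$X[te, , drop = FALSE])
    predicted <- vapply(preds, function(p) p$predicted, integer(1))
    reports[[trial]] <- .eval_report(
      labels[te], predicted, classes,
      split = sprintf("hold-out %s trial %d",
                      paste(fractions, collapse = "/"), trial),
      seed = seed + trial)
  }
  list(reports = reports, summary = summarize_reports(reports))
}

#' Stratified k-fold cross-validation
#'
#' @param recordings Labelled recordings.
#' @param k Number of folds (every class must have at least `k` instances).
#' @param seed Seed for the fold assignment.
#' @param config A [dlksrn_config()].
#' @param features Optional precomputed feature list.
#' @return List `reports` (per fold), `summary`, `fold_ids`.
#' @export
kfold_evaluate <- function(recordings, k = 10L, seed = 1L,
                           config = dlksrn_config(), features = NULL) {
  if (k < 2L) stop("k must be >= 2")
  if (is.null(features)) features <- pcg_feature_matrix(recordings, config)
  labels <- features$labels
  tab <- table(labels)
  if (any(tab < k)) {
    stop("every class needs at least k = ", k, " instances")
  }
  classes <- sort(unique(labels))
  fold_ids <- integer(length(labels))
  .with_seed(seed, {
    for (cls in classes) {
      idx <- sample(which(labels == cls))
      fold_ids[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    te <- which(fold_ids == f); tr <- which(fold_ids != f)
    head <- .fit_head(features$X[tr, , drop = FALSE], labels[tr], config)
    preds <- .predict_head(head, features$X[te, , drop = FALSE])
    predicted <- vapply(preds, function(p) p$predicted, integer(1))
    reports[[f]] <- .eval_report(labels[te], predicted, classes,
                                 split = sprintf("%d-fold CV fold %d", k, f),
                                 seed = seed)
  }
  list(reports = reports, summary = summarize_reports(reports),
       fold_ids = fold_ids)
}

#' Write an evaluation result as structured JSON
#'
#' @param result Output of [holdout_evaluate()] or [kfold_evaluate()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(result, path) {
  out <- list(
    summary = list(oa_mean = result$summary$oa_mean,
                   oa_sd = result$summary$oa_sd,
                   per_class = result$summary$per_class),
    trials = lapply(result$reports, function(r) {
      list(split = r$split, seed = r$seed, oa = r$oa,
           confusion = unname(apply(r$confusion, 1L, as.integer,
                                    simplify = FALSE)),
           per_class = r$per_class)
    }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
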