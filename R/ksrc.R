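# Kernel sparse representation classification (KSRC).
#
# A test feature vector is mapped implicitly to kernel space and expressed as
# a sparse combination of the kernel-mapped training atoms. A
# pseudotransformation matrix S (m x d) reduces the kernel-space dimension,
# so the working linear system is
#
#   S' k_t  ~=  (S' K) gamma
#
# with K the training kernel matrix and k_t the test kernel vector. gamma is
# recovered by L1-regularized least squares; each class's residual keeps only
# that class's coefficients,
#
#   rs_c = || S' k_t - S' K delta_c(gamma) ||_2 ,
#
# and the predicted label is the argmin over classes.

#' Kernel configuration
#'
#' @param type `rbf` (`exp(-||x-y||^2 / (2 sigma^2))`), `linear`, or
#'   `polynomial` (`(x.y + coef0)^degree`).
#' @param sigma RBF bandwidth; `NULL` selects the median heuristic (median
#'   pairwise training distance) at fit time.
#' @param degree,coef0 Polynomial kernel parameters.
#' @return A `kernel_config`.
#' @export
kernel_config <- function(type = c("rbf", "linear", "polynomial"),
                          sigma = NULL, degree = 2, coef0 = 1) {
  type <- match.arg(type)
  if (!is.null(sigma) && (!is.numeric(sigma) || sigma <= 0)) {
    stop("sigma must be positive")
  }
  structure(list(type = type, sigma = sigma, degree = degree, coef0 = coef0),
            class = "kernel_config")
}

.pairwise_sq_dists <- function(X, Y = X) {
  sx <- rowSums(X^2); sy <- rowSums(Y^2)
  d2 <- outer(sx, sy, `+`) - 2 * tcrossprod(X, Y)
  pmax(d2, 0)
}

.median_bandwidth <- function(X) {
  d2 <- .pairwise_sq_dists(X)
  d <- sqrt(d2[upper.tri(d2)])
  d <- d[d > 0]
  if (length(d) == 0L) 1 else stats::median(d)
}

#' Build a kernel matrix
#'
#' @param X Instance matrix (rows) -- or, with `Y`, the cross-kernel
#'   `k(x_i, y_j)`.
#' @param kernel A [kernel_config()]; an RBF `sigma = NULL` is resolved by
#'   the median heuristic on `X`.
#' @param Y Optional second instance matrix.
#' @return Kernel matrix `nrow(X) x nrow(Y %||% X)`; the resolved
#'   [kernel_config()] is attached as attribute `kernel`.
#' @export
build_kernel_matrix <- function(X, kernel = kernel_config(), Y = NULL) {
  stopifnot(inherits(kernel, "kernel_config"))
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop("X is empty")
  Yv <- if (is.null(Y)) X else as.matrix(Y)
  K <- switch(kernel$type,
    rbf = {
      if (is.null(kernel$sigma)) kernel$sigma <- .median_bandwidth(X)
      exp(-.pairwise_sq_dists(X, Yv) / (2 * kernel$sigma^2))
    },
    linear = tcrossprod(X, Yv),
    polynomial = (tcrossprod(X, Yv) + kernel$coef0)^kernel$degree)
  attr(K, "kernel") <- kernel
  K
}

#' Fit the pseudotransformation matrix S
#'
#' Kernel-space dimension reduction for the sparse-coding constraint:
#' \describe{
#'   \item{kpca}{top-`d` eigenvectors of the doubly centered kernel matrix,
#'     scaled by inverse square-root eigenvalues; near-zero eigenvalues are
#'     dropped with a warning (returned `d` may shrink).}
#'   \item{random}{seeded Gaussian `m x d` matrix.}
#'   \item{klda}{kernel Fisher discriminant directions (requires `labels`);
#'     at most `C - 1` informative directions.}
#' }
#'
#' @param K `m x m` training kernel matrix.
#' @param method `kpca`, `random`, or `klda`.
#' @param d Target reduced dimension (`<= m`).
#' @param seed Seed for `random`.
#' @param labels Class codes for `klda`.
#' @return `m x d'` matrix `S` (`d' <= d`).
#' @export
fit_pseudotransformation <- function(K, method = c("kpca", "random", "klda"),
                                     d, seed = 1L, labels = NULL) {
  method <- match.arg(method)
  K <- as.matrix(K)
  m <- nrow(K)
  if (d > m) stop("d = ", d, " exceeds number of training instances m = ", m)
  if (d < 1L) stop("d must be >= 1")
  switch(method,
    kpca = {
      J <- diag(m) - matrix(1 / m, m, m)
      Kc <- J %*% K %*% J
      Kc <- (Kc + t(Kc)) / 2
      eg <- eigen(Kc, symmetric = TRUE)
      tol <- max(eg$values) * 1e-10
      keep <- which(eg$values > tol)[seq_len(min(d, sum(eg$values > tol)))]
      if (length(keep) < d) {
        warning("kpca: only ", length(keep),
                " informative components (near-zero eigenvalues dropped)")
      }
      eg$vectors[, keep, drop = FALSE] %*%
        diag(1 / sqrt(eg$values[keep]), length(keep))
    },
    random = .with_seed(seed, matrix(stats::rnorm(m * d), m, d) / sqrt(d)),
    klda = {
      if (is.null(labels)) stop("klda requires training labels")
      labels <- as.integer(labels)
      cls <- sort(unique(labels))
      mu <- rowMeans(K)
      Sb <- matrix(0, m, m); Sw <- matrix(0, m, m)
      for (c in cls) {
        idx <- which(labels == c)
        nc <- length(idx)
        mc <- rowMeans(K[, idx, drop = FALSE])
        Sb <- Sb + nc * tcrossprod(mc - mu)
        Kc <- K[, idx, drop = FALSE]
        Sw <- Sw + Kc %*% (diag(nc) - matrix(1 / nc, nc, nc)) %*% t(Kc)
      }
      Sw <- Sw + diag(1e-6 * mean(diag(Sw)) + 1e-12, m)
      eg <- eigen(solve(Sw, Sb))
      d_eff <- min(d, length(cls) - 1L)
      if (d_eff < d) {
        warning("klda: at most C - 1 = ", length(cls) - 1L,
                " informative directions; d reduced to ", d_eff)
      }
      Re(eg$vectors[, seq_len(d_eff), drop = FALSE])
    })
}

#' Fit a kernel sparse representation classifier
#'
#' Stores the training atoms as the dictionary, builds the kernel matrix,
#' fits the pseudotransformation, and precomputes the reduced system
#' `A = S'K` together with its Lipschitz constant for the solver.
#'
#' @param Z Training feature matrix (atoms in rows).
#' @param labels Integer class codes, one per atom.
#' @param kernel A [kernel_config()].
#' @param method Dimension-reduction method, see [fit_pseudotransformation()].
#' @param d Reduced dimension; default `min(m - 1, 300)`.
#' @param lambda L1 weight of the sparse-coding relaxation.
#' @param seed Seed (random projection only).
#' @return A `ksrc_model`.
#' @export
ksrc_fit <- function(Z, labels, kernel = kernel_config(),
                     method = c("kpca", "random", "klda"), d = NULL,
                     lambda = 1e-3, seed = 1L) {
  method <- match.arg(method)
  Z <- as.matrix(Z)
  labels <- as.integer(labels)
  m <- nrow(Z)
  stopifnot(length(labels) == m, m >= 2L)
  if (is.null(d)) d <- min(m - 1L, 300L)
  K <- build_kernel_matrix(Z, kernel)
  kernel <- attr(K, "kernel")             # sigma resolved
  S <- fit_pseudotransformation(K, method, d = d, seed = seed,
                                labels = labels)
  A <- crossprod(S, K)                    # d' x m
  lip <- (svd(A, nu = 0, nv = 0)$d[1])^2
  structure(list(dictionary = Z, labels = labels,
                 classes = sort(unique(labels)), kernel = kernel, K = K,
                 S = S, A = A, lipschitz = lip, lambda = lambda,
                 method = method, seed = as.integer(seed)),
            class = "ksrc_model")
}

#' @export
print.ksrc_model <- function(x, ...) {
  cat(sprintf(
    "<ksrc_model> %d atoms, %d classes, kernel %s, reduced dim %d, lambda %g\n",
    nrow(x$dictionary), length(x$classes), x$kernel$type, ncol(x$S),
    x$lambda))
  invisible(x)
}

.soft_threshold <- function(v, t) sign(v) * pmax(abs(v) - t, 0)

#' Recover the sparse coefficient vector for a test instance
#'
#' Solves `min_gamma 0.5 ||S'k_t - S'K gamma||^2 + lambda ||gamma||_1` by
#' monotone FISTA: accelerated iterative shrinkage with fixed step `1/L` and
#' a safeguard that only ever accepts objective-decreasing iterates, so the
#' objective is monotonically non-increasing.
#'
#' @param model A fitted `ksrc_model`.
#' @param z_t Test feature vector in the dictionary's space.
#' @param lambda L1 weight; defaults to the model's.
#' @param tol Convergence tolerance on the iterate change.
#' @param max_iter Iteration cap; a warning is raised if hit.
#' @param keep_trace Record the per-iteration objective?
#' @return List: `gamma` (m coefficients), `b` (the reduced target `S'k_t`),
#'   `iterations`, `converged`, `objective`, and optionally `trace`.
#' @export
solve_sparse_code <- function(model, z_t, lambda = model$lambda, tol = 1e-8,
                              max_iter = 10000L, keep_trace = FALSE) {
  stopifnot(inherits(model, "ksrc_model"))
  z_t <- as.numeric(z_t)
  if (!all(is.finite(z_t))) stop("z_t must be finite")
  kt <- drop(build_kernel_matrix(model$dictionary, model$kernel,
                                 Y = matrix(z_t, nrow = 1L)))
  b <- drop(crossprod(model$S, kt))
  A <- model$A
  L <- max(model$lipschitz, .Machine$double.eps)
  gamma <- numeric(ncol(A))
  obj <- function(g) {
    r <- b - drop(A %*% g)
    0.5 * sum(r^2) + lambda * sum(abs(g))
  }
  trace <- if (keep_trace) numeric(max_iter) else NULL
  converged <- FALSE
  it <- 0L
  Atb <- drop(crossprod(A, b))
  AtA <- crossprod(A)
  z <- gamma
  gamma_prev <- gamma
  f_gamma <- obj(gamma)
  t_k <- 1
  while (it < max_iter) {
    it <- it + 1L
    grad <- drop(AtA %*% z) - Atb
    u <- .soft_threshold(z - grad / L, lambda / L)
    f_u <- obj(u)
    gamma_prev <- gamma
    if (f_u <= f_gamma) { gamma <- u; f_gamma <- f_u }
    t_next <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    z <- gamma + (t_k / t_next) * (u - gamma) +
      ((t_k - 1) / t_next) * (gamma - gamma_prev)
    t_k <- t_next
    if (keep_trace) trace[it] <- f_gamma
    if (max(abs(u - gamma_prev)) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("sparse solver hit the iteration cap (", max_iter,
            "); returning best iterate")
  }
  out <- list(gamma = gamma, b = b, kt = kt, iterations = it,
              converged = converged, objective = obj(gamma))
  if (keep_trace) out$trace <- trace[seq_len(it)]
  out
}

#' Class-masked coefficient vector
#'
#' Keeps the coefficients of atoms belonging to class `c`, zeroing the rest.
#' Summed over all classes these masks reconstruct `gamma`.
#'
#' @param gamma Coefficient vector.
#' @param labels Atom labels.
#' @param c Class code.
#' @return Masked coefficient vector.
#' @export
class_mask <- function(gamma, labels, c) {
  ifelse(labels == c, gamma, 0)
}

#' Classify a test instance by minimal class residual
#'
#' Runs the sparse solver, computes each class's reconstruction residual
#' from its masked coefficients, and predicts the argmin class (ties broken
#' to the smallest class code, with a message).
#'
#' @inheritParams solve_sparse_code
#' @return A `sparse_code`: `gamma`, named `residuals`, `predicted`.
#' @export
ksrc_classify <- function(model, z_t, lambda = model$lambda, tol = 1e-8,
                          max_iter = 10000L) {
  sol <- solve_sparse_code(model, z_t, lambda = lambda, tol = tol,
                           max_iter = max_iter)
  res <- vapply(model$classes, function(c) {
    delta_c <- class_mask(sol$gamma, model$labels, c)
    sqrt(sum((sol$b - drop(model$A %*% delta_c))^2))
  }, numeric(1))
  names(res) <- as.character(model$classes)
  winners <- which(res == min(res))
  if (length(winners) > 1L) {
    message("residual tie between classes ",
            paste(model$classes[winners], collapse = ", "),
            "; choosing the smallest code")
  }
  structure(list(gamma = sol$gamma, residuals = res,
                 predicted = model$classes[winners[1L]],
                 iterations = sol$iterations, converged = sol$converged,
                 objective = sol$objective),
            class = "sparse_code")
}

#' @export
print.sparse_code <- function(x, ...) {
  cat("<sparse_code> predicted class", x$predicted, "\n residuals:",
      paste(sprintf("%s=%.4g", names(x$residuals), x$residuals),
            collapse = " "), "\n")
  invisible(x)
}
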