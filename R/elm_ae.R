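# Extreme-learning-machine autoencoders.
#
# Each layer draws fixed random input weights, maps the input through a
# nonlinearity, H = f(Z R + b), and solves the output weights in closed form
# by ridge regression:
#
#   W = (H' H + I / gamma)^-1 H' Z
#
# W maps hidden -> input, so the layer's feature map uses its transpose,
# f(Z W'). Two stacked layers give the deep feature map
# Z* = f( f(Z W1') W2' ).

.activations <- list(
  sigmoid = function(x) 1 / (1 + exp(-x)),
  tanh = base::tanh,
  relu = function(x) pmax(x, 0),
  identity = identity
)

.get_activation <- function(name) {
  f <- .activations[[name]]
  if (is.null(f)) {
    stop("unknown activation `", name, "`; use one of: ",
         paste(names(.activations), collapse = ", "))
  }
  f
}

#' Construct an ELM-autoencoder layer from explicit weights
#'
#' Low-level constructor; normally layers come from [fit_elm_ae_layer()].
#'
#' @param W Hidden-dim x input-dim output weight matrix.
#' @param activation Activation name (`sigmoid`, `tanh`, `relu`, `identity`).
#' @param random_weights,bias Optional encoder randomization (kept for
#'   reproducibility/serialization).
#' @param reg Ridge parameter used at fit time.
#' @param seed RNG seed used at fit time.
#' @return An `elm_ae_layer`.
#' @export
elm_ae_layer <- function(W, activation = "sigmoid", random_weights = NULL,
                         bias = NULL, reg = NA_real_, seed = NA_integer_) {
  .get_activation(activation)
  structure(list(W = as.matrix(W), activation = activation,
                 random_weights = random_weights, bias = bias,
                 reg = reg, seed = seed),
            class = "elm_ae_layer")
}

#' Fit one ELM-autoencoder layer
#'
#' Draws seeded standard-normal input weights (orthonormalized by QR, a
#' standard stabilization) and a random bias, forms `H = f(Z R + b)`, and
#' solves the ridge system `W = (H'H + I/reg)^-1 H' Z`.
#'
#' @param Z Input matrix, instances in rows.
#' @param hidden_size Number of hidden neurons.
#' @param reg Ridge parameter `gamma_elm` (> 0); larger means weaker
#'   regularization.
#' @param seed Integer seed; fits are deterministic given it.
#' @param activation Activation name.
#' @param orthonormal Orthonormalize the random input weights?
#' @param use_bias Include the random hidden bias?
#' @return An `elm_ae_layer` whose `W` satisfies the ridge normal equations.
#' @export
fit_elm_ae_layer <- function(Z, hidden_size, reg = 1e3, seed = 1L,
                             activation = "sigmoid", orthonormal = TRUE,
                             use_bias = TRUE) {
  Z <- as.matrix(Z)
  if (nrow(Z) < 1L || !all(is.finite(Z))) stop("Z must be nonempty and finite")
  if (hidden_size < 1L) stop("hidden_size must be >= 1")
  if (reg <= 0) stop("reg must be positive")
  d <- ncol(Z)
  rand <- .with_seed(seed, {
    R <- matrix(stats::rnorm(d * hidden_size), d, hidden_size)
    b <- if (use_bias) stats::rnorm(hidden_size) else numeric(hidden_size)
    list(R = R, b = b)
  })
  R <- rand$R
  if (orthonormal) {
    if (hidden_size <= d) {
      R <- qr.Q(qr(R))
    } else {
      R <- t(qr.Q(qr(t(R))))        # orthonormal rows when hidden > input
    }
  }
  f <- .get_activation(activation)
  H <- f(sweep(Z %*% R, 2L, rand$b, `+`))
  W <- solve(crossprod(H) + diag(1 / reg, hidden_size), crossprod(H, Z))
  elm_ae_layer(W, activation = activation, random_weights = R, bias = rand$b,
               reg = reg, seed = seed)
}

#' Feature map of one fitted layer
#'
#' `f(Z W')`: the solved weights, transposed into an input -> hidden map.
#'
#' @param layer An `elm_ae_layer`.
#' @param Z Input matrix (instances x input-dim) or a single vector.
#' @return Matrix instances x hidden-dim.
#' @export
elm_transform <- function(layer, Z) {
  stopifnot(inherits(layer, "elm_ae_layer"))
  vec <- is.null(dim(Z))
  Z <- if (vec) matrix(Z, nrow = 1L) else as.matrix(Z)
  if (ncol(Z) != ncol(layer$W)) {
    stop("dimension mismatch: input has ", ncol(Z), " columns, layer expects ",
         ncol(layer$W))
  }
  f <- .get_activation(layer$activation)
  out <- f(tcrossprod(Z, layer$W))
  if (vec) drop(out) else out
}

#' Deep feature map through two stacked layers
#'
#' `Z* = f( f(Z W1') W2' )`; a row-wise map, so transforming an instance
#' alone or inside a batch gives the same row.
#'
#' @param Z Feature matrix, instances in rows.
#' @param layer1,layer2 Fitted `elm_ae_layer`s with a consistent dimension
#'   chain.
#' @return Matrix instances x (layer-2 hidden size).
#' @export
stack_transform <- function(Z, layer1, layer2) {
  elm_transform(layer2, elm_transform(layer1, Z))
}

#' Ridge reconstruction objective of a layer
#'
#' `||H W - Z||_F^2 + ||W||_F^2 / reg` for a candidate `W`; the fitted `W`
#' is its unique minimizer.
#'
#' @param layer Fitted `elm_ae_layer` (provides the encoder and `reg`).
#' @param Z The input matrix the layer was fitted on.
#' @param W Candidate weight matrix (defaults to the fitted one).
#' @return Scalar objective value.
#' @export
elm_objective <- function(layer, Z, W = layer$W) {
  f <- .get_activation(layer$activation)
  H <- f(sweep(as.matrix(Z) %*% layer$random_weights, 2L, layer$bias, `+`))
  sum((H %*% W - Z)^2) + sum(W^2) / layer$reg
}
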